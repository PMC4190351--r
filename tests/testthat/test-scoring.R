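test_that("yes-counting treats 'no' and 'unclear' alike", {
  expect_equal(count_yes(appraisal("yes", "yes", "yes", "yes", "yes")), 5L)
  expect_equal(count_yes(appraisal("yes", "yes", "yes", "no", "no")), 3L)
  expect_equal(count_yes(appraisal("yes", "unclear", "no", "no", "no")), 1L)
  expect_equal(count_yes(appraisal("yes", "yes", "yes", "unclear", "unclear")),
               count_yes(appraisal("yes", "yes", "yes", "no", "no")))
  expect_error(appraisal("yes", "maybe", "no", "no", "no"),
               class = "conqual_schema_error")
})

test_that("dependability banding follows the 4-5 / 2-3 / 0-1 rule and is monotone", {
  expect_equal(dependability_downgrade(c(5, 4, 3, 2, 1, 0)),
               c(0L, 0L, 1L, 1L, 2L, 2L))
  # monotone non-increasing in yes_count
  bands <- dependability_downgrade(0:5)
  expect_true(all(diff(bands) <= 0))
  expect_error(dependability_downgrade(6), class = "conqual_invalid_appraisal_error")
  expect_error(dependability_downgrade(-1), class = "conqual_invalid_appraisal_error")
})

test_that("a finding inherits its parent study's appraisal band", {
  st5 <- study("s1", "A", make_appraisal_yes(5))
  st2 <- study("s2", "B", make_appraisal_yes(2))
  st1 <- study("s3", "C", make_appraisal_yes(1))
  f <- function(sid) finding("f1", sid, "x", "y", "Unequivocal")
  expect_equal(finding_dependability(f("s1"), st5), 0L)
  expect_equal(finding_dependability(f("s2"), st2), 1L)
  expect_equal(finding_dependability(f("s3"), st1), 2L)
  expect_error(finding_dependability(f("s1"), st2),
               class = "conqual_reference_error")
})

test_that("dependability aggregation takes the strict majority, ties break upward", {
  expect_equal(aggregate_dependability(c(1, 1, 0)), 1L)
  expect_equal(aggregate_dependability(c(0, 0, 0)), 0L)
  expect_equal(aggregate_dependability(c(0, 0, 1, 1)), 1L)
  expect_equal(aggregate_dependability(c(0, 1, 2)), 2L)   # three-way tie
  expect_equal(aggregate_dependability(c(2, 0, 0, 0, 2)), 0L)
  expect_error(aggregate_dependability(integer()),
               class = "conqual_empty_synthesis_error")
  expect_error(aggregate_dependability(c(0, 3)),
               class = "conqual_invalid_appraisal_error")
})

test_that("credibility mixes classify by presence of levels", {
  expect_equal(credibility_mix(c("Unequivocal", "Unequivocal")), "all_unequivocal")
  expect_equal(credibility_mix(c("Unequivocal", "Equivocal")),
               "unequivocal_equivocal_mix")
  expect_equal(credibility_mix("Equivocal"), "all_equivocal")
  expect_equal(credibility_mix(c("Equivocal", "Unsupported")),
               "equivocal_unsupported_mix")
  expect_equal(credibility_mix(c("Unsupported", "Unsupported")), "all_unsupported")
  expect_equal(credibility_mix(c("Unequivocal", "Unsupported")),
               "other_unsupported_mix")
  expect_equal(credibility_mix(c("Unequivocal", "Equivocal", "Unsupported")),
               "other_unsupported_mix")
  # presence-based: one equivocal among many unequivocal still triggers the mix
  expect_equal(credibility_mix(c(rep("Unequivocal", 10), "Equivocal")),
               "unequivocal_equivocal_mix")
  expect_error(credibility_mix(character()), class = "conqual_empty_synthesis_error")
  expect_error(credibility_mix("Strong"), class = "conqual_schema_error")
})

test_that("credibility downgrades map 0/1/2/3/4 across the mix categories", {
  expect_equal(credibility_downgrade("all_unequivocal"), 0L)
  expect_equal(credibility_downgrade("unequivocal_equivocal_mix"), 1L)
  expect_equal(credibility_downgrade("all_equivocal"), 2L)
  expect_equal(credibility_downgrade("equivocal_unsupported_mix"), 3L)
  expect_equal(credibility_downgrade("all_unsupported"), 4L)
  expect_equal(credibility_downgrade("other_unsupported_mix"), 3L)
  expect_error(credibility_downgrade("some_mix"), class = "conqual_schema_error")
})

test_that("confidence labels and ranks are mutual inverses with a floor at Very Low", {
  expect_equal(confidence_label(4:1), c("High", "Moderate", "Low", "Very Low"))
  expect_equal(confidence_label(1, machine = TRUE), "VeryLow")
  expect_equal(confidence_rank(c("High", "Moderate", "Low", "Very Low")), 4:1)
  expect_equal(confidence_rank("VeryLow"), 1L)
  expect_equal(confidence_rank(confidence_label(1:4)), 1:4)
  expect_error(confidence_label(0), class = "conqual_schema_error")
  expect_error(confidence_rank("Medium"), class = "conqual_schema_error")
})

test_that("scoring sums both downgrades once from High and clamps at Very Low", {
  # dep 1 + cred 1 -> Low (the two-single-downgrade worked case)
  st <- study("s1", "A", make_appraisal_yes(3))
  f1 <- finding("f1", "s1", "x", "v", "Unequivocal")
  f2 <- finding("f2", "s1", "y", "v", "Equivocal")
  sf <- synthesised_finding("sf1", "z", c("f1", "f2"))
  res <- conqual_score(sf, list(f1, f2), list(st))
  expect_equal(res$score_label, "Low")
  expect_equal(res$dependability$magnitude, 1L)
  expect_equal(res$credibility$magnitude, 1L)
  expect_length(res$footnotes, 2L)

  # no downgrades -> High, no footnotes
  res_high <- score_review(minimal_review("Unequivocal", 5L))[[1]]
  expect_equal(res_high$score_label, "High")
  expect_length(res_high$footnotes, 0L)

  # dep 2 + cred 4 would be rank -2; clamps to Very Low
  res_floor <- score_review(minimal_review("Unsupported", 0L))[[1]]
  expect_equal(res_floor$score_label, "Very Low")
  expect_equal(res_floor$score, 1L)
})

test_that("scoring validates its references", {
  st <- study("s1", "A", make_appraisal_yes(5))
  f1 <- finding("f1", "s1", "x", "v", "Unequivocal")
  sf_bad <- synthesised_finding("sf1", "z", c("f1", "f9"))
  expect_error(conqual_score(sf_bad, list(f1), list(st)),
               class = "conqual_reference_error")
  f_orphan <- finding("f2", "s9", "x", "v", "Unequivocal")
  sf2 <- synthesised_finding("sf2", "z", "f2")
  expect_error(conqual_score(sf2, list(f_orphan), list(st)),
               class = "conqual_reference_error")
})

test_that("footnote rationales name the most-often-unmet questions and the mix", {
  doc <- load_review(fixture_path())
  res <- score_review(doc)[[1]]
  expect_match(res$dependability$rationale, "locating the researcher")
  expect_match(res$dependability$rationale, "influence of the researcher")
  expect_match(res$credibility$rationale, "mix of unequivocal and equivocal")
})

test_that("scoring is deterministic: identical documents give identical exports", {
  doc <- generate_review(generator_config(seed = 42))
  a <- export_results(score_review(doc), "json")
  b <- export_results(score_review(doc), "json")
  expect_identical(a, b)
})
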