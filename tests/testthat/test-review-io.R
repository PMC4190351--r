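minimal_json <- function() dump_review(minimal_review(), "json")

test_that("a minimal document loads with one of each element", {
  doc <- load_review(text = minimal_json(), dialect = "json")
  expect_s3_class(doc, "conqual_review")
  expect_length(doc$studies, 1L)
  expect_length(doc$findings, 1L)
  expect_length(doc$synthesised_findings, 1L)
})

test_that("dangling references are reported with the offending path and id", {
  raw <- jsonlite::fromJSON(minimal_json(), simplifyVector = FALSE)
  raw$findings[[1]]$study_id <- "s9"
  bad <- jsonlite::toJSON(raw, auto_unbox = TRUE)
  err <- expect_error(load_review(text = bad, dialect = "json"),
                      class = "conqual_reference_error")
  expect_match(conditionMessage(err), "s9")
  expect_match(conditionMessage(err), "findings\\[1\\]")
})

test_that("schema violations carry element paths", {
  raw <- jsonlite::fromJSON(minimal_json(), simplifyVector = FALSE)
  raw$studies[[1]]$appraisal$q3 <- "maybe"
  err <- expect_error(
    load_review(text = jsonlite::toJSON(raw, auto_unbox = TRUE)),
    class = "conqual_schema_error")
  expect_match(conditionMessage(err), "studies\\[1\\]")

  raw2 <- jsonlite::fromJSON(minimal_json(), simplifyVector = FALSE)
  raw2$findings[[1]]$credibility <- NULL
  err2 <- expect_error(
    load_review(text = jsonlite::toJSON(raw2, auto_unbox = TRUE)),
    class = "conqual_schema_error")
  expect_match(conditionMessage(err2), "findings\\[1\\].credibility")

  expect_error(load_review(text = "{not json", dialect = "json"),
               class = "conqual_parse_error")
})

test_that("header metadata is required unless explicitly allowed", {
  raw <- jsonlite::fromJSON(minimal_json(), simplifyVector = FALSE)
  raw$population <- ""
  txt <- jsonlite::toJSON(raw, auto_unbox = TRUE)
  expect_error(load_review(text = txt), class = "conqual_schema_error")
  doc <- load_review(text = txt, allow_empty_header = TRUE)
  expect_identical(doc$population, "")
})

test_that("credibility levels are case-insensitive on input, canonical on output", {
  raw <- jsonlite::fromJSON(minimal_json(), simplifyVector = FALSE)
  raw$findings[[1]]$credibility <- "UNEQUIVOCAL"
  doc <- load_review(text = jsonlite::toJSON(raw, auto_unbox = TRUE))
  expect_identical(doc$findings[[1]]$credibility, "Unequivocal")
  expect_match(dump_review(doc, "json"), '"Unequivocal"')
})

test_that("load/dump round-trips both dialects and dumps are byte-stable", {
  doc <- generate_review(generator_config(n_studies = 3, n_findings = 7,
                                          n_synth = 2, seed = 11))
  for (dialect in c("json", "yaml")) {
    text <- dump_review(doc, dialect)
    expect_identical(dump_review(doc, dialect), text)  # determinism
    expect_identical(load_review(text = text, dialect = dialect), doc)
  }
})

test_that("YAML bare yes/no scalars survive as appraisal strings", {
  doc <- minimal_review("Unequivocal", 3L)
  ytext <- dump_review(doc, "yaml")
  back <- load_review(text = ytext, dialect = "yaml")
  expect_identical(unclass(back$studies[[1]]$appraisal),
                   unclass(doc$studies[[1]]$appraisal))
  # even unquoted yes/no (as a hand-written file might have) parse as strings
  hand <- sub("'yes'", "yes", sub("'no'", "no", ytext))
  back2 <- load_review(text = hand, dialect = "yaml")
  expect_identical(back2, doc)
})

test_that("result exports agree across JSON and CSV", {
  doc <- generate_review(generator_config(seed = 3))
  res <- score_review(doc)
  js <- jsonlite::fromJSON(export_results(res, "json"))
  csv <- utils::read.csv(text = export_results(res, "csv"),
                         stringsAsFactors = FALSE)
  expect_equal(nrow(csv), length(res))
  expect_equal(csv$id, js$id)
  expect_equal(csv$dependability_downgrade, js$dependability_downgrade)
  expect_equal(csv$credibility_downgrade, js$credibility_downgrade)
  expect_equal(csv$score, js$score)
  expect_error(export_results(list(), "json"),
               class = "conqual_empty_synthesis_error")
})

test_that("the packaged worked-example document scores Low", {
  doc <- load_review(fixture_path())
  res <- score_review(doc)
  expect_length(res, 1L)
  expect_equal(res[[1]]$score_label, "Low")
})
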