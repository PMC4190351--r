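# Independent brute-force oracle for the scoring rules, coded separately
# from the package implementation: a frozen band vector, set-membership
# credibility classification, and an explicit (dep x cred) -> label lookup
# table, combined per review.

# yes-count 0..5 -> dependability band
ORACLE_DEP_BAND <- c(2L, 2L, 1L, 1L, 0L, 0L)

oracle_dep_band <- function(yes_count) ORACLE_DEP_BAND[yes_count + 1L]

oracle_aggregate <- function(bands) {
  tb <- table(bands)
  big <- tb[tb > length(bands) / 2]
  if (length(big)) return(as.integer(names(big)))
  modal <- names(tb)[tb == max(tb)]
  max(as.integer(modal))
}

oracle_cred <- function(levels) {
  s <- sort(unique(levels))
  if (identical(s, "Unequivocal")) 0L
  else if (identical(s, c("Equivocal", "Unequivocal"))) 1L
  else if (identical(s, "Equivocal")) 2L
  else if (identical(s, c("Equivocal", "Unsupported"))) 3L
  else if (identical(s, "Unsupported")) 4L
  else 3L  # any mixture containing Unequivocal and Unsupported
}

# rows: dependability 0..2; cols: credibility 0..4
ORACLE_SCORE_TABLE <- matrix(c(
  "High",     "Moderate", "Low",      "Very Low", "Very Low",
  "Moderate", "Low",      "Very Low", "Very Low", "Very Low",
  "Low",      "Very Low", "Very Low", "Very Low", "Very Low"),
  nrow = 3, byrow = TRUE)

oracle_score_label <- function(dep, cred) ORACLE_SCORE_TABLE[dep + 1L, cred + 1L]

# full review -> expected label for each synthesised finding, walking the
# plain list structure directly
oracle_review_labels <- function(doc) {
  yes_by_study <- vapply(doc$studies, function(s)
    sum(unclass(s$appraisal) == "yes"), integer(1))
  names(yes_by_study) <- vapply(doc$studies, `[[`, character(1), "id")
  finding_index <- vapply(doc$findings, `[[`, character(1), "id")
  vapply(doc$synthesised_findings, function(sf) {
    fl <- doc$findings[match(sf$finding_ids, finding_index)]
    bands <- vapply(fl, function(f)
      oracle_dep_band(yes_by_study[[f$study_id]]), integer(1))
    levels <- vapply(fl, `[[`, character(1), "credibility")
    oracle_score_label(oracle_aggregate(bands), oracle_cred(levels))
  }, character(1))
}

# shared shorthand for building tiny documents in tests
make_appraisal_yes <- function(n_yes)
  do.call(appraisal, as.list(ifelse(1:5 <= n_yes, "yes", "no")))

minimal_review <- function(credibility = "Unequivocal", n_yes = 5L) {
  review(title = "Minimal review", population = "Adults",
         phenomena_of_interest = "Experience", context = "Clinic",
         studies = list(study("s1", "Doe 2020", make_appraisal_yes(n_yes))),
         findings = list(finding("f1", "s1", "A finding.",
                                 if (credibility == "Unsupported") "" else "A voice.",
                                 credibility)),
         synthesised_findings = list(
           synthesised_finding("sf1", "A synthesised finding.", "f1")))
}

fixture_path <- function() {
  p <- system.file("extdata", "imaging_review.json", package = "conqual")
  if (nzchar(p)) p else testthat::test_path("../../inst/extdata/imaging_review.json")
}
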