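# The ConQual rule engine: dependability banding, credibility mix
# classification, and the downgrade-from-High score.

#' Count "yes" responses in a dependability appraisal
#'
#' `"no"` and `"unclear"` both count as not-yes: an unclear response gives no
#' evidence that the dependability criterion was met, so it is treated
#' conservatively.
#'
#' @param x A [appraisal()] (or coercible 5-vector of responses).
#' @return Integer in 0..5.
#' @examples
#' count_yes(appraisal("yes", "yes", "yes", "no", "unclear"))
#' @export
count_yes <- function(x) {
  x <- as_appraisal(x)
  sum(unclass(x) == "yes")
}

#' Dependability downgrade from a yes-count
#'
#' Bands the number of "yes" responses to the five dependability questions
#' into a downgrade magnitude: 4--5 yes, no change; 2--3 yes, down one level;
#' 0--1 yes, down two levels.
#'
#' @param yes_count Integer(s) in 0..5 (vectorised).
#' @return Integer downgrade magnitude(s) in \{0, 1, 2\}.
#' @examples
#' dependability_downgrade(5:0)
#' @export
dependability_downgrade <- function(yes_count) {
  if (length(yes_count) == 0L || anyNA(yes_count) ||
      any(yes_count != as.integer(yes_count)) ||
      any(yes_count < 0L | yes_count > 5L))
    conqual_abort("yes_count must be integer(s) in 0..5",
                  "conqual_invalid_appraisal_error")
  yes_count <- as.integer(yes_count)
  ifelse(yes_count >= 4L, 0L, ifelse(yes_count >= 2L, 1L, 2L))
}

#' Dependability downgrade of a single finding
#'
#' A finding inherits the dependability appraisal of its parent study; this
#' returns the banded downgrade for that appraisal after checking the
#' finding/study linkage.
#'
#' @param finding A [finding()].
#' @param study The parent [study()]; `study$id` must equal
#'   `finding$study_id`.
#' @return Integer downgrade in \{0, 1, 2\}.
#' @export
finding_dependability <- function(finding, study) {
  if (!identical(finding$study_id, study$id))
    conqual_abort(sprintf(
      "finding %s references study %s, not the supplied study %s",
      sQuote(finding$id), sQuote(finding$study_id), sQuote(study$id)),
      "conqual_reference_error")
  dependability_downgrade(count_yes(study$appraisal))
}

#' Aggregate per-finding dependability downgrades
#'
#' The synthesised finding takes the downgrade held by a strict majority of
#' its constituent findings. When no magnitude holds a strict majority, the
#' tie among the most frequent magnitudes is broken toward the largest
#' (the conservative choice: downgrade when in doubt). Permutation-invariant.
#'
#' @param downgrades Non-empty integer vector with values in \{0, 1, 2\}.
#' @return Integer downgrade in \{0, 1, 2\}.
#' @examples
#' aggregate_dependability(c(1, 1, 0))   # majority -> 1
#' aggregate_dependability(c(0, 0, 1, 1)) # tie -> 1
#' @export
aggregate_dependability <- function(downgrades) {
  if (length(downgrades) == 0L)
    conqual_abort("cannot aggregate dependability over zero findings",
                  "conqual_empty_synthesis_error")
  if (anyNA(downgrades) || !all(downgrades %in% 0:2))
    conqual_abort("per-finding downgrades must be in {0, 1, 2}",
                  "conqual_invalid_appraisal_error")
  counts <- tabulate(as.integer(downgrades) + 1L, nbins = 3L)
  n <- length(downgrades)
  maj <- which(counts > n / 2)
  if (length(maj)) return(maj - 1L)
  modal <- which(counts == max(counts))
  max(modal) - 1L
}

MIX_CATEGORIES <- c("all_unequivocal", "unequivocal_equivocal_mix",
                    "all_equivocal", "equivocal_unsupported_mix",
                    "all_unsupported", "other_unsupported_mix")

#' Classify the credibility mix of a synthesised finding
#'
#' Classifies the multiset of constituent credibility levels into one of six
#' categories. Categories are presence-based, not proportion-based: a single
#' Equivocal finding among many Unequivocal ones makes the mix
#' `unequivocal_equivocal_mix`. Any mixture containing both Unequivocal and
#' Unsupported findings falls in `other_unsupported_mix`.
#' Permutation-invariant.
#'
#' @param levels Non-empty character vector of credibility levels
#'   (case-insensitive).
#' @return One of `"all_unequivocal"`, `"unequivocal_equivocal_mix"`,
#'   `"all_equivocal"`, `"equivocal_unsupported_mix"`, `"all_unsupported"`,
#'   `"other_unsupported_mix"`.
#' @examples
#' credibility_mix(c("Unequivocal", "Equivocal"))
#' @export
credibility_mix <- function(levels) {
  if (length(levels) == 0L)
    conqual_abort("cannot classify credibility over zero findings",
                  "conqual_empty_synthesis_error")
  lv <- canonical_credibility(levels)
  if (anyNA(lv))
    conqual_abort(sprintf("unknown credibility level(s): %s",
                          paste(sQuote(levels[is.na(lv)]), collapse = ", ")),
                  "conqual_schema_error")
  has_u <- "Unequivocal" %in% lv
  has_e <- "Equivocal" %in% lv
  has_n <- "Unsupported" %in% lv
  if (has_u && !has_e && !has_n) return("all_unequivocal")
  if (has_e && !has_u && !has_n) return("all_equivocal")
  if (has_n && !has_u && !has_e) return("all_unsupported")
  if (has_u && has_e && !has_n) return("unequivocal_equivocal_mix")
  if (has_e && has_n && !has_u) return("equivocal_unsupported_mix")
  "other_unsupported_mix"
}

#' Credibility downgrade for a mix category
#'
#' Maps the credibility mix to a downgrade magnitude: all unequivocal, no
#' change; a mix of unequivocal and equivocal, down one; all equivocal, down
#' two; a mix of equivocal and unsupported, down three; all unsupported, down
#' four. A mixture containing both unequivocal and unsupported findings has
#' no stated rule; it is mapped to three, treating the presence of
#' unsupported findings as severely as the equivocal/unsupported mix.
#'
#' @param category A mix category from [credibility_mix()].
#' @return Integer downgrade magnitude in \{0, 1, 2, 3, 4\}.
#' @examples
#' credibility_downgrade("unequivocal_equivocal_mix")
#' @export
credibility_downgrade <- function(category) {
  if (length(category) != 1L || !(category %in% MIX_CATEGORIES))
    conqual_abort(sprintf("unknown credibility mix category %s",
                          sQuote(as.character(category)[1L])),
                  "conqual_schema_error")
  switch(category,
         all_unequivocal           = 0L,
         unequivocal_equivocal_mix = 1L,
         all_equivocal             = 2L,
         equivocal_unsupported_mix = 3L,
         other_unsupported_mix     = 3L,
         all_unsupported           = 4L)
}

#' Confidence label for an internal rank
#'
#' Ranks run High = 4 down to Very Low = 1. `machine = TRUE` yields the
#' space-free spelling `"VeryLow"` used in machine-readable exports.
#'
#' @param rank Integer rank(s) in 1..4.
#' @param machine Use machine labels.
#' @return Character label(s).
#' @export
confidence_label <- function(rank, machine = FALSE) {
  if (anyNA(rank) || any(!rank %in% 1:4))
    conqual_abort("confidence rank must be in 1..4", "conqual_schema_error")
  labs <- if (machine) CONFIDENCE_MACHINE else CONFIDENCE_LABELS
  labs[5L - as.integer(rank)]
}

#' Internal rank for a confidence label
#'
#' Inverse of [confidence_label()]; accepts both `"Very Low"` and
#' `"VeryLow"`, case-insensitively.
#'
#' @param label Character label(s).
#' @return Integer rank(s) in 1..4 (High = 4).
#' @export
confidence_rank <- function(label) {
  key <- tolower(gsub(" ", "", label))
  m <- match(key, tolower(CONFIDENCE_MACHINE))
  if (anyNA(m))
    conqual_abort(sprintf("unknown confidence label %s",
                          paste(sQuote(label[is.na(m)]), collapse = ", ")),
                  "conqual_schema_error")
  5L - m
}

mix_phrase <- function(category) {
  switch(category,
         all_unequivocal           = "all findings being unequivocal",
         unequivocal_equivocal_mix = "a mix of unequivocal and equivocal findings",
         all_equivocal             = "all findings being equivocal",
         equivocal_unsupported_mix = "a mix of equivocal and unsupported findings",
         other_unsupported_mix     = "a mix of unsupported and unequivocal findings",
         all_unsupported           = "all findings being unsupported")
}

level_word <- function(n) {
  words <- c("one", "two", "three", "four")
  sprintf("%s level%s", words[n], if (n > 1L) "s" else "")
}

dependability_rationale <- function(magnitude, appraisals) {
  # appraisals: one per finding (the parent study's, repeated per finding)
  mat <- do.call(rbind, lapply(appraisals, unclass))
  not_yes <- colSums(mat != "yes")
  worst <- QUESTION_IDS[not_yes == max(not_yes) & not_yes > 0]
  qtext <- if (length(worst))
    sprintf(" (most often unmet: %s)",
            paste(sprintf("%s – %s", worst,
                          sub("\\?$", "", dependability_questions()[worst])),
                  collapse = "; "))
  else ""
  sprintf(
    "Downgraded %s due to common dependability issues across the included primary studies%s.",
    level_word(magnitude), qtext)
}

credibility_rationale <- function(magnitude, category) {
  sprintf("Downgraded %s due to %s.", level_word(magnitude),
          mix_phrase(category))
}

new_downgrade <- function(component, magnitude, rationale = "") {
  structure(list(component = component, magnitude = as.integer(magnitude),
                 rationale = rationale),
            class = "conqual_downgrade")
}

#' Score one synthesised finding
#'
#' Applies the full ConQual procedure: every qualitative synthesised finding
#' starts at *High*; the dependability downgrade is the majority band of its
#' constituent findings' study appraisals ([aggregate_dependability()]); the
#' credibility downgrade follows the mix of constituent credibility levels
#' ([credibility_mix()], [credibility_downgrade()]); both downgrades are
#' summed and applied once, with the score floored at *Very Low*.
#'
#' @param synth A [synthesised_finding()].
#' @param findings The review's findings: a list of [finding()] objects
#'   (named by id, or unnamed).
#' @param studies The review's studies: a list of [study()] objects (named by
#'   id, or unnamed).
#' @return A `conqual_result`: list with `synthesised_finding_id`,
#'   `dependability` and `credibility` downgrade records (component,
#'   magnitude, rationale), integer `score` (High = 4 .. Very Low = 1),
#'   `score_label`, and `footnotes` (one rationale per non-zero downgrade).
#' @examples
#' st <- study("s1", "Smith 2010", appraisal("yes","yes","yes","no","no"))
#' f1 <- finding("f1", "s1", "Patients expect answers.", "\"I hoped...\"",
#'               "Unequivocal")
#' f2 <- finding("f2", "s1", "Scans reassure.", "\"Maybe...\"", "Equivocal")
#' sf <- synthesised_finding("sf1", "Imaging raises expectations.",
#'                           c("f1", "f2"))
#' conqual_score(sf, list(f1, f2), list(st))
#' @export
conqual_score <- function(synth, findings, studies) {
  if (is.null(names(findings)))
    names(findings) <- vapply(findings, `[[`, character(1), "id")
  if (is.null(names(studies)))
    names(studies) <- vapply(studies, `[[`, character(1), "id")
  if (length(synth$finding_ids) == 0L)
    conqual_abort(sprintf("synthesised finding %s has no findings",
                          sQuote(synth$id)), "conqual_empty_synthesis_error")
  missing <- setdiff(synth$finding_ids, names(findings))
  if (length(missing))
    conqual_abort(sprintf("synthesised finding %s: unknown finding %s",
                          sQuote(synth$id),
                          paste(sQuote(missing), collapse = ", ")),
                  "conqual_reference_error")
  fl <- findings[synth$finding_ids]
  st_ids <- vapply(fl, `[[`, character(1), "study_id")
  missing_st <- setdiff(st_ids, names(studies))
  if (length(missing_st))
    conqual_abort(sprintf("synthesised finding %s: unknown study %s",
                          sQuote(synth$id),
                          paste(sQuote(missing_st), collapse = ", ")),
                  "conqual_reference_error")

  appraisals <- lapply(st_ids, function(sid) studies[[sid]]$appraisal)
  dep_each <- vapply(appraisals,
                     function(a) dependability_downgrade(count_yes(a)),
                     integer(1))
  dep_mag <- aggregate_dependability(dep_each)

  levels <- vapply(fl, `[[`, character(1), "credibility")
  category <- credibility_mix(levels)
  cred_mag <- credibility_downgrade(category)

  dep <- new_downgrade("dependability", dep_mag,
                       if (dep_mag > 0L) dependability_rationale(dep_mag, appraisals) else "")
  cred <- new_downgrade("credibility", cred_mag,
                        if (cred_mag > 0L) credibility_rationale(cred_mag, category) else "")
  score <- max(1L, 4L - dep_mag - cred_mag)
  footnotes <- c(if (dep_mag > 0L) dep$rationale,
                 if (cred_mag > 0L) cred$rationale)
  structure(list(synthesised_finding_id = synth$id,
                 dependability = dep, credibility = cred,
                 score = score,
                 score_label = confidence_label(score),
                 footnotes = as.character(footnotes %||% character())),
            class = "conqual_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score every synthesised finding in a review
#'
#' @param doc A validated `conqual_review` (see [review()], [load_review()]).
#' @return List of `conqual_result`, one per synthesised finding, in document
#'   order.
#' @export
score_review <- function(doc) {
  findings <- findings_by_id(doc)
  studies <- studies_by_id(doc)
  lapply(doc$synthesised_findings, conqual_score,
         findings = findings, studies = studies)
}

#' @export
print.conqual_result <- function(x, ...) {
  cat(sprintf("<conqual result> %s: %s (dependability -%d, credibility -%d)\n",
              x$synthesised_finding_id, x$score_label,
              x$dependability$magnitude, x$credibility$magnitude))
  for (fn in x$footnotes) cat("  -", fn, "\n")
  invisible(x)
}
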