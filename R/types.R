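# Domain types: appraisal, study, finding, synthesised finding, review.
# All are plain lists with S3 classes; constructors validate, validators
# return character vectors of path-prefixed problems.

#' Valid appraisal responses, credibility levels and confidence labels
#'
#' Constants of the ConQual vocabulary: the three permissible responses to a
#' dependability appraisal question, the three credibility levels of a
#' finding, and the four confidence labels (highest first).
#'
#' @name conqual-vocabulary
#' @keywords internal
NULL

#' @rdname conqual-vocabulary
#' @export
APPRAISAL_RESPONSES <- c("yes", "no", "unclear")

#' @rdname conqual-vocabulary
#' @export
CREDIBILITY_LEVELS <- c("Unequivocal", "Equivocal", "Unsupported")

# rank 4..1; display labels; machine labels have no space
CONFIDENCE_LABELS <- c("High", "Moderate", "Low", "Very Low")
CONFIDENCE_MACHINE <- c("High", "Moderate", "Low", "VeryLow")

#' The five dependability appraisal questions
#'
#' Full text of the five critical appraisal questions used to establish the
#' dependability of a qualitative study, in fixed order `q1`..`q5`.
#'
#' @return Named character vector of length 5.
#' @examples
#' dependability_questions()[["q4"]]
#' @export
dependability_questions <- function() {
  c(q1 = "Is there congruity between the research methodology and the research question or objectives?",
    q2 = "Is there congruity between the research methodology and the methods used to collect data?",
    q3 = "Is there congruity between the research methodology and the representation and analysis of data?",
    q4 = "Is there a statement locating the researcher culturally or theoretically?",
    q5 = "Is the influence of the researcher on the research, and vice-versa, addressed?")
}

QUESTION_IDS <- paste0("q", 1:5)

conqual_abort <- function(message, class) {
  stop(structure(class = c(class, "conqual_error", "error", "condition"),
                 list(message = message, call = NULL)))
}

canonical_response <- function(x) {
  m <- match(tolower(x), APPRAISAL_RESPONSES)
  ifelse(is.na(m), NA_character_, APPRAISAL_RESPONSES[m])
}

canonical_credibility <- function(x) {
  m <- match(tolower(x), tolower(CREDIBILITY_LEVELS))
  ifelse(is.na(m), NA_character_, CREDIBILITY_LEVELS[m])
}

#' Construct a dependability appraisal
#'
#' Records the yes/no/unclear responses to the five dependability questions
#' for one study. Input is case-insensitive; responses are stored in
#' canonical lower case in fixed order `q1`..`q5`.
#'
#' @param q1,q2,q3,q4,q5 One of `"yes"`, `"no"`, `"unclear"` each.
#' @return A `conqual_appraisal`: named character vector of length 5.
#' @examples
#' appraisal("yes", "yes", "yes", "no", "no")
#' @export
appraisal <- function(q1, q2, q3, q4, q5) {
  resp <- canonical_response(c(q1, q2, q3, q4, q5))
  if (anyNA(resp))
    conqual_abort(sprintf(
      "appraisal responses must be one of %s (got: %s)",
      paste(sQuote(APPRAISAL_RESPONSES), collapse = ", "),
      paste(sQuote(c(q1, q2, q3, q4, q5)[is.na(resp)]), collapse = ", ")),
      "conqual_schema_error")
  structure(stats::setNames(resp, QUESTION_IDS), class = "conqual_appraisal")
}

#' Construct a study
#'
#' A primary qualitative study included in the review, carrying its
#' dependability appraisal.
#'
#' @param id Unique study identifier within the review.
#' @param citation Free-text citation.
#' @param appraisal A [appraisal()] object (or a list/vector of five
#'   responses, which will be coerced).
#' @return A `conqual_study` list.
#' @export
study <- function(id, citation = "", appraisal) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    conqual_abort("study id must be a non-empty string", "conqual_schema_error")
  app <- as_appraisal(appraisal)
  structure(list(id = id, citation = as.character(citation)[1L], appraisal = app),
            class = "conqual_study")
}

as_appraisal <- function(x) {
  if (inherits(x, "conqual_appraisal")) return(x)
  x <- unlist(x, use.names = FALSE)
  if (length(x) != 5L)
    conqual_abort("an appraisal needs exactly 5 responses (q1..q5)",
                  "conqual_schema_error")
  do.call(appraisal, as.list(x))
}

#' Construct a finding
#'
#' An author's analytic interpretation extracted verbatim from a study,
#' accompanied by a supporting illustration (participant voice, fieldwork
#' observation or other data) and rated for credibility. The illustration may
#' be empty only when the finding is Unsupported.
#'
#' @param id Unique finding identifier within the review.
#' @param study_id Identifier of the parent [study()].
#' @param statement The author's interpretive finding (free text).
#' @param illustration Supporting data (free text).
#' @param credibility `"Unequivocal"`, `"Equivocal"` or `"Unsupported"`
#'   (case-insensitive).
#' @return A `conqual_finding` list.
#' @export
finding <- function(id, study_id, statement = "", illustration = "",
                    credibility) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    conqual_abort("finding id must be a non-empty string", "conqual_schema_error")
  if (!is.character(study_id) || length(study_id) != 1L || !nzchar(study_id))
    conqual_abort("finding study_id must be a non-empty string",
                  "conqual_schema_error")
  cred <- canonical_credibility(credibility)
  if (is.na(cred))
    conqual_abort(sprintf("credibility must be one of %s (got %s)",
                          paste(sQuote(CREDIBILITY_LEVELS), collapse = ", "),
                          sQuote(credibility)),
                  "conqual_schema_error")
  illustration <- as.character(illustration)[1L]
  if (!nzchar(illustration) && cred != "Unsupported")
    conqual_abort(sprintf(
      "finding %s: illustration may be empty only for Unsupported findings",
      sQuote(id)), "conqual_schema_error")
  structure(list(id = id, study_id = study_id,
                 statement = as.character(statement)[1L],
                 illustration = illustration, credibility = cred),
            class = "conqual_finding")
}

#' Construct a synthesised finding
#'
#' A review-level statement aggregating several findings; the unit that
#' receives a ConQual score.
#'
#' @param id Unique identifier within the review.
#' @param statement The synthesised statement (free text).
#' @param finding_ids Non-empty character vector of constituent finding IDs
#'   (no duplicates).
#' @param research_type Label shown in the Summary of Findings table;
#'   defaults to `"Qualitative"`.
#' @return A `conqual_synthesised_finding` list.
#' @export
synthesised_finding <- function(id, statement = "", finding_ids,
                                research_type = "Qualitative") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    conqual_abort("synthesised finding id must be a non-empty string",
                  "conqual_schema_error")
  finding_ids <- as.character(unlist(finding_ids, use.names = FALSE))
  if (length(finding_ids) == 0L)
    conqual_abort(sprintf("synthesised finding %s: finding_ids must be non-empty",
                          sQuote(id)), "conqual_schema_error")
  if (anyDuplicated(finding_ids))
    conqual_abort(sprintf("synthesised finding %s: duplicate finding_ids (%s)",
                          sQuote(id),
                          paste(sQuote(unique(finding_ids[duplicated(finding_ids)])),
                                collapse = ", ")),
                  "conqual_schema_error")
  structure(list(id = id, statement = as.character(statement)[1L],
                 finding_ids = finding_ids,
                 research_type = as.character(research_type)[1L]),
            class = "conqual_synthesised_finding")
}

#' Construct a review document
#'
#' The full input to ConQual scoring: review metadata (title, population,
#' phenomena of interest, context), the appraised studies, the credibility-
#' rated findings, and the synthesised findings grouping them. All
#' cross-references are validated; see [validate_review()] for the rules.
#'
#' @param title,population,phenomena_of_interest,context Review metadata as
#'   shown in the Summary of Findings table header. Required; empty strings
#'   are rejected unless `allow_empty_header = TRUE`.
#' @param studies List of [study()] objects.
#' @param findings List of [finding()] objects.
#' @param synthesised_findings List of [synthesised_finding()] objects.
#' @param allow_empty_header Permit empty header fields (for drafts).
#' @return A validated `conqual_review` list.
#' @seealso [load_review()], [score_review()]
#' @export
review <- function(title, population, phenomena_of_interest, context,
                   studies, findings, synthesised_findings,
                   allow_empty_header = FALSE) {
  doc <- structure(list(
    title = as.character(title)[1L],
    population = as.character(population)[1L],
    phenomena_of_interest = as.character(phenomena_of_interest)[1L],
    context = as.character(context)[1L],
    studies = unname(studies),
    findings = unname(findings),
    synthesised_findings = unname(synthesised_findings)),
    class = "conqual_review")
  problems <- validate_review(doc, allow_empty_header = allow_empty_header)
  if (length(problems))
    conqual_abort(paste0("invalid review document:\n",
                         paste0("  - ", problems, collapse = "\n")),
                  validation_error_class(problems))
  doc
}

validation_error_class <- function(problems) {
  if (any(grepl("unknown study|unknown finding", problems)))
    "conqual_reference_error" else "conqual_schema_error"
}

#' Validate a review document
#'
#' Checks every structural invariant of a review document and returns the
#' problems found, each prefixed with the path of the offending element
#' (e.g. `findings[3].study_id`). An empty return value means the document
#' is valid.
#'
#' Rules: the four header fields are present (non-empty unless allowed);
#' study, finding and synthesised-finding IDs are unique per collection;
#' every `finding.study_id` names an existing study; every
#' `synthesised_finding.finding_ids` entry names an existing finding, is
#' non-empty and duplicate-free.
#'
#' @param doc A `conqual_review` (or an untrusted plain list shaped like one).
#' @param allow_empty_header Permit empty header fields.
#' @return Character vector of problems (empty if valid).
#' @export
validate_review <- function(doc, allow_empty_header = FALSE) {
  problems <- character()
  if (!allow_empty_header) {
    for (f in c("title", "population", "phenomena_of_interest", "context")) {
      v <- doc[[f]]
      if (is.null(v) || !nzchar(as.character(v)[1L]))
        problems <- c(problems, sprintf("%s: required header field is missing or empty", f))
    }
  }
  study_ids <- vapply(doc$studies, function(s) s$id, character(1))
  if (anyDuplicated(study_ids))
    problems <- c(problems, sprintf("studies: duplicate id %s",
      paste(sQuote(unique(study_ids[duplicated(study_ids)])), collapse = ", ")))
  finding_ids <- vapply(doc$findings, function(f) f$id, character(1))
  if (anyDuplicated(finding_ids))
    problems <- c(problems, sprintf("findings: duplicate id %s",
      paste(sQuote(unique(finding_ids[duplicated(finding_ids)])), collapse = ", ")))
  synth_ids <- vapply(doc$synthesised_findings, function(s) s$id, character(1))
  if (anyDuplicated(synth_ids))
    problems <- c(problems, sprintf("synthesised_findings: duplicate id %s",
      paste(sQuote(unique(synth_ids[duplicated(synth_ids)])), collapse = ", ")))
  for (i in seq_along(doc$findings)) {
    f <- doc$findings[[i]]
    if (!(f$study_id %in% study_ids))
      problems <- c(problems, sprintf(
        "findings[%d].study_id: unknown study %s", i, sQuote(f$study_id)))
  }
  for (i in seq_along(doc$synthesised_findings)) {
    s <- doc$synthesised_findings[[i]]
    missing <- setdiff(s$finding_ids, finding_ids)
    if (length(missing))
      problems <- c(problems, sprintf(
        "synthesised_findings[%d].finding_ids: unknown finding %s",
        i, paste(sQuote(missing), collapse = ", ")))
  }
  problems
}

studies_by_id <- function(doc) {
  stats::setNames(doc$studies, vapply(doc$studies, `[[`, character(1), "id"))
}

findings_by_id <- function(doc) {
  stats::setNames(doc$findings, vapply(doc$findings, `[[`, character(1), "id"))
}

#' @export
print.conqual_review <- function(x, ...) {
  cat("<conqual review>", x$title, "\n")
  cat(sprintf("  %d studies, %d findings, %d synthesised findings\n",
              length(x$studies), length(x$findings),
              length(x$synthesised_findings)))
  invisible(x)
}

#' @export
print.conqual_appraisal <- function(x, ...) {
  cat("<dependability appraisal>", paste(QUESTION_IDS, unclass(x),
                                         sep = "=", collapse = " "), "\n")
  invisible(x)
}
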