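# Reading, validating and writing review documents (JSON / YAML), and
# machine-readable result exports (JSON / CSV).
#
# The on-disk schema (also published as inst/schema/review-schema.json):
#   title, population, phenomena_of_interest, context : strings
#   studies[]              : {id, citation, appraisal: {q1..q5: yes|no|unclear}}
#   findings[]             : {id, study_id, statement, illustration, credibility}
#   synthesised_findings[] : {id, statement, finding_ids[], research_type}

YAML_STRING_HANDLERS <- list(
  # keep bare yes/no/true/false scalars as the strings the schema expects
  "bool#yes" = function(x) "yes",
  "bool#no" = function(x) "no",
  "bool#true" = function(x) "true",
  "bool#false" = function(x) "false")

infer_dialect <- function(path, dialect = NULL,
                          choices = c("json", "yaml")) {
  if (!is.null(dialect)) return(match.arg(dialect, choices))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("yml", "yaml") && "yaml" %in% choices) return("yaml")
  if (ext == "csv" && "csv" %in% choices) return("csv")
  if (ext %in% c("md", "markdown") && "markdown" %in% choices) return("markdown")
  if (ext %in% c("html", "htm") && "html" %in% choices) return("html")
  choices[[1L]]
}

#' Read and validate a review document
#'
#' Parses a JSON or YAML review document, coerces it through the typed
#' constructors, and checks every invariant ([validate_review()]). Errors
#' carry the path of the offending element: a malformed file signals a
#' `conqual_parse_error`, a missing field or bad enumeration value a
#' `conqual_schema_error`, a dangling cross-reference a
#' `conqual_reference_error`.
#'
#' @param path Path to the document, or a connection.
#' @param dialect `"json"` or `"yaml"`; inferred from the file extension when
#'   `NULL`.
#' @param text Alternatively, the document text itself (overrides `path`).
#' @param allow_empty_header Permit empty header metadata fields.
#' @return A validated `conqual_review`.
#' @examples
#' path <- system.file("extdata", "imaging_review.json", package = "conqual")
#' doc <- load_review(path)
#' doc$synthesised_findings[[1]]$id
#' @export
load_review <- function(path = NULL, dialect = NULL, text = NULL,
                        allow_empty_header = FALSE) {
  if (is.null(text)) {
    if (is.null(path))
      conqual_abort("either path or text must be supplied", "conqual_usage_error")
    text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
    dialect <- infer_dialect(if (is.character(path)) path else "", dialect)
  } else {
    dialect <- if (is.null(dialect)) "json" else match.arg(dialect, c("json", "yaml"))
  }
  raw <- tryCatch(
    switch(dialect,
           json = jsonlite::fromJSON(text, simplifyVector = FALSE),
           yaml = yaml::yaml.load(text, handlers = YAML_STRING_HANDLERS)),
    error = function(e) conqual_abort(
      sprintf("cannot parse %s document: %s", dialect, conditionMessage(e)),
      "conqual_parse_error"))
  review_from_list(raw, allow_empty_header = allow_empty_header)
}

pluck_chr <- function(x, field, path, required = TRUE, default = "") {
  v <- x[[field]]
  if (is.null(v)) {
    if (required)
      conqual_abort(sprintf("%s.%s: required field is missing", path, field),
                    "conqual_schema_error")
    return(default)
  }
  if (length(v) != 1L || (!is.character(v) && !is.numeric(v) && !is.logical(v)))
    conqual_abort(sprintf("%s.%s: expected a single string", path, field),
                  "conqual_schema_error")
  as.character(v)
}

#' Build a review document from a plain list
#'
#' Converts parsed JSON/YAML (nested lists) into a validated
#' `conqual_review`; used by [load_review()] and available directly for
#' documents assembled in R.
#'
#' @param raw Nested list in the review document schema.
#' @param allow_empty_header Permit empty header metadata fields.
#' @return A validated `conqual_review`.
#' @export
review_from_list <- function(raw, allow_empty_header = FALSE) {
  if (!is.list(raw))
    conqual_abort("document root must be a mapping/object", "conqual_schema_error")
  wrap <- function(expr, path) {
    tryCatch(expr, conqual_error = function(e)
      conqual_abort(sprintf("%s: %s", path, conditionMessage(e)), class(e)[1L]))
  }
  studies <- lapply(seq_along(raw$studies), function(i) {
    p <- sprintf("studies[%d]", i)
    s <- raw$studies[[i]]
    app <- s$appraisal
    if (is.null(app))
      conqual_abort(sprintf("%s.appraisal: required field is missing", p),
                    "conqual_schema_error")
    if (!is.null(names(app))) {
      miss <- setdiff(QUESTION_IDS, names(app))
      if (length(miss))
        conqual_abort(sprintf("%s.appraisal: missing question(s) %s", p,
                              paste(sQuote(miss), collapse = ", ")),
                      "conqual_schema_error")
      app <- app[QUESTION_IDS]
    }
    wrap(study(id = pluck_chr(s, "id", p),
               citation = pluck_chr(s, "citation", p, required = FALSE),
               appraisal = app), p)
  })
  findings <- lapply(seq_along(raw$findings), function(i) {
    p <- sprintf("findings[%d]", i)
    f <- raw$findings[[i]]
    wrap(finding(id = pluck_chr(f, "id", p),
                 study_id = pluck_chr(f, "study_id", p),
                 statement = pluck_chr(f, "statement", p, required = FALSE),
                 illustration = pluck_chr(f, "illustration", p, required = FALSE),
                 credibility = pluck_chr(f, "credibility", p)), p)
  })
  synths <- lapply(seq_along(raw$synthesised_findings), function(i) {
    p <- sprintf("synthesised_findings[%d]", i)
    s <- raw$synthesised_findings[[i]]
    ids <- s$finding_ids
    if (is.null(ids))
      conqual_abort(sprintf("%s.finding_ids: required field is missing", p),
                    "conqual_schema_error")
    wrap(synthesised_finding(
      id = pluck_chr(s, "id", p),
      statement = pluck_chr(s, "statement", p, required = FALSE),
      finding_ids = ids,
      research_type = pluck_chr(s, "research_type", p, required = FALSE,
                                default = "Qualitative")), p)
  })
  review(title = if (is.null(raw$title)) "" else as.character(raw$title)[1L],
         population = if (is.null(raw$population)) "" else as.character(raw$population)[1L],
         phenomena_of_interest = if (is.null(raw$phenomena_of_interest)) ""
                                 else as.character(raw$phenomena_of_interest)[1L],
         context = if (is.null(raw$context)) "" else as.character(raw$context)[1L],
         studies = studies, findings = findings, synthesised_findings = synths,
         allow_empty_header = allow_empty_header)
}

review_to_list <- function(doc) {
  # fixed field order => stable serialisation
  list(
    title = doc$title,
    population = doc$population,
    phenomena_of_interest = doc$phenomena_of_interest,
    context = doc$context,
    studies = lapply(doc$studies, function(s)
      list(id = s$id, citation = s$citation,
           appraisal = as.list(stats::setNames(unclass(s$appraisal),
                                               QUESTION_IDS)))),
    findings = lapply(doc$findings, function(f)
      list(id = f$id, study_id = f$study_id, statement = f$statement,
           illustration = f$illustration, credibility = f$credibility)),
    synthesised_findings = lapply(doc$synthesised_findings, function(s)
      list(id = s$id, statement = s$statement,
           finding_ids = as.list(s$finding_ids),
           research_type = s$research_type)))
}

#' Serialise a review document
#'
#' Writes the document in the same schema [load_review()] reads. Field order
#' is fixed, so two dumps of the same document are byte-identical and
#' `load_review(text = dump_review(doc))` reproduces `doc` exactly.
#'
#' @param doc A `conqual_review`.
#' @param dialect `"json"` or `"yaml"`.
#' @param path Optional path to write to; the text is returned invisibly.
#' @return The serialised document text (a single string).
#' @export
dump_review <- function(doc, dialect = c("json", "yaml"), path = NULL) {
  dialect <- match.arg(dialect)
  lst <- review_to_list(doc)
  text <- switch(dialect,
    json = as.character(jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = 2)),
    yaml = yaml::as.yaml(lst, indent.mapping.sequence = TRUE))
  if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
  if (is.null(path)) text else invisible(text)
}

result_record <- function(r) {
  list(id = r$synthesised_finding_id,
       dependability_downgrade = r$dependability$magnitude,
       credibility_downgrade = r$credibility$magnitude,
       score = confidence_label(r$score, machine = TRUE),
       footnotes = as.list(r$footnotes))
}

csv_quote <- function(x) {
  # RFC 4180: quote fields containing comma, quote or newline; double quotes
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Export scoring results
#'
#' One record per synthesised finding: id, the two component downgrades, the
#' machine score label, and the rationale footnotes. JSON keeps footnotes as
#' an array; CSV (RFC 4180) joins them with `" | "`.
#'
#' @param results Non-empty list of `conqual_result` (see [score_review()]).
#' @param dialect `"json"` or `"csv"`.
#' @param path Optional path to write to.
#' @return The export text (single string); invisibly when `path` is given.
#' @export
export_results <- function(results, dialect = c("json", "csv"), path = NULL) {
  dialect <- match.arg(dialect)
  if (length(results) == 0L)
    conqual_abort("no results to export", "conqual_empty_synthesis_error")
  if (inherits(results, "conqual_result")) results <- list(results)
  records <- lapply(results, result_record)
  text <- switch(dialect,
    json = as.character(jsonlite::toJSON(records, auto_unbox = TRUE, pretty = 2)),
    csv = {
      header <- "id,dependability_downgrade,credibility_downgrade,score,footnotes"
      rows <- vapply(records, function(r) paste(csv_quote(c(
        r$id, r$dependability_downgrade, r$credibility_downgrade, r$score,
        paste(unlist(r$footnotes), collapse = " | "))), collapse = ","),
        character(1))
      paste(c(header, rows), collapse = "\n")
    })
  if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
  if (is.null(path)) text else invisible(text)
}
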