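# Summary of Findings table: header metadata block, one row per synthesised
# finding (statement, research type, dependability cell, credibility cell,
# score), footnoted downgrade rationales. Rendered to Markdown, HTML or CSV.

downgrade_cell <- function(magnitude) {
  if (magnitude == 0L) "No change" else sprintf("Downgrade %d level%s",
                                                magnitude,
                                                if (magnitude > 1L) "s" else "")
}

marker_for <- function(n) strrep("*", n)

#' Build a Summary of Findings table
#'
#' Assembles the evidence-profile table for a scored review: a header block
#' with the review title, population, phenomena of interest and context, then
#' one row per synthesised finding showing its statement, the type of
#' research informing it, the dependability and credibility downgrades and
#' the final ConQual score. Every non-zero downgrade cell carries a footnote
#' marker (`*`, `**`, ...); markers are assigned densely in order of first
#' use, and rows sharing an identical rationale share a marker.
#'
#' @param doc A `conqual_review`.
#' @param results Results from [score_review()] (computed from `doc` when
#'   omitted). Must contain exactly one result per synthesised finding, in
#'   any order.
#' @param footnote_overrides Optional named list mapping
#'   `"<synth id>.dependability"` / `"<synth id>.credibility"` to custom
#'   footnote text replacing the auto-composed rationale.
#' @return A `conqual_sof`: list with `header` (named character), `rows`
#'   (data frame: id, statement, research_type, dependability, credibility,
#'   score) and `footnotes` (marker-prefixed character vector).
#' @examples
#' doc <- load_review(system.file("extdata", "imaging_review.json",
#'                                package = "conqual"))
#' sof <- build_sof(doc)
#' cat(render_sof(sof, "markdown"))
#' @export
build_sof <- function(doc, results = score_review(doc),
                      footnote_overrides = list()) {
  synth_ids <- vapply(doc$synthesised_findings, `[[`, character(1), "id")
  res_ids <- vapply(results, `[[`, character(1), "synthesised_finding_id")
  if (length(res_ids) != length(synth_ids) ||
      !setequal(res_ids, synth_ids) || anyDuplicated(res_ids))
    conqual_abort(
      "results must contain exactly one entry per synthesised finding",
      "conqual_consistency_error")
  results <- results[match(synth_ids, res_ids)]

  footnotes <- character()
  cell <- function(synth_id, dg) {
    text <- downgrade_cell(dg$magnitude)
    if (dg$magnitude == 0L) return(text)
    rationale <- footnote_overrides[[paste0(synth_id, ".", dg$component)]] %||%
      dg$rationale
    idx <- match(rationale, footnotes)
    if (is.na(idx)) {
      footnotes <<- c(footnotes, rationale)
      idx <- length(footnotes)
    }
    paste0(text, marker_for(idx))
  }

  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    s <- doc$synthesised_findings[[i]]
    data.frame(id = s$id, statement = s$statement,
               research_type = s$research_type,
               dependability = cell(s$id, r$dependability),
               credibility = cell(s$id, r$credibility),
               score = r$score_label,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    header = c(`Systematic review title` = doc$title,
               Population = doc$population,
               `Phenomena of interest` = doc$phenomena_of_interest,
               Context = doc$context),
    rows = rows,
    footnotes = if (length(footnotes))
      paste0(vapply(seq_along(footnotes), marker_for, character(1)), " ",
             footnotes)
    else character()),
    class = "conqual_sof")
}

SOF_COLUMNS <- c("Synthesised finding", "Type of research", "Dependability",
                 "Credibility", "ConQual score")

md_escape <- function(x) gsub("\\|", "\\\\|", x)

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_sof_markdown <- function(table) {
  header <- sprintf("**%s:** %s  ", names(table$header), table$header)
  body <- as.matrix(table$rows[, c("statement", "research_type",
                                   "dependability", "credibility", "score")])
  grid <- c(paste0("| ", paste(SOF_COLUMNS, collapse = " | "), " |"),
            paste0("|", paste(rep("---", length(SOF_COLUMNS)), collapse = "|"),
                   "|"),
            apply(body, 1L, function(r)
              paste0("| ", paste(md_escape(r), collapse = " | "), " |")))
  paste(c(header, "", grid,
          if (length(table$footnotes)) c("", table$footnotes)),
        collapse = "\n")
}

render_sof_html <- function(table) {
  header <- sprintf("<p><strong>%s:</strong> %s</p>",
                    html_escape(names(table$header)),
                    html_escape(table$header))
  body <- as.matrix(table$rows[, c("statement", "research_type",
                                   "dependability", "credibility", "score")])
  rows <- apply(body, 1L, function(r)
    paste0("    <tr>", paste0("<td>", html_escape(r), "</td>", collapse = ""),
           "</tr>"))
  paste(c('<section class="conqual-sof">',
          header,
          "  <table>",
          paste0("    <tr>", paste0("<th>", SOF_COLUMNS, "</th>",
                                    collapse = ""), "</tr>"),
          rows,
          "  </table>",
          if (length(table$footnotes))
            sprintf('  <p class="footnote">%s</p>', html_escape(table$footnotes)),
          "</section>"),
        collapse = "\n")
}

render_sof_csv <- function(table) {
  meta <- vapply(seq_along(table$header), function(i)
    paste(csv_quote(c(names(table$header)[i], table$header[[i]])),
          collapse = ","), character(1))
  header_row <- paste(csv_quote(SOF_COLUMNS), collapse = ",")
  body <- as.matrix(table$rows[, c("statement", "research_type",
                                   "dependability", "credibility", "score")])
  rows <- apply(body, 1L, function(r) paste(csv_quote(r), collapse = ","))
  fns <- vapply(table$footnotes, function(f)
    paste(csv_quote(c("Footnote", f)), collapse = ","), character(1),
    USE.NAMES = FALSE)
  paste(c(meta, header_row, rows, fns), collapse = "\n")
}

#' Render a Summary of Findings table
#'
#' Deterministic rendering of a [build_sof()] table. Markdown and HTML place
#' the review metadata above the grid and the footnotes below it; CSV
#' flattens the metadata into leading two-column rows and appends footnotes
#' as `Footnote,<text>` rows.
#'
#' @param table A `conqual_sof`.
#' @param format `"markdown"` (pipe table), `"html"` (HTML5 fragment) or
#'   `"csv"` (RFC 4180).
#' @param path Optional path to write to.
#' @return The rendered text (single string); invisibly when `path` is given.
#' @export
render_sof <- function(table, format = c("markdown", "html", "csv"),
                       path = NULL) {
  if (!inherits(table, "conqual_sof"))
    conqual_abort("table must be built with build_sof()", "conqual_usage_error")
  format <- tryCatch(match.arg(format),
                     error = function(e) conqual_abort(
                       sprintf("unknown Summary of Findings format %s",
                               sQuote(format[1L])), "conqual_usage_error"))
  text <- switch(format,
                 markdown = render_sof_markdown(table),
                 html = render_sof_html(table),
                 csv = render_sof_csv(table))
  if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
  if (is.null(path)) text else invisible(text)
}

#' @export
print.conqual_sof <- function(x, ...) {
  cat(render_sof(x, "markdown"), "\n")
  invisible(x)
}
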