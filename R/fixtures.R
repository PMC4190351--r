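# Seeded generator of synthetic review documents, plus the exhaustive
# enumerator of small reviews used for oracle-equivalence testing.

#' Configuration for the synthetic review generator
#'
#' @param n_studies,n_findings,n_synth Positive counts of studies, findings
#'   and synthesised findings; `n_findings >= n_synth` so every synthesised
#'   finding is non-empty.
#' @param p_yes Probability that an appraisal response is `"yes"`.
#' @param p_unclear Probability that a response is `"unclear"` (the remainder
#'   is `"no"`); 0 by default so documents exercise the plain yes/no split,
#'   the three-way split being an option for testing the unclear-as-not-yes
#'   rule.
#' @param credibility_weights Probability triple over (Unequivocal,
#'   Equivocal, Unsupported); must sum to 1.
#' @param assignment `"round_robin"` (deterministic study/finding linkage) or
#'   `"shuffled"` (seeded random linkage).
#' @param seed Integer seed; identical seed and config give byte-identical
#'   documents.
#' @return A `conqual_generator_config` list.
#' @export
generator_config <- function(n_studies = 5L, n_findings = 12L, n_synth = 3L,
                             p_yes = 0.5, p_unclear = 0,
                             credibility_weights = c(1, 1, 1) / 3,
                             assignment = c("round_robin", "shuffled"),
                             seed = 1L) {
  assignment <- match.arg(assignment)
  bad <- function(msg) conqual_abort(msg, "conqual_config_error")
  if (n_studies < 1L || n_findings < 1L || n_synth < 1L)
    bad("n_studies, n_findings and n_synth must be positive")
  if (n_findings < n_synth)
    bad("n_findings must be at least n_synth")
  if (p_yes < 0 || p_yes > 1 || p_unclear < 0 || p_unclear > 1 ||
      p_yes + p_unclear > 1)
    bad("p_yes and p_unclear must be probabilities with p_yes + p_unclear <= 1")
  if (length(credibility_weights) != 3L || any(credibility_weights < 0) ||
      abs(sum(credibility_weights) - 1) > 1e-9)
    bad("credibility_weights must be 3 non-negative values summing to 1")
  structure(list(n_studies = as.integer(n_studies),
                 n_findings = as.integer(n_findings),
                 n_synth = as.integer(n_synth),
                 p_yes = p_yes, p_unclear = p_unclear,
                 credibility_weights = as.numeric(credibility_weights),
                 assignment = assignment, seed = as.integer(seed)),
            class = "conqual_generator_config")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old))
            suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Generate a synthetic review document
#'
#' Emits a valid review document with placeholder text: appraisal responses
#' drawn yes/unclear/no with the configured probabilities, credibility levels
#' drawn from `credibility_weights`, findings linked to studies and
#' partitioned across synthesised findings round-robin (or shuffled). Useful
#' for tests, demos and exploring how the downgrade rules respond to study
#' quality and credibility composition.
#'
#' @param config A [generator_config()].
#' @return A validated `conqual_review`.
#' @examples
#' doc <- generate_review(generator_config(seed = 7))
#' vapply(score_review(doc), `[[`, character(1), "score_label")
#' @export
generate_review <- function(config = generator_config()) {
  if (!inherits(config, "conqual_generator_config"))
    config <- do.call(generator_config, config)
  with_local_seed(config$seed, {
    draw_response <- function(n) {
      u <- runif(n)
      ifelse(u < config$p_yes, "yes",
             ifelse(u < config$p_yes + config$p_unclear, "unclear", "no"))
    }
    studies <- lapply(seq_len(config$n_studies), function(i)
      study(id = sprintf("s%d", i),
            citation = sprintf("Synthetic study %d (2020)", i),
            appraisal = draw_response(5L)))
    study_idx <- if (config$assignment == "round_robin")
      (seq_len(config$n_findings) - 1L) %% config$n_studies + 1L
    else sample.int(config$n_studies, config$n_findings, replace = TRUE)
    levels <- sample(CREDIBILITY_LEVELS, config$n_findings, replace = TRUE,
                     prob = config$credibility_weights)
    findings <- lapply(seq_len(config$n_findings), function(i)
      finding(id = sprintf("f%d", i),
              study_id = sprintf("s%d", study_idx[i]),
              statement = sprintf("Synthetic finding %d.", i),
              illustration = if (levels[i] == "Unsupported") ""
                             else sprintf("Synthetic illustration %d.", i),
              credibility = levels[i]))
    synth_idx <- (seq_len(config$n_findings) - 1L) %% config$n_synth + 1L
    synths <- lapply(seq_len(config$n_synth), function(k)
      synthesised_finding(
        id = sprintf("sf%d", k),
        statement = sprintf("Synthetic synthesised finding %d.", k),
        finding_ids = sprintf("f%d", which(synth_idx == k))))
    review(title = "Synthetic review",
           population = "Synthetic population",
           phenomena_of_interest = "Synthetic phenomena of interest",
           context = "Synthetic context",
           studies = studies, findings = findings,
           synthesised_findings = synths)
  })
}

credibility_multisets <- function(k) {
  # non-decreasing k-tuples over the 3 levels = multisets (order-free)
  grid <- expand.grid(rep(list(seq_len(3L)), k))
  keep <- apply(grid, 1L, function(r) all(diff(r) >= 0))
  m <- as.matrix(grid[keep, , drop = FALSE])
  lapply(seq_len(nrow(m)), function(i) CREDIBILITY_LEVELS[m[i, ]])
}

appraisal_with_yes <- function(yes_count) {
  as_appraisal(c(rep("yes", yes_count), rep("no", 5L - yes_count)))
}

#' Enumerate all small single-study reviews
#'
#' Exhaustively yields one review per combination of study yes-count (0..5),
#' number of findings (1..`max_findings`) and credibility multiset over the
#' findings, deduplicated up to permutation of the findings. Each review has
#' one study carrying all findings and one synthesised finding grouping them.
#' Intended as the input space for brute-force oracle-equivalence tests of
#' the scoring rules (which are permutation-invariant, so multisets suffice).
#'
#' @param max_findings Integer in 1..4.
#' @return List of `conqual_review` documents. With `max_findings = 1` there
#'   are 6 x 3 = 18; each added finding size k adds 6 x choose(k + 2, 2)
#'   more.
#' @export
enumerate_small_reviews <- function(max_findings) {
  if (length(max_findings) != 1L || is.na(max_findings) ||
      max_findings < 1L || max_findings > 4L)
    conqual_abort("max_findings must be an integer in 1..4",
                  "conqual_usage_error")
  out <- list()
  for (yes in 0:5) {
    st <- study(id = "s1", citation = "Enumerated study",
                appraisal = appraisal_with_yes(yes))
    for (k in seq_len(max_findings)) {
      for (levels in credibility_multisets(k)) {
        findings <- lapply(seq_len(k), function(i)
          finding(id = sprintf("f%d", i), study_id = "s1",
                  statement = sprintf("Enumerated finding %d.", i),
                  illustration = if (levels[i] == "Unsupported") ""
                                 else sprintf("Illustration %d.", i),
                  credibility = levels[i]))
        out[[length(out) + 1L]] <- review(
          title = sprintf("Enumerated review (yes=%d, levels=%s)", yes,
                          paste(substr(levels, 1L, 2L), collapse = "")),
          population = "Enumerated population",
          phenomena_of_interest = "Enumerated phenomena",
          context = "Enumerated context",
          studies = list(st), findings = findings,
          synthesised_findings = list(synthesised_finding(
            id = "sf1", statement = "Enumerated synthesised finding.",
            finding_ids = sprintf("f%d", seq_len(k)))))
      }
    }
  }
  out
}
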