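#' Candidate-selection configuration
#'
#' Bundles the selection rules applied to motif matches: the probability
#' threshold (matches scoring below `1e-2` are kept, mirroring the
#' published cut-off), the disorder-localization requirement, and the
#' ortholog-conservation requirement. Classes on the whitelist bypass the
#' probability threshold (see [default_whitelist()]).
#'
#' @param score_threshold Probability threshold in (0, 1); default `1e-2`.
#' @param require_disorder Require overlap with a disorder region
#'   (default `TRUE`).
#' @param conservation_min_fraction Minimum conserved fraction in
#'   `[0, 1]` (default 0.8).
#' @param conservation_slack_columns Alignment-column slack used when
#'   mapping motifs into orthologs (default 5).
#' @param whitelist Character vector of motif ids exempt from the
#'   probability threshold.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(score_threshold = 1e-2, require_disorder = TRUE,
                        conservation_min_fraction = 0.8,
                        conservation_slack_columns = 5,
                        whitelist = character()) {
  stopifnot(score_threshold > 0, score_threshold < 1,
            conservation_min_fraction >= 0, conservation_min_fraction <= 1,
            conservation_slack_columns >= 0)
  structure(list(score_threshold = score_threshold,
                 require_disorder = isTRUE(require_disorder),
                 conservation_min_fraction = conservation_min_fraction,
                 conservation_slack_columns = conservation_slack_columns,
                 whitelist = whitelist),
            class = "scan_config")
}

#' Apply the candidate-selection procedure to scanned matches
#'
#' A match is retained iff (i) its class background probability is below
#' the threshold, or its motif id is whitelisted; (ii) when disorder is
#' required, the match interval overlaps a disorder region -- matches on
#' proteins without any disorder information are retained but flagged
#' `"unknown"`; and (iii) when a conservation value is available, the
#' conserved fraction reaches the configured minimum -- matches with
#' unknown conservation are retained but flagged. Every row carries all
#' three verdicts for audit.
#'
#' @param matches `data.frame` from [scan_motifs()]/[scan_catalog()].
#' @param disorder_regions A `disorder_region_set`, or a named list of
#'   them keyed by protein id, or `NULL` (unknown).
#' @param conservation_reports A `conservation_report`, a list of them,
#'   or a `data.frame` with `protein_id`, `motif_id`, `start`,
#'   `conserved_fraction`; `NULL` when no conservation was assessed.
#' @param config A [scan_config()].
#' @return The candidate table: `matches` plus columns `in_disorder`,
#'   `conserved_fraction`, `score_ok`, `disorder_ok`, `conservation_ok`
#'   (`"yes"`/`"no"`/`"unknown"`), `retained`, `reasons`.
#' @export
select_candidates <- function(matches, disorder_regions = NULL,
                              conservation_reports = NULL,
                              config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  n <- nrow(matches)
  out <- matches
  if (!n) {
    out$score_ok <- character(0); out$disorder_ok <- character(0)
    out$conservation_ok <- character(0); out$retained <- logical(0)
    out$reasons <- character(0)
    return(out)
  }
  if (inherits(disorder_regions, "disorder_region_set")) {
    disorder_regions <- stats::setNames(list(disorder_regions),
                                        disorder_regions$protein_id)
  }
  cons <- normalize_conservation(conservation_reports)

  score_pass <- matches$site_probability < config$score_threshold |
    matches$motif_id %in% config$whitelist
  in_dis <- rep(NA, n)
  for (i in seq_len(n)) {
    set <- disorder_regions[[matches$protein_id[i]]]
    if (!is.null(set)) {
      in_dis[i] <- region_overlaps(matches$start[i], matches$end[i], set)
    }
  }
  frac <- rep(NA_real_, n)
  if (!is.null(cons) && nrow(cons)) {
    key <- paste(matches$protein_id, matches$motif_id, matches$start)
    ckey <- paste(cons$protein_id, cons$motif_id, cons$start)
    idx <- match(key, ckey)
    frac <- cons$conserved_fraction[idx]
  }

  verdict <- function(ok) ifelse(is.na(ok), "unknown", ifelse(ok, "yes", "no"))
  disorder_pass <- if (config$require_disorder) in_dis else rep(TRUE, n)
  cons_pass <- ifelse(is.na(frac), NA,
                      frac >= config$conservation_min_fraction)
  retained <- score_pass &
    (is.na(disorder_pass) | disorder_pass) &
    (is.na(cons_pass) | cons_pass)
  reasons <- vapply(seq_len(n), function(i) {
    r <- character(0)
    if (!score_pass[i]) r <- c(r, "score>=threshold")
    if (config$require_disorder && isFALSE(in_dis[i])) r <- c(r, "not-in-disorder")
    if (isFALSE(cons_pass[i])) r <- c(r, "not-conserved")
    if (is.na(in_dis[i]) && config$require_disorder) r <- c(r, "disorder-unknown")
    if (is.na(cons_pass[i])) r <- c(r, "conservation-unknown")
    if (!length(r)) r <- "retained"
    paste(r, collapse = ";")
  }, character(1))

  out$in_disorder <- in_dis
  out$conserved_fraction <- frac
  out$score_ok <- verdict(score_pass)
  out$disorder_ok <- if (config$require_disorder) verdict(in_dis) else "yes"
  out$conservation_ok <- verdict(cons_pass)
  out$retained <- retained
  out$reasons <- reasons
  out
}

normalize_conservation <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "conservation_report")) x <- list(x)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(r) {
    data.frame(protein_id = r$reference$protein_id, motif_id = r$motif_id,
               start = r$reference$start,
               conserved_fraction = r$conserved_fraction,
               stringsAsFactors = FALSE)
  }))
}

#' Write a candidate table as TSV
#'
#' @param candidates Output of [select_candidates()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
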