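#' Fold-index disorder profile
#'
#' A windowed hydropathy/charge surrogate for intrinsic disorder: for each
#' residue the score is `2.785 * <H> - |<R>| - 1.151`, where `<H>` is the
#' mean Kyte-Doolittle hydropathy rescaled to `[0, 1]` via `(KD + 4.5)/9`
#' and `<R>` the mean net charge (K, R: +1; D, E: -1; H: +0.5) over the
#' window centered on the residue. Windows are truncated (not padded) at
#' the termini. Scores below zero indicate disorder. This surrogate
#' replaces the external consensus predictors whose output can instead be
#' imported with [import_regions()].
#'
#' @param record A [protein_record].
#' @param window Odd window size, at least 3 (default 51).
#' @return An object of class `disorder_profile`: list with `protein_id`,
#'   `score` (one value per residue), `window`, `method`.
#' @export
foldindex_profile <- function(record, window = 51) {
  stopifnot(inherits(record, "protein_record"))
  if (window %% 2 == 0) stop("window must be odd, got ", window)
  if (window < 3) stop("window must be >= 3")
  if (record$length < 3) stop("sequence shorter than 3 residues")
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  h <- (KD_SCALE[chars] + 4.5) / 9
  r <- CHARGE_SCALE[chars]
  r[is.na(r)] <- 0
  half <- (window - 1L) %/% 2L
  score <- 2.785 * windowed_mean(h, half) - abs(windowed_mean(r, half)) - 1.151
  structure(list(protein_id = record$id, score = unname(score),
                 window = window, method = "foldindex-surrogate"),
            class = "disorder_profile")
}

# Mean over the window [i-half, i+half] intersected with [1, n].
windowed_mean <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call disorder regions from a profile
#'
#' Maximal runs of negative score of length at least `min_length`;
#' surviving runs separated by fewer than 3 residues are merged.
#'
#' @param profile A [foldindex_profile()] result.
#' @param min_length Minimum run length (default 5).
#' @return A `disorder_region_set`: list with `protein_id`, `intervals`
#'   (`data.frame` with `start`, `end`, sorted and non-overlapping),
#'   `source`.
#' @export
call_regions <- function(profile, min_length = 5) {
  stopifnot(inherits(profile, "disorder_profile"))
  runs <- rle(profile$score < 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_length
  intervals <- data.frame(start = starts[keep], end = ends[keep])
  region_set(profile$protein_id, merge_intervals(intervals, min_gap = 3L),
             source = profile$method)
}

region_set <- function(protein_id, intervals, source = "") {
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(protein_id = protein_id, intervals = intervals,
                 source = source),
            class = "disorder_region_set")
}

#' @export
print.disorder_region_set <- function(x, ...) {
  cat("<disorder_region_set> ", x$protein_id, ": ", nrow(x$intervals),
      " interval(s) [", x$source, "]\n", sep = "")
  invisible(x)
}

# Merge intervals whose gap is < min_gap (min_gap = 1 merges only
# overlapping/adjacent-at-0 intervals; IRanges handles the union).
merge_intervals <- function(intervals, min_gap = 1L) {
  if (!nrow(intervals)) return(data.frame(start = integer(0), end = integer(0)))
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start, intervals$end),
                        min.gapwidth = min_gap)
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

#' Import disorder regions from an annotation table
#'
#' Takes annotations in the [read_region_table()] schema (rows with label
#' `"disorder"`), unions overlapping intervals, and bounds-checks them
#' when the sequence length is known. External annotations take
#' precedence over the surrogate in the pipeline.
#'
#' @param annotations `data.frame` from [read_region_table()] (or
#'   compatible), or a list of [region_annotation] objects.
#' @param protein_id Keep only rows for this protein (default: the single
#'   protein present; an error if ambiguous).
#' @param seq_length Optional sequence length for bounds checking.
#' @return A `disorder_region_set`.
#' @export
import_regions <- function(annotations, protein_id = NULL, seq_length = NULL) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- do.call(rbind, lapply(annotations, function(a) {
      data.frame(protein_id = a$protein_id, label = a$label, start = a$start,
                 end = a$end, source = a$source, stringsAsFactors = FALSE)
    }))
  }
  tab <- annotations[annotations$label == "disorder", , drop = FALSE]
  if (is.null(protein_id)) {
    ids <- unique(tab$protein_id)
    if (length(ids) > 1L) stop("multiple proteins in table; give protein_id")
    protein_id <- if (length(ids)) ids else NA_character_
  } else {
    tab <- tab[tab$protein_id == protein_id, , drop = FALSE]
  }
  if (!is.null(seq_length) && nrow(tab)) {
    bad <- which(tab$start < 1L | tab$end > seq_length)
    if (length(bad)) {
      stop("disorder interval ", tab$start[bad[1]], "..", tab$end[bad[1]],
           " out of bounds (1..", seq_length, ")")
    }
  }
  src <- paste(unique(tab$source), collapse = "+")
  region_set(protein_id, merge_intervals(tab[, c("start", "end"), drop = FALSE]),
             source = if (nzchar(src)) src else "imported")
}

#' Union of two disorder region sets
#'
#' @param a,b `disorder_region_set` objects for the same protein.
#' @return A merged `disorder_region_set` (commutative).
#' @export
merge_region_sets <- function(a, b) {
  stopifnot(inherits(a, "disorder_region_set"),
            inherits(b, "disorder_region_set"))
  if (!identical(a$protein_id, b$protein_id)) {
    stop("cannot merge region sets of different proteins")
  }
  region_set(a$protein_id, merge_intervals(rbind(a$intervals, b$intervals)),
             source = paste(unique(c(a$source, b$source)), collapse = "+"))
}

#' Does an interval overlap a region set?
#'
#' Inclusive-bound overlap query: true when `[start, end]` shares at
#' least one residue with any interval of the set.
#'
#' @param start,end Query interval, 1-based inclusive.
#' @param set A `disorder_region_set`.
#' @return Logical scalar.
#' @examples
#' s <- sydescan:::region_set("p", data.frame(start = 10, end = 20))
#' region_overlaps(15, 16, s)  # TRUE
#' region_overlaps(21, 25, s)  # FALSE
#' @export
region_overlaps <- function(start, end, set) {
  stopifnot(inherits(set, "disorder_region_set"))
  if (!nrow(set$intervals)) return(FALSE)
  any(set$intervals$start <= end & set$intervals$end >= start)
}
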