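# Segment compositions for the family simulator. Disordered spans are
# enriched in E, S, P, K, Q, R and depleted in W, F, I, L, V (the
# compositional bias of intrinsically disordered regions); ordered spans
# use a globular, mildly hydrophobic composition. Both are normalized at
# use.
DISORDERED_COMPOSITION <- c(
  A = 0.055, C = 0.005, D = 0.050, E = 0.140, F = 0.004, G = 0.060,
  H = 0.010, I = 0.004, K = 0.120, L = 0.004, M = 0.005, N = 0.030,
  P = 0.120, Q = 0.100, R = 0.100, S = 0.140, T = 0.040, V = 0.004,
  W = 0.004, Y = 0.005)

ORDERED_COMPOSITION <- c(
  A = 0.120, C = 0.020, D = 0.025, E = 0.030, F = 0.060, G = 0.070,
  H = 0.015, I = 0.100, K = 0.030, L = 0.130, M = 0.040, N = 0.020,
  P = 0.015, Q = 0.020, R = 0.025, S = 0.040, T = 0.050, V = 0.110,
  W = 0.020, Y = 0.040)

#' Parameters for a synthetic ortholog family
#'
#' Defines the generative conditions for [simulate_family()]: a root
#' sequence with compositionally biased disordered spans, motif implants,
#' and per-site substitution when deriving orthologs. The defaults are
#' the package's reference study conditions: 8 orthologs of length 800
#' with two disordered spans, background substitution probability 0.2,
#' fully conserved implants (`q_motif = 0`), six conserved implants
#' inside disordered spans plus four decoy implants in ordered spans.
#'
#' @param n_orthologs Number of orthologs (the first is the unmutated
#'   root, used as the reference).
#' @param length Root sequence length.
#' @param disordered_spans `data.frame` with `start`, `end` (1-based
#'   inclusive, non-overlapping) of disordered segments.
#' @param implants `data.frame` with `motif_id`, `position`, `conserved`;
#'   implants must fall within bounds and not overlap.
#' @param q_bg Per-site substitution probability outside implants, in
#'   `[0, 1]`.
#' @param q_motif Per-site substitution probability inside conserved
#'   implants; must be `<= q_bg`.
#' @param indel_rate Reserved; only 0 (no indels) is supported, which
#'   keeps the trivial alignment exact.
#' @param seed Integer seed.
#' @return An object of class `family_params`.
#' @export
family_params <- function(n_orthologs = 8, length = 800,
                          disordered_spans = data.frame(
                            start = c(1L, 521L), end = c(260L, 660L)),
                          implants = default_implants(),
                          q_bg = 0.2, q_motif = 0, indel_rate = 0,
                          seed = 1) {
  stopifnot(n_orthologs >= 1, length >= 10,
            q_bg >= 0, q_bg <= 1, q_motif >= 0, q_motif <= 1)
  if (indel_rate != 0) stop("indels are not supported (indel_rate must be 0)")
  if (any(implants$conserved) && q_motif > q_bg) {
    stop("conserved implants require q_motif <= q_bg")
  }
  if (any(disordered_spans$start < 1 | disordered_spans$end > length |
          disordered_spans$start > disordered_spans$end)) {
    stop("disordered spans out of bounds")
  }
  structure(list(n_orthologs = as.integer(n_orthologs),
                 length = as.integer(length),
                 disordered_spans = disordered_spans,
                 implants = implants, q_bg = q_bg, q_motif = q_motif,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "family_params")
}

#' Default implant layout for the reference study conditions
#'
#' Six conserved implants placed in the disordered spans and four decoy
#' implants placed in the ordered spans (used to verify that the
#' disorder criterion rejects them).
#'
#' @return `data.frame` with `motif_id`, `position`, `conserved`,
#'   `in_disordered_span`.
#' @export
default_implants <- function() {
  data.frame(
    motif_id = c("LIG_LIR_Gen1", "DOC_PP2B_LxvP1", "LIG_14_3_3",
                 "DEG_SCF_FBW7", "DOC_PP4", "LIG_SH2_Grb2",
                 "DOC_Cyclin_RxL", "LIG_SH2_Crk_Nck", "LIG_WW3", "DOC_MAPK"),
    position = c(40L, 90L, 140L, 200L, 560L, 610L, 320L, 380L, 440L, 700L),
    conserved = rep(TRUE, 10),
    in_disordered_span = c(rep(TRUE, 6), rep(FALSE, 4)),
    stringsAsFactors = FALSE)
}

sample_residues <- function(n, composition) {
  composition <- composition / sum(composition)
  sample(names(composition), n, replace = TRUE, prob = composition)
}

# Sample a concrete peptide matching the class pattern: pick a length
# variant uniformly, then a residue uniformly from each position's
# allowed set.
sample_motif_peptide <- function(compiled) {
  v <- compiled$variants[[sample.int(length(compiled$variants), 1L)]]
  paste(vapply(seq_len(ncol(v)), function(j) {
    allowed <- AA20[v[, j]]
    if (!length(allowed)) stop("implant peptide cannot satisfy pattern")
    allowed[sample.int(length(allowed), 1L)]
  }, character(1)), collapse = "")
}

#' Simulate an ortholog family with implanted motifs and known truth
#'
#' Draws a root sequence with segment-specific composition (disordered
#' spans compositionally biased), overwrites the root with peptides
#' sampled to match each implant's class pattern, and derives orthologs
#' by per-site substitution: probability `q_bg` outside implants and
#' `q_motif` inside them, substitutions drawn from the segment's own
#' composition (excluding the current residue). Ortholog 1 is the
#' unmutated root and serves as the reference. Non-conserved implants
#' are disrupted in every non-reference ortholog by forcing the most
#' constrained motif position to a residue outside its allowed class.
#' The ground truth is recomputed from the emitted sequences (an implant
#' "survives" in an ortholog iff its class pattern still matches inside
#' the implant interval); matches of an implanted class elsewhere in the
#' reference are recorded as `incidental`.
#'
#' @param params A [family_params()] object.
#' @param catalog Motif catalog supplying the implant classes (default:
#'   packaged).
#' @return List with `records` (named list of [protein_record]s,
#'   ortholog 1 = reference), `msa` (the trivial alignment), and `truth`
#'   (list: `implants` data frame with per-implant coordinates and
#'   `survived_reference`, `survival` ortholog x implant matrix,
#'   `incidental` data frame, `disordered_spans`, `params`).
#' @export
simulate_family <- function(params, catalog = load_catalog()) {
  stopifnot(inherits(params, "family_params"))
  set.seed(params$seed)
  L <- params$length
  in_disorder <- rep(FALSE, L)
  for (i in seq_len(nrow(params$disordered_spans))) {
    in_disorder[params$disordered_spans$start[i]:
                params$disordered_spans$end[i]] <- TRUE
  }
  root <- character(L)
  root[in_disorder] <- sample_residues(sum(in_disorder),
                                       DISORDERED_COMPOSITION)
  root[!in_disorder] <- sample_residues(sum(!in_disorder),
                                        ORDERED_COMPOSITION)

  implants <- params$implants
  implants$peptide <- rep(NA_character_, nrow(implants))
  implants$start <- implants$position
  implants$end <- rep(NA_integer_, nrow(implants))
  variant_sets <- vector("list", nrow(implants))
  for (i in seq_len(nrow(implants))) {
    cl <- catalog$classes[[implants$motif_id[i]]]
    if (is.null(cl)) stop("unknown implant motif_id '",
                          implants$motif_id[i], "'")
    pep <- sample_motif_peptide(cl$compiled)
    start <- implants$position[i]
    end <- start + nchar(pep) - 1L
    if (start < 1 || end > L) stop("implant ", i, " out of bounds")
    implants$peptide[i] <- pep
    implants$end[i] <- end
    len <- nchar(pep)
    variant_sets[[i]] <- Filter(function(v) ncol(v) == len,
                                cl$compiled$variants)[[1]]
    root[start:end] <- strsplit(pep, "", fixed = TRUE)[[1]]
  }
  if (nrow(implants) >= 2) {
    ir <- IRanges::IRanges(implants$start, implants$end)
    if (any(IRanges::countOverlaps(ir, ir) > 1)) {
      stop("overlapping implants")
    }
  }
  in_implant <- rep(FALSE, L)
  for (i in seq_len(nrow(implants))) {
    in_implant[implants$start[i]:implants$end[i]] <- TRUE
  }

  mutate <- function(seq_chars) {
    q <- ifelse(in_implant, params$q_motif, params$q_bg)
    hit <- which(stats::runif(L) < q)
    for (pos in hit) {
      comp <- if (in_disorder[pos]) DISORDERED_COMPOSITION else
        ORDERED_COMPOSITION
      comp <- comp[names(comp) != seq_chars[pos]]
      seq_chars[pos] <- sample(names(comp), 1L, prob = comp / sum(comp))
    }
    seq_chars
  }
  disrupt <- function(seq_chars) {
    for (i in which(!implants$conserved)) {
      v <- variant_sets[[i]]
      j <- which.min(colSums(v))  # most constrained motif position
      outside <- AA20[!v[, j]]
      pos <- implants$start[i] + j - 1L
      seq_chars[pos] <- outside[sample.int(length(outside), 1L)]
    }
    seq_chars
  }

  ids <- sprintf("ortho%d", seq_len(params$n_orthologs))
  records <- vector("list", params$n_orthologs)
  records[[1]] <- protein_record(ids[1], paste(root, collapse = ""),
                                 species = "synthetic reference")
  for (k in seq_len(params$n_orthologs)[-1]) {
    chars <- disrupt(mutate(root))
    records[[k]] <- protein_record(ids[k], paste(chars, collapse = ""),
                                   species = "synthetic ortholog")
  }
  names(records) <- ids

  # Ground truth, recomputed from the emitted sequences.
  survival <- matrix(FALSE, params$n_orthologs, nrow(implants),
                     dimnames = list(ids, sprintf("implant%d",
                                                  seq_len(nrow(implants)))))
  for (k in seq_len(params$n_orthologs)) {
    for (i in seq_len(nrow(implants))) {
      cl <- catalog$classes[[implants$motif_id[i]]]
      window <- substr(records[[k]]$sequence, implants$start[i],
                       implants$end[i])
      code <- encode_sequence(window)
      survival[k, i] <- any(vapply(cl$compiled$variants, function(v)
        length(variant_matches(code, v)) > 0, logical(1)))
    }
  }
  implants$survived_reference <- survival[1, ]
  implants$true_conserved_fraction <- if (params$n_orthologs > 1) {
    colMeans(survival[-1, , drop = FALSE])
  } else NA_real_

  incidental <- list()
  for (mid in unique(implants$motif_id)) {
    cl <- catalog$classes[[mid]]
    hits <- scan_motifs(records[[1]], cl)
    for (h in seq_len(nrow(hits))) {
      overlaps_implant <- any(hits$start[h] <= implants$end &
                              hits$end[h] >= implants$start)
      if (!overlaps_implant) {
        incidental[[length(incidental) + 1L]] <-
          hits[h, c("motif_id", "start", "end", "peptide")]
      }
    }
  }
  incidental <- if (length(incidental)) do.call(rbind, incidental) else
    data.frame(motif_id = character(0), start = integer(0),
               end = integer(0), peptide = character(0))
  rownames(incidental) <- NULL

  msa <- as_msa(vapply(records, `[[`, character(1), "sequence"))
  list(records = records, msa = msa,
       truth = list(implants = implants, survival = survival,
                    incidental = incidental,
                    disordered_spans = params$disordered_spans,
                    params = params))
}

#' Precision and recall of pipeline candidates against generator truth
#'
#' A retained candidate is a true positive iff it overlaps an implant of
#' the same motif class that survived in the reference; retained
#' candidates overlapping only an `incidental` match of their class
#' (a spontaneous background match) count as neither true nor false
#' positives. Recall is computed over implants that survived in the
#' reference. When no positives are predicted, precision is reported as
#' `NaN` with `precision_defined = FALSE`.
#'
#' @param candidates Candidate table from [select_candidates()].
#' @param truth The `truth` element of [simulate_family()].
#' @return List with `per_class` and `overall` data frames and
#'   `precision_defined`.
#' @export
evaluate_recovery <- function(candidates, truth) {
  kept <- candidates[isTRUE_vec(candidates$retained), , drop = FALSE]
  implants <- truth$implants
  classes <- unique(implants$motif_id)
  per <- lapply(classes, function(mid) {
    imp <- implants[implants$motif_id == mid & implants$survived_reference, ,
                    drop = FALSE]
    cand <- kept[kept$motif_id == mid, , drop = FALSE]
    inc <- truth$incidental[truth$incidental$motif_id == mid, , drop = FALSE]
    hit_implant <- logical(nrow(imp))
    tp <- 0L; fp <- 0L
    for (i in seq_len(nrow(cand))) {
      ov_imp <- which(cand$start[i] <= imp$end & cand$end[i] >= imp$start)
      if (length(ov_imp)) {
        tp <- tp + 1L
        hit_implant[ov_imp] <- TRUE
      } else {
        ov_inc <- any(cand$start[i] <= inc$end & cand$end[i] >= inc$start)
        if (!ov_inc) fp <- fp + 1L
      }
    }
    fn <- sum(!hit_implant)
    data.frame(motif_id = mid, tp = tp, fp = fp, fn = fn,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  recall <- if (tp + fn > 0) tp / (tp + fn) else NaN
  per$precision <- ifelse(per$tp + per$fp > 0, per$tp / (per$tp + per$fp), NaN)
  per$recall <- ifelse(per$tp + per$fn > 0, per$tp / (per$tp + per$fn), NaN)
  list(per_class = per,
       overall = data.frame(tp = tp, fp = fp, fn = fn,
                            precision = precision, recall = recall),
       precision_defined = tp + fp > 0)
}
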