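#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch global alignment (affine gap penalties: a gap
#' of length k costs `gap_open + k * gap_extend`), computed with
#' Biostrings. Residues unknown to the substitution matrix (`X`) are
#' scored as 0 against everything, with a warning.
#'
#' @param a,b Sequences as [protein_record]s or plain strings.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (default 10 and 0.5).
#' @return An object of class `pairwise_alignment`: list with `a_gapped`,
#'   `b_gapped`, `score`, `matrix`, `gap_open`, `gap_extend`, `ids`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  ida <- if (inherits(a, "protein_record")) a$id else "a"
  idb <- if (inherits(b, "protein_record")) b$id else "b"
  sa <- toupper(if (inherits(a, "protein_record")) a$sequence else a)
  sb <- toupper(if (inherits(b, "protein_record")) b$sequence else b)
  if (!nzchar(sa) || !nzchar(sb)) stop("both sequences must be non-empty")
  mat <- substitution_matrix(matrix)
  unknown <- setdiff(unique(strsplit(paste0(sa, sb), "")[[1]]), rownames(mat))
  if (length(unknown) || (grepl("X", sa, fixed = TRUE) ||
                          grepl("X", sb, fixed = TRUE))) {
    warning("residues outside the substitution matrix scored as 0 mismatch")
    for (ch in union(unknown, "X")) {
      if (!ch %in% rownames(mat)) {
        mat <- rbind(cbind(mat, 0), 0)
        rownames(mat)[nrow(mat)] <- colnames(mat)[ncol(mat)] <- ch
      } else {
        mat[ch, ] <- 0; mat[, ch] <- 0
      }
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  structure(list(a_gapped = as.character(Biostrings::alignedPattern(pa)),
                 b_gapped = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa),
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, ids = c(ida, idb)),
            class = "pairwise_alignment")
}

substitution_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$ids[1], " vs ", x$ids[2], ", score ",
      format(x$score), ", ", nchar(x$a_gapped), " columns\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' `100 * identical columns / total alignment columns`, reported to 0.1.
#' This is the operational reading of the published domain "homology"
#' percentages; whether those were identity or similarity is not stated,
#' hence the tolerance used wherever this number is compared.
#'
#' @param aln A [global_align()] result.
#' @return Percentage in `[0, 100]`, rounded to one decimal.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  a <- strsplit(aln$a_gapped, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$b_gapped, "", fixed = TRUE)[[1]]
  round(100 * sum(a == b & a != "-") / length(a), 1)
}

#' Construct a multiple alignment object
#'
#' @param gapped Named character vector of equal-length gapped sequences
#'   (gap character `-`).
#' @return An object of class `msa`.
#' @export
as_msa <- function(gapped) {
  stopifnot(is.character(gapped), !is.null(names(gapped)),
            all(nzchar(names(gapped))))
  gapped <- toupper(gsub(".", "-", gapped, fixed = TRUE))
  widths <- nchar(gapped)
  if (length(unique(widths)) != 1L) {
    stop("gapped sequences have unequal lengths")
  }
  rows <- do.call(rbind, strsplit(gapped, "", fixed = TRUE))
  if (any(colSums(rows != "-") == 0)) {
    stop("alignment has an all-gap column")
  }
  structure(list(gapped = gapped, n_columns = unname(widths[1])), class = "msa")
}

#' Read an aligned FASTA file
#' @param path Path to aligned FASTA (gap character `-` or `.`).
#' @return An [as_msa()] object.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no sequences in ", path)
  gapped <- stats::setNames(as.character(set),
                            vapply(names(set), function(h)
                              parse_fasta_header(h)$id, character(1)))
  as_msa(gapped)
}

#' Write a multiple alignment as aligned FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  lines <- unlist(lapply(names(msa$gapped), function(id) {
    s <- msa$gapped[[id]]
    starts <- seq(1L, nchar(s), by = 60L)
    c(paste0(">", id), substring(s, starts, pmin(starts + 59L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Map a residue position to its alignment column
#'
#' Residue positions (1-based, ungapped) and non-gap alignment columns
#' are in bijection; [map_column()] is the inverse.
#'
#' @param msa An `msa` object.
#' @param seq_id Sequence id in the alignment.
#' @param residue_pos 1-based residue position.
#' @return Column index.
#' @export
map_position <- function(msa, seq_id, residue_pos) {
  row <- msa_row(msa, seq_id)
  nongap <- which(row != "-")
  if (residue_pos < 1 || residue_pos > length(nongap)) {
    stop("residue position ", residue_pos, " beyond ungapped length ",
         length(nongap), " of '", seq_id, "'")
  }
  nongap[residue_pos]
}

#' Map an alignment column back to a residue position
#'
#' @param msa An `msa` object.
#' @param seq_id Sequence id in the alignment.
#' @param column Column index holding a residue of `seq_id`.
#' @return 1-based residue position.
#' @export
map_column <- function(msa, seq_id, column) {
  row <- msa_row(msa, seq_id)
  if (column < 1 || column > length(row)) {
    stop("column ", column, " outside alignment (1..", length(row), ")")
  }
  if (row[column] == "-") {
    stop("column ", column, " is a gap in '", seq_id, "'")
  }
  sum(row[seq_len(column)] != "-")
}

msa_row <- function(msa, seq_id) {
  stopifnot(inherits(msa, "msa"))
  if (!seq_id %in% names(msa$gapped)) {
    stop("sequence '", seq_id, "' not in alignment")
  }
  strsplit(msa$gapped[[seq_id]], "", fixed = TRUE)[[1]]
}

#' Ortholog conservation of a motif match
#'
#' Maps a reference match through the alignment: the reference interval's
#' columns are widened by `slack` columns on both sides, the ungapped
#' residues that each ortholog carries in that column window are
#' extracted, and the ortholog counts as conserved iff the class pattern
#' matches inside that window. The conserved fraction is computed over
#' the orthologs assessed (all sequences except the reference).
#'
#' @param msa An `msa` containing the reference sequence.
#' @param reference_match List (or one-row `data.frame`) with
#'   `protein_id`, `start`, `end` of the match in reference coordinates.
#' @param motif A `motif_class` (or list with `motif_id` and `pattern`).
#' @param slack Column slack (default 5).
#' @return An object of class `conservation_report`: list with
#'   `motif_id`, `reference`, `per_ortholog` (`data.frame` of `id`,
#'   `conserved`, `window_peptide`), `conserved_fraction`.
#' @export
motif_conservation <- function(msa, reference_match, motif, slack = 5) {
  stopifnot(inherits(msa, "msa"))
  ref_id <- reference_match$protein_id
  c1 <- map_position(msa, ref_id, reference_match$start)
  c2 <- map_position(msa, ref_id, reference_match$end)
  lo <- max(1L, c1 - slack)
  hi <- min(msa$n_columns, c2 + slack)
  compiled <- motif$compiled %||% compile_motif_pattern(motif$pattern)
  others <- setdiff(names(msa$gapped), ref_id)
  verdicts <- lapply(others, function(id) {
    row <- msa_row(msa, id)
    window <- paste(row[lo:hi][row[lo:hi] != "-"], collapse = "")
    conserved <- FALSE
    if (nzchar(window)) {
      code <- encode_sequence(window)
      conserved <- any(vapply(compiled$variants, function(v)
        length(variant_matches(code, v)) > 0, logical(1)))
    }
    data.frame(id = id, conserved = conserved, window_peptide = window,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, verdicts) %||%
    data.frame(id = character(0), conserved = logical(0),
               window_peptide = character(0))
  structure(list(motif_id = motif$motif_id %||% NA_character_,
                 reference = list(protein_id = ref_id,
                                  start = reference_match$start,
                                  end = reference_match$end),
                 per_ortholog = per,
                 conserved_fraction = if (nrow(per)) mean(per$conserved)
                                      else NA_real_),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("<conservation_report> ", x$motif_id, " @ ", x$reference$protein_id,
      ":", x$reference$start, "-", x$reference$end, ", conserved fraction ",
      format(x$conserved_fraction), " (", sum(x$per_ortholog$conserved), "/",
      nrow(x$per_ortholog), ")\n", sep = "")
  invisible(x)
}

#' Star-progressive multiple alignment
#'
#' Builds a multiple alignment by aligning every sequence pairwise to a
#' center sequence with [global_align()] and merging the pairwise gap
#' patterns into a common coordinate frame. Adequate for mapping motifs
#' across closely related orthologs (the intended use); a dedicated MSA
#' tool should be preferred for distant sequences.
#'
#' @param records Named list of [protein_record]s.
#' @param center_id Id of the center (reference) sequence.
#' @param ... Passed to [global_align()].
#' @return An `msa` object.
#' @export
star_align <- function(records, center_id, ...) {
  stopifnot(center_id %in% names(records))
  center <- records[[center_id]]
  others <- records[names(records) != center_id]
  if (!length(others)) {
    return(as_msa(stats::setNames(center$sequence, center_id)))
  }
  pairs <- lapply(others, function(r) global_align(center, r, ...))
  L <- center$length
  # Common frame: L aligned positions interleaved with L + 1 insertion
  # slots (slot i holds residues inserted after center residue i).
  # cell index: insertion slot i -> 2*i + 1; aligned position i -> 2*i.
  layouts <- lapply(pairs, function(p) {
    a <- strsplit(p$a_gapped, "", fixed = TRUE)[[1]]
    b <- strsplit(p$b_gapped, "", fixed = TRUE)[[1]]
    pos <- cumsum(a != "-")
    list(is_ins = a == "-", pos = pos, b = b)
  })
  ins <- integer(L + 1L)   # widest insertion seen per slot
  for (lay in layouts) {
    runs <- table(lay$pos[lay$is_ins])
    if (length(runs)) {
      idx <- as.integer(names(runs)) + 1L
      ins[idx] <- pmax(ins[idx], as.integer(runs))
    }
  }
  new_cells <- function() {
    cells <- vector("list", 2L * L + 1L)
    for (i in 0:L) cells[[2L * i + 1L]] <- rep("-", ins[i + 1L])
    for (i in seq_len(L)) cells[[2L * i]] <- "-"
    cells
  }
  out <- list()
  cells <- new_cells()
  center_chars <- strsplit(center$sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(L)) cells[[2L * i]] <- center_chars[i]
  out[[center_id]] <- paste(unlist(cells), collapse = "")
  for (k in seq_along(layouts)) {
    lay <- layouts[[k]]
    cells <- new_cells()
    used <- integer(L + 1L)
    for (j in seq_along(lay$b)) {
      if (lay$is_ins[j]) {
        slot <- lay$pos[j] + 1L
        used[slot] <- used[slot] + 1L
        cells[[2L * lay$pos[j] + 1L]][used[slot]] <- lay$b[j]
      } else {
        cells[[2L * lay$pos[j]]] <- lay$b[j]
      }
    }
    out[[names(layouts)[k]]] <- paste(unlist(cells), collapse = "")
  }
  as_msa(unlist(out))
}

#' Pairwise domain identity report
#'
#' Computes [percent_identity()] of [global_align()]ed domain regions for
#' every protein pair sharing a domain label in the boundary table. The
#' boundary table is an input (e.g. InterProScan-derived), never
#' computed.
#'
#' @param records Named list of [protein_record]s (names matching
#'   `protein_id` in `boundaries`).
#' @param boundaries `data.frame` in the [read_region_table()] schema
#'   with domain labels (e.g. `"RhoGAP"`, `"C2"`).
#' @param ... Passed to [global_align()].
#' @return `data.frame` with `label`, `protein_a`, `protein_b`,
#'   `percent_identity`, `columns`.
#' @export
domain_identity_report <- function(records, boundaries, ...) {
  out <- list()
  for (label in unique(boundaries$label)) {
    rows <- boundaries[boundaries$label == label, , drop = FALSE]
    rows <- rows[rows$protein_id %in% names(records), , drop = FALSE]
    ids <- rows$protein_id
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        ra <- records[[ids[i]]]; rb <- records[[ids[j]]]
        seg_a <- extract_region(ra, rows[i, ])
        seg_b <- extract_region(rb, rows[j, ])
        aln <- global_align(seg_a, seg_b, ...)
        out[[length(out) + 1L]] <- data.frame(
          label = label, protein_a = ids[i], protein_b = ids[j],
          percent_identity = percent_identity(aln),
          columns = nchar(aln$a_gapped), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out) %||%
    data.frame(label = character(0), protein_a = character(0),
               protein_b = character(0), percent_identity = numeric(0),
               columns = integer(0))
}
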