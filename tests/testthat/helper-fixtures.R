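# Shared fixtures and independent oracles. Oracles are deliberately
# naive (position-by-position loops, enumeration, recursion) and never
# call the implementation paths they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_record <- function(i, n = sample(20:80, 1)) {
  protein_record(
    id = sprintf("REC%02d_TEST", i),
    sequence = random_sequence(n),
    accession = if (i %% 2 == 0) sprintf("P%05d", i) else "",
    species = if (i %% 3 == 0) "Homo sapiens" else ""
  )
}

# Brute-force substring finder (oracle for locate_peptide).
naive_locate <- function(sequence, peptide) {
  n <- nchar(sequence); m <- nchar(peptide)
  hits <- integer(0)
  if (m > n) return(hits)
  for (i in 1:(n - m + 1)) {
    if (substr(sequence, i, i + m - 1) == peptide) hits <- c(hits, i)
  }
  hits
}

# Brute-force motif matcher (oracle for scan_motifs): tries the class
# pattern as a plain anchored regex at every start and every length.
naive_scan <- function(sequence, pattern) {
  variants <- sydescan::compile_motif_pattern(pattern)$variants
  n <- nchar(sequence)
  out <- list()
  for (start in seq_len(n)) {
    for (v in variants) {
      L <- ncol(v)
      if (start + L - 1 > n) next
      chars <- strsplit(substr(sequence, start, start + L - 1), "")[[1]]
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!chars[j] %in% rownames(v)[v[, j]]) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1]] <- c(start = start, end = start + L - 1)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- unique(as.data.frame(do.call(rbind, out)))
  df[order(df$start, df$end), , drop = FALSE]
}

# Memoized state-machine recursion for optimal global alignment score
# with affine gaps (gap of length k costs open + k * ext). Independent
# of the Biostrings dynamic program used by global_align().
oracle_align_score <- function(a, b, open = 10, ext = 0.5) {
  mat <- local({
    env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
    get("BLOSUM62", envir = env)
  })
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  memo <- new.env(hash = TRUE)
  # state: 0 = last move was a match/mismatch, 1 = gap in b, 2 = gap in a
  best <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i > na && j > nb) {
      0
    } else {
      cand <- -Inf
      if (i <= na && j <= nb) {
        cand <- max(cand, mat[ca[i], cb[j]] + best(i + 1, j + 1, 0))
      }
      if (i <= na) {  # ca[i] against a gap
        pen <- ext + if (state == 1) 0 else open
        cand <- max(cand, -pen + best(i + 1, j, 1))
      }
      if (j <= nb) {
        pen <- ext + if (state == 2) 0 else open
        cand <- max(cand, -pen + best(i, j + 1, 2))
      }
      cand
    }
    memo[[key]] <- val
    val
  }
  best(1, 1, 0)
}

# A random tree with known positive branch lengths and its induced
# (additive) leaf-to-leaf distance matrix; oracle input for NJ.
random_additive_case <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(n) runif(n, 0.5, 2))
  tree$tip.label <- sprintf("T%02d", seq_len(n_taxa))
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = ape::unroot(tree), d = d)
}

tiny_catalog_yaml <- function(path) {
  writeLines(c(
    "version: 99",
    "classes:",
    "- motif_id: TOY_A",
    "  pattern: \"W..L\"",
    "  interactor: ToyA",
    "  kind: ligand-site",
    "  instances:",
    "  - {protein_id: P1, start: 2, end: 5, peptide: WAAL}",
    "- motif_id: TOY_B",
    "  pattern: \"[ST]P\"",
    "  interactor: ToyB",
    "  kind: modification-site",
    "  whitelisted: true",
    "  instances:",
    "  - {protein_id: P1, start: 7, end: 8, peptide: SP}"
  ), path)
  path
}
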