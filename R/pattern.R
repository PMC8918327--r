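#' Background amino-acid frequencies
#'
#' Returns the background model used to score motif classes: a named
#' probability vector over the 20 standard residues. The packaged default
#' is a SwissProt-like composition; a custom model may be supplied as a
#' named numeric vector or as a two-column TSV (`residue`, `frequency`).
#' Frequencies are normalized to sum to one; all must be positive.
#'
#' @param x `NULL` for the packaged default, a named numeric vector, or a
#'   path to a TSV file.
#' @return Named numeric vector over [AA20] summing to 1, of class
#'   `background_frequencies`.
#' @export
background_frequencies <- function(x = NULL) {
  if (is.null(x)) {
    freq <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37,
              Q = 3.93, E = 6.75, G = 7.07, H = 2.27, I = 5.96,
              L = 9.66, K = 5.84, M = 2.42, F = 3.86, P = 4.74,
              S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87)
  } else if (is.character(x) && length(x) == 1L) {
    tab <- utils::read.delim(x, stringsAsFactors = FALSE)
    freq <- stats::setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
  } else if (is.numeric(x) && !is.null(names(x))) {
    freq <- x
  } else {
    stop("background frequencies must be NULL, a named vector, or a TSV path")
  }
  missing <- setdiff(AA20, names(freq))
  if (length(missing)) {
    stop("background frequencies missing residue(s): ",
         paste(missing, collapse = ", "))
  }
  freq <- freq[AA20]
  if (any(!is.finite(freq)) || any(freq <= 0)) {
    stop("background frequencies must all be positive")
  }
  freq <- freq / sum(freq)
  structure(freq, class = c("background_frequencies", "numeric"))
}

#' Uniform background over the 20 residues
#' @return A [background_frequencies] object with every mass 0.05.
#' @export
uniform_background <- function() {
  background_frequencies(stats::setNames(rep(1, 20), AA20))
}

parse_residue_class <- function(body) {
  negate <- startsWith(body, "^")
  if (negate) body <- substring(body, 2)
  residues <- strsplit(body, "", fixed = TRUE)[[1]]
  bad <- setdiff(residues, AA20)
  if (length(bad)) {
    stop("unknown residue '", bad[1], "' in class [", body, "]")
  }
  set <- AA20 %in% residues
  if (negate) set <- !set
  if (!any(set)) stop("empty residue class [", body, "]")
  stats::setNames(set, AA20)
}

#' Compile a motif pattern into fixed-length variants
#'
#' Motif patterns are a restricted regular-expression dialect over the
#' amino-acid alphabet: literal residues, `.` (any of the 20 residues),
#' residue classes `[KR]` and negated classes `[^P]`, and *bounded*
#' quantifiers `{m}`, `{m,n}` or `?` on the previous element. Unbounded
#' repetition (`*`, `+`, `{m,}`) is rejected, which guarantees that every
#' pattern expands into a finite alternation of fixed-length residue-class
#' strings -- the form required by the scanner and by
#' [site_probability()]. `X` in a sequence never matches any class.
#'
#' @param pattern Pattern string.
#' @return An object of class `motif_pattern` with elements `pattern` and
#'   `variants` (a list of 20 x L logical membership matrices, ordered by
#'   increasing length).
#' @examples
#' p <- compile_motif_pattern("[RK].L.{0,1}[FYLIVMP]")
#' lengths <- vapply(p$variants, ncol, integer(1))  # 4 5
#' @export
compile_motif_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("*", "+")) {
      stop("unbounded repetition '", ch, "' in pattern '", pattern, "'")
    }
    if (ch == ".") {
      set <- stats::setNames(rep(TRUE, 20), AA20)
      i <- i + 1L
    } else if (ch == "[") {
      close <- i + which(chars[(i + 1):n] == "]")[1]
      if (is.na(close)) stop("unterminated class in pattern '", pattern, "'")
      set <- parse_residue_class(paste(chars[(i + 1):(close - 1)], collapse = ""))
      i <- close + 1L
    } else if (ch %in% AA20) {
      set <- stats::setNames(AA20 == ch, AA20)
      i <- i + 1L
    } else {
      stop("unsupported pattern element '", ch, "' in '", pattern, "'")
    }
    lo <- 1L; hi <- 1L
    if (i <= n && chars[i] == "?") {
      lo <- 0L; i <- i + 1L
    } else if (i <= n && chars[i] == "{") {
      close <- i + which(chars[(i + 1):n] == "}")[1]
      if (is.na(close)) stop("unterminated quantifier in pattern '", pattern, "'")
      body <- paste(chars[(i + 1):(close - 1)], collapse = "")
      if (grepl("^[0-9]+$", body)) {
        lo <- hi <- as.integer(body)
      } else if (grepl("^[0-9]+,[0-9]+$", body)) {
        parts <- as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
        lo <- parts[1]; hi <- parts[2]
        if (lo > hi) stop("invalid quantifier {", body, "}")
      } else {
        stop("unbounded or malformed quantifier {", body,
             "} in pattern '", pattern, "'")
      }
      i <- close + 1L
    }
    tokens[[length(tokens) + 1L]] <- list(set = set, lo = lo, hi = hi)
  }
  counts <- lapply(tokens, function(t) t$lo:t$hi)
  n_variants <- prod(vapply(counts, length, integer(1)))
  if (n_variants > 256) stop("pattern '", pattern, "' expands to too many variants")
  grid <- expand.grid(rev(counts))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  variants <- lapply(seq_len(nrow(grid)), function(k) {
    reps <- as.integer(grid[k, ])
    cols <- unlist(lapply(seq_along(tokens), function(j) {
      rep(list(tokens[[j]]$set), reps[j])
    }), recursive = FALSE)
    if (!length(cols)) return(NULL)
    m <- do.call(cbind, cols)
    rownames(m) <- AA20
    m
  })
  variants <- Filter(Negate(is.null), variants)
  if (!length(variants)) stop("pattern '", pattern, "' matches only the empty string")
  lens <- vapply(variants, ncol, integer(1))
  variants <- variants[order(lens)]
  structure(list(pattern = pattern, variants = variants),
            class = "motif_pattern")
}

encode_sequence <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], AA20)
}

# All (start, end) matches of one fixed-length variant in an encoded
# sequence; X encodes as NA and never matches.
variant_matches <- function(code, variant) {
  L <- ncol(variant)
  n <- length(code)
  if (L > n) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    v <- variant[, j][code[j:(j + n - L)]]
    v[is.na(v)] <- FALSE
    ok <- ok & v
  }
  which(ok)
}

#' Scan a sequence with one motif class
#'
#' Reports *all* matches of the class pattern, overlapping matches
#' included, ordered by ascending start and, at equal start, by ascending
#' length. Coordinates are 1-based inclusive. The class-level background
#' match probability is attached to every row (it is a property of the
#' pattern, not of the individual hit).
#'
#' @param record A [protein_record].
#' @param motif A `motif_class` (see [load_catalog()]), or any list with
#'   fields `motif_id` and `pattern`.
#' @param bg Background model for the attached probability
#'   (default [background_frequencies()]).
#' @return A `data.frame` with columns `protein_id`, `motif_id`, `start`,
#'   `end`, `peptide`, `site_probability`, `in_disorder`,
#'   `conserved_fraction`. Zero rows when there is no match.
#' @export
scan_motifs <- function(record, motif, bg = background_frequencies()) {
  stopifnot(inherits(record, "protein_record"))
  compiled <- motif$compiled %||% compile_motif_pattern(motif$pattern)
  code <- encode_sequence(record$sequence)
  hits <- do.call(rbind, lapply(compiled$variants, function(v) {
    starts <- variant_matches(code, v)
    if (!length(starts)) return(NULL)
    data.frame(start = starts, end = starts + ncol(v) - 1L)
  }))
  prob <- site_probability(motif, bg)
  if (is.null(hits)) {
    return(data.frame(protein_id = character(0), motif_id = character(0),
                      start = integer(0), end = integer(0),
                      peptide = character(0), site_probability = numeric(0),
                      in_disorder = logical(0), conserved_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  hits <- unique(hits)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  data.frame(protein_id = record$id, motif_id = motif$motif_id,
             start = hits$start, end = hits$end,
             peptide = substring(record$sequence, hits$start, hits$end),
             site_probability = prob, in_disorder = NA,
             conserved_fraction = NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a sequence with every class of a catalog
#'
#' @param record A [protein_record].
#' @param catalog A motif catalog from [load_catalog()].
#' @param bg Background model (default [background_frequencies()]).
#' @return Row-bound [scan_motifs()] results for all classes.
#' @export
scan_catalog <- function(record, catalog, bg = background_frequencies()) {
  out <- do.call(rbind, lapply(catalog$classes, scan_motifs,
                               record = record, bg = bg))
  rownames(out) <- NULL
  out
}

#' Background probability that a position starts a motif match
#'
#' The probability that a random sequence position begins a match of the
#' class pattern under the background model: the sum, over the pattern's
#' fixed-length variants, of the product over variant positions of the
#' background mass of the allowed residue set. This is the package's
#' internal analogue of a motif probability score; it does not reproduce
#' any external resource's numbers.
#'
#' @param motif A `motif_class` or list with a `pattern` field (a
#'   pre-compiled `motif_pattern` is also accepted).
#' @param bg A [background_frequencies] model.
#' @return A probability in (0, 1].
#' @examples
#' site_probability(list(pattern = "[ST]P"), uniform_background())  # 0.005
#' @export
site_probability <- function(motif, bg = background_frequencies()) {
  compiled <- if (inherits(motif, "motif_pattern")) motif else {
    motif$compiled %||% compile_motif_pattern(motif$pattern)
  }
  bg <- if (inherits(bg, "background_frequencies")) bg else background_frequencies(bg)
  p <- sum(vapply(compiled$variants, function(v) {
    prod(colSums(v * as.numeric(bg)))
  }, numeric(1)))
  min(p, 1)
}
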