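#' Corrected protein distance between two aligned sequences
#'
#' From two gapped strings of equal length: `p` is the mismatch fraction
#' over columns where both sequences carry a residue, and the distance is
#' the Kimura-style correction `d = -ln(1 - p - 0.2 p^2)`. Saturated
#' pairs (`1 - p - 0.2 p^2 <= 0`) are capped at 10 with a warning.
#'
#' @param gapped_a,gapped_b Gapped sequences (equal length, gap `-`).
#' @return Non-negative distance.
#' @examples
#' protein_distance("ACDE", "ACDE")  # 0
#' @export
protein_distance <- function(gapped_a, gapped_b) {
  a <- strsplit(toupper(gapped_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(gapped_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  shared <- a != "-" & b != "-"
  if (!any(shared)) stop("no shared ungapped columns")
  p <- mean(a[shared] != b[shared])
  arg <- 1 - p - 0.2 * p^2
  if (arg <= 0) {
    warning("saturated distance (p = ", format(p), "); capped at 10")
    return(10)
  }
  -log(arg)
}

#' Pairwise distance matrix of a multiple alignment
#'
#' @param msa An `msa` object.
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
distance_matrix <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  ids <- names(msa$gapped)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- protein_distance(msa$gapped[[i]],
                                               msa$gapped[[j]])
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration on a labelled distance matrix,
#' with a deterministic tie-break: when several pairs minimize the Q
#' criterion, the pair whose (lexicographically sorted) cluster labels
#' are smallest is joined; a cluster is labelled by its smallest member
#' leaf. Negative branch-length estimates are clamped to zero and counted
#' in the `clamped` attribute. With two taxa the degenerate tree splits
#' the distance evenly across the two pendant branches.
#'
#' @param d Symmetric distance matrix with labels (or `dist`).
#' @return An [ape::read.tree] `phylo` object (unrooted; trifurcating
#'   root for more than three taxa).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 taxa")
  clamped <- 0L
  bl <- function(x) {  # clamp negative NJ estimates
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  # build the Newick text with placeholder tip labels so metacharacters
  # in taxa names cannot break the parse; restore labels afterwards
  placeholder <- stats::setNames(sprintf("t%d", seq_along(labels)), labels)
  frag <- stats::setNames(placeholder, labels)
  key <- stats::setNames(labels, labels)  # smallest member leaf per cluster
  active <- labels
  D <- d
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D[active, active])
    best <- NULL
    best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        a <- active[i]; b <- active[j]
        q <- (m - 2) * D[a, b] - r[a] - r[b]
        pair_key <- sort(c(key[a], key[b]))
        if (q < best_q - 1e-12 ||
            (abs(q - best_q) <= 1e-12 && !is.null(best) &&
             (pair_key[1] < best$pk[1] ||
              (pair_key[1] == best$pk[1] && pair_key[2] < best$pk[2])))) {
          best <- list(a = a, b = b, pk = pair_key)
          best_q <- min(best_q, q)
        }
      }
    }
    a <- best$a; b <- best$b
    va <- bl(0.5 * D[a, b] + (r[a] - r[b]) / (2 * (m - 2)))
    vb <- bl(D[a, b] - (0.5 * D[a, b] + (r[a] - r[b]) / (2 * (m - 2))))
    u <- paste0(".node", length(active))
    others <- setdiff(active, c(a, b))
    Du <- stats::setNames(0.5 * (D[a, others] + D[b, others] - D[a, b]),
                          others)
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- u
    D[u, others] <- D[others, u] <- Du
    frag[u] <- paste0("(", frag[a], ":", format_bl(va), ",",
                      frag[b], ":", format_bl(vb), ")")
    key[u] <- min(key[a], key[b])
    active <- c(others, u)
  }
  if (length(active) == 2L) {
    a <- active[1]; b <- active[2]
    half <- bl(D[a, b] / 2)
    text <- paste0("(", frag[a], ":", format_bl(half), ",",
                   frag[b], ":", format_bl(half), ");")
  } else {
    a <- active[1]; b <- active[2]; c3 <- active[3]
    xa <- bl((D[a, b] + D[a, c3] - D[b, c3]) / 2)
    xb <- bl((D[a, b] + D[b, c3] - D[a, c3]) / 2)
    xc <- bl((D[a, c3] + D[b, c3] - D[a, b]) / 2)
    text <- paste0("(", frag[a], ":", format_bl(xa), ",",
                   frag[b], ":", format_bl(xb), ",",
                   frag[c3], ":", format_bl(xc), ");")
  }
  tree <- ape::read.tree(text = text)
  tree$tip.label <- labels[match(tree$tip.label, placeholder)]
  attr(tree, "clamped") <- clamped
  tree
}

format_bl <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

#' Neighbor-joining tree with column-bootstrap supports
#'
#' Builds the full-data NJ tree ([distance_matrix()] +
#' [neighbor_joining()]), then resamples alignment columns with
#' replacement `n_replicates` times, rebuilds the tree per replicate, and
#' reports for each internal bipartition of the full-data tree the
#' percentage of replicates containing it (stored in `node.label`).
#' Column resampling depends only on the seed and the column count, so
#' supports are invariant to taxa order.
#'
#' @param msa An `msa` object.
#' @param n_replicates Number of bootstrap replicates (default 500).
#' @param seed Integer seed (required, for reproducibility).
#' @return The full-data `phylo` tree with `node.label` set to supports
#'   (0-100; the root label is empty) and attribute `replicates`.
#' @export
bootstrap_supports <- function(msa, n_replicates = 500, seed) {
  stopifnot(inherits(msa, "msa"))
  if (missing(seed)) stop("a seed is required for bootstrap reproducibility")
  full <- neighbor_joining(distance_matrix(msa))
  nc <- msa$n_columns
  rows <- do.call(rbind, strsplit(msa$gapped, "", fixed = TRUE))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  reps <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    sub <- rows[, idx, drop = FALSE]
    gapped <- stats::setNames(apply(sub, 1, paste, collapse = ""),
                              names(msa$gapped))
    m <- tryCatch(as_msa(gapped), error = function(e) NULL)
    if (is.null(m)) { reps[[k]] <- NULL; next }  # all-gap column resample
    reps[[k]] <- tryCatch(neighbor_joining(distance_matrix(m)),
                          error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- round(100 * counts / length(reps))
  labels <- as.character(supports)
  labels[1] <- ""  # root pseudo-bipartition is not informative
  full$node.label <- labels
  attr(full, "supports") <- supports
  attr(full, "replicates") <- length(reps)
  full
}

quote_newick_label <- function(label) {
  needs <- grepl("[][(),:;'\"\\s]", label, perl = TRUE)
  out <- label
  out[needs] <- paste0("'", gsub("'", "''", label[needs]), "'")
  out
}

#' Write a tree in Newick format
#'
#' Serializes a `phylo` tree with branch lengths and node (support)
#' labels. Labels containing Newick metacharacters (spaces, parentheses,
#' commas, colons, quotes) are single-quoted.
#'
#' @param tree A `phylo` object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  el <- tree$edge.length
  node_label <- function(node) {
    if (node <= n_tip) return(quote_newick_label(tree$tip.label[node]))
    lbl <- tree$node.label[node - n_tip]
    if (is.null(lbl) || is.na(lbl)) "" else quote_newick_label(lbl)
  }
  render <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(node_label(node))
    inner <- vapply(kids, function(e) {
      child <- tree$edge[e, 2]
      paste0(render(child),
             if (!is.null(el)) paste0(":", format_bl(el[e])) else "")
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")", node_label(node))
  }
  root <- n_tip + 1L
  text <- paste0(render(root), ";")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Write a distance matrix as TSV
#' @param d Labelled distance matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(data.frame(id = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
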