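test_that("protein distance matches hand-evaluated values and handles gaps", {
  expect_equal(protein_distance("ACDE", "ACDE"), 0)
  # p = 0.5: d = -ln(1 - 0.5 - 0.2*0.25) = -ln(0.45)
  expect_equal(protein_distance("AAAA", "AAGG"), -log(0.45))
  # gapped columns are ignored
  expect_equal(protein_distance("AC-E", "ACD-"), 0)
  expect_error(protein_distance("--A", "A--"), "shared")
  expect_error(protein_distance("AC", "ACD"), "length")
  # saturation cap
  expect_warning(d <- protein_distance("AAAAAAAAAA", "CCCCCCCCCC"), "saturated")
  expect_equal(d, 10)
})

test_that("corrected distance increases strictly with the mismatch fraction", {
  p <- seq(0, 0.84, by = 0.04)
  d <- -log(1 - p - 0.2 * p^2)
  expect_true(all(diff(d) > 0))
})

test_that("three-taxon NJ reproduces the closed-form pendant lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  # pendant to A = (d_AB + d_AC - d_BC)/2 = 1, B = 2, C = 3
  tips <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                          tree$edge[, 2])], tree$tip.label)
  expect_equal(tips[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ recovers additive four-taxon splits", {
  d <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(d)
  parts <- ape::prop.part(tree)
  # ((A,B),(C,D)): the internal edge separates {A,B} from {C,D}
  split_found <- any(vapply(parts, function(p) {
    tips <- sort(tree$tip.label[p])
    identical(tips, c("A", "B")) || identical(tips, c("C", "D"))
  }, logical(1)))
  expect_true(split_found)
  expect_equal(sum(tree$edge.length), 2 * 1 + 2 * 1 + 5)
})

test_that("NJ reconstructs random additive trees exactly (topology and lengths)", {
  set.seed(51)
  for (rep in 1:8) {
    case <- random_additive_case(sample(4:9, 1))
    mine <- neighbor_joining(case$d)
    expect_equal(as.numeric(ape::dist.topo(mine, case$tree)), 0,
                 ignore_attr = TRUE)
    back <- ape::cophenetic.phylo(mine)
    back <- back[rownames(case$d), colnames(case$d)]
    expect_equal(back, case$d, tolerance = 1e-9)
  }
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    case <- random_additive_case(n)
    d <- case$d + matrix(runif(n * n, 0, 0.01), n)  # mild noise
    d <- (d + t(d)) / 2; diag(d) <- 0
    mine <- neighbor_joining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(mine, ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate inputs give the documented shapes", {
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(2, 2))
  expect_error(neighbor_joining(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
  # equal-distance ultrametric matrix: any resolution, consistent length
  de <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(de) <- 0
  te <- neighbor_joining(de)
  expect_true(all(te$edge.length >= 0))
  expect_equal(ape::cophenetic.phylo(te)[LETTERS[1:4], LETTERS[1:4]], de,
               tolerance = 1e-9)
})

test_that("bootstrap supports are deterministic and separate synthetic clades", {
  ctl <- load_catalog()
  # two clearly separated clades: high divergence between, low within
  spans <- data.frame(start = 1L, end = 100L)
  fam1 <- simulate_family(family_params(n_orthologs = 4, length = 300,
                                        disordered_spans = spans,
                                        implants = default_implants()[0, ],
                                        q_bg = 0.03, seed = 61), ctl)
  fam2 <- simulate_family(family_params(n_orthologs = 4, length = 300,
                                        disordered_spans = spans,
                                        implants = default_implants()[0, ],
                                        q_bg = 0.03, seed = 62), ctl)
  gapped <- c(setNames(vapply(fam1$records, `[[`, character(1), "sequence"),
                       paste0("cladeA_", names(fam1$records))),
              setNames(vapply(fam2$records, `[[`, character(1), "sequence"),
                       paste0("cladeB_", names(fam2$records))))
  msa <- as_msa(gapped)
  tree <- suppressWarnings(bootstrap_supports(msa, n_replicates = 100, seed = 7))
  expect_equal(attr(tree, "replicates"), 100)
  # the clade-A vs clade-B bipartition must be strongly supported
  parts <- ape::prop.part(tree)
  supports <- attr(tree, "supports")
  idx <- which(vapply(parts, function(p) {
    tips <- tree$tip.label[p]
    all(startsWith(tips, "cladeA_")) && length(tips) == 4 ||
      all(startsWith(tips, "cladeB_")) && length(tips) == 4
  }, logical(1)))
  expect_true(length(idx) >= 1)
  expect_true(all(supports[idx] >= 95))
  # determinism under the same seed
  tree2 <- suppressWarnings(bootstrap_supports(msa, n_replicates = 100, seed = 7))
  expect_identical(tree$node.label, tree2$node.label)
  # identical sequences: uninformative but no crash
  flat <- as_msa(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "ACDEFGHIKL"))
  expect_s3_class(bootstrap_supports(flat, n_replicates = 10, seed = 1),
                  "phylo")
})

test_that("newick output round-trips and quotes awkward labels", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  text <- write_newick(tree)
  back <- ape::read.tree(text = text)
  expect_equal(as.numeric(ape::dist.topo(back, tree)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
  expect_equal(sum(back$edge.length), sum(tree$edge.length))
  # random trees round-trip topology + lengths
  set.seed(71)
  for (rep in 1:5) {
    case <- random_additive_case(sample(4:8, 1))
    t0 <- neighbor_joining(case$d)
    b0 <- ape::read.tree(text = write_newick(t0))
    expect_equal(as.numeric(ape::dist.topo(b0, t0)), 0,
                 ignore_attr = TRUE)
    expect_equal(sum(b0$edge.length), sum(t0$edge.length), tolerance = 1e-9)
  }
  # two-leaf form
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_match(write_newick(neighbor_joining(d2)), "^\\(A:2,B:2\\);$")
  # metacharacter quoting
  dq <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("D. rerio", "H sapiens", "C"),
                               c("D. rerio", "H sapiens", "C")))
  tq <- neighbor_joining(dq)
  expect_match(write_newick(tq), "'D. rerio'", fixed = TRUE)
})
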