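test_that("global alignment handles identity and single-substitution cases", {
  aln <- global_align("ACDE", "ACDE")
  expect_equal(aln$a_gapped, "ACDE")
  expect_equal(aln$b_gapped, "ACDE")
  expect_equal(percent_identity(aln), 100.0)
  aln2 <- global_align("A", "G")
  expect_equal(nchar(aln2$a_gapped), 1)
  expect_equal(percent_identity(aln2), 0.0)
  expect_error(global_align("", "A"), "non-empty")
  expect_warning(global_align("AXC", "AAC"), "mismatch")
})

test_that("alignment scores equal the exhaustive affine-gap oracle (length <= 8)", {
  set.seed(31)
  cases <- c(replicate(12, list(c(random_sequence(sample(3:8, 1)),
                                  random_sequence(sample(3:8, 1))))),
             list(c("WWWW", "W"), c("ACDEFGHI", "ACEFGHI")))
  for (cs in cases) {
    aln <- global_align(cs[1], cs[2])
    expect_equal(aln$score, oracle_align_score(cs[1], cs[2]),
                 info = paste(cs, collapse = " vs "))
    # gapped strings degap to the inputs and have equal length
    expect_equal(gsub("-", "", aln$a_gapped), cs[1])
    expect_equal(gsub("-", "", aln$b_gapped), cs[2])
    expect_equal(nchar(aln$a_gapped), nchar(aln$b_gapped))
  }
})

test_that("percent identity is symmetric and counts identical columns", {
  set.seed(33)
  for (rep in 1:8) {
    a <- random_sequence(sample(10:40, 1))
    b <- random_sequence(sample(10:40, 1))
    expect_equal(percent_identity(global_align(a, b)),
                 percent_identity(global_align(b, a)))
  }
  # gapless all-different alignment
  expect_equal(percent_identity(global_align("AAAA", "GGGG")), 0.0)
})

test_that("position/column maps are mutually inverse on random gapped strings", {
  expect_equal(map_position(as_msa(c(x = "-AB", y = "CAB")), "x", 1), 2)
  expect_equal(map_column(as_msa(c(x = "-AB", y = "CAB")), "x", 2), 1)
  msa0 <- as_msa(c(a = "ACDE", b = "AGDE"))
  for (k in 1:4) expect_equal(map_position(msa0, "a", k), k)
  set.seed(35)
  for (rep in 1:10) {
    n <- 30
    a <- strsplit(random_sequence(n), "")[[1]]
    gaps <- sample(1:n, sample(3:10, 1))
    a[gaps] <- "-"
    b <- strsplit(random_sequence(n), "")[[1]]
    b[a != "-" & seq_len(n) %% 7 == 0] <- "-"  # keep columns non-empty
    msa <- as_msa(c(s1 = paste(a, collapse = ""), s2 = paste(b, collapse = "")))
    ungapped <- sum(a != "-")
    for (pos in seq_len(ungapped)) {
      expect_equal(map_column(msa, "s1", map_position(msa, "s1", pos)), pos)
    }
    expect_error(map_position(msa, "s1", ungapped + 1), "beyond")
  }
})

test_that("msa invariants are enforced", {
  expect_error(as_msa(c(a = "AC", b = "ACD")), "unequal")
  expect_error(as_msa(c(a = "A-", b = "C-")), "all-gap")
})

test_that("motif conservation maps matches through alignments", {
  ctl <- load_catalog()
  lxvp <- ctl$classes$DOC_PP2B_LxvP1
  # identical sequences conserve everything
  seqs <- c(ref = "GGSFLRPPGG", o1 = "GGSFLRPPGG", o2 = "GGSFLRPPGG")
  rep1 <- motif_conservation(as_msa(seqs),
                             list(protein_id = "ref", start = 3, end = 8), lxvp)
  expect_equal(rep1$conserved_fraction, 1.0)
  # motif destroyed in one of two orthologs
  seqs2 <- c(ref = "GGSFLRPPGG", o1 = "GGSFLRPPGG", o2 = "GGAAAAAAGG")
  rep2 <- motif_conservation(as_msa(seqs2),
                             list(protein_id = "ref", start = 3, end = 8), lxvp)
  expect_equal(rep2$conserved_fraction, 0.5)
  expect_equal(rep2$per_ortholog$conserved,
               c(TRUE, FALSE))
  # slack widens the window: shifted motif recovered only with slack
  seqs3 <- c(ref = "GGGGSFLRPPGGGG", o1 = "SFLRPPGGGGGGGG")
  ref_match <- list(protein_id = "ref", start = 5, end = 10)
  wide <- motif_conservation(as_msa(seqs3), ref_match, lxvp, slack = 5)
  narrow <- motif_conservation(as_msa(seqs3), ref_match, lxvp, slack = 0)
  expect_equal(wide$conserved_fraction, 1.0)
  expect_equal(narrow$conserved_fraction, 0.0)
})

test_that("conservation fraction is non-increasing as slack decreases", {
  ctl <- load_catalog()
  set.seed(41)
  fam <- simulate_family(family_params(seed = 4, q_bg = 0.3), ctl)
  matches <- scan_catalog(fam$records[[1]], ctl)
  matches <- matches[sample(nrow(matches), min(15, nrow(matches))), ]
  for (i in seq_len(nrow(matches))) {
    cl <- ctl$classes[[matches$motif_id[i]]]
    fr <- vapply(c(8, 5, 2, 0), function(s)
      motif_conservation(fam$msa, matches[i, ], cl, slack = s)$conserved_fraction,
      numeric(1))
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("conservation equals generator truth when the background is frozen", {
  ctl <- load_catalog()
  fam <- simulate_family(family_params(seed = 11, q_bg = 0, q_motif = 0), ctl)
  tr <- fam$truth$implants
  for (i in seq_len(nrow(tr))) {
    rep_ <- motif_conservation(
      fam$msa, list(protein_id = "ortho1", start = tr$start[i], end = tr$end[i]),
      ctl$classes[[tr$motif_id[i]]])
    expect_equal(rep_$conserved_fraction, tr$true_conserved_fraction[i])
    expect_equal(rep_$conserved_fraction, 1.0)
  }
})

test_that("star alignment reproduces simple indel layouts", {
  recs <- list(
    ref = protein_record("ref", "ACDEFGHIKL"),
    ins = protein_record("ins", "ACDEWWFGHIKL"),  # insertion after E
    del = protein_record("del", "ACDEFGHI"))      # C-terminal loss
  msa <- star_align(recs, "ref")
  expect_equal(sort(names(msa$gapped)), sort(names(recs)))
  for (id in names(recs)) {
    expect_equal(gsub("-", "", msa$gapped[[id]]), recs[[id]]$sequence)
  }
  # the reference row gains exactly the insertion width
  expect_equal(msa$n_columns, 12)
  expect_equal(map_position(msa, "ref", 5), 7)  # F displaced by WW
})
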