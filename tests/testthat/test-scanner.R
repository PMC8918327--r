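test_that("pattern compiler expands bounded quantifiers and rejects unbounded ones", {
  p <- compile_motif_pattern("[KR][KR].{2,4}[ILVM].[ILVF]")
  expect_equal(vapply(p$variants, ncol, integer(1)), c(7L, 8L, 9L))
  p2 <- compile_motif_pattern("AC?D")
  expect_equal(vapply(p2$variants, ncol, integer(1)), c(2L, 3L))
  expect_error(compile_motif_pattern("A*"), "unbounded")
  expect_error(compile_motif_pattern("A{2,}"), "unbounded|malformed")
  expect_error(compile_motif_pattern("[KB]"), "unknown residue")
})

test_that("overlapping matches are all reported in deterministic order", {
  ctl <- load_catalog()
  rec <- protein_record("toy", "SFLRPPSFLRPP")
  m <- scan_motifs(rec, ctl$classes$DOC_PP2B_LxvP1)
  expect_equal(m$start, c(1L, 7L))
  expect_equal(m$peptide, c("SFLRPP", "SFLRPP"))
  # no-match case
  m0 <- scan_motifs(protein_record("toy", "AAAAAA"), ctl$classes$DOC_PP4)
  expect_equal(nrow(m0), 0)
  # equal starts sort shortest first
  rxl <- scan_motifs(protein_record("toy", "KKLPPP"), ctl$classes$DOC_Cyclin_RxL)
  expect_true(all(diff(rxl$start) >= 0))
  same <- rxl[rxl$start == 1, ]
  expect_equal(same$end, sort(same$end))
})

test_that("X never matches any residue class", {
  ctl <- load_catalog()
  rec <- protein_record("toy", "SXLRPP")
  expect_equal(nrow(scan_motifs(rec, ctl$classes$DOC_PP2B_LxvP1)), 0)
  # even negated classes exclude X
  rec2 <- protein_record("toy", "X")
  expect_equal(nrow(scan_motifs(rec2, list(motif_id = "t", pattern = "[^P]"))), 0)
})

test_that("scanner equals the brute-force matcher on random sequences", {
  ctl <- load_catalog()
  set.seed(101)
  for (rep in 1:6) {
    seq <- random_sequence(sample(200:2000, 1))
    rec <- protein_record("rand", seq)
    for (cl in ctl$classes) {
      got <- scan_motifs(rec, cl)[, c("start", "end")]
      want <- naive_scan(seq, cl$pattern)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want,
                   info = paste("class", cl$motif_id, "rep", rep))
    }
  }
})

test_that("site_probability reproduces closed-form values", {
  u <- uniform_background()
  expect_equal(site_probability(list(pattern = "."), u), 1.0)
  expect_equal(site_probability(list(pattern = "A"), u), 0.05)
  expect_equal(site_probability(list(pattern = "[ST]P"), u), 0.005)
  # variable length: sum over variants
  expect_equal(site_probability(list(pattern = "AC?"), u), 0.05 + 0.0025)
})

test_that("site_probability agrees with Monte-Carlo match frequency within 3 SE", {
  ctl <- load_catalog()
  bg <- background_frequencies()
  set.seed(2024)
  n <- 1e6
  seq <- paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
  rec <- protein_record("mc", seq)
  for (cl in ctl$classes[c("LIG_LIR_Gen1", "DOC_PP4", "DOC_MAPK", "LIG_WW3")]) {
    p <- site_probability(cl, bg)
    # p is the expected number of matches per position summed over
    # length variants, so count matches (with variant multiplicity)
    hits <- nrow(scan_motifs(rec, cl))
    se <- sqrt(p * (1 - p) * n)
    expect_lt(abs(hits - p * n), 3 * se + 1,
              label = paste("MC deviation for", cl$motif_id))
  }
})

test_that("restricting a residue class never increases the probability", {
  bg <- background_frequencies()
  base <- site_probability(list(pattern = "[ILVF].[KR]"), bg)
  for (restricted in c("[ILV].[KR]", "[ILVF].[K]", "[IL].[R]")) {
    expect_lte(site_probability(list(pattern = restricted), bg), base)
  }
})

test_that("selection applies threshold, disorder and conservation rules with audit trail", {
  matches <- data.frame(
    protein_id = "P", motif_id = c("m_lo", "m_hi", "m_wl", "m_out", "m_uncons"),
    start = c(10L, 10L, 10L, 200L, 15L), end = c(14L, 14L, 14L, 204L, 19L),
    peptide = "XXXXX", site_probability = c(1e-4, 2e-2, 2e-2, 1e-4, 1e-4),
    in_disorder = NA, conserved_fraction = NA_real_, stringsAsFactors = FALSE)
  regions <- structure(list(protein_id = "P",
                            intervals = data.frame(start = 1L, end = 100L),
                            source = "test"), class = "disorder_region_set")
  cons <- data.frame(protein_id = "P",
                     motif_id = c("m_lo", "m_hi", "m_wl", "m_out", "m_uncons"),
                     start = c(10L, 10L, 10L, 200L, 15L),
                     conserved_fraction = c(1, 1, 1, 1, 0.5))
  cfg <- scan_config(whitelist = "m_wl")
  out <- select_candidates(matches, regions, cons, cfg)
  expect_equal(out$retained,
               c(TRUE,   # low probability, disordered, conserved
                 FALSE,  # excluded by threshold
                 TRUE,   # whitelisted despite probability
                 FALSE,  # outside disorder
                 FALSE)) # conservation below minimum
  expect_match(out$reasons[2], "score>=threshold")
  expect_match(out$reasons[4], "not-in-disorder")
  expect_match(out$reasons[5], "not-conserved")
  # unknown disorder/conservation: retained but flagged
  out2 <- select_candidates(matches[1, ], NULL, NULL, cfg)
  expect_true(out2$retained)
  expect_equal(out2$disorder_ok, "unknown")
  expect_equal(out2$conservation_ok, "unknown")
})

test_that("raising the threshold never removes a retained match", {
  ctl <- load_catalog()
  set.seed(77)
  rec <- protein_record("rand", random_sequence(500))
  matches <- scan_catalog(rec, ctl)
  regions <- structure(list(protein_id = "rand",
                            intervals = data.frame(start = 1L, end = 500L),
                            source = "test"), class = "disorder_region_set")
  kept <- list()
  thresholds <- c(1e-4, 1e-3, 1e-2, 0.05, 0.5)
  for (t in thresholds) {
    out <- select_candidates(matches, regions, NULL,
                             scan_config(score_threshold = t))
    kept[[as.character(t)]] <- paste(out$motif_id, out$start)[out$retained]
  }
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(kept[[i - 1]] %in% kept[[i]]))
  }
})
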