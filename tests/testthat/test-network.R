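test_that("empty inputs give a hub-only network", {
  net <- assemble_network()
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$nodes$name, c("SYDE1", "SYDE2"))
  expect_equal(net$nodes$kind, c("SYDE hub", "SYDE hub"))
  s <- summarize_network(net)
  expect_equal(s$per_hub$interactors, c(0L, 0L))
  expect_equal(sum(s$per_tier$edges), 0L)
})

test_that("the packaged motif table yields eleven SYDE1 interactor entities", {
  ctl <- load_catalog()
  net <- assemble_network(candidates = catalog_candidates(ctl),
                          catalog = ctl, structural = "packaged")
  s <- summarize_network(net)
  expect_equal(s$per_hub$interactors[s$per_hub$hub == "SYDE1"], 11L)
  # SYDE2 under the same entity rule
  expect_equal(s$per_hub$interactors[s$per_hub$hub == "SYDE2"], 8L)
  # every predicted edge carries a motif id resolvable in the catalog
  pred <- net$edges[net$edges$tier == "high-throughput-or-predicted", ]
  expect_true(all(pred$motif_or_region %in% names(ctl$classes)))
  # docking-derived edges are structural-prediction tier, not SLiM edges
  expect_setequal(
    net$edges$interactor[net$edges$tier == "structural-prediction"],
    c("RhoA", "RhoB"))
})

test_that("entity merging gives one Crk node with SH3- and SH2-derived edges", {
  ctl <- load_catalog()
  net <- assemble_network(candidates = catalog_candidates(ctl), catalog = ctl)
  expect_equal(sum(net$nodes$name == "Crk"), 1)
  crk_edges <- net$edges[net$edges$interactor == "Crk", ]
  expect_setequal(unique(crk_edges$motif_or_region),
                  c("LIG_SH3_3_Crk", "LIG_SH2_Crk_Nck"))
  # assembling twice from the same inputs is idempotent
  net2 <- assemble_network(candidates = catalog_candidates(ctl), catalog = ctl)
  expect_identical(net, net2)
})

test_that("candidate rows with unknown motif ids are rejected", {
  ctl <- load_catalog()
  cand <- catalog_candidates(ctl)[1, ]
  cand$motif_id <- "NOT_A_CLASS"
  expect_error(assemble_network(candidates = cand, catalog = ctl),
               "unknown motif_id")
})

test_that("curated interactions load, validate methods, and set tiers", {
  cur <- read_curated_interactions()
  expect_equal(nrow(cur), 13)  # transcription keeps every published row
  expect_setequal(unique(cur$protein), c("SYDE1", "SYDE2", "DmSyd1"))
  net <- assemble_network(curated = cur)
  # AP-MS-only rows are high-throughput; any low-throughput method wins
  xpo1 <- net$edges[net$edges$interactor == "XPO1", ]
  expect_equal(xpo1$tier, "high-throughput-or-predicted")
  munc <- net$edges[net$edges$interactor == "Munc18", ]
  expect_equal(munc$tier, "curated-low-throughput")
  arh <- net$edges[net$edges$interactor == "ARHGAP28", ]
  expect_equal(arh$tier, "curated-low-throughput")  # coIP + AP-MS
  # bad method vocabulary
  cur$method[1] <- "EMSA"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(cur, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_curated_interactions(path), "unknown method")
})

test_that("summaries equal a naive recount and duplicates collapse", {
  ctl <- load_catalog()
  cand <- catalog_candidates(ctl)
  net <- assemble_network(curated = read_curated_interactions(),
                          candidates = rbind(cand, cand),  # duplicated rows
                          catalog = ctl, structural = "packaged")
  net_once <- assemble_network(curated = read_curated_interactions(),
                               candidates = cand, catalog = ctl,
                               structural = "packaged")
  expect_identical(net, net_once)
  s <- summarize_network(net)
  for (h in s$per_hub$hub) {
    expect_equal(s$per_hub$edges[s$per_hub$hub == h],
                 sum(net$edges$paralog == h))
    expect_equal(s$per_hub$interactors[s$per_hub$hub == h],
                 length(unique(net$edges$interactor[net$edges$paralog == h])))
  }
  expect_equal(sum(s$per_tier$edges), nrow(net$edges))
  expect_equal(sum(s$per_category$nodes),
               sum(net$nodes$kind == "interactor"))
})

test_that("TSV export round-trips losslessly, including names with spaces", {
  ctl <- load_catalog()
  net <- assemble_network(curated = read_curated_interactions(),
                          candidates = catalog_candidates(ctl),
                          catalog = ctl, structural = "packaged")
  expect_true("Cyclin B/CDK1" %in% net$nodes$name)
  expect_true(any(grepl(", ", net$nodes$name, fixed = TRUE)))
  prefix <- file.path(withr::local_tempdir(), "net")
  export_network(net, prefix, format = "tsv")
  back <- import_network(prefix, format = "tsv")
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  # empty network too
  prefix0 <- file.path(withr::local_tempdir(), "empty")
  export_network(assemble_network(), prefix0, format = "tsv")
  back0 <- import_network(prefix0, format = "tsv")
  expect_equal(nrow(back0$edges), 0)
})

test_that("GML export is valid and re-imports with all fields", {
  ctl <- load_catalog()
  net <- assemble_network(candidates = catalog_candidates(ctl),
                          catalog = ctl, structural = "packaged")
  path <- file.path(withr::local_tempdir(), "net.gml")
  export_network(net, path, format = "gml")
  back <- import_network(path, format = "gml")
  expect_setequal(back$nodes$name, net$nodes$name)
  key <- function(e) sort(paste(e$paralog, e$interactor, e$tier,
                                e$motif_or_region))
  expect_equal(key(back$edges), key(net$edges))
  # GML of the empty network parses
  path0 <- file.path(withr::local_tempdir(), "empty.gml")
  export_network(assemble_network(), path0, format = "gml")
  g0 <- igraph::read_graph(path0, format = "gml")
  expect_equal(igraph::vcount(g0), 2)
  expect_error(export_network(net, path, format = "dot"), "arg")
})
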