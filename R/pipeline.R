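#' Pipeline configuration
#'
#' Collects every input and knob of [run_pipeline()]: the sequences to
#' scan, the motif catalog, how disorder is obtained (`"import"` an
#' annotation TSV, compute the `"surrogate"` profile, or `"both"`,
#' where imported annotations take precedence and are unioned with the
#' surrogate), an optional alignment for conservation and phylogeny, an
#' optional domain-boundary table for identity reports, the selection
#' rules, and the output directory.
#'
#' @param fasta Path(s) to input FASTA file(s).
#' @param catalog_path Catalog YAML path, or `NULL` for the packaged one.
#' @param disorder_mode `"surrogate"`, `"import"` or `"both"`.
#' @param disorder_tsv Annotation TSV (required for `"import"`/used by
#'   `"both"` when present).
#' @param alignment Aligned FASTA path, or `NULL`.
#' @param build_alignment Build a star alignment from the input records
#'   (first record is the center) when no alignment file is given.
#' @param boundaries Domain-boundary TSV path, or `NULL`.
#' @param curated Curated-interaction TSV path, `NULL` to use the
#'   packaged table, or `FALSE` to omit curated edges.
#' @param scan A [scan_config()]; when `NULL`, the default with the
#'   catalog's whitelist.
#' @param n_bootstrap Bootstrap replicates for the tree stage.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, catalog_path = NULL,
                            disorder_mode = c("both", "surrogate", "import"),
                            disorder_tsv = NULL, alignment = NULL,
                            build_alignment = FALSE, boundaries = NULL,
                            curated = NULL, scan = NULL, n_bootstrap = 100,
                            out_dir, seed = 1) {
  disorder_mode <- match.arg(disorder_mode)
  for (p in c(fasta, catalog_path, disorder_tsv, alignment, boundaries)) {
    if (!is.null(p) && !isFALSE(p) && !file.exists(p)) {
      stop("input file not found: ", p)
    }
  }
  if (disorder_mode == "import" && is.null(disorder_tsv)) {
    stop("disorder_mode 'import' requires disorder_tsv")
  }
  structure(list(fasta = fasta, catalog_path = catalog_path,
                 disorder_mode = disorder_mode, disorder_tsv = disorder_tsv,
                 alignment = alignment, build_alignment = build_alignment,
                 boundaries = boundaries, curated = curated, scan = scan,
                 n_bootstrap = n_bootstrap, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full prediction pipeline
#'
#' Orchestrates: sequence input, catalog load + validation, disorder
#' (imported and/or surrogate), motif scanning, ortholog conservation
#' (when an alignment is available), candidate selection, domain
#' identity report (when boundaries are given), neighbor-joining tree
#' with bootstrap (when an alignment is available), and network
#' assembly. Writes `candidates.tsv`, `conservation.tsv`,
#' `identity.tsv`, `tree.nwk`, `distances.tsv`, `network_nodes.tsv` /
#' `network_edges.tsv`, `network.gml` and `manifest.json` into
#' `out_dir`. Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the result bundle: list with `records`, `catalog`,
#'   `validation`, `disorder`, `candidates`, `conservation`, `identity`,
#'   `tree`, `network`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- stage("seqio", {
    recs <- unlist(lapply(config$fasta, read_fasta), recursive = FALSE)
    if (!length(recs)) stop("no input records")
    recs
  })
  catalog <- stage("catalog", load_catalog(config$catalog_path))
  validation <- stage("catalog", validate_catalog(catalog))
  if (!validation$pass) stop("stage 'catalog' failed: catalog invalid")

  scan_cfg <- config$scan %||% scan_config(whitelist = default_whitelist(catalog))

  disorder_sets <- stage("disorder", {
    imported <- NULL
    if (!is.null(config$disorder_tsv) &&
        config$disorder_mode %in% c("import", "both")) {
      tab <- read_region_table(config$disorder_tsv)
      imported <- lapply(stats::setNames(nm = unique(tab$protein_id)),
                         function(id) {
        import_regions(tab, protein_id = id,
                       seq_length = if (id %in% names(records))
                         records[[id]]$length else NULL)
      })
    }
    sets <- list()
    for (rec in records) {
      surrogate <- if (config$disorder_mode %in% c("surrogate", "both")) {
        call_regions(foldindex_profile(rec))
      } else NULL
      imp <- imported[[rec$id]]
      sets[[rec$id]] <- if (!is.null(imp) && !is.null(surrogate)) {
        merge_region_sets(imp, surrogate)
      } else imp %||% surrogate
    }
    sets
  })

  matches <- stage("scan", {
    out <- do.call(rbind, lapply(records, scan_catalog, catalog = catalog))
    rownames(out) <- NULL
    out
  })

  msa <- stage("align", {
    if (!is.null(config$alignment)) read_alignment(config$alignment)
    else if (isTRUE(config$build_alignment) && length(records) > 1) {
      star_align(records, names(records)[1])
    } else NULL
  })

  conservation <- stage("conserve", {
    if (is.null(msa) || !nrow(matches)) NULL else {
      rows <- which(matches$protein_id %in% names(msa$gapped))
      do.call(rbind, lapply(rows, function(i) {
        rep_ <- motif_conservation(
          msa, matches[i, ], catalog$classes[[matches$motif_id[i]]],
          slack = scan_cfg$conservation_slack_columns)
        data.frame(protein_id = matches$protein_id[i],
                   motif_id = matches$motif_id[i], start = matches$start[i],
                   conserved_fraction = rep_$conserved_fraction,
                   stringsAsFactors = FALSE)
      }))
    }
  })

  candidates <- stage("select", {
    select_candidates(matches, disorder_sets, conservation, scan_cfg)
  })

  identity <- stage("identity", {
    if (is.null(config$boundaries)) NULL else {
      domain_identity_report(records, read_region_table(config$boundaries))
    }
  })

  tree <- stage("tree", {
    if (is.null(msa) || length(msa$gapped) < 3) NULL else {
      bootstrap_supports(msa, n_replicates = config$n_bootstrap,
                         seed = config$seed)
    }
  })

  network <- stage("network", {
    curated <- if (isFALSE(config$curated)) NULL else
      read_curated_interactions(config$curated)
    assemble_network(curated = curated, candidates = candidates,
                     catalog = catalog, structural = "packaged")
  })

  out <- function(name) file.path(config$out_dir, name)
  write_candidates(candidates, out("candidates.tsv"))
  if (!is.null(conservation)) {
    utils::write.table(conservation, out("conservation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(identity)) {
    utils::write.table(identity, out("identity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tree)) {
    write_newick(tree, out("tree.nwk"))
    if (!is.null(msa)) write_distance_matrix(distance_matrix(msa),
                                             out("distances.tsv"))
  }
  export_network(network, out("network"), format = "tsv")
  export_network(network, out("network.gml"), format = "gml")

  manifest <- list(
    package = "sydescan",
    version = as.character(utils::packageVersion("sydescan")),
    seed = config$seed,
    n_records = length(records),
    records = vapply(records, `[[`, character(1), "id"),
    catalog = catalog$path,
    catalog_classes = length(catalog$classes),
    disorder_mode = config$disorder_mode,
    scan_config = unclass(scan_cfg),
    n_bootstrap = config$n_bootstrap,
    outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(records = records, catalog = catalog,
                 validation = validation, disorder = disorder_sets,
                 candidates = candidates, conservation = conservation,
                 identity = identity, tree = tree, network = network,
                 summary = summarize_network(network), manifest = manifest))
}
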