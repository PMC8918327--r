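CURATION_METHODS <- c("AP-MS", "FLAP", "Y2H", "coIP", "pull-down", "ITC")
EVIDENCE_TIERS <- c("curated-low-throughput", "high-throughput-or-predicted",
                    "conserved-inferred", "structural-prediction")

# Entity canonicalization: entities listed together in one catalog row
# ("Cyclin B/CDK1", "p38 alpha/beta") are one entity; the noncanonical
# SH3 row "Crk, Src" is carried by its primary partner Crk so that the
# SH3- and SH2-mediated predictions share one node.
ENTITY_ALIASES <- c("Crk, Src" = "Crk", "calcineurin" = "Calcineurin")

canonical_entity <- function(name) {
  name <- trimws(name)
  unname(ifelse(name %in% names(ENTITY_ALIASES), ENTITY_ALIASES[name], name))
}

#' Read a curated-interaction table
#'
#' TSV transcription of experimentally supported SYDE interactions:
#' columns `protein`, `interactor`, `domain_architecture`, `pathway`,
#' `method` (one or more of `AP-MS`, `FLAP`, `Y2H`, `coIP`, `pull-down`,
#' `ITC`, `;`-separated), `reference`, `interacting_region`.
#'
#' @param path Path to the TSV, or `NULL` for the packaged table.
#' @return Validated `data.frame`.
#' @export
read_curated_interactions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "curated_interactions.tsv",
                        package = "sydescan")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("protein", "interactor", "domain_architecture", "pathway",
              "method", "reference", "interacting_region")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("curated table missing column(s): ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(tab))) {
    methods <- trimws(strsplit(tab$method[i], ";", fixed = TRUE)[[1]])
    bad <- setdiff(methods, CURATION_METHODS)
    if (length(bad)) {
      stop("curated table row ", i, ": unknown method '", bad[1], "'")
    }
  }
  tab
}

read_node_categories <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "node_categories.tsv", package = "sydescan")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

read_structural_predictions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "structural_predictions.tsv",
                        package = "sydescan")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble the tiered SYDE interaction network
#'
#' Combines curated interactions, retained SLiM candidates and
#' structural-prediction edges into one network. One node is created per
#' distinct interactor entity (entities listed together in a single
#' catalog row count as one; the same protein appearing in several rows
#' is merged into one node); SYDE1 and SYDE2 are always present as hub
#' nodes. Edge tiers: curated rows supported by any low-throughput method
#' are `curated-low-throughput`, purely high-throughput rows and SLiM
#' candidates are `high-throughput-or-predicted`, docking-derived edges
#' are `structural-prediction`. Every predicted edge carries its
#' motif id. Node and edge ordering is deterministic (lexicographic).
#'
#' @param curated `data.frame` from [read_curated_interactions()], or
#'   `NULL`.
#' @param candidates Candidate table (see [select_candidates()] /
#'   [catalog_candidates()]); only rows with `retained == TRUE`
#'   contribute edges. `NULL` for none.
#' @param catalog The `motif_catalog` used to resolve candidate
#'   `motif_id`s to interactor entities (required when `candidates` is
#'   given; unknown ids are an error).
#' @param structural Structural-prediction edge table (`paralog`,
#'   `interactor`, `region`, `reference`); `NULL` for none, `"packaged"`
#'   for the shipped docking-derived edges.
#' @return An object of class `interaction_network`: list with `nodes`
#'   and `edges` data frames.
#' @export
assemble_network <- function(curated = NULL, candidates = NULL,
                             catalog = NULL, structural = NULL) {
  edges <- list()
  if (!is.null(candidates) && nrow(candidates)) {
    if (is.null(catalog)) stop("candidates given without a catalog")
    kept <- candidates[isTRUE_vec(candidates$retained), , drop = FALSE]
    for (i in seq_len(nrow(kept))) {
      cl <- catalog$classes[[kept$motif_id[i]]]
      if (is.null(cl)) {
        stop("candidate row ", i, ": unknown motif_id '",
             kept$motif_id[i], "'")
      }
      edges[[length(edges) + 1L]] <- data.frame(
        paralog = kept$protein_id[i],
        interactor = canonical_entity(cl$interactor),
        tier = "high-throughput-or-predicted",
        motif_or_region = kept$motif_id[i],
        reference = cl$elm_class, stringsAsFactors = FALSE)
    }
  }
  if (identical(structural, "packaged")) {
    structural <- read_structural_predictions()
  }
  if (!is.null(structural) && nrow(structural)) {
    for (i in seq_len(nrow(structural))) {
      edges[[length(edges) + 1L]] <- data.frame(
        paralog = structural$paralog[i],
        interactor = canonical_entity(structural$interactor[i]),
        tier = "structural-prediction",
        motif_or_region = structural$region[i],
        reference = structural$reference[i], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(curated) && nrow(curated)) {
    for (i in seq_len(nrow(curated))) {
      methods <- trimws(strsplit(curated$method[i], ";", fixed = TRUE)[[1]])
      tier <- if (all(methods == "AP-MS")) "high-throughput-or-predicted"
              else "curated-low-throughput"
      edges[[length(edges) + 1L]] <- data.frame(
        paralog = curated$protein[i],
        interactor = canonical_entity(curated$interactor[i]),
        tier = tier,
        motif_or_region = curated$interacting_region[i],
        reference = curated$reference[i], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(paralog = character(0), interactor = character(0),
               tier = character(0), motif_or_region = character(0),
               reference = character(0))
  edges <- edges[order(edges$paralog, edges$interactor, edges$tier,
                       edges$motif_or_region), , drop = FALSE]
  rownames(edges) <- NULL

  hubs <- sort(unique(c("SYDE1", "SYDE2", edges$paralog)))
  cats <- read_node_categories()
  interactors <- sort(setdiff(unique(edges$interactor), hubs))
  idx <- match(interactors, cats$interactor)
  interactor_nodes <- data.frame(
    name = interactors, kind = rep("interactor", length(interactors)),
    category = ifelse(is.na(idx), "uncategorized", cats$category[idx]),
    molecule_class = ifelse(is.na(idx), "other", cats$molecule_class[idx]),
    stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(name = hubs, kind = "SYDE hub", category = "Rho-family modulator",
               molecule_class = "other", stringsAsFactors = FALSE),
    interactor_nodes)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

isTRUE_vec <- function(x) if (is.null(x)) TRUE else !is.na(x) & x

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$kind == "SYDE hub"), " hubs), ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Summarize an interaction network
#'
#' @param network An `interaction_network`.
#' @return List of data frames: `per_hub` (distinct interactor entities
#'   and edge counts per hub), `per_tier`, `per_category`.
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  hubs <- network$nodes$name[network$nodes$kind == "SYDE hub"]
  per_hub <- data.frame(
    hub = hubs,
    interactors = vapply(hubs, function(h)
      length(unique(e$interactor[e$paralog == h])), integer(1)),
    edges = vapply(hubs, function(h) sum(e$paralog == h), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  tier_tab <- table(factor(e$tier, levels = EVIDENCE_TIERS))
  per_tier <- data.frame(tier = names(tier_tab),
                         edges = as.integer(tier_tab),
                         stringsAsFactors = FALSE)
  inter <- network$nodes[network$nodes$kind == "interactor", , drop = FALSE]
  cat_tab <- table(inter$category)
  per_category <- data.frame(category = names(cat_tab),
                             nodes = as.integer(cat_tab),
                             stringsAsFactors = FALSE)
  list(per_hub = per_hub, per_tier = per_tier, per_category = per_category)
}

#' Export an interaction network
#'
#' `format = "tsv"` writes a lossless node/edge TSV pair
#' (`<prefix>_nodes.tsv`, `<prefix>_edges.tsv`); `format = "gml"` writes
#' a GML file via igraph (attribute names are camel-cased to satisfy GML
#' key syntax and restored on import).
#'
#' @param network An `interaction_network`.
#' @param prefix Output path prefix (TSV) or file path (GML).
#' @param format `"tsv"` or `"gml"`.
#' @return Invisibly, the path(s) written.
#' @export
export_network <- function(network, prefix, format = c("tsv", "gml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv"))
    utils::write.table(network$nodes, paths[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(network$edges, paths[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(paths))
  }
  g <- as_igraph(network)
  path <- if (grepl("\\.gml$", prefix)) prefix else paste0(prefix, ".gml")
  igraph::write_graph(g, path, format = "gml")
  # igraph stamps a timestamp into the Creator line; pin it so exports
  # of the same network are byte-identical
  lines <- readLines(path)
  lines[1] <- "Creator \"sydescan\""
  writeLines(lines, path)
  invisible(path)
}

as_igraph <- function(network) {
  nodes <- network$nodes
  names(nodes) <- c("name", "kind", "category", "moleculeClass")
  edges <- network$edges
  g_edges <- data.frame(from = edges$paralog, to = edges$interactor,
                        tier = edges$tier,
                        motifOrRegion = edges$motif_or_region,
                        reference = edges$reference, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(g_edges, directed = FALSE, vertices = nodes)
}

#' Import an interaction network
#'
#' Inverse of [export_network()]; TSV import is lossless.
#'
#' @param prefix Path prefix (TSV pair) or GML file path.
#' @param format `"tsv"` or `"gml"`.
#' @return An `interaction_network`.
#' @export
import_network <- function(prefix, format = c("tsv", "gml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"),
                               stringsAsFactors = FALSE)
    edges <- utils::read.delim(paste0(prefix, "_edges.tsv"),
                               stringsAsFactors = FALSE)
    if (!nrow(edges)) {
      edges <- data.frame(paralog = character(0), interactor = character(0),
                          tier = character(0), motif_or_region = character(0),
                          reference = character(0))
    }
    return(structure(list(nodes = nodes, edges = edges),
                     class = "interaction_network"))
  }
  path <- if (grepl("\\.gml$", prefix)) prefix else paste0(prefix, ".gml")
  g <- igraph::read_graph(path, format = "gml")
  nodes <- data.frame(name = igraph::V(g)$name, kind = igraph::V(g)$kind,
                      category = igraph::V(g)$category,
                      molecule_class = igraph::V(g)$moleculeClass,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(paralog = el[, 1], interactor = el[, 2],
                      tier = igraph::E(g)$tier,
                      motif_or_region = igraph::E(g)$motifOrRegion,
                      reference = igraph::E(g)$reference,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}
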