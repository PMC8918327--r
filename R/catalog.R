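#' Load a motif catalog
#'
#' Reads a SLiM catalog from a YAML file (see the packaged default at
#' `system.file("extdata", "motif_catalog.yaml", package = "sydescan")`
#' for the schema: one block per motif class with consensus text, machine
#' pattern, printed probability score kept as metadata, interactor and
#' pathway annotations, and the class's packaged instances). Patterns are
#' compiled at load time, so unbounded patterns are rejected here.
#'
#' @param path Path to a catalog YAML file, or `NULL` for the packaged
#'   default transcribed from the published SYDE1/SYDE2 interactor table.
#' @return An object of class `motif_catalog`: a list with
#'   * `classes`: named list of `motif_class` objects (fields `motif_id`,
#'     `elm_class`, `interactor`, `consensus_text`, `pattern`, `compiled`,
#'     `elm_score_printed`, `pathway`, `kind`, `whitelisted`, `syde`);
#'   * `instances`: `data.frame` of packaged instances (`motif_id`,
#'     `protein_id`, `start`, `end`, `peptide`);
#'   * `sites`: `data.frame` of site annotations (palmitoylation, NES).
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_catalog.yaml", package = "sydescan")
  }
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || (is.null(raw$classes) && is.null(raw$sites))) {
    warning("catalog file ", path, " contains no motif classes")
    return(empty_catalog())
  }
  classes <- list()
  instances <- list()
  for (cl in raw$classes %||% list()) {
    id <- cl$motif_id
    if (is.null(id) || !nzchar(id)) stop("catalog class without motif_id")
    if (id %in% names(classes)) stop("duplicate motif_id '", id, "' in catalog")
    score <- cl$elm_score_printed
    if (!is.null(score) && (score <= 0 || score >= 1)) {
      stop("class '", id, "': printed score must be in (0,1)")
    }
    mc <- structure(list(
      motif_id = id,
      elm_class = cl$elm_class %||% id,
      interactor = cl$interactor %||% "",
      consensus_text = cl$consensus_text %||% "",
      pattern = cl$pattern,
      compiled = compile_motif_pattern(cl$pattern),
      elm_score_printed = score,
      pathway = cl$pathway %||% "",
      kind = cl$kind %||% "ligand-site",
      whitelisted = isTRUE(cl$whitelisted),
      syde = cl$syde %||% ""
    ), class = "motif_class")
    classes[[id]] <- mc
    for (inst in cl$instances %||% list()) {
      pep <- toupper(inst$peptide)
      start <- as.integer(inst$start); end <- as.integer(inst$end)
      if (end - start + 1L != nchar(pep)) {
        stop("class '", id, "': instance '", pep, "' at ", start, "-", end,
             " disagrees with peptide length ", nchar(pep))
      }
      instances[[length(instances) + 1L]] <- data.frame(
        motif_id = id, protein_id = inst$protein_id,
        start = start, end = end, peptide = pep,
        stringsAsFactors = FALSE)
    }
  }
  instances <- if (length(instances)) do.call(rbind, instances) else
    data.frame(motif_id = character(0), protein_id = character(0),
               start = integer(0), end = integer(0), peptide = character(0))
  sites <- do.call(rbind, lapply(raw$sites %||% list(), function(s) {
    data.frame(protein_id = s$protein_id, site_type = s$site_type,
               start = as.integer(s$start), end = as.integer(s$end),
               peptide = toupper(s$peptide %||% ""), source = s$source %||% "",
               stringsAsFactors = FALSE)
  }))
  if (is.null(sites)) {
    sites <- data.frame(protein_id = character(0), site_type = character(0),
                        start = integer(0), end = integer(0),
                        peptide = character(0), source = character(0))
  }
  structure(list(classes = classes, instances = instances, sites = sites,
                 version = raw$version %||% NA, path = path),
            class = "motif_catalog")
}

empty_catalog <- function() {
  structure(list(
    classes = list(),
    instances = data.frame(motif_id = character(0), protein_id = character(0),
                           start = integer(0), end = integer(0),
                           peptide = character(0)),
    sites = data.frame(protein_id = character(0), site_type = character(0),
                       start = integer(0), end = integer(0),
                       peptide = character(0), source = character(0)),
    version = NA, path = NA_character_), class = "motif_catalog")
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat("<motif_catalog> ", length(x$classes), " classes, ",
      nrow(x$instances), " instances, ", nrow(x$sites),
      " site annotations\n", sep = "")
  invisible(x)
}

#' Serialize a catalog back to YAML
#'
#' Writes a catalog in the same schema accepted by [load_catalog()], so
#' that write/load round-trips are lossless.
#'
#' @param catalog A `motif_catalog`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "motif_catalog"))
  classes <- lapply(catalog$classes, function(cl) {
    inst <- catalog$instances[catalog$instances$motif_id == cl$motif_id, ,
                              drop = FALSE]
    out <- list(motif_id = cl$motif_id, elm_class = cl$elm_class,
                interactor = cl$interactor,
                consensus_text = cl$consensus_text, pattern = cl$pattern,
                elm_score_printed = cl$elm_score_printed,
                pathway = cl$pathway, kind = cl$kind, syde = cl$syde)
    if (cl$whitelisted) out$whitelisted <- TRUE
    out$instances <- lapply(seq_len(nrow(inst)), function(i) {
      list(protein_id = inst$protein_id[i], start = inst$start[i],
           end = inst$end[i], peptide = inst$peptide[i])
    })
    out
  })
  sites <- lapply(seq_len(nrow(catalog$sites)), function(i) {
    s <- catalog$sites[i, ]
    list(protein_id = s$protein_id, site_type = s$site_type,
         start = s$start, end = s$end, peptide = s$peptide,
         source = s$source)
  })
  yaml::write_yaml(list(version = catalog$version, classes = unname(classes),
                        sites = sites), path)
  invisible(path)
}

#' Validate a motif catalog
#'
#' Runs, for every packaged instance, (a) the pattern-vs-instance check --
#' the owning class pattern must match somewhere inside the instance
#' peptide -- and, when the corresponding sequences are supplied, (b) the
#' coordinate check: the instance peptide must occur at its stated start
#' (via [locate_peptide()]). Site annotations are bounds-checked against
#' supplied sequences. Validation reports; it does not throw.
#'
#' @param catalog A `motif_catalog`.
#' @param sequences Optional named list of [protein_record]s; names (or
#'   record ids) must match instance `protein_id`s (e.g. `"SYDE1"`).
#' @return An object of class `catalog_validation`: list with `instances`
#'   (per-instance `data.frame` of verdicts), `sites`, and `pass`
#'   (overall logical over all checks that could be run).
#' @export
validate_catalog <- function(catalog, sequences = NULL) {
  stopifnot(inherits(catalog, "motif_catalog"))
  inst <- catalog$instances
  pattern_ok <- logical(nrow(inst))
  coord_ok <- rep(NA, nrow(inst))
  for (i in seq_len(nrow(inst))) {
    cl <- catalog$classes[[inst$motif_id[i]]]
    pep_rec <- protein_record(".instance", inst$peptide[i])
    pattern_ok[i] <- nrow(scan_motifs(pep_rec, cl)) > 0
    if (!is.null(sequences) && inst$protein_id[i] %in% names(sequences)) {
      rec <- sequences[[inst$protein_id[i]]]
      coord_ok[i] <- inst$start[i] %in% locate_peptide(rec, inst$peptide[i])
    }
  }
  inst_report <- cbind(inst,
                       data.frame(pattern_ok = pattern_ok, coord_ok = coord_ok))
  site_ok <- rep(NA, nrow(catalog$sites))
  if (!is.null(sequences) && nrow(catalog$sites)) {
    for (i in seq_len(nrow(catalog$sites))) {
      s <- catalog$sites[i, ]
      if (s$protein_id %in% names(sequences)) {
        rec <- sequences[[s$protein_id]]
        within <- s$start >= 1 && s$end <= rec$length
        pep_there <- !nzchar(s$peptide) ||
          (within && extract_region(rec, s) == s$peptide)
        site_ok[i] <- within && pep_there
      }
    }
  }
  checks <- c(pattern_ok, coord_ok[!is.na(coord_ok)], site_ok[!is.na(site_ok)])
  structure(list(instances = inst_report,
                 sites = cbind(catalog$sites, data.frame(site_ok = site_ok)),
                 pass = all(checks)),
            class = "catalog_validation")
}

#' @export
print.catalog_validation <- function(x, ...) {
  n <- nrow(x$instances)
  cat("<catalog_validation> ", sum(x$instances$pattern_ok), "/", n,
      " pattern checks pass", sep = "")
  nc <- sum(!is.na(x$instances$coord_ok))
  if (nc) cat("; ", sum(x$instances$coord_ok, na.rm = TRUE), "/", nc,
              " coordinate checks pass", sep = "")
  cat("; overall ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  failed <- x$instances[!x$instances$pattern_ok |
                          (!is.na(x$instances$coord_ok) & !x$instances$coord_ok), ]
  if (nrow(failed)) print(failed)
  invisible(x)
}

#' Default selection whitelist of a catalog
#'
#' Motif classes flagged `whitelisted` in the catalog file: these bypass
#' the probability threshold during [select_candidates()] (modification
#' site classes and LIG_SH3_3, which are selected on disorder propensity
#' and annotated phosphosites rather than on motif probability).
#'
#' @param catalog A `motif_catalog`.
#' @return Character vector of motif ids.
#' @export
default_whitelist <- function(catalog) {
  ids <- vapply(catalog$classes, `[[`, character(1), "motif_id")
  unname(ids[vapply(catalog$classes, `[[`, logical(1), "whitelisted")])
}

#' Candidate rows from the packaged instances
#'
#' Converts the catalog's packaged instances into retained candidate-table
#' rows (the published instances are, by construction, located in
#' disordered regions and conserved), mainly for assembling the published
#' interaction network without rescanning the source sequences.
#'
#' @param catalog A `motif_catalog`.
#' @param bg Background model for the attached probabilities.
#' @return A candidate `data.frame` compatible with [assemble_network()].
#' @export
catalog_candidates <- function(catalog, bg = background_frequencies()) {
  inst <- catalog$instances
  probs <- vapply(catalog$classes, site_probability, numeric(1), bg = bg)
  data.frame(protein_id = inst$protein_id, motif_id = inst$motif_id,
             start = inst$start, end = inst$end, peptide = inst$peptide,
             site_probability = unname(probs[inst$motif_id]),
             in_disorder = TRUE, conserved_fraction = 1,
             retained = TRUE, reasons = "packaged-instance",
             stringsAsFactors = FALSE)
}
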