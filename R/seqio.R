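#' Create a protein record
#'
#' A protein record is an identified amino-acid sequence with optional
#' accession and species metadata. Sequences are case-normalized to upper
#' case and may contain the 20 standard residues plus `X` (unknown).
#'
#' @param id Short label for the sequence (e.g. `"SYDE1_HUMAN"`).
#' @param sequence Amino-acid sequence as a single string.
#' @param accession UniProt-style accession, or `""` when unknown.
#' @param species Free-text species tag, or `""`.
#' @return An object of class `protein_record` with fields `id`,
#'   `accession`, `species`, `sequence` and `length`.
#' @examples
#' protein_record("toy", "MKRP")
#' @export
protein_record <- function(id, sequence, accession = "", species = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("protein record '", id, "': sequence is empty")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(AA20, "X"))
  if (length(bad)) {
    stop("protein record '", id, "': illegal character '", chars[bad[1]],
         "' at position ", bad[1])
  }
  structure(
    list(id = id, accession = accession, species = species,
         sequence = sequence, length = nchar(sequence)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  acc <- if (nzchar(x$accession)) paste0(" [", x$accession, "]") else ""
  cat("<protein_record> ", x$id, acc, ", ", x$length, " aa\n", sep = "")
  invisible(x)
}

parse_fasta_header <- function(header) {
  header <- sub("^>", "", header)
  token <- sub("\\s.*$", "", header)
  rest <- sub("^\\S+\\s*", "", header)
  species <- ""
  m <- regmatches(rest, regexpr("OS=.*?(?=\\s+[A-Z]{2}=|$)", rest, perl = TRUE))
  if (length(m) && nzchar(m)) species <- sub("^OS=", "", m)
  if (grepl("^(sp|tr)\\|", token)) {
    parts <- strsplit(token, "|", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed UniProt header: '", header, "'")
    }
    list(id = parts[3], accession = parts[2], species = species)
  } else {
    list(id = token, accession = "", species = species)
  }
}

#' Read protein sequences from a FASTA file
#'
#' UniProt-style headers (`sp|ACC|NAME` or `tr|ACC|NAME`) are parsed into
#' accession and id; any `OS=` tag is kept as the species. Plain headers
#' keep the full first token as the id with an empty accession. Input
#' order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record] objects, named by id.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("no sequences in ", path))
  if (length(set) == 0L) stop("no sequences in ", path)
  records <- lapply(seq_along(set), function(i) {
    h <- parse_fasta_header(names(set)[i])
    tryCatch(
      protein_record(h$id, as.character(set[[i]]),
                     accession = h$accession, species = h$species),
      error = function(e) stop("while reading ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  names(records) <- vapply(records, `[[`, character(1), "id")
  records
}

#' Write protein records to a FASTA file
#'
#' Records with an accession are written with a UniProt-style `sp|ACC|ID`
#' header so that [read_fasta()] round-trips them exactly; a non-empty
#' species is appended as an `OS=` tag. Sequences are wrapped at
#' `width` columns.
#'
#' @param records A [protein_record] or list of them.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (inherits(records, "protein_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    head <- if (nzchar(r$accession)) {
      paste0(">sp|", r$accession, "|", r$id)
    } else {
      paste0(">", r$id)
    }
    if (nzchar(r$species)) head <- paste0(head, " OS=", r$species)
    starts <- seq(1L, r$length, by = width)
    c(head, substring(r$sequence, starts, pmin(starts + width - 1L, r$length)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Create a region annotation
#'
#' An interval annotation on a protein, 1-based inclusive. Point
#' annotations (e.g. a palmitoylation site) have `start == end`.
#'
#' @param protein_id Protein the annotation refers to.
#' @param label One of `"C2"`, `"RhoGAP"`, `"disorder"`, `"NES"`,
#'   `"palmitoylation-site"`, or a custom label.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param source Free-text provenance (e.g. `"InterProScan-derived"`).
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(protein_id, label, start, end, source = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("non-integer coordinate in annotation")
  if (start < 1L) stop("coordinates are 1-based: start ", start, " < 1")
  if (start > end) stop("invalid annotation: start ", start, " > end ", end)
  structure(list(protein_id = protein_id, label = label,
                 start = start, end = end, source = source),
            class = "region_annotation")
}

#' Extract the residues covered by a region
#'
#' @param record A [protein_record].
#' @param region A [region_annotation], or any list with `start` and `end`.
#' @return The substring `record$sequence[start..end]` (1-based inclusive).
#' @examples
#' r <- protein_record("toy", "ABCDE")
#' extract_region(r, list(start = 2, end = 4))  # "BCD"
#' @export
extract_region <- function(record, region) {
  stopifnot(inherits(record, "protein_record"))
  start <- as.integer(region$start); end <- as.integer(region$end)
  if (start < 1L || end > record$length || start > end) {
    stop("region ", start, "..", end, " out of bounds for '", record$id,
         "' (1..", record$length, ")")
  }
  substr(record$sequence, start, end)
}

#' Locate all exact occurrences of a peptide
#'
#' Reports every 1-based start position at which `peptide` occurs in the
#' record, including overlapping occurrences, in ascending order.
#'
#' @param record A [protein_record].
#' @param peptide Non-empty peptide string.
#' @return Integer vector of start positions (possibly empty).
#' @examples
#' locate_peptide(protein_record("toy", "AAAA"), "AA")  # 1 2 3
#' @export
locate_peptide <- function(record, peptide) {
  stopifnot(inherits(record, "protein_record"))
  peptide <- toupper(peptide)
  if (!nzchar(peptide)) stop("peptide must be non-empty")
  if (nchar(peptide) > record$length) return(integer(0))
  hits <- Biostrings::matchPattern(peptide, Biostrings::BString(record$sequence))
  sort(as.integer(IRanges::start(hits)))
}

region_table_columns <- c("protein_id", "label", "start", "end", "source")

#' Read an interval annotation table
#'
#' Expects a TSV with columns `protein_id`, `label`, `start`, `end`,
#' `source` (the import format for disorder, domain-boundary, NES and
#' site tables). Coordinates are validated as 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of validated annotations, one row per interval.
#' @seealso [write_region_table()]
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(region_table_columns, names(tab))
  if (length(missing)) {
    stop("annotation table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, region_table_columns]
  for (col in c("start", "end")) {
    val <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(val) | as.numeric(tab[[col]]) != val)
    if (length(bad)) {
      stop("annotation table ", path, ", row ", bad[1],
           ": non-integer ", col, " '", tab[[col]][bad[1]], "'")
    }
    tab[[col]] <- val
  }
  bad <- which(tab$start < 1L)
  if (length(bad)) {
    stop("annotation table ", path, ", row ", bad[1],
         ": coordinates are 1-based (start ", tab$start[bad[1]], ")")
  }
  bad <- which(tab$start > tab$end)
  if (length(bad)) {
    stop("annotation table ", path, ", row ", bad[1], ": start ",
         tab$start[bad[1]], " > end ", tab$end[bad[1]])
  }
  tab
}

#' Write an interval annotation table
#'
#' @param annotations A `data.frame` with the columns of
#'   [read_region_table()], or a list of [region_annotation] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_table <- function(annotations, path) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- do.call(rbind, lapply(annotations, function(a) {
      data.frame(protein_id = a$protein_id, label = a$label,
                 start = a$start, end = a$end, source = a$source,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(region_table_columns %in% names(annotations)))
  utils::write.table(annotations[, region_table_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
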