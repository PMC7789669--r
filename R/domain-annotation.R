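#' Read a per-strain protein-domain annotation table
#'
#' Parses the tab-separated annotation format produced by domain-annotation
#' tools (and by [write_domain_annotations()]): one domain hit per row with
#' columns `strain_id`, `protein_id`, `domain_accession`, `start`, `end`.
#' Coordinates are 1-based residue positions on the protein, `end` inclusive.
#'
#' @param file Path to a tab-separated annotation table with a header line.
#' @return A tibble of domain hits, one row per hit, in file order.
#' @details Rows violating the coordinate invariant (`1 <= start <= end`) or
#'   with non-integer coordinates raise a parse error naming the offending
#'   data line (line 1 is the first line after the header).
#' @export
read_domain_annotations <- function(file) {
  raw <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("strain_id", "protein_id", "domain_accession", "start", "end")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("annotation table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "anaerodesign_parse_error")
  }
  as_domain_hits(raw[required])
}

# Validate a raw hits data frame and coerce coordinate columns to integer.
as_domain_hits <- function(df) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) {
    return(tibble::tibble(strain_id = character(), protein_id = character(),
                          domain_accession = character(),
                          start = integer(), end = integer()))
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad_num <- which(is.na(start) | is.na(end) |
                     start != floor(start) | end != floor(end))
  if (length(bad_num) > 0) {
    abort(sprintf("non-integer domain coordinates on line %d", bad_num[1]),
          class = "anaerodesign_parse_error", line = bad_num[1])
  }
  bad_ord <- which(start < 1 | end < start)
  if (length(bad_ord) > 0) {
    abort(sprintf("invalid domain coordinates (need 1 <= start <= end) on line %d",
                  bad_ord[1]),
          class = "anaerodesign_parse_error", line = bad_ord[1])
  }
  df$start <- as.integer(start)
  df$end <- as.integer(end)
  df
}

#' Write a domain annotation table
#'
#' Inverse of [read_domain_annotations()]; emits the tab-separated format the
#' reader consumes, so simulated data round-trips through the ingest path.
#'
#' @param hits A domain-hit tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_domain_annotations <- function(hits, file) {
  readr::write_tsv(hits, file, progress = FALSE)
  invisible(file)
}

#' Build per-strain domain-architecture catalogs
#'
#' A domain architecture is the ordered list of domain accessions along a
#' protein (N- to C-terminal, ordered by start position; ties broken by end,
#' then accession). Identical architectures within one strain are collapsed
#' and counted, giving a copy number that is part of the orthology identity:
#' a strain carrying two copies of an architecture carries a different
#' orthology key than a strain carrying one.
#'
#' @param hits A domain-hit tibble (see [read_domain_annotations()]).
#' @return A tibble with one row per (strain, architecture): columns
#'   `strain_id`, `architecture` (accessions joined by `";"`), `copy_number`,
#'   and `key` (the orthology key: the architecture string, suffixed
#'   `"|<copy_number>"` when the copy number exceeds 1).
#' @export
build_architectures <- function(hits) {
  hits <- as_domain_hits(hits)
  if (nrow(hits) == 0) {
    return(tibble::tibble(strain_id = character(), architecture = character(),
                          copy_number = integer(), key = character()))
  }
  hits |>
    dplyr::arrange(.data$start, .data$end, .data$domain_accession) |>
    dplyr::group_by(.data$strain_id, .data$protein_id) |>
    dplyr::summarise(
      architecture = paste(.data$domain_accession, collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::count(.data$strain_id, .data$architecture, name = "copy_number") |>
    dplyr::mutate(key = orthology_key(.data$architecture, .data$copy_number)) |>
    dplyr::arrange(.data$strain_id, .data$architecture)
}

#' Form an orthology key from an architecture string and a copy number
#'
#' @param architecture Architecture strings (accessions joined by `";"`).
#' @param copy_number Integer copy numbers (>= 1).
#' @return Character keys; single-copy architectures keep the bare
#'   architecture string, multi-copy ones gain a `"|<n>"` suffix.
#' @export
orthology_key <- function(architecture, copy_number) {
  ifelse(copy_number > 1L,
         paste0(architecture, "|", copy_number),
         architecture)
}

#' Strip the copy-number suffix from orthology keys
#'
#' @param key Orthology keys as produced by [orthology_key()].
#' @return The bare architecture strings.
#' @export
strip_copy_number <- function(key) {
  sub("\\|[0-9]+$", "", key)
}

#' Assemble the strains-by-architectures matrix
#'
#' @param catalogs Per-strain architecture catalog, as returned by
#'   [build_architectures()] (or any tibble with `strain_id`, `architecture`
#'   and `copy_number`).
#' @param labels Strain label table: a tibble with columns `strain_id` and
#'   `lifestyle` (values `"aerobic"` / `"anaerobic"`). Every strain present
#'   in `catalogs` must appear here; strains with no catalog entries get
#'   all-zero rows.
#' @return A `domain_matrix` object: an integer copy-count matrix (strains in
#'   label-table order by rows, architectures lexicographically by columns)
#'   with the label table attached. Use [binarize()] for the presence/absence
#'   view and [tidy()] for a long tibble.
#' @export
build_architecture_matrix <- function(catalogs, labels) {
  labels <- validate_labels(labels)
  catalogs <- tibble::as_tibble(catalogs)
  unknown <- setdiff(unique(catalogs$strain_id), labels$strain_id)
  if (length(unknown) > 0) {
    abort(sprintf("strain(s) in catalog missing from label table: %s",
                  paste(sort(unknown), collapse = ", ")),
          class = "anaerodesign_label_error", strains = unknown)
  }
  archs <- sort(unique(catalogs$architecture))
  counts <- matrix(0L, nrow = nrow(labels), ncol = length(archs),
                   dimnames = list(labels$strain_id, archs))
  if (nrow(catalogs) > 0) {
    counts[cbind(match(catalogs$strain_id, labels$strain_id),
                 match(catalogs$architecture, archs))] <-
      as.integer(catalogs$copy_number)
  }
  new_domain_matrix(counts, labels)
}

validate_labels <- function(labels) {
  labels <- tibble::as_tibble(labels)
  required <- c("strain_id", "lifestyle")
  if (!all(required %in% names(labels))) {
    abort("label table needs columns 'strain_id' and 'lifestyle'",
          class = "anaerodesign_label_error")
  }
  if (anyDuplicated(labels$strain_id)) {
    abort("duplicate strain_id in label table",
          class = "anaerodesign_label_error")
  }
  bad <- setdiff(unique(labels$lifestyle), c("aerobic", "anaerobic"))
  if (length(bad) > 0) {
    abort(sprintf("unknown lifestyle label(s): %s", paste(bad, collapse = ", ")),
          class = "anaerodesign_label_error")
  }
  labels
}

new_domain_matrix <- function(counts, labels) {
  stopifnot(is.matrix(counts), nrow(counts) == nrow(labels))
  structure(list(counts = counts, labels = labels), class = "domain_matrix")
}

#' @export
print.domain_matrix <- function(x, ...) {
  cat(sprintf("<domain_matrix> %d strains x %d architectures (%d aerobic, %d anaerobic)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$labels$lifestyle == "aerobic"),
              sum(x$labels$lifestyle == "anaerobic")))
  invisible(x)
}

#' @export
dim.domain_matrix <- function(x) dim(x$counts)

#' Binarize a domain matrix to presence/absence
#'
#' Clips copy counts to 0/1. Idempotent; copy-number information is dropped,
#' matching the presence/absence view used for ordination and clustering.
#'
#' @param x A `domain_matrix`.
#' @return A `domain_matrix` whose counts are in `{0, 1}`.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "domain_matrix"))
  counts <- x$counts
  counts[counts > 1L] <- 1L
  new_domain_matrix(counts, x$labels)
}

#' Expand a domain matrix to copy-aware orthology-key indicators
#'
#' Orthologs are identified by architecture identity *considering copy
#' number*: the unit of comparison is the pair (architecture, copy number).
#' This returns the binary indicator matrix over the orthology keys observed
#' anywhere in the data set.
#'
#' @param x A `domain_matrix`.
#' @return A binary integer matrix, strains by orthology keys.
#' @export
orthology_indicators <- function(x) {
  stopifnot(inherits(x, "domain_matrix"))
  counts <- x$counts
  idx <- which(counts > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(matrix(0L, nrow = nrow(counts), ncol = 0,
                  dimnames = list(rownames(counts), character())))
  }
  keys <- orthology_key(colnames(counts)[idx[, "col"]], counts[idx])
  ukeys <- sort(unique(keys))
  out <- matrix(0L, nrow = nrow(counts), ncol = length(ukeys),
                dimnames = list(rownames(counts), ukeys))
  out[cbind(idx[, "row"], match(keys, ukeys))] <- 1L
  out
}

#' @export
tidy.domain_matrix <- function(x, ...) {
  idx <- which(x$counts > 0L, arr.ind = TRUE)
  tibble::tibble(
    strain_id = rownames(x$counts)[idx[, "row"]],
    architecture = colnames(x$counts)[idx[, "col"]],
    count = x$counts[idx]
  ) |>
    dplyr::arrange(.data$strain_id, .data$architecture)
}

#' Write a domain matrix as a sparse triplet table
#'
#' @param x A `domain_matrix`.
#' @param file Output path; tab-separated `strain_id`, `architecture`, `count`.
#' @return `file`, invisibly.
#' @export
write_architecture_matrix <- function(x, file) {
  readr::write_tsv(tidy(x), file, progress = FALSE)
  invisible(file)
}

#' Read and write strain label tables
#'
#' Tab-separated, columns `strain_id` and `lifestyle`.
#'
#' @param file Path to read from or write to.
#' @return `read_label_table()` returns the validated label tibble;
#'   `write_label_table()` returns `file` invisibly.
#' @export
read_label_table <- function(file) {
  validate_labels(readr::read_tsv(file, col_types = "cc", progress = FALSE))
}

#' @rdname read_label_table
#' @param labels A label tibble.
#' @export
write_label_table <- function(labels, file) {
  readr::write_tsv(validate_labels(labels), file, progress = FALSE)
  invisible(file)
}
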