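# Evidence integration: merge protein-domain-comparison lists, transcriptome
# selections and metabolic-model gap findings into one categorized design.

KNOWN_FUNCTION_CATEGORIES <- c(
  "nitrogen metabolism", "hydrogenases", "cytochrome C",
  "pyrimidine & amino acid biosynthesis", "ATP generation"
)
DESIGN_CATEGORIES <- c(KNOWN_FUNCTION_CATEGORIES, "unknown function", "excluded")

#' Merge candidate evidence from all methods
#'
#' Builds the union of candidates found by protein domain comparison (PDC),
#' transcriptome analysis (T) and genome-scale-model simulation (GSM), with
#' source tags recording which method(s) contributed each candidate.
#' Cumulative Gini coefficients are attached as weights where available
#' (0 otherwise) and do not gate inclusion. Candidates on the
#' aerobe-specific PDC list are tagged `excluded`.
#'
#' @param pdc A `core_split` (the anaerobe-specific list is the PDC
#'   evidence; the aerobe-specific list marks exclusions).
#' @param gini Optional `gini_table` for weights.
#' @param transcriptome Character vector of architecture keys selected by
#'   the consistency filter (mapped via [map_genes_to_architectures()]).
#' @param gsm Character vector of gene labels implicated by the
#'   flux-balance gap analysis.
#' @param category_map Optional tibble (`key`, `category`) assigning
#'   functional categories; categories must come from the fixed design set.
#'   Unmapped candidates fall into `"unknown function"`.
#' @param gsm_join Optional tibble (`gene`, `key`) translating GSM gene
#'   labels onto architecture keys; every GSM gene must then be covered.
#' @return An `evidence_table` tibble: `key`, `source` (comma-joined tags),
#'   `src_pdc`, `src_t`, `src_gsm`, `gini_weight`, `category`,
#'   `unknown_function`.
#' @export
merge_evidence <- function(pdc, gini = NULL, transcriptome = character(),
                           gsm = character(), category_map = NULL,
                           gsm_join = NULL) {
  stopifnot(inherits(pdc, "core_split"))
  if (!is.null(gsm_join)) {
    gsm_join <- tibble::as_tibble(gsm_join)
    missing <- setdiff(gsm, gsm_join$gene)
    if (length(missing) > 0) {
      abort(sprintf("GSM gene(s) missing from join table: %s",
                    paste(sort(missing), collapse = ", ")),
            class = "anaerodesign_join_error", offenders = missing)
    }
    gsm <- gsm_join$key[match(gsm, gsm_join$gene)]
  }
  keys <- sort(unique(c(pdc$anaerobe_specific, pdc$aerobe_specific,
                        transcriptome, gsm)))
  out <- tibble::tibble(
    key = keys,
    src_pdc = keys %in% c(pdc$anaerobe_specific, pdc$aerobe_specific),
    src_t = keys %in% transcriptome,
    src_gsm = keys %in% gsm
  )
  out$source <- purrr::pmap_chr(out[c("src_pdc", "src_t", "src_gsm")],
                                function(src_pdc, src_t, src_gsm) {
                                  paste(c("PDC", "T", "GSM")[c(src_pdc, src_t, src_gsm)],
                                        collapse = ",")
                                })
  out$gini_weight <- 0
  if (!is.null(gini)) {
    idx <- match(out$key, gini$architecture)
    out$gini_weight[!is.na(idx)] <- gini$cumulative_gini[idx[!is.na(idx)]]
  }
  out$category <- "unknown function"
  if (!is.null(category_map)) {
    category_map <- tibble::as_tibble(category_map)
    bad <- setdiff(unique(category_map$category), DESIGN_CATEGORIES)
    if (length(bad) > 0) {
      abort(sprintf("unknown design categor(ies): %s", paste(bad, collapse = ", ")),
            class = "anaerodesign_config_error")
    }
    idx <- match(out$key, category_map$key)
    out$category[!is.na(idx)] <- category_map$category[idx[!is.na(idx)]]
  }
  out$category[out$key %in% pdc$aerobe_specific] <- "excluded"
  out$unknown_function <- out$category == "unknown function"
  structure(out, class = c("evidence_table", class(out)))
}

#' Co-localisation filter for domains of unknown function
#'
#' A DUF is retained when, in at least `min_fraction` of the anaerobic
#' genomes carrying it, its gene lies within `window` genes (gene-order
#' distance, strand-agnostic) of a gene whose architecture is on the
#' retained known-function list. Other DUFs are reported `unresolved`.
#'
#' @param duf Character vector of DUF architecture keys.
#' @param coords Gene coordinate tibble (`strain_id`, `gene_index`,
#'   `architecture`), covering the anaerobic strains.
#' @param retained Character vector of retained known-function architecture
#'   keys (the co-localisation anchors).
#' @param labels Optional strain label tibble; when given, only anaerobic
#'   strains are considered carriers.
#' @param window Maximum gene-order distance (default 5); `window = 0`
#'   retains nothing since distinct genes are at distance >= 1.
#' @param min_fraction Minimum fraction of carrier genomes with a
#'   co-localised anchor (default 0.5).
#' @return Tibble `key`, `n_carriers`, `n_colocalised`, `fraction`,
#'   `status` (`"retained"` / `"unresolved"`).
#' @export
duf_colocalisation_filter <- function(duf, coords, retained, labels = NULL,
                                      window = 5, min_fraction = 0.5) {
  if (!is.numeric(window) || length(window) != 1L || window < 0) {
    abort("window must be a non-negative gene count",
          class = "anaerodesign_config_error")
  }
  coords <- tibble::as_tibble(coords)
  if (!is.null(labels)) {
    ana <- labels$strain_id[labels$lifestyle == "anaerobic"]
    coords <- coords[coords$strain_id %in% ana, ]
  }
  purrr::map_dfr(sort(unique(duf)), function(d) {
    carriers <- coords[coords$architecture == d, ]
    n_carriers <- dplyr::n_distinct(carriers$strain_id)
    n_coloc <- 0L
    for (s in unique(carriers$strain_id)) {
      duf_pos <- carriers$gene_index[carriers$strain_id == s]
      anchor_pos <- coords$gene_index[coords$strain_id == s &
                                        coords$architecture %in% retained]
      if (length(anchor_pos) > 0 &&
          any(vapply(duf_pos, function(p) {
            d_min <- min(abs(anchor_pos - p))
            d_min >= 1 && d_min <= window
          }, logical(1)))) {
        n_coloc <- n_coloc + 1L
      }
    }
    frac <- if (n_carriers > 0) n_coloc / n_carriers else 0
    tibble::tibble(key = d, n_carriers = n_carriers, n_colocalised = n_coloc,
                   fraction = frac,
                   status = if (n_carriers > 0 && frac >= min_fraction)
                     "retained" else "unresolved")
  })
}

#' Summarize a design into category counts and totals
#'
#' @param design A design tibble with at least `entry` and `category`
#'   columns; optional `n_domains` (default 1 per entry) and `entry_type`
#'   (`"gene"`, `"domain"` or `"vitamin"`; `"unknown function"` rows default
#'   to `"domain"`, all other rows to `"gene"`). Vitamin rows are moved to
#'   the supplement list. Rows in category `"excluded"` are dropped from
#'   the retained design but kept in the table for audit.
#' @param supplements Additional vitamin supplement names.
#' @return A `design_table`: list with `design` (retained entries, ordered
#'   by category then entry), `excluded`, `supplements`, `summary`
#'   (per-category gene and domain counts) and `totals` (one-row tibble:
#'   `known_function_genes`, `unknown_function_domains`, `total_entries`,
#'   `n_vitamins`).
#' @export
summarize_design <- function(design, supplements = character()) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("entry", "category") %in% names(design)))
  bad <- setdiff(unique(design$category), DESIGN_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("unknown design categor(ies): %s", paste(bad, collapse = ", ")),
          class = "anaerodesign_config_error")
  }
  if (!"n_domains" %in% names(design)) design$n_domains <- 1L
  if (!"entry_type" %in% names(design)) {
    design$entry_type <- ifelse(design$category == "unknown function",
                                "domain", "gene")
  }
  supplements <- sort(unique(c(supplements,
                               design$entry[design$entry_type == "vitamin"])))
  design <- design[design$entry_type != "vitamin", ]
  overlap <- intersect(supplements, design$entry)
  if (length(overlap) > 0) {
    abort(sprintf("vitamin list overlaps gene list: %s",
                  paste(overlap, collapse = ", ")),
          class = "anaerodesign_config_error")
  }
  retained <- design[design$category != "excluded", ]
  retained <- retained[order(match(retained$category, DESIGN_CATEGORIES),
                             retained$entry), ]
  summary <- retained |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_genes = sum(.data$entry_type == "gene"),
                     n_domains = sum(.data$n_domains), .groups = "drop") |>
    dplyr::arrange(match(.data$category, DESIGN_CATEGORIES))
  known <- retained[retained$category %in% KNOWN_FUNCTION_CATEGORIES, ]
  unknown <- retained[retained$category == "unknown function", ]
  totals <- tibble::tibble(
    known_function_genes = sum(known$entry_type == "gene"),
    unknown_function_domains = nrow(unknown),
    total_entries = sum(known$entry_type == "gene") + nrow(unknown),
    n_vitamins = length(supplements)
  )
  structure(list(design = retained,
                 excluded = design[design$category == "excluded", ],
                 supplements = supplements,
                 summary = summary, totals = totals),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %d known-function genes + %d unknown-function domains = %d entries; %d vitamin supplement(s)\n",
              x$totals$known_function_genes, x$totals$unknown_function_domains,
              x$totals$total_entries, x$totals$n_vitamins))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.design_table <- function(x, ...) x$design

#' @export
glance.design_table <- function(x, ...) x$totals

#' @export
autoplot.design_table <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$n_genes,
                               stats::reorder(.data$category, .data$n_genes))) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = "genes in design", y = NULL) +
    ggplot2::theme_minimal()
}

#' Packaged reference design tables
#'
#' The curated gene/vitamin design for converting an obligate aerobic
#' *Pseudomonas putida* to anaerobic respiration, shipped as a plain-text
#' fixture: one row per design entry with its functional category, domain
#' count and evidence source tags (PDC/T/GSM).
#'
#' @return A tibble with columns `category`, `entry`, `entry_type`, `pfam`,
#'   `n_domains`, `source`.
#' @export
load_design_tables <- function() {
  readr::read_tsv(system.file("extdata", "design_tables.tsv",
                              package = "anaerodesign", mustWork = TRUE),
                  col_types = "ccccic", progress = FALSE)
}

#' Packaged strain group counts
#'
#' Lifestyle-group sizes of the genome comparison underlying the reference
#' design: the full strain collection and the restricted dendrogram branch.
#'
#' @return A tibble with columns `scope`, `lifestyle`, `n_strains`.
#' @export
load_strain_group_counts <- function() {
  readr::read_tsv(system.file("extdata", "strain_group_counts.tsv",
                              package = "anaerodesign", mustWork = TRUE),
                  col_types = "cci", progress = FALSE)
}
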