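#' A counts-plus-conditions container
#'
#' Bundles a genes-by-samples count matrix with its sample-to-condition map
#' and the reference condition against which all fold changes are computed.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene IDs), samples in columns (colnames are sample IDs); or a data frame
#'   with a `gene_id` column followed by sample columns.
#' @param condition_map Tibble with columns `sample` and `condition`
#'   covering every count column.
#' @param reference Reference condition label; must occur in the map.
#' @return A `count_dataset` object.
#' @export
count_dataset <- function(counts, condition_map, reference) {
  if (is.data.frame(counts)) {
    stopifnot("gene_id" %in% names(counts))
    m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
    rownames(m) <- counts$gene_id
    counts <- m
  }
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) abort("counts must be non-negative",
                             class = "anaerodesign_config_error")
  condition_map <- tibble::as_tibble(condition_map)
  unmapped <- setdiff(colnames(counts), condition_map$sample)
  if (length(unmapped) > 0) {
    abort(sprintf("sample(s) missing from condition map: %s",
                  paste(unmapped, collapse = ", ")),
          class = "anaerodesign_config_error")
  }
  condition_map <- condition_map[match(colnames(counts), condition_map$sample), ]
  if (!reference %in% condition_map$condition) {
    abort(sprintf("reference condition '%s' has no samples", reference),
          class = "anaerodesign_config_error")
  }
  structure(list(counts = counts, condition_map = condition_map,
                 reference = reference),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("<count_dataset> %d genes x %d samples, %d conditions (reference: %s)\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$condition_map$condition), x$reference))
  invisible(x)
}

#' Conditions of a count data set
#' @param x A `count_dataset`.
#' @param drop_reference Drop the reference condition from the result.
#' @return Character vector of condition labels in map order.
#' @export
conditions <- function(x, drop_reference = FALSE) {
  stopifnot(inherits(x, "count_dataset"))
  out <- unique(x$condition_map$condition)
  if (drop_reference) out <- setdiff(out, x$reference)
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of that sample's count to the gene's geometric mean across all
#' samples. Genes with a zero count in any sample are excluded from the
#' reference set, as in the standard count-normalization scheme used for
#' RNA-seq differential expression.
#'
#' @param x A `count_dataset`.
#' @return Tibble with columns `sample` and `size_factor` (all positive).
#' @export
size_factors <- function(x) {
  stopifnot(inherits(x, "count_dataset"))
  counts <- x$counts
  eligible <- rowSums(counts == 0) == 0
  if (!any(eligible)) {
    abort("no gene has nonzero counts in every sample; cannot normalize",
          class = "anaerodesign_normalization_error")
  }
  logc <- log(counts[eligible, , drop = FALSE])
  log_geo_mean <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(median(col - log_geo_mean)))
  tibble::tibble(sample = colnames(counts), size_factor = as.numeric(sf))
}

normalized_counts <- function(x) {
  sf <- size_factors(x)
  sweep(x$counts, 2, sf$size_factor, "/")
}

#' Per-condition log2 fold change against the anaerobic reference
#'
#' Replicates within a condition are collapsed by the mean of normalized
#' counts; the fold change is reference over condition, so positive values
#' mean up-regulation during anaerobic respiration. Zero numerators or
#' denominators give infinite or undefined values, which downstream
#' imputation resolves. The per-gene FDR comes from a two-sample Welch test
#' on `log2(normalized + 0.5)` with Benjamini-Hochberg correction across
#' genes (it only gates the imputation of non-finite cells).
#'
#' @param x A `count_dataset`.
#' @param condition A non-reference condition label.
#' @param alpha Unused here; kept for interface symmetry with the rule.
#' @return Tibble `gene_id`, `log2fc`, `fdr`.
#' @export
condition_log2fc <- function(x, condition, alpha = 0.05) {
  stopifnot(inherits(x, "count_dataset"))
  if (!condition %in% x$condition_map$condition) {
    abort(sprintf("unknown condition '%s'", condition),
          class = "anaerodesign_lookup_error")
  }
  if (identical(condition, x$reference)) {
    abort("condition must differ from the reference",
          class = "anaerodesign_lookup_error")
  }
  norm <- normalized_counts(x)
  ref_cols <- x$condition_map$sample[x$condition_map$condition == x$reference]
  cond_cols <- x$condition_map$sample[x$condition_map$condition == condition]
  ref_mean <- rowMeans(norm[, ref_cols, drop = FALSE])
  cond_mean <- rowMeans(norm[, cond_cols, drop = FALSE])
  log2fc <- log2(ref_mean / cond_mean)

  pvals <- welch_p(log2(norm[, ref_cols, drop = FALSE] + 0.5),
                   log2(norm[, cond_cols, drop = FALSE] + 0.5))
  tibble::tibble(gene_id = rownames(norm),
                 log2fc = as.numeric(log2fc),
                 fdr = p.adjust(pvals, method = "BH"))
}

# Row-wise Welch t-test p-values; NA when a group has < 2 replicates or both
# groups are constant.
welch_p <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) return(rep(NA_real_, nrow(a)))
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[!is.finite(t)] <- NA_real_
  p
}

#' The direction-consistency selection rule
#'
#' Captures the selection thresholds: a gene is called consistently
#' regulated during anaerobic respiration when the same direction of
#' regulation is seen in at least `min_consistent` of the pairwise
#' comparisons against the reference, with a linear fold change of at least
#' `strong_fold` in at least `min_strong` of those same-direction
#' comparisons. With 14 conditions there are 13 comparisons and the defaults
#' are 7 consistent, 3 strong at fold 4.
#'
#' @param min_consistent Minimum same-direction comparisons (default 7).
#' @param min_strong Minimum strong comparisons among them (default 3).
#' @param strong_fold Linear fold defining "strong" (default 4, i.e.
#'   `|log2FC| >= 2`).
#' @param alpha FDR level gating imputation to `+/-4` (default 0.05).
#' @return A `consistency_rule` list.
#' @export
consistency_rule <- function(min_consistent = 7, min_strong = 3,
                             strong_fold = 4, alpha = 0.05) {
  rule <- list(
    min_consistent = check_count(min_consistent, "min_consistent", min = 1L),
    min_strong = check_count(min_strong, "min_strong", min = 0L),
    strong_fold = check_fraction(strong_fold, "strong_fold", lo = 1, hi = Inf),
    alpha = check_fraction(alpha, "alpha", lo = 0, hi = 1)
  )
  if (rule$min_strong > rule$min_consistent) {
    stop_config("min_strong", "must not exceed min_consistent")
  }
  structure(rule, class = "consistency_rule")
}

#' Impute non-finite log2 fold changes
#'
#' Missing or infinite fold changes arise from genes with very low counts in
#' some condition. They are imputed to `+4`/`-4` when the differential
#' expression is significant (FDR below `alpha`), in the direction the
#' non-finite value defines, and to `0` otherwise. `NaN` (zero in both
#' groups) carries no direction and is imputed to `0`. Finite values pass
#' through unflagged.
#'
#' @param log2fc Numeric vector of fold changes (may contain `Inf`, `-Inf`,
#'   `NaN`, `NA`).
#' @param fdr Numeric vector of FDR values (NA treated as non-significant).
#' @param rule A [consistency_rule()].
#' @return Tibble `log2fc` (finite), `imputed` (logical).
#' @export
impute_log2fc <- function(log2fc, fdr, rule = consistency_rule()) {
  stopifnot(inherits(rule, "consistency_rule"))
  out <- log2fc
  imputed <- !is.finite(log2fc)
  sig <- !is.na(fdr) & fdr < rule$alpha
  out[imputed] <- 0
  out[imputed & sig & log2fc == Inf] <- 4
  out[imputed & sig & log2fc == -Inf] <- -4
  tibble::tibble(log2fc = out, imputed = imputed)
}

#' Full imputed log2 fold-change matrix
#'
#' Computes [condition_log2fc()] for every non-reference condition and
#' applies [impute_log2fc()] cell-wise.
#'
#' @param x A `count_dataset`.
#' @param rule A [consistency_rule()].
#' @return A `log2fc_matrix`: a long tibble (`gene_id`, `condition`,
#'   `log2fc`, `fdr`, `imputed`) with the rule attached; all `log2fc`
#'   values are finite.
#' @export
log2fc_matrix <- function(x, rule = consistency_rule()) {
  stopifnot(inherits(x, "count_dataset"))
  conds <- conditions(x, drop_reference = TRUE)
  long <- purrr::map_dfr(conds, function(cond) {
    fc <- condition_log2fc(x, cond, alpha = rule$alpha)
    imp <- impute_log2fc(fc$log2fc, fc$fdr, rule)
    tibble::tibble(gene_id = fc$gene_id, condition = cond,
                   log2fc = imp$log2fc, fdr = fc$fdr, imputed = imp$imputed)
  })
  structure(list(table = long, rule = rule, reference = x$reference),
            class = "log2fc_matrix")
}

#' @export
print.log2fc_matrix <- function(x, ...) {
  cat(sprintf("<log2fc_matrix> %d genes x %d comparisons vs '%s' (%d imputed cells)\n",
              dplyr::n_distinct(x$table$gene_id),
              dplyr::n_distinct(x$table$condition),
              x$reference, sum(x$table$imputed)))
  invisible(x)
}

#' @export
tidy.log2fc_matrix <- function(x, ...) x$table

#' @export
autoplot.log2fc_matrix <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$condition, .data$gene_id, fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "darkgreen", midpoint = 0) +
    ggplot2::labs(x = sprintf("condition (vs %s)", object$reference),
                  y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Select consistently regulated genes
#'
#' Applies the direction-consistency rule to an imputed fold-change matrix.
#' A gene is selected with direction `up` (or `down`) when its sign agrees
#' in at least `min_consistent` comparisons and at least `min_strong` of
#' those same-direction cells reach `|log2FC| >= log2(strong_fold)`. Cells
#' equal to zero count for neither direction.
#'
#' @param fc A `log2fc_matrix`.
#' @param rule A [consistency_rule()]; defaults to the rule attached to `fc`.
#' @return Tibble `gene_id`, `direction`, `n_consistent`, `n_strong`,
#'   one row per selected gene.
#' @export
consistency_filter <- function(fc, rule = NULL) {
  stopifnot(inherits(fc, "log2fc_matrix"))
  rule <- rule %||% fc$rule
  stopifnot(inherits(rule, "consistency_rule"))
  if (any(!is.finite(fc$table$log2fc))) {
    abort("fold-change matrix contains non-finite cells; impute first",
          class = "anaerodesign_config_error")
  }
  strong_cut <- log2(rule$strong_fold)
  per_gene <- fc$table |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_up = sum(.data$log2fc > 0),
      n_down = sum(.data$log2fc < 0),
      n_up_strong = sum(.data$log2fc >= strong_cut),
      n_down_strong = sum(.data$log2fc <= -strong_cut),
      .groups = "drop"
    )
  up <- per_gene |>
    dplyr::filter(.data$n_up >= rule$min_consistent,
                  .data$n_up_strong >= rule$min_strong) |>
    dplyr::transmute(.data$gene_id, direction = "up",
                     n_consistent = .data$n_up, n_strong = .data$n_up_strong)
  down <- per_gene |>
    dplyr::filter(.data$n_down >= rule$min_consistent,
                  .data$n_down_strong >= rule$min_strong) |>
    dplyr::transmute(.data$gene_id, direction = "down",
                     n_consistent = .data$n_down, n_strong = .data$n_down_strong)
  dplyr::bind_rows(up, down) |> dplyr::arrange(.data$gene_id)
}

#' Map selected genes to domain architectures
#'
#' @param genes Character vector of selected gene IDs.
#' @param annotation A tibble linking genes to architectures for the
#'   transcriptome organism: columns `gene_id` and `architecture` (a
#'   per-strain catalog from [build_architectures()] joined to locus tags,
#'   or any equivalent mapping).
#' @return A list with `architectures` (sorted unique architecture keys of
#'   mapped genes) and `unmapped` (gene IDs absent from the annotation,
#'   reported rather than silently dropped).
#' @export
map_genes_to_architectures <- function(genes, annotation) {
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("gene_id", "architecture") %in% names(annotation)))
  hit <- annotation[annotation$gene_id %in% genes, ]
  list(architectures = sort(unique(hit$architecture)),
       unmapped = sort(setdiff(genes, annotation$gene_id)))
}

#' Read and write count matrices with condition maps
#'
#' `write_count_dataset()` writes `<stem>_counts.tsv` (gene_id plus one
#' column per sample) and `<stem>_conditions.tsv` (sample, condition);
#' `read_count_dataset()` reads them back.
#'
#' @param x A `count_dataset`.
#' @param stem Path stem for the two files.
#' @param reference Reference condition label for reading.
#' @return The `count_dataset` (read) or `stem` invisibly (write).
#' @export
write_count_dataset <- function(x, stem) {
  stopifnot(inherits(x, "count_dataset"))
  counts <- tibble::as_tibble(x$counts, rownames = "gene_id")
  readr::write_tsv(counts, paste0(stem, "_counts.tsv"), progress = FALSE)
  readr::write_tsv(x$condition_map, paste0(stem, "_conditions.tsv"), progress = FALSE)
  invisible(stem)
}

#' @rdname write_count_dataset
#' @export
read_count_dataset <- function(stem, reference) {
  counts <- readr::read_tsv(paste0(stem, "_counts.tsv"),
                            col_types = readr::cols(gene_id = readr::col_character(),
                                                    .default = readr::col_integer()),
                            progress = FALSE)
  cmap <- readr::read_tsv(paste0(stem, "_conditions.tsv"), col_types = "cc",
                          progress = FALSE)
  count_dataset(as.data.frame(counts), cmap, reference)
}
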