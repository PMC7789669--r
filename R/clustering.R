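#' Principal component analysis of the binarized domain matrix
#'
#' Runs PCA on the presence/absence matrix (columns centered, not scaled)
#' to visualise strain-level differences in protein-domain content.
#'
#' @param x A `domain_matrix`; it is binarized internally.
#' @return A `domain_pca` object. [tidy()] gives per-strain scores with
#'   lifestyle labels, [glance()] per-component variance fractions, and
#'   [autoplot()] the 2-D score plot. On a degenerate input (all strains
#'   identical) all variance fractions are reported as 0.
#' @export
run_pca <- function(x) {
  stopifnot(inherits(x, "domain_matrix"))
  m <- binarize(x)$counts
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("PCA needs at least 2 strains and 2 architectures",
          class = "anaerodesign_domain_error")
  }
  storage.mode(m) <- "double"
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  var_frac <- if (total_var > 0) fit$sdev^2 / total_var else rep(0, length(fit$sdev))
  structure(list(scores = fit$x, variance_fraction = var_frac,
                 rotation = fit$rotation, labels = x$labels),
            class = "domain_pca")
}

#' @export
print.domain_pca <- function(x, ...) {
  cat(sprintf("<domain_pca> %d strains, %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$variance_fraction[1],
              100 * (if (length(x$variance_fraction) > 1) x$variance_fraction[2] else 0)))
  invisible(x)
}

#' @export
tidy.domain_pca <- function(x, ...) {
  scores <- tibble::as_tibble(x$scores, .name_repair = "minimal")
  dplyr::bind_cols(x$labels, scores)
}

#' @export
glance.domain_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance_fraction),
                 variance_fraction = x$variance_fraction)
}

#' @export
autoplot.domain_pca <- function(object, ...) {
  df <- tidy(object)
  vf <- object$variance_fraction
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$lifestyle)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%% of variance)", 100 * vf[1]),
      y = sprintf("PC2 (%.1f%% of variance)", 100 * vf[2]),
      colour = "lifestyle"
    ) +
    ggplot2::theme_minimal()
}

#' Hierarchical clustering of strains by domain content
#'
#' Complete-linkage clustering on Euclidean distances between binary
#' presence/absence profiles (both configurable). The resulting dendrogram
#' is used to select a restricted branch of closely related strains.
#'
#' @param x A `domain_matrix`; binarized internally.
#' @param method Linkage method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @return A `domain_tree`: the `hclust` fit plus the label table.
#' @export
hierarchical_tree <- function(x, method = "complete", metric = "euclidean") {
  stopifnot(inherits(x, "domain_matrix"))
  m <- binarize(x)$counts
  storage.mode(m) <- "double"
  fit <- hclust(dist(m, method = metric), method = method)
  structure(list(hclust = fit, labels = x$labels), class = "domain_tree")
}

#' @export
print.domain_tree <- function(x, ...) {
  cat(sprintf("<domain_tree> %d strains (%s linkage)\n",
              length(x$hclust$labels), x$hclust$method))
  invisible(x)
}

#' Extract the dendrogram branch containing a focal strain
#'
#' Starting at the root, descends `depth` splits, at each split following the
#' child subtree that contains the focal strain, and returns the strain IDs
#' under the final node. `depth = 0` returns all strains. The returned subset
#' is the strain scope for the restricted persistence lists.
#'
#' @param tree A `domain_tree` from [hierarchical_tree()].
#' @param focal_strain Strain ID that the branch must contain.
#' @param depth Number of splits to descend from the root.
#' @return Character vector of strain IDs on the branch.
#' @export
extract_branch <- function(tree, focal_strain, depth = 1L) {
  stopifnot(inherits(tree, "domain_tree"))
  depth <- check_count(depth, "depth")
  if (!focal_strain %in% tree$hclust$labels) {
    abort(sprintf("focal strain '%s' not in tree", focal_strain),
          class = "anaerodesign_lookup_error")
  }
  node <- stats::as.dendrogram(tree$hclust)
  for (i in seq_len(depth)) {
    if (is.leaf(node)) break
    found <- FALSE
    for (j in seq_along(node)) {
      if (focal_strain %in% labels(node[[j]])) {
        node <- node[[j]]
        found <- TRUE
        break
      }
    }
    if (!found) break  # unreachable for a well-formed dendrogram
  }
  labels(node)
}

#' Export a strain dendrogram in Newick format
#'
#' @param tree A `domain_tree`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_newick <- function(tree, file) {
  stopifnot(inherits(tree, "domain_tree"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the 'ape' package")
  }
  ape::write.tree(ape::as.phylo(tree$hclust), file = file)
  invisible(file)
}
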