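#' Configuration for the synthetic transcriptome generator
#'
#' Emulates a multi-condition bulk RNA-seq count data set with an anaerobic
#' reference condition and genes planted to be consistently up- or
#' down-regulated in that reference relative to every other condition.
#' Counts are negative-binomial with a shared dispersion; per-sample library
#' size factors are drawn log-uniformly in `[0.5, 2]` so normalization is
#' non-trivial. "Weak" genes are differentially expressed in fewer
#' conditions than the downstream consistency rule requires, violating it by
#' construction.
#'
#' @param n_genes Total genes.
#' @param n_conditions Number of environmental conditions (default 14,
#'   giving 13 pairwise comparisons against the reference).
#' @param replicates_per_condition Samples per condition (default 3).
#' @param reference_condition Label of the anaerobic reference condition.
#' @param n_planted_up,n_planted_down Genes consistently up-/down-regulated
#'   in the reference.
#' @param planted_fold Linear fold change (>= 1) of planted genes.
#' @param n_planted_weak Genes with the fold change in only a minority of
#'   conditions.
#' @param n_weak_conditions Number of non-reference conditions in which a
#'   weak gene keeps the fold difference (default 4, below the
#'   7-of-13 consistency minimum).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param base_mean_range Range of per-gene expected baseline counts.
#' @param dropout_conditions Per planted gene, number of non-reference
#'   conditions forced to near-zero counts, to exercise the imputation rule.
#' @param seed Integer RNG seed.
#' @return A validated `transcriptome_sim_config` list.
#' @export
transcriptome_sim_config <- function(n_genes = 1000, n_conditions = 14,
                                     replicates_per_condition = 3,
                                     reference_condition = "anaerobic",
                                     n_planted_up = 15, n_planted_down = 15,
                                     planted_fold = 8,
                                     n_planted_weak = 10, n_weak_conditions = 4,
                                     dispersion = 0.05,
                                     base_mean_range = c(50, 500),
                                     dropout_conditions = 0,
                                     seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 1L),
    n_conditions = check_count(n_conditions, "n_conditions", min = 2L),
    replicates_per_condition = check_count(replicates_per_condition,
                                           "replicates_per_condition", min = 1L),
    reference_condition = check_string(reference_condition, "reference_condition"),
    n_planted_up = check_count(n_planted_up, "n_planted_up"),
    n_planted_down = check_count(n_planted_down, "n_planted_down"),
    planted_fold = check_fraction(planted_fold, "planted_fold", lo = 1, hi = Inf),
    n_planted_weak = check_count(n_planted_weak, "n_planted_weak"),
    n_weak_conditions = check_count(n_weak_conditions, "n_weak_conditions"),
    dispersion = check_fraction(dispersion, "dispersion", lo = 0, hi = Inf),
    base_mean_range = base_mean_range,
    dropout_conditions = check_count(dropout_conditions, "dropout_conditions"),
    seed = check_seed(seed)
  )
  if (length(base_mean_range) != 2 || !is.numeric(base_mean_range) ||
      any(base_mean_range <= 0) || base_mean_range[1] > base_mean_range[2]) {
    stop_config("base_mean_range", "must be a positive increasing interval")
  }
  n_planted <- cfg$n_planted_up + cfg$n_planted_down + cfg$n_planted_weak
  if (n_planted > cfg$n_genes) {
    stop_config("n_genes", "must be at least the total number of planted genes")
  }
  if (cfg$n_weak_conditions > cfg$n_conditions - 1L) {
    stop_config("n_weak_conditions", "must be below the number of comparisons")
  }
  structure(cfg, class = "transcriptome_sim_config")
}

#' Simulate a multi-condition transcriptome count data set
#'
#' @param cfg A [transcriptome_sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{counts}{a [count_dataset()]: integer gene-by-sample counts,
#'       condition map and reference condition}
#'     \item{truth}{tibble `gene_id`, `direction` in
#'       \{up, down, weak, null\}}
#'   }
#'   Planted `up` genes have expected normalized mean `planted_fold` times
#'   higher in the reference condition than in every other condition
#'   (`down` genes: lower); `weak` genes keep the fold in only
#'   `n_weak_conditions` conditions.
#' @export
simulate_transcriptome <- function(cfg = transcriptome_sim_config()) {
  stopifnot(inherits(cfg, "transcriptome_sim_config"))
  set.seed(cfg$seed)

  other <- sprintf("cond%02d", seq_len(cfg$n_conditions - 1L))
  conditions <- c(cfg$reference_condition, other)
  samples <- tibble::tibble(
    condition = rep(conditions, each = cfg$replicates_per_condition)
  )
  samples$sample <- sprintf("s%03d_%s", seq_len(nrow(samples)), samples$condition)

  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  direction <- rep("null", cfg$n_genes)
  n_up <- cfg$n_planted_up; n_down <- cfg$n_planted_down; n_weak <- cfg$n_planted_weak
  if (n_up > 0) direction[seq_len(n_up)] <- "up"
  if (n_down > 0) direction[n_up + seq_len(n_down)] <- "down"
  if (n_weak > 0) direction[n_up + n_down + seq_len(n_weak)] <- "weak"
  truth <- tibble::tibble(gene_id = gene_ids, direction = direction)

  base_mean <- exp(runif(cfg$n_genes, log(cfg$base_mean_range[1]),
                         log(cfg$base_mean_range[2])))

  # Expected normalized mean per gene x condition. "up" = higher in the
  # anaerobic reference than elsewhere.
  mu <- matrix(base_mean, nrow = cfg$n_genes, ncol = length(conditions),
               dimnames = list(gene_ids, conditions))
  fold <- cfg$planted_fold
  mu[direction == "up", 1] <- mu[direction == "up", 1] * fold
  mu[direction == "down", 1] <- mu[direction == "down", 1] / fold
  for (g in which(direction == "weak")) {
    # Strongly up in only n_weak_conditions comparisons; mildly DOWN (half
    # the reference level, below the strong-fold cut) everywhere else, so
    # neither direction can satisfy the consistency rule.
    affected <- sample(other, cfg$n_weak_conditions)
    mu[g, 1] <- mu[g, 1] * fold
    mu[g, setdiff(other, affected)] <- mu[g, setdiff(other, affected)] * fold * 2
  }
  if (cfg$dropout_conditions > 0) {
    for (g in which(direction %in% c("up", "down"))) {
      drop <- sample(other, min(cfg$dropout_conditions, length(other)))
      mu[g, drop] <- 0.01
    }
  }

  size_factor <- exp(runif(nrow(samples), log(0.5), log(2)))
  counts <- matrix(0L, nrow = cfg$n_genes, ncol = nrow(samples),
                   dimnames = list(gene_ids, samples$sample))
  size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
  for (j in seq_len(nrow(samples))) {
    m <- mu[, samples$condition[j]] * size_factor[j]
    counts[, j] <- as.integer(
      if (is.finite(size)) rnbinom(cfg$n_genes, mu = m, size = size)
      else stats::rpois(cfg$n_genes, lambda = m))
  }

  cd <- count_dataset(counts,
                      condition_map = samples[, c("sample", "condition")],
                      reference = cfg$reference_condition)
  list(counts = cd, truth = truth)
}
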