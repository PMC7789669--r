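#' Configuration for the repeated random-forest protocol
#'
#' Repeated balanced-subsample training: per repetition, `n_per_class`
#' genomes are drawn from each lifestyle class without replacement, a
#' random-forest classifier is trained on the binarized domain matrix, and
#' its impurity-decrease (Gini) importances are recorded. Importances are
#' summed over repetitions into the cumulative Gini coefficient.
#'
#' @param n_per_class Genomes sampled per lifestyle class per repetition
#'   (default 300).
#' @param repetitions Number of models (default 100).
#' @param trees_per_model Trees per forest (default 500).
#' @param mtry Features tried per split; `NULL` (default) uses the square
#'   root of the feature count.
#' @param seed Integer seed for the whole protocol.
#' @param allow_smaller_classes If a class has fewer strains than
#'   `n_per_class`, take all of them instead of erroring.
#' @return A validated `rf_protocol_config` list.
#' @export
rf_protocol_config <- function(n_per_class = 300, repetitions = 100,
                               trees_per_model = 500, mtry = NULL,
                               seed = 1L, allow_smaller_classes = FALSE) {
  structure(list(
    n_per_class = check_count(n_per_class, "n_per_class", min = 1L),
    repetitions = check_count(repetitions, "repetitions", min = 1L),
    trees_per_model = check_count(trees_per_model, "trees_per_model", min = 1L),
    mtry = if (!is.null(mtry)) check_count(mtry, "mtry", min = 1L),
    seed = check_seed(seed),
    allow_smaller_classes = check_flag(allow_smaller_classes, "allow_smaller_classes")
  ), class = "rf_protocol_config")
}

#' Balanced subsample of strains for one repetition
#'
#' Each repetition draws `n_per_class` distinct strains per class without
#' replacement; distinct repetitions are independent draws from one stream
#' seeded by the protocol seed, so a strain may recur between repetitions.
#'
#' @param labels Strain label tibble (`strain_id`, `lifestyle`).
#' @param cfg An [rf_protocol_config()].
#' @param repetition_index Which repetition's subsample to return (1-based).
#' @return Character vector of strain IDs (aerobic then anaerobic draws).
#' @export
balanced_subsample <- function(labels, cfg, repetition_index = 1L) {
  stopifnot(inherits(cfg, "rf_protocol_config"))
  repetition_index <- check_count(repetition_index, "repetition_index", min = 1L)
  if (repetition_index > cfg$repetitions) {
    stop_config("repetition_index", "exceeds the configured repetitions")
  }
  subsample_plan(labels, cfg)[[repetition_index]]
}

# All repetitions' subsamples, drawn sequentially from one seeded stream.
subsample_plan <- function(labels, cfg) {
  labels <- validate_labels(labels)
  classes <- split(labels$strain_id, labels$lifestyle)
  for (cl in c("aerobic", "anaerobic")) {
    n <- length(classes[[cl]] %||% character())
    if (n == 0) {
      abort(sprintf("lifestyle class '%s' absent from label table", cl),
            class = "anaerodesign_label_error")
    }
    if (n < cfg$n_per_class && !cfg$allow_smaller_classes) {
      abort(sprintf("class '%s' has %d strains, fewer than n_per_class = %d",
                    cl, n, cfg$n_per_class),
            class = "anaerodesign_size_error", lifestyle = cl)
    }
  }
  take <- function(pool) sample(pool, min(cfg$n_per_class, length(pool)))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$repetitions), function(i) {
    c(take(classes$aerobic), take(classes$anaerobic))
  })
}

#' Train one forest and return impurity-decrease importances
#'
#' @param x A `domain_matrix`; binarized internally (presence/absence is
#'   the classifier input).
#' @param subset Strain IDs to train on; must contain both classes.
#' @param cfg An [rf_protocol_config()].
#' @param seed Seed for this single model.
#' @return Named numeric vector: one non-negative Gini importance per
#'   architecture (architectures giving no split gain get 0).
#' @export
train_importances <- function(x, subset, cfg = rf_protocol_config(), seed = 1L) {
  stopifnot(inherits(x, "domain_matrix"))
  lab <- x$labels[match(subset, x$labels$strain_id), ]
  if (anyNA(lab$strain_id)) {
    abort("subset contains strains absent from the matrix",
          class = "anaerodesign_label_error")
  }
  y <- factor(lab$lifestyle, levels = c("aerobic", "anaerobic"))
  if (dplyr::n_distinct(y) < 2) {
    abort("training subset must contain both lifestyle classes",
          class = "anaerodesign_training_error")
  }
  m <- binarize(x)$counts[subset, , drop = FALSE]
  fit <- ranger::ranger(
    x = m, y = y,
    num.trees = cfg$trees_per_model,
    mtry = cfg$mtry %||% max(1L, floor(sqrt(ncol(m)))),
    importance = "impurity",
    seed = check_seed(seed),
    num.threads = 1
  )
  imp <- fit$variable.importance
  imp[imp < 0] <- 0  # guard; impurity decrease is non-negative by construction
  imp
}

#' Combine per-repetition importances into cumulative Gini coefficients
#'
#' @param importance_list List of named importance vectors over an identical
#'   architecture set (one per repetition).
#' @return A `gini_table`: tibble `architecture`, `cumulative_gini`, `rank`
#'   (descending by cumulative Gini, ties broken lexicographically), with
#'   the per-repetition matrix attached as attribute `"repetitions"`.
#' @export
cumulative_gini <- function(importance_list) {
  if (length(importance_list) < 1) {
    abort("need at least one repetition", class = "anaerodesign_config_error")
  }
  archs <- names(importance_list[[1]])
  same <- vapply(importance_list, function(v) identical(sort(names(v)), sort(archs)),
                 logical(1))
  if (!all(same)) {
    abort("repetitions cover different architecture sets",
          class = "anaerodesign_alignment_error")
  }
  reps <- do.call(rbind, lapply(importance_list, function(v) v[archs]))
  cum <- colSums(reps)
  out <- tibble::tibble(architecture = archs, cumulative_gini = as.numeric(cum)) |>
    dplyr::arrange(dplyr::desc(.data$cumulative_gini), .data$architecture) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(out, class = c("gini_table", class(out)), repetitions = reps)
}

#' Run the full repeated-forest protocol
#'
#' @param x A `domain_matrix` with lifestyle labels.
#' @param cfg An [rf_protocol_config()].
#' @return A `gini_table` (see [cumulative_gini()]).
#' @export
run_rf_protocol <- function(x, cfg = rf_protocol_config()) {
  stopifnot(inherits(x, "domain_matrix"), inherits(cfg, "rf_protocol_config"))
  plan <- subsample_plan(x$labels, cfg)
  imps <- lapply(seq_along(plan), function(i) {
    train_importances(x, plan[[i]], cfg, seed = derive_seed(cfg$seed, i))
  })
  cumulative_gini(imps)
}

#' @export
glance.gini_table <- function(x, ...) {
  tibble::tibble(n_architectures = nrow(x),
                 max_cumulative_gini = max(x$cumulative_gini),
                 n_repetitions = nrow(attr(x, "repetitions")))
}

#' @export
autoplot.gini_table <- function(object, top_n = 20, ...) {
  df <- head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(.data$cumulative_gini,
                                   stats::reorder(.data$architecture,
                                                  .data$cumulative_gini))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cumulative Gini coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Select architectures by cumulative Gini threshold
#'
#' Returns all architectures at or above the threshold, tagged with
#' lifestyle specificity by comparing group persistence (the
#' higher-persistence group wins; exact ties stay untagged). Cumulative
#' Gini values are raw summed impurity decreases and therefore scale with
#' sample and tree counts; absolute thresholds are protocol-specific.
#'
#' @param gini A `gini_table`.
#' @param threshold Non-negative cumulative-Gini cutoff.
#' @param pt Optional two-group persistence tibble
#'   ([persistence_by_group()], `copy_number = FALSE` recommended so keys
#'   match architectures) used for specificity tagging.
#' @return Tibble `architecture`, `cumulative_gini`, `rank`, `specificity`
#'   (`"aerobe_specific"`, `"anaerobe_specific"` or `"untagged"`).
#' @export
select_by_gini <- function(gini, threshold, pt = NULL) {
  stopifnot(inherits(gini, "gini_table"))
  if (!is.numeric(threshold) || threshold < 0) {
    abort("threshold must be non-negative", class = "anaerodesign_config_error")
  }
  out <- tibble::as_tibble(gini)[gini$cumulative_gini >= threshold, ]
  out$specificity <- "untagged"
  if (!is.null(pt) && nrow(out) > 0) {
    idx <- match(out$architecture, pt$key)
    aer <- pt$persistence_aerobic[idx]
    ana <- pt$persistence_anaerobic[idx]
    out$specificity[!is.na(idx) & aer > ana] <- "aerobe_specific"
    out$specificity[!is.na(idx) & ana > aer] <- "anaerobe_specific"
  }
  out
}
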