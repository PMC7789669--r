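#' Gene persistence within a strain group
#'
#' Persistence of an ortholog in a group of genomes is `N(orth) / N`: the
#' number of genomes in the group carrying the ortholog over the number of
#' genomes considered. Orthologs are domain-architecture orthology keys
#' (copy-number aware by default; see [orthology_indicators()]).
#'
#' @param x A `domain_matrix`.
#' @param strains Character vector of strain IDs defining the group; must be
#'   a non-empty subset of the matrix strains.
#' @param copy_number If `TRUE` (default), orthology keys distinguish copy
#'   numbers; if `FALSE`, plain architecture presence/absence is used.
#' @return A tibble with columns `key`, `architecture` and `persistence`
#'   (in `[0, 1]`), one row per orthology key observed in the full matrix.
#' @export
persistence <- function(x, strains, copy_number = TRUE) {
  stopifnot(inherits(x, "domain_matrix"))
  if (length(strains) == 0) {
    abort("strain group must be non-empty", class = "anaerodesign_domain_error")
  }
  missing <- setdiff(strains, rownames(x$counts))
  if (length(missing) > 0) {
    abort(sprintf("strain(s) not in matrix: %s", paste(missing, collapse = ", ")),
          class = "anaerodesign_domain_error")
  }
  ind <- if (copy_number) orthology_indicators(x) else binarize(x)$counts
  carried <- colSums(ind[strains, , drop = FALSE] > 0)
  tibble::tibble(
    key = colnames(ind),
    architecture = strip_copy_number(colnames(ind)),
    persistence = as.numeric(carried) / length(strains)
  )
}

#' Persistence of every orthology key in both lifestyle groups
#'
#' @param x A `domain_matrix` whose label table assigns each strain to
#'   `"aerobic"` or `"anaerobic"`.
#' @param copy_number Passed to [persistence()].
#' @param strains Optional strain subset restricting both groups (e.g. a
#'   dendrogram branch); defaults to all strains.
#' @return A tibble with columns `key`, `architecture`,
#'   `persistence_aerobic`, `persistence_anaerobic`.
#' @export
persistence_by_group <- function(x, copy_number = TRUE, strains = NULL) {
  stopifnot(inherits(x, "domain_matrix"))
  strains <- strains %||% x$labels$strain_id
  lab <- x$labels[x$labels$strain_id %in% strains, ]
  aer <- lab$strain_id[lab$lifestyle == "aerobic"]
  ana <- lab$strain_id[lab$lifestyle == "anaerobic"]
  if (length(aer) == 0 || length(ana) == 0) {
    abort("both lifestyle groups must be represented in the strain scope",
          class = "anaerodesign_domain_error")
  }
  dplyr::inner_join(
    dplyr::rename(persistence(x, aer, copy_number), persistence_aerobic = "persistence"),
    dplyr::rename(persistence(x, ana, copy_number)[, c("key", "persistence")],
                  persistence_anaerobic = "persistence"),
    by = "key"
  ) |>
    dplyr::relocate("architecture", .after = "key")
}

#' Domain core at a persistence threshold
#'
#' The domain core of a group is the set of orthology keys whose persistence
#' meets the threshold (e.g. present in at least 95% of the group's genomes).
#'
#' @param pt A persistence tibble with columns `key` and `persistence`
#'   (one group's column from [persistence()]).
#' @param tau Persistence threshold in `(0, 1]`.
#' @return Character vector of core keys (sorted).
#' @export
core_at_threshold <- function(pt, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0 || tau > 1) {
    abort("threshold tau must be in (0, 1]", class = "anaerodesign_domain_error")
  }
  sort(pt$key[pt$persistence >= tau])
}

new_core_split <- function(shared, aerobe_specific, anaerobe_specific,
                           thresholds, scope = "full") {
  structure(list(shared = sort(shared),
                 aerobe_specific = sort(aerobe_specific),
                 anaerobe_specific = sort(anaerobe_specific),
                 thresholds = thresholds, scope = scope),
            class = "core_split")
}

#' @export
print.core_split <- function(x, ...) {
  cat(sprintf("<core_split> scope=%s [%s]\n  shared: %d  aerobe-specific: %d  anaerobe-specific: %d\n",
              x$scope,
              paste(names(x$thresholds), unlist(x$thresholds), sep = "=", collapse = ", "),
              length(x$shared), length(x$aerobe_specific), length(x$anaerobe_specific)))
  invisible(x)
}

#' @export
tidy.core_split <- function(x, ...) {
  tibble::tibble(
    key = c(x$shared, x$aerobe_specific, x$anaerobe_specific),
    list_membership = rep(c("shared", "aerobe_specific", "anaerobe_specific"),
                          c(length(x$shared), length(x$aerobe_specific),
                            length(x$anaerobe_specific)))
  ) |>
    dplyr::mutate(architecture = strip_copy_number(.data$key), .after = "key")
}

#' Split two domain cores into shared and lifestyle-specific sets
#'
#' Set algebra over the aerobic and anaerobic domain cores: the shared core
#' is the intersection, each specific core the difference.
#'
#' @param core_aerobic,core_anaerobic Character vectors of core keys, e.g.
#'   from [core_at_threshold()].
#' @param thresholds Named list recorded on the result (bookkeeping only).
#' @param scope `"full"` or `"restricted-branch"`; recorded on the result.
#' @return A `core_split` with disjoint `shared`, `aerobe_specific` and
#'   `anaerobe_specific` sets.
#' @export
split_cores <- function(core_aerobic, core_anaerobic,
                        thresholds = list(), scope = "full") {
  new_core_split(
    shared = intersect(core_aerobic, core_anaerobic),
    aerobe_specific = setdiff(core_aerobic, core_anaerobic),
    anaerobe_specific = setdiff(core_anaerobic, core_aerobic),
    thresholds = thresholds, scope = scope
  )
}

#' Lifestyle-specific domains by the low-persistence rule
#'
#' The reverse separation: a key is anaerobe-specific when it is nearly
#' absent from aerobic genomes (persistence at most `epsilon`) while being
#' part of the anaerobic core (persistence at least `tau_presence`);
#' symmetrically for aerobe-specific. Keys at or above `tau_presence` in both
#' groups form the shared set. The presence requirement keeps universally
#' absent domains out of the specific lists.
#'
#' @param pt Two-group persistence tibble from [persistence_by_group()].
#' @param epsilon Low-persistence ceiling (default 0.01).
#' @param tau_presence Presence floor in the focal group (default 0.95).
#' @param scope Recorded on the result.
#' @return A `core_split`.
#' @export
specific_by_low_persistence <- function(pt, epsilon = 0.01, tau_presence = 0.95,
                                        scope = "full") {
  if (!(epsilon >= 0 && epsilon < tau_presence && tau_presence <= 1)) {
    abort("need 0 <= epsilon < tau_presence <= 1",
          class = "anaerodesign_domain_error")
  }
  ana <- pt$key[pt$persistence_aerobic <= epsilon &
                  pt$persistence_anaerobic >= tau_presence]
  aer <- pt$key[pt$persistence_anaerobic <= epsilon &
                  pt$persistence_aerobic >= tau_presence]
  shared <- pt$key[pt$persistence_aerobic >= tau_presence &
                     pt$persistence_anaerobic >= tau_presence]
  new_core_split(shared, aer, ana,
                 thresholds = list(epsilon = epsilon, tau_presence = tau_presence),
                 scope = scope)
}

#' Persistence-threshold core split
#'
#' Convenience wrapper: computes both group cores at `tau` and splits them.
#'
#' @inheritParams persistence_by_group
#' @param tau Persistence threshold for both group cores.
#' @param scope Recorded on the result.
#' @return A `core_split`.
#' @export
core_split_at_threshold <- function(x, tau = 0.95, copy_number = TRUE,
                                    strains = NULL, scope = "full") {
  pt <- persistence_by_group(x, copy_number = copy_number, strains = strains)
  split_cores(
    core_at_threshold(dplyr::rename(pt[, c("key", "persistence_aerobic")],
                                    persistence = "persistence_aerobic"), tau),
    core_at_threshold(dplyr::rename(pt[, c("key", "persistence_anaerobic")],
                                    persistence = "persistence_anaerobic"), tau),
    thresholds = list(tau = tau), scope = scope
  )
}

#' Write a persistence/list-membership export
#'
#' @param pt Two-group persistence tibble.
#' @param split A `core_split` giving list membership.
#' @param file Output path (tab-separated).
#' @return `file`, invisibly.
#' @export
write_persistence_table <- function(pt, split, file) {
  membership <- tidy(split)[, c("key", "list_membership")]
  out <- dplyr::left_join(pt, membership, by = "key") |>
    dplyr::mutate(list_membership = dplyr::coalesce(.data$list_membership, "none"))
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}
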