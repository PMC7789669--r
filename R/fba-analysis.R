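# Anoxic gap analysis: which biomass precursors become unproducible when
# oxygen is removed, which single changes relieve each of them, and which
# minimal medium supplements restore growth.

biomass_substrates <- function(model) {
  st <- model$reactions$stoichiometry[[match(model$objective, model$reactions$id)]]
  names(st)[st < 0]
}

# Maximal synthesis flux of one metabolite: optimize a temporary demand
# reaction in place of biomass (biomass itself clamped to zero so precursor
# availability is probed, not growth).
max_synthesis <- function(model, met, med = NULL) {
  model <- apply_medium(model, med)
  dm <- tibble::tibble(id = "DM_probe__", stoichiometry = list(setNames(-1, met)),
                       lb = 0, ub = 1000, genes = "", insertable = FALSE,
                       enabled_lb = 0, enabled_ub = 1000)
  model$reactions$lb[model$reactions$id == model$objective] <- 0
  model$reactions$ub[model$reactions$id == model$objective] <- 0
  probe <- model
  probe$reactions <- dplyr::bind_rows(model$reactions, dm)
  sol <- fba(probe, med = NULL, objective = "DM_probe__")
  if (sol$status == "optimal") sol$objective else 0
}

#' Biomass precursors blocked under a medium
#'
#' For each substrate of the biomass reaction, optimizes a temporary demand
#' reaction in its place and reports the maximal synthesis flux. A precursor
#' is blocked when that maximum does not exceed `1e-6`.
#'
#' @param model A `metabolic_model`.
#' @param med A [medium()] (e.g. aerobic or anoxic).
#' @return Tibble `metabolite`, `max_flux`, `blocked`, one row per biomass
#'   substrate (empty for a substrate-free biomass reaction).
#' @export
blocked_biomass_precursors <- function(model, med = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  subs <- biomass_substrates(model)
  purrr::map_dfr(subs, function(met) {
    mx <- max_synthesis(model, met, med)
    tibble::tibble(metabolite = met, max_flux = mx, blocked = mx <= GROWTH_TOL)
  })
}

#' Trace a blocked precursor to its oxygen dependencies
#'
#' Tests single changes, one at a time: (i) each oxygen-consuming reaction
#' with its oxygen requirement removed, (ii) each insertable reaction
#' enabled, and (iii) each closed exchange opened. Every change that raises
#' the precursor's maximal synthesis above `1e-6` is reported with its gene
#' labels.
#'
#' @param model A `metabolic_model`.
#' @param med The medium under which the precursor is blocked.
#' @param precursor A biomass-substrate metabolite ID, blocked under `med`.
#' @param oxygen_metabolite Intracellular oxygen species consumed by
#'   oxygen-requiring reactions.
#' @return Tibble `change`, `reaction`, `genes`, `max_flux` (empty when no
#'   single change unblocks the precursor).
#' @export
trace_oxygen_dependencies <- function(model, med, precursor,
                                      oxygen_metabolite = "o2_c") {
  stopifnot(inherits(model, "metabolic_model"))
  if (max_synthesis(model, precursor, med) > GROWTH_TOL) {
    abort(sprintf("precursor '%s' is not blocked under this medium", precursor),
          class = "anaerodesign_precondition_error")
  }
  applied <- apply_medium(model, med)
  results <- list()

  # (i) relieve each oxygen-consuming (non-exchange) reaction
  exch <- exchange_reactions(model)
  for (i in seq_len(nrow(model$reactions))) {
    id <- model$reactions$id[i]
    st <- model$reactions$stoichiometry[[i]]
    if (id %in% exch || !oxygen_metabolite %in% names(st) ||
        st[[oxygen_metabolite]] >= 0) next
    relieved <- model
    relieved$reactions$stoichiometry[[i]] <-
      st[setdiff(names(st), oxygen_metabolite)]
    mx <- max_synthesis(relieved, precursor, med)
    if (mx > GROWTH_TOL) {
      results[[length(results) + 1]] <-
        tibble::tibble(change = "relieve_oxygen_requirement", reaction = id,
                       genes = model$reactions$genes[i], max_flux = mx)
    }
  }
  # (ii) enable each insertable reaction
  for (id in model$reactions$id[model$reactions$insertable]) {
    mx <- max_synthesis(enable_insertable(model, id), precursor, med)
    if (mx > GROWTH_TOL) {
      i <- match(id, model$reactions$id)
      results[[length(results) + 1]] <-
        tibble::tibble(change = "enable_insertable", reaction = id,
                       genes = model$reactions$genes[i], max_flux = mx)
    }
  }
  # (iii) open each closed exchange (closed after applying the medium)
  closed <- intersect(exch, applied$reactions$id[applied$reactions$lb >= 0])
  for (id in closed) {
    opened <- applied
    opened$reactions$lb[opened$reactions$id == id] <- -1000
    mx <- max_synthesis(opened, precursor, med = NULL)
    if (mx > GROWTH_TOL) {
      i <- match(id, model$reactions$id)
      results[[length(results) + 1]] <-
        tibble::tibble(change = "open_exchange", reaction = id,
                       genes = model$reactions$genes[i], max_flux = mx)
    }
  }
  if (length(results) == 0) {
    return(tibble::tibble(change = character(), reaction = character(),
                          genes = character(), max_flux = numeric()))
  }
  dplyr::bind_rows(results)
}

#' Minimal medium supplements restoring growth
#'
#' Enumerates subsets of candidate exchange reactions in increasing size
#' (capped at `max_size`) and returns every minimal subset whose opening
#' (uptake cap 1000) restores biomass flux above `1e-6`.
#'
#' @param model A `metabolic_model`.
#' @param med A medium under which biomass flux is zero.
#' @param candidates Character vector of exchange reaction IDs to consider
#'   as supplements.
#' @param max_size Largest subset size tried (default 4).
#' @return A list of character vectors (each a minimal supplement set);
#'   empty when no subset works or `candidates` is empty.
#' @export
propose_media_supplements <- function(model, med, candidates, max_size = 4) {
  stopifnot(inherits(model, "metabolic_model"))
  base <- fba(model, med)
  if (base$status == "optimal" && base$objective > GROWTH_TOL) {
    abort("biomass flux is already positive under this medium",
          class = "anaerodesign_precondition_error")
  }
  if (length(candidates) == 0) return(list())
  unknown <- setdiff(candidates, exchange_reactions(model))
  if (length(unknown) > 0) {
    abort(sprintf("candidate(s) not exchange reactions: %s",
                  paste(unknown, collapse = ", ")),
          class = "anaerodesign_config_error")
  }
  applied <- apply_medium(model, med)
  grows_with <- function(subset) {
    m <- applied
    idx <- match(subset, m$reactions$id)
    m$reactions$lb[idx] <- -1000
    sol <- fba(m)
    sol$status == "optimal" && sol$objective > GROWTH_TOL
  }
  minimal <- list()
  for (k in seq_len(min(max_size, length(candidates)))) {
    for (subset in combn(sort(candidates), k, simplify = FALSE)) {
      if (any(vapply(minimal, function(m) all(m %in% subset), logical(1)))) next
      if (grows_with(subset)) minimal[[length(minimal) + 1]] <- subset
    }
  }
  minimal
}
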