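# Flux balance analysis: maximize an objective flux subject to steady-state
# stoichiometric constraints and flux bounds. Solved as a dense LP via the
# simplex method after shifting fluxes to non-negative variables.

GROWTH_TOL <- 1e-6   # fluxes at or below this are "no growth" / "blocked"
LP_TOL <- 1e-9       # steady-state and bound tolerance on solutions

#' Define a growth medium
#'
#' A medium assigns each exchange reaction a maximal uptake rate
#' (mmol gdw^-1 h^-1); applying it sets the exchange lower bound to minus
#' that rate (negative flux = uptake). Exchanges not listed keep their model
#' bounds.
#'
#' @param exchange_id Character vector of exchange reaction IDs.
#' @param max_uptake Non-negative uptake caps, recycled if length 1.
#' @return A `medium` tibble (`exchange_id`, `max_uptake`).
#' @export
medium <- function(exchange_id, max_uptake) {
  max_uptake <- rep_len(max_uptake, length(exchange_id))
  if (any(max_uptake < 0)) {
    abort("uptake rates must be non-negative", class = "anaerodesign_config_error")
  }
  structure(tibble::tibble(exchange_id = exchange_id, max_uptake = max_uptake),
            class = c("medium", "tbl_df", "tbl", "data.frame"))
}

#' Close the oxygen exchange of a medium
#'
#' @param med A `medium` containing an oxygen exchange entry.
#' @param oxygen_exchange Oxygen exchange reaction ID.
#' @return The same medium with the oxygen uptake set to 0 (idempotent).
#' @export
set_anoxic <- function(med, oxygen_exchange = "EX_o2") {
  stopifnot(inherits(med, "medium"))
  if (!oxygen_exchange %in% med$exchange_id) {
    abort(sprintf("medium has no oxygen exchange entry '%s'", oxygen_exchange),
          class = "anaerodesign_config_error")
  }
  med$max_uptake[med$exchange_id == oxygen_exchange] <- 0
  med
}

#' Read and write medium files
#'
#' Tab-separated, columns `exchange_id` and `max_uptake`.
#' @param file Path.
#' @return The `medium` (read) or `file` invisibly (write).
#' @export
read_medium <- function(file) {
  df <- readr::read_tsv(file, col_types = "cd", progress = FALSE)
  medium(df$exchange_id, df$max_uptake)
}

#' @rdname read_medium
#' @param med A `medium`.
#' @export
write_medium <- function(med, file) {
  readr::write_tsv(tibble::as_tibble(med), file, progress = FALSE)
  invisible(file)
}

apply_medium <- function(model, med) {
  if (is.null(med)) return(model)
  stopifnot(inherits(med, "medium"))
  unknown <- setdiff(med$exchange_id, model$reactions$id)
  if (length(unknown) > 0) {
    abort(sprintf("medium references unknown exchange(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "anaerodesign_config_error")
  }
  idx <- match(med$exchange_id, model$reactions$id)
  model$reactions$lb[idx] <- -med$max_uptake
  model
}

# Maximize obj'v subject to S v = 0, lb <= v <= ub. Fluxes are shifted to
# x = v - lb >= 0 and upper bounds become slack rows, giving the standard
# form max c'x, A x = b, x >= 0 solved by a dense two-phase primal simplex.
solve_lp <- function(obj, S, lb, ub) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n)
  m <- nrow(S)
  # rows: S x = -S lb (steady state), x + s = ub - lb (upper bounds)
  A <- rbind(cbind(S, matrix(0, m, n)),
             cbind(diag(n), diag(n)))
  b <- c(as.vector(-S %*% lb), ub - lb)
  cost <- c(obj, rep(0, n))
  sol <- simplex_two_phase(A, b, cost)
  if (sol$status != "optimal") {
    return(list(status = sol$status, objective = NA_real_,
                fluxes = rep(NA_real_, n)))
  }
  v <- sol$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), fluxes = v)
}

# Dense two-phase primal simplex (maximization, equality constraints,
# non-negative variables) with Bland's anti-cycling rule. Written for the
# small LPs of desk-scale metabolic models; not meant for large problems.
simplex_two_phase <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # phase 1: artificial basis, maximize -sum(artificials)
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(-1, m))
  res <- simplex_iterate(Tab, basis, cost1, allowed = seq_len(n + m), tol = tol)
  phase1_value <- sum(cost1[res$basis] * res$Tab[, n + m + 1])
  if (phase1_value < -1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # drive remaining basic artificials out of the basis (pivot on any
  # structural column; an all-zero row is redundant and is dropped)
  Tab <- res$Tab; basis <- res$basis
  drop_rows <- integer()
  for (i in which(basis > n)) {
    piv_col <- which(abs(Tab[i, seq_len(n)]) > tol)
    if (length(piv_col) == 0) {
      drop_rows <- c(drop_rows, i)
    } else {
      j <- piv_col[1]
      Tab[i, ] <- Tab[i, ] / Tab[i, j]
      upd <- setdiff(which(abs(Tab[, j]) > 0), i)
      if (length(upd) > 0) {
        Tab[upd, ] <- Tab[upd, , drop = FALSE] - outer(Tab[upd, j], Tab[i, ])
      }
      basis[i] <- j
    }
  }
  if (length(drop_rows) > 0) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # phase 2: artificial columns are never allowed to re-enter
  res <- simplex_iterate(Tab, basis, c(cost, rep(0, m)),
                         allowed = seq_len(n), tol = tol)
  if (res$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  x <- numeric(n)
  rhs <- res$Tab[, n + m + 1]
  keep <- res$basis <= n
  x[res$basis[keep]] <- rhs[keep]
  list(status = "optimal", x = x, value = sum(cost * x))
}

simplex_iterate <- function(Tab, basis, cost, allowed, tol = 1e-9) {
  m <- nrow(Tab); ncols <- ncol(Tab) - 1L
  rhs_col <- ncols + 1L
  repeat {
    red <- cost[allowed] -
      as.vector(crossprod(cost[basis], Tab[, allowed, drop = FALSE]))
    enter_pos <- which(red > tol)
    if (length(enter_pos) == 0) {
      return(list(Tab = Tab, basis = basis, status = "optimal"))
    }
    j <- allowed[enter_pos[1]]            # Bland: smallest eligible index
    col <- Tab[, j]
    pos <- which(col > tol)
    if (length(pos) == 0) {
      return(list(Tab = Tab, basis = basis, status = "unbounded"))
    }
    ratios <- Tab[pos, rhs_col] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    i <- cand[which.min(basis[cand])]     # Bland: smallest leaving variable
    piv <- Tab[i, j]
    Tab[i, ] <- Tab[i, ] / piv
    upd <- which(abs(Tab[, j]) > 0 & seq_len(m) != i)
    if (length(upd) > 0) {
      Tab[upd, ] <- Tab[upd, , drop = FALSE] -
        outer(Tab[upd, j], Tab[i, ])
    }
    basis[i] <- j
  }
}

#' Flux balance analysis
#'
#' Maximizes the model objective under steady state (`S v = 0`) and flux
#' bounds, optionally after applying a medium (exchange lower bound set to
#' minus the uptake cap).
#'
#' @param model A `metabolic_model`.
#' @param med Optional [medium()].
#' @param objective Optional alternative objective reaction ID.
#' @return A `flux_solution`: `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective` value and a flux tibble. Optimal solutions
#'   satisfy steady state and bounds to within `1e-9`.
#' @export
fba <- function(model, med = NULL, objective = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  model <- apply_medium(model, med)
  objective <- objective %||% model$objective
  if (!objective %in% model$reactions$id) {
    abort(sprintf("objective reaction '%s' not in model", objective),
          class = "anaerodesign_model_error")
  }
  S <- stoichiometry_matrix(model)
  obj <- as.numeric(model$reactions$id == objective)
  sol <- solve_lp(obj, S, model$reactions$lb, model$reactions$ub)
  structure(list(status = sol$status, objective = sol$objective,
                 fluxes = tibble::tibble(reaction = model$reactions$id,
                                         flux = sol$fluxes),
                 objective_reaction = objective),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status=%s, %s = %s\n", x$status,
              x$objective_reaction,
              if (is.na(x$objective)) "NA" else format(x$objective, digits = 6)))
  invisible(x)
}

#' @export
tidy.flux_solution <- function(x, ...) x$fluxes

#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective = x$objective,
                 objective_reaction = x$objective_reaction)
}

#' The aerobic reference medium of the toy model
#'
#' Mirrors an in-silico minimal medium: inorganic uptakes capped at
#' 1000 mmol gdw^-1 h^-1, the carbon source at 6.14 mmol gdw^-1 h^-1, and
#' the oxygen exchange open (or closed via [set_anoxic()]).
#'
#' @param aerobic Open the oxygen exchange?
#' @param carbon_uptake Carbon-source uptake cap (default 6.14).
#' @return A `medium`.
#' @export
toy_medium <- function(aerobic = TRUE, carbon_uptake = 6.14) {
  med <- medium(
    exchange_id = c("EX_carbon", "EX_o2", "EX_no3", "EX_nh4", "EX_pi",
                    "EX_so4", "EX_n2", "EX_b12", "EX_b6", "EX_k2"),
    max_uptake = c(carbon_uptake, 1000, 1000, 1000, 1000, 1000, 0, 0, 0, 0)
  )
  if (!aerobic) med <- set_anoxic(med) else med
}

#' A deterministic toy genome-scale model
#'
#' A desk-scale stand-in for a published genome-scale reconstruction,
#' built to exercise the anoxic gap analysis: a carbon source feeding a
#' central precursor and reducing equivalents; ATP only from oxygen
#' respiration or from an insertable denitrification chain
#' (nitrate -> nitrite -> NO -> N2O -> N2, each step translocating protons
#' and yielding ATP); three cofactor syntheses (B12-, B6- and K2-like) that
#' require molecular oxygen, with closed exchange reactions for each
#' cofactor; and a biomass reaction consuming ATP, the central precursor and
#' all three cofactors. A catabolic route burns the precursor to reducing
#' equivalents and a fermentative overflow reaction (no ATP yield) keeps
#' redox balanced when no terminal electron acceptor is available.
#' Parameter-free and deterministic.
#'
#' @return A `metabolic_model` with 29 reactions.
#' @export
toy_model <- function() {
  rxn <- function(id, st, lb, ub, genes = "", insertable = FALSE) {
    tibble::tibble(id = id, stoichiometry = list(st), lb = lb, ub = ub,
                   genes = genes, insertable = insertable)
  }
  reactions <- dplyr::bind_rows(
    # exchanges (single-metabolite; negative flux = uptake)
    rxn("EX_carbon", c(carbon_e = -1), -6.14, 1000),
    rxn("EX_o2",     c(o2_e = -1), -1000, 1000),
    rxn("EX_no3",    c(no3_e = -1), -1000, 1000),
    rxn("EX_n2",     c(n2_e = -1), 0, 1000),
    rxn("EX_nh4",    c(nh4_e = -1), -1000, 1000),
    rxn("EX_pi",     c(pi_e = -1), -1000, 1000),
    rxn("EX_so4",    c(so4_e = -1), -1000, 1000),
    rxn("EX_b12",    c(b12_e = -1), 0, 1000),   # closed: vitamin not in medium
    rxn("EX_b6",     c(b6_e = -1), 0, 1000),
    rxn("EX_k2",     c(k2_e = -1), 0, 1000),
    rxn("EX_waste",  c(waste_e = -1), 0, 1000),  # fermentation product outlet
    # transport
    rxn("CARBONt", c(carbon_e = -1, carbon_c = 1), 0, 1000, "gntP"),
    rxn("O2t",     c(o2_e = -1, o2_c = 1), 0, 1000),
    rxn("NO3t",    c(no3_e = -1, no3_c = 1), 0, 1000, "narK1;narK2", insertable = TRUE),
    rxn("B12t",    c(b12_e = -1, b12_c = 1), 0, 1000, "btuB"),
    rxn("B6t",     c(b6_e = -1, b6_c = 1), 0, 1000),
    rxn("K2t",     c(k2_e = -1, k2_c = 1), 0, 1000),
    # central metabolism: carbon -> precursor + reducing equivalents;
    # no net substrate-level ATP, so energy needs a terminal acceptor
    rxn("GLY", c(carbon_c = -1, prec_c = 1, red_c = 2), 0, 1000, "gap;pyk"),
    # full oxidation of the precursor to reducing equivalents
    rxn("OXID", c(prec_c = -1, red_c = 3), 0, 1000, "icd;sdh"),
    # redox-balancing fermentative overflow (no ATP yield)
    rxn("FERM", c(prec_c = -1, red_c = -3, waste_e = 1), 0, 1000, "ldhA"),
    # aerobic respiration: reducing equivalents + O2 -> ATP
    rxn("RESP", c(red_c = -1, o2_c = -0.5, atp_c = 2), 0, 1000, "cyoABCD"),
    # insertable denitrification chain, proton-motive ATP at each step
    rxn("NAR", c(no3_c = -1, red_c = -1, no2_c = 1, atp_c = 0.5), 0, 1000,
        "narGHJI", insertable = TRUE),
    rxn("NIR", c(no2_c = -1, red_c = -0.5, no_c = 1, atp_c = 0.25), 0, 1000,
        "nirS", insertable = TRUE),
    rxn("NOR", c(no_c = -2, red_c = -1, n2o_c = 1, atp_c = 0.5), 0, 1000,
        "norBC", insertable = TRUE),
    rxn("NOS", c(n2o_c = -1, red_c = -0.5, n2_e = 1, atp_c = 0.25), 0, 1000,
        "nosZ", insertable = TRUE),
    # oxygen-requiring cofactor biosyntheses (biomass precursors)
    rxn("B12S", c(prec_c = -1, o2_c = -0.25, b12_c = 1), 0, 1000, "cobG;cobNST"),
    rxn("B6S",  c(prec_c = -1, o2_c = -0.25, b6_c = 1), 0, 1000, "pdxH"),
    rxn("K2S",  c(prec_c = -1, o2_c = -0.25, k2_c = 1), 0, 1000, "menG;ubiE"),
    # biomass
    rxn("BIOMASS",
        c(atp_c = -10, prec_c = -1, b12_c = -0.01, b6_c = -0.01, k2_c = -0.01),
        0, 1000, "")
  )
  mets <- sort(unique(unlist(lapply(reactions$stoichiometry, names))))
  metabolic_model(reactions, mets, objective = "BIOMASS")
}
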