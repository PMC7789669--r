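# Independent FBA oracle: exhaustive vertex enumeration of the flux polytope
# {v : S v = 0, lb <= v <= ub}. Every vertex has enough active bound
# constraints to pin the point down; we enumerate all variable subsets fixed
# at either bound, solve the remaining square system, and keep feasible
# points. The LP optimum of a bounded feasible problem is the best vertex.
vertex_enumerate_max <- function(obj, S, lb, ub, tol = 1e-8) {
  n <- length(obj)
  best <- -Inf
  for (k in 0:n) {
    for (fixed in combn_list(n, k)) {
      free <- setdiff(seq_len(n), fixed)
      if (length(free) > 0) {
        Sf <- S[, free, drop = FALSE]
        if (qr(Sf)$rank < length(free)) next
      }
      for (signs in bound_choices(k)) {
        v <- numeric(n)
        v[fixed] <- ifelse(signs, ub[fixed], lb[fixed])
        if (length(free) > 0) {
          rhs <- -S[, fixed, drop = FALSE] %*% v[fixed]
          sol <- tryCatch(qr.solve(S[, free, drop = FALSE], rhs),
                          error = function(e) NULL)
          if (is.null(sol)) next
          v[free] <- sol
        }
        if (max(abs(S %*% v)) > tol) next
        if (any(v < lb - tol) || any(v > ub + tol)) next
        best <- max(best, sum(obj * v))
      }
    }
  }
  best
}

combn_list <- function(n, k) {
  if (k == 0) return(list(integer()))
  utils::combn(n, k, simplify = FALSE)
}

bound_choices <- function(k) {
  if (k == 0) return(list(logical()))
  unname(split(expand.grid(rep(list(c(FALSE, TRUE)), k)) == TRUE,
               seq_len(2^k)))
}

# Random small metabolic model: n_rxn reactions over n_met metabolites with
# sparse integer stoichiometry; bounds contain zero so v = 0 is feasible.
random_small_model <- function(n_met = 3, n_rxn = 5) {
  repeat {
    S <- matrix(sample(-2:2, n_met * n_rxn, replace = TRUE,
                       prob = c(.1, .2, .4, .2, .1)),
                nrow = n_met)
    if (all(colSums(S != 0) > 0)) break
  }
  lb <- ifelse(runif(n_rxn) < 0.5, -sample(1:10, n_rxn, replace = TRUE), 0)
  ub <- sample(1:10, n_rxn, replace = TRUE)
  obj <- as.numeric(seq_len(n_rxn) == sample(n_rxn, 1))
  list(obj = obj, S = S, lb = as.numeric(lb), ub = as.numeric(ub))
}

write_toy_model_file <- function(path = withr::local_tempfile(
                                   fileext = ".tsv",
                                   .local_envir = parent.frame())) {
  write_reaction_table(toy_model(), path)
  path
}
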