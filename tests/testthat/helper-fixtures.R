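# Shared fixture builders. Everything is generated in code; no stored data.

# A six-strain toy: 2 aerobic, 4 anaerobic; D3 carried by all anaerobes only.
toy_labels <- function() {
  tibble::tibble(
    strain_id = c("a1", "a2", "n1", "n2", "n3", "n4"),
    lifestyle = c("aerobic", "aerobic", rep("anaerobic", 4))
  )
}

toy_catalog <- function() {
  tibble::tibble(
    strain_id = c("a1", "a2", "n1", "n2", "n3", "n4",   # D1 in all strains
                  "a1", "a2",                            # D2 aerobes only
                  "n1", "n2", "n3", "n4"),               # D3 anaerobes only
    architecture = c(rep("D1", 6), rep("D2", 2), rep("D3", 4)),
    copy_number = 1L
  )
}

toy_matrix <- function() {
  build_architecture_matrix(toy_catalog(), toy_labels())
}

# Random binary domain matrix with random lifestyle labels (both present).
random_matrix <- function(n_strains, n_archs, density = 0.5) {
  labels <- tibble::tibble(
    strain_id = sprintf("s%02d", seq_len(n_strains)),
    lifestyle = c("aerobic", "anaerobic",
                  sample(c("aerobic", "anaerobic"), n_strains - 2, replace = TRUE))
  )
  counts <- matrix(rbinom(n_strains * n_archs, 1, density),
                   nrow = n_strains,
                   dimnames = list(labels$strain_id,
                                   sprintf("ARCH%03d", seq_len(n_archs))))
  build_architecture_matrix(
    tidyr::pivot_longer(
      tibble::as_tibble(counts, rownames = "strain_id"),
      -strain_id, names_to = "architecture", values_to = "copy_number"
    ) |> dplyr::filter(copy_number > 0),
    labels
  )
}

# Brute-force persistence oracle: plain loops over a strains x keys matrix.
brute_persistence <- function(ind, strains) {
  vapply(colnames(ind), function(k) {
    sum(ind[strains, k] > 0) / length(strains)
  }, numeric(1))
}

# Minimal count_dataset with two conditions.
tiny_counts <- function(counts, conditions, reference = "anaerobic") {
  samples <- sprintf("smp%02d", seq_len(ncol(counts)))
  colnames(counts) <- samples
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  count_dataset(counts,
                tibble::tibble(sample = samples, condition = conditions),
                reference = reference)
}

# Build a log2fc_matrix directly from a genes x conditions matrix of finite
# values (for filter tests that construct cells explicitly).
manual_fc <- function(m, rule = consistency_rule()) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "gene_id"),
    -gene_id, names_to = "condition", values_to = "log2fc"
  )
  long$fdr <- 0.5
  long$imputed <- FALSE
  structure(list(table = long, rule = rule, reference = "anaerobic"),
            class = "log2fc_matrix")
}
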