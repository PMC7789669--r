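#' Configuration for the synthetic genome-annotation generator
#'
#' Defines a two-lifestyle strain collection with planted domain structure:
#' a shared core carried by (almost) every strain, aerobe- and
#' anaerobe-specific architectures carried by one lifestyle group only,
#' and accessory background architectures with lifestyle-independent,
#' architecture-specific prevalence. Dropout removes an expected
#' architecture from a genome; contamination leaks a group-specific
#' architecture into the other group.
#'
#' @param n_aerobic,n_anaerobic Strains per lifestyle group.
#' @param n_shared_core Planted shared-core architectures.
#' @param n_aerobe_specific,n_anaerobe_specific Planted group-specific
#'   architectures.
#' @param n_anaerobe_duf How many of the anaerobe-specific architectures are
#'   domains of unknown function (accessions prefixed `DUF`); must not
#'   exceed `n_anaerobe_specific`.
#' @param n_accessory Random background architectures.
#' @param dropout_rate Probability that an expected core architecture is
#'   absent from one genome.
#' @param contamination_rate Probability that a group-specific architecture
#'   appears in a genome of the other group.
#' @param genes_per_strain Genes per genome, for gene-order coordinates.
#' @param operon_block_size Genes per co-localised block; planted
#'   anaerobe-specific genes are laid out in consecutive blocks of this size.
#' @param seed Integer RNG seed; identical configuration and seed give
#'   byte-identical output.
#' @return A validated `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_aerobic = 20, n_anaerobic = 20,
                              n_shared_core = 50,
                              n_aerobe_specific = 5, n_anaerobe_specific = 5,
                              n_anaerobe_duf = 0,
                              n_accessory = 100,
                              dropout_rate = 0.02, contamination_rate = 0.005,
                              genes_per_strain = 400, operon_block_size = 5,
                              seed = 1L) {
  cfg <- list(
    n_aerobic = check_count(n_aerobic, "n_aerobic"),
    n_anaerobic = check_count(n_anaerobic, "n_anaerobic"),
    n_shared_core = check_count(n_shared_core, "n_shared_core"),
    n_aerobe_specific = check_count(n_aerobe_specific, "n_aerobe_specific"),
    n_anaerobe_specific = check_count(n_anaerobe_specific, "n_anaerobe_specific"),
    n_anaerobe_duf = check_count(n_anaerobe_duf, "n_anaerobe_duf"),
    n_accessory = check_count(n_accessory, "n_accessory"),
    dropout_rate = check_rate(dropout_rate, "dropout_rate"),
    contamination_rate = check_rate(contamination_rate, "contamination_rate"),
    genes_per_strain = check_count(genes_per_strain, "genes_per_strain", min = 1L),
    operon_block_size = check_count(operon_block_size, "operon_block_size", min = 1L),
    seed = check_seed(seed)
  )
  if (cfg$n_anaerobe_duf > cfg$n_anaerobe_specific) {
    stop_config("n_anaerobe_duf", "must not exceed n_anaerobe_specific")
  }
  n_planted <- cfg$n_shared_core + cfg$n_aerobe_specific + cfg$n_anaerobe_specific +
    cfg$n_accessory
  if (n_planted > cfg$genes_per_strain) {
    stop_config("genes_per_strain",
                "must be at least the total number of planted architectures")
  }
  structure(cfg, class = "genome_sim_config")
}

#' Simulate a lifestyle-labelled genome-annotation data set
#'
#' Generates per-strain domain-annotation hits (one single-domain protein per
#' planted architecture occurrence), a strain label table, gene-order
#' coordinates and ground-truth architecture categories. Anaerobe-specific
#' genes are placed in consecutive operon-like blocks at the start of each
#' anaerobic genome, so each planted anaerobe-specific gene co-localises with
#' at least one other planted gene (when two or more are planted).
#'
#' @param cfg A [genome_sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{labels}{strain label tibble (`strain_id`, `lifestyle`)}
#'     \item{hits}{domain-hit tibble in the annotation-table format}
#'     \item{matrix}{the assembled `domain_matrix`}
#'     \item{coords}{gene coordinate tibble (`strain_id`, `gene_index`,
#'       `protein_id`, `architecture`, `strand`); gene indices are 1-based
#'       gene-order positions, not base pairs}
#'     \item{truth}{tibble `architecture`, `category` in
#'       \{shared_core, aerobe_specific, anaerobe_specific, accessory\},
#'       plus a `duf` flag}
#'   }
#' @export
simulate_domain_dataset <- function(cfg = genome_sim_config()) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  set.seed(cfg$seed)

  strain_ids <- c(sprintf("AER%04d", seq_len(cfg$n_aerobic)),
                  sprintf("ANA%04d", seq_len(cfg$n_anaerobic)))
  lifestyle <- rep(c("aerobic", "anaerobic"), c(cfg$n_aerobic, cfg$n_anaerobic))
  labels <- tibble::tibble(strain_id = strain_ids, lifestyle = lifestyle)

  n_known <- cfg$n_anaerobe_specific - cfg$n_anaerobe_duf
  arch_ana <- c(if (n_known > 0) sprintf("PFN%04d", seq_len(n_known)),
                if (cfg$n_anaerobe_duf > 0) sprintf("DUF%04d", seq_len(cfg$n_anaerobe_duf)))
  arch_sets <- list(
    shared_core = if (cfg$n_shared_core > 0) sprintf("PFS%04d", seq_len(cfg$n_shared_core)) else character(),
    aerobe_specific = if (cfg$n_aerobe_specific > 0) sprintf("PFA%04d", seq_len(cfg$n_aerobe_specific)) else character(),
    anaerobe_specific = arch_ana,
    accessory = if (cfg$n_accessory > 0) sprintf("PFX%04d", seq_len(cfg$n_accessory)) else character()
  )
  truth <- tibble::tibble(
    architecture = unlist(arch_sets, use.names = FALSE),
    category = rep(names(arch_sets), lengths(arch_sets)),
    duf = startsWith(unlist(arch_sets, use.names = FALSE), "DUF")
  )

  n_strain <- length(strain_ids)
  # Accessory prevalence is architecture-specific but identical in both
  # groups, so accessory architectures carry no lifestyle signal. The range
  # stays clearly below core-level prevalence: an "accessory" architecture
  # drawn at near-core prevalence would contradict its own ground-truth
  # label (core membership is defined by high persistence).
  accessory_prev <- runif(cfg$n_accessory, 0.05, 0.85)

  present <- function(arch, prob_aer, prob_ana) {
    keep <- c(rbinom(cfg$n_aerobic, 1L, prob_aer),
              rbinom(cfg$n_anaerobic, 1L, prob_ana)) == 1L
    if (!any(keep)) return(NULL)
    tibble::tibble(strain_id = strain_ids[keep], architecture = arch)
  }

  occ <- vector("list", nrow(truth))
  p_keep <- 1 - cfg$dropout_rate
  for (i in seq_len(nrow(truth))) {
    arch <- truth$architecture[i]
    occ[[i]] <- switch(
      truth$category[i],
      shared_core = present(arch, p_keep, p_keep),
      aerobe_specific = present(arch, p_keep, cfg$contamination_rate),
      anaerobe_specific = present(arch, cfg$contamination_rate, p_keep),
      accessory = {
        p <- accessory_prev[match(arch, arch_sets$accessory)]
        present(arch, p, p)
      }
    )
  }
  occurrences <- dplyr::bind_rows(occ)

  coords <- layout_coordinates(occurrences, labels, truth, cfg)
  hits <- tibble::tibble(
    strain_id = coords$strain_id,
    protein_id = coords$protein_id,
    domain_accession = coords$architecture,
    start = 10L,
    end = 10L + 40L
  )
  matrix <- build_architecture_matrix(build_architectures(hits), labels)
  list(labels = labels, hits = hits, matrix = matrix, coords = coords,
       truth = truth)
}

# Assign 1-based gene-order indices. Anaerobe-specific genes occupy the
# leading consecutive blocks (operon-like co-localisation); all other genes
# are placed in a seed-determined order after them.
layout_coordinates <- function(occurrences, labels, truth, cfg) {
  if (is.null(occurrences) || nrow(occurrences) == 0) {
    return(tibble::tibble(strain_id = character(), gene_index = integer(),
                          protein_id = character(), architecture = character(),
                          strand = character()))
  }
  ana_arch <- truth$architecture[truth$category == "anaerobe_specific"]
  occurrences |>
    dplyr::left_join(labels, by = "strain_id") |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::group_modify(function(df, key) {
      is_operon <- df$architecture %in% ana_arch
      ordered <- c(sort(df$architecture[is_operon]),
                   sample(df$architecture[!is_operon]))
      tibble::tibble(
        gene_index = seq_along(ordered),
        protein_id = sprintf("%s_p%04d", key$strain_id, seq_along(ordered)),
        architecture = ordered,
        strand = ifelse(seq_along(ordered) <= sum(is_operon), "+",
                        sample(c("+", "-"), length(ordered), replace = TRUE))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$strain_id, .data$gene_index)
}
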