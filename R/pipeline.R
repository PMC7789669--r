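#' Configure an end-to-end synthetic pipeline run
#'
#' Bundles the stage configurations and thresholds for [run_pipeline()].
#' Sub-configuration seeds are derived deterministically from the master
#' seed, so a single integer reproduces the whole run.
#'
#' @param seed Master integer seed.
#' @param genome A [genome_sim_config()]; its seed is overridden.
#' @param transcriptome A [transcriptome_sim_config()] or `NULL` to skip the
#'   transcriptome stage; its seed is overridden.
#' @param rf An [rf_protocol_config()] or `NULL` to skip the random-forest
#'   stage; its seed is overridden and `allow_smaller_classes` is enabled.
#' @param tau_core Persistence threshold for the domain cores (default 0.95).
#' @param epsilon Low-persistence ceiling for the reverse separation
#'   (default 0.01).
#' @param rule A [consistency_rule()].
#' @param window,min_fraction Co-localisation filter parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            genome = genome_sim_config(n_anaerobe_duf = 1),
                            transcriptome = transcriptome_sim_config(),
                            rf = rf_protocol_config(n_per_class = 20,
                                                    repetitions = 10,
                                                    trees_per_model = 200),
                            tau_core = 0.95, epsilon = 0.01,
                            rule = consistency_rule(),
                            window = 5, min_fraction = 0.5) {
  seed <- check_seed(seed)
  genome$seed <- derive_seed(seed, 1L)
  if (!is.null(transcriptome)) transcriptome$seed <- derive_seed(seed, 2L)
  if (!is.null(rf)) {
    rf$seed <- derive_seed(seed, 3L)
    rf$allow_smaller_classes <- TRUE
  }
  structure(list(seed = seed, genome = genome, transcriptome = transcriptome,
                 rf = rf,
                 tau_core = check_fraction(tau_core, "tau_core", lo = 0, hi = 1,
                                           lo_open = TRUE),
                 epsilon = check_fraction(epsilon, "epsilon"),
                 rule = rule, window = window, min_fraction = min_fraction),
            class = "pipeline_config")
}

# Functional categories of the toy-model gene labels, used when tagging GSM
# evidence in synthetic runs.
toy_gene_categories <- function() {
  tibble::tribble(
    ~pattern, ~category,
    "^nar|^nir|^nor|^nos", "nitrogen metabolism",
    "^cob|^btu|^pdx|^men|^ubi", "pyrimidine & amino acid biosynthesis",
    "^cyo|^ack", "ATP generation",
    "^hup|^hyp|^hya|^hyb", "hydrogenases"
  )
}

categorize_toy_genes <- function(genes) {
  rules <- toy_gene_categories()
  vapply(genes, function(g) {
    hit <- which(stringr::str_detect(g, rules$pattern))
    if (length(hit) > 0) rules$category[hit[1]] else "unknown function"
  }, character(1))
}

# Split toy-model gene-association strings ("narK1;narK2") into gene labels.
split_gene_labels <- function(genes) {
  sort(unique(unlist(strsplit(genes[nzchar(genes)], ";", fixed = TRUE))))
}

#' Run the full in-silico design pipeline on synthetic data
#'
#' Executes all stages in order: genome simulation and architecture matrix
#' assembly; persistence cores and lifestyle-specific lists (threshold and
#' low-persistence separations); repeated random-forest Gini ranking;
#' transcriptome simulation, fold-change imputation and consistency
#' filtering; flux-balance gap analysis of the toy model under anoxia; and
#' evidence integration into a categorized design table with vitamin
#' supplements. Stages configured as `NULL` are skipped with a logged
#' warning. Re-running with the same configuration reproduces every output.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all intermediate tables,
#'   the design and a JSON run manifest are written there.
#' @return A named list (`bundle`) with elements `genome`, `persistence`,
#'   `split_core`, `split_low`, `gini`, `transcriptome`, `selected_genes`,
#'   `tx_architectures`, `fba`, `evidence`, `duf`, `design` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "anaerodesign_pipeline_error", stage = name, parent = e)
    })
  }

  genome <- stage("genome_simulation", simulate_domain_dataset(config$genome))
  pt <- stage("persistence", persistence_by_group(genome$matrix))
  split_core <- stage("core_split",
                      core_split_at_threshold(genome$matrix, tau = config$tau_core))
  split_low <- stage("low_persistence_split",
                     specific_by_low_persistence(pt, epsilon = config$epsilon,
                                                 tau_presence = config$tau_core))

  gini <- NULL
  if (!is.null(config$rf)) {
    gini <- stage("random_forest", run_rf_protocol(genome$matrix, config$rf))
  } else {
    warnings_log <- c(warnings_log, "random-forest stage skipped (no config)")
  }

  tx <- NULL; selected <- NULL; tx_arch <- character(); tx_annotation <- NULL
  if (!is.null(config$transcriptome)) {
    tx <- stage("transcriptome_simulation",
                simulate_transcriptome(config$transcriptome))
    fc <- stage("fold_changes", log2fc_matrix(tx$counts, config$rule))
    selected <- stage("consistency_filter", consistency_filter(fc))
    tx_annotation <- link_genes_to_planted(tx$truth, genome$truth)
    mapped <- stage("gene_architecture_mapping",
                    map_genes_to_architectures(selected$gene_id, tx_annotation))
    tx_arch <- mapped$architectures
    tx$fc <- fc
  } else {
    warnings_log <- c(warnings_log, "transcriptome stage skipped (no config)")
    rlang::warn("transcriptome input missing; design will carry PDC/GSM tags only")
  }

  fba_res <- stage("fba_gap_analysis", run_toy_gap_analysis())

  category_map <- dplyr::bind_rows(
    tibble::tibble(
      key = genome$truth$architecture[genome$truth$category == "anaerobe_specific" &
                                        !genome$truth$duf],
      category = "nitrogen metabolism"
    ),
    tibble::tibble(
      key = genome$truth$architecture[genome$truth$duf],
      category = "unknown function"
    ),
    tibble::tibble(key = fba_res$gsm_genes,
                   category = categorize_toy_genes(fba_res$gsm_genes))
  )

  evidence <- stage("evidence_merge",
                    merge_evidence(split_core, gini = gini,
                                   transcriptome = tx_arch,
                                   gsm = fba_res$gsm_genes,
                                   category_map = category_map))

  duf_keys <- evidence$key[evidence$unknown_function]
  duf <- stage("duf_colocalisation",
               duf_colocalisation_filter(
                 duf = duf_keys, coords = genome$coords,
                 retained = evidence$key[!evidence$unknown_function &
                                           evidence$category != "excluded"],
                 labels = genome$labels,
                 window = config$window, min_fraction = config$min_fraction))

  design_rows <- evidence |>
    dplyr::filter(!.data$unknown_function | .data$key %in%
                    duf$key[duf$status == "retained"]) |>
    dplyr::transmute(entry = .data$key, category = .data$category,
                     n_domains = 1L,
                     entry_type = ifelse(.data$unknown_function, "domain", "gene"),
                     source = .data$source, gini_weight = .data$gini_weight)
  design <- stage("design_summary",
                  summarize_design(design_rows,
                                   supplements = fba_res$supplement_names))

  manifest <- list(
    seed = config$seed,
    thresholds = list(tau_core = config$tau_core, epsilon = config$epsilon,
                      min_consistent = config$rule$min_consistent,
                      min_strong = config$rule$min_strong,
                      strong_fold = config$rule$strong_fold,
                      alpha = config$rule$alpha,
                      window = config$window,
                      min_fraction = config$min_fraction),
    stage_seeds = list(genome = config$genome$seed,
                       transcriptome = if (!is.null(config$transcriptome))
                         config$transcriptome$seed,
                       rf = if (!is.null(config$rf)) config$rf$seed),
    warnings = warnings_log
  )

  bundle <- list(genome = genome, persistence = pt, split_core = split_core,
                 split_low = split_low, gini = gini, transcriptome = tx,
                 selected_genes = selected, tx_architectures = tx_arch,
                 fba = fba_res, evidence = evidence, duf = duf,
                 design = design, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Deterministic linkage of simulated transcriptome genes onto planted
# architectures: planted DE genes map onto the planted anaerobe-specific
# architectures (round-robin), background genes onto accessory ones.
link_genes_to_planted <- function(tx_truth, genome_truth) {
  ana <- genome_truth$architecture[genome_truth$category == "anaerobe_specific"]
  acc <- genome_truth$architecture[genome_truth$category == "accessory"]
  planted <- tx_truth$gene_id[tx_truth$direction %in% c("up", "down", "weak")]
  background <- tx_truth$gene_id[tx_truth$direction == "null"]
  dplyr::bind_rows(
    if (length(planted) > 0 && length(ana) > 0)
      tibble::tibble(gene_id = planted,
                     architecture = rep_len(ana, length(planted))),
    if (length(background) > 0 && length(acc) > 0)
      tibble::tibble(gene_id = background,
                     architecture = rep_len(acc, length(background)))
  )
}

# The standard gap analysis of the deterministic toy model: growth under
# aerobic and anoxic media, blocked precursors, per-precursor oxygen
# tracing, and the minimal vitamin supplement search with the
# denitrification set inserted.
run_toy_gap_analysis <- function() {
  model <- toy_model()
  med_aer <- toy_medium(aerobic = TRUE)
  med_ana <- set_anoxic(med_aer)
  aerobic <- fba(model, med_aer)
  anoxic <- fba(model, med_ana)
  blocked <- blocked_biomass_precursors(model, med_ana)
  traces <- purrr::map(setNames(nm = blocked$metabolite[blocked$blocked]),
                       function(met)
                         trace_oxygen_dependencies(model, med_ana, met))
  denitrified <- enable_insertable(model)
  supplements <- propose_media_supplements(
    denitrified, med_ana,
    candidates = c("EX_b12", "EX_b6", "EX_k2")
  )
  anoxic_restored <- local({
    m <- apply_medium(denitrified, med_ana)
    if (length(supplements) > 0) {
      idx <- match(supplements[[1]], m$reactions$id)
      m$reactions$lb[idx] <- -1000
    }
    fba(m)
  })
  trace_genes <- unlist(purrr::map(traces, function(tr) {
    tr$genes[tr$change %in% c("enable_insertable", "relieve_oxygen_requirement")]
  }))
  # the insertable reaction set jointly restores anoxic energy metabolism,
  # so its gene associations are part of the model-derived evidence
  insertion_genes <- if (anoxic_restored$status == "optimal" &&
                         anoxic_restored$objective > GROWTH_TOL) {
    model$reactions$genes[model$reactions$insertable]
  } else character()
  gsm_genes <- split_gene_labels(c(trace_genes, insertion_genes))
  supplement_names <- sort(unique(unlist(purrr::map(
    supplements,
    function(s) paste("vitamin", toupper(sub("^EX_", "", s)))
  ))))
  list(model = model, aerobic = aerobic, anoxic = anoxic,
       anoxic_restored = anoxic_restored, blocked = blocked, traces = traces,
       supplements = supplements, supplement_names = supplement_names,
       gsm_genes = gsm_genes)
}

# Write every bundle table plus a JSON manifest to a directory.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_label_table(bundle$genome$labels, p("strain_labels.tsv"))
  write_architecture_matrix(bundle$genome$matrix, p("architecture_matrix.tsv"))
  readr::write_tsv(bundle$persistence, p("persistence.tsv"), progress = FALSE)
  readr::write_tsv(tidy(bundle$split_core), p("core_split.tsv"), progress = FALSE)
  readr::write_tsv(tidy(bundle$split_low), p("low_persistence_split.tsv"),
                   progress = FALSE)
  if (!is.null(bundle$gini)) {
    readr::write_tsv(tibble::as_tibble(bundle$gini), p("cumulative_gini.tsv"),
                     progress = FALSE)
  }
  if (!is.null(bundle$selected_genes)) {
    readr::write_tsv(bundle$selected_genes, p("selected_genes.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(bundle$transcriptome$fc), p("log2fc.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(bundle$fba$blocked, p("blocked_precursors.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble::as_tibble(bundle$evidence), p("evidence.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$duf, p("duf_colocalisation.tsv"), progress = FALSE)
  readr::write_tsv(bundle$design$design, p("design.tsv"), progress = FALSE)
  readr::write_tsv(bundle$design$summary, p("design_summary.tsv"),
                   progress = FALSE)
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
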