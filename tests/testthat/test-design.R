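test_that("evidence merging unions candidates with sound source tags", {
  pdc <- split_cores(core_aerobic = c("shared1", "aerX"),
                     core_anaerobic = c("shared1", "anaA", "anaB"))
  gini <- cumulative_gini(list(c(anaA = 120, anaB = 15, aerX = 2, shared1 = 1)))
  ev <- merge_evidence(pdc, gini = gini,
                       transcriptome = c("anaA", "onlyT"),
                       gsm = "narG",
                       category_map = tibble::tibble(
                         key = c("anaA", "anaB", "narG"),
                         category = "nitrogen metabolism"))
  expect_setequal(ev$key, c("anaA", "anaB", "aerX", "onlyT", "narG"))
  get <- function(k) ev[ev$key == k, ]
  expect_equal(get("anaA")$source, "PDC,T")
  expect_equal(get("onlyT")$source, "T")
  expect_equal(get("narG")$source, "GSM")
  expect_equal(get("aerX")$category, "excluded")
  expect_equal(get("anaA")$gini_weight, 120)
  expect_equal(get("onlyT")$gini_weight, 0)
  expect_true(get("onlyT")$unknown_function)
  # tag soundness: a tag is present iff the method contributed the key
  expect_true(all(ev$src_t == (ev$key %in% c("anaA", "onlyT"))))
  expect_true(all(ev$src_gsm == (ev$key == "narG")))
  expect_true(all(nchar(ev$source) > 0))

  expect_error(
    merge_evidence(pdc, gsm = "narG",
                   gsm_join = tibble::tibble(gene = "other", key = "x")),
    "narG", class = "anaerodesign_join_error")
})

test_that("DUF co-localisation keeps only window-proximal domains", {
  coords <- tibble::tibble(
    strain_id = rep(c("n1", "n2"), each = 4),
    gene_index = rep(1:4, 2),
    architecture = rep(c("DUFa", "KNOWN", "bg", "DUFfar"), 2)
  )
  coords$gene_index[coords$architecture == "DUFfar"] <- c(50L, 50L)
  labels <- tibble::tibble(strain_id = c("n1", "n2"),
                           lifestyle = "anaerobic")
  res <- duf_colocalisation_filter(c("DUFa", "DUFfar"), coords,
                                   retained = "KNOWN", labels = labels,
                                   window = 5, min_fraction = 0.5)
  expect_equal(res$status[res$key == "DUFa"], "retained")
  expect_equal(res$fraction[res$key == "DUFa"], 1)
  expect_equal(res$status[res$key == "DUFfar"], "unresolved")

  # window 0 can never retain a distinct gene
  res0 <- duf_colocalisation_filter("DUFa", coords, retained = "KNOWN",
                                    labels = labels, window = 0)
  expect_equal(res0$status, "unresolved")

  # DUF present only in strains lacking anchors is unresolved
  coords2 <- tibble::tibble(strain_id = "n3", gene_index = 1L,
                            architecture = "DUFa")
  labels2 <- tibble::tibble(strain_id = "n3", lifestyle = "anaerobic")
  res2 <- duf_colocalisation_filter("DUFa", coords2, retained = "KNOWN",
                                    labels = labels2)
  expect_equal(res2$status, "unresolved")

  expect_error(duf_colocalisation_filter("D", coords, "KNOWN", window = -1),
               class = "anaerodesign_config_error")
})

test_that("design summaries recount the packaged reference tables exactly", {
  tables <- load_design_tables()
  design <- summarize_design(tables)
  expect_equal(design$totals$known_function_genes, 49)
  expect_equal(design$totals$total_entries, 57)
  expect_equal(design$totals$unknown_function_domains, 8)
  expect_equal(design$totals$n_vitamins, 3)

  summary <- design$summary
  pick <- function(cat, col) summary[[col]][summary$category == cat]
  expect_equal(pick("nitrogen metabolism", "n_genes"), 35)
  expect_equal(pick("nitrogen metabolism", "n_domains"), 45)
  expect_equal(pick("hydrogenases", "n_genes"), 9)
  expect_equal(pick("hydrogenases", "n_domains"), 9)
  expect_equal(pick("cytochrome C", "n_genes"), 1)
  expect_equal(pick("pyrimidine & amino acid biosynthesis", "n_genes"), 3)
  expect_equal(pick("pyrimidine & amino acid biosynthesis", "n_domains"), 6)
  expect_equal(pick("ATP generation", "n_genes"), 1)

  # count consistency: totals equal direct recounts of the retained table
  expect_equal(design$totals$known_function_genes,
               sum(design$design$entry_type == "gene" &
                     design$design$category != "unknown function"))
  expect_equal(design$totals$total_entries,
               design$totals$known_function_genes +
                 design$totals$unknown_function_domains)
  expect_setequal(design$supplements,
                  c("vitamin B12", "vitamin B6", "vitamin K2"))

  # empty table -> all counts zero
  empty <- summarize_design(tibble::tibble(entry = character(),
                                           category = character()))
  expect_equal(empty$totals$total_entries, 0)
  expect_equal(empty$totals$n_vitamins, 0)

  # vitamins must not overlap the gene list
  expect_error(
    summarize_design(tibble::tibble(entry = "AckA",
                                    category = "ATP generation"),
                     supplements = "AckA"),
    class = "anaerodesign_config_error")
})

test_that("packaged strain group counts sum to the published collection sizes", {
  counts <- load_strain_group_counts()
  full <- counts[counts$scope == "full", ]
  branch <- counts[counts$scope == "restricted-branch", ]
  expect_equal(sum(full$n_strains), 1628)
  expect_equal(full$n_strains[full$lifestyle == "aerobic"], 344)
  expect_equal(full$n_strains[full$lifestyle == "anaerobic"], 1284)
  expect_equal(sum(branch$n_strains), 225)
})

test_that("the pipeline integrates all stages and degrades without transcriptome", {
  cfg <- pipeline_config(
    seed = 7,
    genome = genome_sim_config(n_aerobic = 15, n_anaerobic = 15,
                               n_shared_core = 15, n_aerobe_specific = 2,
                               n_anaerobe_specific = 4, n_anaerobe_duf = 1,
                               n_accessory = 30, genes_per_strain = 80),
    transcriptome = transcriptome_sim_config(n_genes = 200, n_planted_up = 6,
                                             n_planted_down = 6,
                                             n_planted_weak = 4),
    rf = rf_protocol_config(n_per_class = 10, repetitions = 3,
                            trees_per_model = 100))
  b <- run_pipeline(cfg)

  planted <- b$genome$truth$architecture[
    b$genome$truth$category == "anaerobe_specific" & !b$genome$truth$duf]
  # planted anaerobe-specific architectures carry tag PDC in the evidence
  ev_planted <- b$evidence[b$evidence$key %in% planted, ]
  expect_true(all(ev_planted$src_pdc))
  # and reach the final design
  expect_true(all(planted %in% b$design$design$entry))
  # transcriptome architectures land with tag T
  expect_true(any(b$evidence$src_t))
  # toy-model denitrification genes and vitamins reach the design
  expect_true("narGHJI" %in% b$design$design$entry)
  expect_setequal(b$design$supplements,
                  c("vitamin B12", "vitamin B6", "vitamin K2"))

  # dropping the transcriptome stage degrades to PDC/GSM tags with a warning
  cfg2 <- pipeline_config(seed = 7, genome = cfg$genome,
                          transcriptome = NULL, rf = cfg$rf)
  expect_warning(b2 <- run_pipeline(cfg2), "transcriptome")
  expect_true(all(!b2$evidence$src_t))
  expect_true(any(b2$manifest$warnings != ""))
})

test_that("seeded pipeline runs are bit-identical and write a full bundle", {
  cfg <- pipeline_config(
    seed = 11,
    genome = genome_sim_config(n_aerobic = 10, n_anaerobic = 10,
                               n_shared_core = 10, n_aerobe_specific = 1,
                               n_anaerobe_specific = 3, n_anaerobe_duf = 1,
                               n_accessory = 20, genes_per_strain = 60),
    transcriptome = transcriptome_sim_config(n_genes = 120, n_planted_up = 4,
                                             n_planted_down = 4,
                                             n_planted_weak = 2),
    rf = rf_protocol_config(n_per_class = 8, repetitions = 2,
                            trees_per_model = 50))
  b1 <- run_pipeline(cfg)
  b2 <- run_pipeline(cfg)
  expect_identical(b1, b2)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  run_pipeline(cfg, out_dir = dir1)
  run_pipeline(cfg, out_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_true(file.exists(file.path(dir1, "design.tsv")))
})
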