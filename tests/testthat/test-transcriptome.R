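test_that("median-of-ratios size factors behave like the standard estimator", {
  # identical columns -> all factors 1
  m <- matrix(rep(c(10L, 20L, 40L), 3), ncol = 3,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  cd <- tiny_counts(m, c("anaerobic", "c1", "c2"))
  expect_equal(size_factors(cd)$size_factor, rep(1, 3))

  # hand oracle on a 3-gene toy: doubling one column doubles its factor
  # relative to the others. With columns (x, x, 2x): geometric means are
  # x * 2^(1/3), so ratios are 2^(-1/3) twice and 2^(2/3) once.
  m2 <- cbind(m[, 1], m[, 1], 2L * m[, 1])
  cd2 <- tiny_counts(m2, c("anaerobic", "c1", "c2"))
  sf <- size_factors(cd2)$size_factor
  expect_equal(sf, c(2^(-1 / 3), 2^(-1 / 3), 2^(2 / 3)))
  expect_equal(sf[3] / sf[1], 2)

  # single sample -> factor 1
  cd1 <- tiny_counts(m[, 1, drop = FALSE], "anaerobic")
  expect_equal(size_factors(cd1)$size_factor, 1)

  # genes with a zero anywhere are excluded from the reference set
  m3 <- rbind(m, g4 = c(0L, 100L, 100L))
  expect_equal(size_factors(tiny_counts(m3, c("anaerobic", "c1", "c2")))$size_factor,
               rep(1, 3))
  # no eligible gene -> normalization error
  zeros <- matrix(c(0L, 5L, 5L, 0L), 2, 2,
                  dimnames = list(c("g1", "g2"), NULL))
  expect_error(size_factors(tiny_counts(zeros, c("anaerobic", "c1"))),
               class = "anaerodesign_normalization_error")
})

test_that("size factors match the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  withr::local_seed(42)
  counts <- matrix(rnbinom(200 * 8, mu = 100, size = 5), nrow = 200,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("s%d", 1:8)))
  cd <- count_dataset(counts,
                      tibble::tibble(sample = sprintf("s%d", 1:8),
                                     condition = rep(c("anaerobic", "x"), 4)),
                      reference = "anaerobic")
  ours <- size_factors(cd)$size_factor
  theirs <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(ours, unname(theirs), tolerance = 1e-8)
})

test_that("condition fold changes are reference-over-condition with infinities passed on", {
  m <- matrix(c(40L, 40L, 10L, 10L,   # g1: ref 40 vs cond 10 -> log2 4 = 2
                30L, 30L, 30L, 30L,   # g2: equal -> 0
                0L,  0L,  50L, 50L,   # g3: ref 0 -> -Inf
                60L, 60L, 0L,  0L,    # g4: cond 0 -> +Inf
                rep(100L, 12)),       # three stable genes pin size factors at 1
              nrow = 7, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:7), NULL))
  cd <- tiny_counts(m, c("anaerobic", "anaerobic", "c1", "c1"))
  fc <- condition_log2fc(cd, "c1")
  expect_equal(fc$log2fc[fc$gene_id == "g1"], 2)
  expect_equal(fc$log2fc[fc$gene_id == "g2"], 0)
  expect_equal(fc$log2fc[fc$gene_id == "g3"], -Inf)
  expect_equal(fc$log2fc[fc$gene_id == "g4"], Inf)
  expect_error(condition_log2fc(cd, "anaerobic"),
               class = "anaerodesign_lookup_error")
  expect_error(condition_log2fc(cd, "nope"),
               class = "anaerodesign_lookup_error")
})

test_that("imputation maps non-finite cells to 0 or +/-4 by significance", {
  rule <- consistency_rule(alpha = 0.05)
  imp <- impute_log2fc(c(Inf, -Inf, -Inf, NaN, 1.7),
                       c(0.001, 0.3, 0.01, 0.001, 0.9), rule)
  expect_equal(imp$log2fc, c(4, 0, -4, 0, 1.7))
  expect_equal(imp$imputed, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # NA fdr counts as non-significant
  expect_equal(impute_log2fc(Inf, NA, rule)$log2fc, 0)
})

test_that("the consistency filter applies the 7-of-13 and 3-strong rules exactly", {
  rule <- consistency_rule(min_consistent = 7, min_strong = 3, strong_fold = 4)
  conds <- sprintf("c%02d", 1:13)
  row <- function(v) matrix(v, nrow = 1, dimnames = list("g", conds))

  # +2.5 in 8 comparisons (4 strong) -> selected up
  sel <- consistency_filter(manual_fc(row(c(rep(2.5, 4), rep(0.5, 4), rep(-0.3, 5))),
                                      rule))
  expect_equal(sel$direction, "up")
  expect_equal(sel$n_consistent, 8)
  expect_equal(sel$n_strong, 4)

  # + sign in 7 comparisons but only 2 strong -> rejected
  expect_equal(nrow(consistency_filter(
    manual_fc(row(c(rep(2.5, 2), rep(0.5, 5), rep(-0.2, 6))), rule))), 0)

  # + sign in only 6 of 13 (all strong) -> rejected
  expect_equal(nrow(consistency_filter(
    manual_fc(row(c(rep(3, 6), rep(-0.1, 7))), rule))), 0)

  # zeros count for neither direction
  expect_equal(nrow(consistency_filter(
    manual_fc(row(c(rep(2.5, 6), rep(0, 7))), rule))), 0)

  # down-regulation selected symmetrically
  seld <- consistency_filter(manual_fc(row(c(rep(-2.5, 7), rep(0.4, 6))), rule))
  expect_equal(seld$direction, "down")

  # raising thresholds never grows the selection
  m <- row(c(rep(2.5, 4), rep(0.5, 4), rep(-0.3, 5)))
  n_base <- nrow(consistency_filter(manual_fc(m, rule)))
  stricter <- consistency_rule(min_consistent = 9, min_strong = 3)
  strong <- consistency_rule(min_consistent = 7, min_strong = 5)
  expect_lte(nrow(consistency_filter(manual_fc(m, stricter))), n_base)
  expect_lte(nrow(consistency_filter(manual_fc(m, strong))), n_base)

  expect_error(consistency_rule(min_consistent = 2, min_strong = 5),
               class = "anaerodesign_config_error")
})

test_that("rescaling one sample's library leaves all fold changes unchanged", {
  withr::local_seed(7)
  counts <- matrix(rnbinom(100 * 6, mu = 80, size = 10) + 1L, nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  cond <- c("anaerobic", "anaerobic", "c1", "c1", "c2", "c2")
  cd <- tiny_counts(counts, cond)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 5L
  cds <- tiny_counts(scaled, cond)
  sf <- size_factors(cd)$size_factor
  sfs <- size_factors(cds)$size_factor
  # the scaled sample's factor moves by 5x relative to the others
  expect_equal(sfs[3] / sfs[1], 5 * sf[3] / sf[1])
  for (cc in c("c1", "c2")) {
    expect_equal(condition_log2fc(cds, cc)$log2fc,
                 condition_log2fc(cd, cc)$log2fc)
  }
})

test_that("full matrices impute every cell and map genes to architectures", {
  cfg <- transcriptome_sim_config(n_genes = 80, n_planted_up = 5,
                                  n_planted_down = 5, n_planted_weak = 0,
                                  dropout_conditions = 3, seed = 55)
  sim <- simulate_transcriptome(cfg)
  fc <- log2fc_matrix(sim$counts)
  expect_true(all(is.finite(tidy(fc)$log2fc)))
  expect_true(any(tidy(fc)$imputed))  # dropouts exercised the rule
  expect_true(all(tidy(fc)$log2fc[tidy(fc)$imputed] %in% c(-4, 0, 4)))
  expect_equal(dplyr::n_distinct(tidy(fc)$condition), 13)

  annotation <- tibble::tibble(gene_id = c("gA", "gB"),
                               architecture = c("PF1", "PF2"))
  mapped <- map_genes_to_architectures(c("gA", "gB", "gZ"), annotation)
  expect_setequal(mapped$architectures, c("PF1", "PF2"))
  expect_equal(mapped$unmapped, "gZ")

  # 22 genes over 35 architectures via multi-domain proteins
  ann <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:22), times = c(rep(2, 13), rep(1, 9))),
    architecture = sprintf("ARCH%02d", 1:35)
  )
  expect_length(map_genes_to_architectures(sprintf("g%02d", 1:22), ann)$architectures,
                35)
})

test_that("count datasets round-trip through the TSV writer", {
  cfg <- transcriptome_sim_config(n_genes = 20, n_planted_up = 2,
                                  n_planted_down = 2, n_planted_weak = 2,
                                  seed = 3)
  sim <- simulate_transcriptome(cfg)
  stem <- file.path(withr::local_tempdir(), "tx")
  write_count_dataset(sim$counts, stem)
  back <- read_count_dataset(stem, reference = "anaerobic")
  expect_identical(back$counts, sim$counts$counts)
  expect_equal(back$condition_map, sim$counts$condition_map)
})
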