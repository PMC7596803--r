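test_that("degenerate parameters give the Poisson limit with the configured baseline", {
  cfg <- cohort_config(n_genes = 400, group_sizes = c(A = 30L, B = 30L),
                       n_informative_genes = 100, baseline_mean = 50,
                       log2_effect_size = 0, dispersion = 0, libsize_sigma = 0,
                       seed = 7)
  cohort <- generate_cohort(cfg)
  chk <- empirical_dispersion_check(cohort)
  # per-gene mean within 3 standard errors of the baseline (Poisson: se = sqrt(mu/n))
  se <- sqrt(50 / 60)
  expect_gt(mean(abs(chk$mean - 50) <= 3 * se), 0.99)
  # variance ~ mean in the Poisson limit
  expect_lt(abs(median(chk$variance / chk$mean) - 1), 0.15)
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg1 <- cohort_config(n_genes = 60, group_sizes = c(A = 5L, B = 5L),
                        n_informative_genes = 20, seed = 1)
  expect_identical(generate_cohort(cfg1)$counts$values,
                   generate_cohort(cfg1)$counts$values)
  cfg2 <- cohort_config(n_genes = 60, group_sizes = c(A = 5L, B = 5L),
                        n_informative_genes = 20, seed = 2)
  expect_false(identical(generate_cohort(cfg1)$counts$values,
                         generate_cohort(cfg2)$counts$values))
})

test_that("adding genes does not reshuffle the counts of existing genes", {
  base <- cohort_config(n_genes = 50, group_sizes = c(A = 6L, B = 6L),
                        n_informative_genes = 10, seed = 3)
  more <- cohort_config(n_genes = 80, group_sizes = c(A = 6L, B = 6L),
                        n_informative_genes = 10, seed = 3)
  expect_identical(generate_cohort(base)$counts$values,
                   generate_cohort(more)$counts$values[1:50, ])
})

test_that("strong effects make groups exactly recoverable by nearest centroid", {
  cfg <- cohort_config(log2_effect_size = 3, dispersion = 0.05,
                       libsize_sigma = 0, seed = 5)
  cohort <- generate_cohort(cfg)
  lc <- log2(cohort$counts$values + 1)
  centroids <- sapply(levels(cohort$true_group),
                      function(g) rowMeans(lc[, cohort$true_group == g, drop = FALSE]))
  pred <- levels(cohort$true_group)[apply(lc, 2, function(x)
    which.min(colSums((x - centroids)^2)))]
  keep <- !(colnames(lc) %in% cohort$discordant_ids)
  expect_equal(mean(pred[keep] == as.character(cohort$true_group)[keep]), 1)
})

test_that("nearest-centroid recovery never degrades as the effect size grows", {
  acc <- function(effect, seed) {
    cohort <- small_cohort(seed = seed, effect = effect, dispersion = 0.2)
    lc <- log2(cohort$counts$values + 1)
    centroids <- sapply(levels(cohort$true_group),
                        function(g) rowMeans(lc[, cohort$true_group == g, drop = FALSE]))
    pred <- levels(cohort$true_group)[apply(lc, 2, function(x)
      which.min(colSums((x - centroids)^2)))]
    mean(pred == as.character(cohort$true_group))
  }
  for (seed in 1:4) {
    accs <- vapply(c(0.5, 1.5, 3), acc, numeric(1), seed = seed)
    expect_true(all(diff(accs) >= 0))
  }
})

test_that("the empirical mean-variance relationship matches the dispersion", {
  cfg <- cohort_config(n_genes = 600, group_sizes = c(A = 60L, B = 60L),
                       n_informative_genes = 0, baseline_mean = 100,
                       log2_effect_size = 0, dispersion = 0.5,
                       libsize_sigma = 0, seed = 11)
  chk <- empirical_dispersion_check(generate_cohort(cfg))
  expect_lt(abs(median(chk$dispersion_hat) - 0.5) / 0.5, 0.2)
})

test_that("a single-sample cohort has no defined variance", {
  cfg <- cohort_config(n_genes = 20, group_sizes = c(A = 1L, B = 1L),
                       n_informative_genes = 5, seed = 1)
  cohort <- generate_cohort(cfg)
  cohort$counts$values <- cohort$counts$values[, 1, drop = FALSE]
  expect_warning(out <- empirical_dispersion_check(cohort), "single sample")
  expect_equal(nrow(out), 0)
})

test_that("a fully mixed discordant sample carries its molecular group's expected expression", {
  cfg <- cohort_config(n_genes = 90, group_sizes = c(A = 8L, B = 8L),
                       n_informative_genes = 30, libsize_sigma = 0,
                       discordant = data.frame(histology = "A", molecular = "B",
                                               weight = 1, n = 2L),
                       seed = 2)
  cohort <- generate_cohort(cfg)
  disc <- cohort$discordant_ids
  pure_b <- colnames(cohort$mu)[cohort$histology == "B"][1]
  for (id in disc) expect_identical(cohort$mu[, id], unname(cohort$mu[, pure_b]) |>
                                      stats::setNames(rownames(cohort$mu)))
  expect_identical(as.character(cohort$true_group[match(disc, colnames(cohort$mu))]),
                   rep("B", 2))
})

test_that("gene roles flag sex and mitochondrial genes with matching chromosomes", {
  cohort <- small_cohort(n_genes = 200, frac_sex_genes = 0.1, frac_mito_genes = 0.05)
  chrom <- cohort$counts$gene_chrom
  expect_identical(unname(chrom[cohort$gene_roles == "mito"]),
                   rep("MT", sum(cohort$gene_roles == "mito")))
  expect_true(all(chrom[cohort$gene_roles == "sex"] %in% c("X", "Y")))
  expect_equal(sum(cohort$gene_roles == "sex"), 20)
  expect_equal(sum(cohort$gene_roles == "mito"), 10)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_genes = 10, n_informative_genes = 20),
               class = "lnen_config_error")
  expect_error(cohort_config(group_sizes = c(A = 1L)), class = "lnen_config_error")
  expect_error(cohort_config(group_sizes = c(A = 0L, B = 5L), n_informative_genes = 5),
               class = "lnen_config_error")
  expect_error(cohort_config(group_sizes = c(A = 5L, B = 5L),
                             discordant = data.frame(histology = "A", molecular = "B",
                                                     weight = 1.2, n = 1L)),
               class = "lnen_config_error")
  expect_error(cohort_config(group_sizes = c(A = 5L, B = 5L),
                             discordant = data.frame(histology = "A", molecular = "C",
                                                     weight = 0.5, n = 1L)),
               class = "lnen_config_error")
  expect_error(cohort_config(frac_sex_genes = 1.5), class = "lnen_config_error")
  bad_S <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(cohort_config(group_sizes = c(A = 5L, B = 5L),
                             group_similarity = bad_S),
               class = "lnen_config_error")
})

test_that("the default six-group similarity encodes the expected relations", {
  S <- default_group_similarity(c("SCLC", "LCNEC_TypeI", "LCNEC_TypeII",
                                  "Carcinoid_A1", "Carcinoid_A2", "Carcinoid_B"))
  expect_true(isSymmetric(S))
  expect_identical(unname(diag(S)), rep(1, 6))
  # Type II LCNEC sits closer to SCLC than Type I does
  expect_gt(S["SCLC", "LCNEC_TypeII"], S["SCLC", "LCNEC_TypeI"])
  # carcinoid B is the carcinoid nearest the LCNECs
  expect_gt(S["Carcinoid_B", "LCNEC_TypeII"], S["Carcinoid_A1", "LCNEC_TypeII"])
  # non-default groups fall back to private programs
  expect_identical(default_group_similarity(c("X", "Y")),
                   matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y"))))
})
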