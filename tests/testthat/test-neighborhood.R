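test_that("kNN ranking solves small geometries by hand", {
  pts <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(c("p1", "p2", "p3"), NULL))
  r <- knn_ranks(pts, k = 1)
  expect_identical(as.integer(r$idx), c(2L, 1L, 2L))
  # k = n - 1 lists every other sample exactly once per sample
  set.seed(1)
  m <- matrix(rnorm(14), ncol = 2)
  rownames(m) <- sprintf("s%d", 1:7)
  full <- knn_ranks(m, k = 6)
  for (i in 1:7) expect_setequal(full$idx[i, ], setdiff(1:7, i))
  expect_error(knn_ranks(m, k = 7), class = "lnen_qc_error")
})

test_that("kNN ranking matches the brute-force oracle on random points", {
  set.seed(17)
  m <- matrix(rnorm(40), ncol = 2)
  rownames(m) <- sprintf("s%d", 1:20)
  for (k in c(1, 5, 19)) {
    expect_identical(knn_ranks(m, k)$idx, oracle_knn(m, k))
  }
})

test_that("distance ties are broken by ascending sample index", {
  # three coincident points: each one's nearest neighbor is the lowest index
  pts <- matrix(0, nrow = 3, ncol = 2, dimnames = list(c("a", "b", "c"), NULL))
  r <- knn_ranks(pts, k = 2)
  expect_identical(r$idx[1, ], c(2L, 3L))
  expect_identical(r$idx[2, ], c(1L, 3L))
  expect_identical(r$idx[3, ], c(1L, 2L))
})

test_that("the SD statistic is zero on identical rankings and maximal on disjoint ones", {
  set.seed(5)
  m <- matrix(rnorm(24), ncol = 2)
  rownames(m) <- sprintf("s%d", 1:12)
  r <- knn_ranks(m, k = 4)
  expect_identical(unname(sd_metric(r, r)), rep(0, 12))
  # disjoint neighborhoods score k(k+1)/2
  o <- structure(list(idx = matrix(c(2L, 3L), 1), k = 2L, n = 5L,
                      sample_ids = "x", space_tag = "a"),
                 class = "neighbor_ranking")
  p <- structure(list(idx = matrix(c(4L, 5L), 1), k = 2L, n = 5L,
                      sample_ids = "x", space_tag = "b"),
                 class = "neighbor_ranking")
  expect_equal(unname(sd_metric(o, p)), 2 * 3 / 2)
})

test_that("the SD statistic reproduces the hand-enumerated example", {
  # orig neighbors {a(1), b(2)}, proj {a(1), c(2)}: lost b at rank 2, gained c
  # at rank 2; w(2) = k - 2 + 1 = 1, so SD = 0.5 + 0.5 = 1
  o <- structure(list(idx = matrix(c(2L, 3L), 1), k = 2L, n = 4L,
                      sample_ids = "x", space_tag = "a"),
                 class = "neighbor_ranking")
  p <- structure(list(idx = matrix(c(2L, 4L), 1), k = 2L, n = 4L,
                      sample_ids = "x", space_tag = "b"),
                 class = "neighbor_ranking")
  expect_equal(unname(sd_metric(o, p)), 1)
  # the alternative weight rule gives w(2) = 0 here
  expect_equal(unname(sd_metric(o, p, weight = "linear0")), 0)
})

test_that("SD profiles vanish for identity and full-rank isometric embeddings", {
  set.seed(12)
  X <- matrix(rnorm(15 * 4), nrow = 15)
  rownames(X) <- sprintf("s%d", 1:15)
  prof <- sd_profile(X, X, k_grid = c(2, 5, 9, 13))
  expect_identical(prof$mean, rep(0, 4))
  # a full-rank PCA rotation preserves all distances
  ex <- toy_expr(t(X))
  emb <- pca_embed(ex, d = 4, scale = FALSE)
  prof2 <- sd_profile(X, emb, k_grid = c(2, 5, 9, 13))
  expect_identical(prof2$mean, rep(0, 4))
})

test_that("SD profiles equal the brute-force oracle exactly", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(8:30, 1)
    X <- matrix(rnorm(n * 5), nrow = n, dimnames = list(sprintf("s%d", 1:n), NULL))
    Y <- matrix(rnorm(n * 2), nrow = n, dimnames = list(sprintf("s%d", 1:n), NULL))
    kg <- sort(sample(2:(n - 2), 3))
    for (w in c("linear1", "linear0")) {
      prof <- sd_profile(X, Y, k_grid = kg, weight = w)
      expect_equal(prof$mean, oracle_sd_profile(X, Y, kg, w), tolerance = 1e-12)
    }
  }
})

test_that("anchor scaling fixes PCA-5D at 0 and PCA-2D at 1 and is affine in between", {
  a5 <- manual_sd_profile(2:6, c(1, 2, 3, 4, 5), "PCA-5D")
  a2 <- manual_sd_profile(2:6, c(5, 6, 7, 8, 9), "PCA-2D")
  x <- manual_sd_profile(2:6, c(3, 4, 5, 6, 7), "X")
  expect_identical(scaled_sd(a5, a5, a2)$value, rep(0, 5))
  expect_identical(scaled_sd(a2, a5, a2)$value, rep(1, 5))
  expect_identical(scaled_sd(x, a5, a2)$value, rep(0.5, 5))
  # zero denominator errors, naming the k
  a2bad <- manual_sd_profile(2:6, c(5, 2, 7, 8, 9), "PCA-2D")
  expect_error(scaled_sd(x, a5, a2bad), "k = 3", class = "lnen_qc_error")
  # mismatched grids are rejected
  expect_error(scaled_sd(manual_sd_profile(3:7, 1:5), a5, a2), class = "lnen_qc_error")
})

test_that("local and global summary means split the grid at k = 30", {
  k <- c(10, 20, 40, 50)
  sc <- scaled_sd(manual_sd_profile(k, c(2, 4, 10, 20)),
                  manual_sd_profile(k, c(1, 2, 3, 4)),
                  manual_sd_profile(k, c(3, 4, 5, 6)))
  expect_equal(attr(sc, "mean_local"), mean(c(1 / 2, 1)))
  expect_equal(attr(sc, "mean_global"), mean(c(7 / 2, 8)))
})

test_that("the replicate protocol records spread and rejects bad seed sets", {
  cohort <- small_cohort(seed = 9, n_per_group = 12)
  ex <- filter_genes_by_chromosome(vst_transform(cohort$counts))
  gs <- select_variable_genes(ex)
  one <- replicate_umap_sd(ex, gs, n_neighbors = 8, k_grid = c(3, 8, 15), R = 1)
  expect_identical(one$sd, rep(0, 3))
  expect_error(replicate_umap_sd(ex, gs, n_neighbors = 8, k_grid = c(3, 8),
                                 R = 2, seeds = c(4, 4)),
               class = "lnen_qc_error")
  expect_error(replicate_umap_sd(ex, gs, R = 0), class = "lnen_qc_error")
})

test_that("replicate means are stable across disjoint seed batches", {
  cohort <- small_cohort(seed = 10, n_per_group = 15)
  ex <- filter_genes_by_chromosome(vst_transform(cohort$counts))
  gs <- select_variable_genes(ex)
  kg <- c(5, 10, 20)
  b1 <- replicate_umap_sd(ex, gs, n_neighbors = 15, k_grid = kg, R = 12,
                          seeds = 1:12)
  b2 <- replicate_umap_sd(ex, gs, n_neighbors = 15, k_grid = kg, R = 12,
                          seeds = 101:112)
  expect_true(all(is.finite(b1$sd)))
  pooled_se <- sqrt(b1$sd^2 + b2$sd^2) / sqrt(12)
  expect_true(all(abs(b1$mean - b2$mean) <= 3 * pooled_se + 1e-9))
})

test_that("method comparison degenerates gracefully and matches the paired t formula", {
  k <- 2:21
  a5 <- manual_sd_profile(k, seq(1, 4, length.out = 20))
  a2 <- manual_sd_profile(k, seq(2, 8, length.out = 20))
  sa <- scaled_sd(manual_sd_profile(k, seq(1.2, 5, length.out = 20), "A"), a5, a2)
  # identical profiles tie with p = 1
  same <- compare_methods(sa, sa)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_identical(same$direction, "tie")
  # constant nonzero offset: degenerate, direction only
  sb <- sa
  sb$value <- sa$value + 1
  off <- compare_methods(sa, sb)
  expect_true(off$degenerate)
  expect_identical(off$direction, "a_better")
  expect_true(is.na(off$p_value))
  # random profiles match the textbook formula
  set.seed(31)
  sc1 <- scaled_sd(manual_sd_profile(k, runif(20, 1, 8), "C"), a5, a2)
  sc2 <- scaled_sd(manual_sd_profile(k, runif(20, 1, 8), "D"), a5, a2)
  got <- compare_methods(sc1, sc2, alternative = "less")
  want <- oracle_paired_t(sc1$value, sc2$value, alternative = "less")
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_equal(tidy(got)$p.value, got$p_value)
})

test_that("SD values always lie in [0, k(k+1)/2] across random embeddings", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(6:25, 1)
    X <- matrix(rnorm(n * 4), nrow = n, dimnames = list(sprintf("s%d", 1:n), NULL))
    Y <- matrix(rnorm(n * 2), nrow = n, dimnames = list(sprintf("s%d", 1:n), NULL))
    k <- sample(seq_len(n - 2), 1) + 1
    vals <- sd_metric(knn_ranks(X, k), knn_ranks(Y, k))
    expect_true(all(vals >= 0 & vals <= k * (k + 1) / 2))
  }
})
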