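test_that("kNN weights solve the unit square by hand and match brute force", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE,
               dimnames = list(paste0("c", 1:4), NULL))
  W <- knn_weight_matrix(sq, k = 2)$W
  expect_identical(unname(diag(W)), rep(0, 4))
  for (i in 1:4) {
    adjacent <- setdiff(which(as.matrix(dist(sq))[i, ] == 1), i)
    expect_setequal(which(W[i, ] == 1), adjacent)
  }
  # k = n - 1 flags everything off-diagonal
  Wfull <- knn_weight_matrix(sq, k = 3)$W
  expect_identical(unname(Wfull), 1 - diag(4))
  # rows match the brute-force kNN on random points
  set.seed(3)
  m <- matrix(rnorm(30), ncol = 2, dimnames = list(sprintf("s%d", 1:15), NULL))
  for (k in c(1, 4, 14)) {
    Wk <- knn_weight_matrix(m, k)$W
    idx <- oracle_knn(m, k)
    for (i in 1:15) expect_setequal(which(Wk[i, ] == 1), idx[i, ])
  }
  # symmetrization takes the elementwise max
  Ws <- knn_weight_matrix(m, 3, symmetrize = TRUE)$W
  expect_identical(Ws, t(Ws))
  expect_true(all(Ws >= knn_weight_matrix(m, 3)$W))
})

test_that("the Moran index reproduces hand-computed extremes", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE,
               dimnames = list(paste0("c", 1:4), NULL))
  W <- knn_weight_matrix(sq, k = 2)
  expect_equal(moran_i(c(1, -1, 1, -1), W), -1)
  # coincident pairs pointing at their partner: perfect positive autocorrelation
  pairs <- matrix(c(0, 0, 0, 0, 5, 5, 5, 5), ncol = 2, byrow = TRUE,
                  dimnames = list(paste0("p", 1:4), NULL))
  W1 <- knn_weight_matrix(pairs, k = 1)
  expect_equal(moran_i(c(2, 2, -2, -2), W1), 1)
  expect_error(moran_i(rep(3, 4), W1), class = "lnen_qc_error")
})

test_that("the Moran index equals the naive double loop and the ape implementation", {
  set.seed(19)
  for (rep in 1:6) {
    n <- sample(10:25, 1)
    m <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(sprintf("s%d", 1:n), NULL))
    x <- rnorm(n)
    W <- knn_weight_matrix(m, k = sample(2:5, 1))
    expect_equal(moran_i(x, W), oracle_moran(x, W$W), tolerance = 1e-12)
  }
  skip_if_not_installed("ape")
  set.seed(20)
  m <- matrix(rnorm(50), ncol = 2, dimnames = list(sprintf("s%d", 1:25), NULL))
  x <- rnorm(25)
  W <- knn_weight_matrix(m, k = 4)
  # ape row-normalizes; with k ones per row that rescaling cancels exactly
  expect_equal(moran_i(x, W), ape::Moran.I(x, W$W)$observed, tolerance = 1e-12)
})

test_that("permuted values average to the null expectation -1/(n-1)", {
  set.seed(27)
  n <- 25
  m <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(sprintf("s%d", 1:n), NULL))
  W <- knn_weight_matrix(m, k = 4)
  x <- rnorm(n)
  perms <- replicate(2000, moran_i(sample(x), W))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 3 * se)
})

test_that("a planted spatial marker gene scores near-maximal mean MI", {
  set.seed(35)
  n <- 50
  coords <- rbind(matrix(rnorm(15 * 2, sd = 0.1), ncol = 2),
                  matrix(rnorm(35 * 2, sd = 0.1, mean = 4), ncol = 2))
  rownames(coords) <- sprintf("s%d", 1:n)
  marker <- c(rep(5, 15), rep(0, 35)) + rnorm(n, sd = 0.05)
  noise <- rnorm(n)
  ex <- toy_expr(rbind(marker = marker, noise = noise) |>
                   `colnames<-`(rownames(coords)))
  res <- moran_profile(ex, spaces = list(map = coords), k_grid = c(3, 5, 8))
  expect_gt(res$mean_mi[res$gene_id == "marker"], 0.8)
  expect_lt(abs(res$mean_mi[res$gene_id == "noise"]), 0.3)
  # a single-k grid is just the single Moran index
  one <- moran_profile(ex, spaces = list(map = coords), k_grid = 5)
  W <- knn_weight_matrix(coords, 5)
  expect_equal(one$mean_mi[one$gene_id == "marker"], moran_i(marker, W),
               tolerance = 1e-12)
})

test_that("a stronger planted effect never lowers the marker's mean MI", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    coords <- rbind(matrix(rnorm(20, sd = 0.3), ncol = 2),
                    matrix(rnorm(40, sd = 0.3, mean = 3), ncol = 2))
    rownames(coords) <- sprintf("s%d", 1:30)
    noise <- rnorm(30)
    mis <- vapply(c(0.5, 1, 2, 4), function(effect) {
      x <- effect * c(rep(1, 10), rep(0, 20)) + noise
      mean(vapply(c(3, 6), function(k) moran_i(x, knn_weight_matrix(coords, k)),
                  numeric(1)))
    }, numeric(1))
    expect_true(all(diff(mis) >= -1e-12))
  }
})

test_that("constant genes are excluded from the profile with a message", {
  set.seed(41)
  coords <- matrix(rnorm(20), ncol = 2, dimnames = list(sprintf("s%d", 1:10), NULL))
  ex <- toy_expr(rbind(flat = rep(1, 10), ok = rnorm(10)) |>
                   `colnames<-`(rownames(coords)))
  expect_message(res <- moran_profile(ex, spaces = list(map = coords), k_grid = 3),
                 "constant")
  expect_identical(unique(res$gene_id), "ok")
  expect_identical(attr(res, "excluded"), "flat")
})

test_that("rank concordance handles identical, reversed and random rankings", {
  G <- 10
  mi <- seq(1, 0.1, length.out = G)
  same <- manual_moran_result(list(a = mi, b = mi, c = mi))
  rc <- rank_concordance(same, N_grid = c(2, 5, 10))
  expect_true(all(rc$overlap == 1))
  expect_equal(rc$null_expectation[rc$comparison == "a & b"],
               c(2, 5, 10) / G)
  # reversed rankings share nothing in the top half
  rev2 <- manual_moran_result(list(a = mi, b = rev(mi)))
  rc2 <- rank_concordance(rev2, N_grid = 5)
  expect_equal(rc2$overlap, 0)
  expect_error(rank_concordance(rev2, N_grid = 11), class = "lnen_qc_error")
  # triple-intersection row present with its hypergeometric null
  rc3 <- rank_concordance(same, N_grid = 5)
  expect_equal(rc3$null_expectation[rc3$comparison == "all spaces"], 0.25)
  expect_lte(rc3$overlap[rc3$comparison == "all spaces"],
             min(rc3$overlap[rc3$comparison != "all spaces"]))
})

test_that("Euler counts partition the three top lists", {
  set.seed(51)
  vals <- list(a = runif(40), b = runif(40), c = runif(40))
  res <- manual_moran_result(vals)
  ec <- euler_counts(res, N = 15)
  total_a <- ec$only_a + ec$ab_only + ec$ac_only + ec$all_three
  expect_equal(total_a, 15)
  expect_equal(ec$prop_all, ec$all_three / 15)
})

test_that("the space concordance test matches the paired formula and flags ties", {
  set.seed(61)
  mi_a <- runif(30, 0, 0.8)
  mi_b <- mi_a - rnorm(30, mean = 0.05, sd = 0.05)
  res <- manual_moran_result(list(orig = mi_a, map = mi_b))
  got <- concordance_test(res, "orig", "map", alternative = "greater")
  want <- oracle_paired_t(mi_a, mi_b, alternative = "greater")
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_identical(tidy(got)$direction, "a_higher")
  # a space against itself is a flagged one-sided tie at p = 0.5
  tie <- concordance_test(res, "orig", "orig")
  expect_true(tie$degenerate)
  expect_equal(tie$p_value, 0.5)
  # constant shift: degenerate with direction only
  shift <- manual_moran_result(list(orig = mi_a, map = mi_a - 0.1))
  deg <- concordance_test(shift, "orig", "map")
  expect_true(deg$degenerate)
  expect_identical(deg$direction, "a_higher")
  expect_true(is.na(deg$p_value))
})
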