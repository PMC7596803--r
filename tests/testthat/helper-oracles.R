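# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops over a fully sorted distance matrix.

oracle_knn <- function(coords, k) {
  D <- as.matrix(stats::dist(coords))
  n <- nrow(D)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

oracle_sd_weight <- function(r, k, weight) {
  if (weight == "linear1") k - r + 1 else k - r
}

# per-sample SD at a single k, by explicit set and rank comparison
oracle_sd <- function(X, Y, k, weight = "linear1") {
  a_idx <- oracle_knn(X, k)
  b_idx <- oracle_knn(Y, k)
  vapply(seq_len(nrow(a_idx)), function(i) {
    a <- a_idx[i, ]
    b <- b_idx[i, ]
    lost <- 0
    for (r in seq_len(k)) {
      if (!(a[r] %in% b)) lost <- lost + oracle_sd_weight(r, k, weight)
    }
    gained <- 0
    for (r in seq_len(k)) {
      if (!(b[r] %in% a)) gained <- gained + oracle_sd_weight(r, k, weight)
    }
    0.5 * lost + 0.5 * gained
  }, numeric(1))
}

oracle_sd_profile <- function(X, Y, k_grid, weight = "linear1") {
  vapply(k_grid, function(k) mean(oracle_sd(X, Y, k, weight)), numeric(1))
}

oracle_moran <- function(x, W) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * (x[i] - xbar) * (x[j] - xbar)
    }
  }
  (n / sum(W)) * num / sum((x - xbar)^2)
}

# textbook paired t-test from the raw formula
oracle_paired_t <- function(a, b, alternative = "two.sided") {
  d <- a - b
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  t <- mean(d) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df = n - 1),
              less = stats::pt(t, df = n - 1),
              greater = stats::pt(t, df = n - 1, lower.tail = FALSE))
  list(statistic = t, df = n - 1, p = p)
}
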