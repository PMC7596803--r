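# Neighborhood-preservation QC: rank-weighted sequence-difference (SD)
# statistic between a sample's k-neighborhoods in the original expression
# space and in an embedding, its scaling between PCA-5D and PCA-2D anchors,
# and the replicate protocol for stochastic embeddings.

# Full neighbor-rank matrix: R[i, j] = rank of j among the Euclidean
# neighbors of i (1 = nearest), ties broken by ascending sample index; the
# self entry gets rank n so it never enters any k <= n - 1 neighborhood.
neighbor_rank_matrix <- function(coords) {
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  if (n < 2L) abort("Need at least two points.", class = "lnen_qc_error")
  diag(D) <- Inf
  R <- matrix(0L, n, n)
  idx <- seq_len(n)
  for (i in idx) R[i, order(D[i, ], idx)] <- idx
  R
}

#' k-nearest-neighbor ranking of samples
#'
#' For every sample, the `k` nearest other samples by Euclidean distance,
#' with ranks 1..k. Distance ties are broken by ascending sample index and
#' the sample itself is never its own neighbor.
#'
#' @param coords Samples-by-dimensions numeric matrix, or an
#'   `lnen_embedding`.
#' @param k Neighborhood size, between 1 and `n - 1`.
#' @param space_tag Optional label naming the space.
#' @return An object of class `neighbor_ranking`: list with `idx`
#'   (`n x k` integer matrix of neighbor indices by rank), `k`, `sample_ids`
#'   and `space_tag`.
#' @export
knn_ranks <- function(coords, k, space_tag = NULL) {
  m <- coords_of(coords)
  n <- nrow(m)
  if (k < 1L || k > n - 1L) {
    abort(sprintf("`k` must lie in [1, %d]; got %d.", n - 1L, k), class = "lnen_qc_error")
  }
  R <- neighbor_rank_matrix(m)
  idx <- t(apply(R, 1, function(rr) order(rr)[seq_len(k)]))
  if (k == 1L) idx <- matrix(idx, ncol = 1L)
  structure(list(idx = idx, k = as.integer(k),
                 sample_ids = rownames(m), n = n,
                 space_tag = space_tag %||% "space"),
            class = "neighbor_ranking")
}

sd_weight <- function(r, k, weight) {
  switch(weight, linear1 = k - r + 1, linear0 = k - r,
         abort("Unknown SD weight rule.", class = "lnen_qc_error"))
}

#' Sequence-difference (SD) neighborhood dissimilarity
#'
#' Compares, for each sample, its `k`-neighborhood in an original space with
#' that in a projection. Neighbors present in one space's neighborhood but
#' not the other contribute a rank weight `w(r)` — by default
#' `w(r) = k - r + 1`, so losing a nearest neighbor (rank 1) costs `k` while
#' losing the rank-`k` neighbor costs 1 — and each side's sum enters with
#' factor 1/2:
#' `SD_k(i) = 1/2 * sum_{j in O\P} w(r_O(j)) + 1/2 * sum_{j in P\O} w(r_P(j))`.
#' The statistic is 0 exactly when the two neighbor sets coincide and at most
#' `k (k + 1) / 2` (disjoint sets).
#'
#' @param orig,proj [knn_ranks()] objects built with the same `k` over the
#'   same samples.
#' @param weight Rank-weight rule: `"linear1"` (`k - r + 1`, default) or
#'   `"linear0"` (`k - r`).
#' @return Numeric vector of per-sample SD values (named by sample id when
#'   available).
#' @export
sd_metric <- function(orig, proj, weight = c("linear1", "linear0")) {
  stopifnot(inherits(orig, "neighbor_ranking"), inherits(proj, "neighbor_ranking"))
  weight <- match.arg(weight)
  if (orig$k != proj$k) abort("Rankings use different k.", class = "lnen_qc_error")
  if (orig$n != proj$n || !identical(orig$sample_ids, proj$sample_ids)) {
    abort("Rankings cover different sample sets.", class = "lnen_qc_error")
  }
  k <- orig$k
  n_rows <- nrow(orig$idx)
  if (nrow(proj$idx) != n_rows) {
    abort("Rankings cover different sample sets.", class = "lnen_qc_error")
  }
  out <- numeric(n_rows)
  for (i in seq_len(n_rows)) {
    a <- orig$idx[i, ]
    b <- proj$idx[i, ]
    ra <- which(!(a %in% b))
    rb <- which(!(b %in% a))
    out[i] <- 0.5 * sum(sd_weight(ra, k, weight)) + 0.5 * sum(sd_weight(rb, k, weight))
  }
  if (length(orig$sample_ids) == n_rows) names(out) <- orig$sample_ids
  out
}

# Default scale grid: every integer from 2 to n - 2, thinned to at most
# `max_points` evenly spaced values. k = n - 1 is excluded because there the
# k-neighborhood of every sample is the entire cohort in any space, making
# SD identically zero and the anchor scaling undefined.
default_k_grid <- function(n, max_points = 100L) {
  top <- n - 2L
  if (top < 2L) abort("Too few samples for an SD grid.", class = "lnen_qc_error")
  ks <- seq(2L, top)
  if (length(ks) > max_points) {
    ks <- unique(round(seq(2L, top, length.out = max_points)))
  }
  as.integer(ks)
}

# vectorized mean SD per k from two rank matrices
sd_means_from_ranks <- function(R_o, R_p, k_grid, weight) {
  vapply(k_grid, function(k) {
    A <- R_o <= k
    B <- R_p <= k
    W_o <- pmax(sd_weight(R_o, k, weight), 0)
    W_p <- pmax(sd_weight(R_p, k, weight), 0)
    per_sample <- 0.5 * rowSums(W_o * (A & !B)) + 0.5 * rowSums(W_p * (B & !A))
    mean(per_sample)
  }, numeric(1))
}

#' Neighborhood-preservation profile across scales
#'
#' Computes the mean sequence-difference statistic `SD_k` (averaged across
#' samples) for every `k` in a grid, comparing an embedding's neighborhoods
#' with those of the original space. Low `k` probes preservation of local
#' structure, large `k` of global structure.
#'
#' @param orig_space The original coordinates — by convention the
#'   gene-selected, variance-stabilized matrix with samples as points
#'   (samples x genes), i.e. the embedding input. A matrix or
#'   `lnen_embedding`.
#' @param embedding The low-dimensional embedding (matrix or
#'   `lnen_embedding`).
#' @param k_grid Increasing integer vector of neighborhood sizes; defaults to
#'   every integer in `[2, n - 1]`, thinned to at most 100 evenly spaced
#'   values.
#' @param weight Rank-weight rule, see [sd_metric()].
#' @param method_tag Label for the embedding (defaults to its method).
#' @return A tibble of class `sd_profile` with columns `k`, `method`,
#'   `mean` (the per-k mean SD) and `sd` (spread across replicates; 0 for a
#'   single deterministic embedding).
#' @export
sd_profile <- function(orig_space, embedding, k_grid = NULL,
                       weight = c("linear1", "linear0"), method_tag = NULL) {
  weight <- match.arg(weight)
  X <- coords_of(orig_space)
  Y <- coords_of(embedding)
  if (nrow(X) != nrow(Y)) abort("Spaces have different sample counts.", class = "lnen_qc_error")
  n <- nrow(X)
  k_grid <- as.integer(k_grid %||% default_k_grid(n))
  if (any(diff(k_grid) <= 0) || k_grid[1] < 1L || max(k_grid) > n - 1L) {
    abort("`k_grid` must be strictly increasing within [1, n - 1].", class = "lnen_qc_error")
  }
  if (is.null(method_tag)) {
    method_tag <- if (inherits(embedding, "lnen_embedding")) {
      if (embedding$method == "UMAP") {
        paste0("UMAP-nn-", embedding$params$n_neighbors)
      } else paste0(embedding$method, "-", embedding$d, "D")
    } else "embedding"
  }
  R_o <- neighbor_rank_matrix(X)
  R_p <- neighbor_rank_matrix(Y)
  means <- sd_means_from_ranks(R_o, R_p, k_grid, weight)
  out <- tibble::tibble(k = k_grid, method = method_tag, mean = means, sd = 0)
  structure(out, class = c("sd_profile", class(out)),
            n_samples = n, weight = weight, replicates = 1L)
}

#' Scale SD profiles between the PCA-5D and PCA-2D anchors
#'
#' Rescales a method's `SD_k` profile so that the PCA-5D reference maps to 0
#' and the PCA-2D reference to 1 at every `k`:
#' `SD'_k = (SD_k(X) - SD_k(PCA-5D)) / (SD_k(PCA-2D) - SD_k(PCA-5D))`.
#' Values near 0 mean the method preserves `k`-neighborhoods as well as a
#' 5-component PCA, values near 1 as well as a 2-component PCA, values above
#' 1 worse than both; negative values beat PCA-5D.
#'
#' @param profile_x `sd_profile` of the evaluated method.
#' @param anchor5,anchor2 `sd_profile`s of the PCA-5D and PCA-2D anchors on
#'   the same `k` grid and samples.
#' @param k_split Split separating the "local" (`k < k_split`) and "global"
#'   (`k > k_split`) summary means (default 30, roughly the smallest-cluster
#'   size in the motivating cohort).
#' @return A tibble of class `scaled_sd_profile` with columns `k`, `method`,
#'   `value` and `sd` (scaled replicate spread), carrying `mean_local` /
#'   `mean_global` summary attributes.
#' @export
scaled_sd <- function(profile_x, anchor5, anchor2, k_split = 30) {
  for (p in list(profile_x, anchor5, anchor2)) {
    if (!inherits(p, "sd_profile")) abort("Inputs must be `sd_profile`s.", class = "lnen_qc_error")
  }
  if (!identical(profile_x$k, anchor5$k) || !identical(profile_x$k, anchor2$k)) {
    abort("Profiles must share the same k grid.", class = "lnen_qc_error")
  }
  denom <- anchor2$mean - anchor5$mean
  if (any(denom == 0)) {
    abort(sprintf("Anchors indistinguishable (zero denominator) at k = %s.",
                  paste(profile_x$k[denom == 0], collapse = ", ")),
          class = "lnen_qc_error")
  }
  value <- (profile_x$mean - anchor5$mean) / denom
  out <- tibble::tibble(k = profile_x$k, method = profile_x$method,
                        value = value, sd = profile_x$sd / abs(denom))
  structure(out, class = c("scaled_sd_profile", class(out)),
            k_split = k_split,
            mean_local = mean(value[profile_x$k < k_split]),
            mean_global = mean(value[profile_x$k > k_split]))
}

#' Replicated UMAP neighborhood-preservation profile
#'
#' Because UMAP's optimization is stochastic, its SD profile is a random
#' quantity; this runs `R` independently seeded UMAP embeddings and reports
#' the per-`k` mean and standard deviation of `SD_k` (and of the scaled
#' `SD'_k` when anchors are supplied).
#'
#' @param expr An [lnen_expr] object.
#' @param gene_set Optional gene restriction.
#' @param n_neighbors UMAP neighborhood size.
#' @param k_grid Grid of SD neighborhood sizes (see [sd_profile()]).
#' @param R Number of replicates (`R = 1` records a zero spread).
#' @param seeds Distinct integer seeds, one per replicate; defaults to
#'   `1:R`.
#' @param anchor5,anchor2 Optional anchor profiles enabling the scaled
#'   summary.
#' @param weight Rank-weight rule, see [sd_metric()].
#' @return An `sd_profile` tibble (columns `k`, `method`, `mean`, `sd`
#'   summarizing SD across replicates); when anchors are given the scaled
#'   per-replicate curves are summarized in a `scaled` attribute holding a
#'   `scaled_sd_profile` whose `value`/`sd` are the across-replicate mean and
#'   spread of `SD'_k`.
#' @export
replicate_umap_sd <- function(expr, gene_set = NULL, n_neighbors = 15L,
                              k_grid = NULL, R = 1L, seeds = NULL,
                              anchor5 = NULL, anchor2 = NULL,
                              weight = c("linear1", "linear0")) {
  weight <- match.arg(weight)
  R <- as.integer(R)
  if (R < 1L) abort("`R` must be at least 1.", class = "lnen_qc_error")
  seeds <- seeds %||% seq_len(R)
  if (length(seeds) != R || anyDuplicated(seeds)) {
    abort("`seeds` must be R distinct integers.", class = "lnen_qc_error")
  }
  X <- expr_points(expr, gene_set)
  n <- nrow(X)
  k_grid <- as.integer(k_grid %||% default_k_grid(n))
  R_o <- neighbor_rank_matrix(X)
  raw <- matrix(NA_real_, length(k_grid), R)
  for (r in seq_len(R)) {
    emb <- umap_embed(expr, gene_set, n_neighbors = n_neighbors, seed = seeds[r])
    raw[, r] <- sd_means_from_ranks(R_o, neighbor_rank_matrix(emb$coords), k_grid, weight)
  }
  tag <- paste0("UMAP-nn-", n_neighbors)
  rep_sd <- if (R > 1L) apply(raw, 1, sd) else rep(0, length(k_grid))
  out <- tibble::tibble(k = k_grid, method = tag,
                        mean = rowMeans(raw), sd = rep_sd)
  out <- structure(out, class = c("sd_profile", class(out)),
                   n_samples = n, weight = weight, replicates = R, seeds = seeds)
  if (!is.null(anchor5) && !is.null(anchor2)) {
    denom <- anchor2$mean - anchor5$mean
    if (any(denom == 0)) {
      abort(sprintf("Anchors indistinguishable (zero denominator) at k = %s.",
                    paste(k_grid[denom == 0], collapse = ", ")),
            class = "lnen_qc_error")
    }
    scaled_raw <- (raw - anchor5$mean) / denom
    sc <- tibble::tibble(k = k_grid, method = tag,
                         value = rowMeans(scaled_raw),
                         sd = if (R > 1L) apply(scaled_raw, 1, sd) else rep(0, length(k_grid)))
    k_split <- 30
    sc <- structure(sc, class = c("scaled_sd_profile", class(sc)),
                    k_split = k_split,
                    mean_local = mean(sc$value[k_grid < k_split]),
                    mean_global = mean(sc$value[k_grid > k_split]))
    attr(out, "scaled") <- sc
  }
  out
}

#' Compare two scaled SD profiles across the k grid
#'
#' Paired t-test of the per-`k` scaled neighborhood-preservation values of
#' two methods over the shared `k` grid; a negative mean difference means
#' method `a` preserves neighborhoods better (lower `SD'_k`) than method `b`.
#' When the per-`k` differences have zero variance the t statistic is
#' undefined; the comparison is then flagged degenerate and only the
#' direction is reported (identical profiles report a tie with `p = 1`).
#'
#' @param scaled_a,scaled_b `scaled_sd_profile`s on the same `k` grid with at
#'   least 3 levels.
#' @param alternative `"two.sided"` (default), `"less"` (a below b) or
#'   `"greater"`.
#' @return An object of class `sd_comparison`; see [tidy.sd_comparison()].
#' @export
compare_methods <- function(scaled_a, scaled_b,
                            alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(scaled_a, "scaled_sd_profile"), inherits(scaled_b, "scaled_sd_profile"))
  if (!identical(scaled_a$k, scaled_b$k)) {
    abort("Profiles must share the same k grid.", class = "lnen_qc_error")
  }
  if (length(scaled_a$k) < 3L) abort("Need at least 3 k levels.", class = "lnen_qc_error")
  diffs <- scaled_a$value - scaled_b$value
  mean_diff <- mean(diffs)
  direction <- if (mean_diff < 0) "a_better" else if (mean_diff > 0) "b_better" else "tie"
  if (isTRUE(all.equal(var(diffs), 0)) || var(diffs) == 0) {
    p <- if (all(diffs == 0)) 1 else NA_real_
    return(structure(list(statistic = NA_real_, df = NA_real_, p_value = p,
                          mean_difference = mean_diff, direction = direction,
                          alternative = alternative, degenerate = TRUE,
                          methods = c(scaled_a$method[1], scaled_b$method[1])),
                     class = "sd_comparison"))
  }
  tt <- t.test(scaled_a$value, scaled_b$value, paired = TRUE, alternative = alternative)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_difference = mean_diff,
                 direction = direction, alternative = alternative,
                 degenerate = FALSE,
                 methods = c(scaled_a$method[1], scaled_b$method[1])),
            class = "sd_comparison")
}

#' @export
print.sd_comparison <- function(x, ...) {
  cat(sprintf("<sd_comparison> %s vs %s: mean diff %.4g, p = %s%s\n",
              x$methods[1], x$methods[2], x$mean_difference,
              format(x$p_value), if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Tidy an SD profile comparison
#'
#' @param x An `sd_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A one-row tibble with the statistic, p-value, mean difference,
#'   direction and degeneracy flag.
#' @method tidy sd_comparison
#' @export
tidy.sd_comparison <- function(x, ...) {
  tibble::tibble(method_a = x$methods[1], method_b = x$methods[2],
                 statistic = x$statistic, df = x$df, p.value = x$p_value,
                 mean_difference = x$mean_difference, direction = x$direction,
                 alternative = x$alternative, degenerate = x$degenerate)
}
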