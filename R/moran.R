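# Spatial-autocorrelation QC: per-gene Moran index in the original space and
# in each embedding, and concordance of the top-gene rankings against a
# hypergeometric null.

#' Binary k-nearest-neighbor weight matrix
#'
#' Gives weight 1 to each point's `k` nearest neighbors by Euclidean
#' distance and 0 otherwise, so the spatial scale at which autocorrelation is
#' assessed is controlled by `k`. The matrix is row-wise asymmetric by
#' default (each row has exactly `k` ones); `symmetrize` replaces it with
#' `max(W, t(W))`.
#'
#' @param coords Samples-by-dimensions matrix or `lnen_embedding`.
#' @param k Neighborhood size in `[1, n - 1]`.
#' @param symmetrize Make the weights symmetric (default `FALSE`).
#' @return An object of class `knn_weights`: list with the binary matrix
#'   `W`, `k`, `symmetrize` and `S0 = sum(W)`.
#' @export
knn_weight_matrix <- function(coords, k, symmetrize = FALSE) {
  m <- coords_of(coords)
  n <- nrow(m)
  if (k < 1L || k > n - 1L) {
    abort(sprintf("`k` must lie in [1, %d]; got %d.", n - 1L, k), class = "lnen_qc_error")
  }
  R <- neighbor_rank_matrix(m)
  W <- (R <= k) * 1
  if (symmetrize) W <- pmax(W, t(W))
  structure(list(W = W, k = as.integer(k), symmetrize = symmetrize, S0 = sum(W)),
            class = "knn_weights")
}

#' Moran index of a variable over a weight matrix
#'
#' The classic spatial-autocorrelation statistic
#' `I = (n / S0) * sum_ij W_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`,
#' ranging from -1 (neighbors systematically dissimilar) to about 1
#' (neighbors share similar values); under random permutation of `x` its
#' expectation is `-1 / (n - 1)`.
#'
#' @param x Numeric vector, one value per sample; must not be constant.
#' @param W A [knn_weight_matrix()] result or a plain numeric matrix with
#'   zero diagonal.
#' @return The Moran index (scalar).
#' @export
moran_i <- function(x, W) {
  Wm <- if (inherits(W, "knn_weights")) W$W else as.matrix(W)
  n <- length(x)
  if (nrow(Wm) != n || ncol(Wm) != n) abort("`W` must be n x n.", class = "lnen_qc_error")
  y <- x - mean(x)
  denom <- sum(y^2)
  if (denom == 0) abort("`x` is constant; Moran index undefined.", class = "lnen_qc_error")
  (n / sum(Wm)) * sum(Wm * tcrossprod(y)) / denom
}

#' Per-gene mean Moran index across spatial scales and spaces
#'
#' For each gene and each coordinate space (conventionally the original
#' gene-selected expression space, the PCA-5D projection and the UMAP map),
#' computes the Moran index of the gene's expression over binary kNN weights
#' for every `k` in a grid and averages across `k`. Genes with high mean MI
#' drive the structure of the map; genes constant across samples are
#' excluded and counted.
#'
#' @param expr An [lnen_expr] object supplying the per-gene values.
#' @param spaces Named list of coordinate spaces (matrices or
#'   `lnen_embedding`s) sharing the sample set, e.g.
#'   `list(original = ..., "PCA-5D" = ..., UMAP = ...)`.
#' @param k_grid Integer grid of kNN scales (default `seq(5, 50, by = 5)`).
#' @param gene_set Optional [select_variable_genes()] restriction; default
#'   uses all genes of `expr`.
#' @param keep_per_k Retain the per-`k` values in a `per_k` attribute.
#' @return A tibble of class `moran_result` with columns `gene_id`, `space`
#'   and `mean_mi`, plus attributes `k_grid` and `excluded` (constant gene
#'   ids).
#' @export
moran_profile <- function(expr, spaces, k_grid = seq(5L, 50L, by = 5L),
                          gene_set = NULL, keep_per_k = FALSE) {
  if (length(k_grid) == 0L) abort("`k_grid` is empty.", class = "lnen_qc_error")
  if (is.null(names(spaces)) || any(names(spaces) == "")) {
    abort("`spaces` must be a named list.", class = "lnen_qc_error")
  }
  Y <- expr_points(expr, gene_set)              # samples x genes
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  v <- colSums(Yc^2)
  excluded <- colnames(Y)[v == 0]
  if (length(excluded) > 0L) {
    inform(sprintf("Excluding %d constant gene(s) from the Moran profile.", length(excluded)))
    Yc <- Yc[, v > 0, drop = FALSE]
    v <- v[v > 0]
  }
  res <- purrr::map_dfr(names(spaces), function(tag) {
    m <- coords_of(spaces[[tag]])
    if (nrow(m) != n) abort("Spaces must share the sample set.", class = "lnen_qc_error")
    R <- neighbor_rank_matrix(m)
    per_k <- vapply(k_grid, function(k) {
      W <- (R <= k) * 1
      (n / sum(W)) * colSums(Yc * (W %*% Yc)) / v
    }, numeric(ncol(Yc)))
    per_k <- matrix(per_k, ncol = length(k_grid))
    out <- tibble::tibble(gene_id = colnames(Yc), space = tag,
                          mean_mi = rowMeans(per_k))
    if (keep_per_k) {
      colnames(per_k) <- paste0("k", k_grid)
      out <- dplyr::bind_cols(out, tibble::as_tibble(per_k))
    }
    out
  })
  structure(res, class = c("moran_result", class(res)),
            k_grid = as.integer(k_grid), excluded = excluded)
}

moran_ranking <- function(result, space) {
  sub <- result[result$space == space, ]
  if (nrow(sub) == 0L) abort(sprintf("Unknown space '%s'.", space), class = "lnen_qc_error")
  sub$gene_id[order(-sub$mean_mi, seq_len(nrow(sub)))]
}

#' Top-N concordance of Moran-index rankings across spaces
#'
#' Ranks the genes by mean Moran index within each space and measures, for
#' each `N`, the proportion of overlap between the top-`N` gene sets of every
#' space pair (and of the triple intersection when three spaces are
#' present). Under the null of independent rankings the expected pairwise
#' overlap proportion is the hypergeometric mean `N / G`.
#'
#' @param result A [moran_profile()] result.
#' @param N_grid Integer vector of list sizes (each at most the gene count).
#' @return A tibble of class `overlap_curve` with columns `N`, `comparison`,
#'   `overlap` (observed proportion) and `null_expectation`.
#' @export
rank_concordance <- function(result, N_grid) {
  stopifnot(inherits(result, "moran_result"))
  spaces <- unique(result$space)
  rankings <- lapply(stats::setNames(spaces, spaces), function(s) moran_ranking(result, s))
  G <- unique(lengths(rankings))
  if (length(G) != 1L) abort("Spaces rank different gene universes.", class = "lnen_qc_error")
  if (any(N_grid < 1L) || any(N_grid > G)) {
    abort(sprintf("`N_grid` must lie in [1, %d].", G), class = "lnen_qc_error")
  }
  pairs <- utils::combn(spaces, 2, simplify = FALSE)
  rows <- purrr::map_dfr(as.integer(N_grid), function(N) {
    tops <- lapply(rankings, head, N)
    pair_rows <- purrr::map_dfr(pairs, function(p) {
      tibble::tibble(N = N, comparison = paste(p, collapse = " & "),
                     overlap = length(intersect(tops[[p[1]]], tops[[p[2]]])) / N,
                     null_expectation = N / G)
    })
    if (length(spaces) >= 3L) {
      tri <- Reduce(intersect, tops)
      pair_rows <- dplyr::bind_rows(pair_rows,
        tibble::tibble(N = N, comparison = "all spaces",
                       overlap = length(tri) / N,
                       null_expectation = (N / G)^(length(spaces) - 1L)))
    }
    pair_rows
  })
  structure(rows, class = c("overlap_curve", class(rows)), n_genes = G)
}

#' Euler-diagram counts of top-N genes across three spaces
#'
#' Cardinalities of the seven regions of the three-set Euler diagram of the
#' top-`N` Moran-ranked genes (plus the overall proportion of genes shared
#' by all three spaces), matching the counts displayed alongside the
#' concordance curves.
#'
#' @param result A [moran_profile()] result covering exactly three spaces.
#' @param N Top-list size.
#' @return A named list of region counts and `prop_all` (triple overlap /
#'   N).
#' @export
euler_counts <- function(result, N = 1000L) {
  stopifnot(inherits(result, "moran_result"))
  spaces <- unique(result$space)
  if (length(spaces) != 3L) abort("Euler counts need exactly three spaces.", class = "lnen_qc_error")
  tops <- lapply(stats::setNames(spaces, spaces),
                 function(s) head(moran_ranking(result, s), N))
  ab <- intersect(tops[[1]], tops[[2]])
  ac <- intersect(tops[[1]], tops[[3]])
  bc <- intersect(tops[[2]], tops[[3]])
  abc <- intersect(ab, tops[[3]])
  counts <- list(
    only_a = length(setdiff(tops[[1]], union(tops[[2]], tops[[3]]))),
    only_b = length(setdiff(tops[[2]], union(tops[[1]], tops[[3]]))),
    only_c = length(setdiff(tops[[3]], union(tops[[1]], tops[[2]]))),
    ab_only = length(setdiff(ab, abc)),
    ac_only = length(setdiff(ac, abc)),
    bc_only = length(setdiff(bc, abc)),
    all_three = length(abc),
    prop_all = length(abc) / N)
  names(counts)[1:3] <- paste0("only_", spaces)
  counts
}

#' One-sided test of Moran-index conservation between two spaces
#'
#' Paired t-test on the per-gene mean Moran indices of two spaces, asking
#' whether space `a` is more conservative of the spatial autocorrelations
#' (higher MI) than space `b`.
#'
#' @param result A [moran_profile()] result.
#' @param space_a,space_b Space tags present in `result`.
#' @param alternative `"greater"` (default: `a` has higher MI), `"less"` or
#'   `"two.sided"`.
#' @return An object of class `mi_comparison`; `tidy()` gives a one-row
#'   tibble. All-zero per-gene differences report a tie (`p = 0.5` one-sided,
#'   1 two-sided); non-zero constant differences are flagged degenerate with
#'   direction only.
#' @export
concordance_test <- function(result, space_a, space_b,
                             alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(result, "moran_result"))
  a <- result[result$space == space_a, ]
  b <- result[result$space == space_b, ]
  if (nrow(a) == 0L || nrow(b) == 0L) abort("Unknown space tag.", class = "lnen_qc_error")
  b <- b[match(a$gene_id, b$gene_id), ]
  if (anyNA(b$mean_mi)) abort("Spaces cover different genes.", class = "lnen_qc_error")
  diffs <- a$mean_mi - b$mean_mi
  mean_diff <- mean(diffs)
  direction <- if (mean_diff > 0) "a_higher" else if (mean_diff < 0) "b_higher" else "tie"
  if (var(diffs) == 0 || isTRUE(all.equal(var(diffs), 0))) {
    p <- if (all(diffs == 0)) { if (alternative == "two.sided") 1 else 0.5 } else NA_real_
    return(structure(list(statistic = NA_real_, df = NA_real_, p_value = p,
                          mean_difference = mean_diff, direction = direction,
                          alternative = alternative, degenerate = TRUE,
                          spaces = c(space_a, space_b)),
                     class = "mi_comparison"))
  }
  tt <- t.test(a$mean_mi, b$mean_mi, paired = TRUE, alternative = alternative)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_difference = mean_diff,
                 direction = direction, alternative = alternative,
                 degenerate = FALSE, spaces = c(space_a, space_b)),
            class = "mi_comparison")
}

#' @export
print.mi_comparison <- function(x, ...) {
  cat(sprintf("<mi_comparison> %s vs %s: mean MI diff %.4g, p = %s%s\n",
              x$spaces[1], x$spaces[2], x$mean_difference, format(x$p_value),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Tidy a Moran-index space comparison
#'
#' @param x An `mi_comparison` from [concordance_test()].
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy mi_comparison
#' @export
tidy.mi_comparison <- function(x, ...) {
  tibble::tibble(space_a = x$spaces[1], space_b = x$spaces[2],
                 statistic = x$statistic, df = x$df, p.value = x$p_value,
                 mean_difference = x$mean_difference, direction = x$direction,
                 alternative = x$alternative, degenerate = x$degenerate)
}
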