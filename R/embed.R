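# Embeddings: the 2D UMAP map and the PCA-2D / PCA-5D reference projections.

new_embedding <- function(coords, method, params, source_tag = NA_character_) {
  structure(list(coords = coords, sample_ids = rownames(coords),
                 method = method, d = ncol(coords), params = params,
                 source_tag = source_tag),
            class = "lnen_embedding")
}

#' @export
print.lnen_embedding <- function(x, ...) {
  p <- paste(names(x$params), unlist(lapply(x$params, paste, collapse = ",")),
             sep = "=", collapse = ", ")
  cat(sprintf("<lnen_embedding> %s, %d samples x %dD (%s)\n",
              x$method, nrow(x$coords), x$d, p))
  invisible(x)
}

coords_of <- function(x) {
  if (inherits(x, "lnen_embedding")) x$coords else as.matrix(x)
}

#' PCA reference embedding
#'
#' Projects samples onto the first `d` principal axes of the gene-restricted
#' expression matrix. Genes are centered and, by default, scaled to unit
#' variance before the decomposition (the convention of the classic
#' correlation-matrix PCA used for molecular maps). Each axis is oriented so
#' that its largest-magnitude gene loading is positive, making the output
#' deterministic.
#'
#' @param expr An [lnen_expr] object.
#' @param gene_set Optional [select_variable_genes()] result restricting the
#'   genes; `NULL` uses all genes.
#' @param d Number of principal components to keep (2 and 5 are the usual
#'   reference embeddings).
#' @param scale Scale genes to unit variance (default `TRUE`).
#' @return An `lnen_embedding` with an `explained_variance` entry in `params`.
#' @export
pca_embed <- function(expr, gene_set = NULL, d = 2L, scale = TRUE) {
  X <- expr_points(expr, gene_set)
  n <- nrow(X)
  if (n < 2L) abort("PCA needs at least two samples.", class = "lnen_embed_error")
  if (d > min(n - 1L, ncol(X))) {
    abort(sprintf("d = %d exceeds the available rank (%d).", d, min(n - 1L, ncol(X))),
          class = "lnen_embed_error")
  }
  if (scale) {
    const <- apply(X, 2, function(col) all(col == col[1]))
    if (any(const)) {
      abort(sprintf("Constant gene(s) cannot be unit-scaled: %s.",
                    paste(head(colnames(X)[const], 5), collapse = ", ")),
            class = "lnen_embed_error")
    }
  }
  pr <- prcomp(X, center = TRUE, scale. = scale, rank. = d)
  # deterministic sign: largest-|loading| gene positive on every axis
  for (j in seq_len(d)) {
    i0 <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i0, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  coords <- pr$x[, seq_len(d), drop = FALSE]
  rownames(coords) <- rownames(X)
  new_embedding(coords, method = "PCA",
                params = list(center = TRUE, scale = scale,
                              explained_variance = pr$sdev^2,
                              n_genes = ncol(X)),
                source_tag = expr$transform_tag)
}

#' UMAP embedding of the expression matrix
#'
#' Runs UMAP on the samples of the gene-restricted expression matrix with all
#' parameters at the backend's documented defaults except `n_neighbors`.
#' Small `n_neighbors` values favour local structure; setting it to the
#' number of samples makes UMAP attend to the global structure of the cohort,
#' which is the setting used for the pan-LNEN map. The seed fully determines
#' the stochastic optimization, so identical inputs and seeds give
#' bit-identical coordinates.
#'
#' @param expr An [lnen_expr] object.
#' @param gene_set Optional gene restriction (see [select_variable_genes()]).
#' @param n_neighbors Number of neighbors, between 2 and the number of
#'   samples.
#' @param seed Integer seed for the stochastic optimization.
#' @return A 2D `lnen_embedding`; `params` records every effective setting.
#' @export
umap_embed <- function(expr, gene_set = NULL, n_neighbors = 15L, seed = 1L) {
  X <- expr_points(expr, gene_set)
  n <- nrow(X)
  if (n_neighbors < 2L || n_neighbors > n) {
    abort(sprintf("`n_neighbors` must lie in [2, %d] (n_samples); got %d.", n, n_neighbors),
          class = "lnen_embed_error")
  }
  coords <- withr::with_seed(as.integer(seed), {
    uwot::umap(X, n_neighbors = n_neighbors, n_components = 2L,
               n_threads = 1, n_sgd_threads = 0)
  })
  rownames(coords) <- rownames(X)
  colnames(coords) <- c("dim_1", "dim_2")
  new_embedding(coords, method = "UMAP",
                params = list(n_neighbors = as.integer(n_neighbors),
                              seed = as.integer(seed),
                              min_dist = 0.01, spread = 1, metric = "euclidean",
                              init = "spectral", n_epochs = 500L,
                              backend = paste0("uwot-", as.character(utils::packageVersion("uwot"))),
                              n_genes = ncol(X)),
                source_tag = expr$transform_tag)
}

#' Integrate new samples into an existing map
#'
#' Concatenates new count columns with the reference counts on the shared
#' gene universe and reruns the whole pipeline — size factors,
#' variance-stabilization, chromosome filtering, variable-gene selection and
#' UMAP — on the combined matrix. This is a re-embedding of all samples
#' together, not a projection onto a frozen map: out-of-sample projection is
#' deliberately not offered because the map's coordinates are only meaningful
#' for the cohort they were optimized on.
#'
#' @param reference_counts,new_counts [lnen_counts] objects; gene annotation
#'   is taken from the reference. `new_counts` may have zero columns.
#' @param n_neighbors UMAP neighbors; defaults to the combined sample count.
#' @param seed Seed for the UMAP optimization.
#' @param threshold Variable-gene variance fraction (see
#'   [select_variable_genes()]).
#' @param drop Chromosomes to remove (see [filter_genes_by_chromosome()]).
#' @param min_gene_overlap Warn if the shared gene fraction (relative to the
#'   reference) falls below this floor.
#' @return The combined 2D UMAP `lnen_embedding`.
#' @export
integrate_new_samples <- function(reference_counts, new_counts,
                                  n_neighbors = NULL, seed = 1L,
                                  threshold = 0.5, drop = c("X", "Y", "MT"),
                                  min_gene_overlap = 0.5) {
  stopifnot(inherits(reference_counts, "lnen_counts"),
            inherits(new_counts, "lnen_counts"))
  ref <- reference_counts$values
  new <- new_counts$values
  if (ncol(new) == 0L) {
    combined <- reference_counts
  } else {
    shared <- intersect(rownames(ref), rownames(new))
    if (length(shared) == 0L) {
      abort("No genes shared between reference and new counts.",
            class = "lnen_embed_error")
    }
    frac <- length(shared) / nrow(ref)
    if (frac < min_gene_overlap) {
      warn(sprintf("Only %.1f%% of reference genes are shared with the new samples.",
                   100 * frac))
    }
    dropped <- nrow(ref) - length(shared)
    if (dropped > 0L) inform(sprintf("Dropping %d genes absent from the new samples.", dropped))
    clash <- intersect(colnames(ref), colnames(new))
    if (length(clash) > 0L) {
      abort(sprintf("Sample ids present in both matrices: %s.",
                    paste(head(clash, 5), collapse = ", ")),
            class = "lnen_embed_error")
    }
    combined <- lnen_counts(cbind(ref[shared, , drop = FALSE],
                                  new[shared, , drop = FALSE]),
                            gene_chrom = reference_counts$gene_chrom[shared])
  }
  expr <- vst_transform(combined)
  if (!is.null(combined$gene_chrom)) {
    expr <- filter_genes_by_chromosome(expr, drop = drop)
  }
  gs <- select_variable_genes(expr, threshold = threshold)
  nn <- n_neighbors %||% ncol(combined$values)
  umap_embed(expr, gs, n_neighbors = nn, seed = seed)
}
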