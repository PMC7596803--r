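# Shared in-code fixtures.

# a small two-group cohort with private programs (identity similarity)
small_cohort <- function(seed = 1, n_per_group = 10L, n_genes = 120L,
                         effect = 2, dispersion = 0.1, ...) {
  generate_cohort(cohort_config(
    n_genes = n_genes,
    group_sizes = c(A = n_per_group, B = n_per_group),
    n_informative_genes = round(n_genes / 3),
    log2_effect_size = effect, dispersion = dispersion,
    seed = seed, ...))
}

# tiny counts container with explicit values
toy_counts <- function(values, chrom = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  lnen_counts(values, gene_chrom = chrom)
}

# expression container straight from a numeric matrix (samples keep names)
toy_expr <- function(values) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  lnen_expr(values, transform_tag = "test")
}

# hand-built sd_profile tibble (for scaling arithmetic tests)
manual_sd_profile <- function(k, mean, method = "X", sd = 0) {
  out <- tibble::tibble(k = as.integer(k), method = method,
                        mean = mean, sd = sd)
  structure(out, class = c("sd_profile", class(out)))
}

# hand-built moran_result from a named list of per-gene mean MI vectors
manual_moran_result <- function(values_by_space, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("g%04d", seq_along(values_by_space[[1]]))
  rows <- purrr::map_dfr(names(values_by_space), function(s) {
    tibble::tibble(gene_id = gene_ids, space = s,
                   mean_mi = values_by_space[[s]])
  })
  structure(rows, class = c("moran_result", class(rows)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
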