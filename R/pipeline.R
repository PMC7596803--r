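# End-to-end pipeline and a thin command-line surface over it.

#' Run the full mapping-and-QC pipeline
#'
#' Chains every stage: median-of-ratios size factors, variance-stabilizing
#' transform, sex/mitochondrial gene removal, variable-gene selection, the
#' PCA-2D / PCA-5D reference embeddings and the UMAP map, the
#' neighborhood-preservation (scaled SD) profiles, the per-gene Moran-index
#' concordance, and — when an attribute table is supplied — the
#' centroid-proximity subtype tests. Optionally writes every result (plus
#' TumorMap export files and a provenance sidecar) to `outdir`.
#'
#' @param counts An [lnen_counts] object (with chromosome labels for the
#'   filtering stage) or a path readable by [read_counts()].
#' @param attributes Optional sample attribute data frame (or TSV path) with
#'   `sample_id` and the subtype grouping column.
#' @param threshold Variable-gene variance fraction (default 0.5).
#' @param drop_chromosomes Chromosomes removed before embedding.
#' @param n_neighbors UMAP neighbors; default: the number of samples (the
#'   global-structure setting).
#' @param seed Seed for the UMAP optimization.
#' @param k_grid SD neighborhood grid (default: up to 100 evenly spaced
#'   values in `[2, n - 1]`).
#' @param mi_k_grid Moran-index kNN grid (default `seq(5, 50, 5)`).
#' @param N_grid Top-list sizes for the Moran concordance curve; defaults to
#'   ten sizes up to half the retained genes.
#' @param replicates UMAP replicates for the SD protocol (default 1).
#' @param contrasts Subtype contrast table (see [run_subtype_suite()]);
#'   `NULL` with attributes present uses [default_subtype_contrasts()].
#' @param group_col Attribute column holding the molecular groups.
#' @param outdir Optional output directory.
#' @return A list of class `lnen_map_run` with every intermediate and
#'   result; see `glance()` for a one-row summary.
#' @export
run_pipeline <- function(counts, attributes = NULL, threshold = 0.5,
                         drop_chromosomes = c("X", "Y", "MT"),
                         n_neighbors = NULL, seed = 1L, k_grid = NULL,
                         mi_k_grid = seq(5L, 50L, by = 5L), N_grid = NULL,
                         replicates = 1L, contrasts = NULL,
                         group_col = "molecular_cluster", outdir = NULL) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(attributes)) attributes <- read_attributes(attributes)
  stopifnot(inherits(counts, "lnen_counts"))
  n <- ncol(counts$values)
  n_neighbors <- n_neighbors %||% n

  sf <- size_factors(counts)
  expr <- vst_transform(counts, sf)
  if (!is.null(counts$gene_chrom)) {
    expr <- filter_genes_by_chromosome(expr, drop = drop_chromosomes)
  }
  gs <- select_variable_genes(expr, threshold = threshold)
  pca2 <- pca_embed(expr, gs, d = 2L)
  pca5 <- pca_embed(expr, gs, d = 5L)
  umap <- umap_embed(expr, gs, n_neighbors = n_neighbors, seed = seed)

  orig <- expr_points(expr, gs)
  k_grid <- as.integer(k_grid %||% default_k_grid(n))
  prof2 <- sd_profile(orig, pca2, k_grid, method_tag = "PCA-2D")
  prof5 <- sd_profile(orig, pca5, k_grid, method_tag = "PCA-5D")
  degenerate <- prof2$mean == prof5$mean
  if (any(degenerate)) {
    warn(sprintf("Dropping %d k level(s) where the PCA anchors coincide: %s.",
                 sum(degenerate),
                 paste(head(k_grid[degenerate], 10), collapse = ", ")))
    k_grid <- k_grid[!degenerate]
    if (length(k_grid) < 3L) {
      abort("Fewer than 3 usable k levels: the PCA anchors are indistinguishable.",
            class = "lnen_qc_error")
    }
    prof2 <- prof2[!degenerate, ]
    prof5 <- prof5[!degenerate, ]
  }
  umap_sd <- replicate_umap_sd(expr, gs, n_neighbors = n_neighbors,
                               k_grid = k_grid, R = replicates,
                               seeds = seed + seq_len(replicates) - 1L,
                               anchor5 = prof5, anchor2 = prof2)
  scaled <- list(`PCA-5D` = scaled_sd(prof5, prof5, prof2),
                 `PCA-2D` = scaled_sd(prof2, prof5, prof2),
                 UMAP = attr(umap_sd, "scaled"))

  moran <- moran_profile(expr, gene_set = gs,
                         spaces = list(original = orig, `PCA-5D` = pca5, UMAP = umap),
                         k_grid = mi_k_grid)
  G <- length(gs$gene_ids)
  N_grid <- as.integer(N_grid %||% unique(pmax(1L, round(seq(G / 20, G / 2, length.out = 10)))))
  overlap <- rank_concordance(moran, N_grid)
  mi_test <- concordance_test(moran, "PCA-5D", "UMAP", alternative = "greater")

  subtype <- NULL
  if (!is.null(attributes)) {
    subtype <- run_subtype_suite(umap, attributes,
                                 contrasts = contrasts %||% default_subtype_contrasts(),
                                 group_col = group_col)
  }

  run <- structure(list(counts = counts, size_factors = sf, expr = expr,
                        gene_set = gs, pca2 = pca2, pca5 = pca5, umap = umap,
                        sd_profiles = list(`PCA-2D` = prof2, `PCA-5D` = prof5,
                                           UMAP = umap_sd),
                        scaled_sd = scaled, moran = moran, overlap = overlap,
                        mi_test = mi_test, subtype_tests = subtype,
                        attributes = attributes,
                        params = list(threshold = threshold,
                                      drop_chromosomes = drop_chromosomes,
                                      n_neighbors = n_neighbors, seed = seed,
                                      k_grid = k_grid, mi_k_grid = mi_k_grid,
                                      N_grid = N_grid, replicates = replicates)),
                   class = "lnen_map_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.lnen_map_run <- function(x, ...) {
  cat(sprintf("<lnen_map_run> %d samples, %d/%d genes retained, UMAP n_neighbors = %d\n",
              ncol(x$counts$values), length(x$gene_set$gene_ids),
              nrow(x$counts$values), x$params$n_neighbors))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `lnen_map_run`.
#' @param ... Unused.
#' @return Tibble with the retained-gene count, the local/global scaled-SD
#'   means of the UMAP map, the PCA-5D vs UMAP Moran-test p-value and the
#'   number of subtype tests run.
#' @method glance lnen_map_run
#' @export
glance.lnen_map_run <- function(x, ...) {
  sc <- x$scaled_sd$UMAP
  tibble::tibble(n_samples = ncol(x$counts$values),
                 n_genes_retained = length(x$gene_set$gene_ids),
                 n_neighbors = x$params$n_neighbors,
                 umap_sd_local = attr(sc, "mean_local"),
                 umap_sd_global = attr(sc, "mean_global"),
                 mi_p_value = x$mi_test$p_value,
                 n_subtype_tests = if (is.null(x$subtype_tests)) 0L else nrow(x$subtype_tests))
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_expression(run$expr, file.path(outdir, "expression_vst.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = run$gene_set$gene_ids,
                                  variance = unname(run$gene_set$variances)),
                   file.path(outdir, "variable_genes.tsv"))
  write_embedding(run$pca2, file.path(outdir, "embedding_pca2.tsv"))
  write_embedding(run$pca5, file.path(outdir, "embedding_pca5.tsv"))
  write_embedding(run$umap, file.path(outdir, "embedding_umap.tsv"))
  sd_tbl <- dplyr::bind_rows(run$sd_profiles)
  readr::write_tsv(sd_tbl, file.path(outdir, "sd_profiles.tsv"))
  readr::write_tsv(dplyr::bind_rows(run$scaled_sd), file.path(outdir, "sd_scaled.tsv"))
  readr::write_tsv(run$moran, file.path(outdir, "moran_mean_mi.tsv"))
  readr::write_tsv(run$overlap, file.path(outdir, "moran_overlap.tsv"))
  if (!is.null(run$subtype_tests)) {
    readr::write_tsv(run$subtype_tests, file.path(outdir, "subtype_tests.tsv"))
  }
  write_tumormap(run$umap, run$attributes, outdir)
  sidecar <- c(list(package = paste0("lnenmap-", as.character(utils::packageVersion("lnenmap"))),
                    r_version = paste(R.version$major, R.version$minor, sep = "."),
                    timestamp = format(Sys.time(), tz = "UTC")),
               run$params)
  write_config(sidecar, file.path(outdir, "run_provenance.txt"))
  invisible(outdir)
}

# --- command-line surface -------------------------------------------------

cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (!startsWith(a, "--")) abort(sprintf("Unexpected argument '%s'.", a), class = "lnen_cli_error")
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[[i + 1L]], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- argv[[i + 1L]]; i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' A thin shell surface over the package functions, used by
#' `inst/scripts/lnenmap.R`. Subcommands: `simulate` (write a synthetic
#' cohort: `--seed`, `--out`, optional `--n-genes`), `run-all` (full
#' pipeline: `--counts`, `--annotation`, `--attributes`, `--out`, optional
#' `--threshold`, `--n-neighbors`, `--replicates`, `--seed`) and
#' `export-tumormap` (`--embedding`, `--attributes`, `--out`). Anything the
#' subcommands do not cover is a direct function call in R.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly; errors print a
#'   single `lnenmap-error:` line and return 1.
#' @export
lnen_cli <- function(argv) {
  code <- tryCatch({
    if (length(argv) == 0L) abort("No subcommand given.", class = "lnen_cli_error")
    cmd <- argv[[1]]
    opts <- cli_args(argv[-1])
    num <- function(key, default) as.numeric(opts[[key]] %||% default)
    switch(cmd,
      "simulate" = {
        out <- opts[["out"]] %||% abort("simulate needs --out.", class = "lnen_cli_error")
        cfg <- cohort_config(n_genes = num("n-genes", 1000),
                             n_informative_genes = round(0.3 * num("n-genes", 1000)),
                             seed = num("seed", 1))
        write_cohort(generate_cohort(cfg), out)
        write_config(list(stage = "simulate", seed = num("seed", 1),
                          n_genes = num("n-genes", 1000)),
                     file.path(out, "provenance.txt"))
      },
      "run-all" = {
        counts <- read_counts(opts[["counts"]] %||%
                                abort("run-all needs --counts.", class = "lnen_cli_error"),
                              annotation = opts[["annotation"]])
        thr <- num("threshold", 0.5)
        if (thr <= 0 || thr > 1) abort("--threshold must lie in (0, 1].", class = "lnen_cli_error")
        run_pipeline(counts,
                     attributes = opts[["attributes"]],
                     threshold = thr,
                     n_neighbors = if (!is.null(opts[["n-neighbors"]])) num("n-neighbors", NA),
                     replicates = num("replicates", 1),
                     seed = num("seed", 1),
                     outdir = opts[["out"]] %||%
                       abort("run-all needs --out.", class = "lnen_cli_error"))
      },
      "export-tumormap" = {
        path <- opts[["embedding"]] %||% abort("export-tumormap needs --embedding.",
                                               class = "lnen_cli_error")
        df <- readr::read_tsv(path, show_col_types = FALSE)
        co <- as.matrix(df[, -1, drop = FALSE])
        rownames(co) <- df[[1]]
        emb <- new_embedding(co, method = "imported", params = list(file = path))
        at <- if (!is.null(opts[["attributes"]])) read_attributes(opts[["attributes"]])
        write_tumormap(emb, at, opts[["out"]] %||%
                         abort("export-tumormap needs --out.", class = "lnen_cli_error"))
      },
      abort(sprintf("Unknown subcommand '%s'.", cmd), class = "lnen_cli_error"))
    0L
  }, error = function(e) {
    message("lnenmap-error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
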