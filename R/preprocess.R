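# Preprocessing: raw counts -> variance-stabilized, gene-filtered expression
# matrix on which all embeddings are computed.

#' Count matrix container
#'
#' Wraps a genes-by-samples matrix of non-negative integer counts together
#' with optional per-gene chromosome labels.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. All entries must be non-negative integers.
#' @param gene_chrom Optional character vector of chromosome labels
#'   (`"1"`..`"22"`, `"X"`, `"Y"`, `"MT"`), one per gene.
#' @return An object of class `lnen_counts`.
#' @export
lnen_counts <- function(values, gene_chrom = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    abort("Count matrix needs gene rownames and sample colnames.",
          class = "lnen_counts_error")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    abort("Gene and sample ids must be unique.", class = "lnen_counts_error")
  }
  if (any(values < 0) || any(values != round(values))) {
    bad <- which(values < 0 | values != round(values), arr.ind = TRUE)[1, ]
    abort(sprintf("Counts must be non-negative integers; offending entry gene '%s', sample '%s'.",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]),
          class = "lnen_counts_error")
  }
  if (!is.null(gene_chrom)) {
    gene_chrom <- as.character(gene_chrom)
    if (length(gene_chrom) != nrow(values)) {
      abort("`gene_chrom` must have one label per gene.", class = "lnen_counts_error")
    }
    names(gene_chrom) <- rownames(values)
  }
  structure(list(values = values, gene_chrom = gene_chrom), class = "lnen_counts")
}

#' @export
print.lnen_counts <- function(x, ...) {
  cat(sprintf("<lnen_counts> %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$gene_chrom)) "" else " (annotated)"))
  invisible(x)
}

#' Median-of-ratios library-size factors
#'
#' For each sample, the size factor is the median across genes of the ratio
#' of its count to the gene's geometric mean across samples, taken over genes
#' with a positive geometric mean (i.e. no zero count). This is the classic
#' median-of-ratios normalization used throughout bulk RNA-seq.
#'
#' @param counts An [lnen_counts] object.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "lnen_counts"))
  m <- counts$values
  zero <- colSums(m) == 0
  if (any(zero)) {
    abort(sprintf("Sample(s) with all-zero counts: %s.",
                  paste(colnames(m)[zero], collapse = ", ")),
          class = "lnen_preprocess_error")
  }
  loggeo <- rowMeans(log(m))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    abort("No gene has a positive geometric mean (every gene has a zero count).",
          class = "lnen_preprocess_error")
  }
  geo <- exp(loggeo[ok])
  apply(m[ok, , drop = FALSE], 2, function(col) median(col / geo))
}

#' Variance-stabilizing transform (log shifted, size-factor scaled)
#'
#' Computes `log2(count / size_factor + 1)` per entry. This is a documented
#' stand-in for dispersion-fit variance-stabilizing transforms: it shares
#' their two essential properties for mapping (library-size correction and
#' compression of the count scale) while remaining closed-form; the
#' `transform_tag` records it so results from other transforms are never
#' silently conflated. An externally transformed matrix can be supplied to
#' the downstream stages directly via [lnen_expr()].
#'
#' @param counts An [lnen_counts] object.
#' @param factors Per-sample size factors, typically from [size_factors()].
#' @return An [lnen_expr] object.
#' @export
vst_transform <- function(counts, factors = size_factors(counts)) {
  stopifnot(inherits(counts, "lnen_counts"))
  m <- counts$values
  if (length(factors) != ncol(m) || any(factors <= 0)) {
    abort("`factors` must be one positive value per sample.",
          class = "lnen_preprocess_error")
  }
  vals <- log2(sweep(m, 2, factors, "/") + 1)
  lnen_expr(vals, size_factors = factors, transform_tag = "log2_median_ratio",
            gene_chrom = counts$gene_chrom)
}

#' Expression matrix container
#'
#' Holds transformed (variance-stabilized) expression values with the size
#' factors and a tag naming the transform that produced them. Use this
#' constructor directly to plug in an externally transformed matrix.
#'
#' @param values Numeric genes-by-samples matrix without missing values.
#' @param size_factors Per-sample positive factors used by the transform.
#' @param transform_tag String naming the transform.
#' @param gene_chrom Optional per-gene chromosome labels.
#' @return An object of class `lnen_expr`.
#' @export
lnen_expr <- function(values, size_factors = rep(1, ncol(values)),
                      transform_tag = "external", gene_chrom = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) {
    abort("Expression values must be finite and non-missing.", class = "lnen_expr_error")
  }
  if (any(size_factors <= 0)) abort("Size factors must be positive.", class = "lnen_expr_error")
  if (!is.null(gene_chrom)) names(gene_chrom) <- rownames(values)
  structure(list(values = values,
                 size_factors = stats::setNames(size_factors, colnames(values)),
                 transform_tag = transform_tag,
                 gene_chrom = gene_chrom),
            class = "lnen_expr")
}

#' @export
print.lnen_expr <- function(x, ...) {
  cat(sprintf("<lnen_expr> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$transform_tag))
  invisible(x)
}

#' Drop genes on selected chromosomes
#'
#' Removes genes located on the given chromosomes (by default the sex
#' chromosomes X and Y, to reduce sex influence on expression profiles, and
#' the mitochondrial chromosome MT), preserving the original gene order.
#'
#' @param expr An [lnen_expr] object.
#' @param annotation Per-gene chromosome labels: either `NULL` to use the
#'   labels carried by `expr`, a named character vector, or an
#'   [lnen_counts] object carrying `gene_chrom`.
#' @param drop Character set of chromosome labels to remove.
#' @return The filtered [lnen_expr].
#' @export
filter_genes_by_chromosome <- function(expr, annotation = NULL,
                                       drop = c("X", "Y", "MT")) {
  stopifnot(inherits(expr, "lnen_expr"))
  chrom <- if (is.null(annotation)) {
    expr$gene_chrom
  } else if (inherits(annotation, "lnen_counts")) {
    annotation$gene_chrom
  } else annotation
  if (is.null(chrom)) {
    abort("No chromosome annotation available.", class = "lnen_preprocess_error")
  }
  missing <- setdiff(rownames(expr$values), names(chrom))
  if (length(missing) > 0L) {
    abort(sprintf("Genes missing from the annotation: %s.",
                  paste(head(missing, 5), collapse = ", ")),
          class = "lnen_preprocess_error")
  }
  keep <- !(chrom[rownames(expr$values)] %in% drop)
  if (sum(keep) < 2L) {
    abort("Fewer than 2 genes remain after chromosome filtering.",
          class = "lnen_preprocess_error")
  }
  lnen_expr(expr$values[keep, , drop = FALSE],
            size_factors = expr$size_factors,
            transform_tag = expr$transform_tag,
            gene_chrom = chrom[rownames(expr$values)][keep])
}

#' Select the genes explaining a fraction of total variance
#'
#' Ranks genes by decreasing per-sample variance of their (transformed)
#' expression and returns the shortest prefix whose cumulative variance
#' reaches `threshold` times the total variance. Ties are broken by input
#' gene order, so the selection is deterministic.
#'
#' @param expr An [lnen_expr] object with at least two samples.
#' @param threshold Fraction of total variance to cover, in `(0, 1]`;
#'   defaults to 0.5 (the genes explaining 50% of the total variance).
#' @return An object of class `variable_gene_set`: list with `gene_ids`
#'   (ordered by descending variance), `variances`, `variance_fraction_covered`
#'   and `threshold`.
#' @examples
#' # four genes with variances 4, 3, 2, 1 and threshold 0.5 keep the top two
#' @export
select_variable_genes <- function(expr, threshold = 0.5) {
  stopifnot(inherits(expr, "lnen_expr"))
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].", class = "lnen_preprocess_error")
  }
  m <- expr$values
  if (ncol(m) < 2L) abort("Need at least two samples.", class = "lnen_preprocess_error")
  v <- rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
  total <- sum(v)
  if (total == 0) abort("Total variance is zero.", class = "lnen_preprocess_error")
  ord <- order(-v, seq_along(v))
  n_sel <- which(cumsum(v[ord]) >= threshold * total)[1]
  if (is.na(n_sel)) n_sel <- length(v)   # guard against rounding at threshold 1
  sel <- ord[seq_len(n_sel)]
  structure(list(gene_ids = rownames(m)[sel],
                 variances = stats::setNames(v[sel], rownames(m)[sel]),
                 variance_fraction_covered = sum(v[sel]) / total,
                 threshold = threshold),
            class = "variable_gene_set")
}

#' @export
print.variable_gene_set <- function(x, ...) {
  cat(sprintf("<variable_gene_set> %d genes covering %.1f%% of total variance (threshold %.0f%%)\n",
              length(x$gene_ids), 100 * x$variance_fraction_covered, 100 * x$threshold))
  invisible(x)
}

# samples-by-genes matrix restricted to a gene set; the common embedding input
expr_points <- function(expr, gene_set = NULL) {
  genes <- if (is.null(gene_set)) rownames(expr$values) else gene_set$gene_ids
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing) > 0L) {
    abort(sprintf("Gene set refers to absent genes: %s.",
                  paste(head(missing, 5), collapse = ", ")),
          class = "lnen_preprocess_error")
  }
  t(expr$values[genes, , drop = FALSE])
}
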