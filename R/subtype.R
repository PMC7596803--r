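# Centroid-proximity subtype tests: does a focal sample group lie closer to
# one of two reference groups in the map?

#' Centroid of a sample group in an embedding
#'
#' @param embedding An `lnen_embedding` (or plain coordinate matrix with
#'   sample rownames).
#' @param sample_ids Non-empty character vector of sample ids.
#' @return Numeric vector: the dimension-wise arithmetic mean of the group's
#'   coordinates.
#' @export
group_centroid <- function(embedding, sample_ids) {
  m <- coords_of(embedding)
  if (length(sample_ids) == 0L) abort("Empty sample group.", class = "lnen_test_error")
  missing <- setdiff(sample_ids, rownames(m))
  if (length(missing) > 0L) {
    abort(sprintf("Samples absent from the embedding: %s.",
                  paste(head(missing, 5), collapse = ", ")),
          class = "lnen_test_error")
  }
  colMeans(m[sample_ids, , drop = FALSE])
}

#' Centroid-proximity test for a focal group against two references
#'
#' For each focal sample, computes its Euclidean distance to the centroid of
#' reference group A and to that of reference group B, then applies a
#' one-sided Wilcoxon signed-rank test to the paired distance differences to
#' decide whether the focal group lies closer to one of the two references.
#' This is the procedure used to check that samples with discordant
#' histological and molecular classifications (e.g. histological SCLCs with
#' an LCNEC molecular profile) cluster with their molecular group on the
#' map.
#'
#' Focal samples are removed from the reference groups before computing
#' centroids, avoiding self-attraction. Zero differences are dropped per the
#' standard signed-rank convention; if every difference is zero the result
#' is a tie with `p = 1`. With 5 or more focal samples of uniform sign the
#' exact one-sided p-value is `2^(-n)`.
#'
#' @param embedding An `lnen_embedding` or coordinate matrix; by convention
#'   the 2D map (a flag-free choice — pass the expression matrix's sample
#'   coordinates to test in the pre-embedding space).
#' @param focal_ids,ref_a_ids,ref_b_ids Sample-id vectors.
#' @param alternative `"closer_to_a"` (default), `"closer_to_b"` or
#'   `"two.sided"`.
#' @param labels Optional character vector of length 3 naming the focal and
#'   reference groups in the output.
#' @return An object of class `centroid_test`; `tidy()` renders it as a
#'   one-row tibble, and the per-sample distances are available in
#'   `$distances`.
#' @export
centroid_proximity_test <- function(embedding, focal_ids, ref_a_ids, ref_b_ids,
                                    alternative = c("closer_to_a", "closer_to_b",
                                                    "two.sided"),
                                    labels = c("focal", "ref_a", "ref_b")) {
  alternative <- match.arg(alternative)
  m <- coords_of(embedding)
  if (length(focal_ids) == 0L) abort("Empty focal group.", class = "lnen_test_error")
  ref_a_ids <- setdiff(ref_a_ids, focal_ids)
  ref_b_ids <- setdiff(ref_b_ids, focal_ids)
  if (length(ref_a_ids) == 0L || length(ref_b_ids) == 0L) {
    abort("A reference group is empty after excluding focal samples.",
          class = "lnen_test_error")
  }
  ca <- group_centroid(m, ref_a_ids)
  cb <- group_centroid(m, ref_b_ids)
  fm <- m[focal_ids, , drop = FALSE]
  d_a <- sqrt(rowSums(sweep(fm, 2, ca)^2))
  d_b <- sqrt(rowSums(sweep(fm, 2, cb)^2))
  diffs <- d_a - d_b
  n_eff <- sum(diffs != 0)
  if (length(focal_ids) < 5L) {
    warn("Fewer than 5 focal samples: the exact signed-rank test has little resolution.")
  }
  direction <- if (median(diffs) < 0) "closer_to_a" else if (median(diffs) > 0) "closer_to_b" else "tie"
  if (n_eff == 0L) {
    stat <- NA_real_; p <- 1; direction <- "tie"; tie <- TRUE
  } else {
    tie <- FALSE
    wt_alt <- switch(alternative, closer_to_a = "less", closer_to_b = "greater",
                     two.sided = "two.sided")
    wt <- suppressWarnings(wilcox.test(diffs[diffs != 0], mu = 0, alternative = wt_alt))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(focal_group = labels[1], ref_a = labels[2], ref_b = labels[3],
                 n_focal = length(focal_ids), n_effective = n_eff,
                 statistic = stat, p_value = p, direction = direction,
                 alternative = alternative, tie = tie,
                 distances = tibble::tibble(sample_id = focal_ids,
                                            dist_to_a = unname(d_a),
                                            dist_to_b = unname(d_b)),
                 embedding_tag = if (inherits(embedding, "lnen_embedding"))
                   embedding$method else "matrix"),
            class = "centroid_test")
}

#' @export
print.centroid_test <- function(x, ...) {
  cat(sprintf("<centroid_test> %s vs {%s, %s}: %s, p = %s (n = %d)\n",
              x$focal_group, x$ref_a, x$ref_b, x$direction, format(x$p_value),
              x$n_focal))
  invisible(x)
}

#' Tidy a centroid-proximity test
#'
#' @param x A `centroid_test`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy centroid_test
#' @export
tidy.centroid_test <- function(x, ...) {
  tibble::tibble(focal_group = x$focal_group, ref_a = x$ref_a, ref_b = x$ref_b,
                 n_focal = x$n_focal, statistic = x$statistic,
                 p.value = x$p_value, direction = x$direction,
                 alternative = x$alternative, tie = x$tie,
                 embedding = x$embedding_tag)
}

#' The map's standard subtype contrasts
#'
#' The five focal/reference triples used to validate a pan-LNEN map:
#' molecularly discordant SCLCs and LCNECs against both histologies, the two
#' LCNEC molecular types against each other and SCLC, discordant SCLCs
#' against the LCNEC types, and supra-carcinoids against LCNEC and SCLC.
#'
#' @return A tibble with columns `focal`, `ref_a`, `ref_b`, `alternative`.
#' @export
default_subtype_contrasts <- function() {
  tibble::tribble(
    ~focal,             ~ref_a,         ~ref_b,         ~alternative,
    "SCLC_LCNEC_like",  "LCNEC",        "SCLC",         "closer_to_a",
    "LCNEC_SCLC_like",  "SCLC",         "LCNEC",        "closer_to_a",
    "LCNEC_TypeI",      "LCNEC_TypeII", "SCLC",         "closer_to_a",
    "SCLC_LCNEC_like",  "LCNEC_TypeII", "LCNEC_TypeI",  "closer_to_a",
    "supra_carcinoid",  "LCNEC",        "SCLC",         "closer_to_a")
}

#' Run a suite of centroid-proximity tests
#'
#' Executes one [centroid_proximity_test()] per row of a contrast table,
#' resolving group labels against a sample attribute table. Contrasts whose
#' labels are absent from the attributes are skipped with a warning.
#'
#' @param embedding An `lnen_embedding` or coordinate matrix.
#' @param attributes Data frame with a `sample_id` column and the grouping
#'   column.
#' @param contrasts Tibble with columns `focal`, `ref_a`, `ref_b` and
#'   optionally `alternative`; defaults to [default_subtype_contrasts()].
#' @param group_col Name of the grouping column (default
#'   `"molecular_cluster"`).
#' @return A tibble with one tidy row per executed test.
#' @export
run_subtype_suite <- function(embedding, attributes,
                              contrasts = default_subtype_contrasts(),
                              group_col = "molecular_cluster") {
  contrasts <- tibble::as_tibble(contrasts)
  if (nrow(contrasts) == 0L) {
    return(tibble::tibble(focal_group = character(0), ref_a = character(0),
                          ref_b = character(0), n_focal = integer(0),
                          statistic = numeric(0), p.value = numeric(0),
                          direction = character(0), alternative = character(0),
                          tie = logical(0), embedding = character(0)))
  }
  if (!group_col %in% names(attributes)) {
    abort(sprintf("Attribute table lacks column '%s'.", group_col), class = "lnen_test_error")
  }
  labels <- as.character(attributes[[group_col]])
  ids <- as.character(attributes$sample_id)
  purrr::map_dfr(seq_len(nrow(contrasts)), function(i) {
    row <- contrasts[i, ]
    groups <- c(row$focal, row$ref_a, row$ref_b)
    absent <- groups[!groups %in% labels]
    if (length(absent) > 0L) {
      warn(sprintf("Skipping contrast %s vs {%s, %s}: missing label(s) %s.",
                   row$focal, row$ref_a, row$ref_b, paste(absent, collapse = ", ")))
      return(NULL)
    }
    alt <- if ("alternative" %in% names(row)) row$alternative else "closer_to_a"
    res <- centroid_proximity_test(embedding,
                                   focal_ids = ids[labels == row$focal],
                                   ref_a_ids = ids[labels == row$ref_a],
                                   ref_b_ids = ids[labels == row$ref_b],
                                   alternative = alt,
                                   labels = groups)
    tidy(res)
  })
}
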