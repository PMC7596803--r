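# ggplot2 figure methods for the QC result types.

#' Plot a scaled neighborhood-preservation profile
#'
#' Line chart of `SD'_k` against `k` with across-replicate error bars, the
#' standard way to compare how well embeddings preserve neighborhoods at
#' different scales relative to the PCA anchors (0 = PCA-5D, 1 = PCA-2D).
#'
#' @param object A `scaled_sd_profile`, or a list / row-bound tibble of
#'   several.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scaled_sd_profile
#' @export
autoplot.scaled_sd_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$method)) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "k (neighborhood size)",
                  y = expression("scaled " * bar(SD)[k] * "'"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.scaled_sd_profile
#' @method autoplot sd_profile
#' @export
autoplot.sd_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mean,
                                   colour = .data$method)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "k (neighborhood size)", y = expression(bar(SD)[k]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Moran-index top-N concordance curve
#'
#' Observed overlap proportions of the top-N Moran-ranked genes for each
#' space pair (and the triple intersection) against the hypergeometric null
#' expectation.
#'
#' @param object An `overlap_curve` from [rank_concordance()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_curve
#' @export
autoplot.overlap_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$N)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$overlap, colour = .data$comparison)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_expectation,
                                    linetype = "null (hypergeometric mean)"),
                       colour = "goldenrod") +
    ggplot2::labs(x = "N (top genes)", y = "overlap proportion",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2D embedding colored by group
#'
#' @param embedding A 2D `lnen_embedding`.
#' @param groups Optional per-sample labels (named by sample id or in
#'   embedding order).
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, groups = NULL) {
  stopifnot(inherits(embedding, "lnen_embedding"), embedding$d == 2L)
  df <- tibble::tibble(sample_id = embedding$sample_ids,
                       x = embedding$coords[, 1], y = embedding$coords[, 2])
  if (!is.null(groups)) {
    df$group <- if (!is.null(names(groups))) groups[df$sample_id] else groups
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = paste0(embedding$method, " 1"),
                  y = paste0(embedding$method, " 2"), colour = NULL) +
    ggplot2::theme_minimal()
}
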