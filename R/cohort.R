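# Synthetic cohort generator: negative-binomial counts with group-specific
# expression programs, library-size variation, planted discordant samples and
# sex/mitochondrial gene labels. Provides ground truth for every downstream
# stage of the mapping pipeline.

#' Configuration for a synthetic tumor cohort
#'
#' Describes a simulated bulk RNA-seq cohort with a fixed number of molecular
#' groups, group-specific expression programs, and optional "discordant"
#' samples whose expression interpolates between the program of their
#' histological group and that of a different molecular group — emulating
#' tumors whose histology and molecular profile disagree (e.g. histological
#' SCLCs with an LCNEC molecular profile).
#'
#' The default group sizes emulate a 238-sample pan-LNEN cohort split into six
#' molecular groups (SCLC, LCNEC Type I/II, Carcinoid A1/A2/B) of uneven
#' sizes, the smallest holding roughly 30 samples.
#'
#' @param n_genes Number of simulated genes.
#' @param group_sizes Named integer vector of samples per molecular group.
#' @param n_informative_genes Number of genes carrying a group-specific mean
#'   shift; distributed round-robin across groups among autosomal genes.
#' @param baseline_mean Expected count of a background gene at library-size
#'   factor 1.
#' @param log2_effect_size Log2 fold-change applied to an informative gene in
#'   the samples of its group.
#' @param dispersion Negative-binomial dispersion; the count variance is
#'   `mu + dispersion * mu^2`. `0` gives Poisson counts.
#' @param libsize_sigma Standard deviation (log scale) of the log-normal
#'   per-sample library-size factors; factors have expectation 1.
#' @param discordant Optional data frame with columns `histology`,
#'   `molecular`, `weight` (mixing weight in `[0, 1]`) and `n`: for each row,
#'   `n` samples of the `histology` group have mean expression
#'   `(1 - weight) * mu(histology) + weight * mu(molecular)` and carry the
#'   `molecular` label as their true molecular group.
#' @param frac_sex_genes,frac_mito_genes Fractions of genes labelled as sex
#'   chromosome (X/Y) or mitochondrial (MT) genes. These are ordinary
#'   background genes whose chromosome label exercises the preprocessing
#'   filter.
#' @param group_similarity Square similarity matrix over the groups (unit
#'   diagonal, entries in `[0, 1]`): an informative gene assigned to group
#'   `g` has mean `baseline_mean * 2^(log2_effect_size * S[g, h])` in
#'   samples of group `h`, so off-diagonal entries let expression programs
#'   be partially shared between related groups. The identity matrix gives
#'   fully group-private programs (equidistant clusters); the default
#'   ([default_group_similarity()]) encodes the published relationships
#'   between the six pan-LNEN groups, under which the groups form a
#'   continuum (a carcinoid block and a neuroendocrine-carcinoma block with
#'   the LCNEC types between SCLC and the carcinoids).
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate bit-identical cohorts.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_genes = 1000L,
                          group_sizes = c(SCLC = 51L, LCNEC_TypeI = 32L,
                                          LCNEC_TypeII = 37L, Carcinoid_A1 = 45L,
                                          Carcinoid_A2 = 40L, Carcinoid_B = 33L),
                          n_informative_genes = 300L,
                          baseline_mean = 100,
                          log2_effect_size = 1.2,
                          dispersion = 0.3,
                          libsize_sigma = 0.2,
                          discordant = default_discordant_spec(names(group_sizes)),
                          group_similarity = default_group_similarity(names(group_sizes)),
                          frac_sex_genes = 0.05,
                          frac_mito_genes = 0.01,
                          seed = 1L) {
  if (length(group_sizes) < 1L || any(group_sizes < 1L)) {
    abort("`group_sizes` must be positive integers.", class = "lnen_config_error")
  }
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  }
  if (sum(group_sizes) < 2L) {
    abort("A cohort needs at least 2 samples.", class = "lnen_config_error")
  }
  if (n_genes < 1L) abort("`n_genes` must be positive.", class = "lnen_config_error")
  if (n_informative_genes > n_genes) {
    abort("`n_informative_genes` cannot exceed `n_genes`.", class = "lnen_config_error")
  }
  if (baseline_mean <= 0) abort("`baseline_mean` must be positive.", class = "lnen_config_error")
  if (dispersion < 0) abort("`dispersion` must be non-negative.", class = "lnen_config_error")
  if (libsize_sigma < 0) abort("`libsize_sigma` must be non-negative.", class = "lnen_config_error")
  for (p in c(frac_sex_genes, frac_mito_genes)) {
    if (p < 0 || p > 1) abort("Gene-fraction parameters must lie in [0, 1].", class = "lnen_config_error")
  }
  if (!is.null(discordant)) {
    discordant <- tibble::as_tibble(discordant)
    needed <- c("histology", "molecular", "weight", "n")
    if (!all(needed %in% names(discordant))) {
      abort(paste0("`discordant` needs columns: ", paste(needed, collapse = ", ")),
            class = "lnen_config_error")
    }
    if (any(discordant$weight < 0 | discordant$weight > 1)) {
      abort("Discordant mixing weights must lie in [0, 1].", class = "lnen_config_error")
    }
    bad <- setdiff(c(discordant$histology, discordant$molecular), names(group_sizes))
    if (length(bad) > 0L) {
      abort(paste0("Unknown group labels in `discordant`: ", paste(bad, collapse = ", ")),
            class = "lnen_config_error")
    }
  }
  ng <- length(group_sizes)
  if (is.null(group_similarity)) group_similarity <- diag(ng)
  group_similarity <- as.matrix(group_similarity)
  if (!identical(dim(group_similarity), c(ng, ng)) ||
      any(diag(group_similarity) != 1) ||
      any(group_similarity < 0 | group_similarity > 1)) {
    abort("`group_similarity` must be a square matrix over the groups with unit diagonal and entries in [0, 1].",
          class = "lnen_config_error")
  }
  dimnames(group_similarity) <- list(names(group_sizes), names(group_sizes))
  structure(list(n_genes = as.integer(n_genes),
                 group_sizes = stats::setNames(as.integer(group_sizes), names(group_sizes)),
                 n_informative_genes = as.integer(n_informative_genes),
                 baseline_mean = baseline_mean,
                 log2_effect_size = log2_effect_size,
                 dispersion = dispersion,
                 libsize_sigma = libsize_sigma,
                 discordant = discordant,
                 group_similarity = group_similarity,
                 frac_sex_genes = frac_sex_genes,
                 frac_mito_genes = frac_mito_genes,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default group-similarity matrix for the six pan-LNEN groups
#'
#' Encodes the published relationships between the molecular groups as
#' expression-program similarities: the two LCNEC types are close to each
#' other and to SCLC (Type II closer to SCLC than Type I), the three
#' carcinoid clusters form their own block, and Carcinoid B sits nearest the
#' LCNECs (the supra-carcinoid side of the map). Under this matrix the six
#' groups form a continuum with two super-clusters rather than equidistant
#' islands, which is the geometry the real pan-LNEN map displays.
#'
#' @param group_names Group names; the pan-LNEN matrix is returned when they
#'   are the six default groups, otherwise the identity (fully group-private
#'   programs).
#' @return A named square matrix.
#' @export
default_group_similarity <- function(group_names) {
  lnen <- c("SCLC", "LCNEC_TypeI", "LCNEC_TypeII",
            "Carcinoid_A1", "Carcinoid_A2", "Carcinoid_B")
  if (is.null(group_names) || !setequal(group_names, lnen) ||
      length(group_names) != 6L) {
    n <- max(length(group_names), 1L)
    S <- diag(n)
    dimnames(S) <- list(group_names, group_names)
    return(S)
  }
  S <- matrix(c(
    1.00, 0.35, 0.60, 0.05, 0.05, 0.05,
    0.35, 1.00, 0.50, 0.05, 0.05, 0.20,
    0.60, 0.50, 1.00, 0.05, 0.05, 0.20,
    0.05, 0.05, 0.05, 1.00, 0.45, 0.30,
    0.05, 0.05, 0.05, 0.45, 1.00, 0.40,
    0.05, 0.20, 0.20, 0.30, 0.40, 1.00), 6, 6,
    dimnames = list(lnen, lnen))
  S[group_names, group_names]
}

#' Default discordant-sample specification
#'
#' The minority of samples whose histology and molecular profile disagree,
#' mirroring the discordant entities described for lung neuroendocrine
#' neoplasms: histological SCLCs with an LCNEC molecular profile, LCNECs
#' with an SCLC profile, and carcinoid-morphology tumors with LCNEC-like
#' molecular features (supra-carcinoids). Empty for non-default group
#' names.
#'
#' @param group_names Group names of the cohort.
#' @return A tibble with columns `histology`, `molecular`, `weight`, `n`
#'   (or `NULL` when the groups are not the six pan-LNEN defaults).
#' @export
default_discordant_spec <- function(group_names) {
  needed <- c("SCLC", "LCNEC_TypeII", "Carcinoid_B")
  if (is.null(group_names) || !all(needed %in% group_names)) return(NULL)
  tibble::tribble(
    ~histology,      ~molecular,      ~weight, ~n,
    "SCLC",          "LCNEC_TypeII",  0.8,     6L,
    "LCNEC_TypeII",  "SCLC",          0.8,     5L,
    "Carcinoid_B",   "LCNEC_TypeII",  0.8,     3L)
}

# Sub-seed derivation: one global seed drives an independent stream per stage
# (and per gene for the count stage), so adding genes or changing the library
# stage never reshuffles the others. Kept below 2^31 - 1.
derive_seed <- function(seed, stage, unit = 0L) {
  (as.double(seed) * 48271 + stage * 1299709 + unit * 7919) %% 2147483647
}

#' Generate a synthetic cohort
#'
#' Draws a gene-by-sample count matrix from the model described in
#' [cohort_config()]: gene `g` in sample `s` is negative-binomial with mean
#' `libsize_s * baseline_mean * 2^(log2_effect_size)` if `g` is informative
#' for the group of `s` and `libsize_s * baseline_mean` otherwise; discordant
#' samples mix the mean-expression profiles of their histological and
#' molecular groups.
#'
#' @param config A [cohort_config()].
#' @return An object of class `lnen_cohort`: a list with elements `counts`
#'   (an [lnen_counts] matrix container with chromosome labels), `true_group`
#'   and `histology` (per-sample factors), `discordant_ids` (character),
#'   `gene_roles` (per-gene role: `background`, `sex`, `mito` or
#'   `informative:<group>`), `libsize` and `mu` (the expected count matrix,
#'   library factors included) and the `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_genes = 50,
#'   group_sizes = c(A = 10, B = 10), seed = 1))
#' table(cohort$true_group)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$group_sizes)
  n <- sum(config$group_sizes)
  G <- config$n_genes
  histology <- factor(rep(groups, config$group_sizes), levels = groups)
  sample_ids <- sprintf("S%03d", seq_len(n))

  # Gene roles and chromosome labels are assigned deterministically: the
  # trailing genes carry the sex/mito labels, informative genes fill the
  # leading autosomal slots round-robin across groups.
  n_sex <- round(config$frac_sex_genes * G)
  n_mito <- round(config$frac_mito_genes * G)
  if (config$n_informative_genes > G - n_sex - n_mito) {
    abort("Not enough autosomal genes for the requested informative genes.",
          class = "lnen_config_error")
  }
  gene_ids <- sprintf("gene%04d", seq_len(G))
  roles <- rep("background", G)
  chrom <- as.character(rep_len(1:22, G))
  if (n_mito > 0) {
    idx <- seq.int(G - n_mito + 1L, G)
    roles[idx] <- "mito"; chrom[idx] <- "MT"
  }
  if (n_sex > 0) {
    idx <- seq.int(G - n_mito - n_sex + 1L, G - n_mito)
    roles[idx] <- "sex"; chrom[idx] <- rep_len(c("X", "Y"), n_sex)
  }
  if (config$n_informative_genes > 0) {
    idx <- seq_len(config$n_informative_genes)
    roles[idx] <- paste0("informative:", rep_len(groups, config$n_informative_genes))
  }

  # Per-group mean-expression profiles (at library factor 1): an informative
  # gene assigned to group g is raised in group h by the similarity-weighted
  # effect 2^(log2_effect_size * S[g, h]); with the identity similarity this
  # is the plain group-private program.
  profiles <- matrix(config$baseline_mean, nrow = G, ncol = length(groups),
                     dimnames = list(gene_ids, groups))
  S <- config$group_similarity
  for (g in seq_along(groups)) {
    inf_g <- roles == paste0("informative:", groups[g])
    if (any(inf_g)) {
      profiles[inf_g, ] <- rep(config$baseline_mean *
                                 2^(config$log2_effect_size * S[groups[g], ]),
                               each = sum(inf_g))
    }
  }

  # Sample-level truth: discordant rows convert the first free samples of
  # their histology group.
  true_group <- histology
  disc_ids <- character(0)
  mu <- profiles[, as.character(histology), drop = FALSE]
  dimnames(mu) <- list(gene_ids, sample_ids)
  if (!is.null(config$discordant)) {
    taken <- logical(n)
    for (r in seq_len(nrow(config$discordant))) {
      row <- config$discordant[r, ]
      pool <- which(histology == row$histology & !taken)
      if (length(pool) < row$n) {
        abort(sprintf("Group '%s' has too few samples for its discordant spec.",
                      row$histology), class = "lnen_config_error")
      }
      sel <- pool[seq_len(row$n)]
      taken[sel] <- TRUE
      true_group[sel] <- factor(row$molecular, levels = groups)
      mu[, sel] <- (1 - row$weight) * profiles[, as.character(row$histology)] +
        row$weight * profiles[, as.character(row$molecular)]
      disc_ids <- c(disc_ids, sample_ids[sel])
    }
  }

  # Library-size factors: log-normal with expectation 1.
  set.seed(derive_seed(config$seed, stage = 1L))
  libsize <- if (config$libsize_sigma > 0) {
    exp(rnorm(n, mean = -config$libsize_sigma^2 / 2, sd = config$libsize_sigma))
  } else rep(1, n)

  # Counts, one RNG stream per gene.
  counts <- matrix(0L, nrow = G, ncol = n, dimnames = list(gene_ids, sample_ids))
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  for (g in seq_len(G)) {
    set.seed(derive_seed(config$seed, stage = 2L, unit = g))
    m <- mu[g, ] * libsize
    counts[g, ] <- if (is.finite(size)) rnbinom(n, size = size, mu = m) else rpois(n, m)
  }

  structure(list(counts = lnen_counts(counts, gene_chrom = chrom),
                 true_group = true_group,
                 histology = histology,
                 discordant_ids = disc_ids,
                 gene_roles = roles,
                 libsize = stats::setNames(libsize, sample_ids),
                 mu = sweep(mu, 2, libsize, "*"),
                 config = config),
            class = "lnen_cohort")
}

#' @export
print.lnen_cohort <- function(x, ...) {
  cat(sprintf("<lnen_cohort> %d genes x %d samples, %d groups, %d discordant\n",
              nrow(x$counts$values), ncol(x$counts$values),
              nlevels(x$true_group), length(x$discordant_ids)))
  invisible(x)
}

#' Per-gene moment estimates of a simulated cohort
#'
#' Returns the per-gene empirical mean and variance of the simulated counts,
#' used to verify the negative-binomial mean-variance relationship
#' `var = mu + dispersion * mu^2`.
#'
#' @param cohort An [generate_cohort()] result.
#' @return A tibble with columns `gene_id`, `mean`, `variance` and
#'   `dispersion_hat` (`(variance - mean) / mean^2`). With fewer than two
#'   samples the variance is undefined and a zero-row tibble is returned with
#'   a warning.
#' @export
empirical_dispersion_check <- function(cohort) {
  stopifnot(inherits(cohort, "lnen_cohort"))
  m <- cohort$counts$values
  if (ncol(m) < 2L) {
    warn("Variance undefined with a single sample; returning no rows.")
    return(tibble::tibble(gene_id = character(0), mean = numeric(0),
                          variance = numeric(0), dispersion_hat = numeric(0)))
  }
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (ncol(m) - 1)
  tibble::tibble(gene_id = rownames(m), mean = mu, variance = v,
                 dispersion_hat = (v - mu) / mu^2)
}
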