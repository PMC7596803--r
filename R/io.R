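# Readers and writers: counts (TSV / MatrixMarket), gene annotation, sample
# attributes, embeddings, and TumorMap-compatible layout/attribute exports.
# All writers are deterministic (no timestamps inside data files); run
# provenance lives in a separate sidecar.

#' Read a count matrix
#'
#' TSV dialect: first column gene id, header row of sample ids,
#' tab-separated. MatrixMarket dialect: a `.mtx` file with companion
#' plain-text gene and sample id files (one id per line).
#'
#' @param path Path to the TSV or MatrixMarket file.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @param gene_file,sample_file Companion id files (MatrixMarket only).
#' @param annotation Optional path to a gene annotation TSV (columns
#'   `gene_id`, `chromosome`) or a data frame; attaches chromosome labels.
#' @return An [lnen_counts] object.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        gene_file = NULL, sample_file = NULL,
                        annotation = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          name_repair = "minimal")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      abort("Count columns must be numeric.", class = "lnen_io_error")
    }
    rownames(m) <- genes
  } else {
    if (is.null(gene_file) || is.null(sample_file)) {
      abort("MatrixMarket input needs `gene_file` and `sample_file`.",
            class = "lnen_io_error")
    }
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      abort("MatrixMarket input needs the Matrix package.", class = "lnen_io_error")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gene_file)
    colnames(m) <- readLines(sample_file)
  }
  if (anyNA(m)) abort("Count matrix contains missing values (ragged rows?).",
                      class = "lnen_io_error")
  chrom <- NULL
  if (!is.null(annotation)) {
    ann <- if (is.character(annotation)) read_gene_annotation(annotation) else
      tibble::as_tibble(annotation)
    missing <- setdiff(rownames(m), ann$gene_id)
    if (length(missing) > 0L) {
      abort(sprintf("Annotation lacks gene(s): %s.",
                    paste(head(missing, 5), collapse = ", ")),
            class = "lnen_io_error")
    }
    chrom <- ann$chromosome[match(rownames(m), ann$gene_id)]
  }
  lnen_counts(m, gene_chrom = chrom)
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id` and `chromosome`.
#' @return Tibble with those columns.
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene_id", "chromosome") %in% names(ann))) {
    abort("Annotation needs columns `gene_id` and `chromosome`.", class = "lnen_io_error")
  }
  ann
}

#' Read a sample attribute table
#'
#' @param path TSV with header; first column must be `sample_id`.
#' @return Tibble; duplicate sample ids are rejected.
#' @export
read_attributes <- function(path) {
  at <- readr::read_tsv(path, col_types = readr::cols())
  if (names(at)[1] != "sample_id") {
    abort("First attribute column must be `sample_id`.", class = "lnen_io_error")
  }
  if (anyDuplicated(at$sample_id)) {
    abort("Duplicate sample ids in the attribute table.", class = "lnen_io_error")
  }
  at
}

#' Write a count matrix as TSV
#'
#' @param counts An [lnen_counts] object.
#' @param path Output path (first column `gene_id`, then one column per
#'   sample).
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "lnen_counts"))
  df <- tibble::as_tibble(counts$values, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param expr An [lnen_expr] object.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "lnen_expr"))
  readr::write_tsv(tibble::as_tibble(expr$values, rownames = "gene_id"), path)
  invisible(path)
}

#' Write an embedding with a parameter sidecar
#'
#' Emits a TSV (`sample_id`, `dim_1`..`dim_d`) plus a plain-text key-value
#' sidecar (`<path>.params`) with the method and every effective parameter.
#'
#' @param embedding An `lnen_embedding`.
#' @param path Output path for the coordinate TSV.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "lnen_embedding"))
  co <- embedding$coords
  colnames(co) <- paste0("dim_", seq_len(ncol(co)))
  readr::write_tsv(tibble::as_tibble(co, rownames = "sample_id"), path)
  params <- c(method = embedding$method, d = embedding$d,
              source = embedding$source_tag,
              unlist(lapply(embedding$params, paste, collapse = ",")))
  writeLines(paste(names(params), params, sep = "="), paste0(path, ".params"))
  invisible(path)
}

#' Export a 2D map in TumorMap-compatible form
#'
#' Writes the layout file (tab-separated `sample_id  x  y`, coordinates with
#' six decimal places, headerless by default as the portal's coordinate
#' upload expects) and the attribute file (tab-separated with header, first
#' column `sample_id`), both restricted to the embedding's samples in
#' embedding order. Attribute rows for samples absent from the embedding are
#' dropped with a warning.
#'
#' @param embedding A 2D `lnen_embedding`.
#' @param attributes Data frame with `sample_id` first; `NULL` skips the
#'   attribute file.
#' @param outdir Output directory (created if needed).
#' @param header Write a header line on the layout file (default `FALSE`).
#' @return Invisibly, the paths written.
#' @export
write_tumormap <- function(embedding, attributes = NULL, outdir,
                           header = FALSE) {
  stopifnot(inherits(embedding, "lnen_embedding"))
  if (embedding$d != 2L) abort("TumorMap layouts are 2D.", class = "lnen_io_error")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  layout_path <- file.path(outdir, "tumormap_layout.tsv")
  lines <- sprintf("%s\t%.6f\t%.6f", embedding$sample_ids,
                   embedding$coords[, 1], embedding$coords[, 2])
  if (header) lines <- c("sample_id\tx\ty", lines)
  writeLines(lines, layout_path, sep = "\n")
  paths <- layout_path
  if (!is.null(attributes)) {
    attributes <- tibble::as_tibble(attributes)
    extra <- setdiff(attributes$sample_id, embedding$sample_ids)
    if (length(extra) > 0L) {
      warn(sprintf("Dropping %d attribute row(s) without map coordinates: %s.",
                   length(extra), paste(head(extra, 5), collapse = ", ")))
    }
    at <- attributes[match(embedding$sample_ids, attributes$sample_id), , drop = FALSE]
    at$sample_id <- embedding$sample_ids
    attr_path <- file.path(outdir, "tumormap_attributes.tsv")
    readr::write_tsv(at, attr_path)
    paths <- c(paths, attr_path)
  }
  invisible(paths)
}

#' Write a cohort to disk
#'
#' Emits the counts TSV, the gene annotation TSV (`gene_id`, `chromosome`,
#' `role`) and the sample attribute TSV (`sample_id`, `histology`,
#' `molecular_cluster`, `discordant`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "lnen_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(outdir, "counts.tsv")
  write_counts(cohort$counts, counts_path)
  ann_path <- file.path(outdir, "gene_annotation.tsv")
  readr::write_tsv(tibble::tibble(gene_id = rownames(cohort$counts$values),
                                  chromosome = unname(cohort$counts$gene_chrom),
                                  role = cohort$gene_roles), ann_path)
  attr_path <- file.path(outdir, "sample_attributes.tsv")
  readr::write_tsv(tibble::tibble(sample_id = colnames(cohort$counts$values),
                                  histology = as.character(cohort$histology),
                                  molecular_cluster = as.character(cohort$true_group),
                                  discordant = colnames(cohort$counts$values) %in%
                                    cohort$discordant_ids), attr_path)
  invisible(c(counts_path, ann_path, attr_path))
}

#' Read / write a plain-text key-value configuration
#'
#' One `key=value` pair per line; `#` starts a comment. Comma-separated
#' values parse to vectors, numbers to numerics.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) {
    abort(sprintf("Malformed config line: '%s'.", lines[bad][1]), class = "lnen_io_error")
  }
  vals <- lapply(kv, function(p) {
    v <- strsplit(paste(p[-1], collapse = "="), ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  stats::setNames(vals, trimws(vapply(kv, `[[`, "", 1)))
}

#' @rdname read_config
#' @param config Named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  writeLines(paste0(names(config), "=",
                    vapply(config, paste, "", collapse = ",")), path)
  invisible(path)
}
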