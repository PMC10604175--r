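infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a labeled expression matrix from delimited text
#'
#' Expects a header row and identifiers in the first column: sample ids with
#' samples in rows (the default), or gene ids with `genes_in_rows = TRUE`
#' (the matrix is transposed on read). CSV vs TSV is auto-detected from the
#' file extension. Labels come either from a separate two-column file
#' (sample id, class) or from a designated column of the expression file.
#'
#' @param path Path to the expression matrix (TSV, or CSV by `.csv`
#'   extension).
#' @param labels_path Optional path to a two-column label file with header.
#' @param label_col Optional name of a label column inside the expression
#'   file (removed from the matrix).
#' @param genes_in_rows Matrix is genes x samples on disk (default `FALSE`).
#' @return A validated [labeled_expression].
#' @export
read_expression <- function(path, labels_path = NULL, label_col = NULL,
                            genes_in_rows = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  row_ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  # data.frame subsetting silently uniquifies duplicated header names;
  # restore the on-disk header so duplicate gene ids are caught downstream
  colnames(body) <- colnames(raw)[-1]

  labels <- NULL
  if (!is.null(label_col)) {
    if (genes_in_rows) {
      stop("`label_col` cannot be combined with `genes_in_rows`; supply a ",
           "separate label file", call. = FALSE)
    }
    if (!label_col %in% colnames(body)) {
      stop("label column '", label_col, "' not found", call. = FALSE)
    }
    labels <- body[[label_col]]
    body <- body[, setdiff(colnames(body), label_col), drop = FALSE]
  }

  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow = nrow(body))
  )
  bad <- which(is.na(num) & !is.na(as.matrix(body)) | is.na(as.matrix(body)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad[1, 1], colnames(body)[bad[1, 2]]), call. = FALSE)
  }

  if (genes_in_rows) {
    values <- t(num)
    gene_ids <- row_ids
    sample_ids <- colnames(body)
  } else {
    values <- num
    gene_ids <- colnames(body)
    sample_ids <- row_ids
  }

  if (is.null(labels)) {
    if (is.null(labels_path)) {
      stop("labels are required: supply `labels_path` or `label_col`",
           call. = FALSE)
    }
    lab <- utils::read.table(labels_path, header = TRUE,
                             sep = infer_sep(labels_path),
                             check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character", comment.char = "")
    m <- match(sample_ids, lab[[1]])
    if (anyNA(m)) {
      stop("label missing for sample(s): ",
           paste(sample_ids[is.na(m)], collapse = ", "), call. = FALSE)
    }
    labels <- lab[[2]][m]
  }

  labeled_expression(values, sample_ids, gene_ids, labels)
}

#' Write a labeled expression matrix as TSV
#'
#' Writes the matrix (samples in rows, `sample` id column first) and the
#' labels (two-column `sample`/`class` file); both round-trip through
#' [read_expression()].
#'
#' @param data A [labeled_expression].
#' @param data_path Output path for the matrix TSV.
#' @param labels_path Output path for the label TSV.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(data, data_path, labels_path) {
  df <- data.frame(sample = data$sample_ids,
                   as.data.frame(data$values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, data_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample = data$sample_ids,
                    class = as.character(data$labels))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(data_path, labels_path))
}

#' Write the run report of an optimization
#'
#' Emits three files into `outdir`: `selected_genes.tsv` (gene id and its
#' position in the bit vector), `trace.csv` (iteration, best kappa, best
#' accuracy, selected count; one row per recorded state, iterations 0..T),
#' and `manifest.json` (algorithm, configuration, seed, evaluation count,
#' selected genes, package and R versions).
#'
#' @param record A `run_record` from [run_pilc_bscso()] or [run_bscso()].
#' @param outdir Output directory, created if needed.
#' @param gene_ids Gene identifiers matching the optimizer's feature space
#'   (i.e. the post-prefilter columns).
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(record, outdir, gene_ids) {
  if (length(gene_ids) != length(record$best_bits)) {
    stop("`gene_ids` length must match the optimized feature space",
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)

  sel <- which(record$best_bits == 1L)
  genes_path <- file.path(outdir, "selected_genes.tsv")
  utils::write.table(
    data.frame(gene = gene_ids[sel], rank = sel),
    genes_path, sep = "\t", quote = FALSE, row.names = FALSE
  )

  trace_path <- file.path(outdir, "trace.csv")
  utils::write.csv(record$trace, trace_path, row.names = FALSE, quote = FALSE)

  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- list(
    algorithm = record$algorithm,
    seed = record$seed,
    evaluations = record$evaluations,
    config = unclass(record$config),
    n_selected = record$best_fitness$n_selected,
    best_kappa = record$best_fitness$kappa,
    best_accuracy = record$best_fitness$accuracy,
    selected_genes = as.character(gene_ids[sel]),
    package_version = as.character(utils::packageVersion("pilcbscso")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(c(genes_path, trace_path, manifest_path))
}
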