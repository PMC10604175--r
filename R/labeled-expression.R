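#' Labeled expression matrix
#'
#' The central data container: a samples x genes numeric matrix together with
#' sample identifiers, gene identifiers and a two-class label per sample.
#' Labels may be any two distinct strings; the alphabetically first label is
#' mapped to the negative class, so fold changes and SVM decision values have
#' a deterministic sign regardless of input order.
#'
#' @param values Numeric matrix, samples in rows, genes in columns.
#' @param sample_ids Character vector of sample identifiers (one per row).
#' @param gene_ids Character vector of unique gene identifiers (one per
#'   column).
#' @param labels Vector of class labels, one per sample, with exactly two
#'   distinct values.
#' @return An object of class `labeled_expression`: a list with elements
#'   `values`, `sample_ids`, `gene_ids` and `labels` (a factor with sorted
#'   levels).
#' @examples
#' x <- matrix(rnorm(12), nrow = 3)
#' labeled_expression(x, paste0("s", 1:3), paste0("g", 1:4),
#'                    c("tumor", "normal", "tumor"))
#' @export
labeled_expression <- function(values, sample_ids, gene_ids, labels) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(sample_ids)) {
    stop("row count does not match the number of sample ids", call. = FALSE)
  }
  if (ncol(values) != length(gene_ids)) {
    stop("column count does not match the number of gene ids", call. = FALSE)
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("duplicated gene ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("one label per sample is required", call. = FALSE)
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) {
    stop("exactly two distinct class labels are required, got ",
         length(lv), call. = FALSE)
  }
  labels <- factor(as.character(labels), levels = lv)
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, sample_ids = sample_ids,
         gene_ids = gene_ids, labels = labels),
    class = "labeled_expression"
  )
}

#' @export
print.labeled_expression <- function(x, ...) {
  cat(sprintf("labeled_expression: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  cat("classes: ",
      paste(sprintf("%s (n=%d)", levels(x$labels), table(x$labels)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_expression <- function(x) dim(x$values)

# Column subset preserving the labeled_expression contract.
subset_genes <- function(data, idx) {
  labeled_expression(data$values[, idx, drop = FALSE], data$sample_ids,
                     data$gene_ids[idx], data$labels)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps CV fold construction and data
# generation from consuming draws that belong to the optimizer.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
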