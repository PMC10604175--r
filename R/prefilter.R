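#' Z-score normalize each gene
#'
#' Centers and scales every gene column to sample mean 0 and sample standard
#' deviation 1. Zero-variance genes cannot be scaled; their columns are set
#' to all zeros and their indices recorded in the `zero_variance` attribute
#' instead of raising an error, so a single flat probe does not abort a run.
#'
#' @param data A [labeled_expression].
#' @return A [labeled_expression] with normalized values and an integer
#'   attribute `zero_variance` listing flagged gene columns.
#' @export
zscore_normalize <- function(data) {
  x <- data$values
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  flat <- which(sdv == 0 | is.na(sdv))
  sdv[flat] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  z[, flat] <- 0
  out <- labeled_expression(z, data$sample_ids, data$gene_ids, data$labels)
  attr(out, "zero_variance") <- as.integer(flat)
  out
}

#' Per-gene two-group differential expression
#'
#' Welch two-sample t-test per gene on (assumed log-scale) expression, with
#' Benjamini-Hochberg adjustment across genes. The log2 fold-change is the
#' difference of group means (second minus first sorted class label), which
#' equals the log-ratio on log-scale data. Genes with zero variance in both
#' groups get `t = 0`, `p = 1` rather than failing.
#'
#' The test is vectorized over genes; statistics and p-values match
#' `stats::t.test(..., var.equal = FALSE)` gene by gene.
#'
#' @param data A [labeled_expression] with at least two samples per class.
#' @return A `data.frame` ("DE table") with one row per gene: `gene_id`,
#'   `mean_diff`, `logfc`, `t_stat`, `p_value`, `adj_p`.
#' @export
differential_expression <- function(data) {
  labels <- data$labels
  cnt <- table(labels)
  if (any(cnt < 2)) {
    stop("each class needs at least 2 samples for the Welch test",
         call. = FALSE)
  }
  g1 <- data$values[labels == levels(labels)[1], , drop = FALSE]
  g2 <- data$values[labels == levels(labels)[2], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- !is.finite(tt)
  tt[degenerate] <- 0
  p[degenerate] <- 1
  data.frame(gene_id = data$gene_ids,
             mean_diff = m2 - m1,
             logfc = m2 - m1,
             t_stat = tt,
             p_value = p,
             adj_p = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter differentially expressed genes
#'
#' Keeps genes with BH-adjusted p below `alpha` and, when `logfc_min` is
#' given, absolute log2 fold-change above it. Original gene order is
#' preserved. An empty result warns and returns an empty index set; the
#' caller decides whether to proceed unfiltered.
#'
#' @param table DE table from [differential_expression()].
#' @param alpha Significance level on the adjusted p-value, in (0, 1).
#'   Default 0.05.
#' @param logfc_min Optional absolute log2 fold-change gate (strict `>`).
#' @return Integer vector of surviving gene indices.
#' @export
filter_degs <- function(table, alpha = 0.05, logfc_min = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  keep <- if (alpha >= 1) rep(TRUE, nrow(table)) else table$adj_p < alpha
  if (!is.null(logfc_min)) keep <- keep & abs(table$logfc) > logfc_min
  idx <- which(keep)
  if (length(idx) == 0) {
    warning("no genes pass the differential-expression filter", call. = FALSE)
  }
  idx
}
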