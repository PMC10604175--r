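#' Specification for a synthetic expression matrix
#'
#' Describes a two-class matrix in the mold of the classic microarray
#' benchmarks: a few dozen samples, hundreds of genes, unbalanced classes,
#' and a small planted set of differentially expressed genes carrying an
#' additive mean-shift signal in Gaussian noise. The defaults (60 samples,
#' 500 genes, 10 informative, effect size 2 sd, 65% in the majority class)
#' echo a 40/22-style colon-cancer design at desk scale.
#'
#' @param n_samples Number of samples. Default 60.
#' @param n_genes Number of genes. Default 500.
#' @param n_informative Number of planted differentially expressed genes.
#'   Default 10.
#' @param effect_size Between-class mean shift of each planted gene, in
#'   units of `noise_sd`. Default 2.
#' @param class_balance Proportion of samples in the majority ("tumor")
#'   class, in (0, 1). Default 0.65.
#' @param noise_sd Gaussian noise standard deviation. Default 1.
#' @param seed Integer seed. Default 1.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 60, n_genes = 500, n_informative = 10,
                           effect_size = 2, class_balance = 0.65,
                           noise_sd = 1, seed = 1) {
  stopifnot(n_samples >= 4, n_genes >= 1, n_informative >= 0,
            n_informative <= n_genes, class_balance > 0, class_balance < 1,
            noise_sd > 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 class_balance = class_balance,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled expression matrix with planted signal
#'
#' All genes are drawn i.i.d. Gaussian with standard deviation
#' `spec$noise_sd`; the planted genes additionally receive an additive shift
#' of `effect_size * noise_sd` in the tumor class. The signal is additive
#' (not multiplicative) because downstream stages assume roughly log-scale
#' intensities, on which biological fold changes act additively. Class sizes
#' follow `class_balance` exactly (majority count = `round(n * balance)`).
#' Reproducible from `spec$seed`; the caller's RNG stream is untouched.
#'
#' @param spec A [synthetic_spec].
#' @return A `synthetic_truth` list: `data` (a [labeled_expression]),
#'   `planted` (sorted indices of the informative genes), `spec`.
#' @export
make_synthetic_expression <- function(spec = synthetic_spec()) {
  n <- spec$n_samples
  n_tumor <- round(n * spec$class_balance)
  n_normal <- n - n_tumor
  if (n_tumor < 2 || n_normal < 2) {
    stop("infeasible spec: each class needs at least 2 samples",
         call. = FALSE)
  }
  with_preserved_seed(spec$seed, {
    labels <- c(rep("tumor", n_tumor), rep("normal", n_normal))
    x <- matrix(stats::rnorm(n * spec$n_genes, sd = spec$noise_sd),
                nrow = n, ncol = spec$n_genes)
    planted <- sort(sample.int(spec$n_genes, spec$n_informative))
    shift <- spec$effect_size * spec$noise_sd
    x[labels == "tumor", planted] <- x[labels == "tumor", planted] + shift
    data <- labeled_expression(
      x,
      sample_ids = sprintf("s%03d", seq_len(n)),
      gene_ids = sprintf("g%04d", seq_len(spec$n_genes)),
      labels = labels
    )
    structure(list(data = data, planted = planted, spec = spec),
              class = "synthetic_truth")
  })
}

#' Recall and precision of a selected gene set against the planted truth
#'
#' @param selected Integer indices of the selected genes.
#' @param truth A `synthetic_truth` (or a plain integer vector of planted
#'   indices).
#' @return List with `recall` (selected planted / planted) and `precision`
#'   (selected planted / selected; 0 for an empty selection).
#' @export
recovery_metrics <- function(selected, truth) {
  planted <- if (inherits(truth, "synthetic_truth")) truth$planted else truth
  hit <- length(intersect(selected, planted))
  recall <- if (length(planted) == 0) 1 else hit / length(planted)
  precision <- if (length(selected) == 0) 0 else hit / length(selected)
  list(recall = recall, precision = precision)
}
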