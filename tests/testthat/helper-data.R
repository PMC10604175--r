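# Small fixtures shared across test files. Everything is generated in code;
# no data files on disk.

# A tiny, strongly-separated two-class dataset: gene 1 carries the signal,
# the rest are noise. Small enough for fast SVM cross-validation.
tiny_separable_data <- function(n_per_class = 12, n_noise = 4, gap = 6,
                                seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("caseA", "caseB"), each = n_per_class)
  signal <- ifelse(labels == "caseB", gap / 2, -gap / 2) + rnorm(n, sd = 0.3)
  noise <- matrix(rnorm(n * n_noise), nrow = n)
  labeled_expression(cbind(signal, noise),
                     sample_ids = sprintf("s%02d", seq_len(n)),
                     gene_ids = sprintf("g%d", seq_len(n_noise + 1)),
                     labels = labels)
}

fast_cv <- function(seed = 1) {
  cv_config(n_folds = 3, n_repeats = 1, seed = seed)
}

fast_cfg <- function(pop_size = 6, max_iter = 3, ...) {
  pilc_config(pop_size = pop_size, max_iter = max_iter,
              n_folds = 3, n_repeats = 1, ...)
}

# Independent brute-force kappa from the raw contingency counts.
kappa_bruteforce <- function(y_true, y_pred) {
  lv <- sort(unique(c(y_true, y_pred)))
  n <- length(y_true)
  conf <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(n)) {
    conf[y_true[i], y_pred[i]] <- conf[y_true[i], y_pred[i]] + 1
  }
  p_o <- sum(diag(conf)) / n
  p_e <- sum((rowSums(conf) / n) * (colSums(conf) / n))
  if (p_e == 1) return(0)
  (p_o - p_e) / (1 - p_e)
}

# Independent brute-force Benjamini-Hochberg step-up.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
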