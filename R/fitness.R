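#' Cohen's kappa between two label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, where `p_o` is the
#' observed agreement and `p_e` the agreement expected from the marginal
#' label frequencies. Kappa is preferred over raw accuracy as a fitness
#' signal on unbalanced two-class data because always predicting the
#' majority class scores 0, not the majority proportion.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels, same length and alphabet.
#' @return Kappa in `[-1, 1]`; 0 by convention when `p_e = 1` (both
#'   marginals degenerate on the same class).
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1
#' cohens_kappa(c(1, 1, 0, 0), c(1, 1, 1, 1))  # 0
#' @export
cohens_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("empty label sequences", call. = FALSE)
  lv <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(as.character(y_true), levels = lv)
  yp <- factor(as.character(y_pred), levels = lv)
  n <- length(yt)
  tab <- table(yt, yp) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e == 0) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Cross-validation configuration for the fitness function
#'
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats CV repetitions (default 3).
#' @param svm_cost Regularization constant C of the linear-kernel SVM
#'   (default 1).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param seed Seed controlling fold assignment; all individuals scored under
#'   one configuration share identical splits, so fitness values are
#'   comparable across a population.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 10, n_repeats = 3, svm_cost = 1,
                      stratified = TRUE, seed = 1) {
  stopifnot(n_folds >= 2, n_repeats >= 1, svm_cost > 0)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 svm_cost = svm_cost, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Stratified repeated fold assignment: within each class, shuffle the sample
# indices and deal fold numbers round-robin. Returns a list of integer
# vectors (one per repeat), each assigning every sample to a fold.
make_cv_folds <- function(labels, n_folds, n_repeats, seed,
                          stratified = TRUE) {
  n <- length(labels)
  with_preserved_seed(seed, {
    lapply(seq_len(n_repeats), function(rep_i) {
      fold <- integer(n)
      if (stratified) {
        for (cl in levels(labels)) {
          idx <- which(labels == cl)
          fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
        }
      } else {
        fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
      }
      fold
    })
  })
}

fitness_result <- function(kappa, accuracy, n_selected) {
  structure(list(kappa = kappa, accuracy = accuracy,
                 n_selected = as.integer(n_selected)),
            class = "fitness_result")
}

# Strict "better than" with the parsimony tie-break: higher kappa wins;
# exactly equal kappa falls back to fewer selected genes.
is_better_fitness <- function(a, b) {
  if (a$kappa > b$kappa) return(TRUE)
  if (a$kappa == b$kappa && a$n_selected < b$n_selected) return(TRUE)
  FALSE
}

# One full CV pass for a fixed column subset. `x` is the samples x genes
# matrix, `folds` the output of make_cv_folds().
cv_score <- function(x_sel, labels, folds, svm_cost) {
  kappas <- c()
  accs <- c()
  for (fold in folds) {
    for (k in sort(unique(fold))) {
      test_idx <- which(fold == k)
      train_idx <- which(fold != k)
      fit <- e1071::svm(x = x_sel[train_idx, , drop = FALSE],
                        y = labels[train_idx],
                        kernel = "linear", cost = svm_cost, scale = FALSE)
      pred <- stats::predict(fit, x_sel[test_idx, , drop = FALSE])
      truth <- labels[test_idx]
      kappas <- c(kappas, cohens_kappa(truth, pred))
      accs <- c(accs, mean(as.character(pred) == as.character(truth)))
    }
  }
  list(kappa = mean(kappas), accuracy = mean(accs))
}

#' Score a feature subset by cross-validated SVM kappa
#'
#' Trains a linear-kernel SVM on the selected gene columns under repeated
#' stratified k-fold cross-validation and returns the mean Cohen's kappa and
#' mean accuracy over all folds and repeats. Deterministic given the bits,
#' the data and the configuration (fold assignment is derived from
#' `cfg$seed` alone).
#'
#' The all-zero bit vector gets the sentinel kappa -1 (worst possible) rather
#' than an error, so the optimizer degrades gracefully when an operator
#' produces an empty subset.
#'
#' @param bits Integer bit vector, one per gene column.
#' @param data A [labeled_expression].
#' @param cfg A [cv_config].
#' @return A `fitness_result` with fields `kappa`, `accuracy`, `n_selected`.
#' @export
evaluate_fitness <- function(bits, data, cfg = cv_config()) {
  if (length(bits) != ncol(data$values)) {
    stop("`bits` length must equal the gene count", call. = FALSE)
  }
  if (nlevels(data$labels) != 2 || any(table(data$labels) == 0)) {
    stop("both classes must be present in `data`", call. = FALSE)
  }
  n_sel <- sum(bits)
  if (n_sel == 0) return(fitness_result(-1, 0, 0))
  folds <- make_cv_folds(data$labels, cfg$n_folds, cfg$n_repeats, cfg$seed,
                         cfg$stratified)
  sc <- cv_score(data$values[, bits == 1L, drop = FALSE], data$labels,
                 folds, cfg$svm_cost)
  fitness_result(sc$kappa, sc$accuracy, n_sel)
}

#' Memoizing fitness evaluator for one optimization run
#'
#' Precomputes the fold splits once and caches results keyed by the exact bit
#' string, so re-evaluating an identical subset (common once the swarm
#' converges) costs nothing. The evaluation counter counts classifier
#' trainings triggered by cache misses.
#'
#' @param data A [labeled_expression].
#' @param cfg A [cv_config].
#' @return A list of closures: `evaluate(bits)`, `lookup(bits)` (returns
#'   `NULL` on a miss), and `count()` (number of cache-miss evaluations).
#' @export
make_fitness_evaluator <- function(data, cfg = cv_config()) {
  folds <- make_cv_folds(data$labels, cfg$n_folds, cfg$n_repeats, cfg$seed,
                         cfg$stratified)
  x <- data$values
  labels <- data$labels
  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_evals <- 0L

  evaluate <- function(bits) {
    key <- paste0(bits, collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    n_sel <- sum(bits)
    res <- if (n_sel == 0) {
      fitness_result(-1, 0, 0)
    } else {
      sc <- cv_score(x[, bits == 1L, drop = FALSE], labels, folds,
                     cfg$svm_cost)
      fitness_result(sc$kappa, sc$accuracy, n_sel)
    }
    n_evals <<- n_evals + 1L
    assign(key, res, envir = cache)
    res
  }

  lookup <- function(bits) {
    get0(paste0(bits, collapse = ""), envir = cache, inherits = FALSE)
  }

  list(evaluate = evaluate, lookup = lookup, count = function() n_evals)
}

#' Look up a memoized fitness result
#'
#' @param evaluator An evaluator from [make_fitness_evaluator()].
#' @param bits Bit vector to look up.
#' @return The cached `fitness_result`, or `NULL` on a miss.
#' @export
fitness_cache_lookup <- function(evaluator, bits) {
  evaluator$lookup(bits)
}
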