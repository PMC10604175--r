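#' Optimizer run configuration
#'
#' Bundles every tunable of the swarm loop. Defaults follow the published
#' protocol: 100 sand cats, 50 iterations, initial sensitivity 2, pinhole
#' scale 0.05, kappa fitness from a linear SVM (C = 1) under 10-fold CV
#' repeated 3 times.
#'
#' @param pop_size Number of individuals N. Default 100.
#' @param max_iter Number of iterations T. Default 50.
#' @param sM Initial sensitivity of the linear schedule. Default 2.
#' @param K Pinhole-imaging scale factor. Default 0.05.
#' @param n_folds,n_repeats,svm_cost Cross-validation settings passed to
#'   [cv_config()].
#' @param phase_rule Exploitation test on the phase value R: `"abs"`
#'   (default, exploit when `|R| <= 1`) or `"literal"` (exploit when
#'   `0 < R < 1`).
#' @param use_abs Use the magnitude of the exploitation distance term
#'   (default `TRUE`).
#' @param piobl_threshold Re-binarization threshold inside
#'   [piobl_candidate()]. Default 0.5.
#' @param crossover_writes_row Experimental: also write the winning crossover
#'   offspring into the originating row. Default `FALSE` (the crossover
#'   branch updates only the global best).
#' @return A `pilc_config` list.
#' @export
pilc_config <- function(pop_size = 100, max_iter = 50, sM = 2, K = 0.05,
                        n_folds = 10, n_repeats = 3, svm_cost = 1,
                        phase_rule = c("abs", "literal"), use_abs = TRUE,
                        piobl_threshold = 0.5,
                        crossover_writes_row = FALSE) {
  stopifnot(pop_size >= 1, max_iter >= 0)
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 sM = sM, K = K,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 svm_cost = svm_cost,
                 phase_rule = match.arg(phase_rule),
                 use_abs = isTRUE(use_abs),
                 piobl_threshold = piobl_threshold,
                 crossover_writes_row = isTRUE(crossover_writes_row)),
            class = "pilc_config")
}

#' Initialize the swarm population
#'
#' Every individual starts as the all-ones vector: all features selected.
#' The optimizer then only ever has to learn what to drop, which pairs
#' naturally with the opposition operator's subset-of-best guarantee.
#'
#' @param n_pop Population size N, positive.
#' @param n_dim Feature count D, positive.
#' @return An `n_pop` x `n_dim` integer matrix of ones.
#' @export
init_population <- function(n_pop, n_dim) {
  if (n_pop < 1 || n_dim < 1) {
    stop("population size and dimension must be positive", call. = FALSE)
  }
  matrix(1L, nrow = n_pop, ncol = n_dim)
}

exploit_phase <- function(R, phase_rule) {
  if (phase_rule == "literal") R > 0 && R < 1 else abs(R) <= 1
}

#' One binary sand cat position-update sweep
#'
#' For each individual: draw the phase value R and sensitivity r once, then
#' per dimension draw a movement angle and apply the exploitation update
#' (toward the global best) or the exploration update (relative to a random
#' peer, drawn fresh per dimension). The continuous update is immediately
#' passed through the tansig transfer function and stochastically
#' re-binarized, so positions stay bits between iterations; no continuous
#' state persists.
#'
#' @param bits N x D integer population matrix.
#' @param best Global best bit vector (length D).
#' @param rg Current general sensitivity from [compute_rg()].
#' @param cfg A [pilc_config].
#' @return The successor N x D integer population matrix.
#' @export
bscso_step <- function(bits, best, rg, cfg = pilc_config()) {
  n_pop <- nrow(bits)
  n_dim <- ncol(bits)
  for (i in seq_len(n_pop)) {
    R <- compute_R(rg, stats::runif(1))
    r <- compute_r(rg, stats::runif(1))
    x <- bits[i, ]
    theta <- sample_theta(n_dim)
    v <- if (exploit_phase(R, cfg$phase_rule)) {
      exploit_update(x, best, u1 = stats::runif(n_dim),
                     u2 = stats::runif(n_dim), theta_deg = theta,
                     use_abs = cfg$use_abs)
    } else {
      cp <- pick_candidate(n_pop, stats::runif(n_dim))
      cand <- bits[cbind(cp, seq_len(n_dim))]
      explore_update(x, cand, r, stats::runif(n_dim))
    }
    bits[i, ] <- binarize(transfer_tansig(v), stats::runif(n_dim))
  }
  bits
}

#' One enhancement step (crossover or opposition) for one individual
#'
#' With probability 0.5 the crossover branch recombines the global best with
#' the individual's row at a random cut point, scores both offspring, and
#' promotes an offspring to global best only on strict improvement; the row
#' itself is left untouched. Otherwise the opposition branch forms the
#' pinhole-imaging candidate from the row masked by the best, and on strict
#' improvement replaces both the global best and the row. Strict improvement
#' means higher kappa, or equal kappa with fewer selected genes.
#'
#' @param i Row index of the individual.
#' @param bits N x D population matrix.
#' @param best Global best bit vector.
#' @param best_fit `fitness_result` of `best`.
#' @param evaluator Evaluator from [make_fitness_evaluator()].
#' @param cfg A [pilc_config].
#' @return List with updated `bits`, `best`, `best_fit`.
#' @export
enhancement_step <- function(i, bits, best, best_fit, evaluator,
                             cfg = pilc_config()) {
  n_dim <- ncol(bits)
  if (stats::runif(1) < 0.5) {
    if (n_dim >= 2) {
      cut <- sample.int(n_dim - 1L, 1L)
      off <- single_point_crossover(best, bits[i, ], cut = cut)
      f1 <- evaluator$evaluate(off$q1)
      f2 <- evaluator$evaluate(off$q2)
      if (is_better_fitness(f1, f2) && is_better_fitness(f1, best_fit)) {
        best <- off$q1
        best_fit <- f1
        if (cfg$crossover_writes_row) bits[i, ] <- off$q1
      } else if (is_better_fitness(f2, best_fit)) {
        best <- off$q2
        best_fit <- f2
        if (cfg$crossover_writes_row) bits[i, ] <- off$q2
      }
    }
  } else {
    cand <- piobl_candidate(bits[i, ], best, K = cfg$K,
                            threshold = cfg$piobl_threshold)
    f <- evaluator$evaluate(cand)
    if (is_better_fitness(f, best_fit)) {
      best <- cand
      best_fit <- f
      bits[i, ] <- cand
    }
  }
  list(bits = bits, best = best, best_fit = best_fit)
}

run_swarm <- function(data, cfg, seed, enhance) {
  if (nlevels(data$labels) != 2) {
    stop("two classes are required", call. = FALSE)
  }
  if (min(table(data$labels)) < cfg$n_folds) {
    stop("fewer samples than CV folds in the smaller class; reduce ",
         "`n_folds`", call. = FALSE)
  }
  set.seed(seed)
  cv <- cv_config(n_folds = cfg$n_folds, n_repeats = cfg$n_repeats,
                  svm_cost = cfg$svm_cost, seed = seed)
  evaluator <- make_fitness_evaluator(data, cv)
  n_pop <- cfg$pop_size
  n_dim <- ncol(data$values)
  bits <- init_population(n_pop, n_dim)

  best <- NULL
  best_fit <- NULL
  refresh_best <- function() {
    for (i in seq_len(n_pop)) {
      f <- evaluator$evaluate(bits[i, ])
      if (is.null(best_fit) || is_better_fitness(f, best_fit)) {
        best_fit <<- f
        best <<- bits[i, ]
      }
    }
  }

  trace <- data.frame(iteration = 0:cfg$max_iter, best_kappa = NA_real_,
                      best_accuracy = NA_real_, n_selected = NA_integer_)
  record <- function(row) {
    trace$best_kappa[row] <<- best_fit$kappa
    trace$best_accuracy[row] <<- best_fit$accuracy
    trace$n_selected[row] <<- best_fit$n_selected
  }

  refresh_best()
  record(1L)
  if (cfg$max_iter > 0) {
    for (t in seq_len(cfg$max_iter)) {
      rg <- compute_rg(t, cfg$max_iter, cfg$sM)
      bits <- bscso_step(bits, best, rg, cfg)
      refresh_best()
      if (enhance) {
        for (i in seq_len(n_pop)) {
          st <- enhancement_step(i, bits, best, best_fit, evaluator, cfg)
          bits <- st$bits
          best <- st$best
          best_fit <- st$best_fit
        }
      }
      record(t + 1L)
    }
  }

  structure(list(algorithm = if (enhance) "PILC-BSCSO" else "BSCSO",
                 trace = trace,
                 best_bits = best,
                 best_fitness = best_fit,
                 config = cfg,
                 seed = as.integer(seed),
                 evaluations = evaluator$count()),
            class = "run_record")
}

#' Run the enhanced optimizer (PILC-BSCSO)
#'
#' The full loop: all-ones initialization, per-iteration fitness evaluation
#' of the swarm, elitist global-best bookkeeping, the binary sand cat
#' position update, and per individual the 50/50 crossover-vs-opposition
#' enhancement step. The global best is an elitist archive updated whenever
#' any evaluated vector (population member, offspring or opposition
#' candidate) strictly improves it, so the best-fitness trace is
#' non-decreasing by construction. Fully reproducible from `seed`.
#'
#' @param data A [labeled_expression], typically already reduced by the
#'   differential-expression prefilter.
#' @param cfg A [pilc_config].
#' @param seed Integer seed for every source of randomness in the run.
#' @return A `run_record`: `algorithm`, `trace` (data frame with one row per
#'   recorded state, iterations 0..T), `best_bits`, `best_fitness`,
#'   `config`, `seed`, `evaluations` (count of classifier trainings).
#' @seealso [run_bscso()] for the unenhanced baseline, [select_genes()] for
#'   the full prefilter + optimizer pipeline.
#' @export
run_pilc_bscso <- function(data, cfg = pilc_config(), seed = 1) {
  run_swarm(data, cfg, seed, enhance = TRUE)
}

#' Run the plain binary sand cat baseline (BSCSO)
#'
#' Identical loop minus the enhancement step; used for convergence
#' comparisons against [run_pilc_bscso()].
#'
#' @inheritParams run_pilc_bscso
#' @return A `run_record` (see [run_pilc_bscso()]).
#' @export
run_bscso <- function(data, cfg = pilc_config(), seed = 1) {
  run_swarm(data, cfg, seed, enhance = FALSE)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("%s run (seed %d): %d iterations, %d evaluations\n",
              x$algorithm, x$seed, x$config$max_iter, x$evaluations))
  cat(sprintf("best: kappa %.4f, accuracy %.4f, %d genes selected\n",
              x$best_fitness$kappa, x$best_fitness$accuracy,
              x$best_fitness$n_selected))
  invisible(x)
}

#' Full gene-selection pipeline
#'
#' Z-score normalization, differential-expression prefilter (Welch t + BH at
#' `alpha`, optional fold-change gate), then the swarm optimizer on the
#' surviving genes. If no gene passes the filter the run proceeds unfiltered
#' with a warning.
#'
#' @param data A [labeled_expression] of raw (log-scale) expression.
#' @param cfg A [pilc_config].
#' @param seed Integer seed.
#' @param alpha Adjusted-p threshold of the prefilter. Default 0.05.
#' @param logfc_min Optional absolute log2 fold-change gate.
#' @param prefilter Apply the DE gate (default `TRUE`).
#' @param normalize Apply z-score normalization first (default `TRUE`).
#' @param baseline Run plain BSCSO instead of PILC-BSCSO (default `FALSE`).
#' @return A list: `record` (the `run_record`), `de_table`, `kept_idx`
#'   (column indices, in the original gene space, fed to the optimizer),
#'   `selected_idx` (original indices of the final best subset),
#'   `selected_genes` (their identifiers), and `data_used`.
#' @export
select_genes <- function(data, cfg = pilc_config(), seed = 1, alpha = 0.05,
                         logfc_min = NULL, prefilter = TRUE,
                         normalize = TRUE, baseline = FALSE) {
  if (normalize) data <- zscore_normalize(data)
  de_table <- NULL
  kept_idx <- seq_len(ncol(data$values))
  if (prefilter) {
    de_table <- differential_expression(data)
    idx <- filter_degs(de_table, alpha = alpha, logfc_min = logfc_min)
    if (length(idx) > 0) kept_idx <- idx
  }
  data_used <- subset_genes(data, kept_idx)
  runner <- if (baseline) run_bscso else run_pilc_bscso
  record <- runner(data_used, cfg, seed)
  selected_idx <- kept_idx[record$best_bits == 1L]
  list(record = record, de_table = de_table, kept_idx = kept_idx,
       selected_idx = selected_idx,
       selected_genes = data$gene_ids[selected_idx],
       data_used = data_used)
}
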