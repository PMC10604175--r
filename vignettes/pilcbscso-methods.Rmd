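---
title: "Gene selection with PILC-BSCSO: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene selection with PILC-BSCSO: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilcbscso)
```

## The problem

Two-class expression studies routinely measure thousands of genes on a few
dozen samples. Classifiers trained on all genes overfit, and the genes that
actually discriminate the classes are buried. `pilcbscso` performs *wrapper*
feature selection: candidate gene subsets are scored by the cross-validated
performance of a classifier trained on exactly those genes, and a population
metaheuristic searches the space of subsets.

The pipeline has two stages:

1. **Prefilter.** Genes are z-score normalized and tested for differential
   expression between the two classes (Welch two-sample t per gene,
   Benjamini–Hochberg adjustment across genes). Genes with adjusted
   p < `alpha` (default 0.05), optionally also |log2 fold-change| above a
   threshold, define the search space for the optimizer. This shrinks the
   dimension from thousands to the tens or hundreds and removes genes with no
   marginal signal.
2. **Optimizer.** A binary sand cat swarm (BSCSO), optionally enhanced with
   single-point crossover and pinhole-imaging opposition-based learning
   (PILC-BSCSO), searches over inclusion bit-vectors. The fitness of a
   bit-vector is the mean Cohen's kappa of a linear-kernel SVM (cost C = 1)
   under stratified 10-fold cross-validation repeated 3 times.

## The sand cat swarm and its binary form

Each of N individuals is a bit-vector of length D (one bit per gene). The
continuous sand cat update is driven by a *general sensitivity*
`rg = sM (1 - t/T)` that decays linearly from `sM = 2` to 0 over the T
iterations. Per individual and iteration, a phase value `R ~ U(-rg, rg)` and
a sensitivity `r ~ U(0, rg)` are drawn. When the phase test passes
(`|R| <= 1` by default) the agent *exploits*: per dimension j it computes a
distance term `Xrand = |u1 * xbest_j - x_j|` and moves to
`xbest_j - u2 * Xrand * cos(theta)`, with a fresh angle `theta ~ U(0, 360)`
degrees per dimension. Otherwise it *explores*, moving to
`r (xcand_j - u * x_j)` relative to a uniformly drawn peer. Every continuous
update is immediately mapped through the tansig transfer function
`Tf(v) = 2/(1 + e^(-2v)) - 1 = tanh(v)` and binarized: the bit becomes 1
exactly when `Tf(v)` strictly exceeds a fresh uniform draw. No continuous
state survives between iterations — positions are stored as bits.

A consequence of the tansig rule worth knowing: non-positive updates always
binarize to 0, so bits can only switch on through positive continuous
updates. The scheme is deliberately asymmetric and pairs with the all-ones
initialization (every individual starts with every gene selected): the
search predominantly learns what to *drop*.

## The two enhancement operators

With probability 0.5 per individual per iteration, one of two operators is
applied after the position sweep:

* **Single-point crossover** recombines the global best with the
  individual's row at a uniform random cut; both offspring are scored and an
  offspring replaces the global best only when it strictly improves it. The
  row itself is left unchanged (a config flag can write the winner back, off
  by default).
* **Pinhole-imaging opposition (PIOBL)** reflects the row through the
  pinhole-imaging construction with scale factor K = 0.05 on the binary
  bounds [0, 1]; the reversed values (−9.5 or 10.5) are re-binarized at 0.5,
  which is exactly the bitwise complement, and then masked by the global
  best with a bitwise AND. On strict improvement the candidate replaces both
  the global best and the row. Because of the AND mask the candidate is
  always a subset of the best, so this operator can only shrink or preserve
  the selected-gene count — it is the algorithm's parsimony engine.

"Strictly improves" means higher kappa, or exactly equal kappa with fewer
selected genes. The global best is an elitist archive: every evaluated
vector (population member, offspring, opposition candidate) can update it,
and it never regresses, so the per-iteration best-fitness trace is
non-decreasing by construction.

## Fitness

Cohen's kappa, `(p_o - p_e) / (1 - p_e)`, corrects the observed agreement
`p_o` for the agreement `p_e` expected from the marginals. On unbalanced
data (the intended use case) it is a far better search signal than raw
accuracy, which rewards majority-class guessing. Both kappa (the optimized
quantity) and accuracy (the conventionally reported one) are recorded in
every fitness result.

Fold assignment is stratified and derived once per run from the run seed, so
all individuals in a run are scored on identical splits and fitness values
are comparable across the population. Results are memoized by exact bit
pattern; the evaluation counter in each run record counts actual classifier
trainings. The all-zero subset is assigned the sentinel kappa −1 rather than
an error, so degenerate candidates lose every comparison but never abort a
run. Whether the repeated 3×10 protocol or a single 10-fold pass is used
inside the loop is configurable (`n_repeats`); the default is 3×10.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `pop_size` (N) | 100 | swarm size; desk-scale analyses use ~20 |
| `max_iter` (T) | 50 | iteration budget (the only stop criterion) |
| `sM` | 2 | initial sensitivity of the linear schedule (kHz analogy) |
| `K` | 0.05 | pinhole scale factor; any K < 1 yields the complement after re-binarization |
| `n_folds`, `n_repeats` | 10, 3 | CV protocol behind the fitness |
| `svm_cost` | 1 | linear-SVM regularization C |
| `alpha` | 0.05 | adjusted-p gate of the prefilter |
| `phase_rule` | `"abs"` | exploitation test `|R| <= 1`; `"literal"` uses `0 < R < 1` |

Two genuinely open choices were settled as follows and are exposed as
configuration rather than hard-coded:

* The movement-angle "roulette wheel" has no stated weighting; over equal
  slices it degenerates to a uniform draw on [0, 360], which is what is
  implemented.
* The exploitation distance term is implemented with magnitude bars
  (distance semantics); `use_abs = FALSE` gives the signed literal variant.
* The re-binarization of the opposition candidate is a hard 0.5 threshold;
  a tansig-based binarization of ±9.5/10.5 saturates to the same complement
  behavior, so the choice is benign.
* `sM` defaults to 2; a variant description with `sM = 1` exists, hence the
  parameter is exposed.

## The synthetic benchmark

`make_synthetic_expression()` generates the kind of data this tool targets:
`n_samples = 60`, `n_genes = 500`, two classes split 65/35 (echoing the
classic 40/22 colon-cancer design), and 10 planted genes carrying an
additive mean shift of 2 standard deviations in the tumor class, in
unit-variance Gaussian noise. The shift is additive because the pipeline
assumes roughly log-scale intensities, on which fold changes act
additively. These defaults are the package's reference study conditions;
tests and the acceptance script run N = 20, T = 15 on them, which finishes
in seconds per run while still exercising every code path.

What the generator does *not* emulate: gene–gene correlation, batch
effects, heavy-tailed intensity distributions, and count (RNA-seq)
sampling noise. Passing tests on this benchmark therefore demonstrate the
mechanics of the pipeline — prefilter calibration under the null, signal
recovery, determinism, convergence — not performance on real microarray or
RNA-seq data.

## Behavior on the reference benchmark, and a known limitation

With a 2-sd shift and 60 samples, the prefilter typically retains exactly
the 10 planted genes, and the all-ones start already achieves kappa 1.0.
From there, strict-improvement-with-parsimony means every equal-kappa,
smaller subset lawfully replaces the best, and the optimizer converges to
3–4 genes with precision 1.0. This is the intended parsimony behavior (the
selected count always ends below the post-prefilter dimension), but it also
means *recall* of the full planted set is structurally low whenever the
signal is strong enough to saturate kappa: once two or three planted genes
classify perfectly, the remaining planted genes are redundant and are
dropped. Users who want the full differential signature should read it from
the prefilter's DE table; the optimizer answers a different question — the
smallest subset that classifies best.

On real data, where kappa rarely saturates, exact-kappa ties are rare and
the parsimony tie-break almost never fires; subset sizes are then governed
by the fitness landscape alone.

## Numerical and degenerate-input choices

* Zero-variance genes: z-score sets the column to zeros and flags it; the
  Welch test assigns t = 0, p = 1. Neither aborts.
* An empty DE survivor set warns and the pipeline proceeds unfiltered.
* `filter_degs` uses strict inequalities on both gates; `alpha = 1` keeps
  all genes.
* Kappa returns 0 by convention when `p_e = 1` (both marginals degenerate
  on the same class).
* The binarization threshold comparison is strict (`Tf > u`), so a
  transferred value of exactly 0 can never set a bit.
* All stochastic components flow from a single integer seed per run; CV
  fold construction uses an isolated RNG stream so it does not consume
  draws from the optimizer, and the synthetic generator restores the
  caller's RNG state.

## Worked example

```{r example, eval = FALSE}
truth <- make_synthetic_expression(synthetic_spec())
res <- select_genes(truth$data,
                    cfg = pilc_config(pop_size = 20, max_iter = 15),
                    seed = 1)
res$record
#> PILC-BSCSO run (seed 1): 15 iterations, 61 evaluations
#> best: kappa 1.0000, accuracy 1.0000, 4 genes selected
recovery_metrics(res$selected_idx, truth)
#> $recall [1] 0.4   $precision [1] 1
```

The same pipeline is available from a shell through the CLI (see
`inst/cli/pilcbscso.R`): `simulate`, `prefilter`, `run` and `baseline`
subcommands, every run reproducible from `--seed`.
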