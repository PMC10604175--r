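# pilcbscso

Wrapper gene selection for two-class, high-dimensional expression data
(bulk microarray-style matrices, and anything else shaped samples × genes
with a binary label). The package implements the **binary sand cat swarm
optimizer (BSCSO)** and its enhanced variant **PILC-BSCSO**, which fuses
two operators into the swarm loop:

* **single-point crossover** between the global best subset and each
  individual, and
* **pinhole-imaging opposition-based learning (PIOBL)**, which reflects an
  individual through the pinhole construction with scale factor K = 0.05
  and masks it with the global best — an operator that can only shrink or
  preserve the selected-gene count.

Candidate subsets are scored by the **Cohen's kappa of a linear-kernel SVM
(C = 1) under stratified 10-fold cross-validation repeated 3 times**; kappa
`(p_o − p_e)/(1 − p_e)` is used instead of accuracy because the target
datasets are class-unbalanced. Before the swarm runs, a
differential-expression prefilter (per-gene Welch t + Benjamini–Hochberg,
adjusted p < 0.05, optional |log2FC| gate) shrinks the search space.

The sand cat dynamics: a sensitivity schedule `rg = sM(1 − t/T)` decays
linearly from `sM = 2`; a per-agent phase value `R ∈ [−rg, rg]` switches
between exploitation (`x ← x_best − u·|u′·x_best − x|·cos θ`) and
exploration (`x ← r·(x_cand − u·x)`); every continuous update is mapped
through the tansig transfer `Tf(v) = 2/(1+e^{−2v}) − 1 = tanh(v)` and
re-binarized against a uniform draw.

A synthetic-data generator with planted differential genes makes the whole
pipeline testable end to end without any external datasets.

## Worked example

```r
library(pilcbscso)

truth <- make_synthetic_expression(synthetic_spec())  # 60 x 500, 10 planted genes
res <- select_genes(truth$data,
                    cfg = pilc_config(pop_size = 20, max_iter = 15),
                    seed = 1)
res$record
#> PILC-BSCSO run (seed 1): 15 iterations, 61 evaluations
#> best: kappa 1.0000, accuracy 1.0000, 4 genes selected

res$selected_genes
#> [1] "g0084" "g0112" "g0221" "g0336"

recovery_metrics(res$selected_idx, truth)
#> $recall    0.4
#> $precision 1
```

Reading: the prefilter kept the 10 planted genes; the optimizer then found
a 4-gene subset that classifies the held-out folds perfectly (kappa and
accuracy 1.0). All 4 selected genes are truly planted (precision 1.0);
recall is 0.4 because, once a few strong genes classify perfectly, the
parsimony rule (equal kappa → fewer genes wins) drops the redundant
remainder — the optimizer returns the smallest best-classifying subset, not
the full differential signature (that is the prefilter's job; see
`res$de_table`).

The plain baseline for comparison: `select_genes(..., baseline = TRUE)`
runs BSCSO without the crossover/PIOBL enhancement, and
`res$record$trace` holds the per-iteration best-kappa convergence curve
for either algorithm.

## Command line

A thin Rscript wrapper lives at `inst/cli/pilcbscso.R`:

```sh
Rscript inst/cli/pilcbscso.R simulate --out fixture --seed 1
Rscript inst/cli/pilcbscso.R run --data fixture/expression.tsv \
    --labels fixture/labels.tsv --out results --pop-size 20 --iters 15 --seed 1
```

`run` (and `baseline`) write `selected_genes.tsv`, `trace.csv` and a JSON
run manifest; identical seeds give byte-identical outputs.

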