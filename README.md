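# swarmFS

Ensemble swarm-intelligence feature selection for high-dimensional omics
matrices.

## What problem this solves

Transcriptome and DNA-methylation matrices have thousands to hundreds of
thousands of features for a few dozen labelled samples. Filter methods
score features one at a time and require the analyst to pre-specify how
many to keep; **wrapper** selection instead searches feature *subsets*
directly, scored by the cross-validated performance of a classifier, and
stops wherever the objective says to stop. swarmFS implements that search
with four binary swarm-intelligence metaheuristics — the slime mould
algorithm (SMA), pathfinder algorithm (PFA), Henry gas solubility
optimization (HGSO) and particle swarm optimization (PSO) — and combines
their selected subsets into consensus (intersection) and pooled (union)
ensembles.

Every optimizer minimises the same fitness of a candidate subset `SF`
over the full feature set `AF`:

```
Fit = β · ER + (1 − β) · |SF| / |AF|,        β = 0.99
```

where `ER` is the 5-fold cross-validated error rate of a 5-nearest-
neighbour classifier restricted to the selected columns. Selected subsets
can then be evaluated with five classifier families (SVM, KNN, linear
discriminant analysis, bagged trees, naive Bayes; accuracy, precision,
recall, F1, rank-based AUC), tabulated as feature-selection rates, and
compared across datasets with Wilcoxon signed-rank and Friedman tests.
A synthetic-data generator with planted informative features (Gaussian
expression-like and beta-bounded methylation-like models) makes the whole
pipeline testable without any downloads.

## Worked example

```r
library(swarmFS)

g <- synth_generate(synth_spec(n_per_class = 30, n_features = 2000,
                               n_informative = 5, effect_size = 3, seed = 1))
m <- drop_missing_features(g$matrix)

fit_cfg <- fitness_config(beta = 0.99, knn_k = 5, n_folds = 5, fold_seed = 2)
runs <- lapply(c(SMA = "sma", PFA = "pfa", HGSO = "hgso"), function(a)
  swarm_optimize(m, fit_cfg, optimizer_config(a, seed = 42)))
sapply(runs, function(r) c(fitness = r$best_fitness, n_selected = sum(r$best_mask)))
#>              SMA       PFA    HGSO
#> fitness    3e-05 7.115e-02 0.03304
#> n_selected 6e+00 1.030e+03 8.00000

cs <- combine_masks(lapply(runs, `[[`, "best_mask"))
print(cs)
#> CombinationSet: 3 inputs over 2000 features
#>   SMA&PFA                   5 features
#>   SMA&HGSO                  1 features
#>   PFA&HGSO                  5 features
#>   SMA&PFA&HGSO              1 features
#>   SMA|PFA                1031 features
#>   SMA|HGSO                 13 features
#>   PFA|HGSO               1033 features
#>   SMA|PFA|HGSO           1034 features
```

The three algorithms behave very differently on the same objective: SMA
returns a minimal signature (6 of 2,000 features, fitness dominated by
the tiny size term), PFA keeps roughly half the feature space, HGSO sits
in between — and the triple intersection isolates a single consensus
feature. Independent 5-fold KNN evaluation of the three subsets gives
accuracies of 0.983, 0.983 and 0.967 on this data, and the planted
informative features are recovered completely by PFA's subset
(`recovery_score(runs$PFA$best_mask, g$truth)`).

`rate_table()` turns masks into the selection-rate table (solo,
intersection, union columns, percent of the feature space, em dashes for
empty combinations), `wilcoxon_signed_rank()` / `friedman()` compare
methods across datasets, and `select_best()` applies the
best-classifier / top-algorithms shortlisting rule. `run_pipeline()`
chains every stage (preprocess → select → combine → evaluate → rates →
statistics) and writes all artifacts plus a manifest for byte-identical
re-runs; `inst/scripts/swarmfs` exposes the same stages as shell
subcommands (`synth`, `select`, `ensemble`, `eval`, `pipeline`).

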