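---
title: "Wrapper feature selection with swarm intelligence: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection with swarm intelligence: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmFS)
```

## The problem

Omics matrices — bulk expression arrays, RNA-seq counts, DNA-methylation
beta-value panels — routinely carry tens of thousands of features for a few
dozen samples. A classifier trained on all features overfits, and the
features that drive a phenotype are buried among thousands of irrelevant
probes. *Wrapper* feature selection searches the space of feature subsets
directly, scoring each candidate subset by the cross-validated performance
of a classifier restricted to it. The search space has $2^{|AF|}$ states,
so the search itself has to be heuristic; this package drives it with four
population-based swarm-intelligence metaheuristics and then builds
*ensembles* of the selected subsets by set intersection and union.

## The objective

Every optimizer minimises the same scalar fitness of a candidate mask $SF$
over the full feature set $AF$:

$$\mathrm{Fit} = \beta \cdot ER \;+\; (1-\beta)\,\frac{|SF|}{|AF|}$$

where $ER$ is the $k$-fold cross-validated error rate of a $k$-nearest-
neighbour classifier ($k = 5$, Euclidean distance on the selected columns
only) and $\beta = 0.99$ by default, so classification performance
dominates and the size term merely breaks ties in favour of leaner subsets.
Two conventions make the objective well behaved:

* **the empty subset scores 1.0**, the worst possible value, so the search
  is repelled from the degenerate state the error rate is undefined on;
* **folds are drawn once per run** from `fold_seed` and reused for every
  evaluation, so fitness is a deterministic function of the mask within a
  run — re-splitting per call would turn the objective surface into noise.

All KNN distance and vote ties break by lowest training-sample index,
which makes every fitness value bit-reproducible. Because many continuous
positions binarize to the same mask, evaluations are memoised by mask bits.

## The search

Agents live in the continuous unit hypercube $[0,1]^d$; a strict threshold
(default 0.5) maps a position to a binary mask, and a position whose mask
would be empty is repaired by promoting its single largest component. The
framework is shared by all algorithms: initialise uniformly, update, clip
to $[0,1]^d$, binarize, evaluate, and retain the best mask ever seen
*outside* the population (elitism). Elitism is what makes the best-so-far
trace monotone non-increasing regardless of how disruptive an update rule
is — convergence plots presuppose it.

The four update rules:

* **SMA** (slime mould): ranked-fitness weights on a log scale steer moves
  toward a blend of the global best and two random agents (redrawn per
  dimension), with oscillation ranges $a = \operatorname{arctanh}(1-t/T)$
  and $b = 1 - t/T$ shrinking over the run; with probability $z = 0.03$ an
  agent restarts uniformly. The contraction branch multiplies positions by
  $vc \in [-b, b]$, which relentlessly drives components below threshold —
  SMA therefore produces the smallest subsets by a wide margin.
* **PFA** (pathfinder): the best agent performs a decaying random walk with
  momentum; followers are attracted to a random neighbour and to the
  pathfinder with coefficients drawn from $[1,2]$, plus a distance-scaled
  perturbation decaying as $(1-t/T)$. PFA has no contraction pressure, so
  its subsets stay near the ~50% occupancy of a uniform initialisation.
* **HGSO** (Henry gas solubility): agents are split into gas-type clusters
  (contiguous blocks, fixed for the run); per-cluster Henry coefficients
  decay under an exponential temperature schedule and scale each agent's
  attraction to the global best, while a fitness-ratio factor scales
  attraction to the cluster best; each iteration a random 10–20% of the
  worst agents restart uniformly.
* **PSO** (particle swarm): the classic velocity rule with inertia decaying
  linearly 0.9 → 0.4, cognitive and social coefficients 2, and a velocity
  clamp at 0.6.

Defaults are a population of 10 and 100 iterations; on the matrices this
package targets, convergence is typically visible within the first 10–25
iterations of the trace. One seeded RNG stream per run covers
initialisation, update noise and restarts, so identical configurations
reproduce byte-identical results.

## Ensembles and comparison

Two or three selected subsets combine into all pairwise and triple
intersections and unions — eight combinations for three inputs. Empty
intersections are retained and flagged (methods with disjoint selections
have no consensus), and selection-rate tables render them as an em dash
and exclude them from column averages. Inclusion–exclusion,
$|A \cup B| = |A| + |B| - |A \cap B|$, holds exactly on mask counts and
therefore on rates before rounding; output tables round to 4 decimals of a
percent.

Methods are compared nonparametrically: the Wilcoxon signed-rank test
(zero differences dropped, average ranks on ties, statistic
$\min(R^+, R^-)$, exact two-sided $p$ by rank-distribution convolution up
to $m = 25$ nonzero pairs, normal approximation with tie and continuity
corrections beyond) and the Friedman test in its chi-squared form with tie
correction and $k-1$ degrees of freedom. `select_best()` implements the
shortlisting rule used on a large benchmark: the best classifier is the
one that most often attains the per-cell maximum accuracy (ties credit all
tied classifiers), and algorithms are ranked by wins with that classifier,
ties broken by smaller average selected-feature count, then
lexicographically.

## Synthetic data: what it emulates and what it does not

`synth_generate()` produces two families. The *Gaussian* model mimics
expression matrices: i.i.d. noise features, with planted informative
features shifted between classes by `effect_size` standard deviations. The
*beta* model mimics methylation beta values: every feature has a baseline
location drawn in $[0.2, 0.8]$ with precision 30, and informative features
have their location shifted by `effect_size` latent standard deviations,
clipped into $[0.02, 0.98]$, so all values stay in $[0,1]$. Missing
entries are planted uniformly at a configurable rate. Default desk-scale
shapes are 60 samples by 2,000 features (expression-like); the real
matrices this method targets are one to two orders of magnitude wider.

What the generator deliberately does **not** model: correlated feature
blocks, batch effects, probe-annotation structure, class imbalance, and
the massive redundancy of real omics data (where hundreds of probes track
one biological signal). Passing the planted-recovery tests therefore shows
the search machinery works on a clean, identifiable signal; it does not
certify behaviour under real-data redundancy, where distinct but equally
predictive subsets are the norm rather than the exception.

## Validation design and numerical choices

Two validation benches deserve explanation:

* **Exhaustive-oracle bench** (small $d$): 20 synthetic datasets with 24
  samples and 10 features, 3 informative at effect 2.5, where all
  $2^{10}-1$ masks can be enumerated and the true fitness optimum is
  known. Each algorithm (population 20, 100 iterations) is required to
  land within 5% relative of the optimum in at least 4 of 5 seeds, pooled
  across datasets. The effect size is chosen strong deliberately: with a
  weak signal the exhaustive optimum becomes an idiosyncratic mask that
  exploits cross-validation noise, and closing on it measures
  fold-overfitting rather than search competence.
* **Planted-recovery bench** (expression scale): 60 samples by 2,000
  features, 5 informative at effect 3; each algorithm is asked for
  5-fold KNN accuracy ≥ 0.9 and median recall of the planted features
  ≥ 0.6 over 5 seeds.

A known limitation surfaces on the second bench: SMA reaches the *best*
fitness of all four algorithms (perfect accuracy with 1–2 selected
features) yet recalls only a minority of the planted features. This is not
a search failure — the size term of the objective actively rewards
discarding features that are predictive but redundant, and SMA is the most
aggressive minimiser. Users who want complete marker panels rather than
minimal discriminative sets should prefer PFA/HGSO/PSO, raise $\beta$
toward 1, or use union combinations; users who want parsimonious
signatures will prefer exactly what SMA does.

Other numerical choices: stratified folds deal each class round-robin with
a rolling offset, so fold sizes and per-class counts both differ by at
most one even for awkward class sizes; classes smaller than the fold count
degrade gracefully with a warning. Matrix values are written with 17
significant digits so write/read round trips are exact. Classifier
concretisations for the evaluation suite (the classifier families are
conventions, not contributions): RBF-kernel soft-margin SVM, linear
discriminant analysis, Gaussian naive Bayes, and a 50-tree bagged CART
ensemble grown to purity (`minsplit = 2`, `cp = 0`), with AUC computed as
the Mann–Whitney rank statistic on pooled fold scores. Binary metrics
take the lexicographically larger label as positive unless overridden;
F1 is defined as 0 when precision and recall are both 0. Multiclass tasks
report accuracy only.

## A worked example

```{r example, eval = FALSE}
g <- synth_generate(synth_spec(n_per_class = 30, n_features = 2000,
                               n_informative = 5, effect_size = 3, seed = 1))
m <- drop_missing_features(g$matrix)

fit_cfg <- fitness_config(beta = 0.99, knn_k = 5, n_folds = 5, fold_seed = 2)
runs <- lapply(c(sma = "sma", pfa = "pfa", hgso = "hgso"), function(a)
  swarm_optimize(m, fit_cfg, optimizer_config(a, seed = 42)))

sapply(runs, function(r) c(fitness = r$best_fitness, size = sum(r$best_mask)))

cs <- combine_masks(lapply(runs, `[[`, "best_mask"))
print(cs)
rate_table(list(synthetic = lapply(runs, `[[`, "best_mask")))
```

The same pipeline, end to end with artifacts and a manifest, is
`run_pipeline(pipeline_config(...))`, and a thin command-line wrapper over
the same functions is installed at
`system.file("scripts", "swarmfs", package = "swarmFS")`.
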