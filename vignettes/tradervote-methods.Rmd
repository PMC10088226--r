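---
title: "Trader wrapper selection and voting classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trader wrapper selection and voting classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tradervote)
```

# The problem and the model

`tradervote` classifies biomedical tabular data in two stages: a wrapper
feature-selection stage that searches for a small subset of columns maximizing
the cross-validated accuracy of an SVM, and a voting ensemble that aggregates
the predictions of several models, each trained on its own selected subset.
Wrapper selection scores subsets by the performance of the actual downstream
learner, in contrast to filter methods (per-feature statistics) and embedded
methods (regularization paths); it is more expensive but directly optimizes
the quantity of interest.

## Candidate encoding

A candidate solution is a fixed-length vector of `k` **distinct feature
indices**, not a binary inclusion mask. This is deliberate: the retailing
operator performs integer arithmetic on index values
(`V_j <- V_j + sign * uniform_integer(0, V_j)`), which is meaningful only on
an index encoding, and it keeps the number of selected features constant at
`k`, matching how results are reported (a small, fixed subset per dataset).
Indices are **1-based internally**: under a 0-based encoding the index 0 would
be a fixed point of the multiplicative perturbation (`0 + sign·uniform(0,0)`
can never leave 0). File formats expose 0-based positions; conversion happens
only at the I/O boundary.

## The Trader search loop

The population (default 100) is evaluated, randomly partitioned once into
`n_groups` trader groups of near-equal size, and each group's best member
becomes its *master*; the group's *finance* is the sum of its members'
fitnesses. Per iteration, `ceiling(change_fraction * pop_size)` members are
drawn uniformly (default 30% of 100); a selected slave undergoes *retailing*
or *distributing* (equal probability by default), a selected master undergoes
*importing–exporting* against the other masters. Modified candidates are
evaluated and **accepted only if not worse** than the member they would
replace; masters and finances are then re-derived and the best-so-far fitness
appended to the convergence trace.

Design choices that the procedure description leaves open, and how this
package resolves them:

* **Position sets.** "Randomly selected variables" is realized as each
  position chosen independently with probability `1/k`, with one position
  forced when none is drawn. The expected change is a single position — the
  smallest possible move, fitting retailing's role as a minor-modification
  operator, and it applies uniformly to all three operators.
* **Retailing draw.** `random(0, V_j)` is drawn as a uniform *integer* on
  `[0, V_j]`, since candidate variables live in integer index space. A zero
  draw is allowed and leaves the position unchanged.
* **Repair.** After any operator, values are clamped into `[1, n_features]`
  and duplicate values are replaced by uniform draws from the currently unused
  indices. This keeps `k` constant and introduces no positional bias.
* **Acceptance.** Elitist (keep a modification only if its fitness is at least
  the replaced member's). This guarantees a non-decreasing best-so-far trace —
  the convergence behavior the method is expected to display — and protects
  masters from destructive import–export moves; a separate global-best archive
  makes the guarantee explicit.
* **Groups.** `n_groups = 5` by default ("several groups" is otherwise
  unquantified), giving 20-member traders at the default population. With a
  single group a master has no exporter, so retailing is applied to it
  instead.
* **Changed members.** The 30% modified per iteration are drawn uniformly over
  the whole population, without master/slave stratification.

## Budget accounting

Every evaluation request counts as exactly one objective call — including
requests answered from the memoization cache — so a run's call count is
exactly `pop_size + iterations * ceiling(change_fraction * pop_size)`
(1600 at the 100/50/30% reference protocol). This preserves the comparison
contract under which stochastic optimizers are benchmarked at an identical
number of objective (SVM) calls; the bundled random-search baseline is run at
exactly that budget. The cache only saves wall-clock time, never calls.

## The fitness function

Fitness is the accuracy of an SVM trained on the candidate's columns, under an
internal stratified 5-fold cross-validation whose held-out predictions are
pooled into a single confusion matrix; accuracy is the mean-based multiclass
form `sum_i TP_i / N` (the matrix trace over the sample count), which for two
classes reduces to `(TP + TN)/N`. Cross-validated fitness is the default
because resubstitution accuracy rewards overfitting the selection; a
resubstitution compatibility mode (`inner_folds = 1`) exists and is documented
as leak-prone. SVM hyperparameters are reproducible defaults rather than tuned
claims: RBF kernel, cost 1, kernel width `1/(d * var(X))` (the common "scale"
heuristic), data already on `[0, 1]` so libsvm's internal rescaling is
disabled. The fold split is a deterministic function of the objective seed, so
fitness is a pure function of the subset — invariant to index order and to
repeated evaluation.

# Preprocessing

Missing cells are completed before normalization. For each sample with missing
cells, donor samples are ranked by Pearson correlation with the target over
jointly observed features (undefined below 3 shared positions or under zero
variance); fully observed donors with `r > 0.5` qualify, the best 10 are kept,
and each missing cell receives the correlation-weighted mean
(`w_i = r_i / sum(r)`) of the donors' values in that column. "Interpolation of
the related values" is realized as this weighted mean because it degenerates
exactly to the donor's value when a single perfectly correlated donor exists —
the behaviour the duplicated-sample test pins down. Two fallbacks keep every
sample: if no fully observed donor qualifies, completeness is relaxed to the
target's missing columns only (flagged `relaxed` in the report); if still no
donor qualifies, the column mean over observed values is used (flagged
`fallback`). Samples are never dropped — instance removal is precisely the
practice this pipeline is designed to avoid.

Normalization is per-column min–max to `[0, 1]`; constant columns map to 0.
The per-column `(min, max)` record is returned so held-out folds are
transformed with **training-fold statistics**. During cross-validation the
default is fully nested preprocessing and selection (no leakage);
`leak_compat = TRUE` reproduces the historically common
preprocess-once/select-once-on-all-data protocol for comparability, with
members still trained per fold. Test-fold missing cells are filled with
training-column means rather than re-running donor search against training
rows — simpler, and still strictly training-only information.

# Voting

Each ensemble member is an SVM trained on the full training data restricted to
one search result's best subset; member diversity comes from independent
Trader runs with distinct derived seeds (default 5), optionally mixed with
random-search results. The vote count `F_p_i` for class i is the number of
members predicting i; the prediction is its argmax. Ties default to the
`fitness_weighted` policy — the tied class whose voters have the larger summed
fitness wins — because it is deterministic and prefers the evidence of better
members; any residual tie falls to the lowest class index, guaranteeing
totality. Vote shares `F_p_i / members` serve as the class scores for ROC/PR
construction.

# Evaluation statistics

* **Metrics.** Per class, one-vs-rest precision `TP/(TP+FP)`, sensitivity
  `TP/(TP+FN)` and specificity `TN/(TN+FP)`, each defined as 0 when its
  denominator vanishes; the reported PRE/SEN/SPC are the **unweighted (macro)
  means** over classes — the mean-based extension consistent with the pooled
  accuracy — and F is the harmonic mean of macro PRE and macro SEN (pairing
  the single reported F with the single reported PRE/SEN rather than averaging
  per-class F values). Micro variants are available via the `average`
  argument.
* **Curves.** One-vs-rest ROC and PR curves per class over descending score
  thresholds; the reported curve is the macro average — each class curve
  reduced to its upper envelope, interpolated onto the shared grid of all
  observed x values, and averaged — with trapezoidal AUC. A zero-width anchor
  keeps ROC curves starting at (0, 0). Classes absent from the truth vector
  are skipped with a warning.
* **Wilcoxon rank-sum.** Two-sided, with midranks. Exact by full enumeration
  of the null rank-sum distribution when both samples have at most 10
  observations and there are no ties (enumeration is cheap there and exactness
  is free); otherwise the normal approximation with tie-corrected variance,
  with p = 1 when that variance vanishes (e.g. all values identical). At the
  customary 50 runs per optimizer the approximation branch applies.
* **Run sets.** Stability is summarized by boxplot statistics (median, hinges,
  1.5·IQR whiskers, outliers) of final fitnesses across repeated runs;
  convergence by the element-wise mean of the best-so-far traces.

# The synthetic generator

The generator plants `n_informative` columns carrying class-dependent
Gaussian signal: class centroids are drawn at random in the informative
subspace and rescaled so their **minimum pairwise distance equals
`class_sep`**, and informative cells add `N(0, noise_sd^2)` noise to the
centroid coordinate of the sample's class. Remaining columns are standard
Gaussian noise, a configurable fraction thresholded to {0, 1} to emulate mixed
numeric/binary tables. Labels are balanced up to the remainder; missing cells
are placed uniformly at the requested rate without ever emptying a row or
column. Everything is a deterministic function of the seed. Thirteen presets
reproduce the shape grid of widely used clinical/biological benchmarks
(345×6×2 up to 801×20,531×5, with missing cells where the corresponding
benchmark has them); their informative-column counts match the subset sizes
typically selected on those shapes.

This construction gives a controllable Bayes error and an unambiguous ground
truth, which no real dataset provides — that is what makes oracle and
recovery tests possible. It does **not** emulate feature correlations,
heavy-tailed marginals, label noise, or structured missingness of real
clinical tables, so passing tests demonstrate the machinery is correct under
known conditions, not that any particular real-data accuracy will be
attained.

**Fitness saturation.** At large `class_sep` a subset containing only 2–3 of
the planted features can already classify perfectly; fitness then stops
discriminating among near-optimal subsets and elitist acceptance lets the
remaining positions drift. Recovery of the full planted set is therefore
bounded away from `k` by construction at high separation — a property of the
condition, not a failure of the search.

# Problem sizes and determinism

The test suite and the reproduction script run entirely on generated data at
deliberately modest sizes: the enumeration-oracle instance uses 10 features
(120 possible 3-subsets, every one scored exhaustively); the recovery study
uses 300 samples × 50 features with 10 independent searches at population 30 /
20 iterations (a scaled version of the 100/50 reference protocol, which is
exercised separately for budget accounting with a stub objective); optimizer
comparisons use 8–10 runs per arm. All sub-seeds (population, folds,
generator, member runs) derive deterministically from one global seed via a
counter-mode mix, so every pipeline stage is reproducible and independent
streams never collide.

# Known limitations

* The comparison optimizers from the surrounding literature (WCC, LCA, PSO,
  ICA) are not implemented; the budget-matched random-search baseline stands
  in for matched-budget comparisons.
* Only hard voting is provided — no probability calibration, stacking, or
  weighted member training.
* The SVM hyperparameters are fixed defaults; `sweep_k` explores the subset
  size but no hyperparameter search is attempted.
* Imputation is single-pass; it is idempotent but not a multiple-imputation
  scheme, and uncertainty in imputed cells is not propagated.
* The claimed cubic time order of the original algorithm description is not
  derivable from the procedure and is neither assumed nor enforced; runtime
  is dominated by the SVM fits, i.e. by the objective-call budget.
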