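---
title: "Gain-sequence forward tabu search: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gain-sequence forward tabu search: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsfts)
```

## The problem

Hypertension outcomes — severe cardiac, cerebral, renal, or fundus
complications in hypertensive patients — are rare, serious, and hard to
anticipate from any single examination indicator. A prediction model built
on routine clinical examinations faces three coupled difficulties: the
feature set is wide (on the order of a hundred indicators) and mostly
uninformative; the outcome is strongly imbalanced (roughly one positive per
seven negatives); and records are dirty, with missing values, gross entry
errors, and incommensurable units.

This package implements a wrapper feature-selection method for this
setting: a **gain-sequence forward tabu search** (GSFTS) around a
second-order gradient-boosted-tree classifier, with an EasyEnsemble wrapper
for the class imbalance and a complete evaluation harness (stratified
cross-validation, McNemar paired comparison, improvement-rate tables, grid
search). A synthetic cohort generator with planted informative features
provides the controlled ground truth the method can be validated against.

## The classifier: second-order boosted trees

The wrapped classifier is binary gradient boosting in its
second-order (Newton) form. With additive margin
$\hat y_i^{(t)} = \sum_{k \le t} f_k(x_i)$ and loss
$L^{(t)} = \sum_i l(y_i, \hat y_i^{(t)}) + \sum_k \Omega(f_k)$,
$\Omega(f) = \gamma T + \tfrac{1}{2}\lambda \lVert \omega \rVert^2$,
each round fits one regression tree to the second-order expansion of the
loss at the current margins. For the logistic loss used here,
$g_i = p_i - y_i$ and $h_i = p_i(1 - p_i)$ with $p_i$ the current
predicted probability. A leaf with summed statistics $G = \sum g_i$,
$H = \sum h_i$ takes the Newton weight

$$\omega^\ast = -\frac{G}{H + \lambda},$$

the tree's regularized objective (up to a constant) is
$-\tfrac12 \sum_j G_j^2/(H_j + \lambda) + \gamma T$, and a candidate split
of a node into $(L, R)$ is scored by the gain

$$\mathrm{Gain} = \frac12\left[\frac{G_L^2}{H_L + \lambda} +
\frac{G_R^2}{H_R + \lambda} - \frac{(G_L + G_R)^2}{H_L + H_R + \lambda}
\right] - \gamma,$$

i.e. exactly the parent's structure score minus the children's. The suite
pins this identity to $10^{-9}$ on randomized node statistics; it is the
invariant that fixes the sign conventions unambiguously (a transcription
with "+" before the parent term cannot satisfy it).

Splits are found by **exact greedy enumeration**: every feature, every
midpoint between consecutive distinct sorted values. No histogramming,
no row or column subsampling. At this scale (hundreds of rows, ~100
features) approximations buy nothing, and exactness makes the fit fully
deterministic — identical data and configuration reproduce identical trees,
which the tabu search's determinism contract relies on. Ties between
equal-gain candidates go to the lower feature index, then the lower
threshold. A split must have strictly positive gain; $\gamma$ (default 0)
raises that bar. The inner loops (tree growth, routing) are in C++, as is
conventional for boosting implementations; the objective arithmetic is also
exposed as plain R functions so tests can check the identities
independently.

Defaults: $\lambda = 1$, $\gamma = 0$, $\eta = 0.3$ (shrinkage), base
probability 0.5. The operating point tuned for the motivating cohort is
`max_depth = 7`, `n_estimators = 70`; reduced models (20 trees, depth 3)
are used throughout the validation suite for cost, which is noted wherever
it matters.

### Class imbalance: EasyEnsemble

With a 1:7 outcome ratio, a single model trained on all rows concentrates
on the majority class. `fit_easy_ensemble()` trains `n_members` models,
each on **all** minority samples plus an equal-sized draw (without
replacement) of majority samples, and averages member probabilities. The
default of 10 members follows the usual recommendation for this
method. Ensemble draws happen inside each training fold during
cross-validation, never on data a fold will be evaluated on.

### Gain importance

A feature's importance is its **average split gain** across every internal
node that uses it, over all trees (pooled over ensemble members when the
model is an EasyEnsemble). Unused features score zero; ranking ties break
toward the lower feature index so that rankings are total and
deterministic. On imbalanced cohorts the ensemble-pooled ranking is
noticeably more reliable than a single fit's — balanced subsets stop the
majority class from dominating early splits — and `rank_by_gain(...,
n_members = )` exposes exactly that choice.

## The selector: GSFTS

1. **Rank** all features by average split gain of a model fit on the full
   feature set.
2. **Seed** with a gain-ranked sequential forward search (`gain_sfs()`):
   start from the top-ranked feature, add features in ranking order, stop
   at the first strict drop of the evaluation score and return the subset
   before the drop. Ties are not drops; the walk continues through them.
   The seed is therefore always a prefix of the ranking (a tested
   invariant).
3. **Refine** by tabu search over bit-string encodings (one bit per
   feature, at least one bit set). Each iteration draws up to CSL
   single-bit flips (uniformly, without replacement; a flip that would
   empty the subset is infeasible), scores them, and moves to the best
   *admissible* one — admissible meaning the flipped feature is not on the
   tabu list, or the move beats the best score seen so far (the
   aspiration/amnesty rule). The chosen feature then becomes tabu for TLL
   iterations: it may be neither added nor removed, absent aspiration. If
   every candidate is tabu and none aspirates, the search takes the best
   tabu move (least remaining tenure, then lowest index) rather than
   stalling, and flags it in the trace. The search runs a fixed number of
   iterations and returns the best-so-far solution, which by construction
   never scores below the seed.

Tuned search parameters from the motivating cohort: CSL = 20, TLL = 12,
200 iterations; the tabu attribute is the *feature index*, not the move
direction, matching the "may be neither added nor deleted" rule.

### The evaluator

A subset's score is the chosen metric (accuracy, precision, recall, F1, or
AUC) of the wrapped classifier under stratified k-fold cross-validation on
the training partition (`make_evaluator()`; k = 5 by default, 3 in the
cheaper validation runs). Folds and ensemble draws are frozen when the
evaluator is created, so a subset always maps to the same score — the
evaluator is a deterministic objective function, and results are memoised
by bit string since tabu search revisits subsets. A resubstitution variant
(`scheme = "train"`) exists because the original formulation of the
forward-search step scores on training accuracy; cross-validation is the
default for both phases here, as resubstitution scores saturate and carry
no warning of overfitting.

### Baselines

`run_plain_sfs()` (greedy forward over all remaining features, not
gain-ordered, stop on strict drop) and `run_rfe()` (repeatedly drop the
lowest-average-gain feature, refit, keep the best-scoring size) provide the
comparison selectors used in the report tables.

## Evaluation harness

* **Metrics**: standard definitions; AUC is the Mann–Whitney rank statistic
  with midranks for ties (tested against brute-force pair counting);
  zero-denominator precision/recall/F1 are reported as 0 and flagged.
  Classification threshold is 0.5 on predicted probability throughout.
* **Cross-validation**: stratified folds (the 1:7 imbalance makes
  unstratified folds degenerate); all preprocessing fitted inside the
  training fold; reported as mean ± sd across folds (sd, not se).
* **McNemar**: continuity-corrected statistic $(|b-c|-1)^2/(b+c)$ on the
  discordant counts, referred to $\chi^2_1$; $b + c = 0$ gives statistic 0,
  p = 1. The $\chi^2_1$ upper tail is computed as
  $\mathrm{erfc}(\sqrt{x/2})$ and tested against numerical integration.
* **Improvement rates**: $100(v - b)/b$, computed from the 2-decimal
  rounded metrics as printed in comparison tables, rounded half-up to one
  decimal (base R's banker's rounding would disagree with printed tables on
  exact halves).
* **Grid search**: exhaustive over the Cartesian grid, F1 by default as
  the tuning index, first-in-grid-order tie-break.

## The synthetic cohort generator

Real hypertension-center records are not redistributable, so validation
runs on `generate_cohort()`, which emulates the documented structure of
such a cohort: 752 patients × 84 indicators after preprocessing, 1:7
positive:negative imbalance, and 14 indicators carrying published summary
statistics (e.g. AGE mean 38.31, sd 11.42, range 15–76; right
brachial–ankle pulse-wave velocity mean 15.65, sd 3.05, range 7.3–28.6).

* **Features**: continuous indicators are truncated normals on their
  documented \[low, high\] ranges (inverse-CDF sampling); binary indicators
  are Bernoulli. Only means, sds and ranges are documented, so no
  inter-feature correlation is modelled — a known, deliberate gap between
  the generator and real records.
* **Labels**: logistic-linear in the z-scored informative features — the
  simplest model under which selection methods provably have signal to
  find. Ten features are informative by default, with alternating-sign
  weights of magnitude 0.4–1.2 (selected subsets of 9–16 features were
  reported for the real cohort, so ten planted signals of graded strength
  is a comparable world). The intercept is solved by bisection so expected
  prevalence equals the target (no closed form exists under truncation);
  empirical prevalence lands within ±0.03 over repeated seeds, which the
  suite verifies.
* **Dirt**: `missing_rate` of feature cells are blanked and `outlier_rate`
  of continuous cells are displaced to mean ± (6+u)·sd, u ~ U(0,4) — far
  enough that a 4-sd cell rule detectably fires. Defaults 0.05 and 0.01
  reflect realistic hand-entered examination data. The label column is
  never touched, and binary indicators get no outliers (a 6-sd excursion is
  undefined for a Bernoulli variable).

A green recovery test on this generator establishes that the search finds
*planted log-odds signal under independent features and clean label
semantics*; it does not establish performance on correlated, confounded, or
label-noisy clinical data.

## Preprocessing rules

Order: drop features with > 50% missing, then samples with > 50% missing
over the retained features (strict inequalities; exactly-at-threshold is
kept); mean-impute the rest; flag cells more than `k_sd = 4` sds from their
feature mean and re-impute them from the remaining values; min–max scale to
\[0, 1\] (constant features map to 0). Cell-level outlier treatment
preserves cohort size; whole-row deletion is available
(`action = "drop_sample"`) since "delete the outliers" is ambiguous between
the two. The flag–impute cycle iterates to a fixed point by default, which
makes the whole pipeline idempotent — a property the suite asserts — at the
cost of occasionally flagging second-pass cells a single sweep would keep
(`max_pass = 1` restores the single sweep). Held-out partitions are scaled
with training-fit parameters, without clipping, so out-of-range test values
extrapolate beyond \[0, 1\]; this preserves monotonicity and mirrors
deployment. Every step writes its parameters into a report that
`apply_preprocess()` can replay bit-for-bit on the raw table.

## Numerical and design choices

* **Determinism**: one global seed per run; per-stage seeds derived by a
  stage-name hash; all stochastic steps (cohort draw, folds, ensemble
  draws, neighbor sampling, splits) restore the caller's RNG state.
* **Forward-search stop rule**: strict drop, ties continue. With a noisy
  CV evaluator the rule fires early and seeds are short; that is faithful
  to the stated rule, and the tabu phase is what recovers from it.
* **Aspiration** is strict (`>` best-so-far), so a tabu move that merely
  ties the incumbent best stays tabu.
* **Tabu list capacity** equals TLL active entries; the oldest (smallest
  remaining tenure) entry is evicted first.
* **Tie-breaks everywhere are deterministic**: equal-score neighbors go to
  the lowest flipped index; equal-gain splits to the lowest feature index
  and threshold; equal-importance features to the lowest index; equal
  grid-search scores to the first grid point.
* **"When the gain is less than the regularization, no split"**: read as
  the $\gamma$ threshold in the gain formula ($\gamma$ plays exactly that
  role there); $\lambda$ already enters every denominator.
* **Two-score presentation**: drawings of boosted trees sometimes show one
  tree per class with separate "outcome" and "no outcome" scores. The
  implementation is the standard single-margin binary formulation
  (mathematically the same decision rule); `two_score_view()` renders the
  two-score presentation from it.
* **Per-criterion subsets**: selection can be run under any of the five
  objective tags; how a single deployed subset should be chosen among the
  per-criterion results is left to the user (the report shows them all).

## Known limitations

* The generator draws features independently; correlated indicator blocks
  (e.g. the several blood-pressure channels) are not emulated, so feature
  redundancy — one of the practical motivations for wrapper selection — is
  understated.
* Wrapper search optimizes a cross-validated score and therefore inherits
  its optimism: with small candidate sets and many iterations, the
  best-so-far subset is selected partly for lucky fold noise (a
  winner's-curse bias toward including spurious features). Ensemble
  averaging in the evaluator damps but does not remove this; see the
  recovery test for how it is measured.
* No sparsity-aware missing-value routing inside trees (preprocessing is
  expected to have imputed), no monotone constraints, no multiclass.
* McNemar on small discordant counts (b + c < ~10) is better served by the
  exact binomial test, which is not implemented; the continuity-corrected
  statistic is what comparison tables in this literature print.
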