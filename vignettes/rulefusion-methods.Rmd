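---
title: "Methods: diverse decision-rule fusion for interpretable diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diverse decision-rule fusion for interpretable diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rulefusion` builds a binary diagnostic model (invasive adenocarcinoma,
IAC, versus pre-invasive MIA/AIS) whose predictors are conjunctive
decision rules over lesion features. A rule is a conjunction of
axis-aligned conditions — `feature <= t`, `feature > t`, an interval
`feature ∈ (l, u]`, or an exact flag value — and fires (indicator 1) when
all conditions hold. Boundary semantics mirror binary tree splits: `<=`
inclusive, `>` strict, intervals left-open right-closed. The final model
is ordinary logistic regression on the selected rule indicators,

$$Y_i = \beta_0 + \sum_k \beta_k\, r_k(x_i), \qquad
  P(\mathrm{IAC}_i) = \mathrm{logit}^{-1}(Y_i),$$

so every coefficient reads as the log-odds shift of one interpretable
imaging pattern. The package ships the published 15-rule instance of this
model (intercept −0.3265) as a text fixture.

Assumptions worth keeping in mind: the outcome is binary and observed per
lesion (multiple nodules per patient are treated as independent samples);
features are numeric, with binary radiological flags coded 0/1; rules are
conjunctions only — no disjunctions, negations or soft memberships.

## The pipeline and its parameters

1. **Two-phase feature selection** (`select_features()`): scaling
   normalization; removal of continuous features with pre-scaling variance
   ≤ `variance_tol` (default 1e-8); greedy pruning of feature pairs with
   absolute Spearman correlation > `rho_cutoff` (default 0.9), dropping
   within each pair the feature with the larger mean absolute correlation
   (ties: the lexicographically later name, so the outcome is
   deterministic); mRMR ranking to `mrmr_k` (default 100) features; then
   the binary flags rejoin and `lasso_iters` (default 500) repetitions of
   cross-validated L1-penalized logistic regression with re-randomized
   stratified folds give per-feature selection frequencies. Features with
   frequency ≥ `stability_threshold` (default 0.5) are kept, truncated to
   `max_features` (default 10) by frequency. The repetition count follows
   the study design it implements; the stability-selection reading (rather
   than "best of 500 runs") was chosen because it is reproducible and has
   an established statistical interpretation.
2. **Ensembles** (`fit_ensembles()`): gradient boosting (`xgboost`;
   500 trees, depth 5, learning rate 0.1), random forest
   (`randomForest`; 500 trees, minimum leaf 1, averaged mode with uniform
   weights 1/M), and discrete SAMME AdaBoost implemented in-package over
   `rpart` base trees (30 trees, depth 5), with per-tree log-odds weights
   log((1−err)/err).
3. **Rule extraction** (`extract_rules()`): one candidate rule per
   non-root node — interior nodes included, as in standard RuleFit
   practice. Rules are canonical by construction (path bounds are narrowed
   incrementally), and splits on 0/1 flags become equality conditions.
4. **RuleFit fusion** (`rulefit_fuse()`): per method, candidates are
   deduplicated, truncated to `max_rules` (default 80), and entered with
   winsorized, standardized linear terms into an L1-penalized logistic
   model (`glmnet`), intercept unpenalized. Rule importance is the
   original RuleFit definition, coefficient magnitude times term standard
   deviation: $I_k = |\hat\alpha_k|\sqrt{s_k(1-s_k)}$ for a rule with
   support $s_k$, $I_j = |\hat\beta_j|\,\mathrm{sd}(l_j)$ for a linear
   term.
5. **Selection cascade** (`fuse_and_select()`): importance > 0.1 filters
   the gradient-boosting and random-forest rules; the phi coefficient
   (Pearson correlation of the 0/1 indicator with the 0/1 outcome),
   |phi| > 0.4, filters the AdaBoost rules; the three indicator datasets
   merge with duplicate rules collapsed (provenance retained as the union
   of sources) and indicator-identical rules represented by their simplest
   member; a LASSO on the merged indicators keeps rules with nonzero
   weight at the cross-validated penalty; finally rules whose mean
   absolute SHAP value is at least 0.5 on a normalized scale survive.
6. **Diagnostic model and evaluation** (`fit_logistic()`,
   `evaluate_model()`): maximum-likelihood logistic fit; AUC by the
   tie-corrected Mann–Whitney rank statistic; DeLong confidence interval
   by default (deterministic), stratified bootstrap optional; threshold
   metrics at probability 0.5 by default, with a Youden-optimal cutoff
   available.

## Design choices where the design was open

- **Penalty selection.** The fusion and merged-LASSO stages select the
  penalty at the cross-validation minimum (`lambda_rule = "min"`), the
  behaviour of the reference RuleFit/LassoCV tooling; the 1-SE rule is
  available. Under the 1-SE rule the random-forest branch typically
  retains no rules at the 0.1 importance threshold and the final model
  collapses to a handful of rules, which is inconsistent with the
  retention pattern the method is designed to produce. The
  feature-selection repetitions keep the more conservative 1-SE default,
  where stability, not fit, is the point.
- **SHAP scale.** Mean |SHAP| on the linear-predictor scale depends on
  coefficient magnitudes, so an absolute threshold of 0.5 is not
  dimensionless. Contributions are normalized by their mean, making the
  threshold read "at least half the average rule contribution". Dividing
  by the maximum instead proved far stricter in practice (typically <15%
  retention) and discards most informative near-duplicate variants; both
  raw and normalized values are logged in the selection trace.
- **Rule budget.** `max_rules` truncates candidates by consuming whole
  trees in training order, which is what capping the rule count in the
  reference implementation effectively does; random support-balanced
  subsampling of tens of thousands of candidates would retain informative
  rules only by chance.
- **Exact-tree semantics.** `randomForest` splits with `<=` natively.
  `rpart` and `xgboost` split with strict `<` at cut points; `rpart` cuts
  are data midpoints where the two are indistinguishable, and xgboost
  thresholds are shifted down by half a float32 ulp so the uniform
  `<= / >` frame routes every sample identically to the ensemble itself
  (xgboost compares in float32).
- **Missing values** in a rule's features make the rule evaluate to 0 for
  the affected sample, with a warning; a strict mode errors instead.
- **Winsorization** of linear terms at the 2.5%/97.5% quantiles
  (configurable) guards the linear terms against radiomic outliers; flags
  pass through untouched.
- **Separation.** Binary-indicator designs separate easily at small n;
  quasi-separation in the final logistic fit triggers a ridge refit with
  penalty 1e-6 and a warning.
- **Numbers in text formats.** Serialized thresholds and coefficients use
  the shortest decimal string that round-trips to the identical double, so
  parse → serialize → parse is lossless; the parser additionally accepts
  printed-table quirks (thousands separators, unicode minus, spaced
  `<  =`).

## Synthetic cohorts

`generate_cohort()` emulates the study population without any patient
data. A latent lesion class (invasive-like with probability 0.4) drives a
two-component mixture per feature; marginals are loosely calibrated to the
published axis-length statistics and chosen so that the 1%–99% range of
every continuous feature brackets all of its published rule thresholds.
Three label mechanisms are available:

- `published_model`: labels are Bernoulli draws from
  logit⁻¹(scale · Y) with Y from the published 15-rule equation. The raw
  coefficients are too small for Bernoulli draws to reproduce the
  separability the published model exhibits on its cohorts, so the linear
  predictor is scaled (`signal_scale`, default 4), calibrated so the
  mechanism's intrinsic (Bayes) AUC matches the published training AUC of
  0.9621.
- `planted_rules`: label 1 iff any of three planted ground-truth rules
  fires, then flipped with probability `noise`. The default planted rules
  (a major-axis threshold, the spiculated-margin flag, and an
  entropy-with-pleural-indentation conjunction) each fire in roughly half
  of the invasive-like class and rarely otherwise, giving supports near
  0.25, phi correlations with the outcome comfortably above the cascade's
  0.4 filter, and several percent of samples covered by exactly one rule
  so that no planted rule is redundant.
- `logistic_linear`: a linear-logistic score over a few features, for
  generic benchmarking.

`generate_radiomics_table()` builds the high-dimensional stress input for
feature selection: planted informative features (mean shift 1.2 in the
positive class), exact duplicates of two of them, blocks of near-duplicate
noise columns (within-block Spearman correlation > 0.99), near-constant
columns, and independent noise.

What the generators do *not* emulate: scanner- and site-specific batch
effects, the heavy inter-feature correlation structure of real radiomics
panels beyond the explicit duplicate blocks, non-Gaussian tail behaviour
of texture features, and any association between the flags and the
continuous features beyond the latent class. Passing tests on these
cohorts therefore demonstrate the machinery's correctness and its
behaviour under a controlled data-generating process, not clinical
performance.

## Problem sizes

The test-suite experiments use the sizes the methodology is designed
around: end-to-end discrimination on a published-model cohort of 400
training and 200 held-out lesions with 5% label noise; planted-rule
recovery on 400 lesions with 5% noise; feature-selection recovery on 300
samples by 500 columns with 500 LASSO repetitions. Unit tests use much
smaller fixtures built in code.

## Known limitations

- **Recovery of planted rules under label noise is imperfect.** With 5%
  of labels flipped, the flipped samples are fixed in the realized
  dataset, so they are learnable structure: boosted trees (AdaBoost in
  particular, whose reweighting concentrates exactly on the permanently
  misclassified flips) breed sub-rules that excise the flipped samples
  from a true rule's region. Such a sub-rule fits the realized labels
  better than the true rule both in-sample and under cross-validation, so
  the merged LASSO — forced by the L1 penalty to pick one member of each
  near-collinear cluster — often keeps a variant whose indicator agrees
  with the true rule on only 80–95% of samples (Jaccard). Stability
  selection over subsamples does not repair this (selection frequency
  splits across cluster members). The cascade therefore reliably selects
  rules *covering* the planted structure, but the selected variant can
  deviate from the exact planted boundary by more than 10% of its firing
  set; users should read the selected rules as representatives of a
  cluster of near-equivalent rules, which the selection trace makes
  explicit.
- Rule thresholds inherit the training data's resolution (tree cut
  points); they are not calibrated boundaries.
- The SHAP filter is exact only because the model is additive in
  indicators by construction; no interaction attribution is attempted.
- The AdaBoost implementation is binary (SAMME with K = 2); multi-class
  subtyping is out of scope.
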