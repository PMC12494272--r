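---
title: "From feature importance to causal effects: the heartgc methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From feature importance to causal effects: the heartgc methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(heartgc)
```

## The problem

Machine-learning rankings of clinical predictors answer a predictive
question: which variables, if observed, most reduce uncertainty about a
diagnosis? They do not answer the causal question of what would happen to
the disease risk if a factor were changed. `heartgc` keeps the two
questions separate and answers both on the same 14-column cardiac cohort
schema (thirteen predictors plus a binary heart-disease outcome): stage
one ranks all predictors by three importance methods; stage two estimates,
for four dichotomised candidate treatments, the average treatment effect
(ATE) on disease presence by g-computation.

## Stage one: three importance methods

**Information gain.** For a feature $X$ with groups $g$ and binary outcome
$Y$, $IG(X) = H(Y) - \sum_g \frac{n_g}{n} H(Y \mid g)$, with entropies in
bits. Continuous features are discretised by equal-frequency binning,
five bins by default. The bin count is a tunable; equal-frequency (rather
than equal-width) binning makes the score invariant to monotone
transformations of the feature, which suits skewed clinical measurements
such as ST depression. The score is bounded by $H(Y) \le 1$ bit and equals
the mutual information of the binned feature and the outcome.

**Shadow-feature random-forest selection.** Each iteration appends a
row-permuted ("shadow") copy of every feature, fits a random forest
(`ranger`, 500 trees by default), and counts a hit for a feature whose
importance exceeds the best shadow. Importance is permutation
(out-of-bag accuracy) importance rather than impurity importance: a
permuted shadow is exactly the null of the permutation measure, whereas
Gini impurity importance of a continuous feature remains biased upward
even when the feature is pure noise, which in our simulations inflated
false confirmations several-fold. Impurity importance remains available
through `rf_params`. Hit counts are
binomial under the null that a feature does no better than noise, so each
feature is tested against $\mathrm{Bin}(i, \tfrac12)$ two-sidedly at level
$\alpha = 0.01$ with Bonferroni correction over the feature count:
significantly many hits confirm, significantly few reject, and rejection
is possible only after roughly a dozen iterations (the earliest a
Bonferroni-corrected binomial tail can fall below the threshold). Features
still undecided at `max_iter` (100 by default) are resolved by the rough
fix: confirmed when their median importance across iterations beats the
median of the per-iteration shadow maxima. The seed is mandatory; one
seed fixes the permutations, the forests, and hence the decisions
bit-for-bit.

One caveat is inherent to all-relevant selection: the procedure asks
whether a feature is more informative than noise *conditional on the
observed sample*. In a small cohort the luckiest of many null features
carries a genuine in-sample correlation with the outcome, and a
sufficiently precise forest will — correctly, by the selector's own
criterion — confirm it now and then. Averaged over datasets the
confirmation count on pure noise stays near zero (well under 5% of the
feature set in the test suite's 100-seed simulation), but it is not an
exact per-dataset error-rate guarantee, and no setting of the binomial
test can make it one.

**L1-penalised logistic regression.** Predictors are standardised to zero
mean and unit variance, then a lasso logistic path is fitted with
`glmnet`; the score is the absolute coefficient at the deviance-minimising
penalty from 10-fold cross-validation with seed-controlled folds. A fixed
penalty can be supplied instead; at a vanishing penalty the scores
reproduce the unpenalised maximum-likelihood coefficients.

All three methods return a complete ranking of all features; ties break by
descending score, then by the cohort column order, so rankings are
deterministic. The top-$k$ set (default $k = 5$) can be compared with the
full feature set by held-out accuracy under a single stratified 70/30
split with a mandatory seed, for logistic regression and random forest,
and by a likelihood-ratio chi-square test between the nested logistic
fits. A single split is the default because repeated splitting changes
the estimand from "accuracy of this trained model" to "expected accuracy
over splits"; the split seed is recorded so either is reproducible.

## Stage two: g-computation

For a binary treatment $T$, outcome $Y$, and confounders $C$, the Q-model
is the main-effects logistic regression

$$\mathrm{logit}\, P(Y = 1 \mid T, C) = \beta_0 + \alpha T + \beta' C.$$

Standardising over the empirical confounder distribution gives the
counterfactual risks
$\hat\pi_a = n^{-1} \sum_i \hat P(Y_i = 1 \mid do(T_i = a), C_i)$,
the ATE $\hat\Delta = \hat\pi_1 - \hat\pi_0$, and the marginal log odds
ratio $\log[\hat\pi_1(1-\hat\pi_1)^{-1} / (\hat\pi_0(1-\hat\pi_0)^{-1})]$.

The four candidate treatments are the dichotomised vessel count (3 vs
fewer narrowed vessels on fluoroscopy), thallium stress result (code 7,
ischemia, vs 3/6), sex (male vs female), and high cholesterol (at or
above 240 mg/dl, a guideline threshold exposed as a parameter). When one
member of this set is the treatment, the other three are the confounders.
They enter the Q-model in the same binarised form by default: the
dichotomies are the only concrete definitions of these variables the
analysis uses, and using one scale on the treatment side and another on
the confounder side would make the four analyses incommensurable. The raw
scales remain available (`binarize_confounders = FALSE`) since the choice
is a genuine modelling degree of freedom.

**Inference.** Standard errors come from a nonparametric bootstrap: rows
are resampled with replacement, the Q-model is refitted and the risks
restandardised on each of $B$ resamples (default 1000). Confidence
intervals are percentile by default, with a normal-approximation
alternative; the bilateral test of $\pi_0 = \pi_1$ (OR = 1) is the
two-sided z-test of $\hat\Delta$ against its bootstrap standard error. A
parametric simulation of the coefficient distribution would be a cheaper
variance estimate, but at the cohort sizes this package targets the
bootstrap is affordable and makes fewer assumptions, so only the
bootstrap is implemented. Resamples that lose a treatment arm, lose an
outcome class, or separate are redrawn rather than skipped — keeping $B$
fixed keeps quantile-based intervals well defined — and the redraw count
is reported; inference is refused when redraws exceed $B$, i.e. when more
than half of all draws are degenerate, because the resampling
distribution is then conditioned on a rare event and no longer estimates
the sampling variance.

**Odds-ratio decomposition.** Three views of the same association: the
*raw* OR from the unadjusted 2×2 cross-product, the *conditional* OR
$e^{\hat\alpha}$ from the adjusted model, and the *marginal* OR from the
standardised risks. Odds ratios are non-collapsible, so conditional and
marginal differ even under randomised treatment; the raw-vs-marginal gap
reflects confounding. With an empty confounder set all three coincide
exactly, which the test suite checks.

## The synthetic generator and what it does (not) show

`generator_spec()` defines the generating process the analysis assumes:
independent binary confounders $C_j \sim \mathrm{Bern}(p_j)$,
treatment $T \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\gamma_0 + \gamma'C))$,
outcome
$Y \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\beta_0^* + \alpha^* T + \beta^{*\prime} C))$.
Nonzero $\gamma$ makes $C$ a genuine confounder. Because the coefficients
are known, `true_effects()` computes the exact standardised risks by
summation over the $2^p$ confounder strata; this closed-form truth is the
oracle every recovery test compares against.

The defaults — $n = 270$, prevalences $0.3/0.5/0.4$,
$\gamma = (-0.5, 0.6, 0.4, -0.3)$, $\beta_0^* = -1.2$, $\alpha^* = 1$,
$\beta^* = (0.5, -0.4, 0.8)$ — mimic the scale of a small observational
cardiac cohort: a few hundred patients, an outcome prevalence near 40%,
and a marginal odds ratio in the single digits. They are package
defaults chosen once on that reasoning, not estimates from any dataset.
The draw order (confounders column-wise, then $T$, then $Y$; the nine
filler clinical columns of the full schema afterwards) is part of the
reproducibility contract: one seed, one cohort, on any platform.

In "table-1 mode" the generator emits the full 14-column clinical schema:
the three confounders become the vessel count, sex, and cholesterol
columns, the treatment becomes the thallium code, and the remaining nine
predictors are drawn from plausible marginal ranges independent of the
outcome. This emulates the schema, the value domains, and the
confounding structure of a real cohort — not its joint distribution: real
predictors are mutually correlated, effects need not be logistic-linear,
and real confounding is rarely limited to three binary variables. Passing
tests therefore certify the estimator and the pipeline plumbing, not the
clinical conclusions one would draw from any particular dataset.

## Numerical choices and degenerate inputs

* Logistic fits use iteratively reweighted least squares
  (`stats::glm.fit`) with relative deviance tolerance $10^{-14}$ and at
  most 100 iterations. The tight tolerance is deliberate: the
  saturated-model oracle check requires standardised risks to match
  nonparametric stratification to $10^{-10}$, and the no-confounder
  collapse identity is asserted to near machine precision; IRLS converges
  quadratically, so the extra iterations this costs are one or two.
* Separation is flagged when a coefficient on a binary design column
  exceeds 15 in absolute value — on dichotomised data a log odds ratio of
  15 is far outside anything estimable — and raises an explicit error
  rather than returning a divergent fit. Rank-deficient designs raise an
  error naming the collinear columns.
* Boundary risks (0 or 1) make the odds ratio infinite and raise, as do
  empty 2×2 cells, with the offending cell named.
* Binarisation rules return a {0,1}-only input unchanged, making them
  idempotent. For the vessel rule, whose raw domain contains 0 and 1,
  a cohort in which no patient has more than one narrowed vessel is
  indistinguishable from rule output; such a cohort has no treated arm
  under the rule, so the causal stage refuses it either way.
* Problem sizes in the test suite are chosen so the full suite runs in
  minutes on one core: the standardisation oracle uses 200 random
  stratified tables; parameter recovery uses one cohort of $10^5$; null
  calibration uses 200 replicates of $n = 2000$ with $B = 500$; the
  selector's type-I check uses 100 seeds with reduced forests (64 trees),
  which changes the power of each forest but not the binomial decision
  rule under test. Smaller forests also make the shadow maximum noisier
  and therefore harder for a spuriously correlated null feature to beat
  consistently.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(sim_spec = generator_spec(n = 270), sim_seed = 1,
                  methods = c("information_gain", "lasso"),
                  B = 500, selection_seed = 2, causal_seed = 3)
report <- run_pipeline(cfg)
report
```

The report prints the held-out accuracy table (full vs top-5 feature
sets), the per-treatment g-computation table (standardised risks, ATE,
log-OR, percentile CI, bilateral p-value), the odds-ratio decomposition,
and — for simulated cohorts — the generator truth those estimates should
track. The manifest in `report$manifest` records every seed and setting
needed to reproduce the run byte-for-byte.

## Known limitations

* Treatments and outcome must be binary; multi-level or continuous
  treatments, inverse-probability weighting, TMLE, and time-varying
  regimes are out of scope.
* The Q-model is main-effects logistic by default; the interaction mode
  exists for diagnostics (it makes the single-confounder model saturated),
  not as a recommended analysis model.
* Held-out accuracies from a single 70/30 split carry split-to-split
  variability of several percentage points at $n = 270$; compare feature
  sets on the same seed, or average over seeds.
* With no missing-data handling, cohorts containing missing values are
  rejected at ingestion rather than imputed.
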