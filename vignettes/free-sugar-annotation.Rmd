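---
title: "Annotating free sugars in food composition tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating free sugars in food composition tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarstep)
library(dplyr)
```

## The problem

Dietary guidance limits *free sugars*: added sugars plus the sugars naturally
present in honey, syrups and fruit juices — but not the sugars intrinsic to
intact fruit, vegetables and milk. Most national food composition tables
(FCTs) report only *total* sugar, so free-sugar intake cannot be computed
from a survey without first deciding, food by food, how much of each food's
total sugar is free. Doing that by hand for a 1500-food table is slow and
subjective; `sugarstep` automates it with a four-step cascade:

1. **Step 1** — a food with 0 g total sugar gets 0 g free sugar.
2. **Step 2** — foods in groups that are unprocessed or minimally processed
   with no added sugar (spices, fats and oils, plain grains, eggs, fresh
   produce and meat, plain milk, non-sweetened beverages, nuts, tubers) get
   0 g: any sugar they do contain is intrinsic.
3. **Step 3** — foods in groups with no naturally occurring sugars
   (sugars and syrups, confectionery, sweetened beverages, cookies,
   processed meat, milk-free beverage bases, fruit juices) get 100% of
   their total sugar as free sugar.
4. **Step 4** — every remaining food (mixed dishes, sweetened cereal and
   dairy products, where total sugar is partly intrinsic and partly added)
   is scored by a regression model over seven nutrients.

Precedence is strict, 1 over 2 over 3 over 4, and a label claimed by both a
ZERO and a FULL rule resolves to ZERO: preferring 0 g over 100% is the
conservative error. Matching is case-insensitive exact label match at any of
the three taxonomy levels, with per-`food_id` overrides for items (such as
mixed dishes classified from their recipe) that no group label can resolve.
The rule lists ship as an editable CSV config rather than code, because they
are policy, not arithmetic.

Foods with a *missing* total sugar value can still receive step 2 (assigning
0 g needs no total sugar) but not steps 1, 3 or 4; they are flagged
`unannotated` and excluded downstream rather than silently imputed, since
inventing a total-sugar value would bias the 100% assignments.

## The step-4 model

The predictor set is the seven nutrients that are well covered in most FCTs:
protein, carbohydrate, total sugar, fiber, total fat, saturated fat (g/100 g)
and sodium (mg/100 g). Four base regressors are each tuned by 10-fold
cross-validation on mean squared error:

* support vector regression (RBF kernel; cost in {1, 10}, gamma = 1/7,
  predictors z-scored — kernel methods are scale-sensitive, trees are not);
* random forest (500 trees, mtry in {2, 3});
* gradient-boosted trees (300 rounds, learning rate 0.1, depth in {3, 6});
* rule-fit (rules harvested from 50 shallow boosted trees, binarized and
  combined with winsorized linear terms under an L1 path with
  cross-validated penalty).

The grids are deliberately small and documented: they keep a desk-scale
training run in minutes while giving each learner one meaningful capacity
choice. Ties in CV error resolve to the first grid point, so tuning is
deterministic given the seed, which also drives fold assignment and every
stochastic learner.

The meta-learner is non-negative least squares on the out-of-fold
predictions, without intercept: `w = argmin ||y - P w||^2, w >= 0`. Fitting
on out-of-fold predictions keeps the stack honest (no learner is scored on
rows it trained on), and NNLS optimality guarantees the stack's out-of-fold
error is never above the best single learner's. Predictions are clipped into
`[0, total_sugar]` once, after stacking — the constraint belongs to the
target, not to the individual learners.

```{r, eval = FALSE}
world <- generate_food_table(synthetic_config(n_foods = 1547, seed = 1))
fit <- fit_free_sugar_model(build_training_matrix(world$foods),
                            cv = cv_config(folds = 10, seed = 1))
tidy(fit)
annotations <- annotate_food_table(world$foods, model = fit)
```

## Validation semantics

`evaluate_predictions()` reports the sample Pearson correlation and the mean
absolute error in g/100 g between predictions and known values. When the
truth is constant the correlation is reported as missing, not zero — a
constant column carries no information about agreement. By default the
validation set excludes foods the rules would resolve (steps 1–3), since the
open question is the model step; `evaluate_menu()` complements the per-100 g
metrics with the error in g/day over multi-day menu plans, which is how
per-food errors actually combine in a diet.

## Intake statistics

`compute_daily_intake()` uses the first recall day per respondent by
default: a single 24 h recall estimates the population mean defensibly but
not usual-intake variance, and the package makes no measurement-error
correction (a stated non-goal). Energy comes from the FCT energy field times
amounts — one source of truth — and the percent-of-energy figure uses
4 kcal/g for sugar (Atwater; configurable, since conventions differ).

The weighted mean and its standard error use the with-replacement
linearization estimator: `SE^2 = n/(n-1) * sum((w_i (x_i - mean))^2) /
(sum w_i)^2`. With equal weights this collapses to the classical
`sqrt(s^2/n)`.

Group comparisons are rank-based: Kruskal–Wallis with average-rank ties and
the usual tie correction, then Dunn's pairwise z,

`z_ij = (Rbar_j - Rbar_i) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j))`,

with the tie sum running over tied value groups. This is the common
convention among the minor variants of the tie term; for two groups it
squares exactly to the Kruskal–Wallis H, which the tests exploit as an
independent cross-check. Benjamini–Hochberg adjustment is applied within one
outcome's pairwise family, not across outcomes. Trend tests are weighted
least squares with indicator coding against the lowest category, standard
errors from the weighted residual variance — the conventional layout for
wealth-gradient tables. Respondents with missing wealth are excluded from
wealth analyses only.

SSB servings divide sugar-sweetened-beverage grams by a 240 g serving, a
round one-cup convention; it is a parameter because serving definitions
vary between surveys.

## What the synthetic world emulates

The generator exists so that every module is testable without any
restricted survey data. Its defaults are fixed once, as study conditions:

* **1547 foods** in a 12-group taxonomy, with ~19.5% zero-total-sugar foods,
  ~43% in zero-free-sugar groups, ~10% in all-free-sugar groups and ~27%
  mixed recipes for the model step — the step profile of a real national
  FCT.
* **Mixed recipes** are Dirichlet-weighted combinations of 2–5 ingredient
  archetypes (flour, rice, milk, fruit, vegetable, egg, meat, coconut,
  butter/oil as intrinsic-sugar sources; table sugar, honey, syrup, juice
  concentrate as free-sugar sources). True free sugar is the sugar
  contributed by the free-type ingredients.
* **Analytic noise** is multiplicative lognormal with sd 0.05 on the
  nutrient totals, applied *after* the ground truth is fixed, so the
  learning task has irreducible noise like real analytic data. Total sugar
  is floored at the true free sugar so the defining constraint FS ≤ TS
  survives the noise; setting `noise_sd = 0` makes the construction exact
  and enables exact oracles in tests.
* **The survey** draws three main meals plus probabilistic snack occasions;
  snack occasions preferentially pick free-sugar-rich foods, and serving
  sizes scale inversely with sugar concentration (concentrates by the
  spoonful, staples by the plate). Survey weights are lognormal and
  independent of wealth, so weighted estimators stay unbiased.
* **The wealth gradient** is planted as extra sweetened-beverage
  consumption whose expected free-sugar contribution equals the configured
  per-quintile offset exactly — default (0, 2.5, 5, 6, 9) g/day — giving
  trend models a known estimand. Setting all offsets to 0 plants no
  gradient, which is the null-calibration condition.

What the generator does **not** emulate: real marginal nutrient
distributions, correlated food co-occurrence within meals, seasonality,
day-of-week effects, or under-reporting. Passing tests therefore demonstrate
that the pipeline's logic and estimators are correct and well calibrated
under a faithful data-generating structure, not that any particular
real-world accuracy is guaranteed.

## Problem sizes and calibration checks

The recovery suite trains on a 3000-food synthetic table and evaluates on a
held-out 600-food table generated with different seeds, reporting Pearson r
and MAE on the model-step foods. The gradient battery runs 100 planted and
100 null survey replicates over a 400-food world with the default 800
respondents; coverage is counted per (replicate × coefficient), the reading
under which an unbiased design has ~95% expected coverage (requiring all
four coefficients jointly would push expected coverage to ~0.95^4 ≈ 81% for
any correct estimator). These sizes are the package's chosen desk-scale
study conditions; they complete in a few minutes on one CPU.

## Numerical choices and edge cases

* Duplicate `food_id`s are integrity errors everywhere; unparseable numeric
  cells become missing with a warning, never zero.
* `total_sugar` above 105% of carbohydrate is a logged warning (rounding in
  source tables makes small overshoots legitimate), not an error.
* A constant training response short-circuits every base learner to an exact
  constant predictor (support vector regression would otherwise have no
  support vectors at all).
* NNLS can return the all-zero weight vector when every learner is
  anti-correlated with the response; the stack then falls back to the best
  single learner with a non-negative 1-D least-squares weight, preserving
  the invariant that at least one weight is positive.
* Model files are versioned R serializations; loading anything else, or a
  different format version, is an explicit format error.
* Adult BMI categories default to the standard cutoffs (<18.5, 18.5–24.9,
  25–29.9, ≥30) and BAZ categories to the WHO 2007 z-score bands; both may
  be supplied precomputed, which is how the survey generator provides them.

## Known limitations

The model is trained on whole-food databases, not packaged products with
ingredient lists; taxonomy matching is exact, not fuzzy; and single-recall
intakes are not usual intakes. The published step-group lists are encoded as
shipped defaults, but any real application should review them against the
local taxonomy before annotating.
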