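---
title: "Iterative thematic analysis of wide survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative thematic analysis of wide survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National demographic and health surveys are *wide*: a single respondent
record can carry thousands of variables spanning household economics,
health-care access, knowledge, attitudes and violence exposure. When the
outcome of interest is rare — here, non-marital sexual violence (NMSV),
reported by roughly 1% of respondents — classical hypothesis-driven
regression forces the analyst to pre-select a handful of candidate
correlates and discard the rest of the instrument. `itaml` implements the
opposite strategy: let regularized models screen *every* variable, and let
a structured, auditable elimination loop surface the thematic structure of
the correlates.

The outcome is constructed from two survey items: an ever-forced-sex flag
and a set of perpetrator indicators. A respondent is NMSV-positive iff the
flag is yes **and** at least one indicated perpetrator is not a (former)
husband; husband-only violence is marital violence and is coded as "no",
as is the (rare) case of a yes flag with no perpetrator indicated, since
no non-husband perpetrator is on record. Rows with a missing flag are
excluded and reported, never silently imputed.

## The staged model

Each analysis round fits two regularized logistic regressions on the
one-hot encoded design \(X \in \mathbb{R}^{n\times p}\):

1. **Lasso screen.** Minimize
   \(-\tfrac1n \ell(\beta_0, \beta) + \lambda \lVert\beta\rVert_1\).
   The L1 penalty sets most coefficients exactly to zero; only the
   survivors (strictly \(|\hat\beta_j| > 10^{-8}\)) advance.
2. **Ridge ranking.** Refit on the survivors with
   \(-\tfrac1n \ell(\beta_0, \beta) + \tfrac{\lambda}{2}\lVert\beta\rVert_2^2\).
   Every survivor keeps a finite, generically nonzero coefficient, so the
   magnitudes support a total ranking.

Both penalties are chosen by 5-fold stratified cross-validation maximizing
AUC over a log-spaced grid \(10^{-4} \dots 10^{2}\) (the published
analysis does not print its penalty values, so standard CV practice is
used; grid and folds are configuration options). The fits are delegated to
coordinate descent in `glmnet` with internal standardization disabled —
the design is already 0/1 indicators plus standardized numerics — which
keeps the objective exactly the one above; the test-suite verifies the
solutions against from-scratch proximal-gradient and BFGS
penalized-likelihood optimizers to `1e-6`.

Ranking is on **absolute** coefficient values by default: protective and
risk correlates are equally interesting, and a signed ranking would bury
strong protective factors at the bottom of the curve. A `signed_ranking`
flag restores the signed ordering.

## Knee-point selection

Sorted magnitudes \(y_1 \ge \dots \ge y_p\) over ranks \(x = 1..p\) form a
curve whose "knee" separates the informative head from the shrunken tail.
The knee is the interior rank maximizing the discrete curvature

\[\kappa_i = \frac{|y''_i|}{(1 + y_i'^2)^{3/2}},\]

with \(y'\), \(y''\) the central first and second differences. Numerical
choices, fixed once:

* **No smoothing by default** (`smoothing_window = 1`): the curvature
  definition is applied to the raw ranked values; a centered moving
  average is available when coefficient curves are noisy.
* **Ties**: the earliest rank wins the curvature argmax.
* **Selection is strict**: features with magnitude strictly greater than
  the magnitude *at* the knee are kept, so the knee feature and anything
  tied with it are excluded; `knee_inclusive = TRUE` switches to the
  rank-prefix-inclusive reading. Either way the selection is a prefix of
  the ranking.
* **Degenerate curves**: if the maximal curvature is below `1e-12` (an
  affine curve), there is no knee; all features are kept and the result is
  flagged, rather than fabricating a cut.
* Rankings shorter than 4 cannot support central differences; the loop
  keeps all features in that case and flags the selection as degenerate.

## The iterative thematic analysis loop

A *theme map* — a declarative file assigning each source variable to one
or more named themes — stands in for the study's two-coder qualitative
step. (The companion `theme_map_agreement()` utility computes percent
agreement between two independently authored maps, mirroring an
inter-coder reliability check; the package does not attempt automated
theme induction.) Each iteration:

1. lasso → ridge → ranking → knee selection, as above;
2. selected features are grouped by source variable into themes; a theme
   **qualifies** when it holds at least
   \(\lceil 0.05 \times n_{\text{selected}}\rceil\) of the selected
   features (multi-theme variables count in every theme they map to;
   variables missing from the map are reported in an `<uncategorized>`
   bucket that never qualifies or gets dropped);
3. test-set AUC and BER are recorded;
4. stopping rules are checked **in order**: test AUC below 0.65 → stop;
   no variable selected that was not selected in some earlier iteration →
   stop; no new qualifying theme for 3 consecutive iterations → stop; a
   hard `max_iterations = 20` cap (not part of the published procedure)
   guards against pathological configurations;
5. otherwise the dominant theme is dropped: the qualifying theme holding
   the top-ranked selected feature, with ties across themes broken by the
   larger total coefficient mass (an alternative `max_variance` rule drops
   the qualifying theme whose member coefficients are most dispersed).
   Only the theme's *selected* (above-knee) members are removed from the
   design — they are the features "attached" to the theme this round —
   so other encodings of the same variables may legitimately resurface
   later. The dropped features never reappear.

Design choices worth making explicit, since the procedure admits several
readings: the stop-rule AUC is the **test-set** AUC of the current ridge
model, evaluated after the refit and before the drop; a "new theme" is
one that qualifies now and never qualified before; a "new variable" is a
selected feature absent from all earlier selections. If no theme qualifies
at step 5 the loop cannot proceed and terminates; the final record's empty
qualifying-theme set documents why. If a later iteration's lasso retains
nothing, the empty selection adds no new variables and the loop stops with
that reason (an empty *first* lasso aborts with diagnostics instead).

The full per-iteration audit record — feature counts, selections,
qualifying/new themes, the dropped theme, metrics — serializes to JSON
Lines via `write_trace()`, and the stopping reason is re-derivable from
the serialized records alone with `check_stop()`.

## Evaluation under extreme imbalance

At ~1% prevalence, accuracy is meaningless. The package evaluates with:

* **AUC**, computed exactly by the midrank (Mann–Whitney) identity — the
  probability a random positive outscores a random negative, ties at
  one-half;
* **BER** \(= 1 - \tfrac12(\text{TPR} + \text{TNR})\), the
  prevalence-insensitive average of the class error rates.

BER needs a hard threshold the published analysis never states; the
default is 0.5 on the probability scale, recorded in every trace record.
At very low prevalence a well-calibrated model rarely crosses 0.5, so the
default BER is conservative (≈0.5); analysts comparing thresholds should
set `ber_threshold` near the outcome prevalence. AUC, which needs no
threshold, is the primary metric throughout, as it is in the loop's
stopping rule.

## The neural cross-check

A second, independent route guards against the staged linear models
missing non-linear structure. The same lasso screen feeds a small
feed-forward network: two hidden layers (64, 32 units — the published
description fixes activation, normalization, epochs and batch size but
not the architecture, so a conventional small funnel is used), `tanh`
activations, batch normalization after each hidden affine map, 100
epochs of minibatches of 100, and a `tanh` output unit affinely mapped to
\([0,1]\) via \((a+1)/2\), trained on binary cross-entropy. The optimizer
is a stochastic gradient method with fixed step `1e-3`; Adam is the
default (plain SGD at that fixed step learns too slowly to be a useful
cross-check within 100 epochs), with `optimizer = "sgd"` available. All
initialization and batch shuffling derive from one seed, so training is
exactly reproducible; the analytic gradients, including the batch-norm
backward pass, are verified against numerical differentiation in the test
suite. Trailing minibatches of a single row are skipped (batch
normalization is undefined there).

How per-feature scores were obtained for the published network is not
stated; the package's default is **permutation importance** on the test
split — the mean AUC drop over 10 independent shuffles of one feature at
a time — which is model-agnostic and directly comparable to the ridge
ranking. An alternative `nn_first_layer_importance()` scores features by
the L2 norm of their first-layer weights. The knee rule then cuts the
sorted importance curve exactly as it cuts the coefficient curve.

## The synthetic generator

The real microdata are registration-restricted, so validation runs on
synthetic tables that emulate their *structure*, with signal planted where
the analysis claims to find it: in themes.

Per theme \(t\), each respondent draws a latent factor
\(z_t \sim \mathcal N(0,1)\); every variable in the theme is the
quantile-binned categorical of \(\rho z_t + \sqrt{1-\rho^2}\,\varepsilon\)
(marginally standard normal, so bins are balanced); the outcome is
Bernoulli\((\text{logistic}(\beta_0 + \sum_t \beta_t z_t))\) with
\(\beta_0\) calibrated by Monte-Carlo bisection (`solve_intercept`,
100,000 draws, tolerance `1e-4` on the achieved prevalence). Missingness,
when requested, is completely at random; informative missingness is out
of scope. Signal is planted at the theme level rather than per variable
because the analysis reads its results thematically; setting \(\rho = 0\)
recovers independent per-variable noise.

The reference scenario `synthetic_config_s1()` — 20,000 rows, 10 themes
of 10 three-category variables (\(\rho = 0.6\)), 3 informative themes at
0.8 log-odds per latent unit, 2% prevalence — is sized so that a full
ITA run plus the neural cross-check completes in a few minutes on one
core while still exhibiting the wide-data, rare-outcome regime. On it,
the pipeline's iteration-1 test AUC lands around 0.8, all three planted
themes qualify, and the selected variables recover the informative set
with high recall and precision (the exact figures are computed by
`scripts/acceptance.R` and the test suite, never quoted from memory).

What passing on synthetic data does **not** show: robustness to
informative missingness, survey design effects (weights, stratification,
clustering — out of scope throughout), measurement error correlated with
reporting willingness, or themes whose real-world variables are far more
heterogeneous than one shared latent factor. Results on real survey data
depend on the quality of the analyst's theme map in a way no generator
can emulate.

## Worked example

```{r, eval = FALSE}
library(itaml)

gen <- generate_wide_survey(synthetic_config_s1())
design <- one_hot_encode(gen$table)
split <- split_train_test(design, gen$truth$labels, fraction = 0.2, seed = 11)

trace <- run_ita(design, gen$truth$labels, split, gen$theme_map,
                 ita_config(seed = 11))
ita_report(trace)
trace$stop_reason

nn <- nn_pipeline(design, gen$truth$labels, split, nn_config(seed = 11),
                  seed = 11)
nn$metrics$auc
head(nn$importance)
```

## Known limitations

* BER at the default 0.5 threshold is uninformative at ~1% prevalence
  (see above); it is reported for completeness, with the threshold
  config-exposed.
* The knee rule assumes the ranked curve has a single dominant bend;
  multi-elbow curves resolve to the sharpest one.
* Dropping only above-knee members means a theme can be dropped in
  several consecutive iterations as deeper members surface; this is by
  design (the audit trace records each drop) but lengthens traces on
  strongly redundant themes.
* The network is a cross-check, not a production classifier: no
  early stopping, no hyperparameter search, single-core training.
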