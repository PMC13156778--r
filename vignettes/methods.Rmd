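---
title: "Methods: surrogate modelling and optimization of ultrasonic extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate modelling and optimization of ultrasonic extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoptim)
```

This vignette explains the models and procedures behind `sonoptim`, the
choices that were genuinely open when the package was designed, and what the
test suite does and does not establish about real extraction data.

## The experimental design

Six process factors govern ultrasonic-assisted alkaline extraction of
fungal polysaccharides:

| factor | units | center | step / coded unit | reported decimals |
|---|---|---|---|---|
| soaking time | min | 120 | 60 | 1 |
| NaOH concentration | mol/L | 0.5 | 0.1 | 2 |
| ultrasonic time | min | 30 | 10 | 1 |
| liquid–solid ratio | mL/g | 25 | 5 | 1 |
| ultrasonic power | W | 400 | 100 | 1 |
| ultrasonic temperature | °C | 60 | 10 | 1 |

`ccd_design()` builds the full central composite design: all $2^6 = 64$
factorial corners at coded $\pm 1$, twelve axial runs at $\pm\alpha$ on one
axis each, and ten center replicates — 86 runs. The axial distance uses the
*practical* rule $\alpha = k^{1/4} = 1.5651$. This was a design decision
worth recording: the rotatable rule for a full $2^6$ factorial would give
$\alpha = 64^{1/4} = 2.83$, which is inconsistent with every published
five-level table for this system, while $k^{1/4}$ reproduces all twelve
axial levels to their printed rounding. Reported actual levels round half
away from zero at each factor's printed precision.

A second documented conflict: the published five-level table labels the
rows in a different factor order (liquid–solid ratio as the third symbol,
ultrasonic time as the fifth) than the accompanying text and the ANOVA
significance discussion. The text order is the only mapping under which the
significance statements are coherent, so this package uses it throughout:
the third factor is ultrasonic time and the fourth the liquid–solid ratio.

Run order is shuffled by a seeded Fisher–Yates pass; the *set* of runs is
seed-independent, so models fit on the same design regardless of the seed.

## The synthetic truth

The generator (`crp_yield_surface()` + `simulate_yield()`) emulates the
study conditions the analysis assumes, not extraction chemistry:

* the mean response is the published fitted second-order polynomial in
  coded units (intercept 19.33% at the center point);
* noise is i.i.d. Gaussian with variance 0.4023 (sd 0.6343 yield points),
  the pure-error mean square over the ten center replicates, applied
  homoscedastically; the mild heteroscedasticity the original diagnostics
  detected at extreme yields is deliberately not modelled.

One coefficient required a correction. The printed soak-by-power
interaction (0.780) is inconsistent with its own ANOVA line: on this
orthogonal design an interaction's sum of squares is $b^2 \cdot 64$, and
the printed SS 0.3891 matches $0.078^2 \cdot 64$, not $0.78^2 \cdot 64 =
38.9$. The stored surface therefore uses 0.0780; the as-printed variant
remains selectable (`variant = "as_printed"`). A second, smaller
inconsistency (the NaOH linear SS of 1.22 implies a coefficient near 0.133
rather than the printed 0.1802) is *not* corrected: the printed coefficient
is retained as the truth and the discrepancy simply noted, because there is
no second equation to arbitrate it.

Because the generating surface lies inside the fitted model family, a
noise-free simulation is recovered exactly by OLS (the suite checks
agreement to $10^{-8}$), and with noise the coefficient estimates cover the
truth at their nominal 95% rate.

## Response-surface model and ANOVA

`fit_rsm()` fits all 28 coefficients by OLS in coded space. The ANOVA
(`rsm_anova()`) reports partial (Type-III) per-term sums of squares
$b_j^2 / [(X'X)^{-1}]_{jj}$ — the convention of the commercial DOE software
whose output the published table reflects — with a sequential (Type-I)
option. Pure error is pooled within replicated design points (here, the
ten center runs, df 9), lack of fit takes the remaining residual df (49),
and their mean-square ratio is tested against $F_{49,9}$. Predicted $R^2$
uses PRESS residuals $e_i/(1-h_{ii})$; observations with numerically unit
leverage are excluded with a warning. Per-term F statistics reproduce a
printed ANOVA only to within the rounding of its printed sums of squares
(roughly $\pm 0.25$ on F), which is why the tests pin the *arithmetic*
(lack-of-fit F from SS and df, $R^2$ from SS) rather than refitted values.

## The ε-SVR dual solver

The SVR is the package's core algorithmic component, written from scratch.
With net dual coefficients $\beta_i = \alpha_i - \alpha_i^*$ the dual is

$$\max_\beta\; y^\top\beta - \varepsilon \|\beta\|_1 -
\tfrac12 \beta^\top K \beta
\quad \text{s.t.}\quad \textstyle\sum_i \beta_i = 0,\; |\beta_i| \le C,$$

with $K_{ij} = \exp(-\gamma\|x_i - x_j\|^2)$ on min–max-scaled features.
The solver is SMO with exact pair subproblems: the gain along
$e_i - e_j$ is piecewise-concave-quadratic, and its maximizer is found by
evaluating box endpoints, the two sign breakpoints and the per-sign-pattern
stationary points. Pair selection anchors on the maximal KKT violators and
takes the partner with the largest exact gain.

Three numerical choices matter:

* **Stopping rule.** Convergence is declared on the *duality gap* below
  `tol` (default $10^{-6}$), with the primal bias chosen to minimize the
  primal exactly (the slack sum is piecewise linear in $b$; its minimizing
  set is an interval whose endpoints are residual breakpoints, and the
  midpoint is reported — this also makes the bias well-defined when no
  support vector is free).
* **Cache refreshing.** The incremental cache $f = K\beta$ accumulates
  rounding over long runs; it is recomputed exactly every 1024 updates,
  without which the gap plateaus above tolerance at large $C$.
* **Active-set finish.** On ill-conditioned Gram matrices (wide kernels,
  large $C$) SMO's tail convergence is slow. If the iteration cap is hit,
  an exact active-set refinement solves the KKT system on the free set
  (free residuals pinned at $\pm\varepsilon$), demotes box violators one at
  a time, and accepts candidates only when the dual improves. One or two
  passes close the gap to near machine precision.

The reported bias averages the KKT value over free support vectors when any
exist. Support vectors are the points with $|\beta_i| > 10^{-8} C$. The
solver is validated two independent ways: against an exhaustive KKT
pattern-enumeration QP oracle on $n \le 6$ instances (objective and
predictions to $10^{-6}$ and far beyond), and against a widely used libsvm
binding on larger random instances (prediction RMS below $10^{-3}$).

## Hyperparameter search

`svr_tune_nested()` runs nested five-fold cross-validation over the fixed
grid $C \in \{0.1, 1, 10, 100, 1000\}$, $\gamma \in
\{0.001, 0.01, 0.1, 1, 10\}$, $\varepsilon \in \{0.001, 0.01, 0.1, 1\}$
(100 combinations per fold). The inner loop minimizes mean validation
RMSE; ties break toward smaller $C$, then larger $\varepsilon$ — the
flatter model. Outer folds are scored by refitting at each fold's winner.
The aggregation of fold winners into one final setting was unspecified in
the source workflow; this package takes geometric means for $C$ and
$\gamma$ (they live on log-spaced grids), the arithmetic mean for
$\varepsilon$, and snaps each to the nearest grid value (log-scale nearness
for $C$, $\gamma$). Throwaway inner-grid fits use a relaxed gap tolerance
($10^{-3}$): ranking fold RMSEs does not require tight duality gaps, and
the outer refits and final model go back to $10^{-6}$.

Only the features are scaled; the response stays in yield percent. The
published error metrics are in yield-percent units, which supports this
reading, and it keeps every RMSE in the package interpretable. (The
source's reported cross-validation RMSE of 0.1383 against a test RMSE of
0.5813 in the same nominal units is most plausibly a normalized-scale
value; this package reports CV RMSE in yield percent.)

## Importance fusion

Three per-feature scores are computed on the scaled training data:

* permutation importance $(RMSE_j - RMSE_0)/RMSE_0$, averaged over
  `n_rep = 30` seeded permutations;
* the dynamic range of the partial-dependence curve, computed over the
  empirical distribution of the other features (not a uniform joint) on a
  50-point grid, normalized so ranges sum to one across features;
* support-vector contribution $\sum_{i \in SV} |\beta_i| x_{ij}$,
  normalized across features. The source formula's weight is typeset
  ambiguously; it is read here as the absolute net dual coefficient.

Each score vector is min–max normalized across features — the
normalization domain was unspecified, and across-features scaling is the
choice that makes the three scores commensurate — then fused with weights
(0.50, 0.25, 0.25) and densely ranked. Degenerate all-equal score vectors
are replaced by uniform scores with a warning rather than dividing by zero.

## Optimization and practical rounding

`maximize_surrogate()` draws a seeded Latin-hypercube of 64 starts,
polishes each with projected quasi-Newton ascent (L-BFGS-B on the negated
objective, finite-difference gradients), and keeps the best value seen
anywhere, so the result can never be worse than the best start. Bounds
default to the coded $[-1, 1]^6$ factorial box: the axial region is
star-point extrapolation territory, and published optima for this system
sit inside or on the factorial box (one published range — ultrasonic time
"40–60 min" — contradicts the design's own 20–40 min range and is treated
as a typo). The $\pm\alpha$ box is selectable. Optima are snapped to
operator-settable resolutions (1 min for times, 0.05 mol/L, 1 mL/g, 5 W,
0.5 °C — reverse-engineered from the published rounded settings), ties
rounding half away from zero, and the surrogate is re-evaluated at the
snapped point.

## Process economics

Production rate is yield per hour of total process time; specific energy
consumption is $P\,t$ over the polysaccharide mass recovered from a batch.
Two published reference cells (918.13 and 51.98 kWh/kg) pin down the batch
basis: 0.020 kg raw material, i.e. a 500 mL working volume at 25 mL/g,
with soaking treated as energy-neutral. That basis is the package default
and is configurable. The SEC denominator is polysaccharide mass, not raw
mass — the only reading under which the published cells reproduce, despite
a table footnote saying otherwise. The CO₂ emission factor defaults to the
stated grid value 0.4671 kg/kWh; the published CO₂ cells are instead
consistent with an EF of 0.8, so they are not used as checks anywhere, and
the identity $CO_2 = SEC \times EF$ is enforced exactly in reports.

## What the tests show — and what they cannot

The suite exercises the full pipeline on synthetic data at the study's
scale (86 runs, 69/17 split, 100-combination grid, 5-fold nesting;
Monte-Carlo checks use up to 10,000 draws, coefficient-coverage checks 40
seeds, importance-stability checks 10 seeded replicates with a full nested
CV each). Passing tests establish that the machinery is correct: designs
have the stated structure, the ANOVA identities hold, the dual solver is
optimal against oracles, CV bookkeeping is leak-free, and the economics
arithmetic reproduces published cells.

They cannot establish that SVR will beat the quadratic model on *real*
extraction data. Indeed, on data simulated from the quadratic surface plus
center-replicate noise, the quadratic model is the correctly specified
family and kernel regression generalizes corner-to-corner across a
six-factor hypercube comparatively poorly: nested-CV outer $R^2$ lands
around 0.55–0.8 depending on the seed, short of the high test $R^2$
reported for the original (unpublished) wet-lab dataset, and an
independent scikit-learn implementation of the same nested search gives
the same level on identical data. That shortfall is a property of the
simulated conditions, not an implementation defect, and the acceptance
suite reports it honestly rather than recalibrating the generator toward
the published figure.

Other known limitations: homoscedastic noise only; full-factorial CCDs
only (no fractional, Box–Behnken or optimal designs); box constraints only
in the optimizer; no desirability-type multi-objective composites; and the
solver targets the dense-Gram regime of designed experiments (up to a few
hundred runs), not large datasets.
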