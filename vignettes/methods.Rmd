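---
title: "Heterogeneity-aware ordered logit modelling of driver warning system crash involvement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity-aware ordered logit modelling of driver warning system crash involvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpolr)
```

## The scientific problem

Driver warning systems (DWSs) — here forward collision warning (FCWS) and
blind spot monitoring (BSM) — are designed to prevent exactly the kinds of
conflicts that produce multivehicle fatal crashes.  Yet equipped vehicles
still appear in fatal-crash records, and the analytic question is
comparative: *which driver, road and crash conditions shift fatal-crash
involvement between vehicles carrying zero, one, or two warning systems?*
The outcome is ordinal by construction (more systems, more warning
coverage), so the package models the DWS count on the crash-involved vehicle
with ordered logit regressions, upgraded to handle three distinct sources of
unobserved heterogeneity in crash data:

* **spatial** — equipped-vehicle crashes concentrate in a few metropolitan
  regions, so comparing them to the national pool of unequipped crashes
  confounds location with equipment;
* **temporal** — market penetration of equipped vehicles grew sharply over
  2016–2020, so calendar year shifts the outcome distribution mechanically;
* **behavioural** — driver attributes (age, sex, drinking) modulate crash
  risk in ways that vary from crash to crash and are correlated with one
  another.

## Pipeline and model

**Stage 1 — matched control sampling.**  Case crashes (outcome ≥ 1) are
matched to their k spatially nearest control crashes (outcome 0) by exact
great-circle search (haversine distance, Earth radius fixed at
20,902,231 ft).  k defaults to 3; `knn_profile()` reports the maximum k-th
neighbour distance as k grows, and the choice of k is deliberately left to
the analyst — the package does not claim an automatic optimum because the
trade-off (sample size versus spatial proximity) is study-specific.  Ties in
distance break by control identifier, making matching fully deterministic.
Controls selected by several cases enter the analysis sample once.

**Stage 2 — temporal coding.**  Year enters the design as the linear index
1–5 (2016–2020), not as dummies: the phenomenon being absorbed is a
monotone market-penetration trend, and a single slope keeps the estimate
interpretable as a per-year probability shift.

**Stage 3 — ordered logit with correlated random parameters.**  The latent
propensity is $y_i^* = \beta_i x_i + \varepsilon_i$ with standard logistic
error; categories are cut at $(0, \psi_1)$, the first threshold pinned at
zero for identification with an estimated intercept, and $\psi_1$ optimized
as $\exp(\delta)$ so positivity is structural.  The fixed-parameter model
($\beta_i \equiv \beta$) is both the baseline and the nested null.  The
correlated model lets the five driver-behaviour coefficients vary as
$\beta_i = \beta + \Omega \varphi_i$, $\varphi_i \sim N(0, I)$, with
$\Omega$ an unrestricted lower-triangular Cholesky factor; the implied
coefficient covariance is $\Omega\Omega'$ and off-diagonal elements carry
the correlations that distinguish this model from independent
random-parameter specifications.  Normal mixing is the only distribution
implemented, and neither the means nor the variances are themselves
functions of covariates.

The mixing integral is simulated: per observation, the ordered-logit
probability of the observed outcome is averaged over $D$ draws of
$\varphi$, and the log of that average is summed.  Estimation is
quasi-Newton (BFGS) on the simulated log-likelihood with its analytic
gradient (implemented in C++), followed by Newton polishing; standard
errors come from the inverse numerical Hessian.

## Halton draws

The simulator uses Halton sequences rather than pseudo-random draws: the
radical inverse of $1, 2, 3, \dots$ in a prime base covers $(0,1)$ far more
evenly than uniform random numbers, which lowers simulation noise at a
given $D$.  Choices the sequence itself does not pin down, fixed here as
package defaults:

* dimension $d$ uses the $d$-th prime (2, 3, 5, 7, 11 for five random
  coefficients), overridable;
* the first 10 elements are discarded (the leading elements of a Halton
  sequence are coarse and nearly collinear across bases);
* observation $i$ receives the consecutive block of $D$ elements starting
  at position $\text{discard} + (i-1)D + 1$, the conventional
  simulated-likelihood layout;
* no scrambling, shuffling or antithetic variates — the construction is
  fully deterministic, which is what makes fits byte-reproducible.

$D$ defaults to 900, the draw count at which mixed-logit estimates are
commonly reported as stable in this literature.  The package's tests use
$D$ between 50 and 200: the nesting identity (a zero Cholesky factor makes
the simulated likelihood equal the fixed-model likelihood *exactly*, at any
$D$) and a 50-node Gauss–Hermite comparison give draw-count-independent
correctness checks, so large $D$ is only needed for final estimates, not
for validating the code path.

## Marginal effects and model comparison

Coefficients on a latent scale are not directly interpretable, so the
package reports partial effects: for indicator $x_j$,
$P(Y = k \mid \bar{x}, x_j = 1) - P(Y = k \mid \bar{x}, x_j = 0)$ with all
other covariates at sample means; the numeric year index uses a +1
increment from its mean.  For the correlated model the probabilities are
draw-averages over the fitted mixing distribution.  Effects across the
three outcome categories sum to zero by probability conservation — a
built-in consistency check that holds for every variable and every fitted
model.  Effect p-values use the delta method with a numerical gradient of
the effect with respect to the full parameter vector; an
observation-averaged variant (`average_over = "observations"`) is provided
for sensitivity analysis, without p-values.

Fit is compared by McFadden pseudo-R² against the
intercept-plus-threshold null (whose maximum-likelihood value is the
closed-form entropy of the empirical shares) and by the likelihood-ratio
statistic $2(LL_{\text{corr}} - LL_{\text{fixed}})$ on
$n_r(n_r+1)/2$ degrees of freedom.  Because the null pins variance
parameters to the boundary of the parameter space, the chi-square reference
is conservative in direction; the reported p-value overstates, not
understates, the evidence needed.

## Numerical choices

* Fixed-model convergence: gradient infinity-norm below $10^{-6}$ (BFGS
  plus Newton polish); the correlated model targets $10^{-4}$ — its
  simulated surface is flatter and the gradient scales with $n$.
* The Cholesky elements are optimized unconstrained; after convergence,
  columns are sign-flipped so the reported diagonal is nonnegative.  This
  changes nothing substantive: $\Omega$ and $\Omega$ with a negated column
  imply the same $\Omega\Omega'$, and the reported log-likelihood is the
  one at the estimated parameters.
* Initialization: fixed-model coefficients for all means, $0.1 I$ for
  $\Omega$.
* Simulated probabilities are floored at $10^{-300}$ (flagged) so a
  degenerate parameter point cannot produce `log(0)`.
* "Optional" availability codes are excluded rather than coded as absent:
  an optional feature's presence on the specific vehicle is unknowable from
  the VIN.  Missing model fields cause listwise deletion, with a warning
  once the missing fraction exceeds 2% — beyond that, deletion bias is a
  real concern and the user should address missingness upstream.
* Reference levels of the dummy coding (summer; 6–9 a.m.; angle collision;
  two lanes; dry surface; tracking; principal arterial; daylight; clear
  weather; male; age 24–40; rural) are package defaults chosen as the
  modal or mid categories, overridable through the variable dictionary.

## The synthetic generator, and what passing tests do and do not show

No public, redistributable version of the study data (fatal-crash records
merged with VIN-decoded equipment codes) exists, so the package treats the
data-generating process itself as a first-class object.
`scenario_config()` defaults encode the published sample: covariate
category marginals from the descriptive table; the published correlated
model coefficients, Cholesky factor and threshold (1.644) as the true
parameters; years distributed with rising weight (0.08, 0.12, 0.18, 0.26,
0.36 over 2016–2020) to emulate the growing penetration of equipped
vehicles; coordinates from an east-coast-heavy mixture of six metropolitan
Gaussian clusters.  A design-time check at n = 200,000 confirms this DGP
implies outcome shares within about one point of the published 72.7 / 18.6
/ 8.7 split.  `scenario_compact()` is a reduced variant for recovery
experiments (constant, year, urban, intersection, speeding plus the five
random columns) whose constant (−3.50) was calibrated once, analytically at
large n, to preserve those shares under the smaller covariate set.

Generation draws covariates independently across variables (only marginals
are published), pseudo-random — not Halton — coefficients (so estimation
draws can never alias generation draws), and logistic latent noise.  What
the generator does **not** emulate: covariate dependence (urban area and
lane count are independent here, certainly not in real data), the native
multi-file structure of fatal-crash databases, road-network geography
beyond cluster blobs, and any spatial correlation in the *outcome* beyond
what covariates induce.  Consequently, passing parameter-recovery tests
demonstrates that the estimator recovers a known DGP of the published form
at the published scale — it does not certify behaviour under real-world
covariate dependence or spatial confounding, which is exactly why the
matched-sampling stage exists.

## Problem sizes used by the tests and acceptance script

The estimator validation suite runs, per choice: oracle equivalence of the
fixed model against an independent MLE at n = 2000; the nesting identity at
D ∈ {1, 10, 900}; Gauss–Hermite agreement with one random coefficient at
D = 5000; and a 20-replicate recovery experiment at n = 5000 and D = 200
with all five random means and all five covariance diagonals required
within 3 standard errors of truth — a deliberate scale-down from the
study's n ≈ 8757 and D = 900 that keeps the full suite in the
single-digit-minute range while preserving the identification structure
(five correlated random parameters, 15 free Cholesky elements).  The
acceptance script fits the full-covariate scenario at n = 8757 with
D = 900.

## Known limitations

* **Variance boundary pile-up.**  In occasional replicates the likelihood
  is maximized with a Cholesky row near zero; the delta-method standard
  error of that covariance diagonal then collapses, and Wald-style
  intervals around it are meaningless (this is the variance-component
  boundary problem, not an optimizer failure — restarts from larger factors
  reach the same likelihood).  The likelihood-ratio caveat above is the
  same phenomenon on the testing side.
* Standard errors come from the inverse Hessian of the *simulated*
  likelihood; simulation noise at small D leaks into them.
* The k-selection criterion for matching is exposed as a profile, not
  automated.
* One row is one vehicle-in-crash; crashes contributing two equipped
  vehicles appear as two rows, with no within-crash correlation term.
* Injury severity is out of scope; the outcome is equipment count, not
  harm.
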