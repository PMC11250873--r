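# crpolr

Correlated random parameters ordered logit models for studying how in-vehicle
driver warning systems (DWSs) — forward collision warning (FCWS) and blind
spot monitoring (BSM) — relate to multivehicle fatal crash involvement.

The package is aimed at traffic-safety and crash-epidemiology analysts working
with vehicle-level fatal-crash records whose VINs have been decoded to
equipment availability codes (`Standard` / `Optional` / `Not Available`).
It implements a three-stage pipeline that addresses three sources of
unobserved heterogeneity:

1. **Spatial** — crashes involving DWS-equipped vehicles are rare (< 3% of
   fatal crashes) and spatially clustered, so control crashes (no DWS) are
   sampled from the spatial neighbourhood of each case by exact great-circle
   k-nearest-neighbour matching (default k = 3).
2. **Temporal** — the crash year enters the model as a linear trend index
   (1 for 2016 through 5 for 2020), absorbing the rising market penetration
   of equipped vehicles.
3. **Behavioural** — driver-related coefficients vary across observations as
   correlated random parameters.

## The model

The outcome is the number of warning systems on the crash-involved vehicle,
y ∈ {0, 1, 2} (none / either / both), modelled through a latent propensity

```
y*_i = β_i x_i + ε_i,          ε_i ~ logistic
y_i  = 0 if y*_i ≤ 0,   1 if 0 < y*_i ≤ ψ₁,   2 if y*_i > ψ₁
```

with the first threshold fixed at zero (an intercept is estimated) and ψ₁ > 0
free.  In the fixed-parameter baseline β_i = β for all i.  In the correlated
random parameters model the driver-behaviour coefficients (drink-and-drive,
female, and three driver age bands by default) vary as

```
β_i = β + Ω φ_i,        φ_i ~ N(0, I)
```

where Ω is an **unrestricted lower-triangular Cholesky factor**, so the
coefficients are multivariate normal with covariance ΩΩ′ and free
correlations.  The likelihood integral over φ is approximated by simulated
maximum likelihood with **Halton draws** (default D = 900 per observation,
prime bases 2, 3, 5, 7, 11), maximized by quasi-Newton iteration with the
analytic simulated gradient (C++ core).  Models are compared by
log-likelihood, McFadden pseudo-R² (1 − LL/LL₀ against the
intercept-plus-threshold null) and the likelihood-ratio statistic; covariate
influence is reported as partial effects
`P(Y = k | x̄, x_j = 1) − P(Y = k | x̄, x_j = 0)` per outcome category, which
sum to zero across the three categories.

Because the original FARS + VIN-decoder extract is not redistributable, the
package ships a fully specified synthetic generator
(`scenario_config()` / `generate_crash_table()`) whose defaults reproduce the
published sample's covariate marginals and use the published model estimates
as the data-generating process, so every stage is testable end to end by
parameter recovery.

## Worked example

```r
library(crpolr)

cfg   <- scenario_compact(n = 2000, seed = 7)   # synthetic study scenario
tab   <- generate_crash_table(cfg)
flt   <- apply_filters(tab)                     # multivehicle, decoded, complete
design <- encode_design(code_temporal(flt$records))

fit_f <- fit_fixed(design)                      # fixed-parameter ordered logit
fit_c <- fit_crp(design, crp_spec(D = 200), fixed = fit_f)
likelihood_ratio_test(fit_f, fit_c)
#> Model comparison (fixed vs correlated random parameters)
#>   logLik fixed: -1431.653   logLik correlated: -1423.069
#>   McFadden pseudo-R2: 0.065 vs 0.071 (null logLik -1531.320)
#>   LR statistic 17.168 on 15 df, p = 0.3089

marginal_effects(fit_c, design,
                 variables = c("year_index", "female", "drink_drive"))
#>     variable effect_y0  p_y0 effect_y1  p_y1 effect_y2  p_y2
#>   year_index    -0.113 0.000     0.082 0.000     0.031 0.000
#>       female    -0.102 0.000     0.074 0.000     0.028 0.021
#>  drink_drive     0.059 0.080    -0.046 0.056    -0.012 0.298
```

Reading the output: the correlated model dominates its nested fixed baseline
(it always must at the optimum), and the pseudo-R² gap mirrors the size of
the behavioural heterogeneity.  The year trend shifts probability away from
unequipped vehicles (−0.113 per year for y = 0) toward one or two systems;
female drivers show the same direction; drink-and-drive involvement shifts
probability toward unequipped vehicles.  Each variable's three effects sum
to zero — probability is conserved across the outcome categories.

A command-line front end over the same stages (subcommands `describe`,
`match`, `simulate`, `fit`, `effects`, `recover`) is installed at
`inst/cli/crpolr-pipeline.R`.

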