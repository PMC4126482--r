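# thoriarv

Injury risk functions and injury assessment reference values (IARVs) for
occupant-protection analysis of spacecraft launch aborts and landings with
the THOR anthropomorphic test device.

Capsule landings subject a seated crew to transient impact loads. Protection
requirements are expressed as limits on quantities measured on an
instrumented crash dummy: for each injury metric, the IARV is the
dummy-measured value at which the probability of an AIS ≥ n injury
(abbreviated injury scale severity n or worse) equals an agreed acceptable
probability — 5% nominal / 19% off-nominal for minor (AIS 1+) injuries down
to 0.03% / 0.1% for severe (AIS 4+) ones. This package implements, for
researchers and engineers working on crew injury criteria:

* **Risk models** — the full family of parametric dose–response forms with
  forward (`injury_risk()`) and closed-form inverse (`iarv()`) evaluation:
  Weibull (head `p = 1 − exp(−(HIC/671)^4.34)`, rotational brain criterion,
  age-dependent shoulder), ordered probit (neck tension, chest deflection,
  ankle inversion/eversion, `p(AIS ≥ n) = 1 − Φ(c_n − βx)`), logistic
  (acetabulum, dorsiflexion, forearm moments, distal forearm speed), the
  neck-compression covariate tolerance model, the log-linear spinal-risk
  chain in the dynamic response index (`p% = 10^((DRI−15.8)/3.73)`), hip
  fracture and fracture-risk-index models, and the regulatory (FMVSS/NCAP)
  chest curves.
* **Signal metrics** — `hic15()` (sliding-window head injury criterion,
  exactly equivalent to an all-pairs window enumeration), `bric()`,
  `adfs()` and `adfs_mass_scale()`, `resultant()`, with CSV + YAML-sidecar
  channel I/O.
* **Transfer functions** — a typed catalog of the published maps between
  surrogate scales (THOR ↔ PMHS / WorldSID / EuroSID / Brinkley dynamic
  response), with direction checking and exact inversion.
* **IARV pipeline** — `build_iarv_table()` regenerates the full reference
  table from printed coefficients: risk inversion at the acceptable-risk
  ceilings, two-significant-digit half-up rounding (`round_2sf()`),
  spaceflight deconditioning (`apply_deconditioning()`, 0.86 spine / 0.75
  lower extremity), measurement evaluation with margins, and landing-mode
  threshold statistics.
* **Synthetic data** — seed-deterministic pulse and landing-severity
  generators with closed-form metric values for verification.

All user-facing functions take and return tibbles where the data are
tabular, so results chain with the pipe; fitted models support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(thoriarv)

# invert the neck-tension probit at the 5% nominal ceiling
iarv(neck_tension_model(), p = 0.05, level = 1)
#> [1] 878.3295
round_2sf(878.3295)
#> [1] 880

# regenerate the full reference table and inspect its statuses
tab <- build_iarv_table()
glance(tab)
#> # A tibble: 1 × 6
#>   n_metrics n_cells n_derived n_missing_parameter n_discrepant all_derived_match
#>       <int>   <int>     <int>               <int>        <int> <lgl>
#> 1        11      44        35                   8            1 TRUE

# compute HIC-15 on a synthetic 100 g, 20 ms constant pulse
hic15(make_pulse("constant", amplitude = 100, duration = 0.020))
#> # A tibble: 1 × 3
#>     hic    t1    t2
#>   <dbl> <dbl> <dbl>
#> 1 1500  0.005 0.02

# check measured values against the deconditioned nominal limits
evaluate_measurements(
  tibble::tibble(metric = c("hic15", "neck_tension"), value = c(339, 900)),
  population = "deconditioned", condition = "nominal")
#> # A tibble: 2 × 5
#>   metric       measured  iarv margin pass
#>   <chr>           <dbl> <dbl>  <dbl> <lgl>
#> 1 hic15             339   340      1 TRUE
#> 2 neck_tension      900   760   -140 FALSE
```

The 1,500 is the closed-form HIC of a constant 100 g pulse over the 15 ms
window cap; the table's 35 derived cells all agree with the published
reference values, the 8 `missing-parameter` cells (BrIC, neck compression)
mark coefficients that were never published, and the single
`paper-discrepancy` cell is the off-nominal thoracic-spine limit, where the
computation gives 6,400 N against a printed 6,500 N — both values are
reported.

Model coefficients are embedded with citation strings and can be pinned or
overridden from a YAML/JSON file (`injury_parameters()`; a full mirror
ships in `inst/extdata/thor_injury_params.yaml`).

See the vignette (`vignettes/thor-injury-reference-values.Rmd`) for the
models, the numerical and interpretation choices, and known limitations.

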