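---
title: "Deriving THOR injury assessment reference values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving THOR injury assessment reference values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thoriarv)
library(dplyr)
```

## The problem

Crew returning from orbit in a capsule experience a transient impact at
landing whose severity is, even in the nominal case, closer to an automobile
crash than to ordinary flight loads. Occupant-protection requirements are
therefore written as limits on quantities measured on an instrumented crash
dummy — here the THOR (Test device for Human Occupant Restraint) 50th
percentile male — rather than on the human directly. Each limit, an injury
assessment reference value (IARV), is the dummy-measured value at which the
probability of an injury at or above a stated severity on the abbreviated
injury scale (AIS) equals an agreed acceptable probability.

This package implements that derivation end to end: the parametric
injury-risk functions for each body region, their closed-form inversions,
the transfers that move measurements between surrogate scales (THOR, PMHS
cadaveric surrogates, WorldSID and EuroSID side-impact dummies, and the
Brinkley lumped-parameter dynamic response), the rounding and spaceflight
deconditioning policies, and signal-level calculators for the metrics that
are defined on time histories (HIC-15, BrIC, distal forearm speed).

## Acceptable risk and landing modes

Landing severities are treated as normally distributed. Designs protect to
`mu + 1.5 sigma` for the nominal case and to `mu + 2.5 sigma` for
off-nominal; anything beyond is contingency and is not designed for.
`landing_mode_stats()` reproduces the threshold bookkeeping (share of
landings within `k` sigma, expected exceedance frequency at four flights
per year), and `sample_landings()` draws and classifies synthetic severity
samples against the same thresholds.

The acceptable-risk ceilings per injury class are:

```{r}
acceptable_risk()
```

Class I (AIS 1+, minor) tolerates 5% nominal and 19% off-nominal; class IV
(AIS 4+) tolerates 0.03% and 0.1%. Each metric's IARV is the inversion of
its risk model at the ceiling of its governing class.

## The risk-function families

Five parametric forms cover every metric; all are monotone in their metric
and all invertible forms invert in closed form.

* **Weibull** (`weibull_risk_model()`): `p = 1 - exp(-(x / scale)^shape)`.
  Used for HIC-15 (shape 4.34, scale 671), BrIC (shape 2.84, per-level
  scales), and, with an age-dependent scale, the shoulder.
* **Ordered probit** (`ordered_probit_risk_model()`):
  `p(AIS >= n) = 1 - pnorm(c_n - slope * x)` with strictly increasing cut
  points, so severities are automatically ordered. Used for neck tension,
  chest deflection, and ankle inversion/eversion.
* **Logistic** (`logistic_risk_model()`):
  `p = 1 / (1 + exp(intercept - slope * x))`, accepting either the
  intercept–slope or the location–scale parameterization. Used for the
  pelvis/acetabulum, ankle dorsiflexion, forearm moments, distal forearm
  speed, and the regulatory chest curves.
* **Covariate tolerance + logistic** (`neck_compression_model()`): the 50%
  neck-compression tolerance is linear in age, loading rate and gender;
  the logistic steepness around it was never published (see "Known gaps").
* **Log-linear DRI chain** (`dri_spinal_risk()`): spinal injury risk in
  percent is `10^((DRI - 15.8) / 3.73)`; combined with the regression of
  DRI on THOR spine force, this yields the thoracic-spine limits.

A worked inversion, the nominal neck-tension limit:

```{r}
iarv(neck_tension_model(), p = 0.05, level = 1)  # 878.3 N -> tabulated 880
```

## Numerical and interpretation choices

Several choices were genuinely open and are fixed here as follows.

* **DRI risk is in percent.** The log-linear law is read with `p = 1` at
  DRI 15.8 (1% risk). Under this reading the nominal chain gives 5.80 kN,
  matching the published table; reading `p` as a fraction does not.
* **Which spine regression to invert.** Two near-inverse regressions relate
  DRI and spine force (`DRI = 3.62 Fz - 2.59` and `Fz = 0.277 DRI +
  0.795`). Both are exposed in `transfer_catalog()`; the pipeline inverts
  the first, the only choice that reproduces the tabulated 5,800 N.
* **Natural logarithm in the dorsiflexion inversion.** The closed form
  `60.23 - 9.217 * log(1/p - 1)` reproduces the published 18 and 31 Nm only
  with the natural log, so that base is used.
* **Rounding is two significant digits, half up.** Implemented directly
  (`round_2sf()`), because banker's rounding (`signif()`) turns 16.5 into
  16 and cannot reproduce the published deconditioned ankle cells (17, 14).
* **Deconditioning multiplies the rounded value.** The spine factor 0.86
  and lower-extremity factor 0.75 are applied to the already-rounded
  conditioned IARV and re-rounded. Applying them before rounding gives 880
  instead of 860 for off-nominal neck tension; the published table is only
  reproducible with round-then-decondition.
* **The 1.38 THOR/PMHS neck gain is not in the tabulation path.** The
  tabulated 880 N matches the un-scaled probit inversion; the transfer
  remains available in the catalog for users who need to move PMHS data
  onto the THOR scale.
* **Hip-posture grouping.** In the hip fracture model the posture factor
  `1 - (flexion - abduction)/100` multiplies the stature term inside the
  logarithm. The grouping is isolated inside `hip_fracture_model()` so the
  alternate reading is a one-line change. Note the factor is 1 when the two
  angles are equal, and 0.85 at the neutral posture (30°, 15°).
* **Covariate defaults.** Shoulder limits default to age 56 (the eldest
  male astronaut — the lowest, hence most conservative, limit) and the
  neck-compression loading rate to 2 m/s, the conservative selection for
  capsule landings.
* **BrIC axis peaks are decoupled in time.** The criterion combines the
  per-axis maxima of |angular velocity| wherever they occur, which is the
  published definition's reading and makes the criterion invariant to axis
  sign flips.
* **No default filtering.** No corner-frequency-class filter is specified
  for the signal metrics, so none is applied; `hic15()` exposes a
  `prefilter` hook that defaults to pass-through.

## Signal metrics

`hic15()` maximizes the average-acceleration functional over all windows up
to 15 ms. Integration is trapezoidal on the native, possibly non-uniform
time base, and window endpoints are restricted to sample times, which makes
the efficient cumulative-integral search exactly equivalent to an
enumeration of all admissible sample-time windows — the oracle the test
suite holds it to. Acceleration must be supplied as a non-negative
resultant in g (units are declared per channel and checked).

```{r}
pulse <- make_pulse("constant", amplitude = 100, duration = 0.020)
hic15(pulse)  # closed form: 100^2.5 * 0.015 = 1500
```

`bric()` needs the three angular-velocity channels and their critical
values (66.3, 53.8, 41.5 rad/s for X, Y, Z); `adfs()` reduces a forearm
speed trace by peak or windowed time average — the source literature
alternates between the two readings, so both are exposed, with peak as the
default — and `adfs_mass_scale()` moves an ADFS value between arm masses
(identity at the 2.67 kg reference arm; the THOR arm is 4.27 kg).

## What the synthetic data emulate — and what they do not

`make_pulse()` generates the smooth unimodal pulses (haversine, half-sine,
trapezoid, constant) characteristic of capsule-landing sled channels, at a
default 10 kHz sampling rate typical of crash-channel capture, with
optional additive Gaussian noise that is off by default so closed-form
oracle tests are exact. Generators are seed-deterministic and restore the
caller's RNG state; fixtures regenerate bit-identically.

Real sled channels differ in ways these fixtures deliberately ignore:
multi-modal ringing, sensor bias and drift, anti-alias filtering, and
coupled multi-axis kinematics. Passing the oracle tests therefore
demonstrates the correctness of the calculators on well-posed inputs, not
robustness to instrumentation artifacts — which is the appropriate scope
for verifying closed-form metric definitions.

Test problem sizes are chosen for desk-scale verification: the window-search
oracle comparison uses 200 random pulses of a few hundred samples each (the
all-pairs oracle is quadratic, and equality at these sizes is already
conclusive since both searches enumerate the same finite window set), and
the landing-fraction check uses 10^6 draws, where the Monte-Carlo standard
error of the nominal fraction is about 0.03 percentage points.

## Regenerating the reference table

`build_iarv_table()` regenerates all 44 cells (11 metrics × conditioned/
deconditioned × nominal/off-nominal). Each cell carries a status:

```{r}
tab <- build_iarv_table()
glance(tab)
tab %>% filter(status != "derived") %>%
  select(metric, population, condition, value, computed, status)
```

Statuses are the honest surface for the published table's own rough edges:

* **`missing-parameter`** — the BrIC per-level scale parameters and the
  neck-compression logistic steepness were never published. These cells
  cannot be regenerated; the published values (0.04/0.07 and 580/1,100 N
  and their deconditioned counterparts) are carried as reference constants,
  and the models error informatively if asked to derive without the gap
  being filled.
* **`paper-discrepancy`** — the off-nominal thoracic-spine chain computes
  6,398 N (rounding to 6,400) where the published table prints 6,500. The
  published value is kept as the tabulated reference (its deconditioned
  cell, 5,600, only reproduces from 6,500), the computed value is reported
  alongside, and nothing is asserted equal. Relatedly, the printed
  composite force-risk intercept (4.93) is inconsistent with the chain of
  its two parents (5.08); the package uses the parent chain, which is the
  reading that reproduces the nominal 5,800 N.

Everything else is `derived`, and every derived cell equals its published
reference after rounding.

## Known limitations

* The Brinkley single-degree-of-freedom model that produces DRI values from
  seat acceleration is out of scope; DRI is consumed as an input.
* Confidence scores (0–5) are expert judgments, stored as constants.
* No uncertainty propagation: the source risk fits are published without
  usable covariance information, so the package computes point limits only.
* The small-sample PMHS fits behind several metrics (forearm, ankle
  inversion/eversion) extrapolate poorly below about 1% risk; the
  instrumented-arm forearm fit's inverse goes negative there, which the
  package reports as an explicit clamp to zero rather than hiding.
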