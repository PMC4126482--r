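#' @importFrom stats pnorm qnorm plogis qlogis
#' @importFrom rlang abort warn .data
NULL

# internal constructor: all fitted risk models share the "injury_risk_model"
# parent class so tidy()/glance()/autoplot() dispatch uniformly
new_risk_model <- function(subclass, fields, metric = NA_character_,
                           units = NA_character_, source = NA_character_) {
  structure(
    c(fields, list(metric = metric, units = units, source = source)),
    class = c(subclass, "injury_risk_model")
  )
}

abort_domain <- function(msg) abort(msg, class = "thoriarv_error_domain")
abort_missing_parameter <- function(msg) {
  abort(msg, class = "thoriarv_error_missing_parameter")
}
abort_input <- function(msg) abort(msg, class = "thoriarv_error_input")

check_probability <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort_domain("`p` must be a probability strictly between 0 and 1.")
  }
  invisible(p)
}

#' Probability of injury at a measured metric value
#'
#' Evaluates the forward dose-response function of a fitted injury-risk
#' model: the probability of an injury at or above the requested AIS
#' (abbreviated injury scale) severity level, given the value measured on
#' the test device.
#'
#' @param model An `injury_risk_model` object, e.g. from [hic_risk_model()],
#'   [neck_tension_model()] or [logistic_risk_model()].
#' @param x Numeric vector of metric values (units of the model's metric).
#' @param level AIS severity level ("AIS >= level"); only used by models
#'   parameterized per level.
#' @param ... Covariates required by specific model families (e.g. `age`).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @seealso [iarv()] for the inverse map.
#' @export
injury_risk <- function(model, x, level = 1L, ...) {
  UseMethod("injury_risk")
}

#' Injury assessment reference value at an acceptable probability
#'
#' Inverts an injury-risk model: returns the metric value at which the
#' probability of an AIS >= `level` injury equals `p`. This is the IARV
#' (injury assessment reference value) for that acceptable-risk probability,
#' before any rounding or deconditioning.
#'
#' @inheritParams injury_risk
#' @param p Acceptable injury probability, strictly in (0, 1).
#' @return Numeric vector of metric values. Models whose closed-form inverse
#'   can go negative (intercept-bearing logistics) clamp at 0 and attach a
#'   `clamped` attribute plus a warning, so the clamp is never silent.
#' @export
iarv <- function(model, p, level = 1L, ...) {
  UseMethod("iarv")
}

# ---- Weibull family (HIC-15, BrIC, shoulder) --------------------------------

#' Weibull injury-risk model
#'
#' Two-parameter Weibull dose-response form
#' `p(AIS >= n | x) = 1 - exp(-(x / scale_n)^shape)` with one scale per AIS
#' level. The closed-form inverse is
#' `IARV(p) = scale_n * (-log(1 - p))^(1/shape)`.
#'
#' @param shape Dimensionless Weibull exponent, > 0.
#' @param scale Numeric vector of per-level scale parameters (metric units),
#'   named by AIS level (unnamed vectors are taken as levels
#'   `1..length(scale)`). `NA` marks a level whose scale is not available;
#'   evaluating that level raises a missing-parameter error rather than
#'   guessing.
#' @inheritParams new_risk_model
#' @param metric,units,source Optional labels carried along for printing.
#' @return An object of class `c("weibull_risk_model", "injury_risk_model")`.
#' @examples
#' m <- weibull_risk_model(shape = 4.34, scale = 671)
#' injury_risk(m, 671)   # 1 - exp(-1)
#' iarv(m, 0.05)         # ~ 338.6
#' @export
weibull_risk_model <- function(shape, scale, metric = NA_character_,
                               units = NA_character_, source = NA_character_) {
  if (!is.numeric(shape) || length(shape) != 1L || shape <= 0) {
    abort_domain("`shape` must be a single positive number.")
  }
  if (!is.numeric(scale) || length(scale) < 1L) {
    abort_domain("`scale` must be a numeric vector of per-level scales.")
  }
  if (any(!is.na(scale) & scale <= 0)) {
    abort_domain("Weibull `scale` values must be positive.")
  }
  if (is.null(names(scale))) names(scale) <- as.character(seq_along(scale))
  new_risk_model("weibull_risk_model",
                 list(shape = shape, scale = scale),
                 metric = metric, units = units, source = source)
}

weibull_scale_for <- function(model, level) {
  s <- model$scale[as.character(level)]
  if (length(s) != 1L || is.na(s)) {
    abort_missing_parameter(sprintf(
      "No scale parameter is available for AIS >= %s in this %s model%s.",
      level, if (is.na(model$metric)) "Weibull" else model$metric,
      " (the per-level scale was never published and must be supplied)"))
  }
  unname(s)
}

#' @export
injury_risk.weibull_risk_model <- function(model, x, level = 1L, ...) {
  if (any(x < 0)) abort_domain("Metric value `x` must be non-negative.")
  s <- weibull_scale_for(model, level)
  -expm1(-(x / s)^model$shape)
}

#' @export
iarv.weibull_risk_model <- function(model, p, level = 1L, ...) {
  check_probability(p)
  s <- weibull_scale_for(model, level)
  s * (-log1p(-p))^(1 / model$shape)
}

# ---- ordered probit family (neck tension, chest, ankle inv/ev) --------------

#' Ordered-probit injury-risk model
#'
#' Cumulative probit form `p(AIS >= n | x) = 1 - pnorm(c_n - x * slope)`,
#' with one cut point per AIS level and a shared slope. Because the cut
#' points are strictly increasing, the per-level probabilities are ordered
#' (`p(AIS>=1) >= p(AIS>=2) >= ...`) at every metric value. The inverse is
#' `IARV = (c_n - qnorm(1 - p)) / slope`.
#'
#' @param cut_points Strictly increasing numeric vector of cut points, named
#'   by AIS level (unnamed: levels `1..length(cut_points)`).
#' @param slope Positive regression coefficient (inverse metric units).
#' @inheritParams weibull_risk_model
#' @export
ordered_probit_risk_model <- function(cut_points, slope,
                                      metric = NA_character_,
                                      units = NA_character_,
                                      source = NA_character_) {
  if (!is.numeric(cut_points) || length(cut_points) < 1L) {
    abort_domain("`cut_points` must be a numeric vector.")
  }
  if (length(cut_points) > 1L && any(diff(cut_points) <= 0)) {
    abort_domain("`cut_points` must be strictly increasing across AIS levels.")
  }
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    abort_domain("`slope` must be a single positive number.")
  }
  if (is.null(names(cut_points))) {
    names(cut_points) <- as.character(seq_along(cut_points))
  }
  new_risk_model("ordered_probit_risk_model",
                 list(cut_points = cut_points, slope = slope),
                 metric = metric, units = units, source = source)
}

probit_cut_for <- function(model, level) {
  cn <- model$cut_points[as.character(level)]
  if (length(cn) != 1L || is.na(cn)) {
    abort_missing_parameter(sprintf(
      "No cut point is defined for AIS >= %s in this ordered-probit model.",
      level))
  }
  unname(cn)
}

#' @export
injury_risk.ordered_probit_risk_model <- function(model, x, level = 1L, ...) {
  cn <- probit_cut_for(model, level)
  1 - pnorm(cn - x * model$slope)
}

#' @export
iarv.ordered_probit_risk_model <- function(model, p, level = 1L, ...) {
  check_probability(p)
  cn <- probit_cut_for(model, level)
  (cn - qnorm(1 - p)) / model$slope
}

# ---- logistic family --------------------------------------------------------

#' Logistic injury-risk model
#'
#' Logistic dose-response `p(x) = 1 / (1 + exp(intercept - slope * x))`,
#' increasing in `x` for positive `slope`. The equivalent location-scale
#' parameterization `p(x) = 1 / (1 + exp(-(x - location) / scale))` may be
#' supplied instead (`intercept = location/scale`, `slope = 1/scale`); both
#' describe the same curve and the same closed-form inverse
#' `IARV(p) = (intercept - log(1/p - 1)) / slope`.
#'
#' When the closed-form inverse is negative -- which happens for curves that
#' do not pass through zero, such as narrow-forearm moment fits at very low
#' probabilities -- [iarv()] clamps the result to 0, warns, and marks the
#' returned value with a `clamped` attribute.
#'
#' @param intercept,slope Intercept-slope parameterization.
#' @param location,scale Alternative location-scale parameterization
#'   (supply either pair, not both).
#' @inheritParams weibull_risk_model
#' @export
logistic_risk_model <- function(intercept = NULL, slope = NULL,
                                location = NULL, scale = NULL,
                                metric = NA_character_,
                                units = NA_character_,
                                source = NA_character_) {
  if (!is.null(location) || !is.null(scale)) {
    if (!is.null(intercept) || !is.null(slope)) {
      abort_input("Supply either (intercept, slope) or (location, scale), not both.")
    }
    if (is.null(location) || is.null(scale) || scale == 0) {
      abort_input("Both `location` and a non-zero `scale` are required.")
    }
    intercept <- location / scale
    slope <- 1 / scale
  }
  if (is.null(intercept) || is.null(slope) || slope == 0) {
    abort_input("A logistic model needs `intercept` and a non-zero `slope`.")
  }
  new_risk_model("logistic_risk_model",
                 list(intercept = intercept, slope = slope),
                 metric = metric, units = units, source = source)
}

#' @export
injury_risk.logistic_risk_model <- function(model, x, level = 1L, ...) {
  plogis(model$slope * x - model$intercept)
}

#' @export
iarv.logistic_risk_model <- function(model, p, level = 1L, ...) {
  check_probability(p)
  out <- (model$intercept - log(1 / p - 1)) / model$slope
  clamped <- out < 0
  if (any(clamped)) {
    warn(sprintf(
      "IARV closed form is negative for %d value(s); clamped to 0 (the fitted curve does not pass through zero).",
      sum(clamped)))
    out[clamped] <- 0
    attr(out, "clamped") <- clamped
  }
  out
}

# ---- named models with published coefficients -------------------------------

#' HIC-15 head-injury risk model
#'
#' Weibull risk function for mild traumatic brain injury (AIS 1+) as a
#' function of HIC-15, fitted to instrumented-helmet concussion data:
#' shape 4.34, scale 671.
#' @return A [weibull_risk_model()].
#' @export
hic_risk_model <- function() {
  weibull_risk_model(shape = 4.34, scale = c("1" = 671),
                     metric = "HIC 15", units = "",
                     source = "Funk et al. 2007 mTBI risk fit")
}

#' BrIC rotational brain-injury risk model
#'
#' Weibull form with shape 2.84 and one scale parameter per AIS level. The
#' per-level scale parameters were never published, so the default model is
#' deliberately unparameterized: evaluating it raises a missing-parameter
#' error unless `scales` are supplied. The published IARVs derived from the
#' original (unpublished) scales are available as reference constants in
#' [published_iarv_table()].
#' @param scales Numeric vector of scale parameters for AIS levels 1-4.
#' @export
bric_risk_model <- function(scales = rep(NA_real_, 4)) {
  weibull_risk_model(shape = 2.84,
                     scale = stats::setNames(scales, as.character(1:4)),
                     metric = "BrIC", units = "",
                     source = "Takhounts et al. BrIC risk form")
}

#' Neck axial tension risk model (THOR)
#'
#' Ordered-probit risk in peak neck tension force: cut points 6.30, 8.56,
#' 9.28, 10.19 for AIS 1+..4+ and slope 0.0053 per N, fitted to PMHS
#' (post-mortem human surrogate) axial-tension injury outcomes.
#' @export
neck_tension_model <- function() {
  ordered_probit_risk_model(
    cut_points = c("1" = 6.30, "2" = 8.56, "3" = 9.28, "4" = 10.19),
    slope = 0.0053,
    metric = "Neck axial tension force", units = "N",
    source = "Philippens et al. PMHS ordered probit")
}

#' Maximum chest deflection risk model (THOR)
#'
#' Ordered-probit risk in sternal compression: cut points 4.17, 5.61, 6.29,
#' 7.32 for AIS 1+..4+ and slope 0.103 per mm.
#' @export
chest_deflection_model <- function() {
  ordered_probit_risk_model(
    cut_points = c("1" = 4.17, "2" = 5.61, "3" = 6.29, "4" = 7.32),
    slope = 0.103,
    metric = "Max chest deflection", units = "mm",
    source = "Mertz sternal-compression reanalysis")
}

#' Ankle inversion/eversion moment risk model
#'
#' Probit risk of AIS 2+ ankle injury in inversion/eversion moment:
#' cut point 4.0, slope 0.10 per Nm (fit to the digitized published curve).
#' @export
ankle_inversion_model <- function() {
  ordered_probit_risk_model(
    cut_points = c("2" = 4.0), slope = 0.10,
    metric = "Ankle inversion/eversion moment", units = "Nm",
    source = "Kuppa et al. ankle moment risk")
}

#' Ankle dorsiflexion moment risk model
#'
#' Logistic risk of AIS 2+ ankle injury in dorsiflexion moment, location
#' 60.23 Nm and scale 9.217 Nm (natural-log parameterization).
#' @export
ankle_dorsiflexion_model <- function() {
  logistic_risk_model(location = 60.23, scale = 9.217,
                      metric = "Ankle dorsiflexion moment", units = "Nm",
                      source = "Kuppa et al. ankle moment risk")
}

#' EuroSID-2re pelvic lateral force risk model
#'
#' Logistic AIS 2+ pelvic injury risk in EuroSID-2re pubic force:
#' `p = 1/(1 + exp(6.403 - 0.00163 F))`.
#' @export
eurosid_pelvis_model <- function() {
  logistic_risk_model(intercept = 6.403, slope = 0.00163,
                      metric = "EuroSID pelvic lateral force", units = "N",
                      source = "Kuppa EuroSID-2re pelvic risk")
}

#' THOR lateral (acetabular) force risk model
#'
#' Logistic AIS 2+ risk in THOR lateral contact force obtained by mapping
#' the EuroSID pelvic risk through the THOR/EuroSID transfer:
#' `p = 1/(1 + exp(6.403 - 0.0011 F))`.
#' @export
thor_lateral_force_model <- function() {
  logistic_risk_model(intercept = 6.403, slope = 0.0011,
                      metric = "Acetabular resultant force", units = "N",
                      source = "EuroSID pelvic risk via THOR transfer")
}

#' Forearm moment risk models
#'
#' Logistic AIS 2+ forearm fracture risk in applied moment. `bass_forearm_model()`
#' is the SAE 5th-percentile-female instrumented-arm fit (location 66.2 Nm,
#' scale 15 Nm); its inverse goes negative below about 1.2% risk, which
#' [iarv()] reports as a clamped 0. `duma_forearm_model()` is the
#' 5th-percentile-female PMHS fit (location 58 Nm, scale 6.62 Nm).
#' @name forearm_models
#' @export
bass_forearm_model <- function() {
  logistic_risk_model(location = 66.2, scale = 15,
                      metric = "Forearm moment (SAE arm)", units = "Nm",
                      source = "Bass et al. instrumented-arm fit")
}

#' @rdname forearm_models
#' @export
duma_forearm_model <- function() {
  logistic_risk_model(location = 58, scale = 6.62,
                      metric = "Forearm moment (PMHS)", units = "Nm",
                      source = "Duma et al. PMHS fit")
}

#' Average distal forearm speed risk models
#'
#' Logistic AIS 2+ forearm fracture risk in average distal forearm speed
#' (ADFS, m/s). `adfs_pmhs_model()` is the PMHS-scale fit
#' (`p = 1/(1+exp(6.749 - 0.645 S))`); `adfs_thor_model()` is the same fit
#' mass-scaled to the 4.27 kg THOR arm (`p = 1/(1+exp(9.845 - 0.645 S))`).
#' @name adfs_models
#' @export
adfs_pmhs_model <- function() {
  logistic_risk_model(intercept = 6.749, slope = 0.645,
                      metric = "Average distal forearm speed (PMHS)",
                      units = "m/s", source = "Hardy et al. ADFS fit")
}

#' @rdname adfs_models
#' @export
adfs_thor_model <- function() {
  logistic_risk_model(intercept = 9.845, slope = 0.645,
                      metric = "Average distal forearm speed", units = "m/s",
                      source = "Hardy et al. ADFS fit, THOR arm mass")
}

#' FMVSS 208 chest deflection risk family (Hybrid-III)
#'
#' The four regulatory logistic risk curves in maximum chest deflection
#' (mm), one per AIS level 2-5. These curves do not pass through zero:
#' `fmvss_chest_risk(0, 2)` is about 0.134, so their low-probability
#' inversions are not usable as IARVs.
#'
#' @param deflection Maximum chest deflection in mm, >= 0.
#' @param level AIS level, one of 2, 3, 4, 5.
#' @return `fmvss_chest_model()`: a named list of [logistic_risk_model()]s.
#'   `fmvss_chest_risk()`: probability vector.
#' @examples
#' fmvss_chest_risk(63, level = 3)  # ~ 0.33
#' @export
fmvss_chest_model <- function() {
  coefs <- list("2" = c(1.8706, 0.04439), "3" = c(3.7124, 0.0475),
                "4" = c(5.0952, 0.0475), "5" = c(8.8274, 0.0459))
  lapply(coefs, function(ab) {
    logistic_risk_model(intercept = ab[[1]], slope = ab[[2]],
                        metric = "Max chest deflection", units = "mm",
                        source = "NHTSA FMVSS 208 chest risk")
  })
}

#' @rdname fmvss_chest_model
#' @export
fmvss_chest_risk <- function(deflection, level = 3L) {
  if (any(deflection < 0)) abort_domain("`deflection` must be non-negative.")
  fam <- fmvss_chest_model()
  m <- fam[[as.character(level)]]
  if (is.null(m)) {
    abort_missing_parameter("FMVSS chest risk is defined for AIS levels 2-5.")
  }
  injury_risk(m, deflection)
}

#' NCAP age-dependent chest injury risk
#'
#' The NHTSA NCAP AIS 3+ chest injury risk curve in maximum chest deflection
#' and occupant age:
#' `p = 1 / (1 + exp(12.597 - 0.05861 Age - 1.568 Dmax^0.4612))`.
#'
#' @param deflection Maximum chest deflection in mm, >= 0.
#' @param age Occupant age in years.
#' @return Probability of AIS 3+ chest injury.
#' @examples
#' ncap_chest_risk(63, age = 45)  # ~ 0.654
#' @export
ncap_chest_risk <- function(deflection, age) {
  if (any(deflection < 0)) abort_domain("`deflection` must be non-negative.")
  1 / (1 + exp(12.597 - 0.05861 * age - 1.568 * deflection^0.4612))
}

# ---- shoulder: age-dependent Weibull on the THOR scale ----------------------

#' Age-dependent lateral shoulder force risk model (THOR scale)
#'
#' WorldSID shoulder-contact-force injury risk (Weibull with shape 7.41 and
#' age-dependent scale `exp(8.14 - 0.0055 age)`) mapped to the THOR through
#' the 2.016 contact-force transfer. The IARV closed form is
#' `F = 2.016 * exp(8.14 - 0.0055 age) * (-log(1 - p))^(1/7.41)`; it
#' decreases with age and increases with the acceptable probability.
#'
#' @param transfer THOR/WorldSID contact-force gain (default 2.016; set to 1
#'   for WorldSID-scale values).
#' @export
shoulder_age_model <- function(transfer = 2.016) {
  if (transfer <= 0) abort_domain("`transfer` must be positive.")
  new_risk_model("shoulder_age_model",
                 list(intercept = 8.14, age_slope = 0.0055,
                      shape = 7.41, transfer = transfer),
                 metric = "Lateral shoulder force", units = "N",
                 source = "Petitjean et al. WorldSID risk via THOR transfer")
}

shoulder_scale <- function(model, age) {
  if (any(age <= 0)) abort_domain("`age` must be positive (years).")
  model$transfer * exp(model$intercept - model$age_slope * age)
}

#' @export
injury_risk.shoulder_age_model <- function(model, x, level = 2L, ..., age = 56) {
  if (any(x < 0)) abort_domain("Shoulder force must be non-negative.")
  -expm1(-(x / shoulder_scale(model, age))^model$shape)
}

#' @export
iarv.shoulder_age_model <- function(model, p, level = 2L, ..., age = 56) {
  check_probability(p)
  shoulder_scale(model, age) * (-log1p(-p))^(1 / model$shape)
}

#' Lateral shoulder force IARV
#'
#' Convenience wrapper around [shoulder_age_model()]: the THOR-scale
#' shoulder-force limit at probability `p` for an occupant of the given age.
#' The default age of 56 is the eldest male astronaut, giving the most
#' conservative (lowest) limit.
#' @param p Acceptable probability of AIS 2+ shoulder injury.
#' @param age Occupant age in years.
#' @export
shoulder_iarv <- function(p, age = 56) {
  iarv(shoulder_age_model(), p, age = age)
}

# ---- neck compression: covariate tolerance + logistic -----------------------

#' Neck axial compression risk model with covariates
#'
#' The 50%-risk compression tolerance is the linear covariate model
#' `Fz = b0 + b1*age + b2*rate + b3*gender + b4*age*rate` (N), with
#' published coefficients 934.2, 8.9, 11.0, 665.0 and -0.134; `gender` is 0
#' for females and 1 for males, `rate` is the loading rate in m/s. The full
#' risk curve is a logistic in force around that tolerance with steepness
#' `beta5` -- a coefficient that was never published. The model therefore
#' ships with `beta5 = NULL`: the 50% point (the tolerance itself) is always
#' available, but any other probability raises a missing-parameter error
#' naming the gap, never a silent default.
#'
#' @param beta0,beta1,beta2,beta3,beta4 Tolerance coefficients.
#' @param beta5 Logistic steepness (1/N). Unpublished; must be supplied by
#'   the user for probabilities other than 0.5.
#' @export
neck_compression_model <- function(beta0 = 934.2, beta1 = 8.9, beta2 = 11.0,
                                   beta3 = 665.0, beta4 = -0.134,
                                   beta5 = NULL) {
  new_risk_model("neck_compression_model",
                 list(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                      beta3 = beta3, beta4 = beta4, beta5 = beta5),
                 metric = "Neck axial compression force", units = "N",
                 source = "Pintar et al. cervical-spine tolerance model")
}

check_neck_covariates <- function(age, loading_rate, gender) {
  if (any(!gender %in% c(0, 1))) {
    abort_input("`gender` must be 0 (female) or 1 (male).")
  }
  # calibration ranges of the underlying PMHS study / astronaut corps
  if (any(age < 32 | age > 82)) {
    warn("`age` outside the 32-82 yr calibration range; extrapolating.")
  }
  if (any(loading_rate < 0)) abort_domain("`loading_rate` must be >= 0.")
}

#' 50%-risk neck compression tolerance
#'
#' Evaluates the covariate tolerance model: the axial compression force (N)
#' at which the injury probability is 0.5 for the given age (years), loading
#' rate (m/s) and gender (0 female / 1 male). Tolerance is lower for females
#' and declines with age at typical loading rates.
#' @param age Age in years.
#' @param loading_rate Loading rate in m/s (2 m/s is the conservative
#'   selection for capsule landings).
#' @param gender 0 for female, 1 for male.
#' @param model A [neck_compression_model()].
#' @export
neck_compression_tolerance <- function(age, loading_rate = 2, gender = 0,
                                       model = neck_compression_model()) {
  check_neck_covariates(age, loading_rate, gender)
  model$beta0 + model$beta1 * age + model$beta2 * loading_rate +
    model$beta3 * gender + model$beta4 * age * loading_rate
}

#' @export
injury_risk.neck_compression_model <- function(model, x, level = 2L, ...,
                                               age, loading_rate = 2,
                                               gender = 0) {
  if (is.null(model$beta5)) {
    abort_missing_parameter(paste(
      "The logistic steepness `beta5` of the neck-compression risk model",
      "was never published; supply it via neck_compression_model(beta5 = ...)."))
  }
  tol <- neck_compression_tolerance(age, loading_rate, gender, model)
  plogis(model$beta5 * (x - tol))
}

#' @export
iarv.neck_compression_model <- function(model, p, level = 2L, ...,
                                        age, loading_rate = 2, gender = 0) {
  check_probability(p)
  tol <- neck_compression_tolerance(age, loading_rate, gender, model)
  if (all(p == 0.5)) return(tol)  # logistic midpoint: beta5 drops out
  if (is.null(model$beta5)) {
    abort_missing_parameter(paste(
      "The logistic steepness `beta5` of the neck-compression risk model",
      "was never published; only the 50% point (the tolerance) is derivable."))
  }
  tol - log(1 / p - 1) / model$beta5
}

# ---- DRI spinal risk chain --------------------------------------------------

#' Spinal injury risk from the dynamic response index
#'
#' Log-linear relation between the dynamic response index (DRI, the +Z
#' Brinkley lumped-parameter spinal response) and the probability of any
#' spinal injury, calibrated on ejection data: `risk% = 10^((DRI - 15.8)/3.73)`
#' so DRI 15.8 corresponds to 1% risk. Risk is expressed in PERCENT -- the
#' only reading under which the published thoracic-spine force chain
#' reproduces.
#'
#' @param dri Dynamic response index (dimensionless).
#' @param percent Injury risk in percent, > 0.
#' @return `dri_spinal_risk()`: risk in percent. `dri_from_risk()`: the DRI.
#' @examples
#' dri_from_risk(1)   # 15.8
#' dri_from_risk(5)   # ~ 18.41
#' @export
dri_spinal_risk <- function(dri) {
  10^((dri - 15.8) / 3.73)
}

#' @rdname dri_spinal_risk
#' @export
dri_from_risk <- function(percent) {
  if (any(percent <= 0)) abort_domain("`percent` risk must be positive.")
  3.73 * log10(percent) + 15.8
}

# ---- hip fracture (stature / posture probit) --------------------------------

#' Hip (femoral head) fracture risk model
#'
#' Lognormal-probit fracture risk in peak hip force (kN), with a stature
#' term `exp(-0.2141 + 0.0114 * stature_cm)` and a posture factor
#' `1 - (flexion - abduction)/100` multiplying it inside the log (neutral
#' posture, 30 deg flexion and 15 deg abduction, gives factor 0.85; equal
#' angles give 1). The grouping of the posture factor is isolated here so an
#' alternate reading is a one-line change.
#'
#' @param stature Stature of the target population in cm (178 for
#'   50th-percentile males).
#' @param flexion Hip flexion angle in degrees (neutral 30).
#' @param abduction Hip abduction angle in degrees (neutral 15).
#' @export
hip_fracture_model <- function(stature = 178, flexion = 30, abduction = 15) {
  if (stature <= 0) abort_domain("`stature` must be positive (cm).")
  new_risk_model("hip_fracture_model",
                 list(c0 = -0.2141, c1 = 0.0114, sigma = 0.1991,
                      stature = stature, flexion = flexion,
                      abduction = abduction),
                 metric = "Hip lateral force", units = "kN",
                 source = "NHTSA acetabular risk (Rupp et al.)")
}

#' @export
injury_risk.hip_fracture_model <- function(model, x, level = 2L, ...) {
  if (any(x <= 0)) abort_domain("Hip force must be positive (kN).")
  loc <- exp(model$c0 + model$c1 * model$stature) *
    (1 - (model$flexion - model$abduction) / 100)
  pnorm((log(x) - log(loc)) / model$sigma)
}

#' @export
iarv.hip_fracture_model <- function(model, p, level = 2L, ...) {
  check_probability(p)
  loc <- exp(model$c0 + model$c1 * model$stature) *
    (1 - (model$flexion - model$abduction) / 100)
  exp(qnorm(p) * model$sigma + log(loc))
}

# ---- fracture risk index ----------------------------------------------------

#' Fracture-risk-index (FRI) model
#'
#' Logistic fracture probability in the ratio of applied to fracture force:
#' `p = 1 / (1 + exp(-(F_applied/F_fracture - mu) * phi))`. The probability
#' is 0.5 when the ratio equals `mu`, and depends on the two forces only
#' through their ratio.
#'
#' @param fracture_force Fracture force of the bone, N, > 0.
#' @param mu Position factor: the FRI value at 50% fracture probability.
#' @param phi Slope factor (steepness).
#' @export
fri_model <- function(fracture_force, mu, phi) {
  if (fracture_force <= 0) abort_domain("`fracture_force` must be positive.")
  new_risk_model("fri_model",
                 list(fracture_force = fracture_force, mu = mu, phi = phi),
                 metric = "Applied force", units = "N",
                 source = "Nelson et al. fracture risk index")
}

#' @export
injury_risk.fri_model <- function(model, x, level = 2L, ...) {
  plogis((x / model$fracture_force - model$mu) * model$phi)
}

#' @export
iarv.fri_model <- function(model, p, level = 2L, ...) {
  check_probability(p)
  (qlogis(p) / model$phi + model$mu) * model$fracture_force
}

# ---- convenience scalar IARVs ----------------------------------------------

#' Ankle dorsiflexion moment IARV
#'
#' Closed-form inversion of the dorsiflexion logistic:
#' `IARV(p) = 60.23 - 9.217 * log(1/p - 1)` Nm (natural log). Monotone
#' increasing in `p`; equals the 60.23 Nm location at p = 0.5.
#' @param p Acceptable probability of AIS 2+ ankle injury.
#' @export
dorsiflexion_iarv <- function(p) {
  iarv(ankle_dorsiflexion_model(), p)
}

#' @export
print.injury_risk_model <- function(x, ...) {
  cat("<", class(x)[[1]], ">",
      if (!is.na(x$metric)) paste0(" ", x$metric), "\n", sep = "")
  flds <- x[setdiff(names(x), c("metric", "units", "source"))]
  for (nm in names(flds)) {
    v <- flds[[nm]]
    if (is.null(v)) v <- "<unset>"
    cat("  ", nm, ": ", paste(format(v, digits = 6), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.na(x$source)) cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}
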