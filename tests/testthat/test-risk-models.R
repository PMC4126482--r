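# Forward and inverse evaluation of every parametric risk family, checked
# against closed forms computed independently and against a bisection
# oracle on the forward curve.

test_that("Weibull head-injury risk evaluates and inverts its closed form", {
  m <- hic_risk_model()
  expect_equal(injury_risk(m, 0), 0)
  expect_equal(injury_risk(m, 671), 1 - exp(-1))
  expect_equal(injury_risk(m, 340), 0.0509720147156, tolerance = 1e-9)
  expect_equal(iarv(m, 0.05), 338.455, tolerance = 1e-4)
  expect_equal(iarv(m, 0.19), 468.700, tolerance = 1e-4)
  # p -> 0 limit collapses to 0
  expect_lt(iarv(m, 1e-12), iarv(m, 1e-6))
  expect_lt(iarv(m, 1e-20), 0.1)
  expect_error(iarv(m, 0), class = "thoriarv_error_domain")
  expect_error(iarv(m, 1), class = "thoriarv_error_domain")
  expect_error(injury_risk(m, -1), class = "thoriarv_error_domain")
})

test_that("unparameterized Weibull levels raise a missing-parameter error", {
  b <- bric_risk_model()
  expect_error(injury_risk(b, 0.5, level = 1),
               class = "thoriarv_error_missing_parameter")
  expect_error(iarv(b, 0.05, level = 4),
               class = "thoriarv_error_missing_parameter")
  # once scales are supplied the model works like any Weibull
  b2 <- bric_risk_model(scales = c(0.5, 0.8, 1.0, 1.2))
  expect_equal(injury_risk(b2, 0.5, level = 1), 1 - exp(-1))
})

test_that("ordered probit families are level-ordered with a 0.5 midpoint", {
  neck <- neck_tension_model()
  chest <- chest_deflection_model()
  expect_equal(injury_risk(neck, 6.30 / 0.0053, level = 1), 0.5)
  expect_equal(injury_risk(neck, 880, level = 1), 0.050919793698,
               tolerance = 1e-9)
  expect_equal(injury_risk(chest, 0, level = 1), 1.5229981948e-05,
               tolerance = 1e-8)
  # p(AIS>=n) >= p(AIS>=n+1) at every metric value
  for (x in seq(0, 3000, length.out = 41)) {
    p <- vapply(1:4, function(lv) injury_risk(neck, x, level = lv), numeric(1))
    expect_true(all(diff(p) <= 0))
  }
  expect_error(injury_risk(neck, 100, level = 5),
               class = "thoriarv_error_missing_parameter")
  expect_error(
    ordered_probit_risk_model(cut_points = c(2, 1), slope = 0.1),
    class = "thoriarv_error_domain")
})

test_that("probit inversions reproduce the published reference limits", {
  expect_equal(iarv(neck_tension_model(), 0.05, level = 1), 878.3295,
               tolerance = 1e-6)
  expect_equal(iarv(chest_deflection_model(), 0.19, level = 1), 31.9622,
               tolerance = 1e-5)
  expect_equal(iarv(ankle_inversion_model(), 0.01, level = 2), 16.7365,
               tolerance = 1e-5)
  expect_equal(iarv(ankle_inversion_model(), 0.04, level = 2), 22.4931,
               tolerance = 1e-5)
})

test_that("logistic risk inverts in closed form and clamps negative limits", {
  expect_equal(iarv(thor_lateral_force_model(), 0.01), 1643.5274,
               tolerance = 1e-6)
  expect_equal(iarv(duma_forearm_model(), 0.04), 36.9612836, tolerance = 1e-8)
  expect_equal(iarv(duma_forearm_model(), 0.01), 58 - 6.62 * log(99),
               tolerance = 1e-12)
  # the instrumented-arm fit does not pass through zero: at 1% the closed
  # form is negative and must be clamped to 0, visibly
  expect_warning(v <- iarv(bass_forearm_model(), 0.01), "clamped")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "clamped"))
  expect_equal(iarv(bass_forearm_model(), 0.04), 66.2 - 15 * log(24),
               tolerance = 1e-12)
})

test_that("dorsiflexion limits use a natural-log logistic", {
  expect_equal(dorsiflexion_iarv(0.01), 17.8768, tolerance = 1e-5)
  expect_equal(dorsiflexion_iarv(0.04), 30.9379, tolerance = 1e-5)
  expect_equal(dorsiflexion_iarv(0.5), 60.23)
  expect_true(dorsiflexion_iarv(0.04) > dorsiflexion_iarv(0.01))
  expect_error(dorsiflexion_iarv(0), class = "thoriarv_error_domain")
})

test_that("shoulder limits fall with age and match the published values", {
  expect_equal(shoulder_iarv(0.01, age = 56), 2730.698, tolerance = 1e-4)
  expect_equal(shoulder_iarv(0.04, age = 56), 3299.296, tolerance = 1e-4)
  # fixed p: age enters only through the exponential factor
  expect_equal(shoulder_iarv(0.02, age = 35) / shoulder_iarv(0.02, age = 56),
               exp(0.0055 * 21), tolerance = 1e-12)
  expect_true(shoulder_iarv(0.01, age = 56) < shoulder_iarv(0.01, age = 35))
  m <- shoulder_age_model()
  expect_equal(injury_risk(m, shoulder_iarv(0.04, age = 47), age = 47), 0.04,
               tolerance = 1e-12)
})

test_that("neck compression tolerance follows the covariate model", {
  expect_equal(neck_compression_tolerance(59, 2, 1), 2130.488)
  expect_equal(neck_compression_tolerance(59, 2, 0), 1465.488)
  expect_equal(neck_compression_tolerance(59, 2, 1) -
                 neck_compression_tolerance(59, 2, 0), 665)
  # females tolerate less force at equal age and rate
  expect_lt(neck_compression_tolerance(47, 2, 0),
            neck_compression_tolerance(47, 2, 1))
  m <- neck_compression_model()
  # logistic midpoint: the 50% limit equals the tolerance with no beta5
  expect_equal(iarv(m, 0.5, age = 59, loading_rate = 2, gender = 1), 2130.488)
  expect_error(iarv(m, 0.05, age = 59, gender = 1),
               class = "thoriarv_error_missing_parameter")
  expect_error(injury_risk(m, 1500, age = 59, gender = 1),
               class = "thoriarv_error_missing_parameter")
  # any supplied beta5 makes the model invertible and round-trippable
  m5 <- neck_compression_model(beta5 = 0.01)
  f <- iarv(m5, 0.1, age = 45, gender = 0)
  expect_equal(injury_risk(m5, f, age = 45, gender = 0), 0.1,
               tolerance = 1e-12)
})

test_that("DRI spinal risk chain is the published log-linear law in percent", {
  expect_equal(dri_from_risk(1), 15.8)
  expect_equal(dri_from_risk(5), 18.4071581162, tolerance = 1e-10)
  expect_equal(dri_spinal_risk(19.53), 10, tolerance = 1e-12)
  expect_equal(dri_spinal_risk(dri_from_risk(7.3)), 7.3, tolerance = 1e-12)
  expect_error(dri_from_risk(0), class = "thoriarv_error_domain")
  expect_error(dri_from_risk(-2), class = "thoriarv_error_domain")
})

test_that("hip fracture risk is a lognormal probit in force with posture factor", {
  # equal flexion and abduction angles cancel the posture factor
  m1 <- hip_fracture_model(stature = 178, flexion = 15, abduction = 15)
  loc <- exp(-0.2141 + 0.0114 * 178)
  expect_equal(injury_risk(m1, loc), 0.5, tolerance = 1e-12)
  # at neutral posture (30 deg flexion, 15 deg abduction) the factor is 0.85
  m2 <- hip_fracture_model(stature = 178)
  expect_equal(injury_risk(m2, loc * 0.85), 0.5, tolerance = 1e-12)
  f <- seq(1, 15, length.out = 40)
  expect_true(all(diff(injury_risk(m2, f)) > 0))
  expect_true(all(injury_risk(m2, f) >= 0 & injury_risk(m2, f) <= 1))
  # taller population tolerates more force at the same risk
  short <- hip_fracture_model(stature = 150)
  expect_lt(iarv(short, 0.05), iarv(hip_fracture_model(stature = 190), 0.05))
})

test_that("fracture risk index depends on forces only through their ratio", {
  m <- fri_model(fracture_force = 3000, mu = 1, phi = 10)
  expect_equal(injury_risk(m, 3000), 0.5)
  m2 <- fri_model(fracture_force = 6000, mu = 1, phi = 10)
  expect_equal(injury_risk(m, 2500), injury_risk(m2, 5000))
  # steep slope approaches a step at mu
  steep <- fri_model(3000, mu = 1, phi = 1e4)
  expect_lt(injury_risk(steep, 2990), 1e-4)
  expect_gt(injury_risk(steep, 3010), 1 - 1e-4)
  expect_equal(injury_risk(m, iarv(m, 0.2)), 0.2, tolerance = 1e-12)
})

test_that("regulatory chest risk curves evaluate as published", {
  expect_equal(fmvss_chest_risk(63, level = 3), 0.327415004,
               tolerance = 1e-8)
  expect_equal(fmvss_chest_risk(0, level = 2), 0.133472313,
               tolerance = 1e-8)
  expect_equal(ncap_chest_risk(63, age = 45), 0.654281599, tolerance = 1e-8)
  # AIS ordering holds over the plotted deflection range
  for (d in seq(0, 100, by = 10)) {
    p <- vapply(2:5, function(lv) fmvss_chest_risk(d, lv), numeric(1))
    expect_true(all(diff(p) <= 0))
  }
  # NCAP risk increases with both deflection and age
  expect_true(all(diff(ncap_chest_risk(seq(5, 90, 5), age = 45)) > 0))
  expect_lt(ncap_chest_risk(63, age = 30), ncap_chest_risk(63, age = 70))
  expect_error(fmvss_chest_risk(30, level = 1),
               class = "thoriarv_error_missing_parameter")
})

test_that("inverse-forward round trips hold to 1e-9 over random models", {
  set.seed(421)
  for (k in 1:40) {
    w <- weibull_risk_model(shape = runif(1, 0.5, 8), scale = runif(1, 10, 2000))
    o <- ordered_probit_risk_model(cut_points = sort(runif(3, 1, 10)),
                                   slope = runif(1, 1e-3, 1))
    l <- logistic_risk_model(intercept = runif(1, 1, 12),
                             slope = runif(1, 1e-3, 1))
    p <- runif(1, 1e-4, 0.95)
    expect_equal(injury_risk(w, iarv(w, p)), p, tolerance = 1e-9)
    lv <- sample(1:3, 1)
    expect_equal(injury_risk(o, iarv(o, p, level = lv), level = lv), p,
                 tolerance = 1e-9)
    x <- suppressWarnings(iarv(l, p))  # clamped draws are excluded below
    if (is.null(attr(x, "clamped"))) {
      expect_equal(injury_risk(l, x), p, tolerance = 1e-9)
    }
  }
})

test_that("closed-form inversions agree with a bisection oracle", {
  set.seed(77)
  for (k in 1:15) {
    p <- runif(1, 0.002, 0.6)
    w <- hic_risk_model()
    expect_equal(iarv(w, p),
                 bisect_inverse(function(x) injury_risk(w, x), p, 0, 5000),
                 tolerance = 1e-6)
    o <- neck_tension_model()
    expect_equal(iarv(o, p, level = 1),
                 bisect_inverse(function(x) injury_risk(o, x, level = 1),
                                p, 0, 5000),
                 tolerance = 1e-6)
    l <- thor_lateral_force_model()
    expect_equal(iarv(l, p),
                 bisect_inverse(function(x) injury_risk(l, x), p, 0, 2e4),
                 tolerance = 1e-6)
  }
})

test_that("every forward risk function is non-decreasing on a dense grid", {
  models <- list(hic_risk_model(), neck_tension_model(),
                 chest_deflection_model(), thor_lateral_force_model(),
                 ankle_dorsiflexion_model(), duma_forearm_model(),
                 adfs_thor_model(), shoulder_age_model())
  grids <- list(seq(0, 2000, length.out = 300), seq(0, 3000, length.out = 300),
                seq(0, 80, length.out = 300), seq(0, 8000, length.out = 300),
                seq(0, 120, length.out = 300), seq(0, 120, length.out = 300),
                seq(0, 30, length.out = 300), seq(0, 6000, length.out = 300))
  levels <- c(1, 1, 1, 1, 2, 2, 2, 2)
  for (i in seq_along(models)) {
    p <- injury_risk(models[[i]], grids[[i]], level = levels[[i]])
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("tidy and glance expose model coefficients as tibbles", {
  td <- generics::tidy(neck_tension_model())
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("cut_points[1]", "slope") %in% td$term))
  gl <- generics::glance(hic_risk_model())
  expect_equal(gl$family, "weibull_risk_model")
  expect_equal(gl$n_parameters, nrow(generics::tidy(hic_risk_model())))
})
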