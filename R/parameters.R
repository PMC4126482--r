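# Every published coefficient the package uses, embedded as defaults with a
# citation string, and loadable from a versioned YAML/JSON mirror so a user
# can pin or override a coefficient set without touching code.

default_parameters <- function() {
  list(
    version = "1",
    hic = list(shape = 4.34, scale = 671,
               citation = "Funk et al. 2007 mTBI Weibull fit"),
    bric = list(shape = 2.84, scales = rep(NA_real_, 4),
                critical = c(66.3, 53.8, 41.5),
                citation = "Takhounts et al. BrIC; per-level scales unpublished"),
    neck_tension = list(cut_points = c(6.30, 8.56, 9.28, 10.19), slope = 0.0053,
                        citation = "Philippens et al. PMHS ordered probit"),
    neck_compression = list(beta0 = 934.2, beta1 = 8.9, beta2 = 11.0,
                            beta3 = 665.0, beta4 = -0.134, beta5 = NA_real_,
                            age = 52, loading_rate = 2, gender = 0,
                            citation = "Pintar et al. tolerance model; beta5 unpublished"),
    chest = list(cut_points = c(4.17, 5.61, 6.29, 7.32), slope = 0.103,
                 citation = "Mertz sternal-compression reanalysis"),
    fmvss_chest = list(intercepts = c(1.8706, 3.7124, 5.0952, 8.8274),
                       slopes = c(0.04439, 0.0475, 0.0475, 0.0459),
                       levels = 2:5, citation = "NHTSA FMVSS 208"),
    ncap_chest = list(coefficients = c(12.597, 0.05861, 1.568, 0.4612),
                      citation = "NHTSA NCAP age-dependent chest risk"),
    shoulder = list(intercept = 8.14, age_slope = 0.0055, shape = 7.41,
                    transfer = 2.016, age = 56,
                    citation = "Petitjean et al. WorldSID risk x THOR transfer; eldest male astronaut"),
    acetabular = list(intercept = 6.403, slope = 0.0011,
                      citation = "Kuppa EuroSID pelvic risk on the THOR scale"),
    eurosid_pelvis = list(intercept = 6.403, slope = 0.00163,
                          citation = "Kuppa EuroSID-2re pelvic risk"),
    thoracic_spine = list(risk_slope = 3.73, risk_intercept = 15.8,
                          dri_gain = 3.62, dri_offset = -2.59,
                          force_gain = 0.277, force_offset = 0.795,
                          citation = "DRI ejection-data fit + THOR spine regression"),
    dorsiflexion = list(location = 60.23, scale = 9.217,
                        citation = "Kuppa et al. ankle dorsiflexion"),
    inversion_eversion = list(cut = 4.0, slope = 0.10,
                              citation = "Kuppa et al. ankle inversion/eversion (digitized)"),
    adfs = list(pmhs_intercept = 6.749, thor_intercept = 9.845, slope = 0.645,
                mass_slope = 1.94, reference_mass = 2.67, thor_arm_mass = 4.27,
                citation = "Hardy et al. ADFS fits + arm-mass scaling"),
    forearm = list(bass = list(location = 66.2, scale = 15),
                   duma = list(location = 58, scale = 6.62),
                   citation = "Bass / Duma forearm moment fits"),
    acceptable_risk = list(nominal = c(0.05, 0.01, 0.003, 0.0003),
                           off_nominal = c(0.19, 0.04, 0.01, 0.001),
                           citation = "NASA definition of acceptable risk, class I-IV"),
    deconditioning = list(none = 1.0, spine = 0.86, lower_extremity = 0.75,
                          citation = "NASA spaceflight deconditioning factors")
  )
}

#' Model coefficient set
#'
#' Returns the package's embedded coefficient set -- every published model
#' coefficient with its citation string -- or loads a coefficient set from a
#' YAML (or JSON) parameter file mirroring the same structure. Unknown keys
#' in a file are an error; missing keys fall back to the embedded defaults,
#' so a file may pin only the coefficients it overrides.
#'
#' @param file Optional path to a YAML/JSON parameter file.
#' @return A named list of coefficient groups.
#' @seealso [write_parameters()] to produce a file mirroring the defaults.
#' @export
injury_parameters <- function(file = NULL) {
  params <- default_parameters()
  if (is.null(file)) return(params)
  loaded <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort_input("Reading JSON parameter files requires the jsonlite package.")
    }
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  unknown <- setdiff(names(loaded), names(params))
  if (length(unknown)) {
    abort_input(paste("Unknown parameter group(s):", paste(unknown, collapse = ", ")))
  }
  for (grp in names(loaded)) {
    if (is.list(params[[grp]])) {
      bad <- setdiff(names(loaded[[grp]]), names(params[[grp]]))
      if (length(bad)) {
        abort_input(sprintf("Unknown key(s) in `%s`: %s", grp,
                            paste(bad, collapse = ", ")))
      }
      params[[grp]][names(loaded[[grp]])] <- loaded[[grp]]
    } else {
      params[[grp]] <- loaded[[grp]]
    }
  }
  params
}

#' @rdname injury_parameters
#' @param params Coefficient set to serialize.
#' @param path Output YAML path.
#' @export
write_parameters <- function(params = injury_parameters(), path) {
  yaml::write_yaml(params, path)
  invisible(path)
}
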