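# Deterministic generators for sled-test-like channels and landing-severity
# samples, so every metric calculator can be tested against closed forms
# with no external data.

#' @importFrom stats rnorm approx pnorm median setNames
NULL

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a pulse-shaped test channel
#'
#' Produces a smooth unimodal pulse of the kind seen on capsule-landing sled
#' channels, with a known analytic form so metric values have closed-form
#' oracles: `"constant"` (amplitude over the full duration), `"half-sine"`
#' (`A sin(pi t / D)`), `"haversine"` (`A sin^2(pi t / D)`, peak at mid
#' pulse), or `"trapezoid"` (linear rise and fall over `rise_frac * D` each,
#' flat top; integral `A D (1 - rise_frac)`). Zero padding of length `onset`
#' precedes the pulse and `tail` follows it. Optional additive Gaussian
#' noise is off by default so oracle tests are exact; generation is
#' deterministic for a fixed seed and leaves the caller's RNG state
#' untouched.
#'
#' @param shape Pulse shape.
#' @param amplitude Peak value, in the channel's units.
#' @param duration Pulse duration in seconds, > 0.
#' @param onset Zero-padding before the pulse, seconds.
#' @param tail Zero-padding after the pulse, seconds (defaults to `onset`).
#' @param rate Sampling rate in Hz; must give at least 20 samples per pulse.
#'   10 kHz, typical of crash-channel capture, is the default.
#' @param rise_frac Trapezoid rise/fall fraction of the duration.
#' @param noise_sd Additive Gaussian noise standard deviation (default 0).
#' @param seed RNG seed for the noise.
#' @return Tibble with `time` and `value`.
#' @examples
#' p <- make_pulse("constant", amplitude = 100, duration = 0.020)
#' hic15(p)$hic  # 1500
#' @export
make_pulse <- function(shape = c("haversine", "half-sine", "trapezoid", "constant"),
                       amplitude, duration, onset = 0.005, tail = onset,
                       rate = 10000, rise_frac = 0.1, noise_sd = 0,
                       seed = NULL) {
  shape <- match.arg(shape)
  if (duration <= 0 || rate <= 0) {
    abort_input("`duration` and `rate` must be positive.")
  }
  if (rate * duration < 20) {
    abort_input("Sampling rate too low: need at least 20 samples per pulse.")
  }
  if (rise_frac <= 0 || rise_frac >= 0.5) {
    abort_input("`rise_frac` must be in (0, 0.5).")
  }
  time <- seq(0, onset + duration + tail, by = 1 / rate)
  tp <- time - onset  # time since pulse start
  inside <- tp >= 0 & tp <= duration
  value <- numeric(length(time))
  value[inside] <- switch(shape,
    constant = amplitude,
    `half-sine` = amplitude * sin(pi * tp[inside] / duration),
    haversine = amplitude * sin(pi * tp[inside] / duration)^2,
    trapezoid = {
      u <- tp[inside] / duration
      amplitude * pmin(1, u / rise_frac, (1 - u) / rise_frac)
    })
  if (noise_sd > 0) {
    value <- value + with_seed(seed, rnorm(length(value), sd = noise_sd))
  }
  tibble(time = time, value = value)
}

#' Assemble pulses into a channel set
#'
#' Combines named pulse channels (each a `time`/`value` tibble from
#' [make_pulse()]) into one [channel_set()] on a common time base, with
#' units taken from the supplied mapping. Channels sampled at a different
#' rate are resampled onto the first channel's time base by linear
#' interpolation, with a warning.
#'
#' @param channels Named list of `time`/`value` data frames.
#' @param units Named character vector of units, one per channel.
#' @return A [channel_set()].
#' @export
make_channelset <- function(channels, units) {
  if (length(channels) == 0L || is.null(names(channels))) {
    abort_input("`channels` must be a non-empty named list.")
  }
  base_time <- channels[[1L]][["time"]]
  cols <- list(time = base_time)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    check_channel(ch, "value")
    if (length(ch$time) != length(base_time) ||
        !isTRUE(all.equal(ch$time, base_time))) {
      warn(sprintf("Channel `%s` is on a different time base; resampling.", nm))
      cols[[nm]] <- approx(ch$time, ch$value, xout = base_time,
                           rule = 2)$y
    } else {
      cols[[nm]] <- ch$value
    }
  }
  channel_set(as_tibble(cols), units = units)
}

#' Sample and classify landing severities
#'
#' Draws landing-severity values from a normal distribution and classifies
#' each against the design thresholds: nominal up to `mu + 1.5 sigma`,
#' off-nominal up to `mu + 2.5 sigma`, contingency beyond. The empirical
#' class fractions converge to the normal-CDF values of the landing-mode
#' threshold table (93.3% nominal, 6.1% off-nominal, 0.6% contingency).
#'
#' @param n Number of landings to draw, >= 1.
#' @param mean,sd Severity-index distribution parameters (`sd > 0`).
#' @param seed RNG seed; generation is deterministic for a fixed seed.
#' @return Tibble with `severity` and `class`
#'   (factor: nominal / off_nominal / contingency).
#' @export
sample_landings <- function(n, mean = 0, sd = 1, seed = NULL) {
  if (n < 1) abort_input("`n` must be at least 1.")
  if (sd <= 0) abort_domain("`sd` must be positive.")
  severity <- with_seed(seed, rnorm(n, mean, sd))
  cls <- cut(severity,
             breaks = c(-Inf, mean + 1.5 * sd, mean + 2.5 * sd, Inf),
             labels = c("nominal", "off_nominal", "contingency"))
  tibble(severity = severity, class = cls)
}
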