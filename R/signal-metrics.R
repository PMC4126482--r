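#' @importFrom tibble tibble as_tibble
NULL

# shared validation for a single time/value channel held in a data frame
check_channel <- function(data, value_col, require_nonneg = FALSE) {
  if (!is.data.frame(data)) abort_input("Channel data must be a data frame.")
  if (!"time" %in% names(data)) abort_input("Channel data needs a `time` column (s).")
  if (!value_col %in% names(data)) {
    abort_input(sprintf("Channel column `%s` not found.", value_col))
  }
  t <- data[["time"]]
  v <- data[[value_col]]
  if (length(t) < 2L) abort_input("A channel needs at least 2 samples.")
  if (anyNA(t) || anyNA(v) || any(!is.finite(v))) {
    abort_input("Channel contains NA/NaN/Inf values.")
  }
  if (any(diff(t) <= 0)) {
    abort_input("Channel `time` must be strictly increasing.")
  }
  if (require_nonneg && any(v < 0)) {
    abort_input(sprintf("Channel `%s` must be non-negative.", value_col))
  }
  invisible(data)
}

# cumulative trapezoidal integral on a possibly non-uniform time base;
# element k is the integral from t[1] to t[k]
cumtrapz_channel <- function(t, v) {
  n <- length(t)
  c(0, cumsum(diff(t) * (v[-n] + v[-1]) / 2))
}

#' Head injury criterion over sliding windows (HIC-15)
#'
#' Maximizes `((t2 - t1)^-1 * integral of a(t) dt)^2.5 * (t2 - t1)` over all
#' windows `[t1, t2]` of the trace no longer than `window_max` seconds.
#' Acceleration must be the resultant magnitude in g (the conventional unit
#' of the criterion). Integration is trapezoidal on the native time base and
#' window endpoints are restricted to sample times (no sub-sample
#' interpolation), so the search is exactly equivalent to an all-pairs
#' enumeration of sample-time windows.
#'
#' @param data Data frame with a `time` column (seconds, strictly
#'   increasing) and the acceleration channel.
#' @param channel Name of the acceleration column (default `"value"`).
#' @param window_max Maximum window length in seconds (0.015 for HIC-15).
#' @param prefilter Optional function applied to the acceleration vector
#'   before the search (e.g. a CFC filter). Default: pass-through -- no
#'   filtering is applied unless requested.
#' @return One-row tibble with columns `hic`, `t1`, `t2` (optimal window
#'   bounds in seconds).
#' @examples
#' tr <- make_pulse("constant", amplitude = 100, duration = 0.020)
#' hic15(tr)  # 100^2.5 * 0.015 = 1500
#' @export
hic15 <- function(data, channel = "value", window_max = 0.015,
                  prefilter = NULL) {
  if (!is.numeric(window_max) || length(window_max) != 1L || window_max <= 0) {
    abort_input("`window_max` must be a single positive duration in seconds.")
  }
  check_channel(data, channel, require_nonneg = TRUE)
  t <- data[["time"]]
  v <- data[[channel]]
  if (!is.null(prefilter)) {
    v <- prefilter(v)
    if (length(v) != length(t)) abort_input("`prefilter` must preserve length.")
  }
  un <- attr(data, "units")
  if (!is.null(un) && !is.na(un[channel]) && !identical(unname(un[channel]), "g")) {
    abort_input(sprintf(
      "HIC requires acceleration in g; channel `%s` is declared as `%s`.",
      channel, un[channel]))
  }
  cint <- cumtrapz_channel(t, v)
  n <- length(t)
  best <- 0; best_t1 <- t[1L]; best_t2 <- t[min(2L, n)]
  for (i in seq_len(n - 1L)) {
    jmax <- min(n, i + 2L + findInterval(t[i] + window_max, t[(i + 1L):n]))
    j <- (i + 1L):jmax
    dt <- t[j] - t[i]
    keep <- dt <= window_max
    if (!any(keep)) next
    j <- j[keep]; dt <- dt[keep]
    h <- ((cint[j] - cint[i]) / dt)^2.5 * dt
    k <- which.max(h)
    if (h[k] > best) {
      best <- h[k]; best_t1 <- t[i]; best_t2 <- t[j[k]]
    }
  }
  tibble(hic = best, t1 = best_t1, t2 = best_t2)
}

#' Brain rotational injury criterion (BrIC)
#'
#' Normalized Euclidean combination of the peak absolute angular head
#' velocities about the three anatomical axes:
#' `BrIC = sqrt(sum_i (max|omega_i| / omega_iC)^2)` with critical values
#' 66.3, 53.8 and 41.5 rad/s for X, Y, Z. The per-axis maxima are taken
#' independently over the trace (they need not be simultaneous), and the
#' result is invariant to sign flips of any axis.
#'
#' @param data Data frame with `time` and three angular-velocity columns in
#'   rad/s.
#' @param channels Names of the X, Y, Z angular-velocity columns, in that
#'   order (so critical values move with their axes).
#' @param critical Critical angular velocities (rad/s) for the same axes.
#' @return A single non-negative number.
#' @examples
#' tr <- tibble::tibble(time = c(0, 1), omega_x = c(0, 66.3),
#'                      omega_y = 0, omega_z = 0)
#' bric(tr)  # 1
#' @export
bric <- function(data, channels = c("omega_x", "omega_y", "omega_z"),
                 critical = c(66.3, 53.8, 41.5)) {
  if (length(channels) != 3L || length(critical) != 3L) {
    abort_input("BrIC needs exactly three angular-velocity channels and critical values.")
  }
  for (ch in channels) check_channel(data, ch)
  peaks <- vapply(channels, function(ch) max(abs(data[[ch]])), numeric(1))
  sqrt(sum((peaks / critical)^2))
}

#' Distal forearm speed metric
#'
#' Reduces a forearm-speed trace (m/s) to a scalar predictor of forearm
#' flail injury: either the peak speed or the time-weighted average over a
#' caller-supplied window. The source literature alternates between peak
#' and average readings, so both are exposed; `"peak"` is the default.
#'
#' @param data Data frame with `time` and the speed channel (m/s).
#' @param channel Name of the speed column.
#' @param mode `"peak"` (maximum of the trace) or `"average"`
#'   (trapezoidal time average over `window`).
#' @param window Length-2 numeric `c(t1, t2)` for `mode = "average"`;
#'   defaults to the full trace.
#' @return Speed in m/s.
#' @export
adfs <- function(data, channel = "value", mode = c("peak", "average"),
                 window = NULL) {
  mode <- match.arg(mode)
  check_channel(data, channel, require_nonneg = TRUE)
  t <- data[["time"]]
  v <- data[[channel]]
  if (mode == "peak") return(max(v))
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 2L) abort_input("ADFS averaging window contains fewer than 2 samples.")
  tw <- t[keep]; vw <- v[keep]
  sum(diff(tw) * (vw[-length(vw)] + vw[-1]) / 2) / (tw[length(tw)] - tw[1])
}

#' Mass-scale a distal forearm speed between surrogates
#'
#' Linear mass scaling of an ADFS value from the reference surrogate arm
#' (2.67 kg) to another arm mass:
#' `ADFS_scaled = ADFS_measured + 1.94 * (mass - 2.67)`. Identity at the
#' reference mass; the THOR arm assembly weighs 4.27 kg.
#'
#' @param adfs_measured Measured ADFS, m/s.
#' @param surrogate_mass Arm mass of the target surrogate, kg, > 0.
#' @export
adfs_mass_scale <- function(adfs_measured, surrogate_mass) {
  if (any(surrogate_mass <= 0)) abort_domain("`surrogate_mass` must be positive (kg).")
  adfs_measured + 1.94 * (surrogate_mass - 2.67)
}

#' Pointwise resultant of up to three channels
#'
#' Euclidean norm across the named columns at each sample, e.g. to form the
#' resultant head acceleration for [hic15()] from axis channels sharing one
#' time base. A single channel reduces to its absolute value.
#'
#' @param data Data frame with `time` and the component columns.
#' @param channels Names of 1 to 3 component columns.
#' @return Tibble with `time` and the resultant in `value`.
#' @export
resultant <- function(data, channels) {
  if (length(channels) < 1L || length(channels) > 3L) {
    abort_input("`resultant()` takes 1 to 3 component channels.")
  }
  for (ch in channels) check_channel(data, ch)
  m <- as.matrix(data[channels])
  tibble(time = data[["time"]], value = sqrt(rowSums(m^2)))
}

# ---- channel-set container + CSV/YAML sidecar I/O ---------------------------

#' Assemble a channel set with declared units
#'
#' A channel set is a wide tibble (one `time` column plus one column per
#' channel, all on a shared time base) carrying a named `units` attribute
#' and the sampling rate. This is the in-memory form of a CSV channel file
#' plus its YAML sidecar.
#'
#' @param data Data frame with `time` plus value columns.
#' @param units Named character vector mapping channel names to unit strings
#'   (`"g"`, `"rad/s"`, `"m/s"`, `"N"`).
#' @return The data as a tibble of class `channel_set`.
#' @export
channel_set <- function(data, units) {
  chans <- setdiff(names(data), "time")
  for (ch in chans) check_channel(data, ch)
  if (is.null(names(units)) || !all(chans %in% names(units))) {
    abort_input("`units` must be a named vector covering every channel.")
  }
  out <- as_tibble(data)
  attr(out, "units") <- units[chans]
  attr(out, "rate") <- 1 / stats::median(diff(data[["time"]]))
  class(out) <- c("channel_set", class(out))
  out
}

#' Write / read a channel set as CSV plus YAML sidecar
#'
#' The CSV holds one `time` column (s) and named value columns; the sidecar
#' (same path with `.yaml` appended by default) declares per-channel units
#' and the sampling rate, so a round trip preserves everything but float
#' formatting.
#'
#' @param cs A [channel_set()].
#' @param path CSV path.
#' @param sidecar YAML sidecar path (default `paste0(path, ".yaml")`).
#' @return `write_channelset()`: `path`, invisibly. `read_channelset()`:
#'   a [channel_set()].
#' @export
write_channelset <- function(cs, path, sidecar = paste0(path, ".yaml")) {
  readr::write_csv(as.data.frame(cs), path)
  meta <- list(units = as.list(attr(cs, "units")),
               rate = as.numeric(attr(cs, "rate")))
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' @rdname write_channelset
#' @export
read_channelset <- function(path, sidecar = paste0(path, ".yaml")) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  meta <- yaml::read_yaml(sidecar)
  channel_set(data, units = unlist(meta$units))
}
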