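# Independent oracles used across the suite. They deliberately avoid the
# package's computational paths: the HIC oracle enumerates every admissible
# sample-time window and integrates each one from scratch; the inversion
# oracle is plain bisection on the forward curve.

# all-pairs brute-force HIC: fresh trapezoidal integral per window
hic_brute_force <- function(time, accel, window_max = 0.015) {
  n <- length(time)
  best <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dt <- time[j] - time[i]
      if (dt > window_max) break
      seg <- i:j
      integral <- sum(diff(time[seg]) *
                        (accel[seg][-length(seg)] + accel[seg][-1]) / 2)
      h <- (integral / dt)^2.5 * dt
      if (h > best) best <- h
    }
  }
  best
}

# bisection inverse of a monotone-increasing forward risk function
bisect_inverse <- function(f, target, lower, upper, tol = 1e-12, maxit = 200) {
  for (k in seq_len(maxit)) {
    mid <- (lower + upper) / 2
    if (f(mid) < target) lower <- mid else upper <- mid
    if (upper - lower < tol * max(1, abs(mid))) break
  }
  (lower + upper) / 2
}

# continuous-time HIC for an analytic haversine pulse: exact integral
# A/2 * (t - D sin(2 pi t / D) / (2 pi)) on [0, D], optimized over window
# endpoints with a dense grid + local refinement
hic_haversine_oracle <- function(amplitude, duration, window_max = 0.015) {
  Iexact <- function(t) {
    t <- pmin(pmax(t, 0), duration)
    amplitude / 2 * (t - duration * sin(2 * pi * t / duration) / (2 * pi))
  }
  hic_of <- function(t1, t2) {
    dt <- t2 - t1
    ((Iexact(t2) - Iexact(t1)) / dt)^2.5 * dt
  }
  obj <- function(par) {
    t1 <- par[1]; w <- par[2]
    if (w <= 0 || w > window_max || t1 < 0 || t1 + w > duration) return(Inf)
    -hic_of(t1, t1 + w)
  }
  grid <- expand.grid(t1 = seq(0, duration, length.out = 60),
                      w = seq(duration / 50, min(window_max, duration),
                              length.out = 60))
  vals <- apply(grid, 1, obj)
  st <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  -opt$value
}
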