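#' Relative growth rate of an SPD
#'
#' Transforms a summed probability distribution into a per-annum relative
#' growth rate, `RGR(t) = (SPD(t + dt) - SPD(t)) / (SPD(t) * dt)`, where
#' `t + dt` is one slice later in calendar time (i.e. *younger*, smaller cal
#' BP). A fine-grid SPD is first aggregated to `dt`-wide slices by averaging.
#' Slices with zero (or negative) SPD give an undefined rate, flagged NA --
#' never silently zero.
#'
#' @param spd A [grid_series()] SPD (any step dividing `dt`).
#' @param dt Differencing interval in years (default 100, the slice width).
#' @return An RGR [grid_series()] on `dt` slices (one slice shorter than the
#'   input); attribute `n_undefined` counts flagged bins.
#' @export
rgr <- function(spd, dt = 100) {
  if (any(spd$value < 0, na.rm = TRUE)) abort("SPD must be nonnegative")
  step <- gs_step(spd)
  x <- if (!is.na(step) && step < dt) aggregate_grid(spd, dt) else spd
  v <- x$value
  n <- length(v)
  if (n < 2) abort("series too short for a growth rate")
  nxt <- v[-1]
  cur <- v[-n]
  r <- ifelse(cur > 0, (nxt - cur) / (cur * dt), NA_real_)
  out <- grid_series(x$cal_bp[-n], r, label = "RGR")
  attr(out, "n_undefined") <- sum(is.na(r))
  out
}

# distance-decaying (triangular) kernel smoother with edge renormalization
kernel_smooth <- function(v, step, half_width, kernel = "triangular") {
  if (half_width <= 0) return(v)
  m <- floor(half_width / step)
  if (m < 1) return(v)
  u <- (-m:m) * step
  w <- switch(kernel,
    triangular = pmax(0, 1 - abs(u) / half_width),
    gaussian = dnorm(u, 0, half_width / 2),
    abort(sprintf("unknown kernel '%s'", kernel))
  )
  n <- length(v)
  out <- numeric(n)
  na <- is.na(v)
  vv <- ifelse(na, 0, v)
  for (i in seq_len(n)) {
    j <- max(1, i - m):min(n, i + m)
    wj <- w[j - i + m + 1]
    wj[na[j]] <- 0
    sw <- sum(wj)
    out[i] <- if (sw > 0) sum(wj * vv[j]) / sw else NA_real_
  }
  out
}

# moving average with window truncated at the series ends
moving_average <- function(v, step, width) {
  m <- floor(width / step / 2)
  n <- length(v)
  out <- numeric(n)
  na <- is.na(v)
  vv <- ifelse(na, 0, v)
  cs <- cumsum(vv)
  cn <- cumsum(as.numeric(!na))
  for (i in seq_len(n)) {
    lo <- max(1, i - m); hi <- min(n, i + m)
    cnt <- cn[hi] - if (lo > 1) cn[lo - 1] else 0
    s <- cs[hi] - if (lo > 1) cs[lo - 1] else 0
    out[i] <- if (cnt > 0) s / cnt else NA_real_
  }
  out
}

#' Bandpass preprocessing: smooth, detrend, normalize
#'
#' The standard treatment applied to every series before comparison: a
#' distance-decaying (triangular) smoothing kernel of length `smooth_len`
#' removes sub-centennial noise (high-pass cut), subtracting a
#' `detrend_win`-wide moving average removes the millennial trend (low-pass
#' cut), the residual is mean-centred and, if requested, divided by its
#' standard deviation. Moving-average windows are truncated at the series
#' ends rather than padded.
#'
#' @param series A [grid_series()] (NA bins are carried through).
#' @param smooth_len Smoothing kernel half-width in years (default 130).
#' @param detrend_win Moving-average trend window in years (default 1500).
#' @param normalize Divide by the standard deviation (default TRUE).
#' @param kernel Smoothing kernel shape, `"triangular"` (default) or
#'   `"gaussian"`.
#' @return A preprocessed [grid_series()].
#' @export
preprocess <- function(series, smooth_len = 130, detrend_win = 1500,
                       normalize = TRUE, kernel = "triangular") {
  step <- gs_step(series)
  sm <- kernel_smooth(series$value, step, smooth_len, kernel)
  trend <- moving_average(sm, step, detrend_win)
  out <- sm - trend
  mu <- mean(out, na.rm = TRUE)
  out <- out - mu
  if (normalize) {
    s <- sd(out, na.rm = TRUE)
    tol <- 1e-10 * max(1, max(abs(series$value), na.rm = TRUE))
    if (!is.finite(s) || s < tol) abort("zero-variance series cannot be normalized")
    out <- out / s
  }
  grid_series(series$cal_bp, out, label = attr(series, "label"),
              normalized = normalize)
}

#' Boom/bust event density from occupation-density series
#'
#' Converts independent (non-SPD) occupation-density series into a
#' continental boom/bust density: each series' change rate is smoothed,
#' detrended and normalized, time steps where it exceeds +`threshold` count
#' as a boom (+1) and below -`threshold` as a bust (-1); event series are
#' summed across records and divided by the number of series covering each
#' time step.
#'
#' @param series_list List of [grid_series()] occupation-density series, each
#'   on its own support (steps must agree).
#' @param threshold Event threshold on the normalized change rate (default
#'   0.5).
#' @param ... Passed to [preprocess()].
#' @return A [grid_series()] of normalized boom-minus-bust density on the
#'   union support.
#' @export
occupation_boom_bust_density <- function(series_list, threshold = 0.5, ...) {
  if (length(series_list) == 0) abort("no occupation series supplied")
  steps <- vapply(series_list, gs_step, numeric(1))
  if (max(steps) - min(steps) > 1e-8) abort("series steps must agree")
  step <- steps[1]
  hi <- max(vapply(series_list, function(s) max(s$cal_bp), numeric(1)))
  lo <- min(vapply(series_list, function(s) min(s$cal_bp), numeric(1)))
  grid <- seq(hi, lo, by = -step)
  events <- matrix(NA_real_, length(grid), length(series_list))
  for (k in seq_along(series_list)) {
    s <- series_list[[k]]
    # forward-in-time (toward smaller cal BP) change rate per annum
    rate <- c(diff(s$value) / step, NA)
    pr <- preprocess(grid_series(s$cal_bp, rate), ...)
    ev <- ifelse(is.na(pr$value), NA_real_,
                 ifelse(pr$value > threshold, 1, ifelse(pr$value < -threshold, -1, 0)))
    idx <- match(round(s$cal_bp, 6), round(grid, 6))
    ok <- !is.na(idx)
    events[idx[ok], k] <- ev[ok]
  }
  cover <- rowSums(!is.na(events))
  dens <- ifelse(cover > 0, rowSums(events, na.rm = TRUE) / cover, NA_real_)
  grid_series(grid, dens, label = "boom-bust density")
}
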