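series_values <- function(x) {
  if (inherits(x, "grid_series") || (is.data.frame(x) && "value" %in% names(x))) x$value
  else as.numeric(x)
}

series_step <- function(x, default = 100) {
  if (inherits(x, "grid_series")) gs_step(x) else default
}

#' Fourier power spectrum of a preprocessed series
#'
#' Raw periodogram (mean removed, no taper, no padding) of a regularly
#' sampled series; dominant periods appear as peaks and are read off as
#' inverse peak frequencies. Frequency resolution is one Rayleigh bin,
#' `1 / (n * step)` per annum.
#'
#' @param series A [grid_series()] (or numeric vector with `step` given).
#' @param step Grid step in years when `series` is a bare vector.
#' @return A `spectrum_result` tibble: `frequency` (1/a), `period` (a),
#'   `power`; attributes `step`, `n`, `rayleigh`.
#' @export
power_spectrum <- function(series, step = NULL) {
  v <- series_values(series)
  step <- step %||% series_step(series)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 8) abort("series too short for a spectrum")
  sp <- spec.pgram(stats::ts(v), taper = 0, fast = FALSE, detrend = TRUE,
                   plot = FALSE)
  out <- tibble::tibble(
    frequency = sp$freq / step,
    period = step / sp$freq,
    power = sp$spec
  )
  class(out) <- c("spectrum_result", class(out))
  attr(out, "step") <- step
  attr(out, "n") <- n
  attr(out, "rayleigh") <- 1 / (n * step)
  out
}

#' @rdname power_spectrum
#' @param spec A `spectrum_result`.
#' @param n_peaks How many dominant periods to report.
#' @return `dominant_periods()`: tibble of local spectral maxima ordered by
#'   power.
#' @export
dominant_periods <- function(spec, n_peaks = 3) {
  p <- spec$power
  n <- length(p)
  is_peak <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) p[i - 1] else -Inf
    r <- if (i < n) p[i + 1] else -Inf
    p[i] >= l && p[i] >= r
  }, logical(1))
  pk <- spec[is_peak, ]
  pk <- pk[order(-pk$power), ]
  head(tibble::as_tibble(pk), n_peaks)
}

#' Trimmed correlation (zero-lag cross-extremogram)
#'
#' Pearson correlation restricted to the extremal part of the reference
#' series: only time steps where `a` lies in its lower or upper
#' `tail_fraction` quantiles are retained, removing low-amplitude noise.
#' With `tail_fraction = 0.5` every point is retained and the statistic
#' equals the plain Pearson correlation.
#'
#' @param a,b Series on the same grid ([grid_series()] or numeric).
#' @param tail_fraction Fraction retained in each tail (default 0.25).
#' @param symmetric Also retain points extremal in `b` (union mask)?
#' @return Correlation in `[-1, 1]`, or NA (with a warning) when fewer than
#'   8 points remain.
#' @export
trim_correlation <- function(a, b, tail_fraction = 0.25, symmetric = FALSE) {
  va <- series_values(a); vb <- series_values(b)
  stopifnot(length(va) == length(vb))
  ok <- !is.na(va) & !is.na(vb)
  va2 <- va[ok]; vb2 <- vb[ok]
  mask_of <- function(v) {
    qlo <- quantile(v, tail_fraction, names = FALSE)
    qhi <- quantile(v, 1 - tail_fraction, names = FALSE)
    v <= qlo | v >= qhi
  }
  keep <- mask_of(va2)
  if (symmetric) keep <- keep | mask_of(vb2)
  if (sum(keep) < 8) {
    warn("fewer than 8 extremal points; trimmed correlation undefined")
    return(NA_real_)
  }
  cor(va2[keep], vb2[keep])
}

# peak runs of a series: maximal stretches with |v| > eps and constant sign
peak_runs <- function(v, eps) {
  state <- ifelse(is.na(v), 0, ifelse(v > eps, 1L, ifelse(v < -eps, -1L, 0L)))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  data.frame(start = starts[keep], end = ends[keep], sign = r$values[keep])
}

# weights and reference signs for the tapered peak windows of `v`
peak_weights <- function(v, eps, step, taper) {
  runs <- peak_runs(v, eps)
  n <- length(v)
  w <- numeric(n)
  s <- integer(n)
  if (nrow(runs) == 0) return(NULL)
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start[k]:runs$end[k]
    w[idx] <- 1
    s[idx] <- runs$sign[k]
    if (taper > 0 && step > 0) {
      m <- ceiling(taper / step) - 1L
      if (m >= 1) {
        for (d in seq_len(m)) {
          wt <- 1 - d * step / taper
          if (wt <= 0) break
          for (i in c(runs$start[k] - d, runs$end[k] + d)) {
            if (i >= 1 && i <= n && wt > w[i]) {
              w[i] <- wt
              s[i] <- runs$sign[k]
            }
          }
        }
      }
    }
  }
  list(w = w, sign = s)
}

phase_overlap_raw <- function(pw, vb) {
  use <- pw$w > 0 & !is.na(vb)
  den <- sum(pw$w[use] * abs(vb[use]))
  if (den <= 0) return(NA_real_)
  agree <- sign(vb[use]) == pw$sign[use]
  100 * sum(pw$w[use] * abs(vb[use]) * agree) / den
}

#' Phase overlap between two series
#'
#' Measures how much of a comparison series `b` shares the sign of the
#' reference series `a` during `a`'s boom and bust phases. Peak intervals of
#' `a` (|a| above a small `peak_eps`) carry weight 1 and are extended by
#' `taper` years on each side with linearly decreasing weight; the weighted
#' |b|-mass agreeing in sign with the peak is divided by the total weighted
#' |b|-mass. A re-adjustment factor (the reciprocal of `a`'s raw
#' self-overlap, a number close to one) guarantees that two identical
#' signals overlap at exactly 100%; results are clipped to [0, 100].
#' Identical series give 100%, sign-flipped copies ~0%, and independent
#' series ~50%.
#'
#' @param a Reference series (defines the peak windows).
#' @param b Comparison series on the same grid.
#' @param peak_eps Peak threshold; default `0.05 * sd(a)`.
#' @param taper Taper length in years (default 100).
#' @param step Grid step when the inputs are bare vectors.
#' @return Overlap percentage in [0, 100]; NA (with a warning) when `a` has
#'   no peak interval.
#' @export
phase_overlap <- function(a, b, peak_eps = NULL, taper = 100, step = NULL) {
  va <- series_values(a); vb <- series_values(b)
  stopifnot(length(va) == length(vb))
  step <- step %||% series_step(a)
  eps <- peak_eps %||% (0.05 * sd(va, na.rm = TRUE))
  pw <- peak_weights(va, eps, step, taper)
  if (is.null(pw)) {
    warn("reference series has no peak interval; phase overlap undefined")
    return(NA_real_)
  }
  raw_self <- phase_overlap_raw(pw, va)
  raw <- phase_overlap_raw(pw, vb)
  if (is.na(raw) || is.na(raw_self) || raw_self <= 0) return(NA_real_)
  min(max(raw * 100 / raw_self, 0), 100)
}

#' Classify the synchrony of two series
#'
#' Applies the working thresholds: overlap above 67% is "strong synchrony"
#' (empirically corresponding to trimmed correlations above 0.5); overlap
#' below 49% together with a negative trimmed correlation is "antiphase";
#' everything else is "intermediate".
#'
#' @param overlap Phase overlap in percent.
#' @param r_t Trimmed correlation.
#' @return Character vector of labels.
#' @export
classify_synchrony <- function(overlap, r_t) {
  ifelse(is.na(overlap) | is.na(r_t), NA_character_,
    ifelse(overlap > 67, "strong synchrony",
      ifelse(overlap < 49 & r_t < 0, "antiphase", "intermediate")))
}

#' All synchrony statistics of a pair of series
#'
#' @param a,b Preprocessed series on the same grid.
#' @param tail_fraction,peak_eps,taper See [trim_correlation()] and
#'   [phase_overlap()].
#' @param step Grid step for bare vectors.
#' @return One-row tibble: `overlap`, `r_t`, `label`.
#' @export
synchrony_stats <- function(a, b, tail_fraction = 0.25, peak_eps = NULL,
                            taper = 100, step = NULL) {
  ov <- phase_overlap(a, b, peak_eps = peak_eps, taper = taper, step = step)
  rt <- trim_correlation(a, b, tail_fraction = tail_fraction)
  tibble::tibble(overlap = ov, r_t = rt, label = classify_synchrony(ov, rt))
}
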