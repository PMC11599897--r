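#' Regular calendar-time series on a cal BP grid
#'
#' All regularly sampled series in the pipeline (SPDs, growth rates, stability
#' indices, forcings) share one container: a tibble with columns `cal_bp` and
#' `value`, where `cal_bp` is a uniform, strictly *descending* grid of calendar
#' years before present (0 BP = 1950 CE). Descending order means the series
#' reads forward in time from top to bottom.
#'
#' @param cal_bp Numeric vector, uniform strictly descending grid (cal BP).
#' @param value Numeric vector, one value per grid point (NA marks bins where
#'   the quantity is undefined, e.g. a growth rate over an empty SPD bin).
#' @param label Short description carried along for plots.
#' @param normalized Logical flag recording whether `value` has been
#'   variance-normalized.
#' @return A `grid_series` tibble with attributes `step`, `label`,
#'   `normalized`.
#' @examples
#' gs <- grid_series(seq(9000, 3000, by = -100), sin(seq_len(61)))
#' gs_step(gs)
#' @export
grid_series <- function(cal_bp, value, label = "", normalized = FALSE) {
  if (length(cal_bp) != length(value)) {
    abort("`cal_bp` and `value` must have the same length.")
  }
  if (length(cal_bp) >= 2) {
    d <- diff(cal_bp)
    if (any(d >= 0)) abort("`cal_bp` must be strictly descending (old to young).")
    if (max(d) - min(d) > 1e-6 * abs(mean(d))) {
      abort("`cal_bp` must be a uniform grid.")
    }
  }
  out <- tibble::tibble(cal_bp = as.numeric(cal_bp), value = as.numeric(value))
  class(out) <- c("grid_series", class(out))
  attr(out, "step") <- if (length(cal_bp) >= 2) abs(cal_bp[2] - cal_bp[1]) else NA_real_
  attr(out, "label") <- label
  attr(out, "normalized") <- normalized
  out
}

#' @rdname grid_series
#' @param x A data frame with columns `cal_bp` and `value`.
#' @export
as_grid_series <- function(x, label = "", normalized = FALSE) {
  if (inherits(x, "grid_series")) return(x)
  stopifnot(is.data.frame(x), all(c("cal_bp", "value") %in% names(x)))
  x <- x[order(-x$cal_bp), ]
  grid_series(x$cal_bp, x$value, label = label, normalized = normalized)
}

#' @rdname grid_series
#' @export
gs_step <- function(x) attr(x, "step")

gs_relabel <- function(x, label = NULL, normalized = NULL) {
  if (!is.null(label)) attr(x, "label") <- label
  if (!is.null(normalized)) attr(x, "normalized") <- normalized
  x
}

#' Aggregate a grid series into wider time slices
#'
#' Averages consecutive bins into slices of width `width` (a multiple of the
#' native step); used to move from the fine internal calibration grid to the
#' 100 a analysis slices. Slice time stamps are the mean cal BP of the member
#' bins.
#'
#' @param x A [grid_series()].
#' @param width Target slice width in years.
#' @return A `grid_series` at step `width`.
#' @export
aggregate_grid <- function(x, width) {
  step <- gs_step(x)
  if (is.na(step)) abort("series too short to aggregate")
  k <- width / step
  if (abs(k - round(k)) > 1e-8) abort("`width` must be a multiple of the grid step.")
  k <- as.integer(round(k))
  if (k == 1L) return(x)
  n <- nrow(x) %/% k
  if (n < 1) abort("series shorter than one slice")
  idx <- rep(seq_len(n), each = k)
  keep <- seq_len(n * k)
  cal <- tapply(x$cal_bp[keep], idx, mean)
  val <- tapply(x$value[keep], idx, mean)
  grid_series(as.numeric(cal), as.numeric(val),
              label = attr(x, "label"), normalized = attr(x, "normalized"))
}

#' Resample an irregular (cal BP, value) series onto a regular grid
#'
#' Linear interpolation within the support of the input; points of the target
#' grid outside the support are NA.
#'
#' @param x Data frame with `cal_bp` and `value` (any order, need not be
#'   regular).
#' @param step Target grid step in years.
#' @param window Optional `c(older, younger)` cal BP bounds for the target
#'   grid; defaults to the input's support rounded to the step.
#' @return A `grid_series`.
#' @export
resample_grid <- function(x, step, window = NULL) {
  stopifnot(is.data.frame(x), all(c("cal_bp", "value") %in% names(x)))
  x <- x[order(-x$cal_bp), ]
  if (is.null(window)) {
    window <- c(floor(max(x$cal_bp) / step) * step,
                ceiling(min(x$cal_bp) / step) * step)
  }
  grid <- seq(window[1], window[2], by = -step)
  v <- approx(x$cal_bp, x$value, xout = grid, rule = 1)$y
  grid_series(grid, v)
}

restrict_window <- function(x, window) {
  keep <- x$cal_bp <= window[1] + 1e-9 & x$cal_bp >= window[2] - 1e-9
  grid_series(x$cal_bp[keep], x$value[keep],
              label = attr(x, "label"), normalized = attr(x, "normalized"))
}

# align two grid series onto their common support; returns list(a, b)
common_support <- function(a, b) {
  sa <- gs_step(a); sb <- gs_step(b)
  if (abs(sa - sb) > 1e-8) abort("series must share the same grid step")
  hi <- min(max(a$cal_bp), max(b$cal_bp))
  lo <- max(min(a$cal_bp), min(b$cal_bp))
  if (hi < lo) abort("series have no overlapping support")
  list(a = restrict_window(a, c(hi, lo)), b = restrict_window(b, c(hi, lo)))
}
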