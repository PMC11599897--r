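# Shared fixtures, all built in code at test time.

# identity calibration curve over a cal BP range, optionally with zero error
identity_curve <- function(from = 2000, to = 10000, step = 5, sigma = 0) {
  cal <- seq(from, to, by = step)
  paleocycles:::new_calibration_curve(cal, cal, rep(sigma, length(cal)))
}

# curve with a near-plateau (slope `slope`) between plateau[1] and plateau[2]
plateau_curve <- function(from = 2000, to = 10000, step = 5,
                          plateau = c(6100, 5900), slope = 0.05, sigma = 0) {
  cal <- seq(from, to, by = step)
  d <- ifelse(cal > plateau[2] & cal <= plateau[1], slope, 1)
  # rescale so the total mu range matches the cal range
  mu <- cumsum(c(cal[1], d[-1] * step))
  paleocycles:::new_calibration_curve(cal, mu, rep(sigma, length(cal)))
}

# white-noise grid series of n bins at 100 a step
noise_series <- function(n = 120, step = 100, start = NULL) {
  if (is.null(start)) start <- 3000 + step * (n - 1)
  grid_series(seq(start, by = -step, length.out = n), rnorm(n))
}

# preprocessed sine mixture used as a generic nontrivial signal
sine_series <- function(n = 61, step = 100, periods = c(500), start = 9000) {
  grid <- seq(start, by = -step, length.out = n)
  t <- grid[1] - grid
  v <- rowSums(sapply(periods, function(p) sin(2 * pi * t / p)))
  grid_series(grid, v)
}

# synthetic world for the logistic boom/bust recovery experiments:
# a growth-rate signal with the standard multicentennial periods, two
# exogenous inputs tracking it through independent noise, and labels drawn
# from a known logistic law on (lagged RGR, stability, TSI)
make_logit_world <- function(seed, n_bins = 120, beta = c(0, 1, 1.5, 1)) {
  set.seed(seed)
  grid <- seq(3400 + 100 * (n_bins - 1) + 400, 3400, by = -100)
  t <- grid[1] - grid
  raw <- sin(2 * pi * t / 360 + runif(1, 0, 2 * pi)) +
    sin(2 * pi * t / 500 + runif(1, 0, 2 * pi)) +
    sin(2 * pi * t / 680 + runif(1, 0, 2 * pi)) +
    rnorm(length(grid), 0, 0.4)
  g <- preprocess(grid_series(grid, raw))
  lag <- lagged_rgr(g)
  stab <- preprocess(grid_series(grid, 0.9 * g$value + 0.45 * rnorm(length(grid))))
  tsi <- preprocess(grid_series(grid, 0.8 * g$value + 0.6 * rnorm(length(grid))))
  eta <- beta[1] + beta[2] * lag$value + beta[3] * stab$value + beta[4] * tsi$value
  lab <- ifelse(is.na(eta), NA_real_,
                rbinom(length(grid), 1, stats::plogis(ifelse(is.na(eta), 0, eta))))
  tibble::tibble(cal_bp = grid, label = lab, rgr = g$value,
                 rgr_lag = lag$value, stability = stab$value, tsi = tsi$value)
}

# spatial date table with a growth anomaly injected into one 4x4 degree cell:
# background sites have flat population, the anomalous cell's dates are drawn
# from a steeply growing trajectory
anomaly_dates <- function(seed, n_background = 600, n_anomaly = 120,
                          slice = c(7400, 7000), growth = 0.004) {
  set.seed(seed)
  window <- c(slice[1] + 600, slice[2] - 600)
  grid <- seq(window[1], window[2], by = -5)
  flat <- rep(1, length(grid))
  grow <- exp(growth * (grid[1] - grid))
  draw <- function(n, wts, lon0, lat0, spread, tag) {
    if (n == 0) return(tibble::tibble())
    idx <- sample.int(length(grid), n, replace = TRUE, prob = wts)
    site <- sample.int(max(8, n %/% 12), n, replace = TRUE)
    tibble::tibble(
      lab_id = paste0(tag, seq_len(n)),
      c14_age = grid[idx] + rnorm(n, 0, 40),
      c14_sd = runif(n, 30, 60),
      lon = lon0 + runif(max(site), -spread, spread)[site],
      lat = lat0 + runif(max(site), -spread, spread)[site],
      site_id = paste0(tag, "S", site)
    )
  }
  bg <- dplyr::bind_rows(
    draw(n_background %/% 3, flat, 2, 38, 1.8, "A"),
    draw(n_background %/% 3, flat, 10, 46, 1.8, "B"),
    draw(n_background %/% 3, flat, 18, 54, 1.8, "C")
  )
  an <- draw(n_anomaly, grow, 26, 42, 1.8, "X")
  dplyr::bind_rows(bg, an)
}
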