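#' Synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generators: the analysis window,
#' the multicentennial growth-rate cycles carried by the population
#' trajectory, the radiocarbon sampling design (date counts, lab errors,
#' clustered site geography), the calibration-curve wiggles, the proxy
#' ensemble (shared latent signal, bounded chronological distortions,
#' independent noise) and the solar-forcing construction. Defaults emulate
#' the structure of the European Holocene record at desk scale: a 9--3 ka BP
#' window, growth-rate cycles with periods 360/500/680 a, lab errors around
#' 50 a, proxy dating distortions capped at 150 a.
#'
#' @param seed Integer seed; every generator draws from it reproducibly.
#' @param window `c(older, younger)` cal BP analysis window.
#' @param step Internal calendar grid step (a).
#' @param periods,amplitudes Growth-rate cycle periods (a) and amplitudes
#'   (1/a).
#' @param trend Long-term relative growth trend (1/a).
#' @param n_dates,n_sites Number of radiocarbon dates and of archaeological
#'   sites.
#' @param n_clusters Spatial site clusters (2-D Gaussian mixture).
#' @param lon_range,lat_range Spatial domain (degrees).
#' @param c14_sd_range Range of per-date lab errors (1 sigma, ¹⁴C a).
#' @param curve_wiggle ¹⁴C amplitude of calibration-curve wiggles (a); 0
#'   gives the identity curve.
#' @param curve_error Constant calibration-curve error (¹⁴C a).
#' @param n_proxies Number of proxy records.
#' @param proxy_step Mean sampling interval of proxy records (a).
#' @param distortion_cap Bound on chronological distortion per record (a).
#' @param proxy_noise_sd Independent noise on each record (units of the
#'   standardized latent).
#' @param forcing_periods Periods of the synthetic solar forcing (a).
#' @param forcing_coupling Mixing weight of the proxy latent in the forcing
#'   (0 = independent, 1 = identical up to scale).
#' @return A list of class `scenario`.
#' @export
scenario <- function(seed = 1L,
                     window = c(9000, 3000),
                     step = 5,
                     periods = c(360, 500, 680),
                     amplitudes = c(0.003, 0.003, 0.003),
                     trend = 0.0003,
                     n_dates = 2000,
                     n_sites = 150,
                     n_clusters = 8,
                     lon_range = c(-10, 30),
                     lat_range = c(36, 60),
                     c14_sd_range = c(30, 70),
                     curve_wiggle = 20,
                     curve_error = 10,
                     n_proxies = 12,
                     proxy_step = 25,
                     distortion_cap = 150,
                     proxy_noise_sd = 0.5,
                     forcing_periods = c(360, 500, 680),
                     forcing_coupling = 0) {
  sc <- as.list(environment())
  class(sc) <- "scenario"
  sc
}

# deterministic sub-seed so each generator is reproducible on its own
sub_seed <- function(sc, offset) (as.integer(sc$seed) * 97L + offset) %% .Machine$integer.max

#' Synthetic calibration curve
#'
#' Identity mapping from calendar to ¹⁴C age plus smooth random wiggles,
#' mimicking the plateaus and inversions of an empirical calibration curve.
#' Rejection-sampled so that the cal -> ¹⁴C mapping stays strictly monotone.
#'
#' @param sc A [scenario()].
#' @return A `calibration_curve` tibble with columns `cal_bp` (ascending),
#'   `mu_c14`, `sigma_curve`.
#' @export
make_calibration_curve <- function(sc) {
  margin <- 500
  cal <- seq(sc$window[2] - margin, sc$window[1] + margin, by = sc$step)
  set.seed(sub_seed(sc, 11L))
  for (try in 1:50) {
    mu <- cal
    if (sc$curve_wiggle > 0) {
      wl <- c(250, 420, 700, 1100)
      amp <- sc$curve_wiggle * c(0.5, 0.8, 1, 0.7) / 3
      ph <- runif(length(wl), 0, 2 * pi)
      for (m in seq_along(wl)) mu <- mu + amp[m] * length(wl) / 2 * sin(2 * pi * cal / wl[m] + ph[m])
    }
    if (all(diff(mu) > 0)) {
      return(new_calibration_curve(cal, mu, rep(sc$curve_error, length(cal))))
    }
  }
  inform("curve wiggles broke monotonicity 50 times; falling back to damped amplitude")
  sc$curve_wiggle <- sc$curve_wiggle / 2
  make_calibration_curve(sc)
}

new_calibration_curve <- function(cal_bp, mu_c14, sigma_curve) {
  stopifnot(all(diff(cal_bp) > 0), all(sigma_curve >= 0))
  out <- tibble::tibble(cal_bp = cal_bp, mu_c14 = mu_c14, sigma_curve = sigma_curve)
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Synthetic population trajectory with known growth-rate cycles
#'
#' The generating relative growth rate is a trend plus a sum of sinusoids at
#' the scenario periods (random phases); the population is its cumulative
#' exponential, integrated forward in time (decreasing cal BP).
#'
#' @param sc A [scenario()].
#' @return List with `population` and `rgr`, both [grid_series()] on the
#'   scenario's fine grid (the `rgr` element is the generating truth).
#' @export
make_population <- function(sc) {
  grid <- seq(sc$window[1], sc$window[2], by = -sc$step)
  set.seed(sub_seed(sc, 23L))
  ph <- runif(length(sc$periods), 0, 2 * pi)
  t_fwd <- sc$window[1] - grid  # years elapsed since window start
  r <- rep(sc$trend, length(grid))
  for (m in seq_along(sc$periods)) {
    r <- r + sc$amplitudes[m] * sin(2 * pi * t_fwd / sc$periods[m] + ph[m])
  }
  logN <- cumsum(c(0, r[-length(r)])) * sc$step
  if (max(logN) > 50) abort("population overflow: reduce trend or amplitudes")
  pop <- exp(logN - mean(logN))
  list(population = grid_series(grid, pop, label = "population"),
       rgr = grid_series(grid, r, label = "true RGR"))
}

#' Sample radiocarbon dates from a population trajectory
#'
#' Calendar ages are drawn proportional to the population density
#' (inverse-CDF on the fine grid with within-bin jitter), mapped through the
#' calibration curve, and perturbed by Gaussian lab error. Sites come from a
#' clustered 2-D Gaussian mixture; each date is attached to a site.
#'
#' @param population A [grid_series()] population trajectory.
#' @param curve A `calibration_curve`.
#' @param sc A [scenario()].
#' @return Tibble of dates: `lab_id`, `c14_age`, `c14_sd`, `lon`, `lat`,
#'   `site_id`.
#' @export
sample_dates <- function(population, curve, sc) {
  if (sc$n_dates < 1) abort("`n_dates` must be at least 1")
  set.seed(sub_seed(sc, 37L))
  step <- gs_step(population)
  p <- pmax(population$value, 0)
  if (sum(p) <= 0) abort("population must have positive mass")
  idx <- sample.int(nrow(population), sc$n_dates, replace = TRUE, prob = p)
  cal_age <- population$cal_bp[idx] + runif(sc$n_dates, -step / 2, step / 2)

  # clustered site geography
  cl_lon <- runif(sc$n_clusters, sc$lon_range[1] + 2, sc$lon_range[2] - 2)
  cl_lat <- runif(sc$n_clusters, sc$lat_range[1] + 2, sc$lat_range[2] - 2)
  site_cl <- sample.int(sc$n_clusters, sc$n_sites, replace = TRUE)
  site_lon <- pmin(pmax(rnorm(sc$n_sites, cl_lon[site_cl], 1.5), sc$lon_range[1]), sc$lon_range[2])
  site_lat <- pmin(pmax(rnorm(sc$n_sites, cl_lat[site_cl], 1.2), sc$lat_range[1]), sc$lat_range[2])
  site <- sample.int(sc$n_sites, sc$n_dates, replace = TRUE)

  mu <- approx(curve$cal_bp, curve$mu_c14, xout = cal_age, rule = 2)$y
  c14_sd <- runif(sc$n_dates, sc$c14_sd_range[1], sc$c14_sd_range[2])
  c14_age <- rnorm(sc$n_dates, mu, c14_sd)

  tibble::tibble(
    lab_id = sprintf("SYN-%05d", seq_len(sc$n_dates)),
    c14_age = c14_age,
    c14_sd = c14_sd,
    lon = site_lon[site],
    lat = site_lat[site],
    site_id = sprintf("S%03d", site)
  )
}

# smooth bounded random distortion curve (sum of low-frequency sinusoids)
smooth_distortion <- function(cal_bp, cap) {
  wl <- runif(3, 1500, 4000)
  ph <- runif(3, 0, 2 * pi)
  a <- runif(3, 0.3, 1)
  d <- rowSums(sapply(seq_len(3), function(m) a[m] * sin(2 * pi * cal_bp / wl[m] + ph[m])))
  if (max(abs(d)) > 0) d <- d / max(abs(d)) * runif(1, 0.5, 1) * cap
  d
}

#' Synthetic paleoclimate proxy ensemble
#'
#' Every record observes one shared latent signal through its own smooth
#' chronological distortion (bounded by the scenario cap, emulating age-model
#' drift) plus independent noise, at irregular sampling times.
#'
#' @param sc A [scenario()].
#' @return List: `records` (long tibble `id`, `cal_bp`, `value`), `latent`
#'   ([grid_series()]), `distortions` (long tibble of the true time shifts).
#' @export
make_proxies <- function(sc) {
  if (sc$n_proxies < 3) abort("need at least 3 proxy records")
  if (sc$distortion_cap < 0) abort("`distortion_cap` must be nonnegative")
  set.seed(sub_seed(sc, 53L))
  grid <- seq(sc$window[1], sc$window[2], by = -sc$step)
  t_fwd <- sc$window[1] - grid
  ph <- runif(length(sc$periods), 0, 2 * pi)
  lat_sig <- rowSums(sapply(seq_along(sc$periods), function(m)
    sin(2 * pi * t_fwd / sc$periods[m] + ph[m])))
  # slow background so records are not pure tones
  lat_sig <- lat_sig + 0.8 * sin(2 * pi * t_fwd / 2300 + runif(1, 0, 2 * pi))
  lat_sig <- (lat_sig - mean(lat_sig)) / sd(lat_sig)
  latent <- grid_series(grid, lat_sig, label = "latent")

  recs <- vector("list", sc$n_proxies)
  dists <- vector("list", sc$n_proxies)
  for (i in seq_len(sc$n_proxies)) {
    gaps <- pmax(runif(ceiling(diff(rev(sc$window)) / sc$proxy_step) + 10,
                       0.5 * sc$proxy_step, 1.5 * sc$proxy_step), 1)
    times <- sc$window[1] - cumsum(gaps)
    times <- times[times > sc$window[2]]
    times <- sort(times, decreasing = TRUE)
    dist_i <- smooth_distortion(times, sc$distortion_cap)
    loading <- runif(1, 0.6, 1.4)
    v <- loading * approx(grid, lat_sig, xout = times + dist_i, rule = 2)$y +
      rnorm(length(times), 0, sc$proxy_noise_sd)
    id <- sprintf("P%02d", i)
    recs[[i]] <- tibble::tibble(id = id, cal_bp = times, value = v)
    dists[[i]] <- tibble::tibble(id = id, cal_bp = times, distortion = dist_i)
  }
  list(records = dplyr::bind_rows(recs),
       latent = latent,
       distortions = dplyr::bind_rows(dists))
}

#' Synthetic solar-forcing series
#'
#' Sum of sinusoids at the scenario forcing periods plus AR(1) red noise,
#' optionally mixed with the proxy latent signal with weight
#' `forcing_coupling`.
#'
#' @param sc A [scenario()].
#' @param latent Optional latent [grid_series()] from [make_proxies()] to
#'   couple to.
#' @return A [grid_series()] on the scenario's fine grid.
#' @export
make_forcing <- function(sc, latent = NULL) {
  set.seed(sub_seed(sc, 71L))
  grid <- seq(sc$window[1], sc$window[2], by = -sc$step)
  t_fwd <- sc$window[1] - grid
  ph <- runif(length(sc$forcing_periods), 0, 2 * pi)
  f <- rowSums(sapply(seq_along(sc$forcing_periods), function(m)
    sin(2 * pi * t_fwd / sc$forcing_periods[m] + ph[m])))
  # red noise: AR(1) with decorrelation ~ 200 a
  phi <- exp(-sc$step / 200)
  eps <- rnorm(length(grid))
  red <- as.numeric(stats::filter(eps, phi, method = "recursive"))
  f <- f / sd(f) + 0.5 * red / sd(red)
  f <- (f - mean(f)) / sd(f)
  if (!is.null(latent) && sc$forcing_coupling > 0) {
    lat <- approx(latent$cal_bp, latent$value, xout = grid, rule = 2)$y
    lat <- (lat - mean(lat)) / sd(lat)
    f <- sc$forcing_coupling * lat + (1 - sc$forcing_coupling) * f
    if (sd(f) > 0) f <- (f - mean(f)) / sd(f)
  }
  grid_series(grid, f, label = "forcing", normalized = TRUE)
}
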