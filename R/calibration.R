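#' Read and deduplicate a radiocarbon date table
#'
#' Reads a delimited date table (or accepts a data frame), maps its columns to
#' the standard fields, drops rows that cannot be parsed, and removes
#' duplicate entries that share identical ¹⁴C age, ¹⁴C standard deviation and
#' coordinates -- the same record submitted to several compilations. The
#' deduplication key deliberately excludes the site label, which differs
#' between databases for the same sample.
#'
#' @param x Path to a delimited text file with header, or a data frame.
#' @param columns Named character vector mapping the standard fields
#'   (`lab_id`, `c14_age`, `c14_sd`, `lon`, `lat`, `site_id`) to column names
#'   in the input. Unmapped fields default to their own names.
#' @param delim Field separator when `x` is a path (default: whitespace/tab
#'   sniffed by `read.table`; pass "," for CSV).
#' @return Tibble of dates with attributes `n_raw`, `n_dropped`,
#'   `n_duplicates` recording row accounting.
#' @export
ingest_dates <- function(x, columns = NULL, delim = NULL) {
  fields <- c("lab_id", "c14_age", "c14_sd", "lon", "lat", "site_id")
  map <- setNames(fields, fields)
  if (!is.null(columns)) map[names(columns)] <- columns
  if (is.character(x) && length(x) == 1) {
    x <- if (is.null(delim)) read.table(x, header = TRUE, sep = "", comment.char = "#",
                                        stringsAsFactors = FALSE)
         else read.table(x, header = TRUE, sep = delim, comment.char = "#",
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  missing_cols <- map[!map %in% names(x)]
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n_raw <- nrow(x)
  out <- tibble::tibble(
    lab_id = as.character(x[[map["lab_id"]]]),
    c14_age = suppressWarnings(as.numeric(x[[map["c14_age"]]])),
    c14_sd = suppressWarnings(as.numeric(x[[map["c14_sd"]]])),
    lon = suppressWarnings(as.numeric(x[[map["lon"]]])),
    lat = suppressWarnings(as.numeric(x[[map["lat"]]])),
    site_id = as.character(x[[map["site_id"]]])
  )
  ok <- stats::complete.cases(out[c("c14_age", "c14_sd", "lon", "lat")]) &
    out$c14_sd > 0 & abs(out$lat) <= 90 & abs(out$lon) <= 180
  n_dropped <- sum(!ok)
  if (n_dropped > 0) warn(sprintf("%d unparsable or invalid row(s) skipped", n_dropped))
  out <- out[ok, ]
  dup <- duplicated(out[c("c14_age", "c14_sd", "lon", "lat")])
  out <- out[!dup, ]
  attr(out, "n_raw") <- n_raw
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Read a calibration curve in the 3-column IntCal dialect
#'
#' Columns: cal BP, ¹⁴C age BP, curve error; comma- or whitespace-separated;
#' comment lines start with `#`.
#'
#' @param path File path.
#' @return A `calibration_curve` tibble (ascending cal BP).
#' @export
read_calibration_curve <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!grepl("^\\s*#", first) & nzchar(first)]
  sep <- if (grepl(",", first[1])) "," else ""
  x <- read.table(path, header = FALSE, sep = sep, comment.char = "#")
  x <- x[order(x[[1]]), 1:3]
  new_calibration_curve(x[[1]], x[[2]], x[[3]])
}

curve_at <- function(curve, cal) {
  list(mu = approx(curve$cal_bp, curve$mu_c14, xout = cal, rule = 2)$y,
       sigma = approx(curve$cal_bp, curve$sigma_curve, xout = cal, rule = 2)$y)
}

curve_support <- function(curve) range(curve$cal_bp)

#' Precision filter for radiocarbon dates
#'
#' Removes imprecise dates with a threshold that tightens where dates are
#' regionally abundant: a date is kept when its lab error satisfies
#' `c14_sd <= max(220 - sqrt(8e5 * n), 40)` (years), with `n` the local
#' density of dates per km² on 4° x 4° longitude-latitude cells. Where dates
#' are sparse the full 220 a tolerance applies; in densely dated cells only
#' dates with errors down to 40 a survive.
#'
#' @param dates Date tibble from [ingest_dates()].
#' @param cell_deg Cell size in degrees (default 4).
#' @param density Optional tibble (`cell_lon`, `cell_lat`, `n`) of
#'   precomputed densities (dates/km²); by default computed from `dates`
#'   itself. Dates falling outside any populated density cell are treated as
#'   density 0.
#' @return Filtered tibble with columns `density` and `sd_threshold` added.
#' @export
filter_by_precision <- function(dates, cell_deg = 4, density = NULL) {
  cl_lon <- floor(dates$lon / cell_deg) * cell_deg
  cl_lat <- floor(dates$lat / cell_deg) * cell_deg
  if (is.null(density)) {
    key <- paste(cl_lon, cl_lat)
    cnt <- table(key)
    area <- cell_area_km2(cl_lat, cell_deg)
    n <- as.numeric(cnt[key]) / area
  } else {
    key <- paste(cl_lon, cl_lat)
    dkey <- paste(density$cell_lon, density$cell_lat)
    n <- density$n[match(key, dkey)]
    miss <- is.na(n)
    if (any(miss)) inform(sprintf("%d date(s) outside any density cell; density 0 assumed", sum(miss)))
    n[miss] <- 0
  }
  if (any(n < 0)) abort("densities must be nonnegative")
  thr <- precision_threshold(n)
  keep <- dates$c14_sd <= thr
  out <- dates[keep, ]
  out$density <- n[keep]
  out$sd_threshold <- thr[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' @rdname filter_by_precision
#' @param n Density of dates (dates/km²).
#' @export
precision_threshold <- function(n) pmax(220 - sqrt(8e5 * n), 40)

# spherical-Earth area (km²) of a cell_deg x cell_deg cell whose southern
# edge latitude contains `lat`
cell_area_km2 <- function(lat, cell_deg) {
  R <- 6371
  lat0 <- floor(lat / cell_deg) * cell_deg
  lat1 <- lat0 + cell_deg
  R^2 * (cell_deg * pi / 180) * abs(sin(lat1 * pi / 180) - sin(lat0 * pi / 180))
}

#' Calibrate a single radiocarbon date
#'
#' Maps a lab measurement onto the calendar axis: at each calendar age the
#' density is the Gaussian likelihood of the measured ¹⁴C age under the
#' curve's ¹⁴C age at that calendar age, with combined lab + curve error.
#' By default the density is *not* normalized, since normalization can
#' produce artificial spikes where the calibration curve is steep; with
#' `normalize = TRUE` the density integrates to 1 over the grid.
#'
#' @param c14_age,c14_sd Measurement and its 1-sigma lab error (¹⁴C a).
#' @param curve A `calibration_curve`.
#' @param normalize Normalize the calendar density to unit mass?
#' @param step Calendar grid step (a), default 5.
#' @param window Optional `c(older, younger)` cal BP bounds; defaults to the
#'   curve support.
#' @return A [grid_series()] density over cal BP.
#' @export
calibrate_date <- function(c14_age, c14_sd, curve, normalize = FALSE,
                           step = 5, window = NULL) {
  sup <- curve_support(curve)
  if (is.null(window)) window <- c(sup[2], sup[1])
  grid <- seq(window[1], window[2], by = -step)
  cc <- curve_at(curve, grid)
  sd_tot <- sqrt(c14_sd^2 + cc$sigma^2)
  rng <- range(curve$mu_c14)
  if (c14_age < rng[1] - 5 * max(sd_tot) || c14_age > rng[2] + 5 * max(sd_tot)) {
    abort(sprintf("date %.0f +/- %.0f lies outside the calibration curve support", c14_age, c14_sd))
  }
  dens <- dnorm(c14_age, mean = cc$mu, sd = sd_tot)
  if (normalize) {
    mass <- sum(dens) * step
    if (mass <= 0) abort("zero calibrated mass; date outside window")
    dens <- dens / mass
  }
  grid_series(grid, dens, label = "calibrated density", normalized = normalize)
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= cw[length(cw)] / 2)[1]]
}

#' Summed probability distribution of calibrated dates
#'
#' Calibrates every date (non-normalized by default), groups dates into
#' per-site bins whose calibrated median ages fall within `bin_width` of each
#' other (complete-linkage clustering cut at `bin_width`, the convention of
#' standard SPD software), averages densities within each bin so that heavily
#' resampled site phases do not dominate, and sums the bin means.
#'
#' @param dates Date tibble (`c14_age`, `c14_sd`, `site_id`).
#' @param curve A `calibration_curve`.
#' @param bin_width Per-site binning bandwidth (a), default 100.
#' @param window `c(older, younger)` cal BP window of the result.
#' @param step Internal calendar grid step (a).
#' @param normalize Normalize each calibrated density before summing?
#' @return A [grid_series()] with attributes `n_dates` and `n_bins`.
#' @export
spd <- function(dates, curve, bin_width = 100, window = NULL, step = 5,
                normalize = FALSE) {
  if (nrow(dates) == 0) abort("no dates to sum")
  sup <- curve_support(curve)
  if (is.null(window)) window <- c(sup[2], sup[1])
  if (window[1] > sup[2] || window[2] < sup[1]) {
    abort("window extends beyond the calibration curve support")
  }
  # extend the internal grid a little beyond the window so mass near the
  # edges is represented before restriction
  pad <- 300
  g_hi <- min(window[1] + pad, sup[2])
  g_lo <- max(window[2] - pad, sup[1])
  grid <- seq(g_hi, g_lo, by = -step)
  cc <- curve_at(curve, grid)

  n <- nrow(dates)
  medians <- numeric(n)
  chunk <- 2000L
  for (s in seq(1, n, by = chunk)) {
    j <- s:min(s + chunk - 1L, n)
    sd_tot <- sqrt(outer(cc$sigma^2, dates$c14_sd[j]^2, "+"))
    d <- dnorm(outer(cc$mu, dates$c14_age[j], "-") / sd_tot, 0, 1) / sd_tot
    medians[j] <- apply(d, 2, function(col) {
      if (sum(col) <= 0) return(NA_real_)
      weighted_median(grid, col)
    })
  }
  bin_id <- bin_dates(dates$site_id, medians, bin_width)
  bin_size <- table(bin_id)
  wgt <- 1 / as.numeric(bin_size[bin_id])

  total <- numeric(length(grid))
  for (s in seq(1, n, by = chunk)) {
    j <- s:min(s + chunk - 1L, n)
    sd_tot <- sqrt(outer(cc$sigma^2, dates$c14_sd[j]^2, "+"))
    d <- dnorm(outer(cc$mu, dates$c14_age[j], "-") / sd_tot, 0, 1) / sd_tot
    if (normalize) {
      mass <- colSums(d) * step
      mass[mass <= 0] <- Inf
      d <- sweep(d, 2, mass, "/")
    }
    total <- total + as.numeric(d %*% wgt[j])
  }
  out <- grid_series(grid, total, label = "SPD", normalized = normalize)
  out <- restrict_window(out, window)
  attr(out, "n_dates") <- n
  attr(out, "n_bins") <- length(bin_size)
  out
}

#' Per-site binning of dates by calibrated median age
#'
#' Complete-linkage clustering of each site's calibrated medians, cut at
#' `h` years: dates from one site within `h` of each other share a bin.
#'
#' @param site_id Character vector of site labels.
#' @param medians Calibrated median ages (cal BP).
#' @param h Cut height in years (default 100; sensitivity range 50--150).
#' @return Character vector of bin identifiers.
#' @export
bin_dates <- function(site_id, medians, h = 100) {
  bin <- character(length(site_id))
  groups <- split(seq_along(site_id), site_id)
  for (s in names(groups)) {
    i <- groups[[s]]
    m <- medians[i]
    if (length(i) == 1 || all(is.na(m))) {
      bin[i] <- paste0(s, "_1")
      next
    }
    m[is.na(m)] <- mean(m, na.rm = TRUE)
    if (length(i) == 2) {
      cl <- if (abs(m[1] - m[2]) <= h) c(1L, 1L) else c(1L, 2L)
    } else {
      hc <- stats::hclust(stats::dist(m), method = "complete")
      cl <- stats::cutree(hc, h = h)
    }
    bin[i] <- paste0(s, "_", cl)
  }
  bin
}

#' Calibration-artifact growth rate of a flat ¹⁴C distribution
#'
#' Places dates uniformly on the ¹⁴C-age axis, builds their SPD and returns
#' its relative growth rate: a null spectrum against which growth-rate
#' features suspected to be calibration effects can be compared. With the
#' default non-normalized calibration a uniform ¹⁴C distribution sums to a
#' flat SPD through *any* monotone curve, so the artifact rate stays near
#' zero -- the very reason non-normalized densities are used throughout.
#' Setting `normalize = TRUE` exposes what per-date normalization would do:
#' plateaus and steep stretches of the curve imprint paired
#' positive/negative growth excursions.
#'
#' @param curve A `calibration_curve`.
#' @param window `c(older, younger)` cal BP window.
#' @param n_dates Number of synthetic dates placed on the ¹⁴C axis.
#' @param c14_sd Lab error assigned to each synthetic date (a).
#' @param dt Growth-rate differencing interval (a).
#' @param normalize Normalize each calibrated density before summing?
#' @return An RGR [grid_series()] on `dt` slices.
#' @export
artifact_rgr <- function(curve, window, n_dates = 1e4, c14_sd = 50, dt = 100,
                         normalize = FALSE) {
  cc <- curve_at(curve, c(window[1] + 300, window[2] - 300))
  ages <- seq(cc$mu[2], cc$mu[1], length.out = n_dates)
  fake <- tibble::tibble(
    c14_age = ages, c14_sd = c14_sd,
    site_id = sprintf("A%06d", seq_along(ages))  # one bin per date
  )
  s <- spd(fake, curve, window = window, normalize = normalize)
  rgr(s, dt = dt)
}
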