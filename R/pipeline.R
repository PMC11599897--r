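#' Default pipeline configuration
#'
#' Every stage parameter with its standard value: 100 a slices, 130 a
#' smoothing, 1500 a detrending, 150 a displacement cap, 0.05 significance
#' thresholds, N* = 120 region-size scaling, 350/210 a lags around 7 ka BP,
#' 25% trimming, 100 a phase taper. The `scenario` element holds the
#' synthetic-data settings (see [scenario()]); set `dates_file`,
#' `curve_file`, `tsi_file`, `proxies_file` to run on real tabular inputs
#' instead.
#'
#' @param seed Integer seed.
#' @param ... Overrides of top-level defaults (partial matching not done).
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    window = c(9000, 3000),
    bin_width = 100,
    dt = 100,
    smooth_len = 130,
    detrend_win = 1500,
    cap = 150,
    alpha = 0.05,
    N_star = 120,
    lag_early = 350,
    lag_late = 210,
    lag_break = 7000,
    tail_fraction = 0.25,
    taper = 100,
    n_pc = 5,
    n_perm = 199,
    region_slices = list(c(7400, 7000)),
    dates_file = NULL, curve_file = NULL, tsi_file = NULL, proxies_file = NULL,
    scenario = list(),
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort(paste0("unknown config field(s): ",
                                    paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

read_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  if ("window" %in% names(x)) x$window <- as.numeric(x$window)
  if ("region_slices" %in% names(x)) x$region_slices <- lapply(x$region_slices, as.numeric)
  do.call(default_config, c(list(seed = x$seed %||% 1L),
                            x[setdiff(names(x), "seed")]))
}

write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
}

#' Run the full reconstruction pipeline
#'
#' Orchestrates every stage on one configuration: synthetic (or file-based)
#' inputs, SPD, pooled growth rate, preprocessing, spectrum, regional
#' partition and area-weighted continental growth for the configured slices,
#' proxy alignment and PCA, climate stability index, solar forcing, the
#' three logit variants with their hindcasts, and the synchrony table. All
#' artifacts are returned in a list; when `config$out_dir` is set they are
#' also written as delimited text plus a JSON manifest and the resolved
#' configuration.
#'
#' @param config A `run_config` from [default_config()], a list, or a path
#'   to a YAML file.
#' @return A named list of stage outputs with a `manifest` element.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    inform(sprintf("[%5.1fs] %s %s", as.numeric(Sys.time() - t0, units = "secs"),
                   stage, paste0(..., collapse = " ")))
  }
  if (!is.null(cfg$dates_file) && is.null(cfg$curve_file)) {
    abort("config field `curve_file` is required when `dates_file` is set")
  }
  sc <- do.call(scenario, c(list(seed = cfg$seed, window = cfg$window), cfg$scenario))

  if (is.null(cfg$dates_file)) {
    curve <- make_calibration_curve(sc)
    pop <- make_population(sc)
    dates <- sample_dates(pop$population, curve, sc)
    truth <- pop$rgr
  } else {
    curve <- read_calibration_curve(cfg$curve_file)
    dates <- ingest_dates(cfg$dates_file)
    truth <- NULL
  }
  log_stage("ingest", nrow(dates), "dates")
  dates <- filter_by_precision(dates)
  log_stage("precision filter", nrow(dates), "dates kept")

  s <- spd(dates, curve, bin_width = cfg$bin_width, window = cfg$window)
  g <- rgr(s, dt = cfg$dt)
  g_pp <- preprocess(g, cfg$smooth_len, cfg$detrend_win)
  spec <- power_spectrum(g_pp)
  log_stage("spd/rgr", attr(s, "n_bins"), "bins")

  regions <- lapply(cfg$region_slices, function(sl) {
    sco <- local_deviation_scores(dates, curve, sl, n_perm = cfg$n_perm,
                                  alpha = cfg$alpha)
    part <- cluster_regions(sco, N_star = cfg$N_star)
    rm <- regional_mean_rgr(part, dates, curve, window = cfg$window, dt = cfg$dt)
    list(slice = sl, scores = sco, partition = part, regional = rm)
  })
  log_stage("regions", length(regions), "slice(s)")

  if (is.null(cfg$proxies_file)) {
    px <- make_proxies(sc)
    proxies <- px$records
  } else {
    proxies <- ingest_proxy_dir(cfg$proxies_file)
    px <- NULL
  }
  ali <- align_proxy_ensemble(proxies, cap = cfg$cap)
  pca <- lapply(ali, function(a) principal_components(a$records, a$weights,
                                                      n_pc = cfg$n_pc))
  stab_fine <- stability_index(pca, n_pc = cfg$n_pc)
  stab <- resample_grid(stab_fine, cfg$dt)
  log_stage("stability", "PC var (first 5, late):",
            sprintf("%.0f%%", 100 * sum(pca$late$var_explained[1:cfg$n_pc])))

  if (is.null(cfg$tsi_file)) {
    tsi_raw <- make_forcing(sc, latent = if (!is.null(px)) px$latent)
    tsi <- grid_series(tsi_raw$cal_bp, -tsi_raw$value)  # raw TSI: forcing enters sign-reversed
  } else {
    tt <- read.table(cfg$tsi_file, header = TRUE)
    tsi <- as_grid_series(tibble::tibble(cal_bp = tt[[1]], value = tt[[2]]))
  }
  forcing <- prepare_forcing(tsi, window = c(max(g_pp$cal_bp), min(g_pp$cal_bp)),
                             step = cfg$dt)

  model_tbl <- build_logit_table(g_pp, stab, forcing, cfg)
  fits <- lapply(c("1V", "2V", "3V"), function(v) fit_boom_bust_logit(model_tbl, v))
  names(fits) <- c("1V", "2V", "3V")
  hind <- predict_boom_minus_bust(fits[["3V"]], model_tbl)
  log_stage("logit", sprintf("logLik 1V/2V/3V = %.1f/%.1f/%.1f",
                             fits[["1V"]]$log_lik, fits[["2V"]]$log_lik,
                             fits[["3V"]]$log_lik))

  sync <- dplyr::bind_rows(
    dplyr::mutate(sync_pair(g_pp, stab, cfg), pair = "RGR vs stability"),
    dplyr::mutate(sync_pair(g_pp, forcing, cfg), pair = "RGR vs -TSI"),
    dplyr::mutate(sync_pair(hind, g_pp, cfg), pair = "3V hindcast vs RGR")
  )

  out <- list(config = cfg, curve = curve, dates = dates, spd = s,
              rgr = g, rgr_preprocessed = g_pp, spectrum = spec,
              regions = regions, alignment = ali, pca = pca,
              stability = stab, forcing = forcing,
              logit = fits, hindcast = hind, synchrony = sync,
              truth = truth)
  out$manifest <- build_manifest(out)
  if (!is.null(cfg$out_dir)) write_outputs(out, cfg$out_dir)
  out
}

sync_pair <- function(a, b, cfg) {
  cs <- common_support(a, b)
  synchrony_stats(cs$a, cs$b, tail_fraction = cfg$tail_fraction,
                  taper = cfg$taper)
}

build_logit_table <- function(g_pp, stab, forcing, cfg) {
  lag <- lagged_rgr(g_pp, cfg$lag_break, cfg$lag_early, cfg$lag_late)
  lab <- label_boom_bust(g_pp)
  grid <- g_pp$cal_bp
  at <- function(s) approx(s$cal_bp, s$value, xout = grid, rule = 1)$y
  tibble::tibble(cal_bp = grid, label = lab$value, rgr = g_pp$value,
                 rgr_lag = lag$value, stability = at(stab), tsi = at(forcing))
}

# read a directory of 2-column proxy files named <id>.txt
ingest_proxy_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(txt|csv|tsv)$", full.names = TRUE)
  if (!length(files)) abort(sprintf("no proxy files found in '%s'", dir))
  dplyr::bind_rows(lapply(files, function(f) {
    x <- read.table(f, header = TRUE)
    tibble::tibble(id = sub("\\.[^.]*$", "", basename(f)),
                   cal_bp = x[[1]], value = x[[2]])
  }))
}

build_manifest <- function(out) {
  cfg <- out$config
  list(
    seed = cfg$seed,
    window = cfg$window,
    parameters = cfg[c("bin_width", "dt", "smooth_len", "detrend_win", "cap",
                       "alpha", "N_star", "lag_early", "lag_late",
                       "tail_fraction", "taper", "n_pc", "n_perm")],
    n_dates = nrow(out$dates),
    n_spd_bins = attr(out$spd, "n_bins"),
    n_regions = vapply(out$regions, function(r) attr(r$partition, "k"), numeric(1)),
    pc_var_first5 = vapply(out$pca, function(p)
      sum(p$var_explained[seq_len(min(5, length(p$var_explained)))]), numeric(1)),
    log_lik = vapply(out$logit, function(f) f$log_lik, numeric(1)),
    synchrony = as.data.frame(out$synchrony)
  )
}

write_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series_csv(out$spd, file.path(dir, "spd.csv"))
  write_series_csv(out$rgr_preprocessed, file.path(dir, "rgr.csv"))
  write_series_csv(out$stability, file.path(dir, "stability.csv"))
  write_series_csv(out$forcing, file.path(dir, "forcing.csv"))
  write_series_csv(out$hindcast, file.path(dir, "hindcast_3v.csv"))
  utils::write.csv(as.data.frame(out$synchrony), file.path(dir, "synchrony.csv"),
                   row.names = FALSE)
  for (i in seq_along(out$regions)) {
    utils::write.csv(as.data.frame(out$regions[[i]]$partition),
                     file.path(dir, sprintf("partition_slice%d.csv", i)),
                     row.names = FALSE)
  }
  cfg <- out$config
  cfg$region_slices <- lapply(cfg$region_slices, as.numeric)
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                   file.path(dir, "config.yaml"))
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
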