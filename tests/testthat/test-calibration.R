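test_that("ingest deduplicates on age, error and coordinates but not site", {
  tab <- data.frame(
    lab_id = c("a", "b", "c", "d", "e"),
    c14_age = c(4500, 4500, 4500, 4100, 4500),
    c14_sd = c(30, 30, 30, 30, 30),
    lon = c(5, 5, 5, 5, 5),
    lat = c(45, 45, 45, 45, 45),
    site_id = c("s1", "s1", "s2", "s1", "s3")
  )
  out <- ingest_dates(tab)
  expect_equal(nrow(out), 2)  # the three identical-key rows collapse to one
  expect_equal(attr(out, "n_duplicates"), 3)
  # idempotent
  expect_equal(nrow(ingest_dates(out)), 2)
  # empty table
  expect_equal(nrow(ingest_dates(tab[0, ])), 0)
})

test_that("ingest maps columns, skips bad rows and errors on missing columns", {
  tab <- data.frame(Lab = c("x", "y", "z"), BP = c(5000, NA, 4000),
                    SD = c(40, 40, -5), Long = c(1, 2, 3), Lat = c(40, 41, 42),
                    Site = c("s", "s", "s"))
  expect_warning(
    out <- ingest_dates(tab, columns = c(lab_id = "Lab", c14_age = "BP",
                                         c14_sd = "SD", lon = "Long",
                                         lat = "Lat", site_id = "Site")),
    "2 unparsable"
  )
  expect_equal(out$c14_age, 5000)
  expect_error(ingest_dates(tab), "missing column")
})

test_that("precision threshold follows max(220 - sqrt(8e5 n), 40)", {
  expect_equal(precision_threshold(0), 220)
  expect_equal(precision_threshold(0.0405), 40)
  # monotone non-increasing, bounded in [40, 220]
  n <- seq(0, 0.2, length.out = 200)
  thr <- precision_threshold(n)
  expect_true(all(diff(thr) <= 1e-12))
  expect_true(all(thr >= 40 & thr <= 220))
})

test_that("precision filter keeps and removes dates per the local density", {
  d <- tibble::tibble(lab_id = c("a", "b", "c"), c14_age = c(5000, 5000, 5000),
                      c14_sd = c(200, 230, 250), lon = c(5, 5.5, 6),
                      lat = c(45, 45.5, 46), site_id = c("s1", "s2", "s3"))
  dens <- tibble::tibble(cell_lon = 4, cell_lat = 44, n = 0)
  out <- filter_by_precision(d, density = dens)
  expect_equal(out$lab_id, "a")      # 200 <= 220 kept; 230, 250 removed
  # a date outside any density cell is treated as n = 0
  d2 <- d; d2$lon <- 100
  expect_message(out2 <- filter_by_precision(d2, density = dens), "density 0")
  expect_equal(out2$lab_id, "a")
})

test_that("calibration through the identity curve returns the lab Gaussian", {
  cv <- identity_curve()
  g <- calibrate_date(4500, 30, cv, normalize = TRUE)
  expect_equal(g$cal_bp[which.max(g$value)], 4500, tolerance = 1e-9)
  step <- gs_step(g)
  in2sd <- g$cal_bp >= 4500 - 60 & g$cal_bp <= 4500 + 60
  expect_equal(sum(g$value[in2sd]) * step, 0.954, tolerance = 0.012)
  # non-normalized values equal the pointwise Gaussian likelihood
  raw <- calibrate_date(4500, 30, cv, normalize = FALSE)
  expect_equal(raw$value, dnorm(raw$cal_bp, 4500, 30), tolerance = 1e-12)
})

test_that("curve slope rescales the calendar-domain width of the density", {
  # slope 2 (2 c14 a per cal a): calendar sd should be half the lab sd;
  # oracle: dense numerical mapping of the same likelihood
  cal <- seq(2000, 10000, by = 1)
  cv <- paleocycles:::new_calibration_curve(cal, 2 * cal - 4000, rep(0, length(cal)))
  g <- calibrate_date(2 * 6000 - 4000, 40, cv, normalize = TRUE, step = 1)
  m <- sum(g$cal_bp * g$value) / sum(g$value)
  s <- sqrt(sum((g$cal_bp - m)^2 * g$value) / sum(g$value))
  expect_equal(m, 6000, tolerance = 0.1)
  expect_equal(s, 20, tolerance = 0.2)
})

test_that("calibration rejects dates outside the curve support", {
  cv <- identity_curve(4000, 6000)
  expect_error(calibrate_date(20000, 30, cv), "outside the calibration curve")
})

test_that("SPD of one date equals its calibrated density and bins average duplicates", {
  cv <- identity_curve()
  one <- tibble::tibble(c14_age = 5000, c14_sd = 30, site_id = "s1")
  s1 <- spd(one, cv, window = c(6000, 4000))
  ref <- calibrate_date(5000, 30, cv)
  ref <- paleocycles:::restrict_window(ref, c(6000, 4000))
  expect_equal(s1$value, ref$value, tolerance = 1e-12)
  # two identical dates at one site share a bin: SPD unchanged, not doubled
  two <- one[c(1, 1), ]
  s2 <- spd(two, cv, window = c(6000, 4000))
  expect_equal(s2$value, s1$value, tolerance = 1e-12)
  # the same two dates at different sites do double the SPD
  two$site_id <- c("s1", "s2")
  s3 <- spd(two, cv, window = c(6000, 4000))
  expect_equal(s3$value, 2 * s1$value, tolerance = 1e-12)
  expect_error(spd(one[0, ], cv), "no dates")
})

test_that("SPD equals the analytic Gaussian mixture for the identity curve", {
  cv <- identity_curve()
  set.seed(11)
  ages <- runif(40, 4500, 7500)
  sds <- runif(40, 25, 60)
  d <- tibble::tibble(c14_age = ages, c14_sd = sds,
                      site_id = sprintf("u%02d", seq_along(ages)))
  s <- spd(d, cv, window = c(8000, 4000))
  oracle <- rowSums(sapply(seq_along(ages), function(j) dnorm(s$cal_bp, ages[j], sds[j])))
  expect_equal(s$value, oracle, tolerance = 1e-9)
})

test_that("SPD of uniform calendar dates is flat within sampling error", {
  cv <- identity_curve(2000, 10000, sigma = 0)
  set.seed(5)
  n <- 5000
  d <- tibble::tibble(c14_age = runif(n, 3000, 9000), c14_sd = 30,
                      site_id = sprintf("u%05d", 1:n))
  s <- aggregate_grid(spd(d, cv, window = c(8500, 3500)), 100)
  expect_true(sd(s$value) / mean(s$value) < 0.1)
  expect_true(all(s$value >= 0))
})

test_that("normalized SPD mass grows by one per additional unbinned date", {
  cv <- identity_curve()
  d1 <- tibble::tibble(c14_age = 5000, c14_sd = 30, site_id = "a")
  d2 <- dplyr::bind_rows(d1, tibble::tibble(c14_age = 6500, c14_sd = 40, site_id = "b"))
  m1 <- sum(spd(d1, cv, normalize = TRUE)$value) * 5
  m2 <- sum(spd(d2, cv, normalize = TRUE)$value) * 5
  expect_equal(m2 - m1, 1, tolerance = 1e-6)
})

test_that("per-site binning clusters medians within the bandwidth", {
  bins <- bin_dates(c("s", "s", "s", "t"), c(5000, 5050, 5400, 5000), h = 100)
  expect_equal(bins[1], bins[2])
  expect_false(bins[1] == bins[3])
  expect_false(bins[1] == bins[4])
})

test_that("non-normalized calibration suppresses plateau artifacts", {
  cv <- identity_curve(2000, 10000)
  a <- artifact_rgr(cv, window = c(8000, 4000), n_dates = 2000)
  interior <- a$value[5:(nrow(a) - 5)]
  expect_true(max(abs(interior), na.rm = TRUE) < 5e-4)
  # a plateau leaves the non-normalized null flat too: uniform 14C mass sums
  # to a flat SPD through any monotone curve
  cvp <- plateau_curve()
  ap <- artifact_rgr(cvp, window = c(8000, 4000), n_dates = 2000)
  expect_true(max(abs(ap$value), na.rm = TRUE) < 5e-4)
  # normalization is what imprints the paired excursions at the plateau
  apn <- artifact_rgr(cvp, window = c(8000, 4000), n_dates = 2000, normalize = TRUE)
  near <- apn$cal_bp < 6600 & apn$cal_bp > 5400
  expect_gt(max(apn$value[near], na.rm = TRUE), 1e-3)
  expect_lt(min(apn$value[near], na.rm = TRUE), -1e-3)
  # shared-peak reporting against a data spectrum is plain plumbing
  ps <- power_spectrum(preprocess(apn))
  expect_s3_class(dominant_periods(ps), "tbl_df")
})

test_that("calibration curve files in the 3-column dialect round-trip", {
  cv <- identity_curve(4000, 4100, step = 20)
  f <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# synthetic curve", "## cal BP, 14C age, error",
               paste(cv$cal_bp, cv$mu_c14, cv$sigma_curve, sep = ",")), f)
  rt <- read_calibration_curve(f)
  expect_equal(rt$cal_bp, cv$cal_bp)
  expect_equal(rt$mu_c14, cv$mu_c14)
  # whitespace dialect
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# synthetic curve", paste(cv$cal_bp, cv$mu_c14, cv$sigma_curve)), f2)
  expect_equal(read_calibration_curve(f2)$mu_c14, cv$mu_c14)
})
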