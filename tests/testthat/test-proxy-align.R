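mk_record <- function(id, grid, values) tibble::tibble(id = id, cal_bp = grid, value = values)

test_that("pairwise DTW distance obeys its exact anchors", {
  grid <- seq(9000, 5800, by = -25)
  t <- grid[1] - grid
  v <- sin(2 * pi * t / 500) + 0.5 * sin(2 * pi * t / 680)
  a <- mk_record("a", grid, v)
  # identical records: zero cost, zero distortion, factor 1
  pd <- pairwise_dtw_distance(a, a)
  expect_equal(pd$D, 0, tolerance = 1e-9)
  expect_equal(pd$d, 0, tolerance = 1e-9)
  expect_equal(pd$overlap_frac, 1)
  # the distortion factor doubles the distance at d = 100 a
  expect_equal(1 + (100 / 100)^2, 2)
  b <- mk_record("b", grid - 100, v)  # same shape shifted 100 a younger
  pdb <- pairwise_dtw_distance(a, b)
  expect_equal(pdb$d, 100, tolerance = 25)
  # disjoint supports are sentinel Inf
  far <- mk_record("c", grid - 8000, v)
  expect_equal(pairwise_dtw_distance(a, far)$D, Inf)
})

test_that("unrelated noise pairs score larger distances than matched pairs", {
  set.seed(14)
  grid <- seq(9000, 5800, by = -25)
  t <- grid[1] - grid
  base <- sin(2 * pi * t / 500)
  worse <- replicate(20, {
    sig_pair <- pairwise_dtw_distance(
      mk_record("a", grid, base + rnorm(length(grid), 0, 0.3)),
      mk_record("b", grid, base + rnorm(length(grid), 0, 0.3)))$D
    noise_pair <- pairwise_dtw_distance(
      mk_record("x", grid, rnorm(length(grid))),
      mk_record("y", grid, rnorm(length(grid))))$D
    noise_pair > sig_pair
  })
  expect_gt(mean(worse), 0.9)
})

test_that("aligning identical records leaves timings untouched", {
  grid <- seq(9000, 5800, by = -25)
  t <- grid[1] - grid
  v <- sin(2 * pi * t / 500)
  recs <- dplyr::bind_rows(lapply(c("a", "b", "c"), mk_record, grid = grid, values = v))
  al <- suppressWarnings(align_records(recs, max_iter = 4, min_iter = 1))
  expect_lt(max(abs(al$records$displacement)), 1e-6)
})

test_that("alignment shrinks known shifts and respects the displacement cap", {
  grid <- seq(9000, 5800, by = -25)
  t <- grid[1] - grid
  v <- sin(2 * pi * t / 500) + 0.4 * sin(2 * pi * t / 900)
  shifts <- c(-80, 0, 80)
  recs <- dplyr::bind_rows(lapply(1:3, function(i)
    mk_record(paste0("r", i), grid + shifts[i], v)))
  al <- suppressWarnings(align_records(recs))
  # post-alignment spread of the three chronologies is smaller than initial:
  # the k-th sample of every record observes the same latent event
  mat <- sapply(paste0("r", 1:3), function(k) {
    r <- al$records[al$records$id == k, ]
    r$cal_bp[order(-r$cal_bp_orig)]
  })
  spread_after <- mean(apply(mat, 1, sd))
  expect_lt(spread_after, 0.9 * sd(shifts))
  expect_lte(max(abs(al$records$displacement)), 150 + 1e-9)
  # weights form a distribution
  expect_equal(sum(al$weights), 1, tolerance = 1e-12)
  expect_true(all(al$weights >= 0))
})

test_that("alignment preserves timing order within records", {
  set.seed(9)
  sc <- scenario(seed = 9, n_proxies = 6)
  px <- make_proxies(sc)
  seg <- split_segments(px$records)
  al <- suppressWarnings(align_records(seg$late, max_iter = 4, min_iter = 2))
  for (k in unique(al$records$id)) {
    tt <- al$records$cal_bp[al$records$id == k]
    expect_true(all(diff(tt) < 0))
  }
  expect_lte(max(abs(al$records$displacement)), 150 + 1e-9)
})

test_that("short-overlap and distorted pairs carry smaller weights", {
  grid <- seq(9000, 5800, by = -25)
  t <- grid[1] - grid
  v <- sin(2 * pi * t / 500)
  full1 <- mk_record("f1", grid, v)
  full2 <- mk_record("f2", grid, v + rnorm(length(grid), 0, 0.05))
  short <- mk_record("s", grid[1:40], rnorm(40))
  al <- suppressWarnings(align_records(dplyr::bind_rows(full1, full2, short),
                                       max_iter = 4, min_iter = 1))
  expect_gt(al$weights[["f1"]], al$weights[["s"]])
  expect_gt(al$weights[["f2"]], al$weights[["s"]])
})

test_that("segment split keeps the 5.8-6.2 ka overlap zone on both sides", {
  recs <- mk_record("a", seq(9000, 3000, by = -50), rnorm(121))
  seg <- split_segments(recs)
  expect_true(all(seg$early$cal_bp >= 5800))
  expect_true(all(seg$late$cal_bp <= 6200))
  both <- intersect(seg$early$cal_bp, seg$late$cal_bp)
  expect_true(length(both) > 0)
})

test_that("tidy and glance summarize an alignment", {
  sc <- scenario(seed = 3, n_proxies = 5)
  px <- make_proxies(sc)
  al <- suppressWarnings(align_records(split_segments(px$records)$late,
                                       max_iter = 4, min_iter = 2))
  td <- tidy(al)
  expect_equal(nrow(td), 5)
  expect_true(all(c("mean_abs_displacement", "weight") %in% names(td)))
  gl <- glance(al)
  expect_equal(gl$n_records, 5)
  expect_lte(gl$max_abs_displacement, 150 + 1e-9)
})
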