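test_that("homogeneous dates trigger few or no significant cells", {
  d <- anomaly_dates(seed = 1, n_anomaly = 0)
  cv <- identity_curve()
  set.seed(1)
  sco <- suppressMessages(local_deviation_scores(d, cv, c(7400, 7000), n_perm = 99))
  expect_true(all(sco$q >= sco$p - 1e-12))
  expect_lte(mean(sco$score != 0), 0.25)  # small false-positive allowance
})

test_that("an injected growth anomaly earns a positive signed score", {
  d <- anomaly_dates(seed = 2)
  cv <- identity_curve()
  set.seed(2)
  sco <- suppressMessages(local_deviation_scores(d, cv, c(7400, 7000), n_perm = 199))
  hot <- sco$cell_lon == 24 & sco$cell_lat == 40
  expect_true(any(hot))
  expect_gt(sco$score[hot], 0)
  # combined score bounded by (1-p) + (1-q) < 2
  expect_true(all(abs(sco$score) < 2))
})

test_that("the k-means size penalty follows its formula", {
  # N_min = N*: factor 1 + e^0 = 2; N_min >> N*: factor -> 1
  expect_equal(1 + exp(-10 * (120 / 120 - 1)), 2)
  expect_equal(1 + exp(-10 * (1200 / 120 - 1)), 1, tolerance = 1e-12)
})

test_that("two well-separated score blobs are recovered as two regions", {
  set.seed(33)
  recovered <- replicate(20, {
    sco <- tibble::tibble(
      cell_lon = c(runif(8, 0, 6), runif(8, 20, 26)),
      cell_lat = c(runif(8, 40, 46), runif(8, 52, 58)),
      n_dates = 30L,   # cluster date counts near N* so the size penalty binds
      score = c(rnorm(8, 1.8, 0.05), rnorm(8, -1.8, 0.05))
    )
    part <- cluster_regions(sco, k_range = 2:6, nstart = 10)
    attr(part, "k")
  })
  expect_gte(mean(recovered == 2), 0.95)
})

test_that("partitions are deterministic given a seed and report N_min", {
  sco <- tibble::tibble(cell_lon = rep(seq(0, 28, 4), 2),
                        cell_lat = rep(c(40, 48), each = 8),
                        n_dates = rep(c(50L, 400L), 8),
                        score = rnorm(16))
  set.seed(7); p1 <- cluster_regions(sco, k_range = 2:5)
  set.seed(7); p2 <- cluster_regions(sco, k_range = 2:5)
  expect_identical(p1$region, p2$region)
  expect_true(attr(p1, "N_min") >= min(sco$n_dates))
  # projection onto the fine grid covers every coarse cell
  set.seed(7); p3 <- cluster_regions(sco, k_range = 2:5, project_step = 0.5)
  fine <- attr(p3, "fine_grid")
  expect_true(all(paste(sco$cell_lon, sco$cell_lat) %in%
                    unique(paleocycles:::cell_key(fine$lon, fine$lat, 4))))
})

test_that("area-weighted continental averaging follows the area rule", {
  # two equal-area regions with rates +1 and -1 average to zero; a region of
  # double area counts double
  areas <- c(`1` = 1000, `2` = 1000, `3` = 2000)
  regional <- tibble::tibble(
    region = rep(1:3, each = 3),
    cal_bp = rep(c(7200, 7100, 7000), 3),
    rgr = rep(c(1, -1, 0.5), each = 3)
  )
  wide <- tidyr::pivot_wider(regional, names_from = "region", values_from = "rgr")
  v <- as.matrix(wide[, -1])
  got <- apply(v, 1, function(r) sum(areas * r) / sum(areas))
  expect_equal(unique(round(got, 12)), (1000 * 1 - 1000 * 1 + 2000 * 0.5) / 4000)
})

test_that("regional pipeline reproduces the pooled growth signal", {
  set.seed(4)
  sc <- scenario(seed = 4, n_dates = 3000, n_sites = 400, curve_wiggle = 0)
  cv <- make_calibration_curve(sc)
  pop <- make_population(sc)
  d <- sample_dates(pop$population, cv, sc)
  sco <- suppressMessages(local_deviation_scores(d, cv, c(7400, 7000), n_perm = 99))
  part <- cluster_regions(sco, k_range = 2:4, nstart = 5)
  rm <- regional_mean_rgr(part, d, cv, window = c(8500, 3500))
  pooled <- rgr(spd(d, cv, window = c(8500, 3500)))
  cs <- paleocycles:::common_support(rm$continental, pooled)
  expect_gt(cor(cs$a$value, cs$b$value, use = "complete.obs"), 0.95)
  # area weights normalize to one
  expect_equal(sum(rm$areas / sum(rm$areas)), 1)
})

test_that("spatial autocorrelation separates identical and independent regions", {
  grid <- seq(8000, 4000, by = -100)
  t <- grid[1] - grid
  cen <- tibble::tibble(region = 1:4, lon = c(0, 8, 16, 24), lat = rep(45, 4))
  same <- dplyr::bind_rows(lapply(1:4, function(r)
    tibble::tibble(region = r, cal_bp = grid, rgr = sin(2 * pi * t / 500))))
  ac1 <- spatial_autocorrelation(same, cen)
  expect_true(all(abs(ac1$mean_cor - 1) < 1e-12))
  set.seed(10)
  indep <- dplyr::bind_rows(lapply(1:4, function(r)
    tibble::tibble(region = r, cal_bp = grid, rgr = rnorm(length(grid)))))
  ac2 <- spatial_autocorrelation(indep, cen)
  expect_lt(max(abs(ac2$mean_cor)), 0.35)
  # common forcing + local noise: positive everywhere
  common <- dplyr::bind_rows(lapply(1:4, function(r)
    tibble::tibble(region = r, cal_bp = grid,
                   rgr = sin(2 * pi * t / 500) + rnorm(length(grid), 0, 0.4))))
  ac3 <- spatial_autocorrelation(common, cen)
  expect_true(all(ac3$mean_cor > 0.3))
})

test_that("synchrony with a forcing grows with spatial extent under common forcing", {
  set.seed(12)
  grid <- seq(8900, 3100, by = -100)
  t <- grid[1] - grid
  f_sig <- sin(2 * pi * t / 500)
  forcing <- preprocess(grid_series(grid, f_sig))
  cen <- tibble::tibble(region = 1:9,
                        lon = rep(c(-5, 10, 25), 3),
                        lat = rep(c(40, 48, 56), each = 3))
  areas <- setNames(rep(1000, 9), 1:9)
  ok <- replicate(20, {
    regional <- dplyr::bind_rows(lapply(1:9, function(r)
      tibble::tibble(region = r, cal_bp = grid,
                     rgr = f_sig + rnorm(length(grid), 0, 1.2))))
    sv <- synchrony_vs_extent(regional, areas, cen, forcing,
                              radii_km = c(300, 1200, 4000))
    sv$overlap[nrow(sv)] >= sv$overlap[1] - 5
  })
  expect_gte(mean(ok), 0.9)
})
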