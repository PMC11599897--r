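latent_records <- function(n_rec, grid, latent, noise = 0, loadings = NULL) {
  if (is.null(loadings)) loadings <- rep(1, n_rec)
  dplyr::bind_rows(lapply(seq_len(n_rec), function(i)
    tibble::tibble(id = sprintf("r%02d", i), cal_bp = grid,
                   value = loadings[i] * latent + rnorm(length(grid), 0, noise))))
}

test_that("a single shared latent gives PC1 ~ 100% explained variance", {
  grid <- seq(9000, 5800, by = -20)
  t <- grid[1] - grid
  set.seed(2)
  recs <- latent_records(6, grid, sin(2 * pi * t / 500),
                         loadings = runif(6, 0.5, 1.5))
  p <- principal_components(recs, n_pc = 3)
  expect_gt(p$var_explained[1], 0.999)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-9)
})

test_that("two orthogonal latents occupy two components", {
  grid <- seq(9000, 5800, by = -20)
  t <- grid[1] - grid
  l1 <- sin(2 * pi * t / 500); l2 <- sin(2 * pi * t / 360)
  recs <- dplyr::bind_rows(
    latent_records(3, grid, l1),
    dplyr::mutate(latent_records(3, grid, l2), id = paste0(id, "b"))
  )
  p <- principal_components(recs, n_pc = 4)
  expect_gt(sum(p$var_explained[1:2]), 0.99)
})

test_that("a zero-weight record contributes nothing to the decomposition", {
  grid <- seq(9000, 5800, by = -20)
  t <- grid[1] - grid
  set.seed(6)
  recs <- latent_records(5, grid, sin(2 * pi * t / 500), noise = 0.2)
  odd <- tibble::tibble(id = "odd", cal_bp = grid, value = rnorm(length(grid)))
  w <- setNames(c(rep(0.2, 5), 0), c(sprintf("r%02d", 1:5), "odd"))
  p <- principal_components(dplyr::bind_rows(recs, odd), weights = w, n_pc = 3)
  expect_lt(abs(p$loadings["odd", 1]), 1e-9)
  expect_gt(p$var_explained[1], 0.9)
})

test_that("records with big coverage gaps are dropped with a message", {
  grid <- seq(9000, 5800, by = -20)
  t <- grid[1] - grid
  recs <- latent_records(5, grid, sin(2 * pi * t / 500), noise = 0.1)
  gappy <- tibble::tibble(id = "gap", cal_bp = c(grid[1:20], grid[80:120]),
                          value = rnorm(61))
  expect_message(p <- principal_components(dplyr::bind_rows(recs, gappy), n_pc = 3),
                 "gap")
  expect_equal(p$dropped, "gap")
})

test_that("stability index is low at abrupt changes and sign-invariant in PCs", {
  grid <- seq(9000, 5800, by = -20)
  step_sig <- ifelse(grid > 7400, 0, 4) + 0.02 * sin(grid / 50)
  recs <- latent_records(5, grid, step_sig, noise = 0.01)
  p <- principal_components(recs, n_pc = 3)
  s <- stability_index(p, n_pc = 3)
  expect_equal(s$cal_bp[which.min(s$value)], 7400, tolerance = 150)
  expect_equal(mean(s$value), 0, tolerance = 1e-9)
  expect_equal(sd(s$value), 1, tolerance = 1e-9)
  # flipping the sign of a PC leaves the index unchanged
  p2 <- p
  p2$scores$PC1 <- -p2$scores$PC1
  expect_equal(stability_index(p2, n_pc = 3)$value, s$value, tolerance = 1e-9)
})

test_that("stability index tracks calm versus volatile epochs", {
  set.seed(17)
  hits <- replicate(10, {
    grid <- seq(9000, 5800, by = -20)
    t <- grid[1] - grid
    calm <- grid > 7400   # first half calm, second volatile
    env <- ifelse(calm, 0.15, 1)
    latent <- env * sin(2 * pi * t / 300 + runif(1, 0, 2 * pi))
    recs <- latent_records(5, grid, latent, noise = 0.05)
    s <- stability_index(principal_components(recs, n_pc = 3), n_pc = 3)
    mean(s$value[calm]) > mean(s$value[!calm])
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the two-segment index blends across the mid-Holocene junction", {
  sc <- scenario(seed = 4, n_proxies = 6, proxy_noise_sd = 0.2)
  px <- make_proxies(sc)
  seg <- split_segments(px$records)
  pca <- list(
    early = principal_components(seg$early, n_pc = 3),
    late = principal_components(seg$late, n_pc = 3)
  )
  s <- stability_index(pca, n_pc = 3)
  expect_gt(max(s$cal_bp), 8000)
  expect_lt(min(s$cal_bp), 4000)
  # defined across the junction
  junction <- s$cal_bp <= 6200 & s$cal_bp >= 5800
  expect_true(all(is.finite(s$value[junction])))
  expect_equal(sd(s$value, na.rm = TRUE), 1, tolerance = 1e-6)
})

test_that("forcing preparation reverses sign and normalizes", {
  grid <- seq(9000, 3000, by = -10)
  t <- grid[1] - grid
  tsi <- tibble::tibble(cal_bp = grid, value = 1361 + 0.5 * sin(2 * pi * t / 500))
  f <- prepare_forcing(tsi, window = c(8800, 3200), step = 100)
  expect_equal(sd(f$value), 1, tolerance = 1e-9)
  # antisymmetry round trip (TSI minimum maps to forcing maximum)
  tsi2 <- tsi; tsi2$value <- -tsi2$value
  f2 <- prepare_forcing(tsi2, window = c(8800, 3200), step = 100)
  expect_equal(f2$value, -f$value, tolerance = 1e-9)
  expect_error(prepare_forcing(tsi[tsi$cal_bp < 5000, ], window = c(8800, 3200)),
               "cover")
  # constant TSI has no variance to normalize
  expect_error(prepare_forcing(tibble::tibble(cal_bp = grid, value = 1361),
                               window = c(8800, 3200)), "zero-variance")
})

test_that("tree-ring homogeneity flips the across-tree spread", {
  set.seed(19)
  years <- seq(7000, 6500, by = -1)
  calm <- years > 6750
  widths <- dplyr::bind_rows(lapply(1:8, function(tr)
    tibble::tibble(cal_bp = years, tree = tr,
                   width = 1 + rnorm(length(years), 0, ifelse(calm, 0.05, 0.4)))))
  h <- treering_homogeneity(widths)
  expect_gt(mean(h$value[h$cal_bp > 6780], na.rm = TRUE),
            mean(h$value[h$cal_bp < 6720], na.rm = TRUE))
  # single-tree years are excluded
  widths2 <- dplyr::bind_rows(widths, tibble::tibble(cal_bp = 8000, tree = 1, width = 1))
  expect_message(h2 <- treering_homogeneity(widths2), "single tree")
  expect_lt(max(h2$cal_bp), 7500)
})
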