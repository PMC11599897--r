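cell_key <- function(lon, lat, cell_deg = 4) {
  paste(floor(lon / cell_deg) * cell_deg, floor(lat / cell_deg) * cell_deg)
}

# per-site SPD mass in the first and last 100 a bin of a slice
site_slice_mass <- function(dates, curve, slice, bin = 100) {
  grid1 <- seq(slice[1], slice[1] - bin, by = -5)
  grid2 <- seq(slice[2] + bin, slice[2], by = -5)
  cc1 <- curve_at(curve, grid1)
  cc2 <- curve_at(curve, grid2)
  mass_on <- function(cc) {
    sd_tot <- sqrt(outer(cc$sigma^2, dates$c14_sd^2, "+"))
    d <- dnorm(outer(cc$mu, dates$c14_age, "-") / sd_tot, 0, 1) / sd_tot
    colMeans(d)
  }
  m1 <- mass_on(cc1)
  m2 <- mass_on(cc2)
  rowsum(cbind(first = m1, last = m2), dates$site_id)
}

#' Local growth-rate deviations by spatial permutation test
#'
#' For one time slice, computes each 4° x 4° cell's growth rate (relative
#' change of the cell SPD from the slice's first to its last 100 a bin) and
#' tests it against the null hypothesis of spatial homogeneity by randomly
#' reassigning *sites* (with all their dates) to cells. One-sided p values
#' for positive and negative deviations are combined into
#' `p = min(p_hi, p_lo)`; false discovery rates `q` come from a step-up
#' adjustment over cells. Cells where both p and q fall below `alpha` get a
#' combined score `(1 - p) + (1 - q)`, signed by the direction of the
#' deviation; all other cells score 0.
#'
#' @param dates Date tibble (`c14_age`, `c14_sd`, `lon`, `lat`, `site_id`).
#' @param curve A `calibration_curve`.
#' @param slice `c(older, younger)` cal BP bounds of the (typically 400 a)
#'   slice.
#' @param n_perm Number of permutations (>= 99).
#' @param cell_deg Cell size in degrees (default 4).
#' @param min_dates Cells with fewer dates are excluded (default 10).
#' @param alpha Critical threshold on p and q (default 0.05).
#' @return Tibble per cell: `cell_lon`, `cell_lat`, `n_dates`, `growth`,
#'   `p`, `q`, `sign`, `score`.
#' @export
local_deviation_scores <- function(dates, curve, slice, n_perm = 199,
                                   cell_deg = 4, min_dates = 10, alpha = 0.05) {
  if (n_perm < 99) abort("use at least 99 permutations")
  span <- slice[1] - slice[2] - 100  # between bin centres
  site_mass <- site_slice_mass(dates, curve, slice)
  sites <- rownames(site_mass)
  site_cell <- tapply(cell_key(dates$lon, dates$lat, cell_deg), dates$site_id,
                      function(k) k[1])[sites]
  cell_dates <- table(cell_key(dates$lon, dates$lat, cell_deg))
  cells <- names(cell_dates)[cell_dates >= min_dates]
  if (length(cells) < 2) abort("need at least 2 sufficiently dated cells")
  n_excl <- sum(cell_dates < min_dates)
  if (n_excl > 0) inform(sprintf("%d cell(s) with < %d dates excluded", n_excl, min_dates))

  growth_by_cell <- function(assign) {
    agg <- rowsum(site_mass, assign)
    agg <- agg[rownames(agg) %in% cells, , drop = FALSE]
    g <- rep(NA_real_, length(cells))
    names(g) <- cells
    ok <- agg[, "first"] > 0
    g[rownames(agg)[ok]] <- (agg[ok, "last"] - agg[ok, "first"]) /
      (agg[ok, "first"] * span)
    g
  }
  g_obs <- growth_by_cell(site_cell)
  hi <- lo <- rep(0L, length(cells))
  n_valid <- rep(0L, length(cells))
  for (b in seq_len(n_perm)) {
    g_p <- growth_by_cell(sample(site_cell))
    ok <- !is.na(g_p) & !is.na(g_obs)
    hi <- hi + ifelse(ok & g_p >= g_obs, 1L, 0L)
    lo <- lo + ifelse(ok & g_p <= g_obs, 1L, 0L)
    n_valid <- n_valid + as.integer(ok)
  }
  p_hi <- (hi + 1) / (n_valid + 1)
  p_lo <- (lo + 1) / (n_valid + 1)
  p <- pmin(p_hi, p_lo)
  sgn <- ifelse(p_hi <= p_lo, 1L, -1L)
  q <- p.adjust(p, method = "BH")
  score <- ifelse(p < alpha & q < alpha, (1 - p) + (1 - q), 0) * sgn
  coords <- do.call(rbind, strsplit(cells, " "))
  tibble::tibble(
    cell_lon = as.numeric(coords[, 1]),
    cell_lat = as.numeric(coords[, 2]),
    n_dates = as.integer(cell_dates[cells]),
    growth = unname(g_obs),
    p = p, q = q, sign = sgn, score = score
  )
}

#' Cluster deviation scores into statistically homogeneous regions
#'
#' Feeds each cell's signed score and coordinates (standardized so score and
#' geography are commensurate) into k-means, choosing the cluster count k
#' that minimizes the total within-cluster sum of squares times the
#' small-region penalty `1 + exp(-10 * (N_min / N_star - 1))`, where `N_min`
#' is the date count of the smallest resulting region. With `N_star = 120`
#' this keeps regions large enough for robust SPD construction.
#'
#' @param scores Tibble from [local_deviation_scores()].
#' @param N_star Scaling parameter of the size penalty (default 120).
#' @param k_range Candidate cluster counts (default 2:12, truncated to the
#'   number of cells minus one).
#' @param nstart Random restarts per k (default 25).
#' @param cell_deg Cell size in degrees.
#' @param project_step If not NULL, also project the partition onto this
#'   fine grid (degrees, e.g. 0.1).
#' @return A `region_partition` tibble (`cell_lon`, `cell_lat`, `n_dates`,
#'   `score`, `region`) with attributes `k`, `N_min`, `penalty`,
#'   `objective`, and optionally `fine_grid`.
#' @export
cluster_regions <- function(scores, N_star = 120, k_range = 2:12, nstart = 25,
                            cell_deg = 4, project_step = NULL) {
  feat <- scale(cbind(scores$score, scores$cell_lon, scores$cell_lat))
  feat[, apply(feat, 2, function(c) anyNA(c))] <- 0
  k_range <- k_range[k_range < nrow(scores)]
  if (!length(k_range)) abort("no feasible cluster count for this few cells")
  best <- NULL
  for (k in k_range) {
    km <- kmeans(feat, centers = k, nstart = nstart, iter.max = 50)
    N_min <- min(tapply(scores$n_dates, km$cluster, sum))
    pen <- 1 + exp(-10 * (N_min / N_star - 1))
    obj <- km$tot.withinss * pen
    if (is.null(best) || obj < best$obj) {
      best <- list(km = km, k = k, N_min = N_min, pen = pen, obj = obj)
    }
  }
  out <- scores[c("cell_lon", "cell_lat", "n_dates", "score")]
  out$region <- as.integer(best$km$cluster)
  class(out) <- c("region_partition", class(out))
  attr(out, "k") <- best$k
  attr(out, "N_min") <- best$N_min
  attr(out, "penalty") <- best$pen
  attr(out, "objective") <- best$obj
  attr(out, "cell_deg") <- cell_deg
  if (!is.null(project_step)) {
    attr(out, "fine_grid") <- project_partition(out, project_step, cell_deg)
  }
  out
}

# project a coarse-cell partition onto a fine lon/lat grid
project_partition <- function(partition, step = 0.1, cell_deg = 4) {
  lon <- seq(min(partition$cell_lon), max(partition$cell_lon) + cell_deg - step, by = step)
  lat <- seq(min(partition$cell_lat), max(partition$cell_lat) + cell_deg - step, by = step)
  fine <- expand.grid(lon = lon, lat = lat)
  key <- cell_key(fine$lon, fine$lat, cell_deg)
  pkey <- paste(partition$cell_lon, partition$cell_lat)
  fine$region <- partition$region[match(key, pkey)]
  tibble::as_tibble(fine[!is.na(fine$region), ])
}

partition_areas <- function(partition) {
  cell_deg <- attr(partition, "cell_deg") %||% 4
  a <- cell_area_km2(partition$cell_lat + cell_deg / 2, cell_deg)
  tapply(a, partition$region, sum)
}

partition_centroids <- function(partition) {
  cell_deg <- attr(partition, "cell_deg") %||% 4
  lon <- tapply(partition$cell_lon + cell_deg / 2, partition$region, mean)
  lat <- tapply(partition$cell_lat + cell_deg / 2, partition$region, mean)
  tibble::tibble(region = as.integer(names(lon)), lon = as.numeric(lon),
                 lat = as.numeric(lat))
}

#' Regional and area-weighted continental growth rates
#'
#' Builds a per-region SPD and growth rate from the dates falling into each
#' region's cells, and averages the regional rates with *area* weights: the
#' growth of a sparsely dated region counts as much as that of an equally
#' large densely dated one. Bins where a region's rate is undefined are
#' excluded from that bin's average.
#'
#' @param partition A `region_partition`.
#' @param dates Date tibble.
#' @param curve A `calibration_curve`.
#' @param window `c(older, younger)` cal BP window.
#' @param dt Growth-rate slice width (a).
#' @return List: `regional` (long tibble `region`, `cal_bp`, `rgr`),
#'   `continental` ([grid_series()]), `areas` (km² per region),
#'   `centroids`.
#' @export
regional_mean_rgr <- function(partition, dates, curve, window, dt = 100) {
  cell_deg <- attr(partition, "cell_deg") %||% 4
  pkey <- paste(partition$cell_lon, partition$cell_lat)
  region_of <- partition$region[match(cell_key(dates$lon, dates$lat, cell_deg), pkey)]
  areas <- partition_areas(partition)
  regions <- sort(unique(partition$region))
  reg_list <- list()
  for (r in regions) {
    d <- dates[!is.na(region_of) & region_of == r, ]
    if (nrow(d) == 0) next
    g <- rgr(spd(d, curve, window = window), dt = dt)
    reg_list[[as.character(r)]] <- tibble::tibble(region = r, cal_bp = g$cal_bp,
                                                  rgr = g$value)
  }
  if (!length(reg_list)) abort("no region contains any dates")
  regional <- dplyr::bind_rows(reg_list)
  wide <- tidyr::pivot_wider(regional, names_from = "region", values_from = "rgr")
  wide <- wide[order(-wide$cal_bp), ]
  vals <- as.matrix(wide[, -1, drop = FALSE])
  a <- areas[colnames(vals)]
  cont <- apply(vals, 1, function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(a[ok] * v[ok]) / sum(a[ok])
  })
  list(regional = regional,
       continental = grid_series(wide$cal_bp, cont, label = "continental RGR"),
       areas = areas,
       centroids = partition_centroids(partition))
}

#' Spatial autocorrelation of regional growth rates versus distance
#'
#' Pairwise Pearson correlations between regional growth-rate series,
#' averaged within great-circle distance bins between region centroids.
#'
#' @param regional Long tibble (`region`, `cal_bp`, `rgr`).
#' @param centroids Tibble (`region`, `lon`, `lat`).
#' @param bin_km Distance bin width in km (default 500).
#' @return Tibble: `dist_lo`, `dist_hi`, `mean_cor`, `n_pairs`.
#' @export
spatial_autocorrelation <- function(regional, centroids, bin_km = 500) {
  wide <- tidyr::pivot_wider(regional, names_from = "region", values_from = "rgr")
  vals <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(vals) < 3) abort("need at least 3 regions")
  cm <- suppressWarnings(cor(vals, use = "pairwise.complete.obs"))
  regs <- as.integer(colnames(vals))
  cen <- centroids[match(regs, centroids$region), ]
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  d_km <- geosphere::distHaversine(
    cbind(cen$lon[pairs[, 1]], cen$lat[pairs[, 1]]),
    cbind(cen$lon[pairs[, 2]], cen$lat[pairs[, 2]])) / 1000
  r <- cm[pairs]
  bin <- floor(d_km / bin_km)
  out <- tibble::tibble(bin = bin, r = r) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_cor = mean(.data$r, na.rm = TRUE),
                     n_pairs = dplyr::n(), .groups = "drop")
  tibble::tibble(dist_lo = out$bin * bin_km, dist_hi = (out$bin + 1) * bin_km,
                 mean_cor = out$mean_cor, n_pairs = out$n_pairs)
}

#' Synchrony with a forcing as a function of spatial extent
#'
#' For nested spatial windows (radii around the domain centroid), averages
#' the growth rates of the regions inside each window with area weights and
#' computes their phase overlap with the (already sign-adjusted) forcing.
#'
#' @param regional Long tibble (`region`, `cal_bp`, `rgr`).
#' @param areas Named km² per region.
#' @param centroids Tibble (`region`, `lon`, `lat`).
#' @param forcing A [grid_series()] on the same slice grid.
#' @param radii_km Window radii in km (default `c(250, 500, 1000, 2000, 4000)`).
#' @param ... Passed to [phase_overlap()].
#' @return Tibble: `radius_km`, `n_regions`, `overlap`.
#' @export
synchrony_vs_extent <- function(regional, areas, centroids, forcing,
                                radii_km = c(250, 500, 1000, 2000, 4000), ...) {
  ctr_lon <- weighted.mean(centroids$lon, areas[as.character(centroids$region)])
  ctr_lat <- weighted.mean(centroids$lat, areas[as.character(centroids$region)])
  d_km <- geosphere::distHaversine(cbind(centroids$lon, centroids$lat),
                                   c(ctr_lon, ctr_lat)) / 1000
  wide <- tidyr::pivot_wider(regional, names_from = "region", values_from = "rgr")
  wide <- wide[order(-wide$cal_bp), ]
  vals <- as.matrix(wide[, -1, drop = FALSE])
  out <- list()
  for (rad in radii_km) {
    inside <- centroids$region[d_km <= rad]
    cols <- colnames(vals) %in% as.character(inside)
    if (!any(cols)) next
    a <- areas[colnames(vals)[cols]]
    sub <- vals[, cols, drop = FALSE]
    avg <- apply(sub, 1, function(v) {
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      sum(a[ok] * v[ok]) / sum(a[ok])
    })
    win <- grid_series(wide$cal_bp, avg)
    both <- common_support(preprocess(win), forcing)
    ov <- phase_overlap(both$a, both$b, ...)
    out[[length(out) + 1]] <- tibble::tibble(radius_km = rad,
                                             n_regions = sum(cols),
                                             overlap = ov)
  }
  dplyr::bind_rows(out)
}
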