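#' Weighted principal components of an aligned proxy ensemble
#'
#' Interpolates each record onto a common regular grid (within its own
#' support only), drops records with internal coverage gaps larger than
#' `max_gap`, restricts to time steps covered by every retained record,
#' standardizes each record, multiplies it by its alignment weight `w_j` (so
#' records with higher ensemble synchrony carry more of the decomposition),
#' and runs a principal component analysis.
#'
#' @param records Long tibble (`id`, `cal_bp`, `value`), e.g. the `records`
#'   element of a [align_records()] result.
#' @param weights Named record weights `w_j` (default: equal).
#' @param n_pc Number of components to keep (default 5).
#' @param grid_step Common grid step in years (default 20).
#' @param max_gap Largest tolerated sampling gap within a record (a).
#' @return A `proxy_pca` list: `scores` (tibble `cal_bp`, `PC1`..), `loadings`
#'   (record x component matrix), `var_explained` (fractions of total
#'   variance, non-increasing), `weights`, `dropped` (ids of dropped
#'   records).
#' @export
principal_components <- function(records, weights = NULL, n_pc = 5,
                                 grid_step = 20, max_gap = 500) {
  ids <- unique(records$id)
  if (is.null(weights)) weights <- setNames(rep(1 / length(ids), length(ids)), ids)
  dropped <- character(0)
  keep <- list()
  for (k in ids) {
    r <- records[records$id == k, ]
    r <- r[order(-r$cal_bp), ]
    if (nrow(r) < 4 || max(abs(diff(r$cal_bp))) > max_gap) {
      dropped <- c(dropped, k)
      next
    }
    keep[[k]] <- r
  }
  if (length(keep) < n_pc) abort("fewer usable records than requested components")
  if (length(dropped)) inform(paste("dropped records with coverage gaps:",
                                    paste(dropped, collapse = ", ")))
  hi <- min(vapply(keep, function(r) max(r$cal_bp), numeric(1)))
  lo <- max(vapply(keep, function(r) min(r$cal_bp), numeric(1)))
  if (hi - lo < 10 * grid_step) abort("records share too little common support")
  grid <- seq(floor(hi / grid_step) * grid_step,
              ceiling(lo / grid_step) * grid_step, by = -grid_step)
  M <- sapply(keep, function(r) approx(r$cal_bp, r$value, xout = grid, rule = 1)$y)
  ok <- stats::complete.cases(M)
  M <- M[ok, , drop = FALSE]
  grid <- grid[ok]
  sds <- apply(M, 2, sd)
  sds[sds == 0] <- 1
  M <- scale(M, center = TRUE, scale = sds)
  M <- sweep(M, 2, weights[colnames(M)], "*")
  pc <- prcomp(M, center = FALSE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(n_pc), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(cal_bp = grid), scores)
  structure(list(
    scores = scores,
    loadings = pc$rotation[, seq_len(n_pc), drop = FALSE],
    var_explained = pc$sdev^2 / sum(pc$sdev^2),
    weights = weights[colnames(M)],
    dropped = dropped,
    grid_step = grid_step
  ), class = "proxy_pca")
}

#' @export
glance.proxy_pca <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$loadings),
    n_pc = ncol(x$loadings),
    var_pc1 = x$var_explained[1],
    var_first3 = sum(x$var_explained[seq_len(min(3, length(x$var_explained)))]),
    var_first5 = sum(x$var_explained[seq_len(min(5, length(x$var_explained)))])
  )
}

#' @export
tidy.proxy_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$var_explained)),
    var_explained = x$var_explained
  )
}

# index from one segment's PC scores: -normalize(sum |d smoothed PC / dt|)
stability_from_scores <- function(scores, n_pc, grid_step, smooth_len,
                                  normalize = TRUE) {
  pcs <- setdiff(names(scores), "cal_bp")
  pcs <- pcs[seq_len(min(n_pc, length(pcs)))]
  tot <- numeric(nrow(scores))
  for (p in pcs) {
    sm <- kernel_smooth(scores[[p]], grid_step, smooth_len)
    n <- length(sm)
    der <- numeric(n)
    der[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (2 * grid_step)
    der[1] <- (sm[2] - sm[1]) / grid_step
    der[n] <- (sm[n] - sm[n - 1]) / grid_step
    tot <- tot + abs(der)
  }
  if (normalize) {
    s <- sd(tot)
    if (!is.finite(s) || s == 0) abort("degenerate (constant-change) principal components")
    tot <- (tot - mean(tot)) / s
  } else {
    tot <- tot - mean(tot)
  }
  grid_series(scores$cal_bp, -tot, label = "climate stability", normalized = normalize)
}

#' Climate stability index from principal components
#'
#' Sums the absolute temporal derivatives of the smoothed leading principal
#' components into a measure of how fast the multivariate climate state
#' changes, normalizes it (zero mean, unit variance) and flips the sign so
#' that high values mean slow change, i.e. stable climate. Given two
#' segment-wise PCAs (early/late), the per-segment indices are blended with
#' linear cross-fade weights across the 5.8--6.2 ka BP junction.
#'
#' @param pca A `proxy_pca`, or a list of two (`early`, `late`).
#' @param n_pc Number of components summed (default 5).
#' @param smooth_len Smoothing kernel half-width before differencing (a).
#' @param blend `c(older, younger)` cal BP cross-fade window for the
#'   two-segment case (default 6200--5800).
#' @return A [grid_series()] stability index.
#' @export
stability_index <- function(pca, n_pc = 5, smooth_len = 130,
                            blend = c(6200, 5800)) {
  if (inherits(pca, "proxy_pca")) {
    return(stability_from_scores(pca$scores, n_pc, pca$grid_step, smooth_len))
  }
  stopifnot(is.list(pca), all(c("early", "late") %in% names(pca)))
  se <- stability_from_scores(pca$early$scores, n_pc, pca$early$grid_step, smooth_len)
  sl <- stability_from_scores(pca$late$scores, n_pc, pca$late$grid_step, smooth_len)
  step <- gs_step(se)
  hi <- max(se$cal_bp)
  lo <- min(sl$cal_bp)
  grid <- seq(hi, lo, by = -step)
  ve <- approx(se$cal_bp, se$value, xout = grid, rule = 1)$y
  vl <- approx(sl$cal_bp, sl$value, xout = grid, rule = 1)$y
  # weight of the early segment: 1 above the blend window, 0 below
  w <- pmin(pmax((grid - blend[2]) / (blend[1] - blend[2]), 0), 1)
  w[is.na(vl)] <- 1
  w[is.na(ve)] <- 0
  v <- w * ifelse(is.na(ve), 0, ve) + (1 - w) * ifelse(is.na(vl), 0, vl)
  v[is.na(ve) & is.na(vl)] <- NA
  out <- v
  s <- sd(out, na.rm = TRUE)
  out <- (out - mean(out, na.rm = TRUE)) / s
  grid_series(grid, out, label = "climate stability", normalized = TRUE)
}

#' Prepare a solar-forcing comparison series
#'
#' Resamples a total-solar-irradiance series onto the analysis grid, applies
#' the standard smoothing/detrending/normalization, and reverses the sign:
#' low solar irradiance empirically coincides with high climate stability, so
#' the reversed series is directly comparable with the stability index.
#'
#' @param tsi Data frame (`cal_bp`, `value`) or [grid_series()].
#' @param window `c(older, younger)` cal BP analysis window.
#' @param step Analysis grid step (a, default 100).
#' @param ... Passed to [preprocess()].
#' @return A [grid_series()] of sign-reversed, normalized forcing.
#' @export
prepare_forcing <- function(tsi, window = NULL, step = 100, ...) {
  g <- resample_grid(tsi, step, window)
  if (anyNA(g$value)) abort("TSI series does not cover the analysis window")
  pr <- preprocess(g, normalize = TRUE, ...)
  grid_series(pr$cal_bp, -pr$value, label = "-TSI", normalized = TRUE)
}

#' Environmental homogeneity from tree-ring widths
#'
#' The across-tree spread of ring widths in a given year measures how
#' heterogeneous growing conditions were; its normalized, sign-flipped series
#' is a local high-resolution indicator of environmental homogeneity. Years
#' with fewer than two trees are excluded (flagged by NA before resampling).
#'
#' @param widths Long tibble (`cal_bp`, `tree`, `width`).
#' @param step Output grid step (a, default 1: annual rings).
#' @param ... Passed to [preprocess()].
#' @return A [grid_series()] homogeneity index.
#' @export
treering_homogeneity <- function(widths, step = 1, ...) {
  byyear <- widths |>
    dplyr::group_by(.data$cal_bp) |>
    dplyr::summarise(n_trees = dplyr::n(), sdw = sd(.data$width), .groups = "drop")
  n_single <- sum(byyear$n_trees < 2)
  if (n_single > 0) inform(sprintf("%d year(s) with a single tree excluded", n_single))
  byyear <- byyear[byyear$n_trees >= 2, ]
  if (nrow(byyear) < 4) abort("too few years with at least 2 trees")
  g <- resample_grid(tibble::tibble(cal_bp = byyear$cal_bp, value = byyear$sdw), step)
  pr <- preprocess(g, normalize = TRUE, ...)
  grid_series(pr$cal_bp, -pr$value, label = "tree-ring homogeneity",
              normalized = TRUE)
}
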