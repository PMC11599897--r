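#' Penalized DTW distance between two proxy records
#'
#' Standardizes both records, interpolates them onto a common discrete time
#' grid over their overlapping support, and computes the non-normalized
#' dynamic-time-warping path cost (squared differences, symmetric unit-weight
#' steps). The cost is divided by the relative overlap (fraction of the
#' shorter record covered by the overlap) and amplified by `1 + (d/100)^2`,
#' with `d` the maximal time distortion along the warping path, so short
#' overlaps and large distortions are penalized.
#'
#' @param rec_i,rec_j Tibbles with columns `cal_bp`, `value` (strictly
#'   monotone timings).
#' @param grid_step Discretization step in years (default 20).
#' @return List: `D` (penalized distance, `Inf` if no overlap), `d` (maximal
#'   distortion, a), `overlap_frac`, `warp_i`, `warp_j` (tibbles `cal_bp`,
#'   `warped` giving, for each grid point of one record, the matched time in
#'   the other).
#' @export
pairwise_dtw_distance <- function(rec_i, rec_j, grid_step = 20) {
  ri <- rec_i[order(-rec_i$cal_bp), ]
  rj <- rec_j[order(-rec_j$cal_bp), ]
  hi <- min(max(ri$cal_bp), max(rj$cal_bp))
  lo <- max(min(ri$cal_bp), min(rj$cal_bp))
  if (hi - lo < 3 * grid_step) {
    return(list(D = Inf, d = NA_real_, overlap_frac = 0,
                warp_i = NULL, warp_j = NULL))
  }
  grid <- seq(floor(hi / grid_step) * grid_step,
              ceiling(lo / grid_step) * grid_step, by = -grid_step)
  zi <- std_interp(ri, grid)
  zj <- std_interp(rj, grid)
  ok <- !is.na(zi) & !is.na(zj)
  grid <- grid[ok]; zi <- zi[ok]; zj <- zj[ok]
  if (length(grid) < 4) {
    return(list(D = Inf, d = NA_real_, overlap_frac = 0,
                warp_i = NULL, warp_j = NULL))
  }
  res <- dtw_core(zi, zj)
  t_i <- grid
  t_j <- grid
  warped_i <- t_j[1] - res$xmap * grid_step    # matched time in j per point of i
  warped_j <- t_i[1] - res$ymap * grid_step
  d <- max(abs(warped_i - t_i), abs(warped_j - t_j))
  len_i <- max(ri$cal_bp) - min(ri$cal_bp)
  len_j <- max(rj$cal_bp) - min(rj$cal_bp)
  ovl <- (hi - lo) / max(min(len_i, len_j), grid_step)
  ovl <- min(ovl, 1)
  D <- res$cost / ovl * (1 + (d / 100)^2)
  list(D = D, d = d, overlap_frac = ovl,
       warp_i = tibble::tibble(cal_bp = t_i, warped = warped_i),
       warp_j = tibble::tibble(cal_bp = t_j, warped = warped_j))
}

std_interp <- function(rec, grid) {
  v <- rec$value
  s <- sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  z <- (v - mean(v)) / s
  approx(rec$cal_bp, z, xout = grid, rule = 1)$y
}

# enforce strictly descending timings; returns list(t, n_repaired)
enforce_monotone <- function(t_bp) {
  if (all(diff(t_bp) < 0)) return(list(t = t_bp, n = 0L))
  # isotonic projection on the ascending (negated) sequence
  fit <- isoreg(-t_bp)$yf
  eps <- 1e-6
  fit <- fit + seq_along(fit) * eps  # break ties into strict order
  list(t = -fit, n = sum(diff(t_bp) >= 0))
}

#' Reference-free multi-record chronology alignment
#'
#' Iteratively aligns an ensemble of proxy records without a master
#' chronology. Each iteration computes all pairwise penalized DTW distances
#' `D_ij` and warped timings, converts them to pair weights
#' `w_ij = exp(-(D_ij / Dbar)^2) * w_j` (with `Dbar` the overall mean
#' distance and `w_j` the record weights from the previous iteration,
#' initialized at `1/n`), displaces every record's timings by the weighted
#' mean of its pairwise warps, and updates the record weights
#' `w_j = sum_i w_ij / sum_ij w_ij`. Cumulative displacements are hard-capped
#' at `cap` years; timing order within a record is preserved (violations are
#' repaired by isotonic projection and logged). Iteration stops when the mean
#' absolute displacement update falls below `tol` (after at least `min_iter`
#' rounds) or after `max_iter` rounds, with a warning if not converged.
#'
#' @param records Long tibble (`id`, `cal_bp`, `value`); all records should
#'   belong to one time segment.
#' @param cap Displacement cap in years (default 150).
#' @param max_iter,min_iter Iteration bounds (default 8 and 4).
#' @param tol Convergence tolerance on the mean absolute displacement update
#'   (a, default 1).
#' @param grid_step DTW discretization step (a).
#' @param per_iteration_cap Apply the cap per iteration instead of
#'   cumulatively (default FALSE: cumulative, the stricter reading).
#' @return A `proxy_alignment` list: `records` (aligned long tibble with
#'   `cal_bp`, `cal_bp_orig`, `displacement`), `weights` (named `w_j`),
#'   `D` (distance matrix), `d` (distortion matrix), `D_bar`, `iterations`,
#'   `converged`, `n_monotone_repairs`.
#' @export
align_records <- function(records, cap = 150, max_iter = 8, min_iter = 4,
                          tol = 1, grid_step = 20, per_iteration_cap = FALSE) {
  ids <- unique(records$id)
  n <- length(ids)
  if (n < 3) abort("need at least 3 records to align")
  orig <- lapply(ids, function(k) {
    r <- records[records$id == k, ]
    r <- r[order(-r$cal_bp), ]
    mono <- enforce_monotone(r$cal_bp)
    r$cal_bp <- mono$t
    r
  })
  names(orig) <- ids
  cur_t <- lapply(orig, function(r) r$cal_bp)
  w_j <- setNames(rep(1 / n, n), ids)
  D <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  dmat <- D
  n_rep <- 0L
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    warps <- vector("list", n)
    for (a in seq_len(n)) warps[[a]] <- vector("list", n)
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        pa <- tibble::tibble(cal_bp = cur_t[[a]], value = orig[[a]]$value)
        pb <- tibble::tibble(cal_bp = cur_t[[b]], value = orig[[b]]$value)
        pd <- pairwise_dtw_distance(pa, pb, grid_step = grid_step)
        D[a, b] <- D[b, a] <- pd$D
        dmat[a, b] <- dmat[b, a] <- pd$d
        warps[[a]][[b]] <- pd$warp_i
        warps[[b]][[a]] <- pd$warp_j
      }
    }
    finD <- D[upper.tri(D)]
    finD <- finD[is.finite(finD)]
    if (!length(finD)) abort("no record pair overlaps in time")
    D_bar <- mean(finD)
    if (D_bar <= 0) D_bar <- 1e-12
    W <- exp(-(D / D_bar)^2)
    W[!is.finite(D)] <- 0
    diag(W) <- 0
    W <- sweep(W, 2, w_j, "*")  # w_ij = exp(-(D_ij/Dbar)^2) * w_j

    updates <- numeric(0)
    for (a in seq_len(n)) {
      disp <- numeric(length(cur_t[[a]]))
      for (b in seq_len(n)) {
        if (b == a || is.null(warps[[a]][[b]]) || W[a, b] <= 0) next
        wb <- warps[[a]][[b]]
        shift <- approx(wb$cal_bp, wb$warped - wb$cal_bp, xout = cur_t[[a]],
                        rule = 2)$y
        disp <- disp + W[a, b] * shift
      }
      if (per_iteration_cap) disp <- pmin(pmax(disp, -cap), cap)
      new_t <- cur_t[[a]] + disp
      cum <- new_t - orig[[a]]$cal_bp
      cum <- pmin(pmax(cum, -cap), cap)
      new_t <- orig[[a]]$cal_bp + cum
      mono <- enforce_monotone(new_t)
      n_rep <- n_rep + mono$n
      updates <- c(updates, mean(abs(mono$t - cur_t[[a]])))
      cur_t[[a]] <- mono$t
    }
    csum <- colSums(W)
    if (sum(csum) > 0) w_j <- setNames(csum / sum(csum), ids)
    if (iter >= min_iter && mean(updates) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warn(sprintf("alignment not converged after %d iterations", iter))
  aligned <- dplyr::bind_rows(lapply(seq_len(n), function(a) {
    tibble::tibble(id = ids[a],
                   cal_bp = cur_t[[a]],
                   cal_bp_orig = orig[[a]]$cal_bp,
                   displacement = cur_t[[a]] - orig[[a]]$cal_bp,
                   value = orig[[a]]$value)
  }))
  structure(list(records = aligned, weights = w_j, D = D, d = dmat,
                 D_bar = mean(finD), iterations = iter, converged = converged,
                 n_monotone_repairs = n_rep, cap = cap),
            class = "proxy_alignment")
}

#' Split proxy records into the early and late Holocene segments
#'
#' Records are split at the mid-Holocene shift in climate variability: the
#' early segment keeps everything older than 5.8 ka BP and the late segment
#' everything younger than 6.2 ka BP, so both retain the 5.8--6.2 ka overlap
#' zone used later to blend the stability index.
#'
#' @param records Long tibble (`id`, `cal_bp`, `value`).
#' @param early_min,late_max Segment boundaries in cal BP (defaults 5800 and
#'   6200).
#' @return Named list of two long tibbles, `early` and `late`.
#' @export
split_segments <- function(records, early_min = 5800, late_max = 6200) {
  list(early = records[records$cal_bp >= early_min, ],
       late = records[records$cal_bp <= late_max, ])
}

#' Align a full proxy ensemble segment by segment
#'
#' Convenience wrapper: splits the ensemble with [split_segments()], aligns
#' each segment with [align_records()], and returns both alignments.
#'
#' @inheritParams align_records
#' @inheritParams split_segments
#' @return Named list of two `proxy_alignment` objects.
#' @export
align_proxy_ensemble <- function(records, cap = 150, max_iter = 8,
                                 grid_step = 20, early_min = 5800,
                                 late_max = 6200, ...) {
  seg <- split_segments(records, early_min, late_max)
  lapply(seg, align_records, cap = cap, max_iter = max_iter,
         grid_step = grid_step, ...)
}

#' @export
tidy.proxy_alignment <- function(x, ...) {
  x$records |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_abs_displacement = mean(abs(.data$displacement)),
      max_abs_displacement = max(abs(.data$displacement)),
      weight = unname(x$weights[.data$id[1]]),
      .groups = "drop"
    )
}

#' @export
glance.proxy_alignment <- function(x, ...) {
  tibble::tibble(
    n_records = length(x$weights),
    iterations = x$iterations,
    converged = x$converged,
    D_bar = x$D_bar,
    max_abs_displacement = max(abs(x$records$displacement)),
    n_monotone_repairs = x$n_monotone_repairs
  )
}
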