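#' Boom/bust labels from the sign of the growth rate
#'
#' Booms are phases of positive, busts of negative (preprocessed) relative
#' growth rate; exact zeros and undefined bins are flagged NA and excluded
#' from fitting.
#'
#' @param rgr A preprocessed RGR [grid_series()].
#' @return A [grid_series()] of labels (1 = boom, 0 = bust, NA = undefined).
#' @export
label_boom_bust <- function(rgr) {
  v <- ifelse(is.na(rgr$value) | rgr$value == 0, NA_real_,
              ifelse(rgr$value > 0, 1, 0))
  grid_series(rgr$cal_bp, v, label = "boom/bust")
}

#' Time-lagged growth-rate input
#'
#' The endogenous model input: the growth rate read `lag` years *earlier*
#' (older, larger cal BP), with the lag switching at the 7 ka BP break --
#' 350 a before, 210 a after. Values are linearly interpolated when the lag
#' is not a grid multiple; lagged times outside the series support give NA.
#'
#' @param rgr An RGR [grid_series()].
#' @param break_time Cal BP of the lag switch (default 7000).
#' @param lag_early,lag_late Lags in years before/after the break (defaults
#'   350 and 210).
#' @return A [grid_series()] on the same grid.
#' @export
lagged_rgr <- function(rgr, break_time = 7000, lag_early = 350, lag_late = 210) {
  lag <- ifelse(rgr$cal_bp > break_time, lag_early, lag_late)
  src <- rgr$cal_bp + lag
  v <- approx(rgr$cal_bp, rgr$value, xout = src, rule = 1)$y
  grid_series(rgr$cal_bp, v, label = "lagged RGR")
}

logit_inputs <- function(variant) {
  switch(variant,
    "1V" = "rgr_lag",
    "2V" = c("stability", "tsi"),
    "3V" = c("rgr_lag", "stability", "tsi"),
    abort(sprintf("unknown variant '%s'", variant))
  )
}

# ridge-stabilized IRLS fallback for separated fits
irls_ridge <- function(X, y, lambda = 1e-6, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + diag(lambda, ncol(X)), XtW %*% z)
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- as.numeric(beta_new)
  }
  as.numeric(beta)
}

#' Fit a boom/bust logistic regression
#'
#' Maximum-likelihood logistic regression of boom/bust labels on up to three
#' smoothed, detrended and normalized inputs, in three variants: `"1V"` uses
#' only the time-lagged growth rate (endogenous memory), `"2V"` the climate
#' stability index and sign-reversed solar irradiance (exogenous forcing),
#' and `"3V"` all three. Bins with any undefined value are dropped listwise.
#' Perfect separation triggers a ridge-stabilized refit (penalty 1e-6) with
#' a warning.
#'
#' @param data Tibble with columns `label` (1/0) and the inputs `rgr_lag`,
#'   `stability`, `tsi` as required by the variant (plus optionally
#'   `cal_bp`).
#' @param variant One of `"1V"`, `"2V"`, `"3V"` (default `"3V"`).
#' @return A `boom_bust_logit` object with [tidy()] and [glance()] methods.
#' @export
fit_boom_bust_logit <- function(data, variant = c("3V", "1V", "2V")) {
  variant <- match.arg(variant)
  inputs <- logit_inputs(variant)
  missing_cols <- setdiff(c("label", inputs), names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[c("label", inputs)]), c("label", inputs)]
  if (nrow(d) < length(inputs) + 2) abort("too few complete observations")
  form <- stats::as.formula(paste("label ~", paste(inputs, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (separated || any(!is.finite(coefs)) || any(abs(coefs) > 50)) {
    warn("possible separation; refitting with a small ridge penalty")
    X <- cbind(1, as.matrix(d[inputs]))
    beta <- irls_ridge(X, d$label)
    coefs <- setNames(beta, c("(Intercept)", inputs))
    se <- rep(NA_real_, length(coefs))
  }
  eta <- cbind(1, as.matrix(d[inputs])) %*% coefs
  p <- 1 / (1 + exp(-eta))
  ll <- sum(d$label * log(pmax(p, 1e-12)) + (1 - d$label) * log(pmax(1 - p, 1e-12)))
  structure(list(variant = variant, inputs = inputs,
                 coefficients = coefs, se = se,
                 log_lik = ll, n = nrow(d), fit = fit,
                 separated = separated),
            class = "boom_bust_logit")
}

#' @export
print.boom_bust_logit <- function(x, ...) {
  cat(sprintf("Boom/bust logit (%s), n = %d, logLik = %.2f\n",
              x$variant, x$n, x$log_lik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.boom_bust_logit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$se)
  )
}

#' @export
glance.boom_bust_logit <- function(x, ...) {
  tibble::tibble(variant = x$variant, n = x$n, log_lik = x$log_lik,
                 n_terms = length(x$coefficients), separated = x$separated)
}

#' Boom-minus-bust probability hindcast
#'
#' Predicted probability of a boom minus that of a bust, `2 * p - 1`, per
#' bin; undefined input bins give undefined output bins.
#'
#' @param model A `boom_bust_logit`.
#' @param newdata Tibble with the model's input columns (and optionally
#'   `cal_bp`).
#' @return A [grid_series()] if `cal_bp` is present, else a numeric vector,
#'   with values in `[-1, 1]`.
#' @export
predict_boom_minus_bust <- function(model, newdata) {
  X <- as.matrix(newdata[model$inputs])
  eta <- cbind(1, X) %*% model$coefficients
  p <- 1 / (1 + exp(-eta))
  out <- as.numeric(2 * p - 1)
  out[!stats::complete.cases(newdata[model$inputs])] <- NA_real_
  if ("cal_bp" %in% names(newdata)) {
    grid_series(newdata$cal_bp, out, label = sprintf("%s hindcast", model$variant))
  } else {
    out
  }
}
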