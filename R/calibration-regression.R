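# Methods that regress on (or offset) the published prognostic index in the
# validation data: the calibration slope, the joint misspecification test and
# the proportional-hazards check.

#' Calibration slope on the prognostic index
#'
#' Fits a Cox model in the validation data with the published PI as the sole
#' covariate. The coefficient is the calibration slope: 1 means the published
#' effect strength is preserved, < 1 means the model discriminates less well
#' in the new data, > 1 better. On the dataset whose own Cox fit produced the
#' PI, the slope is exactly 1 by construction. The likelihood-ratio test of
#' slope = 1 compares the fitted model with the model holding the PI as a
#' fixed offset; the resulting P-value can be anti-conservative because it
#' ignores uncertainty in the published coefficients.
#'
#' @param data data frame with follow-up time, event and PI columns. The PI
#'   must be computed exactly as published (no refitting).
#' @param pi,time,event column names.
#' @param ties tie handling for the Cox fits.
#' @return object of class `slope_result` with `slope`, `se`, `lr_statistic`,
#'   `p_value` and the interpretation caveat.
#' @export
calibration_slope <- function(data, pi = "pi", time = "time", event = "event",
                              ties = "efron") {
  if (!pi %in% names(data)) stop_config("column '%s' not found", pi)
  if (length(unique(data[[pi]])) == 1L)
    stop_data("prognostic index is constant; the slope is undefined")
  free <- fit_cox(data, covariates = pi, ties = ties, time = time,
                  event = event)
  fixed <- fit_cox(data, offset = pi, ties = ties, time = time, event = event)
  lr <- max(0, 2 * (free$log_likelihood - fixed$log_likelihood))
  structure(list(slope = unname(free$coefficients[[1]]),
                 se = sqrt(diag(free$covariance))[[1]],
                 lr_statistic = lr,
                 p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 caveat = .caveats$slope, fit = free),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("Calibration slope: %.3f (SE %.3f)\n", x$slope, x$se))
  cat(sprintf("LR test of slope = 1: chi-squared(1) = %.3f, P = %.3g\n",
              x$lr_statistic, x$p_value))
  cat("Note:", x$caveat, "\n")
  invisible(x)
}

#' Joint misspecification test with the prognostic index offset
#'
#' Refits the model's own transformed covariate columns in the validation
#' data while holding the published PI fixed as an offset:
#' \deqn{\ln h(t) = \ln h_0(t) + x'\beta^* + PI,} the PI coefficient
#' constrained to 1. Each \eqn{\beta^*} estimates the difference between the
#' published coefficient (treated as fixed) and the coefficient the
#' validation data support. A joint test of \eqn{\beta^* = 0} checks overall
#' fit; the per-covariate statistics are reported but are secondary, the
#' joint test protecting against type-1 error inflation.
#'
#' @param data data frame with time, event, PI and the transformed covariate
#'   columns.
#' @param covariates names of the model's transformed covariate columns.
#' @param test `"lr"` (offset model versus offset + covariates, default) or
#'   `"wald"`; both statistics are returned, `test` selects which one is
#'   reported as primary.
#' @inheritParams calibration_slope
#' @return object of class `misspec_result` with `beta_star`, `covariance`,
#'   `statistic`, `df`, `p_value`, plus `lr_statistic` and `wald_statistic`.
#' @export
misspecification_test <- function(data, covariates, pi = "pi",
                                  test = c("lr", "wald"), time = "time",
                                  event = "event", ties = "efron") {
  test <- match.arg(test)
  if (!length(covariates)) stop_config("no covariates to test")
  X <- as.matrix(data[, covariates, drop = FALSE])
  qrX <- qr(scale(X, scale = FALSE))
  if (qrX$rank < ncol(X)) {
    dropped <- covariates[-qrX$pivot[seq_len(qrX$rank)]]
    stop_data("collinear covariates in the misspecification test: %s",
              paste(dropped, collapse = ", "))
  }
  full <- fit_cox(data, covariates = covariates, offset = pi, ties = ties,
                  time = time, event = event)
  null <- fit_cox(data, offset = pi, ties = ties, time = time, event = event)
  beta <- full$coefficients
  V <- full$covariance
  wald <- drop(t(beta) %*% solve(V, beta))
  lr <- max(0, 2 * (full$log_likelihood - null$log_likelihood))
  df <- length(beta)
  stat <- if (test == "lr") lr else wald
  per_cov <- data.frame(term = names(beta), beta_star = unname(beta),
                        se = sqrt(diag(V)),
                        z = unname(beta) / sqrt(diag(V)))
  structure(list(beta_star = beta, covariance = V, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 lr_statistic = lr, wald_statistic = wald, test = test,
                 per_covariate = per_cov),
            class = "misspec_result")
}

#' @export
print.misspec_result <- function(x, ...) {
  cat(sprintf("Misspecification (offset) test: chi-squared(%d) = %.3f, P = %.3g [%s]\n",
              x$df, x$statistic, x$p_value, toupper(x$test)))
  cat(sprintf("  (LR %.3f, Wald %.3f)\n", x$lr_statistic, x$wald_statistic))
  cat("Per-covariate coefficient differences (secondary):\n")
  print(x$per_covariate, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Proportional-hazards check for the prognostic index
#'
#' Grambsch-Therneau test based on scaled Schoenfeld residuals from the Cox
#' fit of the PI in the validation data (slope re-estimated), against a
#' chosen transform of time (Kaplan-Meier scaling by default). A breach of
#' proportional hazards means the PI's effect drifts over time; it need not
#' invalidate the model's discrimination, but calibration should then be
#' scrutinised.
#'
#' @inheritParams calibration_slope
#' @param transform time transform for the test: `"km"` (default),
#'   `"identity"` or `"rank"`.
#' @return object of class `ph_result` wrapping the [survival::cox.zph()]
#'   table.
#' @export
ph_check <- function(data, pi = "pi", transform = c("km", "identity", "rank"),
                     time = "time", event = "event", ties = "efron") {
  transform <- match.arg(transform)
  if (sum(data[[event]]) < 3) stop_data("too few events for a PH check")
  fit <- fit_cox(data, covariates = pi, ties = ties, time = time,
                 event = event)
  zph <- survival::cox.zph(fit$fit, transform = transform)
  tab <- zph$table
  structure(list(table = tab,
                 statistic = tab[1, "chisq"], df = tab[1, "df"],
                 p_value = tab[1, "p"], transform = transform,
                 caveat = .caveats$ph, zph = zph),
            class = "ph_result")
}

#' @export
print.ph_result <- function(x, ...) {
  cat(sprintf("PH check (scaled Schoenfeld residuals, %s time): chi-squared(%d) = %.3f, P = %.3g\n",
              x$transform, x$df, x$statistic, x$p_value))
  cat("Note:", x$caveat, "\n")
  invisible(x)
}
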