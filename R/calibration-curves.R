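# Risk-group calibration: model-predicted survival curves from the
# transportable baseline, observed Kaplan-Meier curves, and their comparison.

#' Predicted survival for given prognostic-index values
#'
#' Under the published model, a subject with centered prognostic index
#' \eqn{PI} has survival \eqn{S(t; PI) = S_0(t)^{\exp(PI)}}.
#'
#' @param baseline an `fp2_fit` or [baseline_lookup()].
#' @param pi prognostic-index value(s).
#' @param times strictly positive evaluation times within the baseline's
#'   validity range (truncate the follow-up upstream rather than
#'   extrapolating).
#' @param extrapolate allow evaluation outside the baseline's fitted range.
#' @return numeric vector (one `pi`) or matrix (rows = subjects, columns =
#'   times) of survival probabilities.
#' @export
predict_individual_survival <- function(baseline, pi, times,
                                        extrapolate = FALSE) {
  if (any(!is.finite(pi))) stop_data("pi must be finite")
  s0 <- evaluate_s0(baseline, times, extrapolate)
  out <- outer(exp(pi), seq_along(times),
               function(e, j) s0[j]^e)
  if (length(pi) == 1L) drop(out) else out
}

#' Model-predicted mean survival curve per risk group
#'
#' Averages the member-level predicted curves \eqn{S_0(t)^{\exp(PI_i)}} over
#' the subjects of each risk group, at the observed times of the validation
#' dataset (restricted to the baseline's validity range). Averaging is of
#' survival probabilities, not of PI values: plugging the group-mean PI into
#' the survival formula would differ by Jensen's inequality.
#'
#' @param data data frame with PI and group columns.
#' @param baseline an `fp2_fit` or [baseline_lookup()].
#' @param pi,group,time column names.
#' @return named list of survival-flavour [step_curve()]s, one per non-empty
#'   group.
#' @export
group_mean_curves <- function(data, baseline, pi = "pi", group = "group",
                              time = "time") {
  for (nm in c(pi, group, time))
    if (!nm %in% names(data)) stop_config("column '%s' not found", nm)
  tr <- baseline$time_range
  tt <- sort(unique(data[[time]]))
  tt <- tt[tt >= tr[1] & tt <= tr[2]]
  if (!length(tt)) stop_data("no observed times fall inside the baseline's time range")
  g <- factor(data[[group]])
  out <- list()
  for (lev in levels(g)) {
    members <- data[[pi]][g == lev]
    if (!length(members)) {
      warning(sprintf("risk group '%s' is empty; omitted", lev))
      next
    }
    sm <- predict_individual_survival(baseline, members, tt)
    vals <- if (is.matrix(sm)) colMeans(sm) else sm
    out[[lev]] <- step_curve(tt, vals, flavour = "survival")
  }
  out
}

#' Observed versus predicted survival by risk group
#'
#' For each risk group and report time point, tabulates the observed
#' Kaplan-Meier survival (with Greenwood SE) next to the model-predicted
#' mean survival of the group's members, and their difference. Time points
#' beyond a group's follow-up are flagged unavailable (NA).
#'
#' @param data data frame with time, event, PI and group columns.
#' @param baseline an `fp2_fit` or [baseline_lookup()].
#' @param timepoints report times (default 2 and 5, in the baseline's time
#'   unit).
#' @param pi,group,time,event column names.
#' @return data frame of class `group_calibration` with columns `group`,
#'   `time`, `n`, `events`, `observed`, `se`, `predicted`, `difference`.
#' @export
observed_vs_predicted <- function(data, baseline, timepoints = c(2, 5),
                                  pi = "pi", group = "group", time = "time",
                                  event = "event") {
  check_surv_cols(data, time, event)
  g <- factor(data[[group]])
  rows <- list()
  for (lev in levels(g)) {
    sel <- g == lev
    if (!any(sel)) next
    km <- kaplan_meier(data[[time]][sel], data[[event]][sel])
    maxfu <- max(data[[time]][sel])
    for (tp in timepoints) {
      avail <- tp <= maxfu
      obs <- if (avail) evaluate_step(km, tp) else NA_real_
      se <- if (avail && length(km$times) && any(km$times <= tp)) {
        km$se[max(which(km$times <= tp))]
      } else if (avail) 0 else NA_real_
      pred <- if (tp >= baseline$time_range[1] &&
                  tp <= baseline$time_range[2]) {
        mean(predict_individual_survival(baseline, data[[pi]][sel], tp))
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = lev, time = tp, n = sum(sel),
        events = sum(data[[event]][sel]), observed = obs, se = se,
        predicted = pred, difference = obs - pred)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_calibration", "data.frame")
  out
}

#' @export
print.group_calibration <- function(x, digits = 3, ...) {
  cat("Calibration by risk group (observed Kaplan-Meier vs predicted mean survival)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Hazard ratios between risk groups
#'
#' Fits a Cox model with a dummy variable for each risk group except the
#' lowest-risk (reference) group. Widely separated survival curves give large
#' hazard ratios, so the table is a sensible check of discrimination (unlike
#' between-group significance tests). SEs of the hazard ratios are delta
#' method from the log scale.
#'
#' @param time,event,group subject-level follow-up, event indicator and risk
#'   group (ordered lowest risk first).
#' @param ties tie handling for the Cox fit.
#' @return data frame of class `group_hr` with columns `group`, `n`,
#'   `events`, `loghr`, `se_loghr`, `hr`, `se_hr`, `infinite` (flag for
#'   groups with no events, whose hazard ratio is not estimable).
#' @export
group_hazard_ratios <- function(time, event, group, ties = "efron") {
  d <- data.frame(time = time, event = event,
                  group = factor(group, ordered = FALSE))
  check_surv_cols(d, "time", "event")
  d <- droplevels(d)
  if (nlevels(d$group) < 2L) stop_config("need at least two non-empty groups")
  ev_by_g <- tapply(d$event, d$group, sum)
  estimable <- ev_by_g > 0
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = d,
                    ties = ties),
    warning = function(w) {
      # an event-free group makes its log HR diverge; that case is reported
      # through the 'infinite' flag rather than a fitter warning
      if (!all(estimable) &&
          grepl("did not converge|infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  levs <- levels(d$group)
  out <- data.frame(group = levs[-1],
                    n = as.integer(table(d$group))[-1],
                    events = as.integer(ev_by_g)[-1],
                    loghr = unname(b), se_loghr = unname(se))
  out$infinite <- !estimable[-1] | !is.finite(out$loghr) | out$se_loghr > 50
  out$loghr[out$infinite] <- NA_real_
  out$se_loghr[out$infinite] <- NA_real_
  out$hr <- exp(out$loghr)
  out$se_hr <- out$hr * out$se_loghr
  attr(out, "reference") <- levs[1]
  class(out) <- c("group_hr", "data.frame")
  out
}

#' @export
print.group_hr <- function(x, digits = 3, ...) {
  cat("Hazard ratios versus reference group '", attr(x, "reference"), "'\n",
      sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  if (any(x$infinite))
    cat("Groups flagged 'infinite' have no events; their hazard ratio is not estimable.\n")
  invisible(x)
}

#' Compare the transported baseline with the validation data's own baseline
#'
#' Overlays the derivation dataset's smoothed (FP2) baseline on the empirical
#' baseline of the validation data, estimated by fitting
#' \eqn{\ln h(t) = \ln h_0(t) + PI} with the PI coefficient constrained to 1
#' (so no published coefficient is re-estimated). A large difference between
#' the two suggests fundamental miscalibration. The summary statistic is the
#' maximum absolute difference on the survival scale over the deciles of the
#' validation event times (within the baseline's validity range).
#'
#' @param time,event,pi validation-data follow-up, event indicator and
#'   prognostic index.
#' @param fit the derivation `fp2_fit`.
#' @param band optional [bootstrap_band()] for the derivation baseline.
#' @return object of class `baseline_comparison` with the empirical survival
#'   curve, the smooth curve evaluated at the empirical event times, the
#'   decile table and `max_abs_diff`.
#' @export
compare_baselines <- function(time, event, pi, fit, band = NULL) {
  H_emp <- baseline_cumhaz(time, event, pi)
  S_emp <- cumhaz_to_survival(H_emp)
  tr <- fit$time_range
  inside <- S_emp$times >= tr[1] & S_emp$times <= tr[2]
  if (!any(inside))
    stop_data("no validation event times fall inside the baseline's time range")
  tt <- S_emp$times[inside]
  dec <- unname(stats::quantile(tt, probs = seq(0.1, 0.9, by = 0.1), type = 7))
  s_emp_dec <- evaluate_step(S_emp, dec)
  s_fit_dec <- evaluate_s0(fit, dec)
  structure(list(empirical = S_emp,
                 smooth_times = tt, smooth_values = evaluate_s0(fit, tt),
                 band = band,
                 deciles = data.frame(time = dec, empirical = s_emp_dec,
                                      smooth = s_fit_dec,
                                      difference = s_emp_dec - s_fit_dec),
                 max_abs_diff = max(abs(s_emp_dec - s_fit_dec))),
            class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, digits = 3, ...) {
  cat("Baseline survival: validation empirical vs transported FP2 smooth\n")
  print(x$deciles, digits = digits, row.names = FALSE)
  cat(sprintf("max |difference| over event-time deciles: %.4f\n",
              x$max_abs_diff))
  invisible(x)
}

#' @export
plot.baseline_comparison <- function(x, xlab = "time",
                                     ylab = "baseline survival", ...) {
  plot(x$empirical, conf = FALSE, xlab = xlab, ylab = ylab, ...)
  graphics::lines(x$smooth_times, x$smooth_values, col = 2, lwd = 2)
  if (!is.null(x$band)) {
    graphics::lines(x$band$times, exp(-x$band$lower), col = "grey60", lty = 2)
    graphics::lines(x$band$times, exp(-x$band$upper), col = "grey60", lty = 2)
  }
  graphics::legend("topright", bty = "n", lwd = c(1, 2), col = c(1, 2),
                   legend = c("empirical (offset-constrained)", "FP2 smooth"))
  invisible(x)
}
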