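#' Right-continuous step curve over time
#'
#' Container for nonparametric survival or cumulative-hazard estimates:
#' a value per event time, optional pointwise standard errors and risk-set
#' counts. Survival-flavoured curves must be non-increasing and start at or
#' below 1; cumulative-hazard curves non-negative and non-decreasing.
#'
#' @param times strictly increasing event times.
#' @param values one value per time.
#' @param flavour `"survival"` or `"cumhaz"`.
#' @param se optional pointwise standard errors.
#' @param at_risk,n_events optional counts per time.
#' @return an object of class `step_curve`.
#' @export
step_curve <- function(times, values, flavour = c("survival", "cumhaz"),
                       se = NULL, at_risk = NULL, n_events = NULL) {
  flavour <- match.arg(flavour)
  if (length(times) != length(values))
    stop_config("times and values must have equal length")
  if (length(times) && any(diff(times) <= 0))
    stop_config("times must be strictly increasing")
  tol <- 1e-10
  if (flavour == "survival") {
    if (length(values) && (any(values > 1 + tol) || any(diff(values) > tol)))
      stop_config("survival curve must start <= 1 and be non-increasing")
  } else {
    if (length(values) && (any(values < -tol) || any(diff(values) < -tol)))
      stop_config("cumulative hazard must be non-negative and non-decreasing")
  }
  structure(list(times = times, values = values, flavour = flavour, se = se,
                 at_risk = at_risk, n_events = n_events),
            class = "step_curve")
}

#' Evaluate a step curve
#'
#' Right-continuous evaluation: the value at `t` is the value at the last
#' event time not exceeding `t`. Before the first event time a survival curve
#' is 1 and a cumulative hazard is 0.
#'
#' @param curve a [step_curve()].
#' @param t numeric vector of evaluation times.
#' @return numeric vector of values.
#' @export
evaluate_step <- function(curve, t) {
  stopifnot(inherits(curve, "step_curve"))
  start <- if (curve$flavour == "survival") 1 else 0
  idx <- findInterval(t, curve$times)
  ifelse(idx == 0L, start, curve$values[pmax(idx, 1L)])
}

#' @export
print.step_curve <- function(x, ...) {
  cat("Step curve (", x$flavour, "), ", length(x$times), " event times",
      sep = "")
  if (length(x$times))
    cat(" on [", format(min(x$times), digits = 4), ", ",
        format(max(x$times), digits = 4), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.step_curve <- function(x, add = FALSE, conf = TRUE, col = 1, lty = 1,
                            xlab = "time",
                            ylab = if (x$flavour == "survival")
                              "survival probability" else "cumulative hazard",
                            ...) {
  start <- if (x$flavour == "survival") 1 else 0
  tt <- c(0, x$times); vv <- c(start, x$values)
  if (!add) {
    ylim <- if (x$flavour == "survival") c(0, 1) else range(0, vv)
    plot(tt, vv, type = "s", col = col, lty = lty, xlab = xlab, ylab = ylab,
         ylim = ylim, ...)
  } else {
    graphics::lines(tt, vv, type = "s", col = col, lty = lty, ...)
  }
  if (conf && !is.null(x$se)) {
    graphics::lines(tt, c(start, pmin(x$values + 1.96 * x$se,
                                      if (x$flavour == "survival") 1 else Inf)),
                    type = "s", col = col, lty = 3)
    graphics::lines(tt, c(start, pmax(x$values - 1.96 * x$se, 0)),
                    type = "s", col = col, lty = 3)
  }
  invisible(x)
}

#' Read or write a step curve as delimited text
#'
#' Columns: time, value, se, at_risk, events; the flavour is recorded in a
#' leading comment line.
#'
#' @param curve a [step_curve()].
#' @param path file path.
#' @return `read_step_curve()` returns a [step_curve()].
#' @export
write_step_curve <- function(curve, path) {
  stopifnot(inherits(curve, "step_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flavour: %s", curve$flavour), con)
  n <- length(curve$times)
  tab <- data.frame(time = curve$times, value = curve$values,
                    se = curve$se %||% rep(NA_real_, n),
                    at_risk = curve$at_risk %||% rep(NA_real_, n),
                    events = curve$n_events %||% rep(NA_real_, n))
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_step_curve
#' @export
read_step_curve <- function(path) {
  first <- readLines(path, n = 1L)
  flavour <- sub("^# flavour:\\s*", "", first)
  tab <- utils::read.csv(path, comment.char = "#")
  drop_na <- function(v) if (all(is.na(v))) NULL else v
  step_curve(tab$time, tab$value, flavour = flavour,
             se = drop_na(tab$se), at_risk = drop_na(tab$at_risk),
             n_events = drop_na(tab$events))
}
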