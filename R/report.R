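#' Run a full external-validation analysis
#'
#' Assembles the seven validation methods into one report, executing exactly
#' those permitted by the information available about the derivation model:
#' \describe{
#'   \item{L1 (coefficients only)}{method 1 (calibration slope), method 2
#'     (misspecification and proportional-hazards checks), method 3
#'     (discrimination measures).}
#'   \item{L2 (L1 + risk grouping)}{adds method 4 (risk-group Kaplan-Meier
#'     curves), method 5 (between-group logrank test, reported with its
#'     deprecation caveat) and method 6 (hazard ratios across groups).}
#'   \item{L3 (L2 + baseline survival function)}{adds method 7
#'     (observed-versus-predicted survival by risk group and the
#'     baseline-agreement check).}
#' }
#' Requesting a calibration assessment without a baseline fails with a clear
#' refusal rather than a silent omission.
#'
#' @param model a [published_model()].
#' @param data validation dataset (data frame with the raw covariates and
#'   time/event columns).
#' @param grouping optional [cox_cutpoints()]/[risk_grouping()] (L2).
#' @param baseline optional `fp2_fit` or [baseline_lookup()] (L3).
#' @param timepoints report times for the calibration table.
#' @param horizon truncation horizon for follow-up; defaults to the model's
#'   `max_followup` when set.
#' @param n_boot bootstrap replicates for the baseline band (0 = no band).
#' @param seed integer seed used for any resampling.
#' @param ties tie-handling for all Cox fits.
#' @param time,event column names.
#' @return object of class `validation_report`.
#' @export
run_validation <- function(model, data, grouping = NULL, baseline = NULL,
                           timepoints = c(2, 5), horizon = NULL, n_boot = 0,
                           seed = 1L, ties = "efron", time = "time",
                           event = "event") {
  stopifnot(inherits(model, "published_model"))
  if (!is.null(grouping) && !inherits(grouping, "risk_grouping"))
    stop_config("grouping must be a risk_grouping")
  if (!is.null(baseline) && !inherits(baseline, c("fp2_fit",
                                                  "baseline_lookup")))
    stop_config("baseline must be an fp2_fit or baseline_lookup")
  horizon <- horizon %||% model$max_followup
  if (!is.null(horizon)) data <- truncate_followup(data, horizon, time, event)
  level <- if (!is.null(baseline)) "L3" else if (!is.null(grouping)) "L2"
           else "L1"

  data$pi <- compute_pi(model, data)
  mm <- model_matrix_published(model, data)
  mm_names <- paste0(".term", seq_len(ncol(mm)))
  data[mm_names] <- as.data.frame(mm)

  sections <- list()
  sections$method1 <- calibration_slope(data, time = time, event = event,
                                        ties = ties)
  sections$method2 <- list(
    misspecification = misspecification_test(data, mm_names, time = time,
                                             event = event, ties = ties),
    ph = ph_check(data, time = time, event = event, ties = ties))
  sections$method3 <- discrimination_report(data[[time]], data[[event]],
                                            data$pi)
  if (level %in% c("L2", "L3")) {
    data$group <- assign_groups(data$pi, grouping)
    sections$method4 <- lapply(split(data, data$group), function(g)
      kaplan_meier(g[[time]], g[[event]]))
    sections$method5 <- logrank_test(data[[time]], data[[event]], data$group)
    sections$method6 <- group_hazard_ratios(data[[time]], data[[event]],
                                            data$group, ties = ties)
  }
  band <- NULL
  if (level == "L3") {
    sections$method7 <- list(
      table = observed_vs_predicted(data, baseline, timepoints = timepoints,
                                    time = time, event = event),
      baseline_comparison = compare_baselines(data[[time]], data[[event]],
                                              data$pi, baseline, band = band))
    if (n_boot > 0) {
      band <- bootstrap_band(data[[time]], data[[event]], data$pi,
                             n_boot = n_boot, seed = seed)
      sections$method7$baseline_comparison$band <- band
    }
  }
  structure(list(
    level = level, sections = sections,
    pi_summary = c(mean = mean(data$pi), sd = stats::sd(data$pi)),
    group_shares = if (!is.null(grouping)) group_shares(data$group),
    options = list(timepoints = timepoints, horizon = horizon,
                   n_boot = n_boot, seed = as.integer(seed), ties = ties,
                   percentile_definition = "type-7 linear interpolation",
                   boundary_convention = "left-closed; ties go to the higher-risk group",
                   interpolation = "linear on the log cumulative-hazard scale"),
    provenance = list(package_version =
                        as.character(utils::packageVersion("coxval")),
                      n_subjects = nrow(data),
                      n_events = sum(data[[event]])),
    data = data),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("External validation report (information level ", x$level, ")\n",
      sep = "")
  cat(sprintf("%d subjects, %d events; PI mean (SD) = %.2f (%.2f)\n",
              x$provenance$n_subjects, x$provenance$n_events,
              x$pi_summary[["mean"]], x$pi_summary[["sd"]]))
  cat(sprintf("options: ties = %s, seed = %d%s\n", x$options$ties,
              x$options$seed,
              if (!is.null(x$options$horizon))
                sprintf(", follow-up truncated at %g", x$options$horizon)
              else ""))
  cat(sprintf("conventions: percentiles by %s; group boundaries %s\n",
              x$options$percentile_definition,
              x$options$boundary_convention))
  cat("\n-- Method 1: regression on the PI (L1) --\n")
  print(x$sections$method1)
  cat("\n-- Method 2: misspecification / fit (L1) --\n")
  print(x$sections$method2$misspecification)
  print(x$sections$method2$ph)
  cat("\n-- Method 3: discrimination (L1) --\n")
  print(x$sections$method3)
  if (!is.null(x$sections$method4)) {
    cat("\n-- Method 4: Kaplan-Meier curves by risk group (L2) --\n")
    print(x$group_shares, row.names = FALSE)
    for (g in names(x$sections$method4)) {
      cat(g, ": ", sep = "")
      print(x$sections$method4[[g]])
    }
    cat("\n-- Method 5: logrank test between risk groups (L2, deprecated) --\n")
    print(x$sections$method5)
    cat("\n-- Method 6: hazard ratios across risk groups (L2) --\n")
    print(x$sections$method6)
  }
  if (!is.null(x$sections$method7)) {
    cat("\n-- Method 7: calibration against the baseline (L3) --\n")
    print(x$sections$method7$table)
    print(x$sections$method7$baseline_comparison)
  }
  invisible(x)
}

#' Write a validation report as plain text
#'
#' @param report a `validation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  writeLines(utils::capture.output(print(report)), path)
  invisible(path)
}

# ---- standard figures ----

#' Histogram of the prognostic index with risk-group cutpoints
#'
#' @param pi prognostic-index values.
#' @param grouping optional [risk_grouping()]; cutpoints drawn as vertical
#'   lines.
#' @param ... passed to [graphics::hist()].
#' @export
plot_pi_histogram <- function(pi, grouping = NULL, ...) {
  graphics::hist(pi, xlab = "prognostic index",
                 main = "Distribution of the prognostic index", ...)
  if (!is.null(grouping)) graphics::abline(v = grouping$cutpoints, lty = 2)
  invisible(NULL)
}

#' Kaplan-Meier curves by risk group
#'
#' @param time,event,group subject-level data.
#' @param col colours, one per group.
#' @param ... passed to the step-curve plot method.
#' @export
plot_group_km <- function(time, event, group, col = NULL, ...) {
  g <- factor(group)
  col <- col %||% seq_len(nlevels(g))
  first <- TRUE
  for (k in seq_len(nlevels(g))) {
    sel <- g == levels(g)[k]
    km <- kaplan_meier(time[sel], event[sel])
    plot(km, add = !first, conf = FALSE, col = col[k],
         xlim = c(0, max(time)), ...)
    first <- FALSE
  }
  graphics::legend("bottomleft", legend = levels(g), col = col, lwd = 1,
                   bty = "n")
  invisible(NULL)
}

#' Observed versus predicted survival curves by risk group
#'
#' Overlays the observed Kaplan-Meier curve (jagged) and the model-predicted
#' mean survival curve (smooth) for each risk group.
#'
#' @param data data frame with time, event, pi and group columns.
#' @param baseline an `fp2_fit` or [baseline_lookup()].
#' @param pi,group,time,event column names.
#' @export
plot_observed_vs_predicted <- function(data, baseline, pi = "pi",
                                       group = "group", time = "time",
                                       event = "event") {
  pred <- group_mean_curves(data, baseline, pi = pi, group = group,
                            time = time)
  g <- factor(data[[group]])
  cols <- seq_len(nlevels(g))
  first <- TRUE
  for (k in seq_len(nlevels(g))) {
    sel <- g == levels(g)[k]
    km <- kaplan_meier(data[[time]][sel], data[[event]][sel])
    plot(km, add = !first, conf = FALSE, col = cols[k],
         xlim = c(0, max(data[[time]])))
    first <- FALSE
    pc <- pred[[levels(g)[k]]]
    if (!is.null(pc))
      graphics::lines(pc$times, pc$values, col = cols[k], lwd = 2)
  }
  graphics::legend("bottomleft", legend = levels(g), col = cols, lwd = 2,
                   bty = "n")
  invisible(NULL)
}

#' Empirical distribution of the PI by risk group
#'
#' @param pi prognostic-index values.
#' @param group risk-group labels.
#' @param ... passed to [plot()].
#' @export
plot_pi_ecdf <- function(pi, group, ...) {
  g <- factor(group)
  plot(stats::ecdf(pi), main = "PI distribution by risk group",
       xlab = "prognostic index", ...)
  for (k in seq_len(nlevels(g)))
    graphics::lines(stats::ecdf(pi[g == levels(g)[k]]), col = k + 1)
  graphics::legend("bottomright", legend = c("all", levels(g)),
                   col = seq_len(nlevels(g) + 1), lwd = 1, bty = "n")
  invisible(NULL)
}
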