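#' Risk-group cutpoints on the prognostic index
#'
#' Forms cutpoints at fixed empirical centiles of the prognostic index,
#' following Cox's minimal-information-loss grouping of a continuous variable.
#' For four groups the centiles are the 16th, 50th and 84th (on a standard
#' Normal scale these sit at the mean and roughly one SD either side). For
#' 2, 3 and 5 groups the default centile sets are the Normal-scale optima
#' rounded to whole centiles; an explicit `centiles` vector overrides them.
#'
#' Centiles are computed by linear interpolation of the empirical distribution
#' (the type-7 quantile definition).
#'
#' @param pi numeric vector of prognostic-index values (normally from the
#'   derivation dataset, so the same absolute cutpoints transfer to any
#'   validation dataset).
#' @param n_groups number of risk groups (2 to 5 with the default tables).
#' @param centiles optional explicit centiles in (0, 100), length
#'   `n_groups - 1`.
#' @param labels optional group labels, lowest to highest risk.
#' @return an object of class `risk_grouping` with elements `cutpoints`,
#'   `labels`, `centiles` and `source`.
#' @examples
#' g <- cox_cutpoints(rnorm(500), n_groups = 4)
#' g
#' @export
cox_cutpoints <- function(pi, n_groups = 4, centiles = NULL, labels = NULL) {
  default_centiles <- list(`2` = 50, `3` = c(27, 73), `4` = c(16, 50, 84),
                           `5` = c(11, 35, 65, 89))
  if (is.null(centiles)) {
    key <- as.character(n_groups)
    if (!key %in% names(default_centiles))
      stop_config("no default centile table for %d groups; supply 'centiles'",
                  n_groups)
    centiles <- default_centiles[[key]]
  }
  if (length(centiles) != n_groups - 1L || any(centiles <= 0 | centiles >= 100))
    stop_config("need %d centiles strictly inside (0, 100)", n_groups - 1L)
  pi <- pi[is.finite(pi)]
  if (length(unique(pi)) <= n_groups)
    stop_data("prognostic index is too degenerate to form %d groups", n_groups)
  cut <- unname(stats::quantile(pi, probs = sort(centiles) / 100, type = 7))
  if (any(diff(cut) <= 0))
    stop_data("requested centiles give non-increasing cutpoints")
  if (is.null(labels)) {
    labels <- if (n_groups == 4) {
      c("Good", "Fairly good", "Fairly poor", "Poor")
    } else paste("Group", seq_len(n_groups))
  }
  if (length(labels) != n_groups)
    stop_config("need %d labels", n_groups)
  structure(list(cutpoints = cut, labels = labels, centiles = sort(centiles),
                 source = "derivation centiles"),
            class = "risk_grouping")
}

#' Construct a risk grouping from explicit cutpoints
#'
#' For models published with fixed PI cutpoints rather than centiles.
#'
#' @param cutpoints strictly increasing PI values.
#' @param labels optional group labels (one more than cutpoints).
#' @return a `risk_grouping` object.
#' @export
risk_grouping <- function(cutpoints, labels = NULL) {
  if (length(cutpoints) < 1L || any(!is.finite(cutpoints)) ||
      any(diff(cutpoints) <= 0))
    stop_config("cutpoints must be finite and strictly increasing")
  k <- length(cutpoints) + 1L
  if (is.null(labels)) labels <- paste("Group", seq_len(k))
  if (length(labels) != k) stop_config("need %d labels", k)
  structure(list(cutpoints = cutpoints, labels = labels, centiles = NULL,
                 source = "user-supplied"),
            class = "risk_grouping")
}

#' @export
print.risk_grouping <- function(x, ...) {
  cat("Risk grouping (", length(x$labels), " groups, ", x$source, ")\n",
      sep = "")
  cat("cutpoints:", paste(format(x$cutpoints, digits = 4), collapse = ", "),
      "\n")
  cat("labels:", paste(x$labels, collapse = " < "), "\n")
  invisible(x)
}

#' Assign subjects to risk groups
#'
#' Labels each subject by the interval its prognostic index falls in.
#' Intervals are closed on the left and open on the right, with the lowest
#' interval unbounded below: a PI exactly on a cutpoint goes to the
#' higher-risk group.
#'
#' @param pi numeric vector of prognostic-index values.
#' @param grouping a `risk_grouping`.
#' @return ordered factor of group labels (lowest to highest risk).
#' @export
assign_groups <- function(pi, grouping) {
  stopifnot(inherits(grouping, "risk_grouping"))
  if (is.null(pi)) stop_config("prognostic index must be computed first")
  if (any(!is.finite(pi))) stop_data("prognostic index contains non-finite values")
  idx <- findInterval(pi, grouping$cutpoints, left.open = FALSE) + 1L
  factor(grouping$labels[idx], levels = grouping$labels, ordered = TRUE)
}

#' Tabulate risk-group sizes and shares
#'
#' @param group factor returned by [assign_groups()].
#' @return data frame with counts and percentage shares per group.
#' @export
group_shares <- function(group) {
  tab <- table(group)
  data.frame(group = names(tab), n = as.integer(tab),
             share = 100 * as.integer(tab) / sum(tab))
}
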