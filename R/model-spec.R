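#' Define one term of a published Cox model
#'
#' A term pairs a covariate transformation with its published log hazard-ratio
#' coefficient. The transformation vocabulary (identity, power, power-times-log,
#' indicator) is sufficient to encode fractional-polynomial (FP1/FP2) model
#' terms and dummy variables; spline or other basis terms can be supplied as
#' precomputed columns and declared `identity`.
#'
#' The raw covariate value is first divided by `scale` (some published models
#' rescale continuous covariates before transformation, and the coefficients
#' are only reproducible if the same scaling is applied), then transformed:
#' \describe{
#'   \item{identity}{\eqn{x/s}}
#'   \item{power}{\eqn{(x/s)^p}, with the fractional-polynomial convention
#'     that power 0 means \eqn{\ln(x/s)}}
#'   \item{power_log}{\eqn{(x/s)^p \ln(x/s)}}
#'   \item{indicator}{1 when the covariate equals `level`, else 0}
#' }
#'
#' @param name covariate column name in the data.
#' @param coefficient published log hazard-ratio coefficient.
#' @param kind transformation kind; one of `"identity"`, `"power"`,
#'   `"power_log"`, `"indicator"`.
#' @param power real exponent, used by the power kinds.
#' @param scale positive divisor applied to the raw value before
#'   transformation.
#' @param level category value mapped to 1 for `kind = "indicator"`.
#' @param se optional published standard error of the coefficient.
#' @return an object of class `cov_term`.
#' @examples
#' cov_term("nodes", -1.74, kind = "power", power = -0.5)
#' @export
cov_term <- function(name, coefficient,
                     kind = c("identity", "power", "power_log", "indicator"),
                     power = 1, scale = 1, level = NULL, se = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_config("term needs a single non-empty covariate name")
  if (!is.finite(coefficient))
    stop_config("coefficient for '%s' must be finite", name)
  if (!is.finite(scale) || scale <= 0)
    stop_config("scale for '%s' must be a positive number", name)
  if (kind %in% c("power", "power_log") && !is.finite(power))
    stop_config("power for '%s' must be finite", name)
  if (kind == "indicator" && is.null(level))
    stop_config("indicator term '%s' needs a 'level'", name)
  structure(list(name = name, kind = kind, power = power, scale = scale,
                 level = level, coefficient = coefficient, se = se),
            class = "cov_term")
}

#' Represent a published Cox model
#'
#' Bundles the "level 1" information a publication carries about a Cox model:
#' the covariate transformations, their coefficients, and the centering
#' constant (the mean of the linear predictor in the derivation data) that is
#' subtracted so that the prognostic index is zero at average risk.
#'
#' @param terms list of [cov_term()] objects.
#' @param centering real; mean prognostic index in the derivation data,
#'   subtracted before use. 0 when the model was reported uncentered.
#' @param time_unit label for the time scale, e.g. `"years"`.
#' @param max_followup optional maximum follow-up time in the derivation
#'   dataset (same unit); used to guard against extrapolation.
#' @return an object of class `published_model`.
#' @examples
#' m <- published_model(
#'   list(cov_term("nodes", -1.74, kind = "power", power = -0.5),
#'        cov_term("hormon", -0.35)),
#'   centering = -1.32, time_unit = "years", max_followup = 7)
#' m
#' @export
published_model <- function(terms, centering = 0, time_unit = "years",
                            max_followup = NULL) {
  if (inherits(terms, "cov_term")) terms <- list(terms)
  if (!length(terms)) stop_config("a published model needs at least one term")
  ok <- vapply(terms, inherits, logical(1), what = "cov_term")
  if (!all(ok)) stop_config("all terms must be built with cov_term()")
  if (!is.finite(centering))
    stop_config("centering constant must be finite (use 0 if uncentered)")
  if (!is.null(max_followup) && (!is.finite(max_followup) || max_followup <= 0))
    stop_config("max_followup must be a positive time")
  structure(list(terms = terms, centering = centering, time_unit = time_unit,
                 max_followup = max_followup),
            class = "published_model")
}

#' @export
print.published_model <- function(x, ...) {
  cat("Published Cox model (", length(x$terms), " terms)\n", sep = "")
  tab <- data.frame(
    term = vapply(x$terms, term_label, character(1)),
    coefficient = vapply(x$terms, function(t) t$coefficient, numeric(1)),
    se = vapply(x$terms, function(t) t$se %||% NA_real_, numeric(1)))
  print(tab, row.names = FALSE)
  cat("centering constant:", format(x$centering),
      "  time unit:", x$time_unit, "\n")
  if (!is.null(x$max_followup))
    cat("derivation max follow-up:", format(x$max_followup), x$time_unit, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

term_label <- function(t) {
  base <- if (t$scale != 1) sprintf("(%s/%g)", t$name, t$scale) else t$name
  switch(t$kind,
         identity = base,
         power = if (t$power == 0) sprintf("ln(%s)", base)
                 else sprintf("%s^%g", base, t$power),
         power_log = if (t$power == 0) sprintf("ln(%s)^2", base)
                     else sprintf("%s^%g*ln(%s)", base, t$power, base),
         indicator = sprintf("I(%s == %s)", t$name, format(t$level)))
}

# Evaluate one transformed covariate column; data errors name the offending
# subject rows because silent NA propagation would corrupt the PI.
eval_term <- function(t, data) {
  if (!t$name %in% names(data))
    stop_config("covariate '%s' not found in the data", t$name)
  x <- data[[t$name]]
  if (t$kind == "indicator") {
    miss <- which(is.na(x))
    if (length(miss))
      stop_data("missing value for covariate '%s' (subject %s)",
                t$name, paste(utils::head(miss, 5L), collapse = ", "))
    return(as.numeric(x == t$level))
  }
  x <- as.numeric(x)
  miss <- which(is.na(x))
  if (length(miss))
    stop_data("missing value for covariate '%s' (subject %s)",
              t$name, paste(utils::head(miss, 5L), collapse = ", "))
  z <- x / t$scale
  if (t$kind == "identity") return(z)
  bad <- which(z <= 0)
  if (length(bad))
    stop_data("covariate '%s' must be strictly positive after scaling for a power/log transform (subject %s)",
              t$name, paste(utils::head(bad, 5L), collapse = ", "))
  if (t$kind == "power") {
    if (t$power == 0) log(z) else z^t$power
  } else {                                   # power_log
    if (t$power == 0) log(z)^2 else z^t$power * log(z)
  }
}

#' Transformed design columns of a published model
#'
#' Evaluates each term's covariate transformation (without multiplying by the
#' coefficient), returning the matrix of model columns. Useful for the
#' misspecification test, which refits these columns with the prognostic index
#' as an offset.
#'
#' @param model a [published_model()].
#' @param data data frame holding the raw covariates.
#' @return numeric matrix, one column per term.
#' @export
model_matrix_published <- function(model, data) {
  stopifnot(inherits(model, "published_model"))
  cols <- lapply(model$terms, eval_term, data = data)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(model$terms, term_label, character(1))
  m
}

#' Compute the prognostic index of a published model
#'
#' The prognostic index (PI) is the linear predictor of the published Cox
#' model: the coefficient-weighted sum of the transformed covariates, minus
#' the centering constant. No coefficient is re-estimated; the model is
#' applied exactly as published.
#'
#' @inheritParams model_matrix_published
#' @return numeric vector of centered PI values, one per row of `data`.
#' @examples
#' m <- published_model(list(cov_term("x1", 1), cov_term("x2", 2)))
#' compute_pi(m, data.frame(x1 = 3, x2 = 4))  # 11
#' @export
compute_pi <- function(model, data) {
  m <- model_matrix_published(model, data)
  beta <- vapply(model$terms, function(t) t$coefficient, numeric(1))
  pi <- drop(m %*% beta) - model$centering
  if (any(!is.finite(pi)))
    stop_data("non-finite prognostic index for subject %s",
              paste(utils::head(which(!is.finite(pi)), 5L), collapse = ", "))
  pi
}

#' Truncate follow-up at a horizon
#'
#' Administratively censors the dataset at `horizon`: any subject followed
#' beyond it has the time set to `horizon` and the event indicator to 0.
#' Used to keep the validation follow-up within the range over which the
#' derivation baseline survival function is defined, so that no extrapolation
#' is needed.
#'
#' @param data data frame with follow-up time and event columns.
#' @param horizon positive time (same unit as the data).
#' @param time,event names of the time and event columns.
#' @return `data` with times capped and late events censored.
#' @export
truncate_followup <- function(data, horizon, time = "time", event = "event") {
  if (!is.finite(horizon) || horizon <= 0)
    stop_config("truncation horizon must be a positive time")
  check_surv_cols(data, time, event)
  late <- data[[time]] > horizon
  data[[event]][late] <- 0
  data[[time]][late] <- horizon
  data
}

check_surv_cols <- function(data, time, event) {
  for (nm in c(time, event))
    if (!nm %in% names(data)) stop_config("column '%s' not found", nm)
  t <- data[[time]]; e <- data[[event]]
  if (any(!is.finite(t)) || any(t < 0))
    stop_data("follow-up times must be finite and non-negative")
  if (!all(e %in% c(0, 1)))
    stop_data("event indicator must be coded 0/1")
  invisible(TRUE)
}

# ---- model spec serialization (YAML, round-trips losslessly) ----

#' Read or write a published-model specification
#'
#' The specification is a human-writable YAML document listing the model terms
#' (name, kind, power, scale, level, coefficient, se), the centering constant,
#' the time unit and the maximum derivation follow-up. `write_model_spec()`
#' followed by `read_model_spec()` reproduces the model exactly.
#'
#' @param path file path.
#' @param model a [published_model()].
#' @return `read_model_spec()` returns a [published_model()];
#'   `write_model_spec()` returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$terms)) stop_config("model spec '%s' has no terms", path)
  terms <- lapply(spec$terms, function(s) {
    cov_term(name = s$name, coefficient = s$coefficient,
             kind = s$kind %||% "identity", power = s$power %||% 1,
             scale = s$scale %||% 1, level = s$level, se = s$se)
  })
  published_model(terms, centering = spec$centering %||% 0,
                  time_unit = spec$time_unit %||% "years",
                  max_followup = spec$max_followup)
}

#' @rdname read_model_spec
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "published_model"))
  spec <- list(
    terms = lapply(model$terms, function(t)
      Filter(Negate(is.null),
             list(name = t$name, kind = t$kind, power = t$power,
                  scale = t$scale, level = t$level,
                  coefficient = t$coefficient, se = t$se))),
    centering = model$centering, time_unit = model$time_unit,
    max_followup = model$max_followup)
  yaml::write_yaml(Filter(Negate(is.null), spec), path, precision = 15L)
  invisible(path)
}

#' Read a patient-level survival dataset
#'
#' Reads delimited text (CSV/TSV) or, when the `foreign` package is available,
#' a Stata `.dta` file. The event column must end up coded 1 = event observed,
#' 0 = censored; `event_codes` remaps other codings explicitly (no silent
#' recoding is attempted).
#'
#' @param path file path; format chosen by extension (`.csv`, `.tsv`, `.dta`).
#' @param event name of the event column, or `NULL` to skip checking.
#' @param event_codes optional named vector mapping raw values to 0/1, e.g.
#'   `c("death" = 1, "alive" = 0)`.
#' @return data frame.
#' @export
read_survival_data <- function(path, event = NULL, event_codes = NULL) {
  ext <- tolower(tools::file_ext(path))
  data <- switch(ext,
    csv = utils::read.csv(path),
    tsv = utils::read.delim(path),
    dta = {
      if (!requireNamespace("foreign", quietly = TRUE))
        stop_config("reading .dta files requires the 'foreign' package")
      foreign::read.dta(path)
    },
    stop_config("unsupported data format '.%s'", ext))
  if (!is.null(event)) {
    if (!event %in% names(data)) stop_config("column '%s' not found", event)
    if (!is.null(event_codes)) {
      raw <- as.character(data[[event]])
      unknown <- setdiff(unique(raw), names(event_codes))
      if (length(unknown))
        stop_data("event values not covered by event_codes: %s",
                  paste(unknown, collapse = ", "))
      data[[event]] <- as.numeric(event_codes[raw])
    }
    if (!all(data[[event]] %in% c(0, 1)))
      stop_data("event column '%s' is not coded 0/1; supply event_codes", event)
  }
  data
}
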