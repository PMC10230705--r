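#' Health-state transitions modelled by the cohort engine
#'
#' The five disease-activity transitions estimated from event histories:
#' high to moderate/low (`H2M`), high to remission (`H2R`), moderate/low to
#' high (`M2H`), moderate/low to remission (`M2R`) and remission to
#' moderate/low (`R2M`). Death is handled separately through the life table.
#'
#' @return Character vector of the five transition labels.
#' @export
transition_labels <- function() c("H2M", "H2R", "M2H", "M2R", "R2M")

#' Construct a Weibull transition specification
#'
#' A transition specification carries the proportional-hazards Weibull
#' parameters on the 6-month time axis: cumulative hazard `H(t) = lam * t^shape`,
#' so the per-cycle transition probability over `(t-u, t]` is
#' `1 - exp(lam * ((t-u)^shape - t^shape))`.
#'
#' @param transition_label One of [transition_labels()].
#' @param lam Positive Weibull scale parameter (lambda).
#' @param shape Positive Weibull shape parameter (gamma).
#' @return A `transition_spec` object.
#' @export
transition_spec <- function(transition_label, lam, shape) {
  stopifnot(is.character(transition_label), length(transition_label) == 1L)
  if (!transition_label %in% transition_labels()) {
    stop("unknown transition label: ", transition_label, call. = FALSE)
  }
  if (!is.finite(lam) || lam <= 0) stop("lam must be a positive real", call. = FALSE)
  if (!is.finite(shape) || shape <= 0) stop("shape must be a positive real", call. = FALSE)
  structure(list(transition_label = transition_label, lam = lam, shape = shape),
            class = "transition_spec")
}

#' Validate a table of event histories
#'
#' Event histories are the unit of input to [fit_weibull_ph()]: one row per
#' patient-transition interval with the time at risk (in 6-month units), an
#' event indicator (1 = transition observed, 0 = right-censored) and any
#' covariates (base case: `disease_duration` in years).
#'
#' @param histories Data frame with columns `patient_id`, `transition_label`,
#'   `time_at_risk`, `event`, plus covariate columns.
#' @return The validated data frame, invisibly coerced (event to integer).
#' @export
validate_event_histories <- function(histories) {
  req <- c("patient_id", "transition_label", "time_at_risk", "event")
  missing <- setdiff(req, names(histories))
  if (length(missing)) {
    stop("event histories lack required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(histories$transition_label %in% transition_labels())) {
    bad <- setdiff(unique(histories$transition_label), transition_labels())
    stop("unknown transition label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(histories$time_at_risk)) || any(histories$time_at_risk < 0)) {
    stop("time_at_risk must be finite and non-negative", call. = FALSE)
  }
  if (!all(histories$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (observed)", call. = FALSE)
  }
  if (any(histories$time_at_risk == 0 & histories$event == 1)) {
    stop("records with zero time_at_risk and an observed event are invalid",
         call. = FALSE)
  }
  cov_cols <- setdiff(names(histories), req)
  for (cc in cov_cols) {
    if (is.numeric(histories[[cc]]) && any(!is.finite(histories[[cc]]))) {
      stop("covariate '", cc, "' contains non-finite values", call. = FALSE)
    }
  }
  histories$event <- as.integer(histories$event)
  histories
}

#' Fit a Weibull proportional-hazards model to one transition
#'
#' Maximum-likelihood estimation under right censoring of the model
#' `H(t | x) = exp(constant + sum(coef * x)) * t^shape`. Fitting is delegated
#' to [flexsurv::flexsurvreg()] with `dist = "weibullPH"`, whose scale
#' parameter is exactly `exp(linear predictor)`; standard errors come from the
#' observed information. When `shape_fixed = 1` the exponential special case
#' is fitted instead (constant hazard), for which the intercept-only MLE has
#' the closed form `events / exposure`.
#'
#' @param histories Event-history data frame (see
#'   [validate_event_histories()]); all rows must share one transition label.
#' @param covariates Character vector of covariate column names entering the
#'   linear predictor for the log scale (default none).
#' @param shape_fixed If `1`, fix the shape at 1 (exponential); otherwise the
#'   shape is estimated.
#' @return A `weibull_fit` object: `transition_label`, `constant`,
#'   `coefficients`, `shape`, `standard_errors` (named: `constant`, `shape`,
#'   and one per coefficient), `log_likelihood`, `n`, `n_events`.
#' @export
fit_weibull_ph <- function(histories, covariates = character(), shape_fixed = NULL) {
  histories <- validate_event_histories(histories)
  labs <- unique(histories$transition_label)
  if (length(labs) != 1L) {
    stop("all records must share one transition_label; found: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  n_events <- sum(histories$event)
  if (n_events == 0L) {
    stop("estimation impossible: no events observed for ", labs, call. = FALSE)
  }
  if (n_events < 2L) {
    stop("estimation requires at least 2 observed events (got ", n_events, ")",
         call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(histories))
  if (length(missing_cov)) {
    stop("covariate column(s) absent from histories: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }

  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("survival::Surv(time_at_risk, event) ~", rhs))
  dist <- if (!is.null(shape_fixed) && shape_fixed == 1) "exp" else "weibullPH"
  fit <- tryCatch(
    flexsurv::flexsurvreg(fml, data = histories, dist = dist),
    error = function(e) {
      stop("Weibull fit did not converge for ", labs, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.finite(fit$loglik)) {
    stop("Weibull fit returned a non-finite likelihood for ", labs,
         " (n = ", nrow(histories), ", events = ", n_events, ")", call. = FALSE)
  }

  res <- fit$res.t  # log-scale estimates and SEs
  if (dist == "exp") {
    constant <- unname(res["rate", "est"])
    const_se <- unname(res["rate", "se"])
    shape <- 1
    shape_se <- 0
  } else {
    constant <- unname(res["scale", "est"])
    const_se <- unname(res["scale", "se"])
    shape <- unname(fit$res["shape", "est"])
    shape_se <- unname(fit$res["shape", "se"])
  }
  coefs <- if (length(covariates)) {
    stats::setNames(res[covariates, "est"], covariates)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  coef_se <- if (length(covariates)) {
    stats::setNames(res[covariates, "se"], covariates)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(
    transition_label = labs,
    constant = constant,
    coefficients = coefs,
    shape = shape,
    standard_errors = c(constant = const_se, shape = shape_se, coef_se),
    log_likelihood = fit$loglik,
    n = nrow(histories),
    n_events = n_events
  ), class = "weibull_fit")
}

#' Evaluate the Weibull scale parameter at given covariate values
#'
#' Returns `lambda = exp(constant + sum(coefficient * value))`, the
#' proportional-hazards scale parameter entering `H(t) = lambda * t^shape`.
#'
#' @param fit A `weibull_fit` (or any list with `constant` and `coefficients`).
#' @param covariate_values Named list/vector supplying a value for every
#'   coefficient in the fit.
#' @return Positive scalar lambda.
#' @export
lambda_from_linear_predictor <- function(fit, covariate_values = NULL) {
  lp <- fit$constant
  if (length(fit$coefficients)) {
    for (nm in names(fit$coefficients)) {
      if (is.null(covariate_values) || !nm %in% names(covariate_values)) {
        stop("no value supplied for covariate '", nm, "'", call. = FALSE)
      }
      lp <- lp + fit$coefficients[[nm]] * covariate_values[[nm]]
    }
  }
  exp(lp)
}

#' Convert a fit to a transition specification
#'
#' @param fit A `weibull_fit`.
#' @param covariate_values Covariate values at which to evaluate the scale
#'   (e.g. mean disease duration).
#' @return A [transition_spec()].
#' @export
as_transition_spec <- function(fit, covariate_values = NULL) {
  transition_spec(fit$transition_label,
                  lam = lambda_from_linear_predictor(fit, covariate_values),
                  shape = fit$shape)
}

#' Per-cycle transition probability from a Weibull specification
#'
#' The probability that the event occurs during the cycle ending at time `t`
#' (in 6-month units), i.e. `1 - S(t)/S(t-u)` with `S(t) = exp(-lam * t^shape)`:
#' `tp(u) = 1 - exp(lam * (t-u)^shape - lam * t^shape)`. For `shape = 1` this
#' reduces to `1 - exp(-lam * u)`, independent of `t`.
#'
#' @param spec A [transition_spec()].
#' @param t Time at the end of the cycle, in 6-month units (vectorised).
#' @param u Cycle length in the same units (scalar, default 1).
#' @return Probability in `[0, 1]`, same length as `t`.
#' @export
transition_probability <- function(spec, t, u = 1) {
  stopifnot(inherits(spec, "transition_spec") || (is.list(spec) &&
            all(c("lam", "shape") %in% names(spec))))
  if (!is.numeric(u) || length(u) != 1L || u < 0) {
    stop("u must be a non-negative scalar", call. = FALSE)
  }
  if (any(t < u)) stop("t must be at least u (cycle cannot predate time 0)", call. = FALSE)
  p <- 1 - exp(spec$lam * ((t - u)^spec$shape - t^spec$shape))
  pmin(pmax(p, 0), 1)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull PH fit:", x$transition_label, "\n")
  cat(sprintf("  constant (log lambda): %.4f (SE %.4f)\n",
              x$constant, x$standard_errors[["constant"]]))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  coefficient %s: %.4f (SE %.4f)\n", nm,
                x$coefficients[[nm]], x$standard_errors[[nm]]))
  }
  cat(sprintf("  shape (gamma): %.4f (SE %.4f)\n", x$shape,
              x$standard_errors[["shape"]]))
  cat(sprintf("  log-likelihood %.3f on %d records (%d events)\n",
              x$log_likelihood, x$n, x$n_events))
  invisible(x)
}

#' Serialize fitted transition parameters to a text block
#'
#' Writes one block per fit mirroring the model-input field names
#' (constant for the baseline hazard, covariate coefficients, lambda at the
#' reference covariates, ancillary shape parameter).
#'
#' @param fits List of `weibull_fit` objects.
#' @param path File path to write to.
#' @param covariate_values Reference covariate values used to report lambda.
#' @return `path`, invisibly.
#' @export
write_weibull_fits <- function(fits, path, covariate_values = NULL) {
  lines <- character(0)
  for (f in fits) {
    lines <- c(lines,
      sprintf("transition: %s", f$transition_label),
      sprintf("  constant_baseline_hazard: %.6f", f$constant),
      vapply(names(f$coefficients), function(nm)
        sprintf("  coefficient_%s: %.6f", nm, f$coefficients[[nm]]),
        character(1)),
      sprintf("  lambda: %.6f", lambda_from_linear_predictor(f, covariate_values)),
      sprintf("  ancillary_shape: %.6f", f$shape),
      sprintf("  log_likelihood: %.6f", f$log_likelihood),
      sprintf("  n_events: %d", f$n_events),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write event-history tables
#'
#' Tab-delimited, UTF-8, with header columns `patient_id`,
#' `transition_label`, `time_at_risk`, `event`, `disease_duration`.
#'
#' @param path File path.
#' @return `read_event_histories()` returns the validated data frame.
#' @export
read_event_histories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_event_histories(df)
}

#' @rdname read_event_histories
#' @param histories Event-history data frame.
#' @export
write_event_histories <- function(histories, path) {
  validate_event_histories(histories)
  utils::write.table(histories, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
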