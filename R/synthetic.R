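#' Configuration for the synthetic-data generators
#'
#' The generators stand in for the study's unavailable raw inputs: the
#' 84-patient medical-record review behind the survival fits, the national
#' life table, and the network-meta-analysis efficacy table. Defaults follow
#' the study conditions where stated (84 patients, mean disease duration 14
#' years, 5-year observation window, i.e. 10 six-month cycles).
#'
#' @param n_patients Number of patients (default 84).
#' @param transitions Named list (per transition label) of lists with
#'   `constant`, `coefficients` (named numeric, may be empty) and `shape` —
#'   the generating Weibull PH parameters.
#' @param censoring Target fraction of records randomly censored before the
#'   administrative window closes, in `[0, 1)`.
#' @param max_follow Administrative follow-up in 6-month cycles (default 10,
#'   a 5-year window).
#' @param duration_mean,duration_sd Gamma-distributed disease duration
#'   (years) at baseline; only the high-to-moderate/low transition uses it.
#' @param life_table_params Gompertz-Makeham parameters for the synthetic
#'   life table: `background` (Makeham constant hazard), `rate` (baseline
#'   Gompertz level), `slope` (log-hazard increase per year), `male_factor`
#'   (hazard multiplier for men), `female_weight` (cohort share of women,
#'   0.92 as in the study cohort), `age_min`, `age_max`.
#' @param rr_ranges Uniform sampling ranges (and log-scale CI half-width
#'   range) for the synthetic efficacy table.
#' @param seed Master seed.
#' @return Configuration list.
#' @export
synthetic_config <- function(n_patients = 84,
                             transitions = default_true_transitions(),
                             censoring = 0.2,
                             max_follow = 10,
                             duration_mean = 14, duration_sd = 7,
                             life_table_params = list(
                               background = 5e-4, rate = 3e-5, slope = 0.085,
                               male_factor = 1.6, female_weight = 0.92,
                               age_min = 35, age_max = 110),
                             rr_ranges = list(
                               h2r = c(1.5, 3.0), h2m = c(1.05, 1.40),
                               sae = c(0.90, 1.80), ci_halfwidth = c(0.15, 0.35)),
                             seed = 20220101) {
  stopifnot(n_patients >= 1, censoring >= 0, censoring < 1, max_follow > 0,
            duration_mean > 0, duration_sd > 0)
  for (tr in transitions) stopifnot(tr$shape > 0)
  list(n_patients = n_patients, transitions = transitions,
       censoring = censoring, max_follow = max_follow,
       duration_mean = duration_mean, duration_sd = duration_sd,
       life_table_params = life_table_params, rr_ranges = rr_ranges,
       seed = seed)
}

#' Generating parameters mirroring the fitted survival models
#'
#' Constants and shapes as printed in the model-input table; the
#' high-to-moderate/low transition carries the disease-duration coefficient
#' (-0.08 per year).
#' @return Named list of per-transition generating parameters.
#' @export
default_true_transitions <- function() {
  list(
    H2M = list(constant = 1.55, coefficients = c(disease_duration = -0.08), shape = 1.08),
    H2R = list(constant = -2.92, coefficients = NULL, shape = 1.00),
    M2H = list(constant = -1.39, coefficients = NULL, shape = 0.50),
    M2R = list(constant = -1.86, coefficients = NULL, shape = 0.63),
    R2M = list(constant = -0.22, coefficients = NULL, shape = 0.96)
  )
}

# Internal: inverse-CDF Weibull PH event time, H(t) = lam * t^shape
rweibull_ph <- function(n, lam, shape) {
  (-log(stats::runif(n)) / lam)^(1 / shape)
}

#' Generate synthetic patient event histories
#'
#' For each patient and transition, an event time is drawn from the Weibull
#' proportional-hazards model with covariate-adjusted scale
#' `lam = exp(constant + coef * disease_duration)`. Records are right-censored
#' at the administrative follow-up window and, to reach the configured
#' censoring fraction, by an independent exponential censoring time whose rate
#' targets that fraction at the cohort-average hazard.
#'
#' @param config A [synthetic_config()].
#' @return Event-history data frame (see [validate_event_histories()]).
#' @export
gen_patient_histories <- function(config) {
  set.seed(config$seed)
  n <- config$n_patients
  g_shape <- (config$duration_mean / config$duration_sd)^2
  g_rate <- config$duration_mean / config$duration_sd^2
  duration <- stats::rgamma(n, shape = g_shape, rate = g_rate)

  out <- list()
  for (lab in names(config$transitions)) {
    tr <- config$transitions[[lab]]
    lp <- tr$constant
    if (!is.null(tr$coefficients) && length(tr$coefficients)) {
      lp <- lp + tr$coefficients[["disease_duration"]] * duration
    }
    lam <- exp(lp)
    t_event <- rweibull_ph(n, lam, tr$shape)
    # independent random censoring targeting the configured fraction at the
    # typical hazard (exact for shape = 1, approximate otherwise)
    if (config$censoring > 0) {
      lam_typ <- exp(tr$constant +
                       if (!is.null(tr$coefficients) && length(tr$coefficients))
                         tr$coefficients[["disease_duration"]] * config$duration_mean
                       else 0)
      c_rate <- lam_typ * config$censoring / (1 - config$censoring)
      t_cens <- stats::rexp(n, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    follow <- pmin(t_cens, config$max_follow)
    time <- pmin(t_event, follow)
    event <- as.integer(t_event <= follow)
    out[[lab]] <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      transition_label = lab,
      time_at_risk = time,
      event = event,
      disease_duration = duration,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[df$time_at_risk > 0, , drop = FALSE]
}

#' Generate a synthetic life table
#'
#' Gompertz-Makeham annual hazard `h(x) = background + rate * exp(slope * x)`
#' per sex (male hazard scaled by `male_factor`), converted to annual death
#' probabilities `q = 1 - exp(-h)` and mixed with the cohort's female weight.
#' The terminal row carries `q = 1`. This is a clearly synthetic stand-in for
#' a national life table; [read_life_table()] accepts a real one in the same
#' format.
#'
#' @param config A [synthetic_config()] (uses `life_table_params`).
#' @return Data frame with columns `age`, `qx`, `qx_female`, `qx_male`.
#' @export
gen_life_table <- function(config = synthetic_config()) {
  p <- config$life_table_params
  age <- seq(p$age_min, p$age_max)
  h_f <- p$background + p$rate * exp(p$slope * age)
  h_m <- h_f * p$male_factor
  q_f <- pmin(1 - exp(-h_f), 1)
  q_m <- pmin(1 - exp(-h_m), 1)
  if (any(q_f[-length(q_f)] >= 1)) {
    warning("life-table parameters reach q = 1 before the terminal age; clipped")
  }
  qx <- p$female_weight * q_f + (1 - p$female_weight) * q_m
  q_f[length(age)] <- q_m[length(age)] <- qx[length(age)] <- 1
  data.frame(age = age, qx = qx, qx_female = q_f, qx_male = q_m)
}

#' Generate a synthetic efficacy table
#'
#' One record per treatment with relative risks (vs MTX monotherapy) for
#' high-to-remission, high-to-moderate/low and serious infection, each with a
#' 95% CI bracketing the point estimate. Efficacy RRs are drawn above 1 and
#' the serious-infection RR near 1, emulating the structure of the
#' network-meta-analysis output the model consumes. The engine reuses the
#' high-to-remission RR for moderate/low-to-remission.
#'
#' @param config A [synthetic_config()] (uses `rr_ranges` and `seed`).
#' @param treatments Treatment names (default: the 11 intervention
#'   strategies).
#' @return Data frame with columns `treatment`, `rr_h2r`, `rr_h2r_lo`,
#'   `rr_h2r_hi`, `rr_h2m`, ..., `rr_sae_hi`.
#' @export
gen_efficacy_table <- function(config = synthetic_config(),
                               treatments = setdiff(ra_strategies(), "SoC")) {
  set.seed(config$seed + 1L)
  rg <- config$rr_ranges
  draw <- function(range) stats::runif(length(treatments), range[1], range[2])
  ci <- function(point) {
    hw <- stats::runif(length(treatments), rg$ci_halfwidth[1], rg$ci_halfwidth[2])
    list(lo = point * exp(-hw), hi = point * exp(hw))
  }
  h2r <- draw(rg$h2r); h2m <- draw(rg$h2m); sae <- draw(rg$sae)
  ci_h2r <- ci(h2r); ci_h2m <- ci(h2m); ci_sae <- ci(sae)
  data.frame(treatment = treatments,
             rr_h2r = h2r, rr_h2r_lo = ci_h2r$lo, rr_h2r_hi = ci_h2r$hi,
             rr_h2m = h2m, rr_h2m_lo = ci_h2m$lo, rr_h2m_hi = ci_h2m$hi,
             rr_sae = sae, rr_sae_lo = ci_sae$lo, rr_sae_hi = ci_sae$hi,
             stringsAsFactors = FALSE)
}
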