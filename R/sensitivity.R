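#' Build a parameter distribution from its mean and standard error
#'
#' Method-of-moments natural parameters for the families used in the
#' probabilistic analysis: beta for probabilities and utilities
#' (`alpha = m * (m(1-m)/v - 1)`, `beta = (1-m) * (m(1-m)/v - 1)`), gamma for
#' costs (`shape = (m/se)^2`, `scale = se^2/m`), lognormal for survival and
#' hazard-ratio parameters (moment-matched, or matched to a supplied 95% CI),
#' and a degenerate `fixed` family. Each distribution also carries the
#' low/high plausible bounds used by the one-way analysis: a supplied 95% CI
#' where available, otherwise `mean +/- 1.96 * se` truncated to the feasible
#' domain, or +/-20% of the mean for parameters with no standard error.
#'
#' @param name Parameter name (see [set_parameter()] for the naming scheme).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param mean Mean value.
#' @param se Standard error (0 for fixed parameters).
#' @param ci Optional length-2 95% interval.
#' @return A `param_dist` object.
#' @export
make_distribution <- function(name, family, mean, se, ci = NULL) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "fixed"))
  stopifnot(is.finite(mean), is.finite(se), se >= 0)
  pars <- switch(family,
    beta = {
      if (mean <= 0 || mean >= 1) stop("beta mean must be in (0,1)", call. = FALSE)
      v <- se^2
      if (v >= mean * (1 - mean)) {
        stop("infeasible moments for beta: se^2 >= mean*(1-mean) for ", name,
             call. = FALSE)
      }
      k <- mean * (1 - mean) / v - 1
      list(alpha = mean * k, beta = (1 - mean) * k)
    },
    gamma = {
      if (mean <= 0 || se <= 0) stop("gamma requires mean, se > 0", call. = FALSE)
      list(shape = (mean / se)^2, scale = se^2 / mean)
    },
    lognormal = {
      if (mean <= 0) stop("lognormal mean must be > 0", call. = FALSE)
      if (!is.null(ci)) {
        list(meanlog = (log(ci[1]) + log(ci[2])) / 2,
             sdlog = (log(ci[2]) - log(ci[1])) / (2 * stats::qnorm(0.975)))
      } else {
        if (se <= 0) stop("lognormal requires se > 0 or a CI", call. = FALSE)
        sdlog2 <- log(1 + se^2 / mean^2)
        list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
      }
    },
    fixed = list()
  )
  if (!is.null(ci)) {
    low <- ci[1]; high <- ci[2]
  } else if (se > 0) {
    low <- mean - stats::qnorm(0.975) * se
    high <- mean + stats::qnorm(0.975) * se
    if (family == "beta") { low <- max(low, 1e-9); high <- min(high, 1 - 1e-9) }
    if (family %in% c("gamma", "lognormal")) low <- max(low, 1e-12)
  } else {
    low <- 0.8 * mean; high <- 1.2 * mean
  }
  structure(list(name = name, family = family, mean = mean, se = se,
                 pars = pars, low = low, high = high),
            class = "param_dist")
}

#' Draw from a parameter distribution
#'
#' @param dist A `param_dist` from [make_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_distribution <- function(dist, n = 1) {
  switch(dist$family,
    beta = stats::rbeta(n, dist$pars$alpha, dist$pars$beta),
    gamma = stats::rgamma(n, shape = dist$pars$shape, scale = dist$pars$scale),
    lognormal = stats::rlnorm(n, dist$pars$meanlog, dist$pars$sdlog),
    fixed = rep(dist$mean, n))
}

#' Set a named parameter in a model-input bundle
#'
#' Naming scheme: `hr_high`, `sae_prob`, `sae_cost`, `utility_<STATE>`,
#' `lam_<TRANSITION>`, `shape_<TRANSITION>`, `rr_<h2r|h2m|sae>_<treatment>`
#' and `drug_cost_<strategy>`. Values outside the feasible domain
#' (probabilities and utilities beyond `[0, 1]`, non-positive scales) are
#' clipped with a warning.
#'
#' @param inputs Model inputs.
#' @param name Parameter name.
#' @param value New value.
#' @return Modified inputs.
#' @export
set_parameter <- function(inputs, name, value) {
  clip01 <- function(x, what) {
    if (x < 0 || x > 1) {
      warning(what, " clipped to [0,1]: ", format(x))
      x <- min(max(x, 0), 1)
    }
    x
  }
  clip_pos <- function(x, what) {
    if (x <= 0) {
      warning(what, " clipped to a small positive value: ", format(x))
      x <- 1e-9
    }
    x
  }
  if (name == "hr_high") {
    inputs$hr_high <- clip_pos(value, name)
  } else if (name == "sae_prob") {
    inputs$sae_prob <- clip01(value, name)
  } else if (name == "sae_cost") {
    inputs$costs$sae_cost <- clip_pos(value, name)
  } else if (grepl("^utility_", name)) {
    hs <- sub("^utility_", "", name)
    if (!hs %in% names(inputs$utilities)) stop("unknown utility state: ", hs, call. = FALSE)
    inputs$utilities[[hs]] <- clip01(value, name)
  } else if (grepl("^lam_", name)) {
    lab <- sub("^lam_", "", name)
    inputs$specs[[lab]]$lam <- clip_pos(value, name)
  } else if (grepl("^shape_", name)) {
    lab <- sub("^shape_", "", name)
    inputs$specs[[lab]]$shape <- clip_pos(value, name)
  } else if (grepl("^rr_(h2r|h2m|sae)_", name)) {
    m <- regmatches(name, regexec("^rr_(h2r|h2m|sae)_(.+)$", name))[[1]]
    col <- paste0("rr_", m[2])
    i <- which(inputs$efficacy$treatment == m[3])
    if (!length(i)) stop("unknown treatment in parameter ", name, call. = FALSE)
    inputs$efficacy[[col]][i] <- clip_pos(value, name)
  } else if (grepl("^drug_cost_", name)) {
    sg <- sub("^drug_cost_", "", name)
    if (is.null(inputs$costs$drug[[sg]])) stop("unknown strategy in ", name, call. = FALSE)
    inputs$costs$drug[[sg]] <- clip_pos(value, name)
  } else {
    stop("unknown parameter name: ", name, call. = FALSE)
  }
  inputs
}

#' Distributions for the probabilistic sensitivity analysis
#'
#' Every uncertain parameter with a published standard error or CI is
#' sampled: the mortality hazard ratio (lognormal, matched to its 95% CI),
#' the adverse-event probability (beta) and admission cost (gamma), the three
#' utilities (beta), the Weibull lambda and shape of each transition
#' (lognormal; no SE is published, so a 10% coefficient of variation is
#' assumed), and each treatment's three relative risks (lognormal, matched to
#' their CIs). Drug prices carry no standard error and are fixed. Draws are
#' independent across parameters.
#'
#' @param inputs Model inputs.
#' @param survival_cv Assumed coefficient of variation for the survival
#'   parameters (default 0.1).
#' @return Named list of `param_dist` objects.
#' @export
psa_distributions <- function(inputs, survival_cv = 0.1) {
  d <- list()
  d$hr_high <- make_distribution("hr_high", "lognormal", inputs$hr_high,
                                 se = 0.5, ci = inputs$hr_high_ci)
  d$sae_prob <- make_distribution("sae_prob", "beta", inputs$sae_prob,
                                  inputs$sae_prob_se)
  d$sae_cost <- make_distribution("sae_cost", "gamma", inputs$costs$sae_cost,
                                  inputs$costs$sae_cost_se)
  for (hs in names(inputs$utilities)) {
    nm <- paste0("utility_", hs)
    d[[nm]] <- make_distribution(nm, "beta", inputs$utilities[[hs]],
                                 inputs$utility_se[[hs]])
  }
  for (lab in transition_labels()) {
    nm <- paste0("lam_", lab)
    d[[nm]] <- make_distribution(nm, "lognormal", inputs$specs[[lab]]$lam,
                                 survival_cv * inputs$specs[[lab]]$lam)
    nm <- paste0("shape_", lab)
    d[[nm]] <- make_distribution(nm, "lognormal", inputs$specs[[lab]]$shape,
                                 survival_cv * inputs$specs[[lab]]$shape)
  }
  for (i in seq_len(nrow(inputs$efficacy))) {
    tr <- inputs$efficacy$treatment[i]
    for (out in c("h2r", "h2m", "sae")) {
      nm <- paste0("rr_", out, "_", tr)
      d[[nm]] <- make_distribution(
        nm, "lognormal", inputs$efficacy[[paste0("rr_", out)]][i], se = 0.1,
        ci = c(inputs$efficacy[[paste0("rr_", out, "_lo")]][i],
               inputs$efficacy[[paste0("rr_", out, "_hi")]][i]))
    }
  }
  d
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Each iteration draws one joint parameter set from [psa_distributions()]
#' (independent draws; infeasible draws are rejected and redrawn, with the
#' rejection count recorded), rebuilds the model inputs and runs every
#' strategy, recording its discounted lifetime cost and QALYs. Iteration `i`
#' re-seeds from the master seed, so results are reproducible and independent
#' of execution order.
#'
#' @param inputs Model inputs.
#' @param n_iterations Number of Monte Carlo iterations (study value 5,000).
#' @param master_seed Master seed.
#' @param strategies Strategies to evaluate (default all).
#' @param distributions Optional distribution list overriding
#'   [psa_distributions()].
#' @return A `psa_result`: matrices `cost` and `qalys`
#'   (`n_iterations x strategies`), `n_iterations`, `master_seed`,
#'   `rejections`, `draws` (iteration-level parameter values).
#' @export
run_psa <- function(inputs, n_iterations, master_seed,
                    strategies = inputs$strategies, distributions = NULL) {
  stopifnot(n_iterations >= 1)
  dists <- if (is.null(distributions)) psa_distributions(inputs) else distributions
  ns <- length(strategies)
  cost <- matrix(NA_real_, n_iterations, ns, dimnames = list(NULL, strategies))
  qaly <- cost
  draws <- matrix(NA_real_, n_iterations, length(dists),
                  dimnames = list(NULL, names(dists)))
  rejections <- 0L
  for (i in seq_len(n_iterations)) {
    set.seed((master_seed + i) %% 2147483647L)
    repeat {
      dr <- vapply(dists, draw_distribution, numeric(1))
      ok <- all(is.finite(dr)) &&
        all(dr[grepl("^(lam|shape|rr|hr)", names(dr))] > 0, na.rm = TRUE) &&
        all(dr[grepl("^(utility|sae_prob)", names(dr))] >= 0) &&
        all(dr[grepl("^(utility|sae_prob)", names(dr))] <= 1)
      if (ok) break
      rejections <- rejections + 1L
    }
    draws[i, ] <- dr
    inp <- inputs
    for (nm in names(dr)) inp <- set_parameter(inp, nm, dr[[nm]])
    for (sg in strategies) {
      res <- aggregate_strategy(run_cohort(inp, sg), inp)
      cost[i, sg] <- res$cost
      qaly[i, sg] <- res$qalys
    }
  }
  if (rejections > 0) {
    message("PSA rejected and redrew ", rejections, " infeasible draw(s)")
  }
  structure(list(cost = cost, qalys = qaly, n_iterations = n_iterations,
                 master_seed = master_seed, rejections = rejections,
                 draws = draws),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curves
#'
#' For every willingness-to-pay threshold, the probability that each strategy
#' maximizes net monetary benefit (`threshold * QALYs - cost`) across the PSA
#' iterations; exact ties split their iteration's probability equally.
#'
#' @param psa A `psa_result`.
#' @param thresholds Non-negative THB/QALY threshold grid.
#' @return Data frame: `threshold` plus one probability column per strategy
#'   (columns sum to 1 at every threshold).
#' @export
compute_ceac <- function(psa, thresholds) {
  if (!length(thresholds)) stop("empty threshold grid", call. = FALSE)
  if (any(thresholds < 0)) stop("thresholds must be non-negative", call. = FALSE)
  strategies <- colnames(psa$cost)
  out <- matrix(0, length(thresholds), length(strategies),
                dimnames = list(NULL, strategies))
  for (k in seq_along(thresholds)) {
    nmb <- thresholds[k] * psa$qalys - psa$cost
    best <- apply(nmb, 1, max)
    win <- nmb == best                      # logical matrix, ties allowed
    out[k, ] <- colMeans(win / rowSums(win))
  }
  data.frame(threshold = thresholds, out, check.names = FALSE)
}

#' Cost-effectiveness plane points from a PSA
#'
#' @param psa A `psa_result`.
#' @param comparator Comparator strategy (default `"SoC"`).
#' @return Data frame of per-iteration incremental cost and QALYs per
#'   strategy (comparator excluded).
#' @export
ce_plane <- function(psa, comparator = "SoC") {
  strategies <- setdiff(colnames(psa$cost), comparator)
  do.call(rbind, lapply(strategies, function(sg) {
    data.frame(strategy = sg,
               iteration = seq_len(psa$n_iterations),
               inc_cost = psa$cost[, sg] - psa$cost[, comparator],
               inc_qalys = psa$qalys[, sg] - psa$qalys[, comparator])
  }))
}

#' Default one-way parameter ranges for a strategy's tornado analysis
#'
#' The mortality hazard ratio varies over its published 95% CI (1.64-3.61);
#' utilities, the adverse-event probability and admission cost over
#' `mean +/- 1.96 * se` (truncated to the feasible domain); the analysed
#' treatment's relative risks over their CIs; the transition lambdas and the
#' analysed treatment's drug price over +/-20% (no published SE).
#'
#' @param inputs Model inputs.
#' @param strategy The analysed intervention strategy.
#' @return Data frame with columns `name`, `base`, `low`, `high`.
#' @export
owsa_parameters <- function(inputs, strategy = "bsIFXi") {
  dists <- psa_distributions(inputs)
  rows <- list()
  add <- function(name, base, low, high) {
    rows[[length(rows) + 1]] <<- data.frame(name = name, base = base,
                                            low = low, high = high)
  }
  add("hr_high", inputs$hr_high, inputs$hr_high_ci[1], inputs$hr_high_ci[2])
  for (hs in names(inputs$utilities)) {
    d <- dists[[paste0("utility_", hs)]]
    add(d$name, d$mean, d$low, d$high)
  }
  for (nm in c("sae_prob", "sae_cost")) {
    d <- dists[[nm]]
    add(nm, d$mean, d$low, d$high)
  }
  for (lab in transition_labels()) {
    lam <- inputs$specs[[lab]]$lam
    add(paste0("lam_", lab), lam, 0.8 * lam, 1.2 * lam)
  }
  erow <- inputs$efficacy[inputs$efficacy$treatment == strategy, ]
  if (nrow(erow) == 1) {
    for (out in c("h2r", "h2m", "sae")) {
      add(paste0("rr_", out, "_", strategy), erow[[paste0("rr_", out)]],
          erow[[paste0("rr_", out, "_lo")]], erow[[paste0("rr_", out, "_hi")]])
    }
  }
  dc <- inputs$costs$drug[[strategy]]
  add(paste0("drug_cost_", strategy), dc, 0.8 * dc, 1.2 * dc)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic model with each parameter at its low and high
#' bound (all others at base) and records the ICER of the analysed strategy
#' against the comparator. Rows are sorted by descending span.
#'
#' @param inputs Model inputs.
#' @param parameters Data frame `name`, `base`, `low`, `high` (default
#'   [owsa_parameters()]).
#' @param strategy Analysed strategy (default `"bsIFXi"`).
#' @param comparator Comparator (default `"SoC"`).
#' @return Data frame: parameter name, base/low/high values, ICER at each
#'   bound, percent change from the base ICER, and span, sorted by
#'   descending span.
#' @export
run_owsa <- function(inputs, parameters = owsa_parameters(inputs, strategy),
                     strategy = "bsIFXi", comparator = "SoC") {
  if (any(parameters$low > parameters$base | parameters$high < parameters$base)) {
    stop("one-way bounds must bracket the base value", call. = FALSE)
  }
  icer_for <- function(inp) {
    r <- aggregate_strategy(run_cohort(inp, strategy), inp)
    comp <- aggregate_strategy(run_cohort(inp, comparator), inp)
    compare_strategies(r, comp)$icer
  }
  base_icer <- icer_for(inputs)
  res <- lapply(seq_len(nrow(parameters)), function(i) {
    p <- parameters[i, ]
    icer_lo <- icer_for(set_parameter(inputs, p$name, p$low))
    icer_hi <- icer_for(set_parameter(inputs, p$name, p$high))
    data.frame(name = p$name, base = p$base, low = p$low, high = p$high,
               icer_low = icer_lo, icer_high = icer_hi,
               pct_change_low = 100 * (icer_lo - base_icer) / base_icer,
               pct_change_high = 100 * (icer_hi - base_icer) / base_icer,
               span = abs(icer_hi - icer_lo))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  attr(out, "strategy") <- strategy
  attr(out, "comparator") <- comparator
  out
}
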