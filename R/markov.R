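#' Expanded state space of the cohort engine
#'
#' Health states (high disease activity, moderate/low, remission, death) are
#' crossed with the treatment line (`int` = first-line novel regimen,
#' `soc` = standard of care) and a phase that encodes the sequencing rules:
#' `act` (on the full regimen), `taper` (remission maintained on MTX only
#' after the one-cycle taper rule), `sae` (one-cycle interruption after a
#' serious adverse event). `H_int_act2` is the optional second trial cycle on
#' the novel regimen used when `switch_after = 2`. Death is a single
#' absorbing state.
#'
#' @return Character vector of the 16 expanded state names.
#' @export
ra_states <- function() {
  c("H_int_act", "H_int_act2", "H_int_sae",
    "M_int_act", "M_int_sae",
    "R_int_act", "R_int_taper", "R_int_sae",
    "H_soc_act", "H_soc_sae",
    "M_soc_act", "M_soc_sae",
    "R_soc_act", "R_soc_taper", "R_soc_sae",
    "death")
}

#' Health state of each expanded state
#' @return Named character vector mapping expanded state to one of
#'   `HIGH`, `MODLOW`, `REMISSION`, `DEATH`.
#' @export
state_health <- function() {
  s <- ra_states()
  h <- ifelse(startsWith(s, "H_"), "HIGH",
       ifelse(startsWith(s, "M_"), "MODLOW",
       ifelse(startsWith(s, "R_"), "REMISSION", "DEATH")))
  stats::setNames(h, s)
}

#' Treatment line of each expanded state (`int`, `soc` or `none` for death)
#' @export
state_line <- function() {
  s <- ra_states()
  l <- ifelse(grepl("_int_", s), "int", ifelse(grepl("_soc_", s), "soc", "none"))
  stats::setNames(l, s)
}

#' Phase of each expanded state (`act`, `taper`, `sae` or `none` for death)
#' @export
state_phase <- function() {
  s <- ra_states()
  p <- ifelse(grepl("taper", s), "taper",
       ifelse(grepl("sae", s), "sae",
       ifelse(s == "death", "none", "act")))
  stats::setNames(p, s)
}

#' Annual death probability from a life table
#'
#' @param life_table Data frame with columns `age` (integer years) and `qx`
#'   (annual death probability). The last row is the terminal age; a terminal
#'   `qx` of 1 lets ages beyond the table be treated as certain death.
#' @param age Age in years (vectorised); fractional ages use the completed
#'   integer age.
#' @return Annual death probabilities.
#' @export
annual_death_probability <- function(life_table, age) {
  stopifnot(all(c("age", "qx") %in% names(life_table)))
  a <- floor(age)
  max_age <- max(life_table$age)
  over <- a > max_age
  if (any(over)) {
    if (life_table$qx[which.max(life_table$age)] < 1) {
      stop("age ", max(a), " beyond life table and no terminal qx = 1 row",
           call. = FALSE)
    }
    a[over] <- max_age
  }
  if (any(a < min(life_table$age))) {
    stop("age below the life table's first row", call. = FALSE)
  }
  idx <- match(a, life_table$age)
  if (any(is.na(idx))) stop("life table has gaps at requested ages", call. = FALSE)
  life_table$qx[idx]
}

#' Per-cycle death probability with the high-activity hazard ratio
#'
#' The annual probability `q` is converted to the hazard scale, multiplied by
#' the mortality hazard ratio when the occupant is in the high-activity
#' state, and rescaled to the 6-month cycle:
#' `1 - (1 - q)^(0.5 * HR_eff)` with `HR_eff = hr_high` iff `state == "HIGH"`.
#'
#' @param model List with `life_table` and `hr_high` (mortality model).
#' @param age Age in years at the start of the cycle.
#' @param state Health state (`"HIGH"`, `"MODLOW"`, `"REMISSION"`).
#' @param cycle_length Cycle length in years (default 0.5).
#' @return Per-cycle death probability.
#' @export
mortality_probability_per_cycle <- function(model, age, state,
                                            cycle_length = 0.5) {
  q <- annual_death_probability(model$life_table, age)
  hr <- if (identical(state, "HIGH")) model$hr_high else 1
  if (!is.finite(hr) || hr <= 0) stop("hr_high must be positive", call. = FALSE)
  1 - (1 - q)^(cycle_length * hr)
}

#' Apply a treatment relative risk to a baseline transition probability
#'
#' Multiplies the baseline per-cycle probability by the relative risk and
#' caps the result so the row remains a probability distribution:
#' `min(rr * base_tp, 1 - competing_exit_total)`.
#'
#' @param base_tp Baseline per-cycle transition probability.
#' @param rr Relative risk (vs the baseline regimen).
#' @param competing_exit_total Total probability already allocated to
#'   competing exits from the state this cycle.
#' @return Adjusted probability, never negative.
#' @export
apply_efficacy <- function(base_tp, rr, competing_exit_total) {
  if (any(base_tp < 0 | base_tp > 1)) stop("base_tp must be in [0,1]", call. = FALSE)
  if (any(competing_exit_total < 0)) stop("competing_exit_total must be >= 0", call. = FALSE)
  if (any(competing_exit_total > 1)) {
    stop("competing exits already exceed probability 1", call. = FALSE)
  }
  if (any(rr < 0)) stop("rr must be non-negative", call. = FALSE)
  pmax(pmin(rr * base_tp, 1 - competing_exit_total), 0)
}

#' Relative risks for a strategy
#'
#' The comparator (`SoC`) uses relative risks of 1 throughout (its transition
#' probabilities are the observed baseline). For the moderate/low-to-remission
#' transition the high-to-remission relative risk is reused, following the
#' assumption that this efficacy is comparable.
#'
#' @param inputs Model inputs (see [ra_model_inputs()]).
#' @param strategy Strategy name.
#' @return List with `h2m`, `h2r`, `m2r`, `sae`.
#' @export
strategy_rr <- function(inputs, strategy) {
  if (identical(strategy, "SoC")) {
    return(list(h2m = 1, h2r = 1, m2r = 1, sae = 1))
  }
  eff <- inputs$efficacy
  row <- eff[eff$treatment == strategy, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no efficacy record for strategy '", strategy, "'", call. = FALSE)
  }
  list(h2m = row$rr_h2m, h2r = row$rr_h2r, m2r = row$rr_h2r, sae = row$rr_sae)
}

# Internal: per-cycle ingredient vectors for the transition matrices.
# Cycle c moves occupancy row c-1 (age start_age + (c-1)/2 years) to row c;
# the per-cycle transition probability is evaluated at t = c (model-time axis,
# 6-month units), u = 1.
engine_ingredients <- function(inputs, strategy, n_cycles) {
  st <- inputs$settings
  cyc <- seq_len(n_cycles)
  tp <- sapply(transition_labels(), function(lab)
    transition_probability(inputs$specs[[lab]], t = cyc, u = 1))
  if (n_cycles == 1L) tp <- matrix(tp, nrow = 1, dimnames = list(NULL, transition_labels()))
  age <- st$start_age + (cyc - 1) * st$cycle_length
  q <- annual_death_probability(inputs$life_table, age)
  d_other <- 1 - (1 - q)^st$cycle_length                  # HR = 1
  d_high  <- 1 - (1 - q)^(st$cycle_length * inputs$hr_high)
  rr <- strategy_rr(inputs, strategy)
  list(tp = tp, d_high = d_high, d_other = d_other, rr = rr,
       sae = inputs$sae_prob)
}

#' Build the full set of per-cycle transition matrices for one strategy
#'
#' Encodes the sequencing rules on the expanded state space: relative-risk
#' adjusted response on the novel regimen, switch of inadequate responders to
#' standard of care, the one-cycle remission taper rule (full regimen for one
#' remission cycle, then MTX only), one-cycle serious-adverse-event
#' interruption with baseline transition probabilities, and competing
#' life-table mortality (hazard-ratio adjusted in the high-activity state).
#' Residual mass stays in place.
#'
#' @param inputs Model inputs.
#' @param strategy Strategy name.
#' @param n_cycles Number of cycles.
#' @return A `n_states x n_states x n_cycles` array; slice `[,,c]` moves
#'   occupancy from cycle `c-1` to cycle `c`.
#' @export
build_transition_array <- function(inputs, strategy, n_cycles) {
  s <- ra_states()
  ns <- length(s)
  ing <- engine_ingredients(inputs, strategy, n_cycles)
  tp <- ing$tp; rr <- ing$rr
  dH <- ing$d_high; dO <- ing$d_other
  sae_base <- rep(ing$sae, n_cycles)
  switch_after <- inputs$settings$switch_after

  arr <- array(0, dim = c(ns, ns, n_cycles), dimnames = list(s, s, NULL))
  idx <- stats::setNames(seq_along(s), s)

  # unconditional-probability composition: exits are capped in a fixed order
  # against the mass already committed (the apply_efficacy rule), residual
  # stays in place
  cap <- function(base, r, competing) pmax(pmin(r * base, 1 - competing), 0)

  ## --- intervention line, active -------------------------------------------
  high_int_row <- function(from, stay_to) {
    d <- dH
    sae <- cap(sae_base, rr$sae, d)
    h2m <- cap(tp[, "H2M"], rr$h2m, d + sae)
    h2r <- cap(tp[, "H2R"], rr$h2r, d + sae + h2m)
    arr[idx[from], idx["H_int_sae"], ] <<- sae
    arr[idx[from], idx["M_int_act"], ] <<- h2m
    arr[idx[from], idx["R_int_act"], ] <<- h2r
    arr[idx[from], idx["death"], ]     <<- d
    arr[idx[from], idx[stay_to], ]     <<- 1 - d - sae - h2m - h2r
  }
  high_int_row("H_int_act", if (switch_after >= 2) "H_int_act2" else "H_soc_act")
  high_int_row("H_int_act2", "H_soc_act")

  { # M_int_act: worsening unadjusted, remission RR-adjusted (H2R reused)
    d <- dO
    sae <- cap(sae_base, rr$sae, d)
    m2h <- cap(tp[, "M2H"], 1, d + sae)
    m2r <- cap(tp[, "M2R"], rr$m2r, d + sae + m2h)
    arr[idx["M_int_act"], idx["M_int_sae"], ] <- sae
    arr[idx["M_int_act"], idx["H_int_act"], ] <- m2h
    arr[idx["M_int_act"], idx["R_int_act"], ] <- m2r
    arr[idx["M_int_act"], idx["death"], ]     <- d
    arr[idx["M_int_act"], idx["M_int_act"], ] <- 1 - d - sae - m2h - m2r
  }
  { # R_int_act: one full-regimen remission cycle, then taper; relapse resumes
    d <- dO
    sae <- cap(sae_base, rr$sae, d)
    r2m <- cap(tp[, "R2M"], 1, d + sae)
    arr[idx["R_int_act"], idx["R_int_sae"], ]   <- sae
    arr[idx["R_int_act"], idx["M_int_act"], ]   <- r2m
    arr[idx["R_int_act"], idx["death"], ]       <- d
    arr[idx["R_int_act"], idx["R_int_taper"], ] <- 1 - d - sae - r2m
  }
  { # R_int_taper: MTX only, no SAE risk; relapse resumes the full regimen
    d <- dO
    r2m <- cap(tp[, "R2M"], 1, d)
    arr[idx["R_int_taper"], idx["M_int_act"], ]   <- r2m
    arr[idx["R_int_taper"], idx["death"], ]       <- d
    arr[idx["R_int_taper"], idx["R_int_taper"], ] <- 1 - d - r2m
  }
  ## --- intervention line, SAE interruption (baseline probabilities) --------
  { d <- dH
    h2m <- cap(tp[, "H2M"], 1, d)
    h2r <- cap(tp[, "H2R"], 1, d + h2m)
    arr[idx["H_int_sae"], idx["M_int_act"], ] <- h2m
    arr[idx["H_int_sae"], idx["R_int_act"], ] <- h2r
    arr[idx["H_int_sae"], idx["death"], ]     <- d
    arr[idx["H_int_sae"], idx["H_int_act"], ] <- 1 - d - h2m - h2r
  }
  { d <- dO
    m2h <- cap(tp[, "M2H"], 1, d)
    m2r <- cap(tp[, "M2R"], 1, d + m2h)
    arr[idx["M_int_sae"], idx["H_int_act"], ] <- m2h
    arr[idx["M_int_sae"], idx["R_int_act"], ] <- m2r
    arr[idx["M_int_sae"], idx["death"], ]     <- d
    arr[idx["M_int_sae"], idx["M_int_act"], ] <- 1 - d - m2h - m2r
  }
  { d <- dO
    r2m <- cap(tp[, "R2M"], 1, d)
    arr[idx["R_int_sae"], idx["M_int_act"], ] <- r2m
    arr[idx["R_int_sae"], idx["death"], ]     <- d
    arr[idx["R_int_sae"], idx["R_int_act"], ] <- 1 - d - r2m
  }
  ## --- standard-of-care line (baseline probabilities, no switch) -----------
  { d <- dH
    sae <- cap(sae_base, 1, d)
    h2m <- cap(tp[, "H2M"], 1, d + sae)
    h2r <- cap(tp[, "H2R"], 1, d + sae + h2m)
    arr[idx["H_soc_act"], idx["H_soc_sae"], ] <- sae
    arr[idx["H_soc_act"], idx["M_soc_act"], ] <- h2m
    arr[idx["H_soc_act"], idx["R_soc_act"], ] <- h2r
    arr[idx["H_soc_act"], idx["death"], ]     <- d
    arr[idx["H_soc_act"], idx["H_soc_act"], ] <- 1 - d - sae - h2m - h2r
  }
  { d <- dO
    sae <- cap(sae_base, 1, d)
    m2h <- cap(tp[, "M2H"], 1, d + sae)
    m2r <- cap(tp[, "M2R"], 1, d + sae + m2h)
    arr[idx["M_soc_act"], idx["M_soc_sae"], ] <- sae
    arr[idx["M_soc_act"], idx["H_soc_act"], ] <- m2h
    arr[idx["M_soc_act"], idx["R_soc_act"], ] <- m2r
    arr[idx["M_soc_act"], idx["death"], ]     <- d
    arr[idx["M_soc_act"], idx["M_soc_act"], ] <- 1 - d - sae - m2h - m2r
  }
  { d <- dO
    sae <- cap(sae_base, 1, d)
    r2m <- cap(tp[, "R2M"], 1, d + sae)
    arr[idx["R_soc_act"], idx["R_soc_sae"], ]   <- sae
    arr[idx["R_soc_act"], idx["M_soc_act"], ]   <- r2m
    arr[idx["R_soc_act"], idx["death"], ]       <- d
    arr[idx["R_soc_act"], idx["R_soc_taper"], ] <- 1 - d - sae - r2m
  }
  { d <- dO
    r2m <- cap(tp[, "R2M"], 1, d)
    arr[idx["R_soc_taper"], idx["M_soc_act"], ]   <- r2m
    arr[idx["R_soc_taper"], idx["death"], ]       <- d
    arr[idx["R_soc_taper"], idx["R_soc_taper"], ] <- 1 - d - r2m
  }
  { d <- dH
    h2m <- cap(tp[, "H2M"], 1, d)
    h2r <- cap(tp[, "H2R"], 1, d + h2m)
    arr[idx["H_soc_sae"], idx["M_soc_act"], ] <- h2m
    arr[idx["H_soc_sae"], idx["R_soc_act"], ] <- h2r
    arr[idx["H_soc_sae"], idx["death"], ]     <- d
    arr[idx["H_soc_sae"], idx["H_soc_act"], ] <- 1 - d - h2m - h2r
  }
  { d <- dO
    m2h <- cap(tp[, "M2H"], 1, d)
    m2r <- cap(tp[, "M2R"], 1, d + m2h)
    arr[idx["M_soc_sae"], idx["H_soc_act"], ] <- m2h
    arr[idx["M_soc_sae"], idx["R_soc_act"], ] <- m2r
    arr[idx["M_soc_sae"], idx["death"], ]     <- d
    arr[idx["M_soc_sae"], idx["M_soc_act"], ] <- 1 - d - m2h - m2r
  }
  { d <- dO
    r2m <- cap(tp[, "R2M"], 1, d)
    arr[idx["R_soc_sae"], idx["M_soc_act"], ] <- r2m
    arr[idx["R_soc_sae"], idx["death"], ]     <- d
    arr[idx["R_soc_sae"], idx["R_soc_act"], ] <- 1 - d - r2m
  }
  arr[idx["death"], idx["death"], ] <- 1

  # residual "stay" entries can round to -1ulp when a cap binds exactly
  if (any(arr < -1e-12)) {
    stop("internal consistency error: negative transition probability",
         call. = FALSE)
  }
  arr[arr < 0] <- 0

  rs <- apply(arr, c(1, 3), sum)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("internal consistency error: transition matrix row sums deviate ",
         "from 1 by up to ", format(max(abs(rs - 1))), call. = FALSE)
  }
  arr
}

#' Transition matrix for a single cycle
#'
#' @inheritParams build_transition_array
#' @param cycle_index Cycle index (>= 1); the matrix moves occupancy from
#'   cycle `cycle_index - 1` to `cycle_index`.
#' @return Row-stochastic matrix over [ra_states()].
#' @export
build_transition_matrix <- function(inputs, strategy, cycle_index) {
  if (cycle_index < 1) stop("cycle_index must be >= 1", call. = FALSE)
  full <- build_transition_array(inputs, strategy, cycle_index)
  full[, , cycle_index]
}

#' Run the cohort simulation for one strategy
#'
#' Starts the whole cohort in the high-activity state on the strategy's
#' assigned line (novel regimen for interventions, standard of care for
#' `SoC`) and propagates occupancy through the per-cycle transition matrices.
#' Besides the trace, the per-cycle flows needed for event costing are
#' recorded: entries into the adverse-event interruption states (admission
#' cost) and switches from the intervention line to standard of care
#' (re-screening cost).
#'
#' @param inputs Model inputs.
#' @param strategy Strategy name.
#' @param horizon_cycles Number of 6-month cycles (default from settings).
#' @return A `cohort_trace`: list with `trace` (matrix, rows `0..N`),
#'   `sae_entries` and `switch_entries` (length-`N` flow vectors; element `c`
#'   is the flow arriving at cycle `c`), `strategy`, `start_age`,
#'   `cycle_length`.
#' @export
run_cohort <- function(inputs, strategy,
                       horizon_cycles = inputs$settings$horizon_cycles) {
  if (horizon_cycles < 1) stop("horizon_cycles must be >= 1", call. = FALSE)
  s <- ra_states()
  arr <- build_transition_array(inputs, strategy, horizon_cycles)
  v <- stats::setNames(numeric(length(s)), s)
  v[if (identical(strategy, "SoC")) "H_soc_act" else "H_int_act"] <- 1

  trace <- matrix(0, nrow = horizon_cycles + 1, ncol = length(s),
                  dimnames = list(0:horizon_cycles, s))
  trace[1, ] <- v
  sae_cols <- which(grepl("sae", s))
  soc_cols <- which(grepl("_soc_", s))
  int_rows <- which(grepl("_int_", s))
  sae_entries <- numeric(horizon_cycles)
  switch_entries <- numeric(horizon_cycles)
  for (cc in seq_len(horizon_cycles)) {
    P <- arr[, , cc]
    prev <- trace[cc, ]
    sae_entries[cc] <- sum(prev %*% P[, sae_cols, drop = FALSE])
    switch_entries[cc] <- sum(prev[int_rows] %*% P[int_rows, soc_cols, drop = FALSE])
    trace[cc + 1, ] <- prev %*% P
  }
  structure(list(trace = trace,
                 sae_entries = sae_entries,
                 switch_entries = switch_entries,
                 strategy = strategy,
                 start_age = inputs$settings$start_age,
                 cycle_length = inputs$settings$cycle_length),
            class = "cohort_trace")
}

#' Collapse a trace to health-state occupancy
#'
#' @param ct A `cohort_trace`.
#' @return Matrix with columns `HIGH`, `MODLOW`, `REMISSION`, `DEATH`.
#' @export
health_occupancy <- function(ct) {
  h <- state_health()
  out <- sapply(c("HIGH", "MODLOW", "REMISSION", "DEATH"), function(hs)
    rowSums(ct$trace[, names(h)[h == hs], drop = FALSE]))
  rownames(out) <- rownames(ct$trace)
  out
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$trace) - 1
  ho <- health_occupancy(x)
  cat(sprintf("Cohort trace: strategy %s, %d cycles from age %g\n",
              x$strategy, n, x$start_age))
  cat(sprintf("  cumulative death at horizon: %.4f\n", ho[n + 1, "DEATH"]))
  invisible(x)
}

#' Write a cohort trace as a delimited table
#'
#' One row per cycle, one column per expanded state, preceded by the cycle
#' index and patient age.
#'
#' @param ct A `cohort_trace`.
#' @param path Output file path.
#' @export
write_cohort_trace <- function(ct, path) {
  n <- nrow(ct$trace) - 1
  df <- data.frame(cycle = 0:n,
                   age = ct$start_age + (0:n) * ct$cycle_length,
                   ct$trace, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
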