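#' Discount factor for a cycle
#'
#' Annual discounting compounded continuously over cycles:
#' `(1 + r)^(-cycle_index * cycle_length)`; cycle 0 is undiscounted.
#'
#' @param cycle_index Cycle index (>= 0, vectorised).
#' @param settings Economic settings (list with `annual_discount_rate` and
#'   `cycle_length` in years).
#' @return Discount factors in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, settings) {
  if (any(cycle_index < 0)) stop("cycle_index must be non-negative", call. = FALSE)
  (1 + settings$annual_discount_rate)^(-cycle_index * settings$cycle_length)
}

# Internal: per-cycle state cost for every expanded state (length-16 vector),
# at a given cycle index (0-based accrual row). Event costs (adverse-event
# admission, re-screening on switch) are flow-based and added in
# aggregate_strategy().
state_cycle_costs <- function(inputs, strategy, cycle_index) {
  s <- ra_states()
  health <- state_health()
  line <- state_line()
  phase <- state_phase()
  cs <- inputs$costs

  drug_int <- cs$drug[[strategy]]
  if (is.null(drug_int)) stop("unknown regimen '", strategy, "'", call. = FALSE)
  drug_soc <- cs$drug[["SoC"]]

  visit_unit <- cs$opd_fee + cs$nonmedical_per_visit
  visits <- c(HIGH = cs$opd_visits[["HIGH"]], MODLOW = cs$opd_visits[["MODLOW"]],
              REMISSION = cs$opd_visits[["REMISSION"]], DEATH = 0)

  inf_n <- infusion_visits(inputs, strategy,
                           first_cycle = (cycle_index == 0))

  out <- stats::setNames(numeric(length(s)), s)
  for (i in seq_along(s)) {
    if (health[[i]] == "DEATH") next
    cost <- visits[[health[[i]]]] * visit_unit
    if (phase[[i]] == "act") {
      if (line[[i]] == "int") {
        cost <- cost + drug_int + cs$infusion_fee * inf_n
      } else {
        cost <- cost + drug_soc
      }
    } else if (phase[[i]] == "taper") {
      cost <- cost + cs$mtx_only
    }
    # sae phase: no drug cost; admission cost is charged on entry (flow)
    out[i] <- cost
  }
  out
}

#' Infusion visits per cycle for a regimen
#'
#' Intravenous regimens incur administration fees: infliximab-type regimens
#' load with 5 infusions in the first 6-month cycle then 3 per maintenance
#' cycle; rituximab-type regimens give 2 infusions every cycle; subcutaneous
#' and oral regimens none.
#'
#' @param inputs Model inputs.
#' @param strategy Strategy name.
#' @param first_cycle Is this the regimen's first cycle?
#' @return Number of infusion visits in the cycle.
#' @export
infusion_visits <- function(inputs, strategy, first_cycle = FALSE) {
  sched <- inputs$costs$infusion_schedule[[strategy]]
  if (is.null(sched)) stop("unknown regimen '", strategy, "'", call. = FALSE)
  switch(sched,
         iv_loading = if (first_cycle) 5 else 3,
         iv_biannual = 2,
         none = 0,
         stop("unknown infusion schedule '", sched, "'", call. = FALSE))
}

#' Per-cycle cost of occupying one expanded state
#'
#' Drug cost (full regimen when active, MTX only in the remission taper, none
#' during an adverse-event interruption), outpatient visits priced at the
#' service fee plus non-medical cost per visit, infusion administration fees,
#' the pre-treatment screening panel when the regimen starts, and the
#' adverse-event admission cost on entry into the interruption state.
#'
#' @param state Expanded state name (one of [ra_states()]).
#' @param inputs Model inputs.
#' @param strategy Strategy name (the regimen context for the `int` line).
#' @param cycle_index Cycle index (0-based); determines infusion loading.
#' @param is_regimen_start Charge the screening panel this cycle?
#' @param is_sae_entry Charge the adverse-event admission cost this cycle?
#' @return Cost in THB (year 2022) for the cycle.
#' @export
cycle_cost <- function(state, inputs, strategy, cycle_index = 0,
                       is_regimen_start = FALSE, is_sae_entry = FALSE) {
  if (!state %in% ra_states()) stop("unknown state '", state, "'", call. = FALSE)
  base <- state_cycle_costs(inputs, strategy, cycle_index)[[state]]
  if (state == "death") return(0)
  if (is_regimen_start) base <- base + inputs$costs$screening
  if (is_sae_entry) base <- base + inputs$costs$sae_cost
  base
}

#' Per-cycle QALY accrued in one expanded state
#'
#' Utility of the occupant's health state times the cycle length in years;
#' death accrues zero.
#'
#' @param state Expanded state name.
#' @param inputs Model inputs.
#' @return QALYs per cycle of occupancy.
#' @export
cycle_qaly <- function(state, inputs) {
  h <- state_health()[[state]]
  if (h == "DEATH") return(0)
  inputs$utilities[[h]] * inputs$settings$cycle_length
}

#' Aggregate a cohort trace to lifetime totals
#'
#' Costs and QALYs accrue for the state occupied at the start of each cycle
#' (rows `0 .. N-1` of the trace), discounted by the cycle's discount factor.
#' Flow-based event costs are added at the arrival cycle: the screening panel
#' at model entry and again on every switch to the standard-of-care regimen,
#' and the adverse-event admission cost on entry into an interruption state.
#' With `half_cycle = TRUE` occupancy is averaged over adjacent rows
#' (mid-cycle transition assumption) before accrual.
#'
#' @param ct A `cohort_trace` from [run_cohort()].
#' @param inputs Model inputs.
#' @return A `strategy_result`: discounted and undiscounted lifetime cost,
#'   life years and QALYs.
#' @export
aggregate_strategy <- function(ct, inputs) {
  trace <- ct$trace
  n <- nrow(trace) - 1
  s <- ra_states()
  if (!identical(colnames(trace), s)) stop("trace state set mismatch", call. = FALSE)
  strategy <- ct$strategy
  st <- inputs$settings

  occ <- trace[seq_len(n), , drop = FALSE]            # rows 0 .. N-1
  if (isTRUE(st$half_cycle)) {
    occ <- (trace[seq_len(n), , drop = FALSE] + trace[seq_len(n) + 1, , drop = FALSE]) / 2
  }
  disc <- discount_factor(0:(n - 1), st)

  cost0 <- state_cycle_costs(inputs, strategy, cycle_index = 0)
  cost1 <- state_cycle_costs(inputs, strategy, cycle_index = 1)
  state_cost <- rbind(cost0, matrix(cost1, nrow = n - 1, ncol = length(s),
                                    byrow = TRUE))
  per_cycle_cost <- rowSums(occ * state_cost)
  # screening at model entry (whole cohort starts a regimen at cycle 0)
  per_cycle_cost[1] <- per_cycle_cost[1] + inputs$costs$screening * sum(trace[1, s != "death"])
  # event flows arriving at cycles 1 .. N-1 accrue at their arrival cycle
  if (n >= 2) {
    arrive <- seq_len(n - 1)                           # arrival cycles 1..N-1
    per_cycle_cost[arrive + 1] <- per_cycle_cost[arrive + 1] +
      inputs$costs$sae_cost * ct$sae_entries[arrive] +
      inputs$costs$screening * ct$switch_entries[arrive]
  }

  util <- stats::setNames(ifelse(state_health() == "DEATH", 0,
                                 inputs$utilities[state_health()]), s)
  per_cycle_qaly <- rowSums(occ * matrix(util, nrow = n, ncol = length(s),
                                         byrow = TRUE)) * st$cycle_length
  alive <- rowSums(occ[, s != "death", drop = FALSE])
  per_cycle_ly <- alive * st$cycle_length

  structure(list(
    strategy = strategy,
    cost = sum(per_cycle_cost * disc),
    cost_undiscounted = sum(per_cycle_cost),
    life_years = sum(per_cycle_ly * disc),
    life_years_undiscounted = sum(per_cycle_ly),
    qalys = sum(per_cycle_qaly * disc),
    qalys_undiscounted = sum(per_cycle_qaly)
  ), class = "strategy_result")
}

#' Incremental comparison of two strategy results
#'
#' @param result A `strategy_result` (or list with `cost` and `qalys`).
#' @param comparator The comparator `strategy_result`.
#' @return List with `inc_cost`, `inc_qalys`, `icer` (THB per QALY, `NA` when
#'   undefined) and flags `dominant` (cheaper and more effective),
#'   `dominated` (costlier and no more effective), `icer_undefined`.
#' @export
compare_strategies <- function(result, comparator) {
  dc <- result$cost - comparator$cost
  dq <- result$qalys - comparator$qalys
  dominant <- dc < 0 && dq > 0
  dominated <- dc > 0 && dq <= 0
  icer_undefined <- dq == 0 && dc != 0
  icer <- if (dq > 0) dc / dq else NA_real_
  list(inc_cost = dc, inc_qalys = dq, icer = icer,
       dominant = dominant, dominated = dominated,
       icer_undefined = icer_undefined)
}

#' Convert THB to USD at the study exchange rate
#'
#' @param amount_thb Amount in THB (year 2022).
#' @param settings Economic settings (uses `thb_per_usd`, study value 34.53).
#' @return USD, rounded to the nearest dollar.
#' @export
thb_to_usd <- function(amount_thb, settings = economic_settings()) {
  if (any(!is.finite(amount_thb))) stop("amount must be finite", call. = FALSE)
  round(amount_thb / settings$thb_per_usd)
}

#' Default economic settings
#'
#' 3% annual discounting, 6-month cycles, the 2022 exchange rate of 34.53
#' THB per USD and the Thai willingness-to-pay threshold of 160,000 THB per
#' QALY gained.
#'
#' @param annual_discount_rate Annual discount rate.
#' @param cycle_length Cycle length in years.
#' @param thb_per_usd Exchange rate.
#' @param wtp_threshold Willingness-to-pay threshold (THB/QALY).
#' @param start_age Cohort age at model entry (years).
#' @param horizon_cycles Number of cycles in the lifetime horizon.
#' @param switch_after Number of failing cycles on the novel regimen before
#'   switching to standard of care (1 or 2).
#' @param half_cycle Apply a half-cycle correction (default off).
#' @return Settings list.
#' @export
economic_settings <- function(annual_discount_rate = 0.03, cycle_length = 0.5,
                              thb_per_usd = 34.53, wtp_threshold = 160000,
                              start_age = 56, horizon_cycles = 200,
                              switch_after = 1, half_cycle = FALSE) {
  stopifnot(annual_discount_rate >= 0, cycle_length > 0, thb_per_usd > 0,
            wtp_threshold >= 0, switch_after %in% c(1, 2))
  list(annual_discount_rate = annual_discount_rate, cycle_length = cycle_length,
       thb_per_usd = thb_per_usd, wtp_threshold = wtp_threshold,
       start_age = start_age, horizon_cycles = horizon_cycles,
       switch_after = switch_after, half_cycle = half_cycle)
}

#' Run the deterministic base case over a set of strategies
#'
#' Runs the cohort engine and economic aggregation for every strategy and
#' compares each against the comparator.
#'
#' @param inputs Model inputs.
#' @param strategies Character vector of strategy names (default: all in the
#'   inputs).
#' @param comparator Comparator strategy (default `"SoC"`).
#' @return Data frame with one row per strategy: discounted/undiscounted
#'   cost, life years, QALYs, incremental cost and QALYs, ICER, dominance
#'   flag and USD cost.
#' @export
run_base_case <- function(inputs, strategies = inputs$strategies,
                          comparator = "SoC") {
  results <- lapply(strategies, function(sg)
    aggregate_strategy(run_cohort(inputs, sg), inputs))
  names(results) <- strategies
  comp <- results[[comparator]]
  if (is.null(comp)) {
    comp <- aggregate_strategy(run_cohort(inputs, comparator), inputs)
  }
  rows <- lapply(strategies, function(sg) {
    r <- results[[sg]]
    inc <- compare_strategies(r, comp)
    data.frame(strategy = sg,
               cost = r$cost, cost_undiscounted = r$cost_undiscounted,
               life_years = r$life_years,
               life_years_undiscounted = r$life_years_undiscounted,
               qalys = r$qalys, qalys_undiscounted = r$qalys_undiscounted,
               inc_cost = inc$inc_cost, inc_qalys = inc$inc_qalys,
               icer = inc$icer,
               dominance = if (inc$dominant) "dominant"
                           else if (inc$dominated) "dominated" else "",
               cost_usd = thb_to_usd(r$cost, inputs$settings))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a base-case results table
#'
#' Delimited table mirroring the lifetime-results layout (strategy, costs,
#' life years, QALYs, incremental values, ICER, dominance, USD), THB amounts
#' rounded to the satang at serialization only.
#'
#' @param base_case Data frame from [run_base_case()].
#' @param path Output file path.
#' @export
write_base_case <- function(base_case, path) {
  out <- base_case
  money <- c("cost", "cost_undiscounted", "inc_cost", "icer")
  out[money] <- lapply(out[money], function(x) round(x, 2))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
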