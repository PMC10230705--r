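# Independent oracles, deliberately coded against different primitives than
# the implementation they check.

# 3 binomial Monte-Carlo SEs for comparing a simulated occupancy matrix with
# the cohort trace; the binomial SE is unknown, so the larger of the two
# plug-in estimates is used, with a 2/n guard for near-empty cells.
microsim_bound <- function(p, sim, n_paths) {
  3 * pmax(sqrt(p * (1 - p) / n_paths), sqrt(sim * (1 - sim) / n_paths)) +
    2 / n_paths
}

# Individual-level microsimulation using the same per-cycle matrices as the
# cohort engine: checks the matrix-product propagation against sampling.
microsimulate <- function(inputs, strategy, n_paths, n_cycles, seed) {
  arr <- build_transition_array(inputs, strategy, n_cycles)
  ns <- length(ra_states())
  start <- if (identical(strategy, "SoC")) which(ra_states() == "H_soc_act") else 1L
  set.seed(seed)
  state <- rep.int(start, n_paths)
  occ <- matrix(0, n_cycles + 1, ns, dimnames = list(0:n_cycles, ra_states()))
  occ[1, start] <- 1
  for (cc in seq_len(n_cycles)) {
    u <- stats::runif(n_paths)
    newstate <- integer(n_paths)
    for (s in unique(state)) {
      m <- state == s
      cp <- cumsum(arr[s, , cc])
      newstate[m] <- pmin(findInterval(u[m], cp) + 1L, ns)
    }
    state <- newstate
    occ[cc + 1, ] <- tabulate(state, ns) / n_paths
  }
  occ
}

# Spreadsheet-style cost/QALY accumulation: explicit loops over cycles and
# states through the public per-state costing functions, with event flows
# recomputed from the transition matrices rather than taken from the trace
# object.
accumulate_independent <- function(ct, inputs) {
  trace <- ct$trace
  n <- nrow(trace) - 1
  s <- ra_states()
  st <- inputs$settings
  r <- st$annual_discount_rate
  total_cost <- total_qaly <- total_ly <- 0
  arr <- build_transition_array(inputs, ct$strategy, n)
  for (k in 0:(n - 1)) {
    disc <- (1 + r)^(-k * st$cycle_length)
    for (state in s) {
      o <- trace[k + 1, state]
      if (o == 0) next
      total_cost <- total_cost + o * disc *
        cycle_cost(state, inputs, ct$strategy, cycle_index = k,
                   is_regimen_start = (k == 0 && state != "death"))
      total_qaly <- total_qaly + o * disc * cycle_qaly(state, inputs)
      if (state != "death") total_ly <- total_ly + o * disc * st$cycle_length
    }
    if (k >= 1) {
      # flows that arrived at cycle k (during transition k)
      prev <- trace[k, ]
      P <- arr[, , k]
      sae_cols <- grepl("sae", s)
      int_rows <- grepl("_int_", s)
      soc_cols <- grepl("_soc_", s)
      sae_in <- sum(prev %*% P[, sae_cols, drop = FALSE])
      switch_in <- sum(prev[int_rows] %*% P[int_rows, soc_cols, drop = FALSE])
      total_cost <- total_cost + disc *
        (sae_in * inputs$costs$sae_cost + switch_in * inputs$costs$screening)
    }
  }
  list(cost = total_cost, qalys = total_qaly, life_years = total_ly)
}
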