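test_that("per-cycle mortality matches the hazard-scale closed form", {
  model <- list(life_table = data.frame(age = 56, qx = 0.01), hr_high = 2.43)
  expect_equal(mortality_probability_per_cycle(model, 56, "MODLOW"),
               1 - 0.99^0.5, tolerance = 1e-12)
  expect_equal(mortality_probability_per_cycle(model, 56, "REMISSION"),
               1 - 0.99^0.5, tolerance = 1e-12)
  expect_equal(mortality_probability_per_cycle(model, 56, "HIGH"),
               1 - 0.99^1.215, tolerance = 1e-12)
  terminal <- list(life_table = data.frame(age = c(56, 57), qx = c(0.5, 1)),
                   hr_high = 2.43)
  for (st in c("HIGH", "MODLOW", "REMISSION")) {
    expect_equal(mortality_probability_per_cycle(terminal, 57, st), 1)
  }
  # beyond the table: fine with a terminal qx of 1, an error without
  expect_equal(mortality_probability_per_cycle(terminal, 90, "MODLOW"), 1)
  open_ended <- list(life_table = data.frame(age = 56, qx = 0.01), hr_high = 2.43)
  expect_error(mortality_probability_per_cycle(open_ended, 90, "MODLOW"),
               "beyond life table")
})

test_that("relative-risk adjustment caps at the remaining probability mass", {
  expect_equal(apply_efficacy(0.3, 1, 0.1), 0.3)
  expect_equal(apply_efficacy(0.3, 2, 0.1), 0.6)
  expect_equal(apply_efficacy(0.55, 2, 0.2), 0.8)
  expect_error(apply_efficacy(0.3, 1, 1.2), "exceed probability 1")
  expect_error(apply_efficacy(1.3, 1, 0), "base_tp")
})

test_that("transition matrices are row-stochastic across strategies and cycles", {
  for (sg in c("SoC", "bsIFXi", "IFX", "RTX")) {
    arr <- build_transition_array(fix_inputs, sg, 200)
    rs <- colSums(aperm(arr, c(2, 1, 3)))
    expect_lt(max(abs(rs - 1)), 1e-9)
    expect_true(all(arr >= 0))
  }
})

test_that("null dynamics freeze health state and kill no one", {
  inp <- fix_inputs
  for (lab in transition_labels()) inp$specs[[lab]]$lam <- 1e-300
  inp$sae_prob <- 0
  inp$life_table <- zero_mortality_table()
  M <- build_transition_matrix(inp, "bsIFXi", cycle_index = 1)
  # each row is deterministic: only the structural sequencing moves remain
  expect_true(all(M %in% c(0, 1)))
  expect_equal(unname(rowSums(M)), rep(1, 16))
  expect_true(all(M[, "death"][ra_states() != "death"] == 0))
  # health state never changes under null dynamics
  h <- state_health()
  for (from in setdiff(ra_states(), "death")) {
    to <- ra_states()[M[from, ] == 1]
    expect_identical(unname(h[to]), unname(h[from]))
  }
  # the standard-of-care active rows are exactly absorbing
  expect_equal(unname(M["H_soc_act", "H_soc_act"]), 1)
  expect_equal(unname(M["M_soc_act", "M_soc_act"]), 1)
})

test_that("the standard-of-care cycle-1 row matches a hand-built matrix", {
  inp <- fix_inputs
  q <- inp$life_table$qx[inp$life_table$age == 56]
  dH <- 1 - (1 - q)^(0.5 * 2.43)
  sae <- min(inp$sae_prob, 1 - dH)
  tp_h2m <- 1 - exp(1.61 * (0 - 1^1.08))
  tp_h2r <- 1 - exp(0.05 * (0 - 1))
  h2m <- min(tp_h2m, 1 - dH - sae)
  h2r <- min(tp_h2r, 1 - dH - sae - h2m)
  M <- build_transition_matrix(inp, "SoC", cycle_index = 1)
  row <- M["H_soc_act", ]
  expect_equal(unname(row["death"]), dH, tolerance = 1e-12)
  expect_equal(unname(row["H_soc_sae"]), sae, tolerance = 1e-12)
  expect_equal(unname(row["M_soc_act"]), h2m, tolerance = 1e-12)
  expect_equal(unname(row["R_soc_act"]), h2r, tolerance = 1e-12)
  expect_equal(unname(row["H_soc_act"]), 1 - dH - sae - h2m - h2r,
               tolerance = 1e-12)
  expect_equal(sum(row), 1, tolerance = 1e-12)
  # intervention rows scale response transitions by the relative risks
  rr <- strategy_rr(inp, "bsIFXi")
  Mi <- build_transition_matrix(inp, "bsIFXi", cycle_index = 1)
  sae_i <- min(inp$sae_prob * rr$sae, 1 - dH)
  h2m_i <- min(tp_h2m * rr$h2m, 1 - dH - sae_i)
  h2r_i <- min(tp_h2r * rr$h2r, 1 - dH - sae_i - h2m_i)
  expect_equal(unname(Mi["H_int_act", "R_int_act"]), h2r_i, tolerance = 1e-12)
  expect_equal(unname(Mi["H_int_act", "M_int_act"]), h2m_i, tolerance = 1e-12)
  # inadequate responders flow to the standard-of-care line, not back
  expect_equal(unname(Mi["H_int_act", "H_int_act"]), 0)
  expect_equal(unname(Mi["H_int_act", "H_soc_act"]),
               1 - dH - sae_i - h2m_i - h2r_i, tolerance = 1e-12)
})

test_that("with switch_after = 2 failing patients get a second novel-regimen cycle", {
  # moderate the very fast high-to-moderate/low transition so that a
  # non-trivial fraction actually fails the first cycle
  inp <- fix_inputs
  inp$specs$H2M$lam <- 0.3
  inp$settings$switch_after <- 2
  M <- build_transition_matrix(inp, "bsIFXi", cycle_index = 1)
  expect_gt(M["H_int_act", "H_int_act2"], 0)
  expect_equal(unname(M["H_int_act", "H_soc_act"]), 0)
  expect_gt(M["H_int_act2", "H_soc_act"], 0)
  inp$settings$switch_after <- 1
  M1 <- build_transition_matrix(inp, "bsIFXi", cycle_index = 1)
  expect_equal(unname(M1["H_int_act", "H_int_act2"]), 0)
  expect_gt(M1["H_int_act", "H_soc_act"], 0)
})

test_that("cohort traces conserve mass with monotone, eventually complete death", {
  for (sg in c("SoC", "bsIFXi")) {
    ct <- run_cohort(fix_inputs, sg)
    expect_lt(max(abs(rowSums(ct$trace) - 1)), 1e-12)
    dead <- ct$trace[, "death"]
    expect_true(all(diff(dead) >= -1e-15))
    expect_lt(1 - dead[length(dead)], 1e-6)  # terminal life-table row
    expect_true(all(ct$trace >= 0))
  }
})

test_that("an all-to-death matrix empties the cohort in one cycle", {
  inp <- fix_inputs
  inp$life_table <- data.frame(age = 35:120, qx = 1)
  ct <- run_cohort(inp, "SoC", horizon_cycles = 1)
  expect_equal(unname(ct$trace[2, "death"]), 1)
})

test_that("higher mortality hazard ratio lowers survival at every cycle", {
  inp1 <- fix_inputs; inp1$hr_high <- 1
  ct1 <- run_cohort(inp1, "SoC", horizon_cycles = 80)
  ct2 <- run_cohort(fix_inputs, "SoC", horizon_cycles = 80)
  alive1 <- 1 - ct1$trace[-1, "death"]
  alive2 <- 1 - ct2$trace[-1, "death"]
  expect_true(all(alive1 > alive2))
})

test_that("null-effect intervention reproduces the standard-of-care health occupancy", {
  inp <- null_effect_inputs(fix_inputs_short)
  h_int <- health_occupancy(run_cohort(inp, "bsIFXi"))
  h_soc <- health_occupancy(run_cohort(inp, "SoC"))
  expect_equal(h_int, h_soc, tolerance = 1e-12)
})

test_that("cohort propagation agrees with an individual-level microsimulation", {
  n_paths <- 20000
  n_cycles <- 12
  for (sg in c("SoC", "bsIFXi")) {
    ct <- run_cohort(fix_inputs, sg, horizon_cycles = n_cycles)
    sim <- microsimulate(fix_inputs, sg, n_paths, n_cycles, seed = 99)
    p <- ct$trace
    expect_true(all(abs(sim - p) <= microsim_bound(p, sim, n_paths)))
  }
})

test_that("traces serialize to a delimited table with cycle and age columns", {
  ct <- run_cohort(fix_inputs, "SoC", horizon_cycles = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_trace(ct, path)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), 5)
  expect_equal(df$age, 56 + (0:4) * 0.5)
  expect_equal(unname(as.matrix(df[, ra_states()])), unname(ct$trace),
               tolerance = 1e-9)
})
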