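test_that("discounting follows the annual rate on the half-year grid", {
  st <- economic_settings()
  expect_equal(discount_factor(0, st), 1)
  expect_equal(discount_factor(2, st), 1 / 1.03, tolerance = 1e-12)
  st0 <- economic_settings(annual_discount_rate = 0)
  expect_equal(discount_factor(0:10, st0), rep(1, 11))
  expect_error(discount_factor(-1, st), "non-negative")
})

test_that("per-cycle state costs assemble the published components", {
  inp <- fix_inputs
  # high activity on SoC+MTX, first cycle with screening:
  # 18,700 + 6 * (78 + 451.52) + 2,309.02
  expect_equal(cycle_cost("H_soc_act", inp, "SoC", 0, is_regimen_start = TRUE),
               18700 + 6 * (78 + 451.52) + 2309.02, tolerance = 1e-9)
  expect_equal(cycle_cost("death", inp, "SoC"), 0)
  # adverse-event interruption: admission cost plus visits, no drug cost
  expect_equal(cycle_cost("H_soc_sae", inp, "SoC", 1, is_sae_entry = TRUE),
               36070 + 6 * (78 + 451.52), tolerance = 1e-9)
  # remission taper runs on the MTX-only assumption cost with 1 visit
  expect_equal(cycle_cost("R_soc_taper", inp, "SoC", 3),
               inp$costs$mtx_only + 1 * (78 + 451.52), tolerance = 1e-9)
  # infliximab-type loading: 5 infusions in cycle 0, 3 in maintenance
  c0 <- cycle_cost("H_int_act", inp, "bsIFXi", 0)
  c1 <- cycle_cost("H_int_act", inp, "bsIFXi", 1)
  expect_equal(c0 - c1, 2 * 31)
  expect_equal(c1, 68000 + 6 * (78 + 451.52) + 3 * 31, tolerance = 1e-9)
  # rituximab-type: 2 infusions every cycle
  expect_equal(infusion_visits(inp, "RTX", first_cycle = TRUE), 2)
  expect_equal(infusion_visits(inp, "ETA"), 0)
  expect_error(cycle_cost("H_int_act", inp, "XYZ"), "unknown regimen")
})

test_that("per-cycle QALYs are utility times cycle length", {
  inp <- fix_inputs
  expect_equal(cycle_qaly("R_soc_act", inp), 0.93 * 0.5)
  expect_equal(cycle_qaly("R_int_taper", inp), 0.93 * 0.5)
  expect_equal(cycle_qaly("H_int_sae", inp), 0.79 * 0.5)
  expect_equal(cycle_qaly("death", inp), 0)
  perfect <- inp; perfect$utilities[["REMISSION"]] <- 1
  expect_equal(cycle_qaly("R_soc_act", perfect), 0.5)
})

test_that("lifetime aggregation matches an independent accumulation", {
  for (sg in c("SoC", "bsIFXi", "RTX")) {
    ct <- run_cohort(fix_inputs_short, sg)
    res <- aggregate_strategy(ct, fix_inputs_short)
    oracle <- accumulate_independent(ct, fix_inputs_short)
    expect_equal(res$cost, oracle$cost, tolerance = 1e-9)
    expect_equal(res$qalys, oracle$qalys, tolerance = 1e-9)
    expect_equal(res$life_years, oracle$life_years, tolerance = 1e-9)
  }
})

test_that("degenerate traces aggregate to closed-form totals", {
  # all dead after cycle 0: only cycle-0 amounts accrue
  inp <- fix_inputs
  inp$life_table <- data.frame(age = 35:120, qx = 1)
  ct <- run_cohort(inp, "SoC", horizon_cycles = 5)
  res <- aggregate_strategy(ct, inp)
  expect_equal(res$cost,
               cycle_cost("H_soc_act", inp, "SoC", 0, is_regimen_start = TRUE),
               tolerance = 1e-9)
  expect_equal(res$qalys, 0.79 * 0.5, tolerance = 1e-12)
  # immortal cohort, frozen state, r = 0: N times the per-cycle amount
  inp2 <- fix_inputs
  for (lab in transition_labels()) inp2$specs[[lab]]$lam <- 1e-300
  inp2$sae_prob <- 0
  inp2$life_table <- zero_mortality_table()
  inp2$settings <- economic_settings(annual_discount_rate = 0, horizon_cycles = 20)
  ct2 <- run_cohort(inp2, "SoC")
  res2 <- aggregate_strategy(ct2, inp2)
  per_cycle <- cycle_cost("H_soc_act", inp2, "SoC", 1)
  expect_equal(res2$cost, 20 * per_cycle + inp2$costs$screening, tolerance = 1e-9)
  expect_equal(res2$qalys, 20 * 0.79 * 0.5, tolerance = 1e-12)
  expect_equal(res2$life_years, 10, tolerance = 1e-12)
})

test_that("incremental comparison flags dominance and computes the ICER", {
  mk <- function(cost, qalys) list(cost = cost, qalys = qalys)
  cmp <- compare_strategies(mk(346728, 5.3), mk(246728, 4.8))
  expect_equal(cmp$inc_cost, 1e5)
  expect_equal(cmp$icer, 1e5 / 0.5)
  # published pair: biosimilar infliximab (Ixifi) vs standard of care
  pair <- compare_strategies(mk(797714, 5.05), mk(246728, 4.80))
  expect_equal(pair$inc_cost, 550986)
  dom <- compare_strategies(mk(-1 + 100, 1.1), mk(100, 1.0))
  expect_true(dom$dominant)
  expect_false(dom$dominated)
  dtd <- compare_strategies(mk(200, 1.0), mk(100, 1.0))
  expect_true(dtd$dominated)
  expect_true(dtd$icer_undefined)
  expect_true(is.na(dtd$icer))
  # antisymmetry under argument swap
  a <- mk(500, 2); b <- mk(300, 1.5)
  ab <- compare_strategies(a, b); ba <- compare_strategies(b, a)
  expect_equal(ab$inc_cost, -ba$inc_cost)
  expect_equal(ab$inc_qalys, -ba$inc_qalys)
})

test_that("currency conversion uses the 2022 exchange rate and round-trips", {
  st <- economic_settings()
  expect_equal(thb_to_usd(160000, st), 4634)
  expect_equal(thb_to_usd(0, st), 0)
  expect_equal(thb_to_usd(246728, st), 7145)
  for (x in c(1, 7, 100, 4634, 99999)) {
    expect_equal(thb_to_usd(x * 34.53, st), x)
  }
  expect_error(thb_to_usd(Inf, st), "finite")
})

test_that("undiscounted totals dominate discounted ones and QALYs stay below life years", {
  bc <- run_base_case(fix_inputs_short, strategies = c("SoC", "bsIFXi", "GOL"))
  expect_true(all(bc$cost_undiscounted > bc$cost))
  expect_true(all(bc$qalys_undiscounted > bc$qalys))
  expect_true(all(bc$qalys < bc$life_years))
  expect_true(all(bc$qalys_undiscounted < bc$life_years_undiscounted))
})

test_that("raising a drug price raises that strategy's cost and ICER only", {
  base <- run_base_case(fix_inputs_short, strategies = c("SoC", "bsIFXi", "ETA"))
  up <- set_parameter(fix_inputs_short, "drug_cost_bsIFXi",
                      1.5 * fix_inputs_short$costs$drug$bsIFXi)
  bumped <- run_base_case(up, strategies = c("SoC", "bsIFXi", "ETA"))
  i <- function(df, sg, col) df[df$strategy == sg, col]
  expect_gt(i(bumped, "bsIFXi", "cost"), i(base, "bsIFXi", "cost"))
  expect_gt(i(bumped, "bsIFXi", "icer"), i(base, "bsIFXi", "icer"))
  expect_equal(i(bumped, "ETA", "cost"), i(base, "ETA", "cost"))
  expect_equal(i(bumped, "SoC", "cost"), i(base, "SoC", "cost"))
})

test_that("the half-cycle correction averages adjacent occupancy rows", {
  inp <- fix_inputs_short
  inp$settings$half_cycle <- TRUE
  ct <- run_cohort(inp, "SoC")
  res_hc <- aggregate_strategy(ct, inp)
  res <- aggregate_strategy(ct, fix_inputs_short)
  # with positive mortality the mid-cycle cohort is smaller than at cycle start
  expect_lt(res_hc$life_years, res$life_years)
  expect_lt(res_hc$qalys, res$qalys)
})
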