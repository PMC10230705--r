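# Shared fixtures: built once per test run. The default bundle reproduces
# the published point estimates with the synthetic life table and efficacy
# table at the master seed; the short-horizon variant keeps property tests
# cheap.

fix_inputs <- ra_model_inputs()

fix_inputs_short <- ra_model_inputs(
  settings = economic_settings(horizon_cycles = 60))

# inputs in which every intervention relative risk is exactly 1
null_effect_inputs <- function(inputs = fix_inputs) {
  eff <- inputs$efficacy
  for (col in grep("^rr_", names(eff), value = TRUE)) eff[[col]] <- 1
  inputs$efficacy <- eff
  inputs
}

# life table with zero mortality over a wide age span (no terminal row)
zero_mortality_table <- function(age_max = 260) {
  data.frame(age = 35:age_max, qx = 0)
}
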