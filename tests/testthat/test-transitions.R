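test_that("constant-hazard special case reproduces the analytic rate MLE", {
  # 10 events over 200 person-cycles of exposure: rate MLE = 10/200 = 0.05
  h <- data.frame(
    patient_id = sprintf("P%03d", 1:200),
    transition_label = "H2R",
    time_at_risk = 1,
    event = c(rep(1L, 10), rep(0L, 190)))
  fit <- fit_weibull_ph(h, shape_fixed = 1)
  expect_equal(exp(fit$constant), 0.05, tolerance = 1e-6)
  expect_equal(fit$shape, 1)
  expect_equal(lambda_from_linear_predictor(fit), 0.05, tolerance = 1e-6)
})

test_that("lambda from the linear predictor matches the closed form", {
  f1 <- list(constant = -2.92, coefficients = stats::setNames(numeric(0), character(0)))
  expect_equal(lambda_from_linear_predictor(f1), exp(-2.92), tolerance = 1e-12)
  expect_equal(round(lambda_from_linear_predictor(f1), 2), 0.05)  # printed value

  f2 <- list(constant = -0.22, coefficients = stats::setNames(numeric(0), character(0)))
  expect_equal(round(lambda_from_linear_predictor(f2), 2), 0.80)  # printed value

  f3 <- list(constant = 1.55, coefficients = c(disease_duration = -0.08))
  expect_equal(lambda_from_linear_predictor(f3, list(disease_duration = 14)),
               exp(0.43), tolerance = 1e-12)
  expect_error(lambda_from_linear_predictor(f3),
               "disease_duration")
})

test_that("per-cycle transition probability matches hand evaluation", {
  s1 <- transition_spec("H2R", lam = 0.05, shape = 1)
  expect_equal(transition_probability(s1, t = 3, u = 0), 0)
  expect_equal(transition_probability(s1, t = 3, u = 1),
               1 - exp(-0.05), tolerance = 1e-12)
  s2 <- transition_spec("M2H", lam = 0.25, shape = 0.5)
  expect_equal(transition_probability(s2, t = 4, u = 1),
               1 - exp(0.25 * sqrt(3) - 0.25 * 2), tolerance = 1e-12)
  expect_error(transition_probability(s1, t = 0.5, u = 1), "t must be at least u")
})

test_that("transition probability equals the survival ratio and is monotone", {
  surv <- function(lam, gam, t) exp(-lam * t^gam)
  tgrid <- seq(1, 100, length.out = 1000)
  for (pars in list(c(1.61, 1.08), c(0.05, 1), c(0.25, 0.5), c(0.8, 0.96))) {
    sp <- transition_spec("H2M", pars[1], pars[2])
    tp <- transition_probability(sp, tgrid, u = 1)
    ratio <- surv(pars[1], pars[2], tgrid) / surv(pars[1], pars[2], tgrid - 1)
    expect_equal(1 - tp, ratio, tolerance = 1e-12)
  }
  # gamma = 1: independent of t, equals 1 - exp(-lam * u)
  s1 <- transition_spec("H2R", 0.05, 1)
  tps <- transition_probability(s1, t = c(1, 7, 50), u = 1)
  expect_equal(tps, rep(1 - exp(-0.05), 3), tolerance = 1e-14)
  # non-decreasing in lam and in u
  lams <- seq(0.01, 2, length.out = 50)
  p_lam <- vapply(lams, function(l)
    transition_probability(transition_spec("H2M", l, 1.2), t = 5, u = 1),
    numeric(1))
  expect_true(all(diff(p_lam) >= 0))
  us <- seq(0, 3, length.out = 40)
  p_u <- vapply(us, function(u)
    transition_probability(transition_spec("H2M", 0.4, 0.7), t = 5, u = u),
    numeric(1))
  expect_true(all(diff(p_u) >= 0))
  expect_true(all(p_lam >= 0 & p_lam <= 1))
})

test_that("maximum-likelihood fitting recovers generating parameters within 3 SE", {
  cfg <- synthetic_config(
    n_patients = 2000,
    transitions = list(R2M = list(constant = log(0.8), coefficients = NULL,
                                  shape = 1.2)),
    censoring = 0.2, seed = 714)
  h <- gen_patient_histories(cfg)
  fit <- fit_weibull_ph(h)
  expect_lt(abs(fit$constant - log(0.8)), 3 * fit$standard_errors[["constant"]])
  shape_se_log <- fit$standard_errors[["shape"]] / fit$shape
  expect_lt(abs(log(fit$shape) - log(1.2)), 3 * shape_se_log)
})

test_that("the disease-duration coefficient is recovered within 3 SE", {
  cfg <- synthetic_config(
    n_patients = 5000,
    transitions = list(H2M = list(constant = 1.55,
                                  coefficients = c(disease_duration = -0.08),
                                  shape = 1.08)),
    censoring = 0.2, seed = 714)
  h <- gen_patient_histories(cfg)
  fit <- fit_weibull_ph(h, covariates = "disease_duration")
  co <- fit$coefficients[["disease_duration"]]
  se <- fit$standard_errors[["disease_duration"]]
  expect_lt(abs(co - (-0.08)), 3 * se)
})

test_that("degenerate event histories are rejected with clear errors", {
  base <- data.frame(patient_id = c("a", "b"), transition_label = "H2R",
                     time_at_risk = c(2, 3), event = c(0L, 0L))
  expect_error(fit_weibull_ph(base), "no events")
  one <- base; one$event <- c(1L, 0L)
  expect_error(fit_weibull_ph(one), "at least 2")
  mixed <- data.frame(patient_id = c("a", "b"), transition_label = c("H2R", "M2H"),
                      time_at_risk = c(2, 3), event = c(1L, 1L))
  expect_error(fit_weibull_ph(mixed), "one transition_label")
  zero <- data.frame(patient_id = "a", transition_label = "H2R",
                     time_at_risk = 0, event = 1L)
  expect_error(validate_event_histories(zero), "zero time_at_risk")
  badlab <- data.frame(patient_id = "a", transition_label = "X2Y",
                       time_at_risk = 1, event = 1L)
  expect_error(validate_event_histories(badlab), "unknown transition label")
})

test_that("event histories and fit summaries round-trip through files", {
  cfg <- synthetic_config(n_patients = 30, seed = 11)
  h <- gen_patient_histories(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_histories(h, path)
  h2 <- read_event_histories(path)
  expect_equal(h2$time_at_risk, h$time_at_risk, tolerance = 1e-9)
  expect_identical(h2$transition_label, h$transition_label)

  fit <- fit_weibull_ph(h[h$transition_label == "R2M", ])
  out <- withr::local_tempfile(fileext = ".txt")
  write_weibull_fits(list(fit), out)
  txt <- readLines(out)
  expect_true(any(grepl("constant_baseline_hazard", txt)))
  expect_true(any(grepl("ancillary_shape", txt)))
})
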