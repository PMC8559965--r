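test_that("phase-plane classification matches the region definitions", {
  p <- base_params
  expect_identical(classify_region(10, 2, p), "Tt")
  expect_identical(classify_region(2, 10, p), "Ta")
  expect_identical(classify_region(10, 10, p), "neither")
  expect_identical(classify_region(2, 2, p), "neither")
  expect_identical(classify_region(8, 10, p), "neither")  # on the threshold
  # indicator and region agree everywhere: I_apop = 1 <=> Ta
  set.seed(3)
  B <- runif(200, 0, 16); X <- runif(200, 0, 16)
  expect_equal(apoptosis_indicator(B, X, p) == 1,
               classify_region(B, X, p) == "Ta")
})

test_that("dose-response curves are pointwise equilibria with a refined crossing", {
  Tg <- seq(0, 1, by = 0.1)
  dr <- dose_response_curve(base_params, Tg, S_fixed = 0.25, A_fixed = 5)
  for (i in c(1, 4, 11)) {
    eq <- intracellular_equilibrium(base_params, S = 0.25, A = 5, T = Tg[i])
    expect_equal(dr$B_star[i], eq$B_star)
    expect_equal(dr$X_star[i], eq$X_star)
  }
  expect_true(all(diff(dr$B_star) <= 0))
  expect_true(all(diff(dr$X_star) >= 0))
  expect_equal(attr(dr, "crossing_dose"), 0.25, tolerance = 1e-3)
  # without TZB inhibition of Bcl-2 there is no crossing
  dr0 <- dose_response_curve(parameter_set(delta = 0), Tg,
                             S_fixed = 0.25, A_fixed = 5)
  expect_true(is.na(attr(dr0, "crossing_dose")))
  expect_equal(diff(range(dr0$B_star)), 0)
  expect_error(dose_response_curve(base_params, numeric(0)), "empty")
  expect_error(dose_response_curve(base_params, c(1, 0.5)), "increasing")
})

test_that("apoptosis persistence is the exact measure of the switched-on set", {
  tt <- seq(0, 960, by = 1)
  sim0 <- make_fake_sim(tt, flat_states(length(tt)))
  expect_equal(apoptosis_persistence(sim0), 0)
  ia <- as.numeric(tt >= 5 * 24 & tt < 25 * 24)
  sim1 <- make_fake_sim(tt, flat_states(length(tt)), I_apop = ia)
  expect_equal(apoptosis_persistence(sim1), 20)
  # under the periodic ATV protocol persistence grows with the dose
  lo <- simulate_model(base_params,
                       periodic_protocol("ATV", 0.05, 4, basal_level = 1))
  hi <- simulate_model(base_params,
                       periodic_protocol("ATV", 2, 4, basal_level = 1))
  expect_gte(apoptosis_persistence(hi), apoptosis_persistence(lo))
})

test_that("efficacy metrics are reciprocal scales with exact weighting", {
  tt <- seq(0, 720, by = 24)
  s1 <- make_fake_sim(tt, flat_states(length(tt), C = 0.2, L = 10))
  s2 <- make_fake_sim(tt, flat_states(length(tt), C = 0.4, L = 10))
  e1 <- efficacy_metrics(s1, t_eval_days = 30, f_T = 1, f_c = 5)
  e2 <- efficacy_metrics(s2, t_eval_days = 30, f_T = 1, f_c = 5)
  expect_equal(e1$E_T, 2 * e2$E_T)        # doubling C halves E_T
  expect_equal(e1$E_c, 0.5)
  expect_equal(e1$E_total, 0.5 * e1$E_T + 0.5 * e1$E_c)  # omega = 1/2: mean
  # for any weights E_total lies between the two component efficacies
  for (w in c(0, 0.3, 0.8, 1)) {
    p <- parameter_set(omega_1 = w, omega_2 = 1 - w)
    e <- efficacy_metrics(s1, params = p, t_eval_days = 30, f_T = 1, f_c = 5)
    expect_gte(e$E_total, min(e$E_T, e$E_c) - 1e-12)
    expect_lte(e$E_total, max(e$E_T, e$E_c) + 1e-12)
  }
  s0 <- make_fake_sim(tt, flat_states(length(tt), C = 0, L = 10))
  expect_error(efficacy_metrics(s0, t_eval_days = 30, f_T = 1, f_c = 1),
               "positive")
})

test_that("percent change compares runs at the evaluation time", {
  tt <- seq(0, 720, by = 24)
  ref <- make_fake_sim(tt, flat_states(length(tt), L = 40))
  same <- make_fake_sim(tt, flat_states(length(tt), L = 40))
  half <- make_fake_sim(tt, flat_states(length(tt), L = 20))
  expect_equal(percent_change(ref, same, "L", 30), 0)
  expect_equal(percent_change(ref, half, "L", 30), 50)
  zero <- make_fake_sim(tt, flat_states(length(tt), L = 0))
  expect_error(percent_change(zero, ref, "L", 30), "zero")
})

test_that("efficacy dose families reproduce the bell and ordering shapes", {
  # combination family (A = 5) and single-therapy family (A = 0) at 30 days
  doses <- c(0, 0.6, 1.0, 4.0)
  run30 <- function(Tl, Al) simulate_model(
    base_params, constant_protocol(Tl, Al, 30), rtol = 1e-6, atol = 1e-8)
  combo <- lapply(doses, run30, Al = 5)
  single <- lapply(doses, run30, Al = 0)
  sc <- default_efficacy_scales(base_params, 30)
  effs <- vapply(combo, function(s)
    efficacy_metrics(s, t_eval_days = 30, f_T = sc$f_T, f_c = sc$f_c)$E_T, 0)
  # anti-tumor efficacy peaks at an interior dose of the combination family
  expect_gt(max(effs[2:3]), effs[1])
  expect_gt(max(effs[2:3]), effs[4])
  # anti-CRCC efficacy decreases with dose and is uniformly larger under the
  # combination than under single therapy
  Ec_c <- vapply(combo, function(s)
    efficacy_metrics(s, t_eval_days = 30, f_T = sc$f_T, f_c = sc$f_c)$E_c, 0)
  Ec_s <- vapply(single, function(s)
    efficacy_metrics(s, t_eval_days = 30, f_T = sc$f_T, f_c = sc$f_c)$E_c, 0)
  expect_true(all(diff(Ec_c) < 0))
  expect_true(all(diff(Ec_s) < 0))
  expect_true(all(Ec_c > Ec_s))
  # the scale convention: E_c = 1 for the combination arm at T = 0
  expect_equal(Ec_c[1], 1, tolerance = 1e-6)
})
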