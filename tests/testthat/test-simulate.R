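test_that("event times collect span, window and CSC breakpoints", {
  prot <- constant_protocol(0, 0, 40)
  expect_equal(event_times(prot, base_params), c(0, 480, 600, 960))
  prot2 <- periodic_protocol("ATV", 2, period_days = 4, duration_days = 1,
                             n_injections = 10, horizon_days = 40)
  ev <- event_times(prot2, base_params)
  w <- prot2$ATV$windows
  # every span endpoint, CSC endpoint and window edge is present ...
  expect_true(all(c(0, 960, 480, 600, w$start_h,
                    w$start_h + w$duration_h) %in% ev))
  # ... exactly once (edges coinciding with CSC endpoints collapse)
  expect_equal(length(ev),
               length(unique(c(0, 960, 480, 600, w$start_h,
                               w$start_h + w$duration_h))))
  expect_true(all(diff(ev) > 0))
  # coincident edges collapse to one breakpoint
  prot3 <- periodic_protocol("ATV", 2, period_days = 20, duration_days = 5,
                             n_injections = 2, horizon_days = 40)
  ev3 <- event_times(prot3, base_params)  # window edge at 600 h == csc_off
  expect_equal(sum(abs(ev3 - 600) < 1e-9), 1L)
})

test_that("a fully silent system stays identically zero", {
  p <- parameter_set(lambda_F = 0, lambda_B = 0, lambda_X = 0, lambda_L = 0,
                     lambda_1 = 0, lambda_2 = 0, lambda_3 = 0, k3 = 0,
                     k5 = 0, k7 = 0, beta = 0, r = 0, delta = 0, gamma = 0)
  init <- c(F = 0, B = 0, X = 0, C = 0, S = 0, L = 0)
  sim <- simulate_model(p, constant_protocol(0, 0, 10), init = init)
  expect_true(all(sim$states == 0))
})

test_that("solutions converge under tolerance refinement on all four arms", {
  arms <- list(c(0, 0), c(0, 5), c(1, 0), c(1, 5))
  for (lv in arms) {
    prot <- constant_protocol(lv[1], lv[2], 40)
    a <- simulate_model(base_params, prot, rtol = 1e-8, atol = 1e-10)
    b <- simulate_model(base_params, prot, rtol = 1e-10, atol = 1e-12)
    fa <- a$states[nrow(a$states), ]
    fb <- b$states[nrow(b$states), ]
    expect_lt(max(abs(fa - fb) / pmax(abs(fb), 1e-8)), 1e-6)
  }
})

test_that("event-split integration matches a brute-force fixed-step RK4", {
  # 5-day window of the clamped TZB arm, which contains an apoptosis switch
  p <- base_params
  prot <- constant_protocol(1, 0, 5)
  sim <- simulate_model(p, prot, t_span = c(0, 120))
  y <- c(default_initial_state()[c("F", "B", "X", "C", "S", "L")],
         A = 0, T = 1)
  y <- y[c("F", "B", "X", "C", "S", "L", "A", "T")]
  dt <- 0.01
  for (k in seq_len(120 / dt)) {
    t0 <- (k - 1) * dt
    k1 <- oracle_rhs(t0, y, p)
    k2 <- oracle_rhs(t0 + dt / 2, y + dt / 2 * k1, p)
    k3 <- oracle_rhs(t0 + dt / 2, y + dt / 2 * k2, p)
    k4 <- oracle_rhs(t0 + dt, y + dt * k3, p)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  fin <- sim$states[nrow(sim$states), ]
  expect_lt(max(abs(fin - y) / pmax(abs(y), 1e-8)), 1e-4)
})

test_that("trajectories stay nonnegative across random parameter draws", {
  set.seed(7)
  for (i in 1:12) {
    fac <- stats::runif(8, 0.3, 2)
    p <- parameter_set(lambda_2 = base_params$lambda_2 * fac[1],
                       delta = base_params$delta * fac[2],
                       gamma = base_params$gamma * fac[3],
                       r = base_params$r * fac[4],
                       lambda_1 = base_params$lambda_1 * fac[5],
                       mu_C = base_params$mu_C * fac[6],
                       k2 = base_params$k2 * fac[7],
                       k3 = base_params$k3 * fac[8])
    Tl <- sample(c(0, 1), 1); Al <- sample(c(0, 5), 1)
    sim <- simulate_model(p, constant_protocol(Tl, Al, 10),
                          rtol = 1e-6, atol = 1e-8)
    expect_true(all(sim$states >= 0))
    expect_true(all(sim$indicators %in% c(0, 1)))
  }
})

test_that("CSC density grows only inside the activation window", {
  sim <- simulate_model(base_params, constant_protocol(1, 0, 40))
  S <- sim$states[, "S"]
  t <- sim$times
  expect_true(all(diff(S) >= -1e-12))          # non-decreasing
  before <- t <= base_params$csc_on
  after <- t >= base_params$csc_off
  expect_equal(diff(range(S[before])), 0)
  expect_equal(diff(range(S[after])), 0)
  expect_gt(S[length(S)], S[1])
})

test_that("the TZB-alone arm switches into apoptosis once and permanently out", {
  sim <- simulate_model(base_params, constant_protocol(1, 0, 40))
  ia <- sim$indicators[, "I_apop"]
  sw <- sim$events[sim$events$kind == "apoptosis_switch", "time"]
  expect_length(sw, 2L)                    # one entry, one exit
  expect_lt(sw[1], base_params$csc_on)     # enters Ta before the CSC window
  expect_gt(sw[2], base_params$csc_on)     # exits after IL-6 rises
  expect_true(all(ia[sim$times > sw[2]] == 0))   # never re-enters
  # the switch matches the phase-plane region along the trajectory; at the
  # switch instants themselves the state sits on a threshold, where the
  # strict region is "neither" while the hybrid mode is one-sided
  reg <- classify_region(sim$states[, "B"], sim$states[, "X"], base_params)
  off_switch <- vapply(sim$times,
                       function(t) all(abs(t - sw) > 1e-3), TRUE)
  expect_equal((ia == 1)[off_switch], (reg == "Ta")[off_switch])
})

test_that("per-step indicator mode agrees with event-resolved switching", {
  prot <- constant_protocol(1, 5, 30)
  a <- simulate_model(base_params, prot)
  b <- simulate_model(base_params, prot, apoptosis_mode = "per-step")
  fa <- a$states[nrow(a$states), ]
  fb <- b$states[match(max(a$times), b$times), ]
  expect_lt(max(abs(fa - fb) / pmax(abs(fa), 1e-8)), 1e-5)
})

test_that("simulations export a tidy table and a JSON manifest", {
  sim <- simulate_model(base_params, constant_protocol(1, 5, 2))
  df <- as.data.frame(sim)
  expect_named(df, c("time_h", "time_d", "F", "B", "X", "C", "S", "L",
                     "A", "T", "I_apop", "I_s"))
  csv <- tempfile(fileext = ".csv")
  man <- tempfile(fileext = ".json")
  write_simulation(sim, csv, man)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(nrow(back), length(sim$times))
  j <- jsonlite::read_json(man)
  expect_equal(j$rtol, sim$rtol)
  expect_equal(j$params$k2, base_params$k2)
})
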