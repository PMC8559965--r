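test_that("apoptosis indicator uses strict threshold inequalities", {
  p <- base_params # th_B = th_X = 8
  expect_identical(apoptosis_indicator(7.9, 8.1, p), 1)
  expect_identical(apoptosis_indicator(9, 9, p), 0)
  expect_identical(apoptosis_indicator(8, 8, p), 0)   # boundary excluded
  expect_identical(apoptosis_indicator(7.9, 7.9, p), 0)
  expect_identical(apoptosis_indicator(c(7.9, 9), c(8.1, 9), p), c(1, 0))
})

test_that("CSC activation window is left-open, right-closed", {
  p <- base_params
  expect_identical(csc_indicator(22 * 24, p), 1)
  expect_identical(csc_indicator(20 * 24, p), 0)  # left endpoint excluded
  expect_identical(csc_indicator(25 * 24, p), 1)  # right endpoint included
  expect_identical(csc_indicator(26 * 24, p), 0)
})

test_that("right-hand side reduces correctly in analytic limits", {
  # sources off, feedbacks off: only the Bcl-2 autocatalytic term remains
  p <- parameter_set(lambda_F = 0, lambda_B = 0, lambda_X = 0,
                     lambda_2 = 0, lambda_3 = 0, lambda_L = 0,
                     lambda_1 = 0, k3 = 0, k7 = 0, beta = 0,
                     delta = 0, gamma = 0, r = 0)
  prot <- constant_protocol(0, 0, 10)
  st <- c(F = 0, B = 1, X = 0, C = 0, S = 0, L = 0, A = 0, T = 0)
  d <- full_rhs(st, t = 5, p, prot)
  expect_equal(unname(d["B"]), p$k5 - p$mu_B * 1)
  expect_equal(unname(d[setdiff(names(d), "B")]), rep(0, 7))

  # logistic fixed point: C = K with no CSC seeding and no killing
  st2 <- c(F = 0, B = 10, X = 0, C = base_params$K, S = 0, L = 0,
           A = 0, T = 0)
  d2 <- full_rhs(st2, t = 5, base_params, prot)
  expect_equal(unname(d2["C"]), 0)

  st_neg <- st
  st_neg["F"] <- -1
  expect_error(full_rhs(st_neg, 5, base_params, prot), "negative")
})

test_that("right-hand side matches an independent term-by-term evaluation", {
  # mid-simulation-like state under the clamped TZB arm at t = 10 days
  p <- base_params
  st <- c(F = 3.2, B = 6.8, X = 9.4, C = 0.4, S = 0.25, L = 21.5,
          A = 0, T = 1)
  got <- full_rhs(st, t = 240, p, constant_protocol(1, 0, 40))
  expect_equal(got, oracle_rhs(240, st, p), tolerance = 1e-14)
  # inside the CSC window the S equation switches on
  st_w <- c(st, A = 0)[names(st)]
  got_w <- full_rhs(st_w, t = 21 * 24, p, constant_protocol(1, 0, 40))
  expect_equal(got_w, oracle_rhs(21 * 24, st_w, p), tolerance = 1e-14)
  expect_equal(unname(got_w["S"]), p$beta * 1)
})

test_that("closed-form equilibrium matches its decoupled and saturation limits", {
  p <- parameter_set(lambda_2 = 0, delta = 0, gamma = 0)
  eq <- intracellular_equilibrium(p, S = 0.25)
  Fs <- p$lambda_F / p$mu_F
  expect_equal(eq$F_star, Fs)
  expect_equal(eq$B_star, (p$lambda_B + p$lambda_3 * Fs + p$k5) / p$mu_B)
  expect_equal(eq$X_star, (p$lambda_X + p$k7) / p$mu_X)

  # very large TZB fully suppresses the autocatalytic Bcl-2 term
  eq_inf <- intracellular_equilibrium(base_params, S = 0.25, T = 1e9)
  expect_equal(eq_inf$B_star,
               (base_params$lambda_B + base_params$lambda_3 * eq_inf$F_star) /
                 base_params$mu_B, tolerance = 1e-6)
  expect_error(intracellular_equilibrium(parameter_set(), S = -1), ">= 0")
})

test_that("equilibrium agrees with long-time integration of the cascade", {
  # integration oracle: run the (L, F, B, X) cascade to steady state
  integrate_to_ss <- function(p, S, A, T) {
    rhs <- function(t, y, parms) {
      list(c(p$lambda_L + p$k3 * S / (p$k1 + p$k2 * A) - p$mu_L * y[1],
             p$lambda_F + p$lambda_2 * y[1] - p$mu_F * y[2],
             p$lambda_B + p$lambda_3 * y[2] +
               p$k5 * p$k4^2 / (p$k4^2 + p$delta * T^2) - p$mu_B * y[3],
             p$lambda_X + p$k7 * p$k6^2 / (p$k6^2 + p$gamma * y[3]^2) -
               p$mu_X * y[4]))
    }
    out <- deSolve::lsoda(c(1, 1, 1, 1), c(0, 4000), rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
    out[2, -1]
  }
  eq <- intracellular_equilibrium(base_params, S = 0.25, A = 0, T = 0.5)
  ss <- integrate_to_ss(base_params, 0.25, 0, 0.5)
  expect_equal(unname(ss),
               c(eq$L_star, eq$F_star, eq$B_star, eq$X_star),
               tolerance = 1e-6)
  # a handful of random operating points (the full 100-draw sweep is in the
  # acceptance suite)
  set.seed(42)
  for (i in 1:10) {
    S <- runif(1, 0, 1.5); A <- runif(1, 0, 10); T <- runif(1, 0, 4)
    eq <- intracellular_equilibrium(base_params, S = S, A = A, T = T)
    ss <- integrate_to_ss(base_params, S, A, T)
    expect_equal(unname(ss),
                 c(eq$L_star, eq$F_star, eq$B_star, eq$X_star),
                 tolerance = 1e-6)
  }
})

test_that("equilibrium dose monotonicity and decoupling properties hold", {
  Tg <- seq(0, 6, by = 0.25)
  eqs <- lapply(Tg, function(Td)
    intracellular_equilibrium(base_params, S = 0.25, A = 0, T = Td))
  B <- vapply(eqs, `[[`, 0, "B_star")
  X <- vapply(eqs, `[[`, 0, "X_star")
  expect_true(all(diff(B) <= 0))   # Bcl-2 non-increasing in TZB dose
  expect_true(all(diff(X) >= 0))   # BAX non-decreasing in TZB dose
  # X*(B*) non-increasing in B*
  expect_true(all(diff(X[order(B)]) <= 0))

  # with delta = 0 the Bcl-2 equilibrium ignores TZB
  p0 <- parameter_set(delta = 0)
  B0 <- vapply(Tg, function(Td)
    intracellular_equilibrium(p0, S = 0.25, T = Td)$B_star, 0)
  expect_equal(max(B0) - min(B0), 0)
  # with k2 = 0 the IL-6 equilibrium ignores ATV
  pk <- parameter_set(k2 = 0)
  L0 <- vapply(c(0, 2, 10, 40), function(Av)
    intracellular_equilibrium(pk, S = 0.25, A = Av)$L_star, 0)
  expect_equal(max(L0) - min(L0), 0)
})

test_that("cascade equilibria are locally stable with decay-rate eigenvalues", {
  for (Tv in c(0, 0.5, 2)) {
    eq <- intracellular_equilibrium(base_params, S = 0.25, A = 5, T = Tv)
    expect_identical(eq$stability, "stable")
    re <- sort(Re(eq$eigenvalues))
    # lower-triangular cascade Jacobian: eigenvalues are -mu_*
    expect_equal(re, sort(-c(base_params$mu_L, base_params$mu_F,
                             base_params$mu_B, base_params$mu_X)),
                 tolerance = 1e-10)
  }
})
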