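# shared fixtures: the working parameter set and a lightweight stand-in
# simulation object for response-analysis tests

base_params <- default_parameters()

# minimal object with the crcc_sim fields used by the response extractors
make_fake_sim <- function(times_h, states, I_apop = NULL,
                          params = base_params) {
  states <- as.matrix(states)
  if (is.null(I_apop)) I_apop <- rep(0, length(times_h))
  structure(list(times = times_h, states = states,
                 indicators = cbind(I_apop = I_apop,
                                    I_s = csc_indicator(times_h, params)),
                 events = data.frame(time = numeric(), kind = character()),
                 params_used = params,
                 protocol = constant_protocol(0, 0, max(times_h) / 24),
                 rtol = NA, atol = NA, mode = "events"),
            class = "crcc_sim")
}

# constant-state trajectory with the eight canonical columns
flat_states <- function(n, F = 0, B = 5, X = 0, C = 0.01, S = 0.25, L = 0,
                        A = 0, T = 0) {
  m <- matrix(rep(c(F, B, X, C, S, L, A, T), each = n), nrow = n)
  colnames(m) <- c("F", "B", "X", "C", "S", "L", "A", "T")
  m
}

# independent literal transcription of the model equations, used as the
# hand-evaluation oracle for derivative and brute-force integration tests
oracle_rhs <- function(t, y, p, uA = 0, uT = 0, clampA = TRUE,
                       clampT = TRUE) {
  Is <- if (t > p$csc_on && t <= p$csc_off) 1 else 0
  Ia <- if (y[["B"]] < p$th_B && y[["X"]] > p$th_X) 1 else 0
  c(F = p$lambda_F + p$lambda_2 * y[["L"]] - p$mu_F * y[["F"]],
    B = p$lambda_B + p$lambda_3 * y[["F"]] +
      p$k5 * p$k4^2 / (p$k4^2 + p$delta * y[["T"]]^2) - p$mu_B * y[["B"]],
    X = p$lambda_X + p$k7 * p$k6^2 / (p$k6^2 + p$gamma * y[["B"]]^2) -
      p$mu_X * y[["X"]],
    C = p$r * y[["C"]] * (1 - y[["C"]] / p$K) + p$lambda_1 * y[["S"]] -
      p$mu_C * (p$alpha / y[["B"]]) * y[["C"]] * Ia,
    S = p$beta * y[["T"]] * Is,
    L = p$lambda_L + p$k3 * y[["S"]] / (p$k1 + p$k2 * y[["A"]]) -
      p$mu_L * y[["L"]],
    A = if (clampA) 0 else uA - p$mu_A * y[["A"]],
    T = if (clampT) 0 else uT - p$mu_T * y[["T"]])
}
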