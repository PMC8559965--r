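#' Apoptosis indicator
#'
#' The switch gating tumor-cell killing: 1 iff the intracellular state lies
#' in the apoptotic region, `B < th_B` and `X > th_X` (strict inequalities;
#' points on the thresholds and the doubly-high/doubly-low quadrants give 0).
#'
#' @param B,X Bcl-2 and BAX levels (vectorized).
#' @param params a [parameter_set()].
#' @return 0/1 vector.
#' @export
apoptosis_indicator <- function(B, X, params) {
  as.numeric(B < params$th_B & X > params$th_X)
}

#' CSC activation indicator
#'
#' Cancer stem cells are produced by trastuzumab only during the activation
#' window that opens after long-term treatment: 1 iff
#' `csc_on < t <= csc_off` (default days 20-25; note the strict lower bound).
#'
#' @param t time in hours (vectorized).
#' @param params a [parameter_set()].
#' @return 0/1 vector.
#' @export
csc_indicator <- function(t, params) {
  as.numeric(t > params$csc_on & t <= params$csc_off)
}

#' Full model right-hand side
#'
#' Time derivatives of the eight state variables
#' `(F, B, X, C, S, L, A, T)`:
#' \deqn{dF/dt = \lambda_F + \lambda_2 L - \mu_F F}
#' \deqn{dB/dt = \lambda_B + \lambda_3 F + k_5 k_4^2/(k_4^2+\delta T^2) - \mu_B B}
#' \deqn{dX/dt = \lambda_X + k_7 k_6^2/(k_6^2+\gamma B^2) - \mu_X X}
#' \deqn{dC/dt = r C (1 - C/K) + \lambda_1 S - \mu_C (\alpha/B) C I_{apop}}
#' \deqn{dS/dt = \beta T I_s}
#' \deqn{dL/dt = \lambda_L + k_3 S/(k_1 + k_2 A) - \mu_L L}
#' with \eqn{dA/dt = u_A(t) - \mu_A A} and \eqn{dT/dt = u_T(t) - \mu_T T}
#' for infused agents (`u` the [infusion_rate()]) and zero for clamped ones.
#'
#' @param state named numeric vector `F, B, X, C, S, L, A, T` (the drug
#'   element is named `T_drug` internally to avoid masking `TRUE`).
#' @param t time in hours.
#' @param params a [parameter_set()].
#' @param protocol a `crcc_protocol`.
#' @param I_apop,I_s optional fixed indicator values; by default they are
#'   evaluated from `state` and `t` (per-evaluation switching).  The
#'   event-resolved integrator passes the current hybrid mode instead.
#' @return Named vector of the eight derivatives.
#' @export
full_rhs <- function(state, t, params, protocol, I_apop = NULL, I_s = NULL) {
  if (any(state < 0))
    stop("negative state component: ",
         paste(names(state)[state < 0], collapse = ", "))
  p <- params
  F_ <- state[["F"]]; B <- state[["B"]]; X <- state[["X"]]
  C <- state[["C"]]; S <- state[["S"]]; L <- state[["L"]]
  A <- state[["A"]]; Td <- state[["T"]]
  if (is.null(I_s)) I_s <- csc_indicator(t, p)
  if (is.null(I_apop)) I_apop <- apoptosis_indicator(B, X, p)
  if (I_apop == 1 && B == 0)
    stop("degenerate state: B = 0 with apoptosis switched on")
  B_safe <- max(B, 1e-12)
  dF <- p$lambda_F + p$lambda_2 * L - p$mu_F * F_
  dB <- p$lambda_B + p$lambda_3 * F_ +
    p$k5 * p$k4^2 / (p$k4^2 + p$delta * Td^2) - p$mu_B * B
  dX <- p$lambda_X + p$k7 * p$k6^2 / (p$k6^2 + p$gamma * B^2) - p$mu_X * X
  dC <- p$r * C * (1 - C / p$K) + p$lambda_1 * S -
    p$mu_C * (p$alpha / B_safe) * C * I_apop
  dS <- p$beta * Td * I_s
  dL <- p$lambda_L + p$k3 * S / (p$k1 + p$k2 * A) - p$mu_L * L
  dA <- if (protocol$ATV$mode == "clamped") 0 else
    infusion_rate(protocol, "ATV", t) - p$mu_A * A
  dT <- if (protocol$TZB$mode == "clamped") 0 else
    infusion_rate(protocol, "TZB", t) - p$mu_T * Td
  c(F = dF, B = dB, X = dX, C = dC, S = dS, L = dL, A = dA, T = dT)
}

#' Closed-form intracellular equilibrium
#'
#' With the CSC density and both drug levels held constant, the
#' IL-6 -- NF-kB -- Bcl-2 -- BAX subsystem is a feed-forward cascade whose
#' unique equilibrium solves in closed form:
#' \deqn{L^* = (\lambda_L + k_3 S/(k_1 + k_2 A))/\mu_L}
#' \deqn{F^* = (\lambda_F + \lambda_2 L^*)/\mu_F}
#' \deqn{B^* = (\lambda_B + \lambda_3 F^* + k_5 k_4^2/(k_4^2+\delta T^2))/\mu_B}
#' \deqn{X^* = (\lambda_X + k_7 k_6^2/(k_6^2+\gamma B^{*2}))/\mu_X}
#' Local stability is classified from the eigenvalues of the subsystem
#' Jacobian, which is lower triangular in the cascade ordering, so the
#' eigenvalues are the negated decay rates and every equilibrium is stable.
#'
#' @param params a [parameter_set()].
#' @param S,A,T constant CSC density and drug levels (all >= 0).
#' @param tol residual tolerance for the internal consistency check.
#' @return Object of class `crcc_equilibrium`: list with `L_star`, `F_star`,
#'   `B_star`, `X_star`, `eigenvalues`, `stability` (one of `"stable"`,
#'   `"unstable"`, `"marginal"`) and `region` (see [classify_region()]).
#' @export
intracellular_equilibrium <- function(params, S, A = 0, T = 0, tol = 1e-8) {
  p <- params
  if (min(p$mu_L, p$mu_F, p$mu_B, p$mu_X) <= 0)
    stop("all decay rates must be > 0")
  if (S < 0 || A < 0 || T < 0) stop("S, A, T must be >= 0")
  L <- (p$lambda_L + p$k3 * S / (p$k1 + p$k2 * A)) / p$mu_L
  F_ <- (p$lambda_F + p$lambda_2 * L) / p$mu_F
  B <- (p$lambda_B + p$lambda_3 * F_ +
          p$k5 * p$k4^2 / (p$k4^2 + p$delta * T^2)) / p$mu_B
  X <- (p$lambda_X + p$k7 * p$k6^2 / (p$k6^2 + p$gamma * B^2)) / p$mu_X
  ## Jacobian of (L, F, B, X), cascade ordering
  dXdB <- -p$k7 * p$k6^2 * 2 * p$gamma * B / (p$k6^2 + p$gamma * B^2)^2
  J <- rbind(c(-p$mu_L, 0, 0, 0),
             c(p$lambda_2, -p$mu_F, 0, 0),
             c(0, p$lambda_3, -p$mu_B, 0),
             c(0, 0, dXdB, -p$mu_X))
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  stability <- if (all(re < -1e-12)) "stable"
    else if (any(re > 1e-12)) "unstable" else "marginal"
  ## residual check against the cascade right-hand side
  res <- c(p$lambda_L + p$k3 * S / (p$k1 + p$k2 * A) - p$mu_L * L,
           p$lambda_F + p$lambda_2 * L - p$mu_F * F_,
           p$lambda_B + p$lambda_3 * F_ +
             p$k5 * p$k4^2 / (p$k4^2 + p$delta * T^2) - p$mu_B * B,
           p$lambda_X + p$k7 * p$k6^2 / (p$k6^2 + p$gamma * B^2) - p$mu_X * X)
  if (max(abs(res)) > tol * max(1, abs(L), abs(F_), abs(B), abs(X)))
    stop("equilibrium residual exceeds tolerance")  # defensive; closed form
  structure(list(L_star = L, F_star = F_, B_star = B, X_star = X,
                 eigenvalues = ev, stability = stability,
                 region = classify_region(B, X, params),
                 S = S, A = A, T = T),
            class = "crcc_equilibrium")
}

#' @export
print.crcc_equilibrium <- function(x, ...) {
  cat(sprintf(
    "<crcc_equilibrium> S=%g A=%g T=%g\n  L*=%.4g F*=%.4g B*=%.4g X*=%.4g  [%s, %s]\n",
    x$S, x$A, x$T, x$L_star, x$F_star, x$B_star, x$X_star,
    x$stability, x$region))
  invisible(x)
}
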