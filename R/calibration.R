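#' Calibrate the nondimensional working parameter set
#'
#' The model is analysed throughout in a nondimensional unit system in which
#' drug levels span T in \[0, 6\] and A in \[0, 40\] and the apoptosis
#' thresholds sit at `th_B = th_X = 8`.  The decay rates carry over unchanged
#' from the dimensional table (time is kept in hours, and first-order decay
#' rates are invariant under any rescaling of the concentration variables),
#' but the source and coupling strengths depend on the concentration scales,
#' which are not fixed by the dimensional table alone.  This function derives
#' them in closed form from the operating anchors of the study design:
#'
#' * the IL-6 equilibrium at high CSC density (`S = 1`) equals `L_high_0`
#'   without atorvastatin and `L_high_A` under `A = A_ref`;
#' * a clamped atorvastatin arm (`A = A_ref`) lowers the 30-day IL-6 level by
#'   `atv_reduction` relative to untreated control at low CSC density
#'   (`S = S_low`);
#' * the combination arm lowers 30-day IL-6 by `combo_reduction` relative to
#'   trastuzumab alone, which pins the CSC mass produced during the 5-day
#'   activation window and hence `beta`;
#' * the equilibrium dose-response enters the apoptotic region at trastuzumab
#'   dose `T_cross_atv` under `A = A_ref` and at `T_cross_plain` without
#'   atorvastatin (both at `S = S_low`);
#' * the BAX equilibrium passes its threshold just above the Bcl-2 threshold:
#'   `X*(th_B) = 8.5` and `X*(th_B + 0.5) = 8`, so that the Bcl-2 branch is
#'   the binding condition for entry into the apoptotic region.
#'
#' The system is linear in the unknown source strengths once the two crossing
#' doses and the Hill constants are fixed, so the solution is exact and
#' deterministic; see the methods vignette for the full derivation.
#'
#' @param mu_L,mu_B,mu_F,mu_X first-order decay rates (1/h) of IL-6, Bcl-2,
#'   NF-kB and BAX.
#' @param S_low low (baseline) CSC density.
#' @param A_ref reference atorvastatin level of the clamped treatment arms.
#' @param L_high_0,L_high_A IL-6 equilibrium anchors at `S = 1` without and
#'   with atorvastatin.
#' @param atv_reduction,combo_reduction fractional 30-day IL-6 reductions
#'   (ATV vs control; combination vs TZB alone).
#' @param T_cross_atv,T_cross_plain trastuzumab doses at which the
#'   equilibrium state enters the apoptotic region with and without
#'   atorvastatin (`S = S_low`).
#' @param window_h duration (hours) of the CSC activation window.
#' @param th_B,th_X apoptosis thresholds on Bcl-2 and BAX.
#' @param delta,k5 inhibition strength of Bcl-2 by trastuzumab and the
#'   autocatalytic Bcl-2 enhancement (free Hill-branch choices; defaults give
#'   the combination arm its apoptotic onset near T = 0.45 at `S = 1`).
#' @param lambda_F,lambda_2 NF-kB source and IL-6-to-NF-kB activation rate
#'   (set the NF-kB scale; the Bcl-2 calibration only constrains their
#'   product with `lambda_3`).
#' @param lambda_X BAX basal source (sets the BAX floor).
#'
#' @return Named list of calibrated nondimensional parameter values:
#'   `lambda_L`, `k2`, `k3`, `beta`, `lambda_B`, `lambda_3`, `gamma`, `k7`,
#'   together with the pass-through choices (`lambda_F`, `lambda_2`, `k5`,
#'   `delta`, `lambda_X`).
#' @export
calibrate_parameters <- function(mu_L = 0.0815, mu_B = 0.0347, mu_F = 0.3,
                                 mu_X = 0.02,
                                 S_low = 0.25, A_ref = 5,
                                 L_high_0 = 60, L_high_A = 18,
                                 atv_reduction = 0.46, combo_reduction = 0.69,
                                 T_cross_atv = 0.25, T_cross_plain = 0.7,
                                 window_h = 120,
                                 th_B = 8, th_X = 8,
                                 delta = 4, k5 = 0.17,
                                 lambda_F = 0.035, lambda_2 = 0.05,
                                 lambda_X = 0.01) {
  ## IL-6 branch.  With a = lambda_L/mu_L, b = k3/mu_L and
  ## q = 1/(1 + k2*A_ref):  a + b = L_high_0,  a + q b = L_high_A, and the
  ## ATV-arm reduction at S = S_low fixes q.
  gap <- L_high_0 - L_high_A
  f_q <- function(q) {
    b <- gap / (1 - q)
    a <- L_high_0 - b
    (a + S_low * q * b) / (a + S_low * b) - (1 - atv_reduction)
  }
  q <- stats::uniroot(f_q, c(1e-9, 1 - gap / L_high_0 - 1e-9),
                      tol = 1e-14)$root
  b <- gap / (1 - q)
  a <- L_high_0 - b
  k2 <- (1 / q - 1) / A_ref
  lambda_L <- a * mu_L
  k3 <- b * mu_L

  ## CSC production: the combination-arm reduction pins the post-window CSC
  ## density S2 reached under clamped T = 1, hence beta over the window.
  S2 <- combo_reduction * a / (b * (1 - combo_reduction - q))
  beta <- (S2 - S_low) / window_h

  ## Bcl-2 branch.  B* = (p + m L* + k5/(1 + delta T^2)) / mu_B with
  ## p = lambda_B + lambda_3 lambda_F / mu_F and m = lambda_3 lambda_2 / mu_F.
  L_star <- function(S, A) (lambda_L + k3 * S / (1 + k2 * A)) / mu_L
  L_atv <- L_star(S_low, A_ref)
  L_plain <- L_star(S_low, 0)
  m <- k5 * (1 / (1 + delta * T_cross_atv^2) -
               1 / (1 + delta * T_cross_plain^2)) / (L_plain - L_atv)
  p <- th_B * mu_B - m * L_atv - k5 / (1 + delta * T_cross_atv^2)
  lambda_3 <- m * mu_F / lambda_2
  lambda_B <- p - lambda_3 * lambda_F / mu_F
  if (lambda_B <= 0)
    stop("calibration produced a non-positive Bcl-2 source; ",
         "widen the crossing-dose gap or lower k5")

  ## BAX branch: X*(th_B) = th_X + 0.5 and X*(th_B + 0.5) = th_X.
  hi <- (th_X + 0.5) * mu_X - lambda_X
  lo <- th_X * mu_X - lambda_X
  gamma <- (hi / lo - 1) / ((th_B + 0.5)^2 - (hi / lo) * th_B^2)
  k7 <- hi * (1 + gamma * th_B^2)

  list(lambda_L = lambda_L, k2 = k2, k3 = k3, beta = beta,
       lambda_B = lambda_B, lambda_3 = lambda_3, gamma = gamma, k7 = k7,
       lambda_F = lambda_F, lambda_2 = lambda_2, k5 = k5, delta = delta,
       lambda_X = lambda_X)
}
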