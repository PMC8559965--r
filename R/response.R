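#' Phase-plane region of the (BAX, Bcl-2) state
#'
#' Classifies intracellular states into the anti-apoptotic region `Tt`
#' (`X < th_X` and `B > th_B`), the apoptotic region `Ta` (`X > th_X` and
#' `B < th_B`), or `neither` (the two regions do not partition the plane;
#' threshold lines and the doubly-high/doubly-low quadrants belong to
#' neither).
#'
#' @param B,X Bcl-2 and BAX levels (vectorized).
#' @param params a [parameter_set()].
#' @return Character vector with values `"Ta"`, `"Tt"`, `"neither"`.
#' @export
classify_region <- function(B, X, params) {
  out <- rep("neither", length(B))
  out[X > params$th_X & B < params$th_B] <- "Ta"
  out[X < params$th_X & B > params$th_B] <- "Tt"
  out
}

#' Equilibrium dose-response curve over trastuzumab dose
#'
#' Evaluates the closed-form intracellular equilibrium
#' ([intracellular_equilibrium()]) along a grid of clamped trastuzumab doses
#' at fixed CSC density and atorvastatin level, and locates the smallest
#' dose at which the equilibrium enters the apoptotic region
#' (`B* < th_B` and `X* > th_X`), refined by bisection between the
#' bracketing grid points to an absolute tolerance of 1e-4.
#'
#' @param params a [parameter_set()].
#' @param T_grid strictly increasing nonnegative dose grid.
#' @param S_fixed,A_fixed held CSC density and atorvastatin level.
#' @return Object of class `crcc_dose_response`: data.frame with columns
#'   `T, L_star, F_star, B_star, X_star, region`, and attributes
#'   `crossing_dose` (numeric or `NA` if the grid never enters the apoptotic
#'   region), `S_fixed`, `A_fixed`.
#' @export
dose_response_curve <- function(params, T_grid, S_fixed = 0.25,
                                A_fixed = 0) {
  if (!length(T_grid)) stop("empty dose grid")
  if (any(T_grid < 0) || any(diff(T_grid) <= 0))
    stop("T_grid must be nonnegative and strictly increasing")
  eqs <- lapply(T_grid, function(Td)
    intracellular_equilibrium(params, S = S_fixed, A = A_fixed, T = Td))
  df <- data.frame(
    T = T_grid,
    L_star = vapply(eqs, `[[`, 0, "L_star"),
    F_star = vapply(eqs, `[[`, 0, "F_star"),
    B_star = vapply(eqs, `[[`, 0, "B_star"),
    X_star = vapply(eqs, `[[`, 0, "X_star"),
    region = vapply(eqs, `[[`, "", "region"))
  ## signed distance into the apoptotic region (positive inside)
  gap <- function(Td) {
    e <- intracellular_equilibrium(params, S = S_fixed, A = A_fixed, T = Td)
    min(params$th_B - e$B_star, e$X_star - params$th_X)
  }
  inside <- df$region == "Ta"
  crossing <- NA_real_
  if (any(inside)) {
    j <- which(inside)[1]
    if (j == 1L) {
      crossing <- T_grid[1]
    } else {
      lo <- T_grid[j - 1L]; hi <- T_grid[j]
      while (hi - lo > 1e-4) {
        mid <- (lo + hi) / 2
        if (gap(mid) > 0) hi <- mid else lo <- mid
      }
      crossing <- (lo + hi) / 2
    }
  }
  structure(df, class = c("crcc_dose_response", "data.frame"),
            crossing_dose = crossing, S_fixed = S_fixed, A_fixed = A_fixed)
}

#' Total time spent in the apoptotic state
#'
#' The Lebesgue measure of `{t : I_apop(t) = 1}` over the simulated span,
#' computed exactly from the event-resolved switch times (between events the
#' indicator is constant), reported in days.
#'
#' @param sim a `crcc_sim`.
#' @param params parameter set (defaults to the one stored in `sim`).
#' @return Duration in days.
#' @export
apoptosis_persistence <- function(sim, params = sim$params_used) {
  t <- sim$times
  ia <- sim$indicators[, "I_apop"]
  ## indicator is piecewise constant and the stored grid contains every
  ## switch time, so left-constant interpolation is exact
  sum(diff(t) * ia[-length(ia)]) / 24
}

#' Treatment efficacy metrics
#'
#' Anti-tumor efficacy is the reciprocal of the tumor burden,
#' `E_T = f_T / C(t)`, and anti-CRCC (anti-chemobrain) efficacy the
#' reciprocal of the IL-6 level, `E_c = f_c / L(t)`; the total efficacy is
#' the weighted sum `E_total = omega_1 E_T + omega_2 E_c`.  The scale
#' factors default to [default_efficacy_scales()]: `f_T` equals the
#' untreated-control tumor burden at `t_eval` (so `E_T = 1` for untreated
#' growth) and `f_c` the IL-6 level of the atorvastatin-only arm (the
#' combination family at zero trastuzumab dose), so its `E_c` is 1.
#'
#' @param sim a `crcc_sim`.
#' @param params parameter set (defaults to the one stored in `sim`).
#' @param t_eval_days evaluation time, days.
#' @param f_T,f_c efficacy scale factors; `NULL` uses the stored parameter
#'   values, or the defaults above when those are `NA`.
#' @return List of class `crcc_efficacy` with `E_T`, `E_c`, `E_total`,
#'   `t_eval_days`, `f_T`, `f_c`.
#' @export
efficacy_metrics <- function(sim, params = sim$params_used, t_eval_days = 30,
                             f_T = NULL, f_c = NULL) {
  st <- state_at(sim, t_eval_days * 24)
  C <- st[["C"]]; L <- st[["L"]]
  if (C <= 0 || L <= 0)
    stop("C and L must be positive at the evaluation time")
  if (is.null(f_T)) f_T <- params$f_T
  if (is.null(f_c)) f_c <- params$f_c
  if (is.na(f_T) || is.na(f_c)) {
    sc <- default_efficacy_scales(params, t_eval_days = t_eval_days)
    if (is.na(f_T)) f_T <- sc$f_T
    if (is.na(f_c)) f_c <- sc$f_c
  }
  E_T <- f_T / C
  E_c <- f_c / L
  structure(list(E_T = E_T, E_c = E_c,
                 E_total = params$omega_1 * E_T + params$omega_2 * E_c,
                 t_eval_days = t_eval_days, f_T = f_T, f_c = f_c),
            class = "crcc_efficacy")
}

#' @rdname efficacy_metrics
#' @param A_level atorvastatin level of the reference combination family.
#' @export
default_efficacy_scales <- function(params, t_eval_days = 30, A_level = 5) {
  span <- c(0, t_eval_days * 24)
  ctrl <- simulate_model(params, constant_protocol(0, 0, t_eval_days),
                         t_span = span, rtol = 1e-8, atol = 1e-10)
  atv <- simulate_model(params, constant_protocol(0, A_level, t_eval_days),
                        t_span = span, rtol = 1e-8, atol = 1e-10)
  list(f_T = state_at(ctrl, t_eval_days * 24)[["C"]],
       f_c = state_at(atv, t_eval_days * 24)[["L"]])
}

#' Percent change of a variable between two runs
#'
#' `100 * (ref - alt) / ref` for the named state variable at the evaluation
#' time: the percent reduction achieved by the alternative arm relative to
#' the reference arm.
#'
#' @param sim_ref,sim_alt two `crcc_sim` objects on a common grid.
#' @param variable state column name (e.g. `"L"`, `"C"`, `"B"`).
#' @param t_eval_days evaluation time, days.
#' @return Percent change (positive = reduction under `sim_alt`).
#' @export
percent_change <- function(sim_ref, sim_alt, variable, t_eval_days = 30) {
  ref <- state_at(sim_ref, t_eval_days * 24)[[variable]]
  alt <- state_at(sim_alt, t_eval_days * 24)[[variable]]
  if (ref == 0) stop("reference value is zero")
  100 * (ref - alt) / ref
}
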