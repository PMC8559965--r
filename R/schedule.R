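#' Evaluate one alternating schedule
#'
#' Builds the six-slot [alternating_protocol()] for a schedule code,
#' simulates the full system to the horizon from the standard initial state,
#' and extracts the outcome summary used for ranking: tumor burden and IL-6
#' level at the horizon, total apoptosis persistence, and whether the
#' apoptotic state, once entered, persisted to the horizon.
#'
#' @param code a [schedule_code()].
#' @param params a [parameter_set()].
#' @param I_A,I_T infusion dose rates.
#' @param horizon_days horizon in days.
#' @param rtol,atol integration tolerances.
#' @return One-row data.frame of class `crcc_schedule_outcome` with columns
#'   `code, final_C, final_L, persistence_d, persistent_Ta`.
#' @export
evaluate_schedule <- function(code, params, I_A = 3.3, I_T = 0.075,
                              horizon_days = 40, rtol = 1e-8, atol = 1e-10) {
  prot <- alternating_protocol(code, I_A = I_A, I_T = I_T,
                               horizon_days = horizon_days)
  sim <- simulate_model(params, prot, rtol = rtol, atol = atol)
  outcome_row(code, sim, params)
}

outcome_row <- function(label, sim, params) {
  fin <- sim$states[nrow(sim$states), ]
  ia <- sim$indicators[, "I_apop"]
  first <- which(ia == 1)[1]
  persistent <- !is.na(first) && all(ia[first:length(ia)] == 1)
  structure(
    data.frame(code = label,
               final_C = fin[["C"]], final_L = fin[["L"]],
               persistence_d = apoptosis_persistence(sim, params),
               persistent_Ta = persistent,
               stringsAsFactors = FALSE),
    class = c("crcc_schedule_outcome", "data.frame"))
}

#' Evaluate every six-slot schedule
#'
#' Runs [evaluate_schedule()] for all 20 codes of [enumerate_codes()] and
#' appends normalized outcome columns (each scaled to the maximum across the
#' family).
#'
#' @inheritParams evaluate_schedule
#' @return Data.frame with one row per code, plus `normalized_C` and
#'   `normalized_L` columns.
#' @export
evaluate_all_schedules <- function(params, I_A = 3.3, I_T = 0.075,
                                   horizon_days = 40,
                                   rtol = 1e-8, atol = 1e-10) {
  rows <- lapply(enumerate_codes(), evaluate_schedule, params = params,
                 I_A = I_A, I_T = I_T, horizon_days = horizon_days,
                 rtol = rtol, atol = atol)
  out <- do.call(rbind, rows)
  out$normalized_C <- out$final_C / max(out$final_C)
  out$normalized_L <- out$final_L / max(out$final_L)
  rownames(out) <- NULL
  out
}

#' Rank schedule outcomes
#'
#' Stable sort of schedule outcomes by an objective, ties broken
#' lexicographically by code: `"min_tumor"` orders by final tumor burden,
#' `"min_IL6"` by final IL-6 level, and `"combined"` by
#' `omega * normalized_C + (1 - omega) * normalized_L`.
#'
#' @param outcomes data.frame as returned by [evaluate_all_schedules()] (or
#'   rbind-ed [evaluate_schedule()] rows; normalized columns are recomputed
#'   if absent).
#' @param objective ranking objective.
#' @param omega tumor weight of the combined objective.
#' @return The outcomes ordered best to worst, with columns `rank`, `best`
#'   and `worst` added.
#' @export
rank_schedules <- function(outcomes,
                           objective = c("min_tumor", "min_IL6", "combined"),
                           omega = 0.5) {
  objective <- match.arg(objective)
  if (!nrow(outcomes)) stop("empty outcome list")
  if (is.null(outcomes$normalized_C))
    outcomes$normalized_C <- outcomes$final_C / max(outcomes$final_C)
  if (is.null(outcomes$normalized_L))
    outcomes$normalized_L <- outcomes$final_L / max(outcomes$final_L)
  key <- switch(objective,
                min_tumor = outcomes$final_C,
                min_IL6 = outcomes$final_L,
                combined = omega * outcomes$normalized_C +
                  (1 - omega) * outcomes$normalized_L)
  ord <- order(key, outcomes$code)   # stable, lexicographic tie-break
  ranked <- outcomes[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  ranked$best <- ranked$rank == 1L
  ranked$worst <- ranked$rank == nrow(ranked)
  rownames(ranked) <- NULL
  ranked
}

#' Scan periodic atorvastatin infusion schedules
#'
#' For every combination of infusion dose `I_A` and period `tau_A` (days;
#' `tau_A = 0` denotes continuous infusion), runs periodic atorvastatin over
#' a clamped basal trastuzumab level and records the final tumor burden,
#' final IL-6 level, apoptosis persistence, and whether the apoptotic state
#' persists to the horizon.  Each grid point is labelled with qualitative
#' zone flags derived from quantile cuts across the evaluated grid:
#' high-cost (`ZC`, top-quartile dose), CRCC-risk (`ZB`, top-quartile final
#' IL-6), and safe (`ZS`, remainder with bottom-quartile final tumor
#' burden).
#'
#' @param params a [parameter_set()].
#' @param I_A_grid,tau_grid_days dose and period grids (defaults: the
#'   published scan grids).
#' @param basal_T clamped trastuzumab level during the scan.
#' @param horizon_days horizon in days.
#' @param duration_days infusion window duration.
#' @param zone_probs quantile cuts `c(ZC dose, ZB IL-6, ZS tumor)`.
#' @param rtol,atol integration tolerances.
#' @return Long-format data.frame: `I_A, tau_A, final_C, final_L,
#'   persistence_d, persistent_Ta, ZC, ZB, ZS`.
#' @export
infusion_grid_scan <- function(params,
                               I_A_grid = c(0.05, 0.1, 0.5, 1, 2, 3, 5, 7,
                                            10, 40),
                               tau_grid_days = c(0, 1, 2, 3, 4, 5, 7, 10),
                               basal_T = 1.0, horizon_days = 40,
                               duration_days = 1,
                               zone_probs = c(0.75, 0.75, 0.25),
                               rtol = 1e-8, atol = 1e-10) {
  if (!length(I_A_grid) || !length(tau_grid_days)) stop("empty scan grid")
  grid <- expand.grid(I_A = I_A_grid, tau_A = tau_grid_days)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    prot <- periodic_protocol("ATV", dose = grid$I_A[i],
                              period_days = grid$tau_A[i],
                              duration_days = duration_days,
                              basal_level = basal_T,
                              horizon_days = horizon_days)
    sim <- simulate_model(params, prot, rtol = rtol, atol = atol)
    cbind(grid[i, , drop = FALSE],
          outcome_row(sprintf("IA%g_tau%g", grid$I_A[i], grid$tau_A[i]),
                      sim, params)[-1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$ZC <- out$I_A >= stats::quantile(I_A_grid, zone_probs[1])
  out$ZB <- out$final_L >= stats::quantile(out$final_L, zone_probs[2])
  out$ZS <- !out$ZC & !out$ZB &
    out$final_C <= stats::quantile(out$final_C, zone_probs[3])
  out
}
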