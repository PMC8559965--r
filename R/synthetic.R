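#' Clamped protocol of a named treatment arm
#'
#' The four experimental arms: `control` (T=0, A=0), `ATV` (T=0, A=5),
#' `TZB` (T=1, A=0) and `combo` (T=1, A=5), all clamped.
#'
#' @param arm arm name.
#' @param horizon_days horizon in days.
#' @param T_level,A_level drug levels of the treated arms.
#' @return A `crcc_protocol`.
#' @export
arm_protocol <- function(arm = c("control", "ATV", "TZB", "combo"),
                         horizon_days = 40, T_level = 1, A_level = 5) {
  arm <- match.arg(arm)
  lev <- switch(arm,
                control = c(0, 0),
                ATV = c(0, A_level),
                TZB = c(T_level, 0),
                combo = c(T_level, A_level))
  constant_protocol(lev[1], lev[2], horizon_days)
}

#' Generate synthetic noisy observations
#'
#' Simulates each requested treatment arm from the standard initial state
#' and draws replicate observations with multiplicative lognormal noise:
#' `obs = truth * exp(eps)`, `eps ~ Normal(0, sigma)` with
#' `sigma = sqrt(log(1 + noise_cv^2))`, so the replicate coefficient of
#' variation equals `noise_cv` and observations of positive quantities stay
#' positive (a zero truth stays exactly zero).  Deterministic given `seed`.
#'
#' @param params generating [parameter_set()].
#' @param arms subset of `c("control", "ATV", "TZB", "combo")`.
#' @param times_days sampling times (days).
#' @param observables subset of `c("L", "B", "C")` (IL-6, Bcl-2, tumor).
#' @param noise_cv replicate coefficient of variation (>= 0).
#' @param n_replicates replicates per arm/time/observable.
#' @param seed RNG seed.
#' @param rtol,atol integration tolerances.
#' @return Object of class `crcc_observations`: tidy data.frame
#'   `arm, time_h, observable, replicate, value` with attributes `truth`
#'   (the generating parameters), `noise_cv` and `seed`.
#' @export
generate_observations <- function(params,
                                  arms = c("control", "ATV", "TZB", "combo"),
                                  times_days = seq(2, 30, length.out = 8),
                                  observables = c("L", "B", "C"),
                                  noise_cv = 0.05, n_replicates = 3,
                                  seed = 1, rtol = 1e-8, atol = 1e-10) {
  arms <- match.arg(arms, several.ok = TRUE)
  observables <- match.arg(observables, several.ok = TRUE)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  times_h <- times_days * 24
  sigma <- sqrt(log(1 + noise_cv^2))
  set.seed(seed)
  rows <- list()
  for (arm in arms) {
    prot <- arm_protocol(arm, horizon_days = max(times_days))
    sim <- simulate_model(params, prot, t_span = c(0, max(times_h)),
                          output_grid = sort(unique(c(0, times_h))),
                          rtol = rtol, atol = atol)
    for (tt in times_h) {
      st <- state_at(sim, tt)
      for (ob in observables) {
        truth <- st[[ob]]
        eps <- if (noise_cv == 0) rep(0, n_replicates) else
          stats::rnorm(n_replicates, 0, sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, time_h = tt, observable = ob,
          replicate = seq_len(n_replicates),
          value = truth * exp(eps))
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("crcc_observations", "data.frame"),
            truth = params, noise_cv = noise_cv, seed = seed)
}

## sum of squared log-residuals of a parameter set against an observation set
observation_loss <- function(params, obs, rtol = 1e-6, atol = 1e-8,
                             eps = 1e-12) {
  loss <- 0
  for (arm in unique(obs$arm)) {
    sub <- obs[obs$arm == arm, ]
    times_h <- sort(unique(sub$time_h))
    prot <- arm_protocol(arm, horizon_days = max(times_h) / 24)
    sim <- tryCatch(
      simulate_model(params, prot, t_span = c(0, max(times_h)),
                     output_grid = sort(unique(c(0, times_h))),
                     rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(sim)) return(1e10)
    for (i in seq_len(nrow(sub))) {
      pred <- state_at(sim, sub$time_h[i])[[sub$observable[i]]]
      loss <- loss + (log(pred + eps) - log(sub$value[i] + eps))^2
    }
  }
  loss
}

#' Fit model parameters to an observation set
#'
#' Minimizes the sum over arms, times, observables and replicates of squared
#' log-residuals (log-space fitting keeps observables of very different
#' magnitudes commensurate) by multi-start bounded local optimization:
#' `n_starts` Latin-hypercube initial points within the bounds, each refined
#' with `L-BFGS-B`.  Deterministic given `seed`.
#'
#' @param obs a [generate_observations()] set (or any data.frame with the
#'   same columns).
#' @param params base parameter set supplying the fixed (non-free) values;
#'   defaults to the observation set's generating truth.
#' @param free_names parameters to estimate.
#' @param bounds named list of `c(lo, hi)` per free parameter; default
#'   `base value * c(0.2, 5)`.
#' @param n_starts number of optimization starts.
#' @param seed RNG seed for the start points.
#' @param rtol,atol integration tolerances of the model evaluations.
#' @return Object of class `crcc_fit`: list with `estimate` (named vector),
#'   `loss`, `params` (full parameter set at the optimum), `starts`
#'   (per-start data.frame with convergence flags), `converged`.
#' @export
fit_parameters <- function(obs, params = attr(obs, "truth"),
                           free_names, bounds = NULL,
                           n_starts = 3, seed = 1,
                           rtol = 1e-6, atol = 1e-8) {
  stopifnot(all(free_names %in% names(params)))
  if (!length(free_names)) {
    l0 <- observation_loss(params, obs, rtol, atol)
    return(structure(list(estimate = numeric(0), loss = l0, params = params,
                          starts = data.frame(), converged = TRUE),
                     class = "crcc_fit"))
  }
  if (is.null(bounds))
    bounds <- lapply(stats::setNames(free_names, free_names),
                     function(nm) params[[nm]] * c(0.2, 5))
  stopifnot(setequal(names(bounds), free_names))
  lo <- vapply(bounds, `[`, 0, 1L)
  hi <- vapply(bounds, `[`, 0, 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("bounds must be finite with lo < hi")
  fn <- function(theta) {
    p2 <- params
    p2[free_names] <- as.list(theta)
    observation_loss(validate_parameter_set(p2), obs, rtol, atol)
  }
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, length(free_names))
  starts <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(starts) <- free_names
  fits <- lapply(seq_len(n_starts), function(i) {
    tryCatch(stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                          lower = lo, upper = hi,
                          control = list(factr = 1e7,
                                         ndeps = (hi - lo) * 1e-5)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("all optimization starts failed")
  losses <- vapply(fits[ok], `[[`, 0, "value")
  best <- fits[ok][[which.min(losses)]]
  p_best <- params
  p_best[free_names] <- as.list(best$par)
  start_df <- data.frame(
    start = which(ok),
    loss = losses,
    converged = vapply(fits[ok], function(f) f$convergence == 0, TRUE))
  structure(list(estimate = best$par, loss = best$value,
                 params = validate_parameter_set(p_best),
                 starts = start_df,
                 converged = any(start_df$converged)),
            class = "crcc_fit")
}

#' Parameter-recovery error report
#'
#' @param truth generating [parameter_set()].
#' @param fit a [fit_parameters()] result.
#' @return Data.frame `parameter, true, estimate, rel_error`, with the fit's
#'   loss and convergence flag as attributes.
#' @export
recovery_report <- function(truth, fit) {
  stopifnot(inherits(fit, "crcc_fit"))
  if (!fit$converged) stop("fit did not converge")
  nms <- names(fit$estimate)
  tv <- vapply(nms, function(nm) truth[[nm]], 0)
  out <- data.frame(parameter = nms, true = unname(tv),
                    estimate = unname(fit$estimate),
                    rel_error = unname(abs(fit$estimate - tv) /
                                         ifelse(tv == 0, 1, abs(tv))))
  attr(out, "loss") <- fit$loss
  attr(out, "converged") <- fit$converged
  out
}

#' @export
print.crcc_fit <- function(x, ...) {
  cat("<crcc_fit> loss", signif(x$loss, 6), "\n")
  if (length(x$estimate)) print(signif(x$estimate, 6))
  invisible(x)
}
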