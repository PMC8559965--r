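#' Construct and validate a model parameter set
#'
#' Bundles every constant of the coupled intracellular / tumor / IL-6 model:
#' source and coupling strengths of the NF-kB--Bcl-2--BAX cascade, tumor
#' growth and killing, CSC production, IL-6 supply and its suppression by
#' atorvastatin, drug decay rates, the apoptosis thresholds, the CSC
#' activation window, and the efficacy weights.  Time is measured in hours
#' internally; the CSC window is supplied in hours (see
#' [default_parameters()] for the day-level defaults).
#'
#' @param ... named parameter values overriding the defaults of
#'   [default_parameters()].
#' @param unit_system `"nondimensional"` (the working system of all analyses)
#'   or `"dimensional"`.
#'
#' @return An object of class `crcc_params`: a named list of validated
#'   parameter values.
#' @seealso [default_parameters()], [dimensional_parameters()],
#'   [convert_units()]
#' @export
parameter_set <- function(..., unit_system = "nondimensional") {
  p <- default_parameters(unit_system = unit_system)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_parameter_set(p)
}

#' @rdname parameter_set
#' @param p a candidate parameter list.
#' @export
validate_parameter_set <- function(p) {
  num <- setdiff(names(p), "unit_system")
  for (nm in num) {
    v <- p[[nm]]
    ok <- is.numeric(v) && length(v) == 1L &&
      (is.finite(v) || (nm %in% c("f_T", "f_c") && is.na(v)))
    if (!ok)
      stop("parameter '", nm, "' must be a single finite number")
  }
  nonneg <- c("lambda_F", "lambda_B", "lambda_X", "lambda_2", "lambda_3",
              "k1", "k2", "k3", "k4", "k5", "k6", "k7", "delta", "gamma",
              "r", "lambda_1", "beta", "lambda_L", "alpha", "mu_C",
              "I_A_max", "I_T_max", "f_T", "f_c")
  nonneg <- intersect(nonneg, names(p))
  bad <- nonneg[vapply(nonneg, function(nm) isTRUE(p[[nm]] < 0), TRUE)]
  if (length(bad))
    stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "))
  pos <- c("mu_F", "mu_B", "mu_X", "mu_L", "mu_T", "mu_A", "K",
           "th_B", "th_X")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, TRUE)]
  if (length(bad))
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  if (p$csc_on >= p$csc_off)
    stop("csc_on must be earlier than csc_off")
  w <- c(p$omega_1, p$omega_2)
  if (any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-12)
    stop("omega_1 and omega_2 must lie in [0, 1] and sum to 1")
  if (!p$unit_system %in% c("nondimensional", "dimensional"))
    stop("unit_system must be 'nondimensional' or 'dimensional'")
  structure(p, class = "crcc_params")
}

#' Default parameter sets
#'
#' `default_parameters()` returns the nondimensional working set used for all
#' analyses.  Decay rates, the tumor growth rate and the Hill saturation
#' constants carry the dimensional per-hour values (they are invariant under
#' rescaling of the concentration variables when time stays in hours); the
#' source and coupling strengths are produced by the closed-form calibration
#' of [calibrate_parameters()], which anchors the model to its operating
#' characteristics (IL-6 equilibria of 60 and 18 at high CSC density,
#' 46%/69% IL-6 reductions of the treated arms, and apoptotic crossing doses
#' of 0.25 and 0.7 with and without atorvastatin).  `dimensional_parameters()`
#' returns the published dimensional table, carried as metadata and bridged
#' by [convert_units()].
#'
#' @param unit_system which system to return.
#' @return A `crcc_params` object.
#' @export
default_parameters <- function(unit_system = c("nondimensional",
                                               "dimensional")) {
  unit_system <- match.arg(unit_system)
  if (unit_system == "dimensional")
    return(dimensional_parameters())
  cal <- calibrate_parameters()
  p <- list(
    ## intracellular cascade
    lambda_F = cal$lambda_F, lambda_B = cal$lambda_B,
    lambda_X = cal$lambda_X,
    lambda_2 = cal$lambda_2, lambda_3 = cal$lambda_3,
    k4 = 1, k5 = cal$k5, k6 = 1, k7 = cal$k7,
    delta = cal$delta, gamma = cal$gamma,
    mu_F = 0.3, mu_B = 0.0347, mu_X = 0.02,
    ## tumor / CSC
    r = 0.07, K = 1, lambda_1 = 1e-5, beta = cal$beta,
    mu_C = 0.3, alpha = 2,
    ## IL-6
    lambda_L = cal$lambda_L, k1 = 1, k2 = cal$k2, k3 = cal$k3,
    mu_L = 0.0815,
    ## drugs
    mu_T = 0.005, mu_A = 0.0495,
    ## switching
    th_B = 8, th_X = 8,
    csc_on = 20 * 24, csc_off = 25 * 24,
    ## efficacy
    f_T = NA_real_, f_c = NA_real_, omega_1 = 0.5, omega_2 = 0.5,
    unit_system = "nondimensional")
  validate_parameter_set(p)
}

#' @rdname default_parameters
#' @export
dimensional_parameters <- function() {
  p <- list(
    lambda_F = 3.5e-2,       # uM / h
    lambda_B = 8.5e-4,       # uM / h
    lambda_X = 3.3e-4,       # uM / h
    lambda_2 = 9.15e8,       # uM mm^3 / (g h)
    lambda_3 = 1.38e-2,      # 1 / h
    k4 = 1, k5 = 1.25e-1,    # uM / h
    k6 = 1, k7 = 1,          # uM / h
    delta = 1.44e18,         # mm^6 / g^2
    gamma = 8,               # 1 / uM^2
    mu_F = 3e-1, mu_B = 3.47e-2, mu_X = 2e-2,     # 1 / h
    r = 7e-2,                # 1 / h
    K = 2.5e-3,              # g / mm^3
    lambda_1 = 5e-14,        # 1 / h
    beta = 3.12e-17,         # 1 / h
    mu_C = 3e-3,             # 1 / h
    alpha = 2,               # uM
    lambda_L = 1.34e-11,     # g / (mm^3 h)
    k1 = 1, k2 = 5e-2,       # 1 / uM
    k3 = 6.56e-17,           # 1 / h
    mu_L = 8.15e-2, mu_T = 5e-3, mu_A = 4.95e-2,  # 1 / h
    th_B = 8, th_X = 8,      # nondimensional thresholds (working system)
    csc_on = 20 * 24, csc_off = 25 * 24,
    f_T = NA_real_, f_c = NA_real_, omega_1 = 0.5, omega_2 = 0.5,
    unit_system = "dimensional")
  validate_parameter_set(p)
}

#' Standard initial state
#'
#' The neutral starting state of all treatment-arm simulations:
#' `(L, F, B, X, S, C) = (0, 0, 5, 0, 0.25, 0.01)`, i.e. no IL-6 or NF-kB,
#' Bcl-2 midway between its floor and threshold, no BAX, the baseline CSC
#' density, and a small tumor seed.  Drug levels are appended by
#' [simulate_model()] from the protocol.
#'
#' @return Named numeric vector with elements `F, B, X, C, S, L`.
#' @export
default_initial_state <- function() {
  c(F = 0, B = 5, X = 0, C = 0.01, S = 0.25, L = 0)
}

#' Unit-system scale constants
#'
#' Positive scale factors linking the dimensional and nondimensional systems:
#' one per state variable (`F_s, B_s, X_s, C_s, S_s, L_s, A_s, T_s`) plus the
#' time scale `t_s` (hours per nondimensional time unit).  Identity scales
#' (all 1) make [convert_units()] the identity map.
#'
#' @param F_s,B_s,X_s,C_s,S_s,L_s,A_s,T_s,t_s positive scale factors.
#' @return Named numeric vector of class `crcc_scales`.
#' @export
unit_scales <- function(F_s = 1, B_s = 1, X_s = 1, C_s = 1, S_s = 1,
                        L_s = 1, A_s = 1, T_s = 1, t_s = 1) {
  s <- c(F_s = F_s, B_s = B_s, X_s = X_s, C_s = C_s, S_s = S_s,
         L_s = L_s, A_s = A_s, T_s = T_s, t_s = t_s)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("all scale constants must be finite and > 0")
  structure(s, class = "crcc_scales")
}

#' Convert a parameter set between unit systems
#'
#' Applies the standard rescaling `x = x_s * x~`, `t = t_s * t~` to every
#' parameter.  Rates acquire a factor `t_s` and each source or coupling
#' strength the ratio of the scales it connects; the Hill saturation
#' constants `k1`, `k4`, `k6` and the efficacy weights are dimensionless and
#' untouched.  The thresholds and the CSC window are expressed in the
#' working (nondimensional) units in both systems and are not rescaled.
#' Converting with the same scales in both directions is the identity to
#' machine precision.
#'
#' Note the published dimensional table and the calibrated working set are
#' not related by any single consistent choice of scales: the table's
#' "estimated" entries were evidently fitted in the working system and
#' back-converted independently per parameter.  The scale mapping is
#' therefore user-supplied rather than packaged as a constant.
#'
#' @param params a `crcc_params` object.
#' @param scales a [unit_scales()] vector.
#' @param to target unit system; defaults to the opposite of
#'   `params$unit_system`.
#' @return A `crcc_params` object tagged with the target unit system.
#' @export
convert_units <- function(params, scales = unit_scales(), to = NULL) {
  stopifnot(inherits(params, "crcc_params"))
  if (!inherits(scales, "crcc_scales"))
    stop("scales must be created by unit_scales()")
  if (is.null(to))
    to <- setdiff(c("dimensional", "nondimensional"), params$unit_system)
  if (to == params$unit_system)
    return(params)
  s <- as.list(unclass(scales))
  ## multiplicative factor taking a DIMENSIONAL value to its NONDIMENSIONAL
  ## counterpart; inverted for the reverse direction
  fac <- list(
    lambda_F = s$t_s / s$F_s,
    lambda_2 = s$t_s * s$L_s / s$F_s,
    lambda_B = s$t_s / s$B_s,
    lambda_3 = s$t_s * s$F_s / s$B_s,
    k5       = s$t_s / s$B_s,
    delta    = s$T_s^2,
    lambda_X = s$t_s / s$X_s,
    k7       = s$t_s / s$X_s,
    gamma    = s$B_s^2,
    r        = s$t_s,
    K        = 1 / s$C_s,
    lambda_1 = s$t_s * s$S_s / s$C_s,
    beta     = s$t_s * s$T_s / s$S_s,
    mu_C     = s$t_s,
    alpha    = 1 / s$B_s,
    lambda_L = s$t_s / s$L_s,
    k2       = s$A_s,
    k3       = s$t_s * s$S_s / s$L_s,
    mu_F = s$t_s, mu_B = s$t_s, mu_X = s$t_s, mu_L = s$t_s,
    mu_T = s$t_s, mu_A = s$t_s)
  out <- unclass(params)
  for (nm in names(fac)) {
    f <- if (to == "nondimensional") fac[[nm]] else 1 / fac[[nm]]
    out[[nm]] <- out[[nm]] * f
  }
  out$unit_system <- to
  validate_parameter_set(out)
}

#' Read or write a scenario configuration
#'
#' A scenario is a YAML document with fields `parameters` (any subset of the
#' parameter names), `unit_system`, `initial_state` and `horizon_days`; it is
#' the on-disk exchange format for parameter sets and initial conditions.
#'
#' @param path file path.
#' @return `read_scenario_config()` returns a list with elements `params`
#'   (a `crcc_params`), `initial_state` and `horizon_days`.
#' @export
read_scenario_config <- function(path) {
  doc <- yaml::read_yaml(path)
  us <- doc$unit_system %||% "nondimensional"
  over <- doc$parameters %||% list()
  params <- do.call(parameter_set, c(over, list(unit_system = us)))
  init <- default_initial_state()
  if (!is.null(doc$initial_state)) {
    iv <- unlist(doc$initial_state)
    unknown <- setdiff(names(iv), names(init))
    if (length(unknown))
      stop("unknown state variable(s) in config: ",
           paste(unknown, collapse = ", "))
    init[names(iv)] <- iv
  }
  list(params = params,
       initial_state = init,
       horizon_days = doc$horizon_days %||% 40)
}

#' @rdname read_scenario_config
#' @param scenario a list as returned by `read_scenario_config()`.
#' @export
write_scenario_config <- function(scenario, path) {
  p <- scenario$params
  doc <- list(
    unit_system = p$unit_system,
    parameters = lapply(unclass(p)[setdiff(names(p), "unit_system")],
                        function(v) unname(v)),
    initial_state = as.list(scenario$initial_state),
    horizon_days = scenario$horizon_days %||% 40)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @export
print.crcc_params <- function(x, ...) {
  cat("<crcc_params> (", x$unit_system, ")\n", sep = "")
  num <- unlist(x[setdiff(names(x), "unit_system")])
  print(signif(num, 6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
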