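#' Latin hypercube sampling design
#'
#' The global sensitivity analysis samples the uncertain parameters
#' (default: the eight without direct experimental support) by stratified
#' Latin hypercube sampling: each parameter's range is divided into
#' `n_samples` equal-width subintervals and exactly one draw falls in each,
#' with the strata randomly permuted per parameter.  Default ranges are
#' baseline value x \[0.5, 1.5\].
#'
#' @param params baseline [parameter_set()] used for the default ranges.
#' @param param_names parameters to sample.
#' @param ranges named list of `c(lo, hi)` ranges; defaults to
#'   `baseline * range_factor`.
#' @param range_factor multiplicative half-width of the default ranges.
#' @param n_samples number of samples (>= 2).
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @return Object of class `crcc_design`.
#' @export
sampling_design <- function(params = default_parameters(),
                            param_names = c("lambda_2", "delta", "gamma",
                                            "r", "lambda_1", "mu_C",
                                            "k2", "k3"),
                            ranges = NULL, range_factor = c(0.5, 1.5),
                            n_samples = 1000, seed = 1) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (is.null(ranges))
    ranges <- lapply(stats::setNames(param_names, param_names),
                     function(nm) params[[nm]] * range_factor)
  stopifnot(setequal(names(ranges), param_names))
  for (nm in param_names) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || rg[1] >= rg[2])
      stop("range for ", nm, " must be c(lo, hi) with lo < hi")
  }
  structure(list(param_names = param_names, ranges = ranges,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "crcc_design")
}

#' Draw a Latin hypercube sample
#'
#' @param design a [sampling_design()].
#' @return `n_samples x p` matrix with one column per parameter; each
#'   marginal has exactly one draw per equal-width stratum.
#' @export
lhs_sample <- function(design) {
  stopifnot(inherits(design, "crcc_design"))
  set.seed(design$seed)
  u <- lhs::randomLHS(design$n_samples, length(design$param_names))
  colnames(u) <- design$param_names
  for (nm in design$param_names) {
    rg <- design$ranges[[nm]]
    u[, nm] <- rg[1] + u[, nm] * (rg[2] - rg[1])
  }
  u
}

#' Simulate the model over a sampled parameter ensemble
#'
#' Runs one simulation per sample row, overriding the baseline parameters by
#' the sampled values, and records the five reported outputs
#' `(C, L, F, B, X)` at each evaluation time.  Rows whose integration fails
#' are dropped (with a message listing their indices); more than 5% failures
#' is an error, since it indicates a design outside the model's valid range.
#'
#' @param samples matrix from [lhs_sample()].
#' @param base_params baseline [parameter_set()].
#' @param protocol treatment protocol under which sensitivities are assessed
#'   (default: the clamped combination arm `T = 1, A = 5`).
#' @param eval_times_h evaluation times in hours.
#' @param outputs state variables to record.
#' @param rtol,atol integration tolerances (ensemble default is coarser than
#'   single-run analyses; the rank-based statistics are insensitive to it).
#' @return Matrix `n_ok x (length(outputs) * length(eval_times_h))` with
#'   columns named `"<output>_<time>"`; attribute `ok` holds the retained
#'   row indices.
#' @export
run_ensemble <- function(samples, base_params,
                         protocol = constant_protocol(1, 5, 40),
                         eval_times_h = c(24, 480, 960),
                         outputs = c("C", "L", "F", "B", "X"),
                         rtol = 1e-6, atol = 1e-8) {
  stopifnot(is.matrix(samples), !is.null(colnames(samples)))
  t_end <- max(eval_times_h)
  cn <- as.vector(outer(outputs, eval_times_h, paste, sep = "_"))
  res <- matrix(NA_real_, nrow(samples), length(cn),
                dimnames = list(NULL, cn))
  failed <- integer()
  for (i in seq_len(nrow(samples))) {
    ok <- tryCatch({
      p_i <- base_params
      p_i[colnames(samples)] <- as.list(samples[i, ])
      p_i <- validate_parameter_set(p_i)
      sim <- simulate_model(p_i, protocol, t_span = c(0, t_end),
                            output_grid = sort(unique(c(0, eval_times_h))),
                            rtol = rtol, atol = atol)
      for (tt in eval_times_h) {
        st <- state_at(sim, tt)
        res[i, paste(outputs, tt, sep = "_")] <- st[outputs]
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failed <- c(failed, i)
  }
  if (length(failed) > 0.05 * nrow(samples))
    stop("more than 5% of ensemble rows failed to integrate")
  if (length(failed)) {
    message("dropped failed ensemble rows: ",
            paste(failed, collapse = ", "))
    res <- res[-failed, , drop = FALSE]
  }
  attr(res, "ok") <- setdiff(seq_len(nrow(samples)), failed)
  res
}

#' Partial rank correlation coefficients
#'
#' For each sampled parameter and each output column: rank-transform all
#' columns (average ranks on ties), regress the parameter's ranks and the
#' output's ranks each on the ranks of all other parameters, and return the
#' Pearson correlation of the two residual vectors.  The sign gives the
#' direction of the parameter's monotone influence on the output after
#' discounting the other parameters.
#'
#' @param samples `n x p` parameter sample matrix (row-aligned with
#'   `outputs`).
#' @param outputs `n x q` output matrix.
#' @return Object of class `crcc_prcc`: `p x q` matrix of coefficients in
#'   `[-1, 1]` with parameter rows and output columns.
#' @export
prcc <- function(samples, outputs) {
  outputs <- as.matrix(outputs)
  if (nrow(samples) != nrow(outputs))
    stop("samples and outputs must be row-aligned")
  const <- function(M) apply(M, 2, function(v) diff(range(v)) == 0)
  if (any(const(samples)))
    stop("constant parameter column(s): ",
         paste(colnames(samples)[const(samples)], collapse = ", "))
  if (any(const(outputs)))
    stop("constant output column(s): ",
         paste(colnames(outputs)[const(outputs)], collapse = ", "))
  R <- apply(samples, 2, rank)
  p <- ncol(R)
  res <- matrix(NA_real_, p, ncol(outputs),
                dimnames = list(colnames(samples), colnames(outputs)))
  for (k in seq_len(ncol(outputs))) {
    ry_full <- rank(outputs[, k])
    for (j in seq_len(p)) {
      Z <- cbind(1, R[, -j, drop = FALSE])
      qz <- qr(Z)
      rx <- qr.resid(qz, R[, j])
      ry <- qr.resid(qz, ry_full)
      res[j, k] <- stats::cor(rx, ry)
    }
  }
  structure(res, class = c("crcc_prcc", "matrix"))
}

#' Long-format PRCC table
#'
#' @param x a `crcc_prcc` matrix whose output columns are named
#'   `"<output>_<time>"`.
#' @param ... unused.
#' @return Data.frame `parameter, output, time_h, prcc`.
#' @export
as.data.frame.crcc_prcc <- function(x, ...) {
  m <- unclass(x)
  parts <- strsplit(colnames(m), "_", fixed = TRUE)
  data.frame(
    parameter = rep(rownames(m), times = ncol(m)),
    output = rep(vapply(parts, `[`, "", 1L), each = nrow(m)),
    time_h = rep(as.numeric(vapply(parts, `[`, "", 2L)), each = nrow(m)),
    prcc = as.vector(m))
}
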