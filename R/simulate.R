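#' Breakpoints of the hybrid system
#'
#' The union of all known discontinuity times of the right-hand side: span
#' endpoints, infusion window edges and the CSC activation window endpoints,
#' sorted and deduplicated within 1e-9 h.  Apoptosis-threshold crossings are
#' state-dependent and located at run time by root-finding instead.
#'
#' @param protocol a `crcc_protocol`.
#' @param params a [parameter_set()].
#' @param t_span numeric length-2, hours.
#' @return Sorted numeric vector of times (hours).
#' @export
event_times <- function(protocol, params, t_span = c(0, protocol$horizon_h)) {
  ev <- c(t_span, params$csc_on, params$csc_off)
  for (ag in c("TZB", "ATV")) {
    a <- protocol[[ag]]
    if (a$mode == "infused" && nrow(a$windows))
      ev <- c(ev, a$windows$start_h, a$windows$start_h + a$windows$duration_h)
  }
  ev <- ev[ev >= t_span[1] - 1e-9 & ev <= t_span[2] + 1e-9]
  ev <- sort(ev)
  ev[!duplicated(round(ev / 1e-9))]
}

## fast internal right-hand side: constant infusion rates and fixed
## indicators within a segment; tolerant of roundoff-scale negatives
rhs_core <- function(t, y, ctx) {
  p <- ctx$p
  y <- pmax(y, 0)
  F_ <- y[1L]; B <- y[2L]; X <- y[3L]; C <- y[4L]
  S <- y[5L]; L <- y[6L]; A <- y[7L]; Td <- y[8L]
  Ia <- if (ctx$per_step) as.numeric(B < p$th_B & X > p$th_X) else ctx$Ia
  dF <- p$lambda_F + p$lambda_2 * L - p$mu_F * F_
  dB <- p$lambda_B + p$lambda_3 * F_ +
    p$k5 * p$k4sq / (p$k4sq + p$delta * Td * Td) - p$mu_B * B
  dX <- p$lambda_X + p$k7 * p$k6sq / (p$k6sq + p$gamma * B * B) - p$mu_X * X
  dC <- p$r * C * (1 - C / p$K) + p$lambda_1 * S -
    p$mu_C * (p$alpha / max(B, 1e-12)) * C * Ia
  dS <- p$beta * Td * ctx$Is
  dL <- p$lambda_L + p$k3 * S / (p$k1 + p$k2 * A) - p$mu_L * L
  dA <- if (ctx$clampA) 0 else ctx$uA - p$mu_A * A
  dT <- if (ctx$clampT) 0 else ctx$uT - p$mu_T * Td
  list(c(dF, dB, dX, dC, dS, dL, dA, dT))
}

rhs_root <- function(t, y, ctx) {
  c(y[2L] - ctx$p$th_B, y[3L] - ctx$p$th_X)
}

#' Simulate the hybrid model
#'
#' Integrates the full system with `deSolve::lsoda`/`lsodar`, splitting the
#' time axis at every known breakpoint ([event_times()]) so that infusion
#' and CSC-window discontinuities fall on integration restarts.  In the
#' canonical `"events"` mode the apoptosis indicator is held constant
#' between threshold crossings of Bcl-2 or BAX, which are located by
#' root-finding and become additional restart points, so the tumor-killing
#' switch flips at crossing times rather than at solver steps.  The
#' `"per-step"` mode instead re-evaluates the indicator inside every
#' right-hand-side call (the classical ode45-style treatment).
#'
#' @param params a [parameter_set()].
#' @param protocol a `crcc_protocol`.
#' @param t_span integration span in hours; defaults to the protocol horizon.
#' @param init named initial state for `F, B, X, C, S, L`
#'   ([default_initial_state()]); initial drug levels come from the protocol
#'   (clamped level, or 0 for infused agents) unless `init` also names
#'   `A`/`T`.
#' @param output_grid output times in hours (default: 1-hour spacing).
#' @param rtol,atol integration tolerances.
#' @param apoptosis_mode `"events"` (canonical) or `"per-step"`.
#' @return Object of class `crcc_sim` with fields `times` (hours), `states`
#'   (matrix, columns `F, B, X, C, S, L, A, T`), `indicators` (matrix with
#'   columns `I_apop`, `I_s`), `events` (data.frame `time`, `kind`),
#'   `params_used`, `protocol`, `rtol`, `atol`, `mode`.
#' @export
simulate_model <- function(params, protocol, t_span = NULL,
                           init = default_initial_state(),
                           output_grid = NULL,
                           rtol = 1e-8, atol = 1e-10,
                           apoptosis_mode = c("events", "per-step")) {
  apoptosis_mode <- match.arg(apoptosis_mode)
  if (is.null(t_span)) t_span <- c(0, protocol$horizon_h)
  if (any(init < 0)) stop("initial state must be nonnegative")
  if (is.null(output_grid))
    output_grid <- seq(t_span[1], t_span[2], by = 1)
  if (min(output_grid) < t_span[1] - 1e-9 ||
      max(output_grid) > t_span[2] + 1e-9)
    stop("output grid must lie within t_span")

  y <- c(F = 0, B = 0, X = 0, C = 0, S = 0, L = 0, A = 0, T = 0)
  y[names(init)] <- init
  if (!"A" %in% names(init))
    y["A"] <- if (protocol$ATV$mode == "clamped") protocol$ATV$level else 0
  if (!"T" %in% names(init))
    y["T"] <- if (protocol$TZB$mode == "clamped") protocol$TZB$level else 0

  p <- unclass(params)
  p$k4sq <- p$k4^2
  p$k6sq <- p$k6^2
  ev <- event_times(protocol, params, t_span)
  grid <- sort(unique(c(output_grid, ev)))

  per_step <- apoptosis_mode == "per-step"
  Ia <- apoptosis_indicator(y[["B"]], y[["X"]], params)
  events <- data.frame(time = ev, kind = "breakpoint")
  rows <- list(); tvec <- list(); ia_seg <- list()

  tcur <- t_span[1]
  for (i in seq_len(length(ev) - 1L)) {
    seg_end <- ev[i + 1L]
    ## indicators / rates constant on this segment
    mid <- (max(tcur, ev[i]) + seg_end) / 2
    ctx <- list(
      p = p, per_step = per_step, Ia = Ia,
      Is = csc_indicator(mid, params),
      clampA = protocol$ATV$mode == "clamped",
      clampT = protocol$TZB$mode == "clamped",
      uA = if (protocol$ATV$mode == "infused")
        infusion_rate(protocol, "ATV", mid) else 0,
      uT = if (protocol$TZB$mode == "infused")
        infusion_rate(protocol, "TZB", mid) else 0)
    repeat {
      tt <- grid[grid >= tcur - 1e-12 & grid <= seg_end + 1e-12]
      tt <- sort(unique(c(tcur, tt, seg_end)))
      if (length(tt) < 2L) break
      out <- if (per_step) {
        deSolve::lsoda(y, tt, rhs_core, ctx, rtol = rtol, atol = atol)
      } else {
        deSolve::lsodar(y, tt, rhs_core, ctx, rootfunc = rhs_root,
                        rtol = rtol, atol = atol)
      }
      if (any(!is.finite(out[nrow(out), ])))
        stop("integration produced non-finite values at t = ",
             out[nrow(out), 1])
      tvec[[length(tvec) + 1L]] <- out[, 1]
      rows[[length(rows) + 1L]] <- out[, -1, drop = FALSE]
      ia_seg[[length(ia_seg) + 1L]] <- rep(Ia, nrow(out))
      tlast <- out[nrow(out), 1]
      y <- out[nrow(out), -1]
      names(y) <- colnames(out)[-1]
      troot <- attr(out, "troot")
      if (!per_step && !is.null(troot) && length(troot) &&
          tlast < seg_end - 1e-9) {
        ## threshold crossing: flip the hybrid mode and restart just past it
        f <- rhs_core(tlast, y, ctx)[[1]]
        h <- 1e-7
        ynext <- pmax(y + h * f, 0)
        Ia_new <- apoptosis_indicator(ynext[["B"]], ynext[["X"]], params)
        kind <- if (Ia_new != Ia) "apoptosis_switch" else "threshold_touch"
        events <- rbind(events, data.frame(time = tlast, kind = kind))
        Ia <- Ia_new
        ctx$Ia <- Ia
        y <- ynext
        tcur <- tlast + h
      } else {
        tcur <- seg_end
        break
      }
    }
    ## refresh the mode at breakpoints in case a discontinuity moved the state
    if (!per_step) {
      Ia_new <- apoptosis_indicator(y[["B"]], y[["X"]], params)
      if (Ia_new != Ia) {
        events <- rbind(events,
                        data.frame(time = tcur, kind = "apoptosis_switch"))
        Ia <- Ia_new
      }
    }
  }

  times <- unlist(tvec)
  states <- do.call(rbind, rows)
  ia <- unlist(ia_seg)
  keep <- !duplicated(round(times / 1e-9))
  times <- times[keep]
  states <- states[keep, , drop = FALSE]
  ia <- ia[keep]
  ## roundoff guard: tiny negatives from the integrator are clipped
  neg <- states < 0
  if (any(states[neg] < -1e-6))
    warning("state components below -1e-6 were clipped to 0")
  states[neg] <- 0
  colnames(states) <- c("F", "B", "X", "C", "S", "L", "A", "T")
  if (per_step)
    ia <- apoptosis_indicator(states[, "B"], states[, "X"], params)
  indicators <- cbind(I_apop = ia, I_s = csc_indicator(times, params))
  events <- events[order(events$time), ]
  rownames(events) <- NULL
  structure(list(times = times, states = states, indicators = indicators,
                 events = events, params_used = params, protocol = protocol,
                 rtol = rtol, atol = atol, mode = apoptosis_mode),
            class = "crcc_sim")
}

#' Extract the state at a time point
#'
#' @param sim a `crcc_sim`.
#' @param t_h time in hours (must be within the simulated span; the nearest
#'   stored grid point within 0.5 h is used).
#' @return Named state vector.
#' @export
state_at <- function(sim, t_h) {
  i <- which.min(abs(sim$times - t_h))
  if (abs(sim$times[i] - t_h) > 0.5)
    stop("requested time not on the output grid")
  sim$states[i, ]
}

#' @export
as.data.frame.crcc_sim <- function(x, ...) {
  data.frame(time_h = x$times, time_d = x$times / 24,
             x$states, I_apop = x$indicators[, "I_apop"],
             I_s = x$indicators[, "I_s"], check.names = FALSE)
}

#' @export
print.crcc_sim <- function(x, ...) {
  cat("<crcc_sim>", length(x$times), "time points over",
      diff(range(x$times)) / 24, "days;",
      sum(x$events$kind == "apoptosis_switch"), "apoptosis switch(es)\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes the tidy trajectory table as CSV and, optionally, a JSON run
#' manifest (parameters, protocol, tolerances, events).
#'
#' @param sim a `crcc_sim`.
#' @param csv_path output CSV path.
#' @param manifest_path optional JSON manifest path.
#' @export
write_simulation <- function(sim, csv_path, manifest_path = NULL) {
  utils::write.csv(as.data.frame(sim), csv_path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    man <- list(
      params = unclass(sim$params_used),
      protocol = list(
        TZB = sim$protocol$TZB, ATV = sim$protocol$ATV,
        horizon_h = sim$protocol$horizon_h),
      rtol = sim$rtol, atol = sim$atol, mode = sim$mode,
      events = sim$events)
    jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(csv_path)
}
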