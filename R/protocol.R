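#' Therapy protocols
#'
#' A therapy protocol fixes, for each agent (trastuzumab `"TZB"` and
#' atorvastatin `"ATV"`), either a clamped constant level or a list of
#' infusion windows (start, duration, dose rate), plus the simulation
#' horizon.  All user-facing times are in days; windows are stored in hours.
#'
#' @param tzb,atv per-agent specification: either
#'   `list(mode = "clamped", level = <value>)` or
#'   `list(mode = "infused", windows = <data.frame start_h, duration_h, dose>)`.
#' @param horizon_days simulation horizon in days.
#' @return Object of class `crcc_protocol`.
#' @export
therapy_protocol <- function(tzb, atv, horizon_days = 40) {
  prot <- list(TZB = validate_agent(tzb, "TZB"),
               ATV = validate_agent(atv, "ATV"),
               horizon_h = horizon_days * 24)
  for (ag in c("TZB", "ATV")) {
    w <- prot[[ag]]$windows
    if (!is.null(w) && nrow(w) && max(w$start_h + w$duration_h) >
          prot$horizon_h + 1e-9)
      stop(ag, " infusion windows extend beyond the horizon")
  }
  structure(prot, class = "crcc_protocol")
}

validate_agent <- function(a, name) {
  if (!is.list(a) || is.null(a$mode))
    stop("agent spec for ", name, " must be a list with a 'mode' field")
  if (a$mode == "clamped") {
    if (is.null(a$level) || a$level < 0)
      stop("clamped level for ", name, " must be >= 0")
    return(list(mode = "clamped", level = as.numeric(a$level)))
  }
  if (a$mode != "infused")
    stop("mode must be 'clamped' or 'infused'")
  w <- a$windows
  if (is.null(w)) w <- data.frame(start_h = numeric(), duration_h = numeric(),
                                  dose = numeric())
  stopifnot(all(c("start_h", "duration_h", "dose") %in% names(w)))
  if (nrow(w)) {
    if (any(w$duration_h <= 0)) stop("window durations must be > 0")
    if (any(w$dose < 0)) stop("window doses must be >= 0")
    if (any(w$start_h < 0)) stop("window starts must be >= 0")
    w <- w[order(w$start_h), , drop = FALSE]
    ends <- w$start_h + w$duration_h
    if (nrow(w) > 1 && any(w$start_h[-1] < ends[-nrow(w)] - 1e-9))
      stop("overlapping infusion windows for ", name)
    rownames(w) <- NULL
  }
  list(mode = "infused", windows = w)
}

#' Constant (clamped) treatment protocol
#'
#' Encodes the four clamped treatment arms: both drugs held at fixed levels
#' for the whole horizon (the `TZB^±ATV^±` arms, e.g. `T = 1, A = 5` for the
#' combination arm).
#'
#' @param T_level,A_level clamped trastuzumab and atorvastatin levels.
#' @param horizon_days horizon in days.
#' @return A `crcc_protocol`.
#' @export
constant_protocol <- function(T_level, A_level, horizon_days = 40) {
  if (T_level < 0 || A_level < 0) stop("clamped levels must be >= 0")
  therapy_protocol(tzb = list(mode = "clamped", level = T_level),
                   atv = list(mode = "clamped", level = A_level),
                   horizon_days = horizon_days)
}

#' Periodic infusion protocol
#'
#' `n_injections` infusion windows of the given agent at
#' `start, start + period, ...`, each of duration `duration_days` and dose
#' rate `dose`, with the other agent clamped at `basal_level` (the scans of
#' periodic atorvastatin run over a basal clamped trastuzumab level).
#' `period_days = 0` denotes continuous infusion: a single window covering
#' the whole horizon at the same dose rate.
#'
#' @param agent `"ATV"` or `"TZB"`.
#' @param dose infusion dose rate while a window is open.
#' @param period_days interval between window starts (days); 0 = continuous.
#' @param duration_days window duration (days).
#' @param n_injections number of windows (ignored for continuous infusion).
#' @param start_days first window start (days).
#' @param basal_level clamped level of the other agent.
#' @param horizon_days horizon in days.
#' @return A `crcc_protocol`.
#' @export
periodic_protocol <- function(agent = c("ATV", "TZB"), dose, period_days,
                              duration_days = 1, n_injections = NULL,
                              start_days = 0, basal_level = 0,
                              horizon_days = 40) {
  agent <- match.arg(agent)
  if (dose < 0) stop("dose must be >= 0")
  if (period_days == 0) {
    w <- data.frame(start_h = start_days * 24,
                    duration_h = (horizon_days - start_days) * 24,
                    dose = dose)
  } else {
    if (period_days < duration_days)
      stop("period shorter than window duration: windows would overlap")
    if (is.null(n_injections))
      n_injections <- floor((horizon_days - start_days) / period_days) + 1
    starts <- (start_days + period_days * (seq_len(n_injections) - 1)) * 24
    starts <- starts[starts + duration_days * 24 <= horizon_days * 24 + 1e-9]
    w <- data.frame(start_h = starts, duration_h = duration_days * 24,
                    dose = dose)
  }
  infused <- list(mode = "infused", windows = w)
  clamped <- list(mode = "clamped", level = basal_level)
  if (agent == "ATV")
    therapy_protocol(tzb = clamped, atv = infused, horizon_days = horizon_days)
  else
    therapy_protocol(tzb = infused, atv = clamped, horizon_days = horizon_days)
}

#' Six-slot alternating schedule codes
#'
#' An alternating schedule distributes three atorvastatin and three
#' trastuzumab infusions over six weekly slots (days 0, 7, ..., 35); a code
#' such as `"ATTTAA"` names the agent injected in each slot.
#'
#' `schedule_code()` validates a code; `enumerate_codes()` lists all
#' `choose(6, 3) = 20` codes in lexicographic order.
#'
#' @param code length-6 string over `{A, T}` with exactly three of each.
#' @return `schedule_code()`: the validated code string;
#'   `enumerate_codes()`: character vector of all 20 codes.
#' @export
schedule_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 6L)
    stop("schedule code must be a single 6-character string")
  ch <- strsplit(code, "")[[1]]
  if (!all(ch %in% c("A", "T")) || sum(ch == "A") != 3L)
    stop("schedule code must contain exactly three 'A' and three 'T'")
  code
}

#' @rdname schedule_code
#' @export
enumerate_codes <- function() {
  ix <- utils::combn(6, 3)
  codes <- apply(ix, 2, function(i) {
    v <- rep("T", 6)
    v[i] <- "A"
    paste(v, collapse = "")
  })
  sort(codes)
}

#' Alternating six-slot infusion protocol
#'
#' Builds the infusion protocol of a [schedule_code()]: six windows at
#' `slot_spacing_days` intervals starting at day 0, slot *k* carrying an
#' atorvastatin window (dose `I_A`, duration `h_A_days`) if the code's *k*-th
#' letter is `A` and a trastuzumab window (dose `I_T`, duration `h_T_days`)
#' otherwise.  Both agents are in infused mode with three injections each.
#'
#' @param code a [schedule_code()].
#' @param I_A,I_T infusion dose rates.
#' @param slot_spacing_days spacing between slots (days).
#' @param h_A_days,h_T_days window durations (days).
#' @param horizon_days horizon in days.
#' @return A `crcc_protocol`.
#' @export
alternating_protocol <- function(code, I_A = 3.3, I_T = 0.075,
                                 slot_spacing_days = 7,
                                 h_A_days = 1, h_T_days = 1,
                                 horizon_days = 40) {
  code <- schedule_code(code)
  ch <- strsplit(code, "")[[1]]
  slots_h <- slot_spacing_days * 24 * (0:5)
  aw <- data.frame(start_h = slots_h[ch == "A"],
                   duration_h = h_A_days * 24, dose = I_A)
  tw <- data.frame(start_h = slots_h[ch == "T"],
                   duration_h = h_T_days * 24, dose = I_T)
  therapy_protocol(tzb = list(mode = "infused", windows = tw),
                   atv = list(mode = "infused", windows = aw),
                   horizon_days = horizon_days)
}

#' Pointwise infusion rate
#'
#' The infusion term of the drug balance equations: the sum of window dose
#' rates over all windows containing `t`, with closed interval endpoints
#' (`t` in `[start, start + duration]` delivers the dose).
#'
#' @param protocol a `crcc_protocol`.
#' @param agent `"ATV"` or `"TZB"`.
#' @param t time(s) in hours; vectorized.
#' @return Numeric vector of dose rates.
#' @export
infusion_rate <- function(protocol, agent = c("ATV", "TZB"), t) {
  agent <- match.arg(agent)
  a <- protocol[[agent]]
  if (a$mode != "infused")
    stop("agent ", agent, " is clamped; infusion_rate is undefined")
  w <- a$windows
  if (!nrow(w)) return(rep(0, length(t)))
  vapply(t, function(tt)
    sum(w$dose[tt >= w$start_h & tt <= w$start_h + w$duration_h]),
    numeric(1))
}

#' Serialize a protocol to or from YAML
#'
#' @param protocol a `crcc_protocol`.
#' @param path file path.
#' @export
write_protocol <- function(protocol, path) {
  enc <- lapply(protocol[c("TZB", "ATV")], function(a) {
    if (a$mode == "clamped") list(mode = "clamped", level = a$level)
    else list(mode = "infused",
              windows = lapply(seq_len(nrow(a$windows)), function(i)
                as.list(a$windows[i, ])))
  })
  yaml::write_yaml(c(enc, list(horizon_days = protocol$horizon_h / 24)),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  dec <- function(a) {
    if (a$mode == "clamped") return(list(mode = "clamped", level = a$level))
    w <- do.call(rbind, lapply(a$windows, as.data.frame))
    if (is.null(w)) w <- data.frame(start_h = numeric(),
                                    duration_h = numeric(), dose = numeric())
    list(mode = "infused", windows = w)
  }
  therapy_protocol(tzb = dec(doc$TZB), atv = dec(doc$ATV),
                   horizon_days = doc$horizon_days)
}

#' @export
print.crcc_protocol <- function(x, ...) {
  cat("<crcc_protocol> horizon", x$horizon_h / 24, "days\n")
  for (ag in c("TZB", "ATV")) {
    a <- x[[ag]]
    if (a$mode == "clamped")
      cat(" ", ag, ": clamped at", a$level, "\n")
    else
      cat(" ", ag, ":", nrow(a$windows), "infusion window(s)\n")
  }
  invisible(x)
}
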