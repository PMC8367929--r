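#' Validate and assemble intravenous dose events
#'
#' @param start Infusion start times, minutes from study start.
#' @param duration Infusion durations, minutes (> 0).
#' @param amount Administered amounts, mg (> 0).
#' @return Tibble sorted by `start` with columns `start`, `duration`,
#'   `amount`.
#' @export
dose_events <- function(start, duration, amount) {
  if (any(duration <= 0) || any(amount <= 0) || any(start < 0)) {
    stop("dose events need start >= 0, duration > 0, amount > 0",
         call. = FALSE)
  }
  dplyr::arrange(
    tibble::tibble(start = start, duration = duration, amount = amount),
    .data$start
  )
}

#' Instantaneous infusion rate of a dosing schedule
#'
#' Each event delivers its amount at the constant rate amount/duration
#' over the half-open window `[start, start + duration)`; overlapping
#' events superpose.
#'
#' @param t Time(s) in minutes.
#' @param events Dose-event tibble ([dose_events()]).
#' @return Rate(s) in mg/min.
#' @export
#' @examples
#' infusion_rate(100, dose_events(0, 240, 3000))  # 12.5 mg/min
infusion_rate <- function(t, events) {
  vapply(t, function(ti) {
    active <- ti >= events$start & ti < events$start + events$duration
    sum(events$amount[active] / events$duration[active])
  }, numeric(1))
}

# Amount administered by time t (exact, piecewise linear in t).
administered_by <- function(t, events) {
  frac <- pmin(1, pmax(0, (t - events$start) / events$duration))
  sum(events$amount * frac)
}

# --- segment machinery ------------------------------------------------------

# Build the integration plan for one patient: per-segment constant
# parameter vectors (infusion rate, physiology) with breakpoints at every
# dose start/stop and lab-panel time, so no discontinuity falls inside a
# solver step.
build_segments <- function(timeline, events, t_end, config) {
  brk <- sort(unique(c(0, timeline$t_start, events$start,
                       events$start + events$duration, t_end)))
  brk <- brk[brk >= 0 & brk <= t_end]
  if (brk[length(brk)] < t_end) brk <- c(brk, t_end)
  t0 <- brk[-length(brk)]
  t1 <- brk[-1]
  mid <- (t0 + t1) / 2
  phys <- physiology_at(timeline, t0)
  rate <- infusion_rate(mid, events)
  base <- matrix(0, nrow = length(t0), ncol = 23L)
  for (i in seq_along(t0)) {
    base[i, ] <- pack_parms(phys[i, ], c(k_cs_isf = 0, k_isf_cs = 0,
                                         k_isf_icf_max = 0,
                                         k_icf_isf_max = 0),
                            config, rate[i])
  }
  list(t0 = t0, t1 = t1, base = base,
       v_isf = phys$v_isf, v_icf = phys$v_icf)
}

.mtx_env <- new.env(parent = emptyenv())

# Pre-resolved native symbols for the compiled derivatives; resolving them
# once per session removes most of the per-segment solver-call overhead.
dll_symbols <- function() {
  sym <- .mtx_env$symbols
  if (is.null(sym)) {
    sym <- tryCatch(
      deSolve:::checkDLL("mtx_derivs", NULL, "mtxpbpk", "mtx_initmod",
                         FALSE, 0L, NULL),
      error = function(e) NULL
    )
    .mtx_env$symbols <- if (is.null(sym)) FALSE else sym
  }
  if (isFALSE(sym)) NULL else .mtx_env$symbols
}

solve_segment <- function(y, times, parms, rtol, atol) {
  sym <- dll_symbols()
  if (is.null(sym)) {
    deSolve::ode(y = y, times = times, func = "mtx_derivs", parms = parms,
                 dllname = "mtxpbpk", initfunc = "mtx_initmod",
                 method = "lsoda", rtol = rtol, atol = atol)
  } else {
    deSolve::lsoda(y = y, times = times, func = sym, parms = parms,
                   rtol = rtol, atol = atol)
  }
}

# Integrate a patient's segments, returning the state matrix at the
# requested output times (must include 0 implicitly; times strictly
# inside [0, t_end]).
integrate_segments <- function(segments, pop, times_out, rtol, atol,
                               y0 = NULL) {
  parms <- segments$base
  parms[, 17] <- pop[["k_cs_isf"]] * segments$v_isf
  parms[, 18] <- pop[["k_isf_cs"]] * segments$v_isf
  parms[, 19] <- pop[["k_isf_icf_max"]] * segments$v_icf
  parms[, 20] <- pop[["k_icf_isf_max"]] * segments$v_icf
  y <- if (is.null(y0)) numeric(7L) else y0
  n_seg <- length(segments$t0)
  out <- matrix(NA_real_, nrow = length(times_out), ncol = 7L)
  for (i in seq_len(n_seg)) {
    t0 <- segments$t0[i]; t1 <- segments$t1[i]
    keep <- which(times_out > t0 & times_out <= t1)
    times <- c(t0, times_out[keep], if (!length(keep) ||
                                        times_out[keep[length(keep)]] < t1) t1)
    times <- unique(times)
    if (all(y == 0) && parms[i, 23L] == 0) {
      # drug-free and no infusion: the state stays identically zero
      if (length(keep)) out[keep, ] <- 0
      next
    }
    sol <- solve_segment(y, times, parms[i, ], rtol, atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop("ODE integration failed in segment [", t0, ", ", t1,
           "] min (state: ", paste(signif(y, 6), collapse = ", "), ")",
           call. = FALSE)
    }
    m <- sol[, -1, drop = FALSE]
    if (length(keep)) out[keep, ] <- m[match(times_out[keep], times), ]
    y <- m[nrow(m), ]
  }
  zero <- which(times_out <= segments$t0[1])
  if (length(zero)) out[zero, ] <- matrix(rep(if (is.null(y0)) numeric(7L)
                                              else y0, each = length(zero)),
                                          nrow = length(zero))
  list(states = out, final = y)
}

#' Simulate a multi-infusion course
#'
#' Integrates the five-compartment system over a dosing course with the
#' patient's piecewise-constant physiology, restarting the stiff solver at
#' every infusion start/stop and lab-panel time.  Cumulative renal and
#' hepatic eliminations are carried as auxiliary ODE states so the mass
#' balance can be audited exactly.  The initial condition is a drug-free
#' body.
#'
#' @param profile One-row patient covariate tibble (`sex`, `age`,
#'   `weight`, `height`, `race`).
#' @param panels Lab-panel tibble (`time`, `hct`, `scr`).
#' @param events Dose-event tibble ([dose_events()]).
#' @param pop [population_params()]; defaults to the packaged mean fitted
#'   values.
#' @param t_end End of the simulation horizon, minutes (beyond the last
#'   event).
#' @param sample_times Output time grid; defaults to 600 points spanning
#'   the horizon plus all breakpoints.
#' @param config Model configuration.
#' @param rtol,atol Solver tolerances (default from config: 1e-8, 1e-12 mg).
#' @param timeline Optional pre-built (possibly hand-modified)
#'   [physiology_timeline()]; when supplied, `profile`/`panels` are not
#'   used to derive physiology.  Useful for counterfactual simulations
#'   (e.g. a fixed GFR).
#' @return An object of class `mtx_sim`: a list with `trace` (tibble of
#'   times, per-compartment amounts in mg and concentrations in mg/mL,
#'   cumulative eliminations) and `audit` (administered, in-body and
#'   eliminated amounts and the mass-balance residual).
#' @export
simulate_course <- function(profile, panels, events,
                            pop = default_population(config),
                            t_end, sample_times = NULL,
                            config = load_config(),
                            rtol = config$solver$rtol,
                            atol = config$solver$atol,
                            timeline = NULL) {
  events <- dose_events(events$start, events$duration, events$amount)
  if (nrow(events) && t_end < max(events$start + events$duration)) {
    stop("`t_end` must lie beyond the last dose event", call. = FALSE)
  }
  if (is.null(timeline)) {
    timeline <- physiology_timeline(profile, panels, config)
  }
  segments <- build_segments(timeline, events, t_end, config)
  if (is.null(sample_times)) {
    sample_times <- sort(unique(c(segments$t0, segments$t1,
                                  seq(0, t_end, length.out = 600L))))
  }
  sample_times <- sort(unique(sample_times))
  res <- integrate_segments(segments, pop, sample_times, rtol, atol)
  states <- res$states
  colnames(states) <- state_names
  phys <- physiology_at(timeline, sample_times)
  vols <- as.matrix(phys[, c("v_cs", "v_rcs", "v_hcs", "v_isf", "v_icf")])
  conc <- states[, 1:5, drop = FALSE] / vols
  colnames(conc) <- c("c_cs", "c_rcs", "c_hcs", "c_isf", "c_icf")
  trace <- dplyr::bind_cols(tibble::tibble(time = sample_times),
                            tibble::as_tibble(states),
                            tibble::as_tibble(conc))
  administered <- administered_by(t_end, events)
  final <- unname(res$final)
  in_body <- sum(final[1:5])
  residual <- administered - (in_body + final[6] + final[7])
  out <- list(
    trace = trace,
    audit = list(administered = administered, in_body = in_body,
                 cum_renal = final[6], cum_hepatic = final[7],
                 residual = residual,
                 residual_rel = if (administered > 0)
                   abs(residual) / administered else abs(residual)),
    timeline = timeline, events = events, pop = pop,
    config_hash = config_hash(config)
  )
  class(out) <- "mtx_sim"
  out
}

#' @export
print.mtx_sim <- function(x, ...) {
  a <- x$audit
  cat("<mtx_sim> ", nrow(x$trace), " time points to ",
      max(x$trace$time), " min\n", sep = "")
  cat(sprintf("  administered %.6g mg | in body %.4g | renal %.4g | hepatic %.4g mg\n",
              a$administered, a$in_body, a$cum_renal, a$cum_hepatic))
  cat(sprintf("  mass-balance residual %.3g mg (relative %.2e)\n",
              a$residual, a$residual_rel))
  invisible(x)
}

#' Overall clearance trace and course mean
#'
#' Instantaneous overall clearance (renal excretion plus hepatic
#' elimination rate, referenced to the unbound global plasma
#' concentration) and its concentration-weighted course mean.
#'
#' @param sim An [simulate_course()] result.
#' @param config Model configuration.
#' @param min_conc Times with `c_cs` below this (mg/mL) are excluded from
#'   the trace (the ratio degenerates as concentrations vanish).
#' @return List with `trace` (tibble `time`, `clearance` in mL/min) and
#'   `mean` (mL/min, weighted by `c_cs`).
#' @export
clearance_summary <- function(sim, config = load_config(),
                              min_conc = 0) {
  tr <- sim$trace
  keep <- tr$c_cs > min_conc
  if (!any(keep)) stop("no usable concentrations (all c_cs <= min_conc)",
                       call. = FALSE)
  tr <- tr[keep, ]
  phys <- physiology_at(sim$timeline, tr$time)
  fu <- config$binding$f_plasma_u
  renal <- vapply(seq_len(nrow(tr)), function(i) {
    renal_excretion_rate(tr$c_rcs[i], phys[i, ], config)
  }, numeric(1))
  hepatic <- phys$q_hepatic_clearance * fu * tr$c_hcs
  cl <- (renal + hepatic) / (fu * tr$c_cs)
  list(trace = tibble::tibble(time = tr$time, clearance = cl),
       mean = stats::weighted.mean(cl, tr$c_cs))
}
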