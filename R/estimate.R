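#' @title Population parameter identification
#' @description Mean-squared-log-error objective over a study dataset,
#'   coarse-to-fine grid-search initialization, simplex refinement in
#'   log10-parameter space, and a patient-resampling bootstrap.
#' @name estimate
NULL

# Precompute everything that does not depend on the population parameters:
# per patient, the integration segments, observation times and the local
# plasma volume at those times.  Returns a list with one entry per patient
# plus bookkeeping.
build_sim_plan <- function(dataset, config, drop_blq = TRUE) {
  loq <- config$derived$loq
  ids <- dataset$covariates$patient_id
  plan <- list()
  for (id in ids) {
    obs <- dataset$observations[dataset$observations$patient_id == id, ]
    if (drop_blq) obs <- obs[obs$conc >= loq, ]
    if (nrow(obs) == 0L) next
    if (any(obs$conc <= 0)) {
      stop("non-positive observed concentration for patient ", id,
           call. = FALSE)
    }
    prof <- dataset$covariates[dataset$covariates$patient_id == id, ]
    panels <- dataset$labs[dataset$labs$patient_id == id, ]
    dos <- dataset$doses[dataset$doses$patient_id == id, ]
    events <- dose_events(dos$start, dos$duration, dos$amount)
    t_end <- max(obs$time, events$start + events$duration)
    timeline <- physiology_timeline(prof, panels, config)
    segments <- build_segments(timeline, events, t_end, config)
    obs <- dplyr::arrange(obs, .data$time)
    v_cs <- physiology_at(timeline, obs$time)$v_cs
    plan[[id]] <- list(id = id, segments = segments,
                       obs_time = obs$time, obs_conc = obs$conc,
                       v_cs = v_cs)
  }
  structure(plan, n_obs = sum(vapply(plan, function(p)
    length(p$obs_time), integer(1))))
}

# Simulated total plasma (CS) concentrations at one patient's observation
# times.
plan_sim_conc <- function(p, pop, rtol, atol) {
  res <- integrate_segments(p$segments, pop, p$obs_time, rtol, atol)
  res$states[, 1] / p$v_cs
}

# `weights` gives the multiplicity of each patient (bootstrap resamples
# evaluate duplicated patients once and weight their contribution).
objective_from_plan <- function(plan, pop, config, rtol, atol,
                                weights = NULL) {
  lb <- log(config$objective$log_base)
  if (is.null(weights)) weights <- rep(1, length(plan))
  sse <- 0
  n <- 0
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    sim <- plan_sim_conc(p, pop, rtol, atol)
    if (any(!is.finite(sim)) || any(sim <= 0)) {
      bad <- which(!is.finite(sim) | sim <= 0)[1]
      stop("non-positive simulated concentration for patient ", p$id,
           " at t = ", p$obs_time[bad], " min", call. = FALSE)
    }
    r <- (log(p$obs_conc) - log(sim)) / lb
    sse <- sse + weights[i] * sum(r * r)
    n <- n + weights[i] * length(r)
  }
  sse / n
}

#' Mean-squared-log-error objective
#'
#' The population objective: each patient is simulated once over their
#' full dose and covariate history and the mean of squared log10
#' differences between observed and simulated total plasma concentrations
#' is taken over all observations of all patients.  Observations below
#' the configured quantification limit are excluded.
#'
#' @param dataset An [mtx_dataset()].
#' @param pop [population_params()].
#' @param config Model configuration.
#' @param rtol,atol Solver tolerances (fit-grade defaults from config).
#' @return Non-negative scalar.
#' @export
msle_objective <- function(dataset, pop, config = load_config(),
                           rtol = config$solver$fit_rtol,
                           atol = config$solver$fit_atol) {
  plan <- build_sim_plan(dataset, config)
  objective_from_plan(plan, as_population(pop), config, rtol, atol)
}

#' Coarse-to-fine grid minimization over a log-spaced box
#'
#' Full-factorial evaluation of an objective on a log-uniform grid over
#' `[lower, upper]^4`, followed by `rounds` refinements on a log-spaced
#' grid spanning `incumbent x/÷ refine_factor` (clipped to the box).
#' Deterministic given the grid specification; refinement never increases
#' the incumbent objective.
#'
#' @param f Function of a named 4-vector (the population parameters)
#'   returning a scalar.
#' @param lower,upper Box bounds (applied per parameter).
#' @param n_coarse,n_refine Points per dimension in the coarse pass and
#'   each refinement.
#' @param refine_factor Multiplicative half-width of the refinement box.
#' @param rounds Number of refinement rounds.
#' @return List with `par` (best grid point), `value`, `n_eval`, and the
#'   evaluation `trace` tibble.
#' @export
grid_optimize <- function(f, lower = 1e-8, upper = 1, n_coarse = 5,
                          n_refine = 3, refine_factor = 3, rounds = 1) {
  if (n_coarse < 1 || lower <= 0 || upper <= lower) {
    stop("invalid grid specification", call. = FALSE)
  }
  eval_grid <- function(axes) {
    pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    colnames(pts) <- pop_names
    vals <- apply(pts, 1, function(x) f(setNames(x, pop_names)))
    list(pts = pts, vals = vals)
  }
  axis <- function(lo, hi, n) {
    if (n == 1L) sqrt(lo * hi)
    else exp(seq(log(lo), log(hi), length.out = n))
  }
  axes <- rep(list(axis(lower, upper, n_coarse)), 4L)
  g <- eval_grid(axes)
  best_i <- which.min(g$vals)
  best <- list(par = g$pts[best_i, ], value = g$vals[best_i])
  trace <- list(tibble::tibble(round = 0L, tibble::as_tibble(g$pts),
                               value = g$vals))
  n_eval <- length(g$vals)
  for (r in seq_len(rounds)) {
    axes <- lapply(best$par, function(p) {
      axis(max(lower, p / refine_factor), min(upper, p * refine_factor),
           n_refine)
    })
    g <- eval_grid(axes)
    n_eval <- n_eval + length(g$vals)
    trace[[r + 1L]] <- tibble::tibble(round = r, tibble::as_tibble(g$pts),
                                      value = g$vals)
    i <- which.min(g$vals)
    if (g$vals[i] < best$value) {
      best <- list(par = g$pts[i, ], value = g$vals[i])
    }
  }
  list(par = as_population(best$par), value = best$value, n_eval = n_eval,
       trace = dplyr::bind_rows(trace))
}

#' Grid-search initialization of the population parameters
#'
#' @param dataset An [mtx_dataset()].
#' @param config Model configuration; `config$grid_search` holds the grid
#'   specification (bounds, points per dimension, refinement).
#' @param rtol,atol Solver tolerances used inside the objective.
#' @return As [grid_optimize()], with `par` the best grid point.
#' @export
grid_search <- function(dataset, config = load_config(),
                        rtol = config$solver$fit_rtol,
                        atol = config$solver$fit_atol) {
  plan <- build_sim_plan(dataset, config)
  gs <- config$grid_search
  # extreme grid corners can drive simulated concentrations below the
  # floating-point floor at late observation times; such points are simply
  # non-competitive
  f <- function(p) {
    tryCatch(suppressWarnings(
      objective_from_plan(plan, p, config, rtol, atol)),
      error = function(e) Inf)
  }
  grid_optimize(f, lower = gs$lower, upper = gs$upper,
                n_coarse = gs$n_coarse, n_refine = gs$n_refine,
                refine_factor = gs$refine_factor, rounds = gs$rounds)
}

fit_plan <- function(plan, init, config, rtol, atol, reltol, maxit,
                     weights = NULL, restarts = 1L) {
  f_log <- function(lp) {
    tryCatch(suppressWarnings(
      objective_from_plan(plan, setNames(10^lp, pop_names), config,
                          rtol, atol, weights)),
      error = function(e) Inf)
  }
  init <- as_population(init)
  lp <- log10(as.numeric(init))
  evals <- 0L
  convergence <- FALSE
  value <- Inf
  # the simplex is restarted at the incumbent: a collapsed simplex in a
  # flat valley re-expands and recovers the remaining directions
  for (r in seq_len(restarts + 1L)) {
    opt <- optim(lp, f_log, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit))
    lp <- opt$par
    value <- opt$value
    evals <- evals + unname(opt$counts["function"])
    convergence <- opt$convergence == 0L
  }
  par <- as_population(setNames(10^lp, pop_names))
  init_value <- f_log(log10(as.numeric(init)))
  if (value > init_value) {  # never worse than the starting point
    par <- init
    value <- init_value
  }
  list(par = par, value = value,
       counts = c("function" = evals),
       convergence = convergence)
}

#' Fit the population parameters
#'
#' Unconstrained simplex (Nelder-Mead) minimization of the MSLE objective
#' in log10-parameter space (which enforces positivity), from a supplied
#' initial point — typically the [grid_search()] incumbent.  The returned
#' objective is never worse than at the initial point; non-convergence
#' within the iteration budget is flagged, with the best-so-far
#' parameters returned.
#'
#' @inheritParams grid_search
#' @param init Initial [population_params()].
#' @param reltol,maxit Simplex control (defaults from config).
#' @return An object of class `mtx_fit`: optimal parameters, objective
#'   value, evaluation counts, convergence flag, per-observation
#'   predictions, and provenance (config hash).
#' @export
fit_population <- function(dataset, init, config = load_config(),
                           rtol = config$solver$fit_rtol,
                           atol = config$solver$fit_atol,
                           reltol = config$fit$reltol,
                           maxit = config$fit$maxit) {
  plan <- build_sim_plan(dataset, config)
  res <- fit_plan(plan, init, config, rtol, atol, reltol, maxit,
                  restarts = config$fit$restarts %||% 1L)
  preds <- dplyr::bind_rows(lapply(plan, function(p) {
    tibble::tibble(patient_id = p$id, time = p$obs_time,
                   observed = p$obs_conc,
                   predicted = plan_sim_conc(p, res$par, rtol, atol))
  }))
  out <- list(par = res$par, value = res$value, counts = res$counts,
              convergence = res$convergence, init = as_population(init),
              n_obs = attr(plan, "n_obs"), n_patients = length(plan),
              predictions = preds, config_hash = config_hash(config))
  class(out) <- "mtx_fit"
  out
}

#' @export
print.mtx_fit <- function(x, ...) {
  cat("<mtx_fit> MSLE objective ", signif(x$value, 6), " over ",
      x$n_obs, " observations from ", x$n_patients, " patients\n",
      sep = "")
  print(signif(unclass(x$par), 5))
  if (!x$convergence) cat("  (iteration budget reached before convergence)\n")
  invisible(x)
}

#' Patient-resampling bootstrap of the population fit
#'
#' Resamples patients (never individual observations) with replacement to
#' the original identification-set size, refits each resample starting
#' from `init` (typically the grid-search incumbent), and summarizes the
#' per-parameter resampling distribution.  Failed per-resample fits are
#' excluded and counted, not imputed.  Fully reproducible under `seed`.
#'
#' @inheritParams fit_population
#' @param n_resamples Number of bootstrap resamples (>= 1).
#' @param seed Integer seed (mandatory).
#' @param maxit Simplex budget per resample
#'   (`config$fit$bootstrap_maxit`).
#' @return An object of class `mtx_boot`: per-resample parameter tibble,
#'   per-parameter mean and SD, failure count, seed.
#' @export
bootstrap_population <- function(dataset, n_resamples, seed, init,
                                 config = load_config(),
                                 rtol = config$solver$fit_rtol,
                                 atol = config$solver$fit_atol,
                                 reltol = config$fit$reltol,
                                 maxit = config$fit$bootstrap_maxit) {
  stopifnot(n_resamples >= 1, is.numeric(seed))
  plan <- build_sim_plan(dataset, config)
  ids <- names(plan)
  n <- length(ids)
  init <- as_population(init)
  draws <- with_seed(as.integer(seed), {
    replicate(n_resamples, sample.int(n, n, replace = TRUE),
              simplify = FALSE)
  })
  rows <- vector("list", n_resamples)
  n_failed <- 0L
  for (b in seq_len(n_resamples)) {
    mult <- tabulate(draws[[b]], nbins = n)
    used <- which(mult > 0L)
    res <- tryCatch(
      fit_plan(plan[used], init, config, rtol, atol, reltol, maxit,
               weights = mult[used], restarts = 0L),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[b]] <- tibble::tibble(resample = b, objective = res$value,
                                tibble::as_tibble(as.list(res$par)))
  }
  samples <- dplyr::bind_rows(rows)
  if (nrow(samples) == 0L) stop("all bootstrap fits failed", call. = FALSE)
  summary <- tibble::tibble(
    term = pop_names,
    mean = vapply(pop_names, function(k) mean(samples[[k]]), numeric(1)),
    sd = vapply(pop_names, function(k) stats::sd(samples[[k]]), numeric(1))
  )
  if (n_resamples == 1L) summary$sd <- 0
  out <- list(samples = samples, summary = summary,
              n_resamples = n_resamples, n_failed = n_failed,
              seed = as.integer(seed), init = init,
              config_hash = config_hash(config))
  class(out) <- "mtx_boot"
  out
}

#' @export
print.mtx_boot <- function(x, ...) {
  cat("<mtx_boot> ", x$n_resamples, " resamples (",
      x$n_failed, " failed)\n", sep = "")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' Screen a raw dataset
#'
#' Applies the study inclusion rules: adults only (age >= 18 y), and
#' exclusion of outlier patients showing a plasma concentration above
#' 0.2 umol/L strictly later than 150 h after the start of a 1.5-1.6 g
#' administration.
#'
#' @param dataset An [mtx_dataset()].
#' @param config Model configuration.
#' @return List with `dataset` (screened) and `exclusions` (tibble
#'   `patient_id`, `reason`, `detail` listing the triggering record).
#' @export
screen_dataset <- function(dataset, config = load_config()) {
  excl <- list()
  minors <- dataset$covariates$patient_id[dataset$covariates$age < 18]
  for (id in minors) {
    age <- dataset$covariates$age[dataset$covariates$patient_id == id]
    excl[[length(excl) + 1L]] <- tibble::tibble(
      patient_id = id, reason = "minor",
      detail = paste0("age ", age, " y < 18 y"))
  }
  thr_conc <- convert_concentration(0.2, "umol/L", "mg/mL", config)
  thr_time <- 150 * 60
  for (id in setdiff(dataset$covariates$patient_id, minors)) {
    dos <- dataset$doses[dataset$doses$patient_id == id, ]
    dos <- dos[dos$amount >= 1500 & dos$amount <= 1600, ]
    if (nrow(dos) == 0L) next
    obs <- dataset$observations[dataset$observations$patient_id == id, ]
    obs <- obs[obs$conc > thr_conc, ]
    if (nrow(obs) == 0L) next
    for (i in seq_len(nrow(obs))) {
      lag <- obs$time[i] - dos$start
      hit <- which(lag > thr_time)
      if (length(hit)) {
        excl[[length(excl) + 1L]] <- tibble::tibble(
          patient_id = id, reason = "persistent_concentration",
          detail = sprintf(
            "%.3g umol/L at %.0f min, %.1f h after %.0f mg dose",
            convert_concentration(obs$conc[i], "mg/mL", "umol/L", config),
            obs$time[i], lag[hit[1]] / 60, dos$amount[hit[1]]))
        break
      }
    }
  }
  exclusions <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(patient_id = character(), reason = character(),
                   detail = character())
  drop <- unique(exclusions$patient_id)
  keep <- !dataset$covariates$patient_id %in% drop
  screened <- mtx_dataset(
    dataset$covariates[keep, ],
    dataset$labs[!dataset$labs$patient_id %in% drop, ],
    dataset$doses[!dataset$doses$patient_id %in% drop, ],
    dataset$observations[!dataset$observations$patient_id %in% drop, ]
  )
  list(dataset = screened, exclusions = exclusions)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
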