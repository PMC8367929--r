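#' Specification of a virtual study population
#'
#' Collects the ranges and rates from which virtual patients, dosing
#' courses and observations are drawn.  The defaults mirror the printed
#' structure of the reference cohort: 84 adults (43 men / 41 women),
#' weight 44-100 kg, height 146-181 cm, age 27-83 y, creatinine chosen so
#' absolute estimated GFR spans 35-162 mL/min, 1-17 infusions of 1-9 g
#' over 0.32-7.71 h (administration counts drawn so the mean matches the
#' cohort's 396 infusions over 84 patients, i.e. about 4.7 per patient),
#' daily sampling at a fixed early-morning clock offset, and
#' multiplicative log-normal residual noise with records censored below
#' 0.05 umol/L.
#'
#' @param n_patients Number of virtual patients.
#' @param seed Integer seed (mandatory; every generator call is fully
#'   reproducible under it).
#' @param female_fraction Probability a patient is female.
#' @param weight_range,height_range,age_range,hct_range,scr_range Uniform
#'   covariate ranges (kg, cm, y, fraction, mg/dL).
#' @param gfr_range Target absolute GFR interval (mL/min); creatinine is
#'   redrawn (up to `max_retries`) until the induced GFR falls inside.
#' @param race Race category assigned to all patients.
#' @param n_inf_mean,n_inf_max Administration count: a geometric count
#'   with the given mean, truncated to `[1, n_inf_max]`.
#' @param amount_range,duration_range Infusion amount (mg) and duration
#'   (min) ranges.
#' @param gap_range Inter-infusion gap range, minutes (start to start
#'   gaps are the gap plus the previous duration, so events never
#'   overlap).
#' @param start_window Clock window (minutes after midnight) of the first
#'   infusion start.
#' @param sampling_offset Daily sampling clock time, minutes after
#'   midnight (default 05:30).
#' @param residual_sd Residual SD of the multiplicative noise, log10
#'   units.
#' @param washout_days Days simulated beyond the last infusion.
#' @param max_retries Per-patient creatinine redraws before giving up.
#' @return A list of class `mtx_popspec`.
#' @export
population_spec <- function(n_patients = 84, seed,
                            female_fraction = 41 / 84,
                            weight_range = c(44, 100),
                            height_range = c(146, 181),
                            age_range = c(27, 83),
                            hct_range = c(0.30, 0.45),
                            scr_range = c(0.45, 2.2),
                            gfr_range = c(35, 162),
                            race = "Asian",
                            n_inf_mean = 396 / 84, n_inf_max = 17,
                            amount_range = c(1000, 9000),
                            duration_range = c(19.2, 462.6),
                            gap_range = c(3, 14) * 1440,
                            start_window = c(585, 1395),
                            sampling_offset = 330,
                            residual_sd = 0.15,
                            washout_days = 14,
                            max_retries = 200) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  ranges <- list(weight_range, height_range, age_range, hct_range,
                 scr_range, gfr_range, amount_range, duration_range,
                 gap_range, start_window)
  if (any(vapply(ranges, function(r) diff(r) <= 0, logical(1)))) {
    stop("all ranges must be non-degenerate (min < max)", call. = FALSE)
  }
  stopifnot(n_patients >= 0, residual_sd >= 0, n_inf_mean >= 1,
            n_inf_max >= 1)
  out <- as.list(environment())
  out$ranges <- NULL
  class(out) <- "mtx_popspec"
  out
}

#' Generate virtual patients and their lab panels
#'
#' Covariates are drawn uniformly within the specified ranges; serum
#' creatinine is redrawn per patient until the induced absolute GFR falls
#' inside the target interval.  One lab panel per patient at study start.
#'
#' @param spec A [population_spec()].
#' @param config Model configuration.
#' @return List with `covariates` and `labs` tibbles (see
#'   [mtx_dataset()]).
#' @export
generate_patients <- function(spec, config = load_config()) {
  with_seed(spec$seed, {
    n <- spec$n_patients
    if (n == 0L) {
      return(list(
        covariates = tibble::tibble(patient_id = character(),
                                    sex = character(), age = numeric(),
                                    weight = numeric(), height = numeric(),
                                    race = character()),
        labs = tibble::tibble(patient_id = character(), time = numeric(),
                              hct = numeric(), scr = numeric())))
    }
    runif_in <- function(m, r) runif(m, r[1], r[2])
    cov <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      sex = ifelse(runif(n) < spec$female_fraction, "female", "male"),
      age = runif_in(n, spec$age_range),
      weight = runif_in(n, spec$weight_range),
      height = runif_in(n, spec$height_range),
      race = spec$race
    )
    hct <- runif_in(n, spec$hct_range)
    scr <- numeric(n)
    for (i in seq_len(n)) {
      surface <- bsa(cov$weight[i], cov$height[i], config)
      ok <- FALSE
      for (try in seq_len(spec$max_retries)) {
        cand <- runif_in(1, spec$scr_range)
        g <- as.numeric(estimate_gfr(cand, cov$sex[i], cov$age[i],
                                     cov$race[i], surface, config))
        if (g >= spec$gfr_range[1] && g <= spec$gfr_range[2]) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not draw a creatinine inducing GFR in [",
             spec$gfr_range[1], ", ", spec$gfr_range[2], "] mL/min for ",
             cov$patient_id[i], " after ", spec$max_retries, " retries",
             call. = FALSE)
      }
      scr[i] <- cand
    }
    list(covariates = cov,
         labs = tibble::tibble(patient_id = cov$patient_id, time = 0,
                               hct = hct, scr = scr))
  })
}

#' Generate dosing courses for virtual patients
#'
#' Per patient: a truncated-geometric number of administrations, uniform
#' amounts and durations, a uniform clock time for the first start, and
#' uniform inter-infusion gaps, so events never overlap within a patient.
#'
#' @param patients Output of [generate_patients()] (or its `covariates`
#'   tibble).
#' @inheritParams generate_patients
#' @return Dose tibble: `patient_id`, `start`, `duration`, `amount`.
#' @export
generate_courses <- function(patients, spec) {
  cov <- if (is.data.frame(patients)) patients else patients$covariates
  with_seed(spec$seed + 1L, {
    p_geom <- 1 / spec$n_inf_mean
    rows <- lapply(cov$patient_id, function(id) {
      repeat {
        k <- stats::rgeom(1, p_geom) + 1L
        if (k <= spec$n_inf_max) break
      }
      duration <- runif(k, spec$duration_range[1], spec$duration_range[2])
      amount <- runif(k, spec$amount_range[1], spec$amount_range[2])
      start <- numeric(k)
      start[1] <- runif(1, spec$start_window[1], spec$start_window[2])
      if (k > 1L) {
        gaps <- runif(k - 1L, spec$gap_range[1], spec$gap_range[2])
        for (j in 2:k) start[j] <- start[j - 1L] + duration[j - 1L] + gaps[j - 1L]
      }
      tibble::tibble(patient_id = id, start = start, duration = duration,
                     amount = amount)
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate noisy plasma observations under known parameters
#'
#' Simulates each patient under `true_params`, samples once per 24 h at
#' the specification's clock offset from the first infusion day until the
#' washout horizon, censors (drops) samples whose noise-free
#' concentration is below 0.05 umol/L, and applies multiplicative
#' log-normal noise (SD in log10 units).  Both the noisy observations and
#' the noise-free truth are returned so recovery tests can compare
#' against ground truth.
#'
#' @param patients Output of [generate_patients()].
#' @param courses Dose tibble from [generate_courses()].
#' @param true_params [population_params()] used as ground truth.
#' @inheritParams generate_patients
#' @return List with `observations` (patient_id, time, conc in mg/mL) and
#'   `truth` (same rows, noise-free `conc_true`).
#' @export
generate_observations <- function(patients, courses, true_params, spec,
                                  config = load_config()) {
  true_params <- as_population(true_params)
  loq <- config$derived$loq
  obs_rows <- list()
  truth_rows <- list()
  cov <- patients$covariates
  for (i in seq_len(nrow(cov))) {
    id <- cov$patient_id[i]
    prof <- cov[i, ]
    panels <- patients$labs[patients$labs$patient_id == id, ]
    dos <- courses[courses$patient_id == id, ]
    if (nrow(dos) == 0L) next
    events <- dose_events(dos$start, dos$duration, dos$amount)
    t_end <- max(events$start + events$duration) +
      spec$washout_days * 1440
    # daily samples at the configured clock offset, after the first dose
    days <- seq(0, ceiling(t_end / 1440))
    times <- spec$sampling_offset + days * 1440
    times <- times[times > min(events$start) & times <= t_end]
    timeline <- physiology_timeline(prof, panels, config)
    segments <- build_segments(timeline, events, t_end, config)
    res <- integrate_segments(segments, true_params, times,
                              config$solver$rtol, config$solver$atol)
    v_cs <- physiology_at(timeline, times)$v_cs
    conc_true <- res$states[, 1] / v_cs
    keep <- conc_true >= loq
    if (!any(keep)) next
    truth_rows[[id]] <- tibble::tibble(patient_id = id,
                                       time = times[keep],
                                       conc_true = conc_true[keep])
  }
  truth <- dplyr::bind_rows(truth_rows)
  observations <- with_seed(spec$seed + 2L, {
    noise <- rnorm(nrow(truth), mean = 0, sd = spec$residual_sd)
    tibble::tibble(patient_id = truth$patient_id, time = truth$time,
                   conc = 10^(log10(truth$conc_true) + noise))
  })
  list(observations = observations, truth = truth)
}

#' Generate a complete synthetic study dataset
#'
#' Chains [generate_patients()], [generate_courses()] and
#' [generate_observations()] into a validated [mtx_dataset()]; the
#' noise-free truth table is attached as attribute `"truth"` and the
#' generating parameters as `"true_params"`.
#'
#' @inheritParams generate_observations
#' @param true_params Generating [population_params()] (defaults to the
#'   packaged mean fitted values).
#' @return An [mtx_dataset()].
#' @export
#' @examples
#' \donttest{
#' spec <- population_spec(n_patients = 4, seed = 1)
#' ds <- generate_study(spec)
#' ds
#' }
generate_study <- function(spec, true_params = default_population(config),
                           config = load_config()) {
  patients <- generate_patients(spec, config)
  courses <- generate_courses(patients, spec)
  obs <- generate_observations(patients, courses, true_params, spec,
                               config)
  ds <- mtx_dataset(patients$covariates, patients$labs, courses,
                    obs$observations)
  attr(ds, "truth") <- obs$truth
  attr(ds, "true_params") <- as_population(true_params)
  attr(ds, "spec_seed") <- spec$seed
  ds
}
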