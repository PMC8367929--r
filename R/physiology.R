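#' @title Individualized physiology
#' @description Functions mapping patient covariates (sex, age, weight,
#'   height) and time-stamped laboratory values (hematocrit, serum
#'   creatinine) to the individualized physiological parameters of the
#'   model: compartment volumes, plasma flows, glomerular filtration rate,
#'   hepatic clearance, and renal transport maxima.
#' @name physiology
NULL

check_sex <- function(sex) {
  if (length(sex) != 1L || !sex %in% c("male", "female")) {
    stop("`sex` must be \"male\" or \"female\", got: ",
         paste(sex, collapse = ", "), call. = FALSE)
  }
  sex
}

#' Total blood volume from sex and body weight
#'
#' Linear per-kg rule: 72 mL/kg for men, 65 mL/kg for women (from the
#' reference blood volumes of a 73 kg man and a 60 kg woman).
#'
#' @param sex `"male"` or `"female"`.
#' @param weight Body weight in kg.
#' @param config Model configuration.
#' @return Blood volume in mL.
#' @export
#' @examples
#' total_blood_volume("female", 60)  # 3900 mL
total_blood_volume <- function(sex, weight, config = load_config()) {
  check_sex(sex)
  stopifnot(is.numeric(weight), all(weight >= 0))
  config$blood$volume_per_kg[[sex]] * weight
}

#' Partition blood volume into plasma compartments
#'
#' Plasma is blood times (1 - hematocrit); the renal and hepatic
#' circulatory-system plasma volumes are fixed fractions (2% and 10%) of
#' total plasma and the global circulatory system holds the remainder, so
#' the three parts sum exactly to total plasma.
#'
#' @param blood_volume Total blood volume, mL.
#' @param hematocrit Hematocrit as a fraction in \[0, 1).
#' @inheritParams total_blood_volume
#' @return A one-row tibble with `v_plasma`, `v_cs`, `v_rcs`, `v_hcs` (mL).
#' @export
plasma_volumes <- function(blood_volume, hematocrit, config = load_config()) {
  stopifnot(blood_volume >= 0)
  if (!is.numeric(hematocrit) || hematocrit < 0 || hematocrit >= 1) {
    stop("`hematocrit` must be a fraction in [0, 1)", call. = FALSE)
  }
  v_plasma <- blood_volume * (1 - hematocrit)
  v_rcs <- config$blood$rcs_fraction * v_plasma
  v_hcs <- config$blood$hcs_fraction * v_plasma
  tibble::tibble(
    v_plasma = v_plasma,
    v_cs = v_plasma - v_rcs - v_hcs,
    v_rcs = v_rcs,
    v_hcs = v_hcs
  )
}

#' Body water volumes from sex-specific reference spaces
#'
#' Extracellular and intracellular water scale linearly with body weight
#' from configured sex-specific per-kg reference values; the interstitial
#' fluid volume is the difference between extracellular fluid and plasma.
#'
#' @inheritParams total_blood_volume
#' @param v_plasma Total plasma volume, mL.
#' @return A one-row tibble with `v_ecf`, `v_icf`, `v_isf` (mL).
#' @export
body_water_volumes <- function(sex, weight, v_plasma,
                               config = load_config()) {
  check_sex(sex)
  stopifnot(weight > 0, v_plasma >= 0)
  ecw <- config$body_water$ecw_per_kg[[sex]]
  icw <- config$body_water$icw_per_kg[[sex]]
  if (is.null(ecw) || is.null(icw)) {
    stop("missing body-water reference values for sex: ", sex,
         call. = FALSE)
  }
  v_ecf <- ecw * weight
  v_isf <- v_ecf - v_plasma
  if (v_isf <= 0) {
    stop("non-positive interstitial volume (ECF ", round(v_ecf),
         " mL <= plasma ", round(v_plasma), " mL)", call. = FALSE)
  }
  tibble::tibble(v_ecf = v_ecf, v_icf = icw * weight, v_isf = v_isf)
}

#' Body surface area (Du Bois)
#'
#' @inheritParams total_blood_volume
#' @param height Height in cm.
#' @return BSA in m^2.
#' @export
#' @examples
#' bsa(73, 176)
bsa <- function(weight, height, config = load_config()) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("`weight` and `height` must be positive", call. = FALSE)
  }
  b <- config$bsa
  b$coefficient * weight^b$weight_exponent * height^b$height_exponent
}

#' Plasma cardiac output and regional plasma flows
#'
#' Resting blood cardiac output from a configured allometric model
#' (sex-specific reference output scaled by BSA, with a linear fractional
#' decline per year beyond a reference age), converted to plasma flow via
#' (1 - hematocrit).  Renal and hepatic plasma flows are configured
#' sex-specific fractions of the plasma cardiac output.  Covariates outside
#' the configured validity ranges trigger a warning but a value is still
#' returned.
#'
#' @inheritParams total_blood_volume
#' @param age Age in years.
#' @param height Height in cm.
#' @param hematocrit Hematocrit fraction.
#' @return One-row tibble with `q_co_plasma`, `q_cs_rcs`, `q_cs_hcs`
#'   (mL/min) and the fractions used.
#' @export
cardiac_output <- function(sex, age, weight, height, hematocrit,
                           config = load_config()) {
  check_sex(sex)
  co <- config$cardiac_output
  v <- co$validity
  if (!is.null(v)) {
    checks <- c(age = age, weight = weight, height = height)
    for (nm in names(checks)) {
      rng <- v[[nm]]
      if (!is.null(rng) && (checks[[nm]] < rng[1] || checks[[nm]] > rng[2])) {
        warning("covariate `", nm, "` = ", checks[[nm]],
                " outside the cardiac-output model validity range [",
                rng[1], ", ", rng[2], "]", call. = FALSE)
      }
    }
  }
  surface <- bsa(weight, height, config)
  decline <- 1 - co$age_decline_per_year * max(0, age - co$age_ref)
  decline <- max(decline, 0.5)
  q_blood <- co$co_ref[[sex]] * (surface / co$bsa_ref[[sex]]) * decline
  q_plasma <- q_blood * (1 - hematocrit)
  f_kid <- co$kidney_fraction[[sex]]
  f_liv <- co$liver_fraction[[sex]]
  tibble::tibble(
    q_co_blood = q_blood,
    q_co_plasma = q_plasma,
    q_cs_rcs = f_kid * q_plasma,
    q_cs_hcs = f_liv * q_plasma,
    kidney_fraction = f_kid,
    liver_fraction = f_liv
  )
}

#' Estimate the glomerular filtration rate
#'
#' CKD-EPI (2009) creatinine equation with a 4-level race coefficient
#' (White, Asian, Black, Other), returning eGFR normalized to 1.73 m^2.
#' The absolute GFR is obtained by de-normalizing with the patient's BSA
#' and is capped at the 97.5th percentile of the full-age-spectrum (FAS)
#' eGFR reference interval for the patient's age.
#'
#' @param serum_creatinine Serum creatinine, mg/dL.
#' @inheritParams cardiac_output
#' @param race One of `"White"`, `"Asian"`, `"Black"`, `"Other"`.
#' @param bsa Body surface area, m^2.
#' @param normalized If `TRUE`, return eGFR in mL/min/1.73 m^2 (uncapped);
#'   otherwise (default) absolute mL/min with the FAS cap applied.
#' @return GFR (mL/min, or mL/min/1.73 m^2 when `normalized = TRUE`), with
#'   attribute `"capped"` indicating whether the FAS bound was binding.
#' @export
#' @examples
#' estimate_gfr(0.8, "female", 50, "White", bsa = 1.73)
estimate_gfr <- function(serum_creatinine, sex, age, race, bsa,
                         config = load_config(), normalized = FALSE) {
  check_sex(sex)
  if (any(serum_creatinine <= 0)) {
    stop("`serum_creatinine` must be positive", call. = FALSE)
  }
  ck <- config$ckd_epi
  if (!race %in% names(ck$race_factor)) {
    stop("unknown race category: ", race, " (expected ",
         paste(names(ck$race_factor), collapse = ", "), ")", call. = FALSE)
  }
  kappa <- ck$kappa[[sex]]
  alpha <- ck$alpha[[sex]]
  ratio <- serum_creatinine / kappa
  egfr <- ck$intercept * pmin(ratio, 1)^alpha * pmax(ratio, 1)^ck$beta *
    ck$age_factor^age * ck$race_factor[[race]]
  if (sex == "female") egfr <- egfr * ck$female_factor
  if (normalized) return(egfr)
  absolute <- egfr * bsa / ck$normalization_bsa
  cap <- fas_gfr_cap(age, bsa, config)
  capped <- absolute > cap
  out <- pmin(absolute, cap)
  attr(out, "capped") <- capped
  out
}

#' Upper reference bound for GFR (full-age-spectrum equation)
#'
#' Absolute GFR at the 97.5th percentile of the FAS eGFR reference
#' interval: the normalized FAS value at the lower reference bound of
#' creatinine/Q, with a multiplicative decline per year beyond the age
#' knot, de-normalized by BSA/1.73.
#'
#' @inheritParams estimate_gfr
#' @return Cap in mL/min.
#' @export
fas_gfr_cap <- function(age, bsa, config = load_config()) {
  fc <- config$fas_cap
  norm_cap <- fc$gfr_normal / fc$scr_q_lower *
    fc$age_decline^pmax(0, age - fc$age_knot)
  norm_cap * bsa / config$ckd_epi$normalization_bsa
}

#' Renal tubular transport maxima
#'
#' Maximum secretion and reabsorption rates, proportional to GFR from
#' their values at the reference GFR of 100 mL/min (5.189 and
#' 1.038 ug/min).
#'
#' @param q_gfr GFR in mL/min.
#' @inheritParams total_blood_volume
#' @return One-row tibble with `m_secretion_max`, `m_reabsorption_max`
#'   in ug/min.
#' @export
renal_transport_maxima <- function(q_gfr, config = load_config()) {
  if (any(q_gfr < 0)) stop("`q_gfr` must be non-negative", call. = FALSE)
  scale <- q_gfr / config$renal$gfr_ref
  tibble::tibble(
    m_secretion_max = config$renal$m_secretion_max_ref * scale,
    m_reabsorption_max = config$renal$m_reabsorption_max_ref * scale
  )
}

#' Hepatic clearance as a fixed share of GFR
#'
#' @inheritParams renal_transport_maxima
#' @return Hepatic clearance in mL/min (default 4% of GFR).
#' @export
hepatic_clearance <- function(q_gfr, config = load_config()) {
  if (any(q_gfr < 0)) stop("`q_gfr` must be non-negative", call. = FALSE)
  config$hepatic$fraction_of_gfr * q_gfr
}

#' Full individualized parameter set for one patient at one lab panel
#'
#' @param profile One-row tibble/list with `sex`, `age`, `weight`,
#'   `height`, `race` (and optionally `patient_id`).
#' @param panel One-row tibble/list with `hct` and `scr` (hematocrit
#'   fraction and serum creatinine in mg/dL).
#' @inheritParams total_blood_volume
#' @return One-row tibble with all individualized parameters (volumes in
#'   mL, flows and clearances in mL/min, transport maxima in ug/min, BSA
#'   in m^2).
#' @export
physiology_params <- function(profile, panel, config = load_config()) {
  profile <- as.list(profile)
  panel <- as.list(panel)
  if (!is.null(profile$age) && profile$age < 18) {
    stop("adult model: age must be >= 18 y", call. = FALSE)
  }
  blood <- total_blood_volume(profile$sex, profile$weight, config)
  pv <- plasma_volumes(blood, panel$hct, config)
  bw <- body_water_volumes(profile$sex, profile$weight, pv$v_plasma, config)
  surface <- bsa(profile$weight, profile$height, config)
  flows <- cardiac_output(profile$sex, profile$age, profile$weight,
                          profile$height, panel$hct, config)
  q_gfr <- as.numeric(estimate_gfr(panel$scr, profile$sex, profile$age,
                                   profile$race, surface, config))
  maxima <- renal_transport_maxima(q_gfr, config)
  tibble::tibble(
    v_plasma = pv$v_plasma, v_cs = pv$v_cs, v_rcs = pv$v_rcs,
    v_hcs = pv$v_hcs, v_isf = bw$v_isf, v_icf = bw$v_icf,
    q_co_plasma = flows$q_co_plasma, q_cs_rcs = flows$q_cs_rcs,
    q_cs_hcs = flows$q_cs_hcs,
    q_gfr = q_gfr,
    q_hepatic_clearance = hepatic_clearance(q_gfr, config),
    m_secretion_max = maxima$m_secretion_max,
    m_reabsorption_max = maxima$m_reabsorption_max,
    bsa = surface
  )
}

#' Piecewise-constant physiology timeline from time-stamped lab panels
#'
#' Physiological parameters are re-evaluated at every lab-panel time and
#' held constant until the next panel (left-closed intervals: a lab taken
#' at time t takes effect at t).  The first panel extends back to the
#' study start.
#'
#' @inheritParams physiology_params
#' @param panels Tibble of lab panels with columns `time` (minutes from
#'   study start), `hct`, `scr`; sorted, unique times.
#' @return A tibble of class `mtx_physiology` with column `t_start`
#'   followed by the parameter columns of [physiology_params()].
#' @export
physiology_timeline <- function(profile, panels, config = load_config()) {
  panels <- tibble::as_tibble(panels)
  if (nrow(panels) == 0L) {
    stop("at least one lab panel is required", call. = FALSE)
  }
  panels <- dplyr::arrange(panels, .data$time)
  if (anyDuplicated(panels$time)) {
    stop("lab panel times must be unique", call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(panels)), function(i) {
    physiology_params(profile, panels[i, ], config)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(t_start = panels$time),
    dplyr::bind_rows(rows)
  )
  class(out) <- c("mtx_physiology", class(out))
  out
}

#' Look up the physiology in force at a time point
#'
#' Left-closed step lookup: at a panel time the new panel's parameters are
#' already in force; before the first panel the first panel applies.
#'
#' @param timeline A [physiology_timeline()] result.
#' @param t Time in minutes (scalar or vector).
#' @return Tibble with one row per element of `t`.
#' @export
physiology_at <- function(timeline, t) {
  idx <- findInterval(t, timeline$t_start)
  idx[idx < 1L] <- 1L
  timeline[idx, setdiff(names(timeline), "t_start"), drop = FALSE]
}
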