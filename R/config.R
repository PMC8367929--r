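#' Load the model configuration
#'
#' Every fixed constant of the model (binding fractions, Michaelis constants,
#' literature covariate-equation coefficients, solver tolerances, search
#' settings) lives in a YAML configuration file; no numeric constant is
#' hard-coded in the package source.  `load_config()` reads the packaged
#' defaults (or a user file) and applies optional overrides.
#'
#' @param path Path to a YAML configuration file.  `NULL` (default) loads the
#'   configuration shipped with the package.
#' @param overrides Named list of overrides using `$`-style nested names,
#'   e.g. `list(binding = list(f_plasma_u = 0.6))`.  Only the named leaves
#'   are replaced; every override is recorded in the `"overrides"` attribute
#'   and reported via a message.
#' @param quiet Suppress the override message.
#'
#' @return A validated nested list of class `mtx_config`.  Derived constants
#'   (Michaelis constants in mg/mL, reference transport maxima in mg/min)
#'   are attached under `$derived`.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$binding$f_plasma_u
#' cfg$renal$k50_secretion
load_config <- function(path = NULL, overrides = list(), quiet = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "config", "default.yaml",
                        package = "mtxpbpk", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  flat <- flatten_overrides(overrides)
  for (key in names(flat)) {
    cfg <- assign_nested(cfg, strsplit(key, ".", fixed = TRUE)[[1]],
                         flat[[key]])
  }
  if (length(flat) && !quiet) {
    message("config overrides applied: ",
            paste(names(flat), unlist(flat), sep = " = ", collapse = "; "))
  }
  cfg <- validate_config(cfg)
  cfg$derived <- derive_constants(cfg)
  attr(cfg, "overrides") <- flat
  attr(cfg, "source") <- path
  class(cfg) <- c("mtx_config", "list")
  cfg
}

flatten_overrides <- function(x, prefix = character()) {
  if (!is.list(x)) {
    out <- list(x)
    names(out) <- paste(prefix, collapse = ".")
    return(out)
  }
  if (length(x) == 0L) return(list())
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  out <- list()
  for (nm in names(x)) {
    out <- c(out, flatten_overrides(x[[nm]], c(prefix, nm)))
  }
  out
}

assign_nested <- function(cfg, keys, value) {
  if (length(keys) == 1L) {
    cfg[[keys]] <- value
    return(cfg)
  }
  if (is.null(cfg[[keys[1L]]])) {
    stop("unknown config section: ", keys[1L], call. = FALSE)
  }
  cfg[[keys[1L]]] <- assign_nested(cfg[[keys[1L]]], keys[-1L], value)
  cfg
}

validate_config <- function(cfg) {
  need <- function(section, keys) {
    if (is.null(cfg[[section]])) {
      stop("config is missing section '", section, "'", call. = FALSE)
    }
    miss <- setdiff(keys, names(cfg[[section]]))
    if (length(miss)) {
      stop("config section '", section, "' is missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need("drug", "molar_mass")
  need("blood", c("volume_per_kg", "rcs_fraction", "hcs_fraction"))
  need("body_water", c("ecw_per_kg", "icw_per_kg"))
  need("binding", c("f_plasma_u", "f_isf_u", "f_icf_u"))
  need("cardiac_output", c("co_ref", "bsa_ref", "age_ref",
                           "age_decline_per_year", "kidney_fraction",
                           "liver_fraction"))
  need("bsa", c("coefficient", "weight_exponent", "height_exponent"))
  need("ckd_epi", c("intercept", "kappa", "alpha", "beta", "age_factor",
                    "female_factor", "race_factor", "normalization_bsa"))
  need("fas_cap", c("gfr_normal", "scr_q_lower", "age_knot", "age_decline"))
  need("renal", c("k50_secretion", "k50_reabsorption", "m_secretion_max_ref",
                  "m_reabsorption_max_ref", "gfr_ref"))
  need("hepatic", "fraction_of_gfr")
  need("cellular", c("k50_influx_umol_l", "k50_efflux_umol_l"))
  need("population", c("k_cs_isf", "k_isf_cs", "k_isf_icf_max",
                       "k_icf_isf_max"))
  need("objective", c("log_base", "loq_umol_l"))
  need("solver", c("rtol", "atol", "fit_rtol", "fit_atol"))

  positive <- c(
    cfg$drug$molar_mass,
    unlist(cfg$blood$volume_per_kg),
    unlist(cfg$body_water),
    unlist(cfg$binding),
    cfg$renal$k50_secretion, cfg$renal$k50_reabsorption,
    cfg$renal$m_secretion_max_ref, cfg$renal$m_reabsorption_max_ref,
    cfg$renal$gfr_ref,
    cfg$cellular$k50_influx_umol_l, cfg$cellular$k50_efflux_umol_l,
    unlist(cfg$population),
    cfg$solver$rtol, cfg$solver$atol
  )
  if (any(!is.finite(positive)) || any(positive <= 0)) {
    stop("config constants that must be positive are not", call. = FALSE)
  }
  frac <- c(cfg$blood$rcs_fraction, cfg$blood$hcs_fraction,
            unlist(cfg$binding))
  if (any(frac <= 0) || any(frac >= 1)) {
    stop("config fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  cfg
}

derive_constants <- function(cfg) {
  mw <- cfg$drug$molar_mass
  list(
    # umol/L -> mg/mL: 1 umol/L = mw * 1e-6 g/L = mw * 1e-6 mg/mL
    k50_influx = cfg$cellular$k50_influx_umol_l * mw * 1e-6,
    k50_efflux = cfg$cellular$k50_efflux_umol_l * mw * 1e-6,
    loq = cfg$objective$loq_umol_l * mw * 1e-6,
    # ug/min -> mg/min at the reference GFR
    m_secretion_max_ref = cfg$renal$m_secretion_max_ref * 1e-3,
    m_reabsorption_max_ref = cfg$renal$m_reabsorption_max_ref * 1e-3
  )
}

#' @export
print.mtx_config <- function(x, ...) {
  cat("<mtx_config> minimal methotrexate PBPK configuration\n")
  cat("  source:", attr(x, "source"), "\n")
  ov <- attr(x, "overrides")
  if (length(ov)) {
    cat("  overrides:", paste(names(ov), unlist(ov), sep = " = ",
                              collapse = "; "), "\n")
  } else {
    cat("  overrides: none\n")
  }
  invisible(x)
}

#' Hash of a configuration
#'
#' A short content hash recorded in fit/bootstrap/audit outputs so any
#' artifact can be traced to the exact constant set that produced it.
#'
#' @param config An `mtx_config`.
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  attr(x, "overrides") <- NULL
  attr(x, "source") <- NULL
  json <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  # small polynomial rolling hash; stable across platforms
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
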