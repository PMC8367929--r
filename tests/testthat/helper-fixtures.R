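# Shared fixtures: a reference adult, hand-crafted physiology rows, and
# small seeded synthetic studies.  All fixtures are built in code.

.helper_env <- new.env()

test_cfg <- function() {
  if (is.null(.helper_env$cfg)) .helper_env$cfg <- load_config()
  .helper_env$cfg
}

ref_profile <- function() {
  tibble::tibble(patient_id = "REF", sex = "male", age = 40, weight = 73,
                 height = 176, race = "Asian")
}

ref_panel <- function(time = 0, hct = 0.45, scr = 1.0) {
  tibble::tibble(time = time, hct = hct, scr = scr)
}

# Physiology timeline of the reference adult with selected parameters
# overridden (e.g. q_gfr fixed, eliminations disabled); transport maxima
# are rescaled consistently when q_gfr is overridden unless given.
ref_timeline <- function(..., config = test_cfg()) {
  tl <- physiology_timeline(ref_profile(), ref_panel(), config)
  over <- list(...)
  if (!is.null(over$q_gfr) && is.null(over$m_secretion_max)) {
    mx <- renal_transport_maxima(over$q_gfr, config)
    over$m_secretion_max <- mx$m_secretion_max
    over$m_reabsorption_max <- mx$m_reabsorption_max
  }
  if (!is.null(over$q_gfr) && is.null(over$q_hepatic_clearance)) {
    over$q_hepatic_clearance <- hepatic_clearance(over$q_gfr, config)
  }
  for (nm in names(over)) tl[[nm]] <- over[[nm]]
  tl
}

# Small synthetic study; dosing defaults to a single infusion per patient
# to keep unit tests fast.
small_study <- function(n = 4, seed = 101, n_inf_mean = 1,
                        residual_sd = 0, ...) {
  spec <- population_spec(n_patients = n, seed = seed,
                          n_inf_mean = n_inf_mean,
                          residual_sd = residual_sd, ...)
  generate_study(spec, config = test_cfg())
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
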