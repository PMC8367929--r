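#' Population parameter set
#'
#' The four intensive constants identified by population regression: the
#' capillary exchange constants `k_cs_isf` and `k_isf_cs` (1/min;
#' multiplied by the interstitial volume they give the
#' permeability-surface area products in mL/min) and the maximum cellular
#' uptake/efflux constants `k_isf_icf_max` and `k_icf_isf_max`
#' (mg/mL/min; multiplied by the intracellular volume they give the
#' maximum carrier rates in mg/min).
#'
#' @param k_cs_isf,k_isf_cs,k_isf_icf_max,k_icf_isf_max Positive scalars.
#' @return A named numeric vector of class `mtx_population`.
#' @export
#' @examples
#' default_population()
population_params <- function(k_cs_isf, k_isf_cs, k_isf_icf_max,
                              k_icf_isf_max) {
  p <- c(k_cs_isf = k_cs_isf, k_isf_cs = k_isf_cs,
         k_isf_icf_max = k_isf_icf_max, k_icf_isf_max = k_icf_isf_max)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("population parameters must be positive and finite", call. = FALSE)
  }
  structure(p, class = c("mtx_population", "numeric"))
}

#' @rdname population_params
#' @param config Model configuration supplying the packaged mean fitted
#'   values.
#' @export
default_population <- function(config = load_config()) {
  population_params(config$population$k_cs_isf,
                    config$population$k_isf_cs,
                    config$population$k_isf_icf_max,
                    config$population$k_icf_isf_max)
}

pop_names <- c("k_cs_isf", "k_isf_cs", "k_isf_icf_max", "k_icf_isf_max")

as_population <- function(x) {
  x <- as.numeric(x[pop_names])
  names(x) <- pop_names
  do.call(population_params, as.list(x))
}

state_names <- c("m_cs", "m_rcs", "m_hcs", "m_isf", "m_icf",
                 "cum_renal", "cum_hepatic")

#' Per-compartment concentrations from a model state
#'
#' @param state Named numeric vector of drug amounts (mg) with elements
#'   `m_cs`, `m_rcs`, `m_hcs`, `m_isf`, `m_icf`.
#' @param phys One-row physiology tibble ([physiology_params()]).
#' @return Named vector of concentrations in mg/mL.
#' @export
concentrations <- function(state, phys) {
  vols <- c(phys$v_cs, phys$v_rcs, phys$v_hcs, phys$v_isf, phys$v_icf)
  if (any(vols <= 0)) stop("compartment volumes must be positive",
                           call. = FALSE)
  out <- as.numeric(state[state_names[1:5]]) / vols
  names(out) <- c("c_cs", "c_rcs", "c_hcs", "c_isf", "c_icf")
  out
}

#' Renal excretion rate
#'
#' Free glomerular filtration of unbound drug plus saturable
#' Michaelis-Menten tubular secretion minus saturable reabsorption, both
#' driven by the unbound plasma concentration in the renal circulatory
#' system.
#'
#' @param c_rcs Total concentration in the renal plasma compartment,
#'   mg/mL.
#' @param phys One-row physiology tibble (uses `q_gfr` in mL/min and the
#'   transport maxima in ug/min).
#' @param config Model configuration.
#' @return Excretion rate in mg/min.
#' @export
renal_excretion_rate <- function(c_rcs, phys, config = load_config()) {
  if (any(c_rcs < 0)) stop("`c_rcs` must be non-negative", call. = FALSE)
  fu <- config$binding$f_plasma_u
  cu <- fu * c_rcs
  sec_max <- phys$m_secretion_max * 1e-3    # ug/min -> mg/min
  reab_max <- phys$m_reabsorption_max * 1e-3
  phys$q_gfr * cu +
    sec_max * cu / (config$renal$k50_secretion + cu) -
    reab_max * cu / (config$renal$k50_reabsorption + cu)
}

#' Hepatic elimination rate
#'
#' Linear clearance of unbound drug from the hepatic plasma compartment.
#'
#' @param c_hcs Total concentration in the hepatic plasma compartment,
#'   mg/mL.
#' @inheritParams renal_excretion_rate
#' @return Elimination rate in mg/min.
#' @export
hepatic_elimination_rate <- function(c_hcs, phys, config = load_config()) {
  if (any(c_hcs < 0)) stop("`c_hcs` must be non-negative", call. = FALSE)
  phys$q_hepatic_clearance * config$binding$f_plasma_u * c_hcs
}

#' Capillary exchange flows between plasma and interstitial fluid
#'
#' Passive diffusion of unbound drug; both permeability-surface area
#' products are the intensive constants times the interstitial volume.
#'
#' @param c_cs,c_isf Total concentrations (mg/mL).
#' @param v_isf Interstitial volume, mL.
#' @param pop [population_params()].
#' @inheritParams renal_excretion_rate
#' @return Named vector `c(cs_to_isf, isf_to_cs)` in mg/min.
#' @export
capillary_flows <- function(c_cs, c_isf, v_isf, pop,
                            config = load_config()) {
  stopifnot(c_cs >= 0, c_isf >= 0, v_isf > 0)
  k_cs_isf <- pop[["k_cs_isf"]] * v_isf
  k_isf_cs <- pop[["k_isf_cs"]] * v_isf
  c(cs_to_isf = k_cs_isf * config$binding$f_plasma_u * c_cs,
    isf_to_cs = k_isf_cs * config$binding$f_isf_u * c_isf)
}

#' Carrier-mediated cellular exchange flows
#'
#' Saturable (reduced folate carrier) uptake from interstitial fluid and
#' efflux from intracellular fluid, each Michaelis-Menten in the local
#' unbound concentration, with maximum rates proportional to the
#' intracellular volume.
#'
#' @param c_isf,c_icf Total concentrations (mg/mL).
#' @param v_icf Intracellular volume, mL.
#' @inheritParams capillary_flows
#' @return Named vector `c(isf_to_icf, icf_to_isf)` in mg/min.
#' @export
cellular_flows <- function(c_isf, c_icf, v_icf, pop,
                           config = load_config()) {
  stopifnot(c_isf >= 0, c_icf >= 0, v_icf > 0)
  cu_isf <- config$binding$f_isf_u * c_isf
  cu_icf <- config$binding$f_icf_u * c_icf
  up_max <- pop[["k_isf_icf_max"]] * v_icf
  out_max <- pop[["k_icf_isf_max"]] * v_icf
  c(isf_to_icf = up_max * cu_isf / (config$derived$k50_influx + cu_isf),
    icf_to_isf = out_max * cu_icf / (config$derived$k50_efflux + cu_icf))
}

#' Right-hand side of the five-compartment material balances
#'
#' Reference R implementation of the model derivatives (the simulator uses
#' an equivalent compiled version; the two are cross-checked in the test
#' suite).  State order: `m_cs`, `m_rcs`, `m_hcs`, `m_isf`, `m_icf`, plus
#' two auxiliary states accumulating renal excretion and hepatic
#' elimination so mass balance is auditable.  The componentwise sum of the
#' five compartment derivatives equals infusion minus renal minus hepatic
#' rates by construction.
#'
#' @param t Time (min, unused: the system is autonomous within a dosing
#'   segment).
#' @param state Named numeric vector of amounts (mg), see above.
#' @param infusion_rate Intravenous administration rate, mg/min.
#' @inheritParams capillary_flows
#' @param phys One-row physiology tibble.
#' @return Named derivative vector (mg/min).
#' @export
pk_rhs <- function(t, state, infusion_rate, phys, pop,
                   config = load_config()) {
  if (any(!is.finite(state))) stop("non-finite model state", call. = FALSE)
  m <- pmax(unname(as.numeric(state[state_names[1:5]])), 0)
  conc <- m / c(phys$v_cs, phys$v_rcs, phys$v_hcs, phys$v_isf, phys$v_icf)
  renal <- renal_excretion_rate(conc[2], phys, config)
  hepatic <- hepatic_elimination_rate(conc[3], phys, config)
  cap <- capillary_flows(conc[1], conc[4], phys$v_isf, pop, config)
  cell <- cellular_flows(conc[4], conc[5], phys$v_icf, pop, config)
  q_rcs <- phys$q_cs_rcs * (conc[1] - conc[2])
  q_hcs <- phys$q_cs_hcs * (conc[1] - conc[3])
  d <- c(
    m_cs = infusion_rate - q_rcs - q_hcs - cap[["cs_to_isf"]] +
      cap[["isf_to_cs"]],
    m_rcs = q_rcs - renal,
    m_hcs = q_hcs - hepatic,
    m_isf = cap[["cs_to_isf"]] - cap[["isf_to_cs"]] -
      cell[["isf_to_icf"]] + cell[["icf_to_isf"]],
    m_icf = cell[["isf_to_icf"]] - cell[["icf_to_isf"]],
    cum_renal = renal,
    cum_hepatic = hepatic
  )
  unname(d[state_names])
}

# Pack one segment's constants into the parameter vector consumed by the
# compiled derivatives.  Order must match src/mtx_rhs.c.
pack_parms <- function(phys, pop, config, infusion_rate) {
  c(phys$v_cs, phys$v_rcs, phys$v_hcs, phys$v_isf, phys$v_icf,
    phys$q_cs_rcs, phys$q_cs_hcs, phys$q_gfr, phys$q_hepatic_clearance,
    phys$m_secretion_max * 1e-3, phys$m_reabsorption_max * 1e-3,
    config$renal$k50_secretion, config$renal$k50_reabsorption,
    config$binding$f_plasma_u, config$binding$f_isf_u,
    config$binding$f_icf_u,
    pop[["k_cs_isf"]] * phys$v_isf, pop[["k_isf_cs"]] * phys$v_isf,
    pop[["k_isf_icf_max"]] * phys$v_icf, pop[["k_icf_isf_max"]] * phys$v_icf,
    config$derived$k50_influx, config$derived$k50_efflux,
    infusion_rate)
}
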