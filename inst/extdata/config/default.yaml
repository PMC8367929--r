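# Default model constants and literature coefficients for the minimal
# methotrexate PBPK model.  Canonical internal units are mg, mL, min.
# No numeric constant used by the model is hard-coded in R or C source:
# everything is read from this file (overridable via load_config()).

drug:
  molar_mass: 454.44            # g/mol; reproduces the packaged mg/mL
                                # Michaelis constants from their umol/L values

blood:
  volume_per_kg:                # mL blood per kg body weight
    male: 72.0                  # 5.3 L reference man at 73 kg -> printed rule
    female: 65.0                # 3.9 L reference woman at 60 kg
  rcs_fraction: 0.02            # renal circulatory system share of plasma
  hcs_fraction: 0.10            # hepatic circulatory system share of plasma

body_water:                     # mean reference water spaces, mL per kg,
  ecw_per_kg:                   # scaled linearly with body weight
    male: 239.0
    female: 199.0
  icw_per_kg:
    male: 342.0
    female: 273.0

binding:                        # unbound fractions (bound = 1 - unbound)
  f_plasma_u: 0.58
  f_isf_u: 0.72
  f_icf_u: 0.10                 # intracellular polyglutamation ~90% bound

cardiac_output:                 # allometric resting cardiac output model:
  co_ref:                       # blood CO (mL/min) at the reference BSA,
    male: 6500.0                # scaled by BSA/BSA_ref with a linear decline
    female: 5900.0              # beyond the reference age (ICRP 89 anchors)
  bsa_ref:
    male: 1.90
    female: 1.66
  age_ref: 35.0                 # years; no decline below this age
  age_decline_per_year: 0.005   # fractional decline per year beyond age_ref
  kidney_fraction:              # regional shares of cardiac output
    male: 0.19
    female: 0.17
  liver_fraction:               # total hepatic (arterial + portal)
    male: 0.255
    female: 0.27
  validity:                     # outside -> warning, value still returned
    age: [18.0, 100.0]
    weight: [35.0, 150.0]
    height: [130.0, 210.0]

bsa:                            # Du Bois body surface area, m2
  coefficient: 0.007184
  weight_exponent: 0.425
  height_exponent: 0.725

ckd_epi:                        # CKD-EPI 2009 creatinine equation with the
  intercept: 141.0              # 4-level race coefficient set
  kappa: {male: 0.9, female: 0.7}
  alpha: {male: -0.411, female: -0.329}
  beta: -1.209
  age_factor: 0.993
  female_factor: 1.018
  race_factor: {White: 1.0, Asian: 1.05, Black: 1.16, Other: 1.01}
  normalization_bsa: 1.73       # mL/min/1.73 m2 -> absolute via BSA / 1.73

fas_cap:                        # full-age-spectrum eGFR upper reference bound
  gfr_normal: 107.3             # mL/min/1.73 m2 at Scr/Q = 1
  scr_q_lower: 0.67             # lower reference bound of Scr/Q -> 97.5th
  age_knot: 40.0                # percentile of the eGFR reference interval
  age_decline: 0.988            # multiplicative per year beyond age_knot

renal:
  k50_secretion: 1.3179e-04     # mg/mL, unbound
  k50_reabsorption: 2.6358e-05  # mg/mL, unbound
  m_secretion_max_ref: 5.189    # ug/min at the reference GFR
  m_reabsorption_max_ref: 1.038 # ug/min at the reference GFR
  gfr_ref: 100.0                # mL/min; maxima scale linearly with GFR

hepatic:
  fraction_of_gfr: 0.04         # hepatic clearance = 4% of GFR

cellular:
  k50_influx_umol_l: 3.6        # reduced folate carrier, unbound, umol/L
  k50_efflux_umol_l: 3.6        # efflux assumed to share the influx constant

population:                     # fitted population constants (defaults)
  k_cs_isf: 1.5782e-03          # 1/min
  k_isf_cs: 5.1829e-03          # 1/min
  k_isf_icf_max: 2.4088e-07     # mg/mL/min (per mL of ICF)
  k_icf_isf_max: 5.6171e-06     # mg/mL/min (per mL of ICF)

objective:
  log_base: 10                  # base of the log in the MSLE objective
  loq_umol_l: 0.05              # observations below this are excluded

solver:
  rtol: 1.0e-08
  atol: 1.0e-12                 # mg
  fit_rtol: 1.0e-06             # looser tolerances used inside the
  fit_atol: 1.0e-09             # objective during parameter estimation

grid_search:                    # coarse-to-fine full-factorial 4-D grid
  lower: 1.0e-08
  upper: 1.0
  n_coarse: 5                   # log-spaced points per dimension, coarse pass
  n_refine: 3                   # points per dimension in each refinement
  refine_factor: 3.0            # half-width (x/÷) of the refinement box
  rounds: 1                     # number of refinement rounds

fit:
  reltol: 1.0e-06               # simplex convergence tolerance (objective)
  maxit: 500
  restarts: 1                   # simplex restarts at the incumbent
  bootstrap_maxit: 120          # simplex budget per bootstrap resample
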