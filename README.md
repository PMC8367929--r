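# mtxpbpk

A minimal physiologically based pharmacokinetic (PBPK) simulator and
population-fitting toolkit for intravenous **high-dose methotrexate
(HDMTX)** in adults.

HDMTX (doses above ~500–1000 mg/m²) is used against primary CNS lymphoma,
osteosarcoma and acute lymphoblastic leukemia. Its pharmacokinetics are
dominated by renal excretion and show very large intra- and
inter-individual variability, so patients with reduced kidney function can
accumulate toxic drug levels. `mtxpbpk` is for pharmacometricians and PK
modellers who want a mechanistic, covariate-driven description of MTX
disposition: per-patient physiology is computed a priori from sex, age,
weight, height, hematocrit and serum creatinine, and only four intensive
population constants are estimated from concentration data.

## Model

Five well-mixed compartments — global (CS), renal (RCS) and hepatic (HCS)
plasma, interstitial fluid (ISF) and intracellular fluid (ICF) — with mass
balances (amounts mᵢ in mg, cᵢ = mᵢ/Vᵢ):

```
dm_CS/dt  = ṁ_IV − Q_RCS (c_CS − c_RCS) − Q_HCS (c_CS − c_HCS) − ṁ_CS→ISF + ṁ_ISF→CS
dm_RCS/dt = Q_RCS (c_CS − c_RCS) − ṁ_renal
dm_HCS/dt = Q_HCS (c_CS − c_HCS) − ṁ_hepatic
dm_ISF/dt = ṁ_CS→ISF − ṁ_ISF→CS − ṁ_ISF→ICF + ṁ_ICF→ISF
dm_ICF/dt = ṁ_ISF→ICF − ṁ_ICF→ISF
```

* **Renal excretion** ṁ_renal = Q_GFR·c_RCSᵘ + saturable Michaelis–Menten
  tubular secretion minus reabsorption, all driven by the unbound plasma
  concentration c_RCSᵘ = f_uᵖ·c_RCS (f_uᵖ = 0.58). GFR is individualized
  with the CKD-EPI (2009, 4-level race) creatinine equation, de-normalized
  by BSA/1.73 and capped at the full-age-spectrum (FAS) 97.5th-percentile
  reference bound.
* **Hepatic elimination** is linear in unbound concentration with
  clearance equal to 4% of GFR.
* **Capillary exchange** is passive and permeability-limited:
  ṁ = k·V_ISF·cᵘ in each direction, with intensive constants
  k_CS→ISF, k_ISF→CS (min⁻¹).
* **Cellular exchange** is carrier-mediated (reduced folate carrier):
  saturable uptake and efflux with K₅₀ = 3.6 µmol/L (unbound) and maximum
  rates proportional to V_ICF.

The four intensive constants (k_CS→ISF, k_ISF→CS, k^max_ISF→ICF,
k^max_ICF→ISF) are identified by minimizing the mean squared log10 error
between observed and simulated total plasma concentrations, with a
coarse-to-fine log-grid initialization, Nelder–Mead refinement in log10
space, and a patient-resampling bootstrap. Packaged defaults are the mean
identified values (k_CS→ISF/k_ISF→CS = 0.3045).

## Worked example

Simulate a 3 g / 4 h infusion in a reference adult (male, 40 y, 73 kg,
176 cm, hematocrit 0.45, creatinine 1.0 mg/dL):

```r
library(mtxpbpk)
cfg <- load_config()
patient <- tibble::tibble(patient_id = "REF", sex = "male", age = 40,
                          weight = 73, height = 176, race = "Asian")
labs <- tibble::tibble(time = 0, hct = 0.45, scr = 1.0)
sim <- simulate_course(patient, labs, dose_events(0, 240, 3000),
                       t_end = 14 * 1440, config = cfg)
sim
#> <mtx_sim> 601 time points to 20160 min
#>   administered 3000 mg | in body 0.01377 | renal 2875 | hepatic 125.2 mg
#>   mass-balance residual -6.37e-12 mg (relative 2.12e-15)
```

After 14 days, 2875 mg left through the kidneys and 125 mg through the
liver (≈ 4% hepatic share); 0.014 mg remains in the body and the
mass-balance audit closes to 2e-15 of the dose. `autoplot(sim)` draws
the plasma/ISF/ICF concentration curves; the plasma log-decline breaks
near 0.1 µmol/L into a slow terminal phase (half-time ≈ 35 h) fed by the
intracellular reservoir.

A full synthetic identification study:

```r
spec <- population_spec(n_patients = 56, seed = 2024, residual_sd = 0.1)
ds   <- generate_study(spec, config = cfg)    # virtual cohort + noisy obs
gs   <- grid_search(ds, cfg)                  # log-grid initialization
fit  <- fit_population(ds, gs$par, cfg)       # simplex refinement
boot <- bootstrap_population(ds, 50, seed = 99, init = fit$par, config = cfg)
tidy(fit); tidy(boot)
```

With the defaults this recovers each generating constant to within a few
percent, and the bootstrap means bracket the truth well inside ±3 SD.

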