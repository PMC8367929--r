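---
title: "Model, identification procedure, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, identification procedure, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mtxpbpk` implements a minimal physiologically based pharmacokinetic
(PBPK) model of intravenous high-dose methotrexate (HDMTX) for adult
patients, together with the population identification machinery (grid
search, simplex regression, patient bootstrap) and a synthetic-population
generator that makes the whole pipeline testable without clinical data.
This vignette explains the science and records the design decisions that
were genuinely open.

## The model and its assumptions

Methotrexate disposition is described with five homogeneous compartments:
three plasma pools — the global circulatory system (CS) and the renal and
hepatic circulatory systems (RCS, HCS) through which elimination occurs —
plus lumped interstitial (ISF) and intracellular (ICF) fluid spaces.
Material balances are ordinary differential equations in drug amounts
(mg); concentrations follow as amount over compartment volume. Canonical
internal units are mg, mL, min.

Key assumptions, in the order they matter clinically:

* **Only unbound drug moves.** Plasma protein binding is fixed at 42%
  (unbound fraction 0.58), ISF binding at 28%, and the ICF pool is 90%
  "bound" — a lumped representation of intracellular polyglutamation,
  which retains methotrexate without modelling the polyglutamate species
  explicitly. Binding is not modulated by albumin measurements; it is a
  population constant.
* **Renal excretion dominates.** Unbound drug is freely filtered
  (GFR × unbound RCS concentration); tubular handling is one saturable
  secretion term minus one saturable reabsorption term, both
  Michaelis–Menten in the unbound plasma concentration. With the packaged
  constants the renal clearance of MTX exceeds pure filtration by at most
  15% (reached near 0.22 µmol/L) and converges to GFR at saturating
  concentrations — the behaviour the constants were chosen to reproduce.
* **Hepatic elimination is minor and lumped**: linear clearance equal to
  4% of GFR, absorbing 7-OH-MTX metabolism, biliary/fecal loss and DAMPA
  formation. Enterohepatic recirculation is not modelled.
* **Capillary exchange is permeability-limited** and attached only to the
  CS pool: unidirectional flows k·V_ISF·cᵘ. At steady state the unbound
  ISF/CS ratio equals k_CS→ISF/k_ISF→CS (0.3045 with the packaged means),
  and the permeability–surface area product is a fraction of a percent of
  plasma cardiac output — consistent with a small hydrophilic molecule.
* **Cellular exchange is carrier-mediated** (reduced folate carrier):
  saturable uptake and efflux with a shared Michaelis constant of
  5 µmol/L scaled by the unbound ISF fraction (3.6 µmol/L), and maximum
  rates proportional to total ICF volume. The packaged maximum efflux
  constant exceeds the uptake constant; because the ICF pool is mostly
  polyglutamated, it nonetheless acts as a slow reservoir that produces
  the characteristic slope break of the plasma log-decline near
  0.1 µmol/L and a terminal half-time of roughly 40 h.

## Individualized physiology

All volumes and flows are assigned a priori from covariates, never
fitted:

* Blood volume: 72 mL/kg (men) / 65 mL/kg (women); plasma = blood ×
  (1 − hematocrit); RCS and HCS hold 2% and 10% of plasma, CS the rest
  (the partition is exact by construction).
* Extracellular and intracellular water scale linearly with weight from
  sex-specific per-kg reference means kept in the configuration (male
  239/342 mL/kg, female 199/273 mL/kg, transcribed from standard adult
  body-composition references); ISF = ECF − plasma.
* Cardiac output uses a configuration-driven allometric model anchored to
  reference resting outputs (6.5/5.9 L/min for a 1.90/1.66 m² man/woman)
  scaled by Du Bois BSA, with a 0.5%/year decline beyond age 35 (floored
  at 50%); plasma flow is blood flow × (1 − hematocrit), and the renal
  and hepatic shares are fixed sex-specific fractions (0.19/0.17 and
  0.255/0.27). Covariates outside the validity ranges warn but still
  return a value.
* GFR: CKD-EPI 2009 with a 4-level race coefficient (the Asian
  coefficient serves cohorts like the one that motivated the model),
  de-normalized from mL/min/1.73 m² by BSA/1.73, and **capped** at the
  97.5th percentile of the full-age-spectrum (FAS) eGFR reference
  interval — 107.3/0.67 ≈ 160 mL/min/1.73 m², declining by 0.988/year
  beyond age 40. The cap prevents implausibly high filtration from low
  creatinine values in cachectic patients.
* Tubular maxima scale linearly with GFR from 5.189 and 1.038 µg/min at
  the 100 mL/min reference; hepatic clearance is 4% of GFR.

Laboratory values are time-stamped; physiology is piecewise constant with
**left-closed** steps (a lab drawn at time t governs from t onward, the
first panel extends back to study start). The solver restarts at every
lab time and infusion start/stop so no discontinuity falls inside an
integration step.

Two literature coefficient sets used by the published model (the
cardiac-output covariate equations and the ECW/ICW reference means) are
not reproduced in it; the equations implemented here are the package's
own, anchored to widely used reference values, and live entirely in the
configuration file so they can be swapped without touching code.

## Numerical choices

* Stiff integration: `deSolve::lsoda` with a compiled C right-hand side;
  reference tolerances rtol 1e-8, atol 1e-12 mg (configurable). Inside
  the estimation objective, rtol 1e-6 / atol 1e-9 are used — residuals on
  the log10 scale are ~0.1, so 1e-6 relative solver error is invisible to
  the fit but ~2× faster.
* Cumulative renal and hepatic eliminations are carried as two auxiliary
  ODE states rather than post-hoc quadrature, so the mass balance audit
  (dose − in-body − eliminated) is exact up to solver tolerance; the
  packaged tests require < 1e-6 relative and typically observe ~1e-12.
* Rate evaluation clamps tiny negative amounts (solver-tolerance
  excursions) to zero; non-finite states are an error.
* Infusion windows are half-open [start, start + duration); overlapping
  infusions superpose.
* Initial condition: drug-free body (no carry-over from unmodelled prior
  therapy).

## Identification

The objective is the mean squared **log10** error between observed and
simulated total CS concentrations, pooled over all observations of all
patients; each patient is simulated once per evaluation over their full
dose and covariate history. The log base is a convention (it rescales the
objective by a constant); log10 is conventional for concentration data
and is configurable. Observations below the 0.05 µmol/L quantification
limit are excluded rather than modelled with a censoring likelihood.

* **Grid search**: full-factorial log-uniform grid over [1e-8, 1]⁴
  followed by a 3×/÷3 refinement around the incumbent. The default is 5
  points per dimension (706 evaluations) — a deliberate desk-scale
  resolution; the grid density is a configuration knob, so a
  3-points-per-decade search (25⁴ evaluations) remains expressible for
  users with the compute budget. Failed evaluations at pathological grid
  corners (concentrations underflowing at late sampling times) count as
  +∞ rather than aborting the search.
* **Regression**: Nelder–Mead in log10-parameter space (which enforces
  positivity), reltol 1e-6, with one restart of the simplex at the
  incumbent — a collapsed simplex in the flat valley that couples the
  two cellular constants re-expands on restart and recovers the remaining
  accuracy. The returned objective is never worse than at the initial
  point.
* **Bootstrap**: patients (never individual observations) are resampled
  with replacement to the identification-set size; duplicated patients
  are simulated once and weighted by multiplicity. Each resample is
  refit with a capped simplex budget **starting from the full-data
  optimum**: at desk-scale iteration budgets, grid-start refits do not
  converge and would report the start rather than the data, whereas
  optimum-start refits converge and give a clean resampling
  distribution. Failed refits are excluded and counted, not imputed.
  Everything is reproducible under the user's seed.

## The synthetic-population generator

`population_spec()` defaults encode the cohort structure the model was
built around: 84 adults (43 male / 41 female), weight 44–100 kg, height
146–181 cm, age 27–83 y, covariates uniform within ranges; serum
creatinine is redrawn per patient until the induced absolute GFR lies in
35–162 mL/min. Dosing: 1–17 infusions per patient with the count drawn
from a truncated geometric distribution whose mean matches the cohort's
396 infusions over 84 patients (≈ 4.7), amounts uniform on 1–9 g,
durations 0.32–7.71 h, inter-infusion gaps 3–14 days. Sampling mimics the
source study's early-morning draws: once daily at 05:30, so simulated
peaks are never observed — exactly as in the real data. Records whose
noise-free concentration falls below 0.05 µmol/L are dropped (the study
stopped sampling there), and multiplicative log-normal noise (default
SD 0.15 log10 for demonstrations, 0.1 for recovery tests) is applied
afterwards, matching the error model implied by the mean-squared-log
objective. The generator returns the noise-free truth alongside the
noisy observations so recovery tests can compare against ground truth.

What the generator does **not** emulate: comedication effects,
progressive renal-function decline over repeated cycles, non-uniform
covariate correlations (e.g. weight–height), or model misspecification —
observations are produced by the same structural model that is fitted.
Passing recovery tests therefore demonstrates identifiability and
correctness of the estimation machinery under the stated noise, not
predictive validity on real patients.

## Problem sizes used by the packaged tests

The test suite exercises the full pipeline at sizes chosen to keep a
complete run in the ten-minute range on one CPU: a 56-patient
identification set with residual SD 0.1 log10 (~800 observations), the
default 706-point grid, a simplex fit (~650 objective evaluations) and a
50-resample bootstrap with a 120-iteration budget per resample. With
those sizes the fit recovers each generating constant to within a few
percent (the packaged check allows 20%) and the truth lies well inside
±3 bootstrap SD of the resampling mean.

## Known limitations

* Population constants are shared by all patients; no inter-individual
  random effects (a deliberate population-PK choice).
* Volumes ignore body composition (fat fraction, hydration, sodium
  balance); binding ignores measured albumin.
* No pediatric physiology; the covariate equations are adult-only.
* No explicit metabolites (7-OH-MTX, DAMPA) or enterohepatic cycling;
  their net effect is absorbed by the 4%-of-GFR hepatic clearance.
* The 2% / 10% RCS/HCS plasma shares and the renal/hepatic flow
  fractions are population constants, not individualized.
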