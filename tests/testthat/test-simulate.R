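cfg <- test_cfg()
pop <- default_population(cfg)

test_that("infusion rate uses half-open windows and superposes events", {
  ev <- dose_events(0, 240, 3000)
  expect_equal(infusion_rate(100, ev), 12.5)
  expect_equal(infusion_rate(240, ev), 0)
  expect_equal(infusion_rate(0, ev), 12.5)
  ev2 <- dose_events(c(0, 100), c(240, 200), c(3000, 1000))
  expect_equal(infusion_rate(150, ev2), 12.5 + 5)
  expect_error(dose_events(0, 0, 100), "duration")
  expect_error(dose_events(0, 10, -1), "amount")
  # events are sorted on construction
  expect_equal(dose_events(c(50, 0), c(10, 10), c(1, 2))$start, c(0, 50))
})

test_that("a zero-dose course stays identically zero", {
  sim <- simulate_course(ref_profile(), ref_panel(), dose_events(
    numeric(), numeric(), numeric()), pop, t_end = 1440, config = cfg)
  expect_true(all(sim$trace[, -1] == 0))
  expect_equal(sim$audit$administered, 0)
})

test_that("with eliminations disabled the administered amount is conserved", {
  tl <- ref_timeline(q_gfr = 0, q_hepatic_clearance = 0,
                     m_secretion_max = 0, m_reabsorption_max = 0)
  sim <- simulate_course(ref_profile(), ref_panel(), dose_events(0, 20, 1000),
                         pop, t_end = 5760, timeline = tl, config = cfg)
  total <- with(sim$trace, m_cs + m_rcs + m_hcs + m_isf + m_icf)
  after <- total[sim$trace$time >= 20]
  expect_lt(max(abs(after - 1000)) / 1000, 1e-9)
})

test_that("mass balance closes to 1e-6 relative on randomized courses", {
  ds <- small_study(n = 3, seed = 31, n_inf_mean = 2)
  for (id in ds$covariates$patient_id) {
    dos <- ds$doses[ds$doses$patient_id == id, ]
    sim <- simulate_course(ds$covariates[ds$covariates$patient_id == id, ],
                           ds$labs[ds$labs$patient_id == id, ],
                           dose_events(dos$start, dos$duration, dos$amount),
                           pop, t_end = max(dos$start + dos$duration) + 7200,
                           config = cfg)
    expect_lt(sim$audit$residual_rel, 1e-6)
    expect_true(all(sim$trace[, grepl("^c_", names(sim$trace))] > -1e-12))
  }
})

test_that("the linear submodel superposes doses exactly", {
  # saturable transport silenced: tubular maxima zero, carrier maxima
  # vanishingly small
  tl <- ref_timeline(m_secretion_max = 0, m_reabsorption_max = 0)
  lin_pop <- population_params(pop[["k_cs_isf"]], pop[["k_isf_cs"]],
                               1e-300, 1e-300)
  s1 <- simulate_course(ref_profile(), ref_panel(), dose_events(0, 60, 1000),
                        lin_pop, t_end = 4320, timeline = tl, config = cfg,
                        sample_times = seq(0, 4320, 30), rtol = 1e-11,
                        atol = 1e-15)
  s2 <- simulate_course(ref_profile(), ref_panel(), dose_events(0, 60, 2000),
                        lin_pop, t_end = 4320, timeline = tl, config = cfg,
                        sample_times = seq(0, 4320, 30), rtol = 1e-11,
                        atol = 1e-15)
  keep <- s1$trace$c_cs > 0
  expect_lt(max(abs(s2$trace$c_cs[keep] / s1$trace$c_cs[keep] - 2)) / 2,
            1e-9)
})

test_that("amounts are continuous across event boundaries", {
  ev <- dose_events(0, 240, 3000)
  eps <- 1e-3
  sim <- simulate_course(ref_profile(), ref_panel(), ev, pop, t_end = 1440,
                         sample_times = c(240 - eps, 240, 240 + eps),
                         config = cfg)
  m <- sim$trace$m_cs
  # state continuous: jump across the boundary is O(rate * eps), not O(1)
  expect_lt(abs(m[2] - m[1]), 1)
  expect_lt(abs(m[3] - m[2]), 1)
})

test_that("plasma AUC strictly decreases as GFR increases", {
  auc <- vapply(c(50, 100, 150), function(g) {
    tl <- ref_timeline(q_gfr = g)
    sim <- simulate_course(ref_profile(), ref_panel(),
                           dose_events(0, 240, 3000), pop, t_end = 14400,
                           timeline = tl, config = cfg,
                           sample_times = seq(0, 14400, 20))
    trapz(sim$trace$time, sim$trace$c_cs)
  }, numeric(1))
  expect_true(all(diff(auc) < 0))
})

test_that("without elimination the unbound ISF/CS ratio relaxes to the k-ratio", {
  tl <- ref_timeline(q_gfr = 0, q_hepatic_clearance = 0,
                     m_secretion_max = 0, m_reabsorption_max = 0)
  sim <- simulate_course(ref_profile(), ref_panel(), dose_events(0, 60, 500),
                         pop, t_end = 4e5, timeline = tl, config = cfg,
                         sample_times = c(0, 4e5), rtol = 1e-10,
                         atol = 1e-14)
  last <- sim$trace[nrow(sim$trace), ]
  ratio <- (cfg$binding$f_isf_u * last$c_isf) /
    (cfg$binding$f_plasma_u * last$c_cs)
  expect_equal(ratio, pop[["k_cs_isf"]] / pop[["k_isf_cs"]],
               tolerance = 1e-4)
})

test_that("the intracellular reservoir slows the terminal plasma decline", {
  tl <- ref_timeline(q_gfr = 100)
  sim <- simulate_course(ref_profile(), ref_panel(),
                         dose_events(0, 240, 3000), pop, t_end = 20160,
                         timeline = tl, config = cfg,
                         sample_times = seq(0, 20160, 30))
  tr <- sim$trace
  conc_um <- convert_concentration(tr$c_cs, "mg/mL", "umol/L", cfg)
  # log-decline slope on either side of the 0.1 uM break
  pre <- conc_um < 10 & conc_um > 0.15 & tr$time > 240
  post <- conc_um < 0.08 & conc_um > 0.005
  slope <- function(sel) {
    stats::coef(stats::lm(log10(conc_um[sel]) ~ tr$time[sel]))[2]
  }
  s_pre <- slope(pre); s_post <- slope(post)
  expect_lt(s_pre, 0)
  expect_lt(s_post, 0)
  expect_gt(s_post, s_pre)  # terminal phase much less steep
  # terminal half-time within a factor two of 40 h
  half_h <- log10(2) / (-s_post) / 60
  expect_gt(half_h, 20)
  expect_lt(half_h, 80)
  # ICF declines far more slowly than plasma over the terminal window
  icf <- tr$m_icf[post]
  expect_gt(icf[length(icf)] / icf[1],
            tr$m_cs[post][sum(post)] / tr$m_cs[post][1])
})

test_that("overall clearance approaches GFR plus its hepatic share at saturation", {
  tl <- ref_timeline(q_gfr = 100)
  sim <- simulate_course(ref_profile(), ref_panel(),
                         dose_events(0, 240, 5000), pop, t_end = 1440,
                         timeline = tl, config = cfg,
                         sample_times = seq(120, 1440, 10))
  cs <- clearance_summary(sim, cfg,
                          min_conc = convert_concentration(
                            10, "umol/L", "mg/mL", cfg))
  # saturated algebraic limit, accounting for the quasi-steady renal and
  # hepatic plasma-flow gradients (c_RCS and c_HCS sit slightly below
  # c_CS because of organ extraction)
  tl1 <- tl[1, ]
  fu <- cfg$binding$f_plasma_u
  renal_part <- 100 * tl1$q_cs_rcs / (tl1$q_cs_rcs + 100 * fu)
  hep_part <- 4 * tl1$q_cs_hcs / (tl1$q_cs_hcs + 4 * fu)
  expect_equal(cs$mean, renal_part + hep_part, tolerance = 0.005)
  # hepatic share: disabling hepatic clearance removes ~4 mL/min
  tl0 <- ref_timeline(q_gfr = 100, q_hepatic_clearance = 0)
  sim0 <- simulate_course(ref_profile(), ref_panel(),
                          dose_events(0, 240, 5000), pop, t_end = 1440,
                          timeline = tl0, config = cfg,
                          sample_times = seq(120, 1440, 10))
  cs0 <- clearance_summary(sim0, cfg,
                           min_conc = convert_concentration(
                             10, "umol/L", "mg/mL", cfg))
  expect_equal(cs$mean - cs0$mean, hep_part, tolerance = 0.02)
  expect_error(clearance_summary(sim, cfg, min_conc = 1e9), "usable")
})

test_that("unit conversions are exact under the configured molar mass", {
  expect_equal(round(convert_concentration(0.2, "ug/mL", "umol/L", cfg), 2),
               0.44)
  expect_equal(convert_concentration(0, "mg/mL", "umol/L", cfg), 0)
  expect_equal(convert_concentration(0.05, "umol/L", "mg/mL", cfg),
               2.2722e-5, tolerance = 1e-10)
  # round trip
  expect_equal(convert_concentration(
    convert_concentration(3.7, "umol/L", "ug/mL", cfg), "ug/mL", "umol/L",
    cfg), 3.7, tolerance = 1e-12)
  expect_error(convert_concentration(1, "mol/L", "mg/mL", cfg), "unknown")
})
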