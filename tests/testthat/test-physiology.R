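cfg <- test_cfg()

test_that("blood volume follows the printed per-kg rules", {
  expect_equal(total_blood_volume("female", 60, cfg), 3900)
  expect_equal(total_blood_volume("male", 73, cfg), 5256)
  expect_equal(total_blood_volume("female", 0, cfg), 0)
  expect_error(total_blood_volume("unknown", 60, cfg), "sex")
  # strictly increasing in weight
  w <- seq(40, 110, by = 5)
  expect_true(all(diff(total_blood_volume("male", w, cfg)) > 0))
})

test_that("plasma partition uses the fixed organ fractions and sums exactly", {
  pv <- plasma_volumes(3900, 0.40, cfg)
  expect_equal(pv$v_plasma, 2340)
  expect_equal(pv$v_rcs, 46.8)
  expect_equal(pv$v_hcs, 234)
  expect_equal(pv$v_cs, 2059.2)
  expect_error(plasma_volumes(3900, 1.0, cfg), "hematocrit")
  expect_equal(plasma_volumes(5256, 0, cfg)$v_plasma, 5256)
  # exact partition over randomized inputs
  set.seed(7)
  for (i in 1:25) {
    pv <- plasma_volumes(runif(1, 2000, 8000), runif(1, 0, 0.6), cfg)
    expect_lte(abs(pv$v_cs + pv$v_rcs + pv$v_hcs - pv$v_plasma),
               4 * .Machine$double.eps * pv$v_plasma)
  }
})

test_that("body water volumes scale linearly and reject non-positive ISF", {
  bw <- body_water_volumes("male", 73, v_plasma = 2890.8, cfg)
  r_e <- cfg$body_water$ecw_per_kg$male
  expect_equal(bw$v_ecf, 73 * r_e)
  expect_equal(bw$v_isf, 73 * r_e - 2890.8)
  expect_equal(bw$v_icf, 73 * cfg$body_water$icw_per_kg$male)
  expect_error(body_water_volumes("male", 73, v_plasma = 73 * r_e, cfg),
               "interstitial")
  bad_cfg <- load_config(overrides = list(
    body_water = list(ecw_per_kg = list(male = 230, female = NULL))),
    quiet = TRUE)
  expect_error(body_water_volumes("female", 60, 2000, bad_cfg), "female")
})

test_that("Du Bois BSA matches direct evaluation and its power law", {
  expect_equal(bsa(73, 176, cfg), 1.889188196, tolerance = 1e-8)
  expect_error(bsa(0, 170, cfg), "positive")
  expect_equal(bsa(4 * 73, 176, cfg) / bsa(73, 176, cfg), 4^0.425,
               tolerance = 1e-12)
})

test_that("cardiac output matches a hand evaluation of the configured model", {
  co <- cardiac_output("male", 40, 73, 176, 0.45, cfg)
  # independent hand evaluation of the documented config equations
  p <- cfg$cardiac_output
  surface <- 0.007184 * 73^0.425 * 176^0.725
  q_blood <- p$co_ref$male * surface / p$bsa_ref$male *
    (1 - p$age_decline_per_year * (40 - p$age_ref))
  expect_equal(co$q_co_blood, q_blood, tolerance = 1e-10)
  expect_equal(co$q_co_plasma, q_blood * 0.55, tolerance = 1e-10)
  expect_equal(co$q_cs_rcs, p$kidney_fraction$male * q_blood * 0.55,
               tolerance = 1e-10)
  expect_equal(co$q_cs_hcs, p$liver_fraction$male * q_blood * 0.55,
               tolerance = 1e-10)
  # regional fractions strictly inside (0, 1) and below plasma CO
  expect_true(co$q_cs_rcs + co$q_cs_hcs < co$q_co_plasma)
  # higher hematocrit -> lower plasma cardiac output
  co_hi <- cardiac_output("male", 40, 73, 176, 0.50, cfg)
  expect_lt(co_hi$q_co_plasma, co$q_co_plasma)
  # determinism
  expect_identical(co, cardiac_output("male", 40, 73, 176, 0.45, cfg))
  # out-of-range covariates warn but return
  expect_warning(co_w <- cardiac_output("male", 40, 200, 176, 0.45, cfg),
                 "validity")
  expect_true(is.finite(co_w$q_co_plasma))
})

test_that("CKD-EPI eGFR matches hand evaluations and is capped by FAS", {
  # White female, Scr 0.8, 50 y: published-formula hand value
  expect_equal(estimate_gfr(0.8, "female", 50, "White", bsa = 1.73, cfg,
                            normalized = TRUE),
               85.96409, tolerance = 1e-6)
  # Asian male, Scr 1.0, 40 y (Asian race coefficient engaged)
  expect_equal(estimate_gfr(1.0, "male", 40, "Asian", bsa = 1.73, cfg,
                            normalized = TRUE),
               98.41415, tolerance = 1e-6)
  expect_error(estimate_gfr(0, "male", 40, "Asian", 1.8, cfg), "positive")
  expect_error(estimate_gfr(1, "male", 40, "Martian", 1.8, cfg), "race")
  # strictly decreasing in creatinine
  scr <- seq(0.4, 4, by = 0.1)
  g <- vapply(scr, function(s)
    as.numeric(estimate_gfr(s, "male", 50, "Asian", 1.8, cfg)), numeric(1))
  expect_true(all(diff(g) < 0))
  # very low creatinine: the FAS 97.5th-percentile bound binds
  low <- estimate_gfr(0.2, "female", 30, "White", bsa = 1.73, cfg)
  expect_true(attr(low, "capped"))
  expect_equal(as.numeric(low), fas_gfr_cap(30, 1.73, cfg))
  expect_equal(fas_gfr_cap(35, 1.73, cfg), 107.3 / 0.67, tolerance = 1e-10)
  expect_equal(fas_gfr_cap(60, 1.73, cfg), 107.3 / 0.67 * 0.988^20,
               tolerance = 1e-10)
  # cap dominance over a randomized covariate sweep
  set.seed(11)
  for (i in 1:40) {
    sex <- sample(c("male", "female"), 1)
    age <- runif(1, 20, 85)
    b <- runif(1, 1.4, 2.2)
    g <- estimate_gfr(runif(1, 0.2, 3), sex, age,
                      sample(c("White", "Asian", "Black", "Other"), 1),
                      b, cfg)
    expect_lte(as.numeric(g), fas_gfr_cap(age, b, cfg))
  }
})

test_that("renal transport maxima and hepatic clearance scale with GFR", {
  mx <- renal_transport_maxima(100, cfg)
  expect_equal(mx$m_secretion_max, 5.189)
  expect_equal(mx$m_reabsorption_max, 1.038)
  expect_equal(unlist(renal_transport_maxima(0, cfg)),
               c(m_secretion_max = 0, m_reabsorption_max = 0))
  mx50 <- renal_transport_maxima(50, cfg)
  expect_equal(mx50$m_secretion_max, 2.5945)
  expect_equal(mx50$m_reabsorption_max, 0.519)
  expect_error(renal_transport_maxima(-1, cfg), "non-negative")
  expect_equal(hepatic_clearance(100, cfg), 4)
  expect_equal(hepatic_clearance(0, cfg), 0)
  expect_equal(hepatic_clearance(150, cfg), 6)
})

test_that("physiology timeline is piecewise constant with left-closed steps", {
  prof <- ref_profile()
  tl1 <- physiology_timeline(prof, ref_panel(), cfg)
  expect_equal(nrow(tl1), 1L)
  expect_equal(physiology_at(tl1, c(0, 500, 1e5))$q_gfr,
               rep(tl1$q_gfr, 3))
  # creatinine doubles at t1: GFR steps down exactly there
  panels <- tibble::tibble(time = c(0, 2000), hct = 0.45, scr = c(1, 2))
  tl2 <- physiology_timeline(prof, panels, cfg)
  expect_equal(nrow(tl2), 2L)
  expect_lt(tl2$q_gfr[2], tl2$q_gfr[1])
  expect_equal(physiology_at(tl2, 1999.9)$q_gfr, tl2$q_gfr[1])
  # at the panel time the NEW panel is already in force
  expect_equal(physiology_at(tl2, 2000)$q_gfr, tl2$q_gfr[2])
  expect_error(physiology_timeline(prof, ref_panel()[0, ], cfg),
               "at least one")
  expect_error(physiology_timeline(prof,
    tibble::tibble(time = c(0, 0), hct = 0.45, scr = 1), cfg), "unique")
  # minors rejected by the adult model
  young <- prof
  young$age <- 17
  expect_error(physiology_timeline(young, ref_panel(), cfg), "18")
})
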