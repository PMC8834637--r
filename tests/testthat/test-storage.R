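test_that("retail light-dose conversion matches the 600 lux / 12 h benchmark", {
  sched <- light_schedule(600, 12)
  expect_equal(round(dose_from_days(180, sched), 1), 1.3)
  expect_equal(dose_from_days(180, sched), 1.296)
  expect_equal(dose_from_days(0, sched), 0)
})

test_that("dose/day conversion is linear and exactly invertible", {
  sched <- light_schedule(600, 12)
  set.seed(5)
  d <- runif(50, 0, 400)
  expect_equal(days_from_dose(dose_from_days(d, sched), sched), d,
               tolerance = 1e-12)
  # linearity
  expect_equal(dose_from_days(2 * d, sched), 2 * dose_from_days(d, sched))
})

test_that("rate re-expression per day commutes with trajectory prediction", {
  sched <- light_schedule(600, 12)
  expect_equal(rate_to_perday(2.44e-2, sched), 2.44e-2 * 0.0072)
  expect_equal(rate_to_perday(2.44e-2, sched), 1.7568e-4)
  expect_equal(rate_to_perday(0, sched), 0)
  # trajectories vs days equal trajectories vs dose composed with the
  # conversion, for all three laws
  days <- seq(0, 180, by = 15)
  p_dose <- param_set(C0 = 1.19, kref = 3.68e-2, Ea = 19.25, Cinf = 0.5)
  for (ord in c("zero", "first", "fractional")) {
    m_dose <- model_spec(ord, "dose_Mluxh")
    m_day <- model_spec(ord, "time_days")
    p_day <- param_set(C0 = p_dose$C0,
                       kref = rate_to_perday(p_dose$kref, sched),
                       Ea = p_dose$Ea,
                       Cinf = if (ord == "fractional") p_dose$Cinf else NULL)
    for (T in c(10, 35)) {
      expect_equal(
        predict_conc(m_day, p_day, T, days),
        predict_conc(m_dose, p_dose, T, dose_from_days(days, sched)),
        tolerance = 1e-12, info = paste(ord, T))
    }
  }
})

test_that("axis rescaling leaves the fit quality invariant", {
  sched <- light_schedule(600, 12)
  tab <- make_paper_fixture("illuminated", "glass",
                            noise = noise_spec(sd = 0.02, seed = 41),
                            carotenoids = "violaxanthin")
  fit_dose <- fit_one_step(tab, model_spec("first", "dose_Mluxh"))
  df <- as.data.frame(tab)
  df$exposure <- days_from_dose(df$exposure, sched)
  df$exposure_unit <- "day"
  df$condition <- "dark" # relabel so the day axis is admissible
  tab_day <- study_table(df, axis = "time_days")
  fit_day <- fit_one_step(tab_day, model_spec("first", "time_days"))
  expect_equal(fit_day$SSQ, fit_dose$SSQ, tolerance = 1e-8)
  expect_equal(fit_day$estimates$kref,
               rate_to_perday(fit_dose$estimates$kref, sched),
               tolerance = 1e-6)
})

test_that("Welch rate comparison reproduces hand-computed t statistics", {
  # dark beta-carotene, without vs with ascorbic acid
  cmp <- compare_rates(1.70, 0.20, 24, 0.39, 0.01, 24)
  expect_equal(cmp$t_statistic, (1.70 - 0.39) / sqrt(0.20^2 + 0.01^2),
               tolerance = 1e-12)
  expect_equal(round(cmp$t_statistic, 2), 6.54)
  expect_true(cmp$significant)
  # illuminated neoxanthin
  cmp2 <- compare_rates(2.75, 0.17, 24, 1.30, 0.12, 24)
  expect_equal(round(cmp2$t_statistic, 2), 6.97)
  expect_true(cmp2$significant)
  # identical inputs: t = 0, not significant
  cmp0 <- compare_rates(1, 0.1, 10, 1, 0.1, 10)
  expect_equal(cmp0$t_statistic, 0)
  expect_false(cmp0$significant)
  expect_equal(cmp0$p_value, 1)
  # df required
  expect_error(compare_rates(1, 0.1, NULL, 2, 0.1, 10), "degrees of freedom")
})

test_that("ascorbic-acid oxygen stoichiometry follows the 0.5 mol ratio", {
  # 1 mmol/L AA consumed needs 0.5 mmol/L O2 = 16 mg/L
  res <- aa_oxygen_fraction(delta_AA = 176.12, delta_O2 = 16)
  expect_equal(res$moles_AA_consumed, 1e-3, tolerance = 1e-12)
  expect_equal(res$moles_O2_required, 0.5e-3, tolerance = 1e-12)
  expect_equal(res$fraction_attributable, 1.0, tolerance = 1e-12)
  # doubling observed O2 halves the fraction
  expect_equal(aa_oxygen_fraction(176.12, 32)$fraction_attributable, 0.5,
               tolerance = 1e-12)
  # no AA consumed -> fraction 0
  expect_equal(aa_oxygen_fraction(0, 16)$fraction_attributable, 0)
  expect_error(aa_oxygen_fraction(10, 0), "undefined")
})

test_that("aa_oxygen_fraction is homogeneous of degree 0 in the deltas", {
  base <- aa_oxygen_fraction(88.06, 12)$fraction_attributable
  for (s in c(0.1, 2, 17)) {
    expect_equal(aa_oxygen_fraction(88.06 * s, 12 * s)$fraction_attributable,
                 base, tolerance = 1e-12)
  }
})

test_that("linear association matches ordinary least squares by hand", {
  res <- linear_association(0:3, c(1.0, 0.8, 0.7, 0.4))
  expect_equal(res$slope, -0.19, tolerance = 1e-12)
  expect_equal(res$r2, 0.9025 / 0.9375, tolerance = 1e-12) # = 0.96267
  # perfectly collinear (summary.lm warns about the perfect fit)
  res1 <- suppressWarnings(linear_association(1:5, 2 * (1:5) + 3))
  expect_equal(res1$r2, 1)
  res2 <- suppressWarnings(linear_association(1:4, -(1:4)))
  expect_equal(res2$slope, -1)
  expect_equal(res2$r2, 1)
  expect_error(linear_association(rep(1, 4), 1:4), "constant")
  expect_error(linear_association(1:2, 1:2), "3 points")
})
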