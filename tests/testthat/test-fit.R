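test_that("noiseless data are recovered exactly by the one-step fit", {
  for (spec in list(list(order = "zero", carotenoid = "antheraxanthin"),
                    list(order = "fractional", carotenoid = "beta-carotene"))) {
    tab <- make_paper_fixture("dark", "glass", noise = NULL,
                              carotenoids = spec$carotenoid)
    truth <- study_truth(tab)[[1]]
    fit <- fit_one_step(tab, model_spec(spec$order, "time_days"))
    expect_lt(abs(fit$estimates$kref - truth$kref) / truth$kref, 1e-6)
    expect_lt(abs(fit$estimates$Ea - truth$Ea) / truth$Ea, 1e-6)
    expect_lt(abs(fit$estimates$C0 - truth$C0) / truth$C0, 1e-6)
    expect_lt(fit$SSQ, 1e-12)
    expect_true(fit$converged)
  }
})

test_that("identical rate constants at all temperatures give Ea near zero", {
  design <- reference_design("dark")
  truth <- param_set(C0 = 1.0, kref = 5e-3, Ea = 0)
  tab <- generate_study(model_spec("zero", "time_days"), truth, design,
                        noise = NULL)
  fit <- fit_one_step(tab, model_spec("zero", "time_days"))
  expect_lt(fit$estimates$Ea, 1e-4)
})

test_that("derived k(T) is internally consistent with the Arrhenius forward map", {
  tab <- make_paper_fixture("dark", "glass",
                            noise = noise_spec(sd = 0.02, seed = 11),
                            carotenoids = "antheraxanthin")
  fit <- fit_one_step(tab, model_spec("zero", "time_days"))
  expect_equal(fit$k_by_temperature$k,
               arrhenius_k(fit$estimates, fit$k_by_temperature$temperature_C),
               tolerance = 1e-12)
  expect_true(all(fit$k_by_temperature$se > 0))
  # SEE/SSQ bookkeeping
  expect_equal(fit$SEE, sqrt(fit$SSQ / (fit$m - fit$p)))
  expect_equal(fit$m, 56)
})

test_that("the fit is invariant to row order and replicate relabeling", {
  tab <- make_paper_fixture("dark", "glass",
                            noise = noise_spec(sd = 0.02, seed = 12),
                            carotenoids = "lutein")
  fit1 <- fit_one_step(tab, model_spec("zero", "time_days"))
  df <- as.data.frame(tab)
  set.seed(99)
  shuf <- study_table(df[sample(nrow(df)), ], axis = "time_days")
  fit2 <- fit_one_step(shuf, model_spec("zero", "time_days"))
  expect_equal(fit1$estimates$kref, fit2$estimates$kref, tolerance = 1e-7)
  expect_equal(fit1$SSQ, fit2$SSQ, tolerance = 1e-10)
  # uniform replicate relabeling
  df$replicate <- 3L - df$replicate
  fit3 <- fit_one_step(study_table(df, axis = "time_days"),
                       model_spec("zero", "time_days"))
  expect_equal(fit1$SSQ, fit3$SSQ, tolerance = 1e-10)
})

test_that("the objective never increases across optimizer iterations", {
  tab <- make_paper_fixture("illuminated", "glass",
                            noise = noise_spec(sd = 0.02, seed = 13),
                            carotenoids = "beta-carotene")
  fit <- fit_one_step(tab, model_spec("fractional", "dose_Mluxh"))
  expect_true(all(diff(fit$ssq_trace) <= 1e-12))
})

test_that("one-step estimates match a two-step oracle on noiseless data", {
  # oracle implemented here from first principles: per-temperature linear
  # fits, then OLS of log k on the inverse-temperature contrast
  tab <- make_paper_fixture("dark", "glass", noise = NULL,
                            carotenoids = "antheraxanthin")
  df <- as.data.frame(tab)
  temps <- sort(unique(df$temperature_C))
  k_t <- vapply(temps, function(T) {
    d <- df[df$temperature_C == T, ]
    -unname(coef(lm(concentration_ug_per_g ~ exposure, data = d))[2])
  }, numeric(1))
  z <- 1 / (25 + 273.15) - 1 / (temps + 273.15)
  reg <- lm(log(k_t) ~ z)
  kref_oracle <- exp(unname(coef(reg)[1]))
  Ea_oracle <- unname(coef(reg)[2]) * 8.314 / 1000
  fit <- fit_one_step(tab, model_spec("zero", "time_days"))
  expect_lt(abs(fit$estimates$kref - kref_oracle) / kref_oracle, 1e-4)
  expect_lt(abs(fit$estimates$Ea - Ea_oracle) / Ea_oracle, 1e-4)
  # and the packaged two-step diagnostic agrees with the in-test oracle
  ts <- fit_two_step(tab, model_spec("zero", "time_days"))
  expect_equal(ts$kref, kref_oracle, tolerance = 1e-10)
  expect_equal(ts$Ea, Ea_oracle, tolerance = 1e-10)
})

test_that("fit_statistics matches hand arithmetic and flags degenerate input", {
  obs <- c(1.0, 0.9, 0.8, 0.7)
  pred <- c(0.95, 0.95, 0.75, 0.75)
  st <- fit_statistics(obs - pred, obs, p = 2)
  expect_equal(st$SSQ, 0.01)
  expect_equal(st$SEE, sqrt(0.01 / 2), tolerance = 1e-10)
  expect_equal(round(st$SEE, 4), 0.0707)
  expect_equal(st$r2adj, 0.70)
  # perfect fit
  st0 <- fit_statistics(rep(0, 4), obs, p = 2)
  expect_equal(st0$r2adj, 1)
  expect_equal(st0$SEE, 0)
  # constant observations are degenerate
  expect_error(fit_statistics(rep(0.1, 4), rep(1, 4), p = 2), "identical")
})

test_that("runs test flags systematic residual sign patterns", {
  # alternating signs: too many runs; long blocks: too few
  alternating <- rep(c(1, -1), 20) * 0.1
  blocks <- c(rep(0.1, 20), rep(-0.1, 20))
  set.seed(42)
  random <- rnorm(40)
  expect_lt(runs_test(blocks), 0.01)
  expect_lt(runs_test(alternating), 0.01)
  expect_gt(runs_test(random), 0.05)
  expect_true(is.na(runs_test(rep(0.1, 5))))
})

test_that("fit errors are informative for unfittable input", {
  tab <- make_paper_fixture("dark", "glass", noise = NULL,
                            carotenoids = "lutein")
  one_t <- study_table(as.data.frame(tab)[tab$temperature_C == 10, ],
                       axis = "time_days")
  expect_error(fit_one_step(one_t, model_spec("zero", "time_days")),
               "not fittable")
  expect_error(fit_one_step(tab, model_spec("zero", "dose_Mluxh")),
               "axis")
  # too few points per temperature
  few <- study_table(as.data.frame(tab)[tab$exposure %in% c(0, 42) &
                                          tab$replicate == 1 &
                                          tab$temperature_C %in% c(10, 20), ],
                     axis = "time_days")
  expect_error(suppressWarnings(
    fit_one_step(few, model_spec("fractional", "time_days"))), "fittable")
  # m <= p guard in the statistics layer
  expect_error(fit_statistics(c(0.1, -0.1, 0), c(1, 2, 3), p = 3), "m > p")
})

test_that("model selection recovers the generating law", {
  design <- reference_design("dark")
  # pronounced plateau -> fractional
  tfrac <- param_set(C0 = 1.22, kref = 7.50e-2, Ea = 15.13, Cinf = 0.75 * 1.22)
  tab <- generate_study(model_spec("fractional", "time_days"), tfrac, design,
                        noise_spec(sd = 0.02, seed = 21))
  cmp <- suppressWarnings(select_model(tab))
  expect_equal(cmp$selected, "fractional")
  # strictly linear decline -> zero order
  tzero <- param_set(C0 = 1.07, kref = 0.64e-2, Ea = 35.48)
  tab <- generate_study(model_spec("zero", "time_days"), tzero, design,
                        noise_spec(sd = 0.02, seed = 22))
  cmp <- suppressWarnings(select_model(tab))
  expect_equal(cmp$selected, "zero")
  expect_equal(cmp$table$order[1], cmp$selected) # ranked by SEE
})

test_that("constant data select zero order by parsimony tie-break", {
  design <- study_design(c(10, 35), seq(0, 42, length.out = 7), 2)
  tconst <- param_set(C0 = 1.0, kref = 1e-12, Ea = 0)
  tab <- generate_study(model_spec("zero", "time_days"), tconst, design,
                        noise_spec(sd = 0.005, seed = 23))
  cmp <- suppressWarnings(select_model(tab))
  expect_equal(cmp$selected, "zero")
})

test_that("replicate averaging is available but off by default", {
  tab <- make_paper_fixture("dark", "glass",
                            noise = noise_spec(sd = 0.02, seed = 24),
                            carotenoids = "antheraxanthin")
  fit <- fit_one_step(tab, model_spec("zero", "time_days"))
  fit_avg <- fit_one_step(tab, model_spec("zero", "time_days"),
                          control = fit_control(average_replicates = TRUE))
  expect_equal(fit$m, 56)
  expect_equal(fit_avg$m, 28)
  # estimates agree closely (averaging is a refinement, not a change of model)
  expect_equal(fit$estimates$kref, fit_avg$estimates$kref, tolerance = 0.05)
})
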