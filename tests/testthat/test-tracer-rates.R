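test_that("fit_linear_rate handles exact, lagged and null series", {
  # exact line: slope 1, no residual, decisive one-sided test
  s <- incubation_series(0:4, as.numeric(0:4))
  est <- fit_linear_rate(s)
  expect_equal(est$rate, 1)
  expect_equal(est$sem, 0)
  expect_equal(est$p_value, 0)
  expect_equal(est$n_points_used, 5L)
  expect_false(est$lag_omitted)

  # lag omission: hand OLS on the three remaining points gives slope 1
  s <- incubation_series(c(0, 1, 2, 5, 8), c(0, 0, 0, 3, 6))
  est <- fit_linear_rate(s, omit_lag_until = 2)
  expect_equal(est$rate, 1)
  expect_equal(est$n_points_used, 3L)
  expect_true(est$lag_omitted)

  # constant series: null case
  s <- incubation_series(0:4, rep(2, 5))
  est <- fit_linear_rate(s)
  expect_equal(est$rate, 0)
  expect_equal(est$p_value, 0.5)
  expect_false(est$significant)

  expect_error(fit_linear_rate(incubation_series(0:2, 1:3), n_points = 2),
               "at least 3")
})

test_that("OLS slope agrees with the longhand normal-equations oracle", {
  set.seed(42)
  for (rep in 1:10) {
    times <- c(0, sort(runif(5, 0.5, 12)))
    vals <- 0.3 * times + rnorm(6, sd = 0.4)
    s <- incubation_series(times, vals)
    est <- fit_linear_rate(s, n_points = 6)
    expect_equal(est$rate, ols_slope_longhand(times, vals),
                 tolerance = 1e-12)
  }
})

test_that("methane oxidation conversion scales with DIC and label fraction", {
  # slope 0.002 d^-1, DIC 100 uM, full labeling -> 0.2 uM d^-1
  s <- ratio_series(0.002, dic_uM = 100, label_fraction = 1)
  expect_equal(ch4_oxidation_rate(s)$rate, 0.2)

  # labeling 0.98 vs 1.0 differ by exactly 1/0.98
  s98 <- ratio_series(0.002, dic_uM = 100, label_fraction = 0.98)
  expect_equal(ch4_oxidation_rate(s98)$rate,
               ch4_oxidation_rate(s)$rate / 0.98)
  # the override argument can disable the labeling correction
  expect_equal(ch4_oxidation_rate(s98, label_fraction = 1)$rate, 0.2)

  # linear in DIC
  s2 <- ratio_series(0.002, dic_uM = 200, label_fraction = 1)
  expect_equal(ch4_oxidation_rate(s2)$rate, 0.4)

  expect_error(ch4_oxidation_rate(ratio_series(0.002)), "dic_uM")
})

test_that("denitrification applies pairing, factor 2 and dilution", {
  times <- c(0, 1, 2, 5, 8)
  # F = 1, no subsampling: rate = 2 x slope
  s <- incubation_series(times, 0.05 * times, observable = "n30_headspace",
                         label_fraction = 1, subsample_times = numeric(0))
  expect_equal(denitrification_rate(s)$rate, 0.10)

  # F = 0.5, same slope: 2 x 0.05 / 0.25 = 0.40
  s <- incubation_series(times, 0.05 * times, observable = "n30_headspace",
                         label_fraction = 0.5,
                         subsample_times = numeric(0))
  expect_equal(denitrification_rate(s)$rate, 0.40)

  # round trip through the generator with 3-ml subsamples from 30 ml
  tr <- sim_truth(true_rate = 0.46, label_fraction = 0.5, noise_sd = 0,
                  headspace_ml = 30, subsample_ml = 3)
  s <- gen_incubation_series(tr, observable = "n30_headspace")
  expect_equal(denitrification_rate(s)$rate, 0.46, tolerance = 1e-12)

  expect_error(denitrification_rate(
    incubation_series(times, 0.05 * times, observable = "n30_headspace",
                      headspace_ml = 3, subsample_ml = 3)),
    "smaller than headspace")
})

test_that("dilution correction leaves a production-free series flat", {
  times <- c(0, 1, 2, 5, 8, 12)
  d <- (30 - 3) / 30
  n_prior <- sapply(times, function(t) sum(times > 0 & times < t))
  raw <- 0.5 * d^n_prior   # constant pool, only dilution acts
  s <- incubation_series(times, raw, observable = "n30_headspace",
                         headspace_ml = 30, subsample_ml = 3)
  corr <- dilution_correct(s)
  expect_equal(corr$value, rep(0.5, length(times)))
  # and the fitted slope of the corrected series is zero
  expect_equal(fit_linear_rate(corr)$rate, 0, tolerance = 1e-14)
})

test_that("bulk assimilation converts POC and labeling exactly", {
  times <- c(0, 1, 2, 5, 8)
  # unit identity: slope 0.01/d x (12.011 ug / 12.011 / 0.010 L) = 1 uM/d
  s <- incubation_series(times, 0.01 * times, observable = "biomass_atpct",
                         poc_ug = 12.011, filter_vol_ml = 10,
                         label_fraction = 1)
  expect_equal(bulk_assimilation_rate(s)$rate, 1.0)

  # zero slope -> rate 0, p = 0.5
  s0 <- incubation_series(times, rep(0, 5), observable = "biomass_atpct",
                          poc_ug = 12.011, filter_vol_ml = 10)
  est <- bulk_assimilation_rate(s0)
  expect_equal(est$rate, 0)
  expect_equal(est$p_value, 0.5)

  expect_error(bulk_assimilation_rate(
    incubation_series(times, 0.01 * times, observable = "biomass_atpct")),
    "poc_ug")
})

test_that("assimilated fraction matches rate pairs and is a fraction", {
  expect_equal(assimilated_fraction(1.29, 1.17), 1.29 / 2.46)
  expect_equal(round(100 * assimilated_fraction(1.29, 1.17)), 52)
  expect_equal(round(100 * assimilated_fraction(0.09, 0.06)), 60)
  expect_equal(assimilated_fraction(0, 5), 0)

  # complement symmetry and range over random pairs
  set.seed(1)
  a <- runif(50, 0, 3)
  o <- runif(50, 0, 3)
  f <- mapply(assimilated_fraction, a, o)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(f + mapply(assimilated_fraction, o, a), rep(1, 50))

  expect_error(assimilated_fraction(0, 0), "both rates")
})

test_that("stoichiometric feasibility uses the 5:8 CH4:NO3 ratio", {
  chk <- stoichiometry_check(0.18, 0.41)
  expect_equal(chk$required_N, 8 / 5 * 0.18)
  expect_true(chk$feasible)

  expect_true(stoichiometry_check(0, 0.0)$feasible)

  chk <- stoichiometry_check(0.30, 0.41)
  expect_equal(chk$required_N, 0.48)
  expect_false(chk$feasible)

  expect_error(stoichiometry_check(-0.1, 0.2), "non-negative")
})
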