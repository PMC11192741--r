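roi_row <- function(n13, n12, n15 = n13, n14 = n12, fov = "fov_01",
                    bg = FALSE) {
  data.frame(roi_id = "r", fov_id = fov, morphotype = "large_rod",
             counts_12C = n12, counts_13C = n13, counts_12C14N = n14,
             counts_12C15N = n15, is_background = bg)
}

test_that("ratio and Poisson error follow the counting-statistics formula", {
  r <- roi_ratio_and_error(roi_row(400, 40000))
  expect_equal(r$ratio_C, 400 / 40400)
  expect_equal(r$rel_poisson_error_C, sqrt(1 / 400 + 1 / 40000))
  expect_equal(r$rel_poisson_error_C, 0.0503, tolerance = 2e-3)

  r <- roi_ratio_and_error(roi_row(1e4, 1e6))
  expect_equal(r$rel_poisson_error_C, sqrt(1 / 1e4 + 1 / 1e6))
  expect_equal(r$rel_poisson_error_C, 0.0100, tolerance = 1e-2)

  # zero minor counts: ratio 0, undefined error, flagged
  r <- roi_ratio_and_error(roi_row(0, 40000))
  expect_equal(r$ratio_C, 0)
  expect_true(is.infinite(r$rel_poisson_error_C))
  expect_true(r$error_undefined)

  expect_error(roi_ratio_and_error(roi_row(0, 0)), "zero total")
})

test_that("the Poisson filter excludes exactly the over-threshold ROIs", {
  rois <- rbind(roi_row(400, 40000), roi_row(1e4, 1e6))
  rois$roi_id <- c("noisy", "clean")
  filt <- poisson_filter(rois, threshold = 0.05)
  expect_equal(filt$excluded$roi_id, "noisy")   # rel error 0.0503 > 5%
  expect_equal(filt$kept$roi_id, "clean")       # rel error 0.0100

  # either isotope pair can trip the cut
  mixed <- roi_row(1e4, 1e6, n15 = 300, n14 = 1e5)
  expect_equal(poisson_filter(mixed)$n_excluded, 1)

  # an infinite threshold keeps everything
  expect_equal(poisson_filter(rois, threshold = Inf)$n_kept, 2)
  expect_error(poisson_filter(rois, threshold = 0), "> 0")
})

test_that("excess enrichment subtracts the FOV background mean", {
  bg <- do.call(rbind, lapply(1:3, function(i) {
    r <- roi_row(round(0.011 * 1e6), round(0.989 * 1e6), bg = TRUE)
    r$roi_id <- paste0("bg", i)
    r
  }))
  cell <- roi_row(3e5, 7e5)
  rois <- excess_atpct(roi_ratio_and_error(rbind(cell, bg)))
  expect_equal(rois$excess_C_atfrac[1], 0.30 - 0.011, tolerance = 1e-6)
  expect_equal(rois$background_source[1], "fov_background")
  # backgrounds against their own FOV mean are centred on zero
  expect_equal(mean(rois$excess_C_atfrac[rois$is_background]), 0,
               tolerance = 1e-12)

  # missing backgrounds: constant fallback with a warning and a flag
  expect_warning(alone <- excess_atpct(roi_ratio_and_error(cell)),
                 "natural-abundance")
  expect_equal(alone$background_source, "constant")
  expect_equal(alone$excess_C_atfrac, 0.3 - 0.011)
})

test_that("biovolume models match sphere, capped-rod and cylinder geometry", {
  # invert the sphere: d = (6V/pi)^(1/3) for V = 3.2
  d32 <- (6 * 3.2 / pi)^(1 / 3)
  expect_equal(biovolume("coccus", d32), 3.2, tolerance = 1e-12)
  expect_equal(biovolume("coccus", 1.827), pi * 1.827^3 / 6)

  # a rod with l = d degenerates to a sphere
  expect_equal(biovolume("large_rod", 2, 2), pi * 8 / 6)

  # filament: plain cylinder, pi r^2 L
  expect_equal(biovolume("filament", 1, 70.4), pi * 0.25 * 70.4)
  expect_equal(biovolume("filament", 1, 70.4), 55.3, tolerance = 1e-3)

  expect_error(biovolume("large_rod", 2, 1), "length must be")
  expect_error(biovolume("coccus", 0), "diameter")
  expect_error(biovolume("cube", 1), "unknown morphotype")
})

test_that("allometric carbon content is exact, increasing and concave", {
  expect_equal(carbon_content(1), 197)
  expect_equal(carbon_content(55.3), 197 * 55.3^0.46)
  expect_equal(carbon_content(55.3), 1248, tolerance = 1e-3)
  expect_equal(carbon_content(7.4), 494.7, tolerance = 1e-3)

  v <- seq(0.1, 60, length.out = 200)
  cc <- carbon_content(v)
  expect_true(all(diff(cc) > 0))                 # increasing
  expect_true(all(diff(diff(cc)) < 0))           # concave
  expect_error(carbon_content(0), "volume")
})

test_that("volume -> carbon -> assimilation reproduces the reference rates", {
  vols <- c(filament = 55.3, large_rod = 7.4, coccus = 3.2,
            small_rod = 1.6, large_rod_anox = 7.4)
  exc <- c(0.29, 0.24, 0.23, 0.21, 0.21)
  ref <- c(30.1, 9.8, 6.4, 4.2, 8.6)
  got <- cell_assimilation_rate(carbon_content(vols), exc, t_days = 1)
  expect_true(all(abs(got - ref) / ref < 0.05))
  expect_equal(cell_assimilation_rate(1248, 0.29, 1), 30.1, tolerance = 0.01)
  expect_equal(cell_assimilation_rate(494.7, 0.21, 1), 8.6, tolerance = 0.01)
  expect_equal(cell_assimilation_rate(500, 0, 3), 0)
  expect_error(cell_assimilation_rate(500, 0.2, 0), "t_days")
})

test_that("growth-rate models obey closed forms and ordering", {
  expect_equal(as.numeric(growth_rate(0.29, 1, 0.74)),
               log(0.74 / 0.45), tolerance = 1e-12)
  expect_equal(as.numeric(growth_rate(0.29, 1, 0.74)), 0.497,
               tolerance = 1e-3)
  expect_equal(as.numeric(growth_rate(0.24, 1, 0.74)), 0.392,
               tolerance = 1e-3)

  # exponential >= linearised small-label estimate, equality as E -> 0
  set.seed(3)
  a <- runif(30, 0.3, 1)
  e <- a * runif(30, 0.01, 0.95)
  mu_exp <- mapply(function(E, A) as.numeric(growth_rate(E, 1, A)), e, a)
  expect_true(all(mu_exp >= e / a - 1e-12))
  expect_equal(as.numeric(growth_rate(1e-8, 1, 0.74)), 1e-8 / 0.74,
               tolerance = 1e-6)
  # exponential estimate never exceeds the linear-addition model
  mu_lin <- mapply(function(E, A)
    as.numeric(growth_rate(E, 1, A, model = "linear")), e, a)
  expect_true(all(mu_exp <= mu_lin + 1e-12))

  expect_error(growth_rate(0.8, 1, 0.74), "label exhaustion")
  expect_error(growth_rate(0.2, 1, 0), "label_fraction")
})

test_that("label-fraction calibration recovers a known generating value", {
  a_true <- 0.6
  e <- c(0.1, 0.2, 0.3, 0.4)
  mu <- log(a_true / (a_true - e))
  cal <- calibrate_label_fraction(e, mu)
  expect_equal(cal$label_fraction, a_true, tolerance = 1e-5)
  expect_equal(cal$fitted, mu, tolerance = 1e-5)
  expect_lt(cal$rss, 1e-8)
})

test_that("per-cell rates from bulk rates scale inversely with density", {
  expect_equal(percell_from_bulk(0.18, 2.0e4), 9.0)
  expect_equal(percell_from_bulk(0, 2.0e4), 0)
  expect_equal(percell_from_bulk(0.18, 1.0e4), 18.0)
  expect_error(percell_from_bulk(0.18, 0), "density")
})

test_that("morphotype summary reports boxplot statistics per group", {
  tr <- sim_truth(seed = 7, true_enrichment = 0.2, mean_counts = 1e6)
  rois <- excess_atpct(roi_ratio_and_error(
    gen_roi_table(tr, n_rois = 50, morphotype = "coccus")))
  s <- summarize_morphotypes(rois)
  expect_equal(s$morphotype, "coccus")
  expect_equal(s$n, 50)
  expect_true(s$q05 <= s$q25 & s$q25 <= s$median & s$median <= s$q75 &
                s$q75 <= s$q95)
  expect_equal(s$median, 0.2, tolerance = 0.01)
})
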