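#' Ground-truth parameter set for synthetic tracer data
#'
#' Bundles the generative parameters used by [gen_incubation_series()] and
#' [gen_roi_table()]: the true volumetric rate, an optional lag phase,
#' measurement noise, pool sizes, incubation geometry and nanoSIMS
#' enrichment/count levels. The defaults describe the emulated study
#' conditions: 220 ml of lake water under ~30 ml headspace in a 250-ml serum
#' bottle, 3-ml helium-replaced gas subsamples, >98% labeled methane, and a
#' deep hard-water-lake DIC pool of 2500 uM.
#'
#' @param seed Integer RNG seed; one stream per bottle/field of view.
#' @param true_rate True volumetric rate (uM d^-1 of the traced process).
#' @param lag_days Lag phase (days); product accumulation is zero before it.
#' @param noise_sd Gaussian noise SD on the observable (same units as the
#'   observable; 0 for noise-free data).
#' @param dic_uM Dissolved inorganic carbon (uM).
#' @param label_fraction Substrate labeling atom fraction in (0, 1].
#' @param headspace_ml,water_ml,subsample_ml Incubation geometry (ml).
#' @param poc_ug Particulate organic carbon per filtered sample (ug C).
#' @param filter_vol_ml Filtered water volume for POC samples (ml).
#' @param true_enrichment True excess \eqn{^{13}C} atom fraction of labeled
#'   cells (for ROI generation).
#' @param true_enrichment_15N True excess \eqn{^{15}N} atom fraction.
#' @param mean_counts Expected total ion counts per ROI and isotope pair.
#' @return A list of class `"sim_truth"`.
#' @export
sim_truth <- function(seed = 1L, true_rate = 0.2, lag_days = 0,
                      noise_sd = 0, dic_uM = 2500, label_fraction = 0.98,
                      headspace_ml = 30, water_ml = 220, subsample_ml = 3,
                      poc_ug = 50, filter_vol_ml = 10,
                      true_enrichment = 0.2, true_enrichment_15N = 0,
                      mean_counts = 1e6) {
  if (true_rate < 0) stop("true_rate must be >= 0")
  if (lag_days < 0) stop("lag_days must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (label_fraction <= 0 || label_fraction > 1)
    stop("label_fraction must be in (0, 1]")
  if (mean_counts <= 0) stop("mean_counts must be > 0")
  structure(list(seed = as.integer(seed), true_rate = true_rate,
                 lag_days = lag_days, noise_sd = noise_sd, dic_uM = dic_uM,
                 label_fraction = label_fraction, headspace_ml = headspace_ml,
                 water_ml = water_ml, subsample_ml = subsample_ml,
                 poc_ug = poc_ug, filter_vol_ml = filter_vol_ml,
                 true_enrichment = true_enrichment,
                 true_enrichment_15N = true_enrichment_15N,
                 mean_counts = mean_counts),
            class = "sim_truth")
}

#' Generate a synthetic incubation time series
#'
#' Produces one bottle's observable with the structure the rate estimators
#' assume: a deterministic trend that is zero during the lag phase and
#' linear afterwards, converted to the observable's scale, plus additive
#' Gaussian noise. For `"n30_headspace"` the accumulated tracer is
#' attenuated by the cumulative headspace-dilution factor of all prior
#' sampling events, which [denitrification_rate()] inverts exactly.
#'
#' Observable scales:
#' * `co2_ratio`: natural-abundance baseline 0.011 plus
#'   `rate * F / DIC * t`.
#' * `n30_headspace`: `rate * F^2 / 2 * t` (uM 30N2 per water volume),
#'   diluted per sampling event.
#' * `biomass_atpct`: excess atom fraction `rate * F / POC_uM * t`.
#'
#' @param truth A [sim_truth()].
#' @param times Sampling times (days), strictly increasing from 0.
#' @param observable Which observable to emit.
#' @param condition,depth_m Metadata copied onto the series.
#' @param molar_mass_C Molar mass of carbon used for the POC scale.
#' @return An [incubation_series()] with the truth attached as attribute
#'   `"truth"` for recovery tests.
#' @export
#' @examples
#' tr <- sim_truth(true_rate = 1.17, noise_sd = 0)
#' s <- gen_incubation_series(tr, observable = "co2_ratio")
#' ch4_oxidation_rate(s)$rate  # 1.17 exactly
gen_incubation_series <- function(truth,
                                  times = c(0, 1, 2, 5, 8, 12),
                                  observable = c("co2_ratio",
                                                 "n30_headspace",
                                                 "biomass_atpct"),
                                  condition = NA_character_,
                                  depth_m = NA_real_,
                                  molar_mass_C = iso_constants()$molar_mass_C) {
  observable <- match.arg(observable)
  stopifnot(inherits(truth, "sim_truth"))
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  prod_t <- truth$true_rate * pmax(0, times - truth$lag_days)
  f <- truth$label_fraction
  if (observable == "co2_ratio") {
    trend <- .const("nat_13C") + prod_t * f / truth$dic_uM
  } else if (observable == "biomass_atpct") {
    poc_uM <- (truth$poc_ug / molar_mass_C) / (truth$filter_vol_ml / 1000)
    trend <- prod_t * f / poc_uM
  } else {
    slope_conc <- truth$true_rate * f^2 / 2   # uM 30N2 per water volume
    undiluted <- slope_conc * pmax(0, times - truth$lag_days)
    events <- times[times > 0]
    d <- (truth$headspace_ml - truth$subsample_ml) / truth$headspace_ml
    n_prior <- vapply(times, function(t) sum(events < t), numeric(1))
    trend <- undiluted * d ^ n_prior
  }
  set.seed(truth$seed)
  noise <- if (truth$noise_sd > 0)
    stats::rnorm(length(times), 0, truth$noise_sd) else 0
  series <- incubation_series(
    times, trend + noise, observable = observable,
    dic_uM = truth$dic_uM, label_fraction = f,
    headspace_ml = truth$headspace_ml, water_ml = truth$water_ml,
    subsample_ml = truth$subsample_ml,
    subsample_times = times[times > 0],
    poc_ug = truth$poc_ug, filter_vol_ml = truth$filter_vol_ml,
    condition = condition, depth_m = depth_m)
  attr(series, "truth") <- truth
  series
}

#' Generate a synthetic nanoSIMS ROI count table
#'
#' Draws per-ROI ion counts as Poisson variates. For each labeled ROI the
#' expected minor-isotope fraction is natural abundance plus the true excess
#' enrichment; background ROIs carry natural abundance only. Counts for the
#' carbon pair (\eqn{^{13}C} vs \eqn{^{12}C}) and the CN pair
#' (\eqn{^{12}C^{15}N} vs \eqn{^{12}C^{14}N}) are drawn independently, each
#' with expected total `mean_counts`.
#'
#' @param truth A [sim_truth()]; uses `true_enrichment`,
#'   `true_enrichment_15N`, `mean_counts`, `seed`.
#' @param n_rois Number of labeled (cell) ROIs.
#' @param n_background Background ROIs per field of view (>= 3).
#' @param n_fov Number of fields of view to spread the ROIs over.
#' @param morphotype Morphotype label for the cell ROIs.
#' @param nat_13C,nat_15N Natural-abundance isotope fractions.
#' @return Data frame with columns `roi_id`, `fov_id`, `morphotype`,
#'   `counts_12C`, `counts_13C`, `counts_12C14N`, `counts_12C15N`,
#'   `is_background`, with the truth attached as attribute `"truth"`.
#' @export
gen_roi_table <- function(truth, n_rois, n_background = 3L, n_fov = 1L,
                          morphotype = "large_rod",
                          nat_13C = iso_constants()$nat_13C,
                          nat_15N = iso_constants()$nat_15N) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_background < 3L) stop("need at least 3 background ROIs per FOV")
  p_c <- nat_13C + truth$true_enrichment
  p_n <- nat_15N + truth$true_enrichment_15N
  if (p_c < 0 || p_n < 0)
    stop("enrichment may not be more negative than natural abundance")
  if (p_c > 1 || p_n > 1) stop("isotope fraction above 1")
  set.seed(truth$seed)
  fov_of_cell <- rep_len(seq_len(n_fov), n_rois)
  rows <- list()
  draw <- function(n, p) {
    m <- truth$mean_counts
    data.frame(minor = stats::rpois(n, m * p),
               major = stats::rpois(n, m * (1 - p)))
  }
  cells_c <- draw(n_rois, p_c)
  cells_n <- draw(n_rois, p_n)
  cells <- data.frame(
    roi_id = sprintf("cell_%04d", seq_len(n_rois)),
    fov_id = sprintf("fov_%02d", fov_of_cell),
    morphotype = morphotype,
    counts_12C = cells_c$major, counts_13C = cells_c$minor,
    counts_12C14N = cells_n$major, counts_12C15N = cells_n$minor,
    is_background = FALSE)
  n_bg <- n_background * n_fov
  bg_c <- draw(n_bg, nat_13C)
  bg_n <- draw(n_bg, nat_15N)
  bg <- data.frame(
    roi_id = sprintf("bg_%04d", seq_len(n_bg)),
    fov_id = sprintf("fov_%02d", rep(seq_len(n_fov), each = n_background)),
    morphotype = "background",
    counts_12C = bg_c$major, counts_13C = bg_c$minor,
    counts_12C14N = bg_n$major, counts_12C15N = bg_n$minor,
    is_background = TRUE)
  out <- rbind(cells, bg)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic concentration-depth profile
#'
#' Piecewise-linear interpolation between user-supplied (depth,
#' concentration) knots, sampled on a regular depth grid, with optional
#' Gaussian noise. Concentrations are clipped at zero. When `noise_sd = 0`
#' the generating slopes are exactly recoverable by zone-wise regression
#' ([segment_zones()]).
#'
#' @param knot_depth_m Knot depths (m, strictly increasing downward, >= 2).
#' @param knot_conc_uM Knot concentrations (uM, non-negative).
#' @param step_m Grid spacing (m).
#' @param noise_sd Gaussian noise SD (uM).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param species Species label.
#' @return A [depth_profile()] with attribute `"knots"`.
#' @export
#' @examples
#' p <- gen_depth_profile(c(120, 180), c(0, 40))
#' segment_zones(p, c(120, 180))$gradient_uM_m  # 40/60
gen_depth_profile <- function(knot_depth_m, knot_conc_uM, step_m = 1,
                              noise_sd = 0, seed = 1L, species = "CH4") {
  if (length(knot_depth_m) < 2L)
    stop("need at least 2 knots")
  if (any(diff(knot_depth_m) <= 0))
    stop("knot depths must be strictly increasing")
  if (length(knot_conc_uM) != length(knot_depth_m))
    stop("knot vectors must have equal length")
  if (any(knot_conc_uM < 0)) stop("knot concentrations must be >= 0")
  depths <- sort(unique(c(seq(min(knot_depth_m), max(knot_depth_m),
                              by = step_m), knot_depth_m)))
  conc <- stats::approx(knot_depth_m, knot_conc_uM, xout = depths)$y
  if (noise_sd > 0) {
    set.seed(seed)
    conc <- pmax(0, conc + stats::rnorm(length(conc), 0, noise_sd))
  }
  prof <- depth_profile(depths, conc, species = species)
  attr(prof, "knots") <- data.frame(depth_m = knot_depth_m,
                                    conc_uM = knot_conc_uM)
  prof
}
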