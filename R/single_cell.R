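#' Isotope ratios and Poisson counting errors for nanoSIMS ROIs
#'
#' For each region of interest (one cell, counts summed over all pixels and
#' planes), computes the minor-isotope fractions
#' \deqn{r_C = \frac{^{13}C}{^{12}C + ^{13}C}, \qquad
#'       r_N = \frac{^{12}C^{15}N}{^{12}C^{14}N + ^{12}C^{15}N}}
#' and the relative Poisson counting error of each ratio,
#' \eqn{\sqrt{1/N_{minor} + 1/N_{major}}}. ROIs with a zero minor count get
#' ratio 0, an undefined (infinite) error, and `error_undefined = TRUE`.
#'
#' @param rois Data frame with integer columns `counts_12C`, `counts_13C`,
#'   `counts_12C14N`, `counts_12C15N` (see [gen_roi_table()] for the full
#'   schema).
#' @return `rois` with columns `ratio_C`, `ratio_N`, `rel_poisson_error_C`,
#'   `rel_poisson_error_N`, `error_undefined` appended.
#' @export
#' @examples
#' r <- roi_ratio_and_error(data.frame(counts_12C = 40000, counts_13C = 400,
#'                                     counts_12C14N = 40000,
#'                                     counts_12C15N = 400))
#' r$rel_poisson_error_C  # sqrt(1/400 + 1/40000) = 0.0503
roi_ratio_and_error <- function(rois) {
  need <- c("counts_12C", "counts_13C", "counts_12C14N", "counts_12C15N")
  if (!all(need %in% names(rois)))
    stop("rois must have columns ", paste(need, collapse = ", "))
  if (any(rois[need] < 0)) stop("ion counts must be non-negative")
  tot_c <- rois$counts_12C + rois$counts_13C
  tot_n <- rois$counts_12C14N + rois$counts_12C15N
  if (any(tot_c == 0) || any(tot_n == 0))
    stop("zero total counts for an isotope pair")
  rel_err <- function(minor, major) {
    ifelse(minor > 0 & major > 0, sqrt(1 / minor + 1 / major), Inf)
  }
  rois$ratio_C <- rois$counts_13C / tot_c
  rois$ratio_N <- rois$counts_12C15N / tot_n
  rois$rel_poisson_error_C <- rel_err(rois$counts_13C, rois$counts_12C)
  rois$rel_poisson_error_N <- rel_err(rois$counts_12C15N, rois$counts_12C14N)
  rois$error_undefined <- !is.finite(rois$rel_poisson_error_C) |
    !is.finite(rois$rel_poisson_error_N)
  rois
}

#' Exclude ROIs with excessive Poisson counting error
#'
#' An ROI is excluded when the relative Poisson error of either isotope
#' ratio exceeds the threshold (default 5%). ROIs whose error is undefined
#' (zero minor counts) are excluded as well.
#'
#' @param rois Data frame with the error columns from
#'   [roi_ratio_and_error()] (computed here if missing).
#' @param threshold Relative-error cut, > 0 (default 0.05).
#' @return List with data frames `kept` and `excluded` plus counts `n_kept`,
#'   `n_excluded`.
#' @export
poisson_filter <- function(rois,
                           threshold = iso_constants()$poisson_threshold) {
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be numeric")
  if (threshold <= 0) stop("threshold must be > 0")
  if (!"rel_poisson_error_C" %in% names(rois))
    rois <- roi_ratio_and_error(rois)
  bad <- rois$rel_poisson_error_C > threshold |
    rois$rel_poisson_error_N > threshold
  bad[is.na(bad)] <- TRUE
  list(kept = rois[!bad, , drop = FALSE],
       excluded = rois[bad, , drop = FALSE],
       n_kept = sum(!bad), n_excluded = sum(bad))
}

#' Excess isotope enrichment relative to field-of-view backgrounds
#'
#' Subtracts from each ROI's isotope ratio the mean ratio of the background
#' ROIs measured in the same field of view (at least 3 per FOV). If a FOV
#' has fewer than 3 backgrounds, the canonical natural-abundance constants
#' (1.1% for \eqn{^{13}C}, 0.36% for \eqn{^{15}N}) are used instead and the
#' rows are flagged with `background_source = "constant"` plus a warning.
#'
#' @param rois Data frame with `fov_id`, `is_background` and ratio columns
#'   (ratios computed via [roi_ratio_and_error()] if missing).
#' @param nat_13C,nat_15N Fallback natural-abundance constants.
#' @return `rois` with columns `excess_C_atfrac`, `excess_N_atfrac`,
#'   `background_source` appended.
#' @export
excess_atpct <- function(rois, nat_13C = iso_constants()$nat_13C,
                         nat_15N = iso_constants()$nat_15N) {
  if (!"ratio_C" %in% names(rois)) rois <- roi_ratio_and_error(rois)
  if (!all(c("fov_id", "is_background") %in% names(rois)))
    stop("rois must have fov_id and is_background columns")
  rois$excess_C_atfrac <- NA_real_
  rois$excess_N_atfrac <- NA_real_
  rois$background_source <- NA_character_
  fell_back <- FALSE
  for (fov in unique(rois$fov_id)) {
    sel <- rois$fov_id == fov
    bg <- rois[sel & rois$is_background, , drop = FALSE]
    if (nrow(bg) >= 3L) {
      base_c <- mean(bg$ratio_C)
      base_n <- mean(bg$ratio_N)
      src <- "fov_background"
    } else {
      base_c <- nat_13C
      base_n <- nat_15N
      src <- "constant"
      fell_back <- TRUE
    }
    rois$excess_C_atfrac[sel] <- rois$ratio_C[sel] - base_c
    rois$excess_N_atfrac[sel] <- rois$ratio_N[sel] - base_n
    rois$background_source[sel] <- src
  }
  if (fell_back)
    warning("fewer than 3 background ROIs in at least one FOV; ",
            "fell back to natural-abundance constants")
  rois
}

#' Cell biovolume from morphotype geometry
#'
#' Geometric models per morphotype: cocci are spheres
#' (\eqn{V = \pi d^3/6}); rods are cylinders capped with a half-sphere on
#' both ends (\eqn{V = \pi (d/2)^2 (l - d) + \pi d^3 / 6}, requiring
#' \eqn{l \ge d}); filaments are plain cylinders over their full length
#' (\eqn{V = \pi (d/2)^2 l}).
#'
#' @param morphotype One of `"coccus"`, `"small_rod"`, `"large_rod"`,
#'   `"nc10_rod"`, `"filament"` (rod variants share the capped-cylinder
#'   model). Vectorised.
#' @param diameter_um Cell diameter (um), > 0.
#' @param length_um Cell/filament length (um); ignored for cocci.
#' @return Biovolume (um^3).
#' @export
#' @examples
#' biovolume("filament", 1, 70.4)  # 55.3 um^3
biovolume <- function(morphotype, diameter_um, length_um = NA_real_) {
  n <- max(length(morphotype), length(diameter_um), length(length_um))
  morphotype <- rep_len(morphotype, n)
  diameter_um <- rep_len(diameter_um, n)
  length_um <- rep_len(length_um, n)
  if (any(diameter_um <= 0)) stop("diameter must be > 0")
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- diameter_um[i]
    l <- length_um[i]
    out[i] <- switch(morphotype[i],
      coccus = pi * d^3 / 6,
      small_rod = ,
      large_rod = ,
      nc10_rod = {
        if (is.na(l) || l < d)
          stop("rod length must be >= diameter")
        pi * (d / 2)^2 * (l - d) + pi * d^3 / 6
      },
      filament = {
        if (is.na(l) || l <= 0) stop("filament length must be > 0")
        pi * (d / 2)^2 * l
      },
      stop("unknown morphotype: ", morphotype[i]))
  }
  out
}

#' Cellular carbon content from biovolume
#'
#' Allometric carbon-to-volume model for bacterioplankton,
#' \deqn{C_{fg} = 197 \times V^{0.46},}
#' with V in um^3 and C in fg. The exponent < 1 makes carbon density
#' decrease with cell size; C(1 um^3) = 197 fg exactly.
#'
#' @param volume_um3 Biovolume (um^3), > 0. Vectorised.
#' @param a,b Allometry coefficients.
#' @return Carbon content (fg C per cell).
#' @export
#' @examples
#' carbon_content(55.3)  # ~1248 fg
carbon_content <- function(volume_um3, a = iso_constants()$allometry_a,
                           b = iso_constants()$allometry_b) {
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0))
    stop("volume must be > 0")
  a * volume_um3^b
}

#' Per-cell carbon assimilation rate from excess enrichment
#'
#' The carbon content of the cell multiplied by its excess
#' \eqn{^{13}C/(^{12}C+^{13}C)} ratio gives the mass of tracer carbon
#' assimilated; dividing by the molar mass of carbon (fg to fmol) and the
#' incubation time gives the rate:
#' \deqn{r = \frac{C_{fg} \times E}{M_C \, t} \quad
#'   [fmol\, ^{13}C\, cell^{-1}\, d^{-1}].}
#'
#' @param carbon_fg Cellular carbon content (fg C).
#' @param excess_atfrac Excess \eqn{^{13}C} atom fraction.
#' @param t_days Incubation time (days), > 0.
#' @param molar_mass_C Molar mass of carbon (fg fmol^-1).
#' @return Rate in fmol 13C cell^-1 d^-1. Vectorised.
#' @export
#' @examples
#' cell_assimilation_rate(carbon_content(55.3), 0.29)  # ~30.1
cell_assimilation_rate <- function(carbon_fg, excess_atfrac, t_days = 1,
                                   molar_mass_C = iso_constants()$molar_mass_C) {
  if (any(t_days <= 0)) stop("t_days must be > 0")
  carbon_fg * excess_atfrac / molar_mass_C / t_days
}

#' Growth rate from single-cell isotope enrichment
#'
#' Under exponential growth on a substrate pool with effective labeling
#' atom fraction `A`, new biomass carries enrichment `A`, so a cell observed
#' with excess enrichment `E` after time `t` has grown at
#' \deqn{\mu = \frac{1}{t} \ln\!\frac{A}{A - E}.}
#' The optional linear model instead treats growth as linear biomass
#' addition: \eqn{\mu = (E/A)/(1 - E/A)/t}. Both reduce to
#' \eqn{E/(A t)} as \eqn{E \to 0}, and the exponential estimate is always
#' the smaller of the two for valid inputs.
#'
#' The effective `A` of an experiment (labeled substrate fraction possibly
#' reduced by assimilation of unlabeled carbon sources) is rarely known
#' a priori; see [calibrate_label_fraction()] to fit it from reference
#' (enrichment, growth-rate) pairs.
#'
#' @param excess_atfrac Excess isotope atom fraction, with
#'   `0 < excess_atfrac < label_fraction`.
#' @param t_days Incubation time (days), > 0.
#' @param label_fraction Effective maximal labeling atom fraction `A` in
#'   (0, 1]; default 1 (fully labeled substrate).
#' @param model `"exponential"` (default) or `"linear"`.
#' @return Growth rate (d^-1), vectorised, with `model` and
#'   `label_fraction` attached as attributes.
#' @export
#' @examples
#' growth_rate(0.29, 1, label_fraction = 0.74)  # ~0.497
growth_rate <- function(excess_atfrac, t_days = 1, label_fraction = 1,
                        model = c("exponential", "linear")) {
  model <- match.arg(model)
  a <- label_fraction
  if (a <= 0 || a > 1) stop("label_fraction must be in (0, 1]")
  if (any(t_days <= 0)) stop("t_days must be > 0")
  if (any(excess_atfrac <= 0)) stop("excess enrichment must be > 0")
  if (any(excess_atfrac >= a))
    stop("excess enrichment >= effective label fraction (label exhaustion)")
  mu <- if (model == "exponential") {
    log(a / (a - excess_atfrac)) / t_days
  } else {
    x <- excess_atfrac / a
    (x / (1 - x)) / t_days
  }
  structure(mu, model = model, label_fraction = a)
}

#' Calibrate the effective labeling fraction of the growth model
#'
#' Least-squares fit of the effective maximal labeling atom fraction `A` of
#' [growth_rate()]'s exponential model to reference pairs of observed excess
#' enrichment and growth rate. Minimises
#' \eqn{\sum_i (\mu(E_i; A) - \mu_i)^2} over
#' `A` in (max(E) + eps, 1] via one-dimensional optimisation.
#'
#' @param excess_atfrac Excess enrichments of the reference set.
#' @param mu_ref Reference growth rates (d^-1).
#' @param t_days Incubation time of the reference observations (days).
#' @return List with `label_fraction` (fitted A), `rss`, and `fitted`
#'   (model growth rates at the fitted A).
#' @export
calibrate_label_fraction <- function(excess_atfrac, mu_ref, t_days = 1) {
  if (length(excess_atfrac) != length(mu_ref))
    stop("excess and mu_ref must have the same length")
  lower <- max(excess_atfrac) + 1e-9
  if (lower >= 1) stop("enrichments leave no admissible label fraction")
  sse <- function(a)
    sum((log(a / (a - excess_atfrac)) / t_days - mu_ref)^2)
  opt <- stats::optimize(sse, c(lower, 1), tol = 1e-10)
  a_hat <- opt$minimum
  list(label_fraction = a_hat, rss = opt$objective,
       fitted = as.numeric(growth_rate(excess_atfrac, t_days,
                                       label_fraction = a_hat)))
}

#' Per-cell rate implied by a bulk rate and a population density
#'
#' Divides a bulk volumetric rate by the density of the population assumed
#' to carry it:
#' \deqn{r_{cell} = \frac{R\, [\mu mol\, L^{-1} d^{-1}]}
#'   {n\, [cells\, L^{-1}]} \times 10^9 \quad [fmol\, cell^{-1} d^{-1}].}
#'
#' @param bulk_rate_uM_d Bulk rate (uM d^-1 = umol L^-1 d^-1).
#' @param cells_per_ml Population density (cells ml^-1), > 0.
#' @return Per-cell rate (fmol cell^-1 d^-1).
#' @export
#' @examples
#' percell_from_bulk(0.18, 2e4)  # 9.0
percell_from_bulk <- function(bulk_rate_uM_d, cells_per_ml) {
  if (any(cells_per_ml <= 0)) stop("cell density must be > 0")
  bulk_rate_uM_d / (cells_per_ml * 1e3) * 1e9
}

#' Reference morphotype geometry table
#'
#' Mean biovolumes of the methanotroph morphotypes distinguished in the
#' emulated survey (cocci, small and large rods, filaments targeted by a
#' gamma-MOB FISH probe, and the small NC10-type rods), for use as fixture
#' defaults in pipelines and examples.
#'
#' @return Data frame with columns `morphotype`, `shape`,
#'   `mean_volume_um3`.
#' @export
morphotype_geometry <- function() {
  data.frame(
    morphotype = c("filament", "large_rod", "coccus", "small_rod",
                   "nc10_rod"),
    shape = c("cylinder", "capped_rod", "sphere", "capped_rod",
              "capped_rod"),
    mean_volume_um3 = c(55.3, 7.4, 3.2, 1.6, 0.14)
  )
}

#' Per-morphotype summary of single-cell enrichment
#'
#' Boxplot-style statistics (median, quartiles, 5th/95th percentiles) of
#' excess \eqn{^{13}C} enrichment per morphotype, for filtered,
#' background-corrected ROI tables.
#'
#' @param rois ROI data frame with `morphotype` and `excess_C_atfrac`
#'   columns (background rows are dropped).
#' @return Data frame with one row per morphotype: `n`, `median`, `q25`,
#'   `q75`, `q05`, `q95` of the excess atom fraction.
#' @export
summarize_morphotypes <- function(rois) {
  rois <- rois[!rois$is_background, , drop = FALSE]
  do.call(rbind, lapply(split(rois, rois$morphotype), function(d) {
    q <- stats::quantile(d$excess_C_atfrac, c(0.05, 0.25, 0.5, 0.75, 0.95),
                         names = FALSE)
    data.frame(morphotype = d$morphotype[1], n = nrow(d),
               median = q[3], q25 = q[2], q75 = q[4], q05 = q[1], q95 = q[5])
  }))
}
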