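#' Cell density from filter counts
#'
#' Standard epifluorescence filter-count scaling: the counted cells are
#' divided by the fraction of the filter area screened
#' (`fields_screened * field_area / filter_area`) and by the filtered water
#' volume. Coccoid cells arranged in clusters contribute the sum of their
#' per-cluster cell numbers on top of the singleton count.
#'
#' @param cells_counted Cells counted across the screened fields (>= 0).
#' @param fields_screened Number of fields of view screened, > 0.
#' @param field_area_mm2 Area of one field of view (mm^2), > 0.
#' @param filter_area_mm2 Effective filtration area of the filter (mm^2),
#'   > 0. Default: a 25-mm filter with ~21 mm effective diameter.
#' @param volume_filtered_ml Filtered water volume (ml), > 0.
#' @param cluster_sizes Optional integer vector of cells per encountered
#'   cluster, added to `cells_counted`.
#' @return Cell density (cells ml^-1).
#' @export
#' @examples
#' counts_to_density(100, 50, 0.0139, 346.4, 10)
counts_to_density <- function(cells_counted, fields_screened,
                              field_area_mm2,
                              filter_area_mm2 = pi * (21 / 2)^2,
                              volume_filtered_ml,
                              cluster_sizes = NULL) {
  if (cells_counted < 0) stop("cells_counted must be >= 0")
  if (fields_screened <= 0) stop("fields_screened must be > 0")
  if (field_area_mm2 <= 0 || filter_area_mm2 <= 0 || volume_filtered_ml <= 0)
    stop("scaling factors must be > 0")
  total <- cells_counted + sum(cluster_sizes)
  area_fraction <- fields_screened * field_area_mm2 / filter_area_mm2
  total / area_fraction / volume_filtered_ml
}

#' Population biomass from density and per-cell carbon
#'
#' \deqn{B = n \,[cells\, ml^{-1}] \times 10^3 \times C_{fg} \times 10^{-9}
#'   \quad [\mu g\, C\, L^{-1}].}
#'
#' @param cells_per_ml Cell density (cells ml^-1), >= 0. Vectorised.
#' @param carbon_fg Per-cell carbon content (fg C), >= 0.
#' @return Biomass (ug C L^-1).
#' @export
#' @examples
#' population_biomass(2e4, carbon_content(7.4))  # ~9.9 ug C/L
population_biomass <- function(cells_per_ml, carbon_fg) {
  if (any(cells_per_ml < 0) || any(carbon_fg < 0))
    stop("inputs must be >= 0")
  cells_per_ml * 1e3 * carbon_fg * 1e-9
}

#' Morphotype biomass shares
#'
#' Relative contribution of each morphotype to total population biomass;
#' the shares form a probability vector.
#'
#' @param cells_per_ml Densities per morphotype.
#' @param carbon_fg Per-cell carbon contents per morphotype.
#' @return Named numeric vector of shares summing to 1.
#' @export
biomass_shares <- function(cells_per_ml, carbon_fg) {
  b <- population_biomass(cells_per_ml, carbon_fg)
  if (sum(b) == 0) stop("total biomass is zero")
  b / sum(b)
}

#' Log-linear growth statistics from a density time series
#'
#' Fits \eqn{\ln n(t) = \ln n_0 + \mu t} by OLS and reports the specific
#' growth rate and the implied doubling time. With exactly two time points
#' this reduces to the two-point estimate
#' \eqn{\mu = \ln(n_2/n_1)/(t_2 - t_1)}.
#'
#' @param time_d Times (days), strictly increasing, >= 2 points.
#' @param cells_per_ml Densities (cells ml^-1), > 0.
#' @return List with `mu_per_d`, `doubling_d` (`Inf` when `mu <= 0`), `n0`
#'   (fitted initial density) and `n_points`.
#' @export
#' @examples
#' growth_curve(c(0, 8), c(1.4e4, 3.7e4))$mu_per_d  # 0.121
growth_curve <- function(time_d, cells_per_ml) {
  if (length(time_d) < 2L) stop("need at least 2 time points")
  if (any(diff(time_d) <= 0)) stop("time_d must be strictly increasing")
  if (any(cells_per_ml <= 0)) stop("densities must be > 0")
  fit <- stats::lm(log(cells_per_ml) ~ time_d)
  mu <- unname(stats::coef(fit)["time_d"])
  list(mu_per_d = mu,
       doubling_d = if (mu > 0) log(2) / mu else Inf,
       n0 = exp(unname(stats::coef(fit)[1])),
       n_points = length(time_d))
}
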