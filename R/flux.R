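#' Construct a concentration-depth profile
#'
#' Depths are metres below the surface, positive downward and strictly
#' increasing; concentrations are uM and non-negative. Gradients are
#' computed as dC/dz with z downward, so a concentration increasing with
#' depth gives a positive gradient and a positive (upward) diffusive flux.
#'
#' @param depth_m Depths (m), strictly increasing.
#' @param conc_uM Concentrations (uM), non-negative.
#' @param species Species label (metadata).
#' @return Data frame of class `"depth_profile"`.
#' @export
depth_profile <- function(depth_m, conc_uM, species = "CH4") {
  if (length(depth_m) != length(conc_uM))
    stop("depth_m and conc_uM must have the same length")
  if (length(depth_m) < 2L || any(diff(depth_m) <= 0))
    stop("depth_m must be strictly increasing with at least two points")
  if (any(conc_uM < 0)) stop("concentrations must be >= 0")
  structure(data.frame(depth_m = as.numeric(depth_m),
                       conc_uM = as.numeric(conc_uM)),
            class = c("depth_profile", "data.frame"),
            species = species)
}

#' Split a profile into depth zones and fit per-zone gradients
#'
#' Breakpoints (including both profile ends) delimit contiguous depth
#' intervals; within each interval, the concentration gradient is the OLS
#' slope of concentration against depth over all points in the interval,
#' boundaries included. Zone boundaries are chosen by the analyst from
#' visible slope changes in the profile; they are never auto-detected.
#'
#' @param profile A [depth_profile()].
#' @param breakpoints Ordered depths (m) delimiting the zones, within the
#'   profile's depth range; `n` breakpoints give `n - 1` zones.
#' @return Data frame with one row per zone: `z_top`, `z_bottom` (m),
#'   `gradient_uM_m` (uM m^-1), `n_points`.
#' @export
segment_zones <- function(profile, breakpoints) {
  stopifnot(inherits(profile, "depth_profile"))
  breakpoints <- sort(unique(as.numeric(breakpoints)))
  if (length(breakpoints) < 2L) stop("need at least 2 breakpoints")
  rng <- range(profile$depth_m)
  if (any(breakpoints < rng[1] | breakpoints > rng[2]))
    stop("breakpoints must lie within the profile depth range")
  zones <- data.frame(z_top = breakpoints[-length(breakpoints)],
                      z_bottom = breakpoints[-1])
  zones$gradient_uM_m <- NA_real_
  zones$n_points <- NA_integer_
  for (i in seq_len(nrow(zones))) {
    sel <- profile$depth_m >= zones$z_top[i] &
      profile$depth_m <= zones$z_bottom[i]
    if (sum(sel) < 2L)
      stop(sprintf("zone %g-%g m has fewer than 2 points",
                   zones$z_top[i], zones$z_bottom[i]))
    fit <- stats::lm(conc_uM ~ depth_m, data = profile[sel, ])
    zones$gradient_uM_m[i] <- unname(stats::coef(fit)["depth_m"])
    zones$n_points[i] <- sum(sel)
  }
  zones
}

#' Fickian diffusive flux from a concentration gradient
#'
#' Fick's first law, \eqn{F = D \times dC/dz}, with the turbulent diffusion
#' coefficient given in cm^2 s^-1 and the gradient in uM m^-1. Unit chain:
#' 1 cm^2 s^-1 = 1e-4 * 86400 m^2 d^-1 = 8.64 m^2 d^-1, and
#' 1 uM m^-1 = 1 mmol m^-4, so the flux comes out in mmol m^-2 d^-1.
#' A positive gradient (concentration increasing downward) gives a positive
#' flux, i.e. upward transport.
#'
#' @param gradient_uM_m Concentration gradient (uM m^-1), possibly a vector.
#' @param D_cm2_s Turbulent diffusion coefficient (cm^2 s^-1), > 0.
#' @return Data frame of class `"flux_estimate"` with columns
#'   `gradient_uM_m`, `D_cm2_s`, `D_m2_d`, `flux_mmol_m2_d`.
#' @export
#' @examples
#' fick_flux(1.55)$flux_mmol_m2_d  # ~3.6
fick_flux <- function(gradient_uM_m,
                      D_cm2_s = iso_constants()$diffusivity_cm2_s) {
  if (!is.finite(D_cm2_s) || D_cm2_s <= 0) stop("D must be > 0")
  d_m2_d <- D_cm2_s * 1e-4 * 86400
  structure(data.frame(gradient_uM_m = gradient_uM_m,
                       D_cm2_s = D_cm2_s, D_m2_d = d_m2_d,
                       flux_mmol_m2_d = d_m2_d * gradient_uM_m),
            class = c("flux_estimate", "data.frame"))
}

#' Zone-wise Fickian fluxes for a profile
#'
#' Convenience wrapper: [segment_zones()] followed by [fick_flux()] on each
#' zone's gradient.
#'
#' @inheritParams segment_zones
#' @inheritParams fick_flux
#' @return The zone table with flux columns appended.
#' @export
zone_fluxes <- function(profile, breakpoints,
                        D_cm2_s = iso_constants()$diffusivity_cm2_s) {
  zones <- segment_zones(profile, breakpoints)
  fx <- fick_flux(zones$gradient_uM_m, D_cm2_s = D_cm2_s)
  cbind(zones, fx[, c("D_cm2_s", "D_m2_d", "flux_mmol_m2_d")])
}
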