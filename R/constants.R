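#' Default physical and analytical constants
#'
#' Central registry of the constants used throughout the quantification
#' chain. Every function that uses one of these values takes it as an
#' argument with the default drawn from here, so a whole run can be
#' re-parameterised from one place (see [run_pipeline()]).
#'
#' @return Named list:
#' \describe{
#'   \item{nat_13C}{Natural abundance of \eqn{^{13}C/(^{12}C+^{13}C)}, 0.011.}
#'   \item{nat_15N}{Natural abundance of \eqn{^{15}N/(^{14}N+^{15}N)}, 0.0036.}
#'   \item{molar_mass_C}{Molar mass of carbon, 12.011 g mol^-1 (equivalently
#'     fg fmol^-1); used for POC and fg-to-fmol conversions.}
#'   \item{diffusivity_cm2_s}{Turbulent diffusion coefficient for water-column
#'     fluxes, 0.27 cm^2 s^-1.}
#'   \item{poisson_threshold}{Relative Poisson counting-error cut for nanoSIMS
#'     ROIs, 0.05.}
#'   \item{stoich_n_per_ch4}{Mol NO3^- reduced to N2 per mol CH4 oxidised to
#'     CO2 under complete denitrification, 8/5.}
#'   \item{n_points}{Number of leading time points used for rate regressions,
#'     5 (the day-12 sample is excluded because tracer-product accumulation
#'     turns exponential).}
#'   \item{allometry_a, allometry_b}{Coefficients of the cell carbon model
#'     C_fg = a * V^b with a = 197 fg C um^-3 and b = 0.46.}
#' }
#' @export
#' @examples
#' iso_constants()$diffusivity_cm2_s
iso_constants <- function() {
  list(
    nat_13C = 0.011,
    nat_15N = 0.0036,
    molar_mass_C = 12.011,
    diffusivity_cm2_s = 0.27,
    poisson_threshold = 0.05,
    stoich_n_per_ch4 = 8 / 5,
    n_points = 5L,
    allometry_a = 197,
    allometry_b = 0.46
  )
}

# internal shorthand
.const <- function(name) iso_constants()[[name]]
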