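#' Membrane-bound gold nanoparticle heat source
#'
#' Steady-state point-absorber model of an optically heated AuNP in water.
#' The absorbed power is a user input: it depends on the particle's
#' absorption cross-section at the trapping wavelength, which is not
#' modelled here. The ambient (bulk) temperature rise produced by the laser
#' focus itself is a configurable constant, typically 4-6 degC at the powers
#' used for domain manipulation; it is never derived.
#'
#' @param np_radius_nm Nanoparticle radius in nm, > 0. Default 75
#'   (150 nm streptavidin-coated particles).
#' @param absorbed_power_uw Absorbed optical power in uW, >= 0.
#' @param medium_conductivity_w_mk Thermal conductivity of the surrounding
#'   medium in W/(m K). Default 0.6 (water).
#' @param ambient_rise_c Bulk temperature rise in degC added on request by
#'   [temperature_at()]. Default 5 (middle of the 4-6 degC range).
#' @return An object of class `np_heat_source`.
#' @export
np_heat_source <- function(np_radius_nm = 75,
                           absorbed_power_uw = 0,
                           medium_conductivity_w_mk = 0.6,
                           ambient_rise_c = 5) {
  stopifnot(is.numeric(np_radius_nm), is.numeric(absorbed_power_uw),
            is.numeric(medium_conductivity_w_mk), is.numeric(ambient_rise_c))
  if (np_radius_nm <= 0) stop("np_radius_nm must be > 0", call. = FALSE)
  if (medium_conductivity_w_mk <= 0) {
    stop("medium conductivity must be > 0", call. = FALSE)
  }
  if (absorbed_power_uw < 0) {
    stop("absorbed power must be >= 0", call. = FALSE)
  }
  structure(list(np_radius_nm = np_radius_nm,
                 absorbed_power_uw = absorbed_power_uw,
                 medium_conductivity_w_mk = medium_conductivity_w_mk,
                 ambient_rise_c = ambient_rise_c),
            class = "np_heat_source")
}

#' Nanoparticle surface temperature rise
#'
#' Steady-state solution for a spherical absorber of radius \eqn{a}
#' dissipating power \eqn{P} into a medium of conductivity \eqn{k}:
#' \eqn{\Delta T_s = P/(4\pi k a)}. Linear in power, inverse in radius and
#' conductivity.
#'
#' @param source A [np_heat_source()].
#' @return Surface temperature rise in degC.
#' @examples
#' surface_temperature_rise(np_heat_source(75, 10)) # about 17.7 degC
#' @export
surface_temperature_rise <- function(source) {
  stopifnot(inherits(source, "np_heat_source"))
  p_w <- source$absorbed_power_uw * 1e-6
  a_m <- source$np_radius_nm * 1e-9
  p_w / (4 * pi * source$medium_conductivity_w_mk * a_m)
}

#' Temperature rise at a distance from the particle centre
#'
#' Inside the (isothermal, metallic) particle the rise is flat at
#' \eqn{\Delta T_s}; outside it decays as the inverse of the distance,
#' \eqn{\Delta T(r) = \Delta T_s \, a/r}, continuous at \eqn{r = a}. The
#' 1/r decay is what confines strong heating (potentially > 100 degC at the
#' particle) to a region comparable to the particle size, leaving most of an
#' encapsulated cargo micrometres away essentially unheated.
#'
#' @param source A [np_heat_source()].
#' @param r_nm Distance(s) from the particle centre in nm, >= 0.
#'   Vectorised.
#' @param include_ambient Add the configured bulk rise (default FALSE).
#' @return Temperature rise(s) in degC.
#' @export
temperature_at <- function(source, r_nm, include_ambient = FALSE) {
  stopifnot(inherits(source, "np_heat_source"), is.numeric(r_nm))
  if (any(r_nm < 0)) stop("distance must be >= 0", call. = FALSE)
  dts <- surface_temperature_rise(source)
  dt <- ifelse(r_nm <= source$np_radius_nm, dts,
               dts * source$np_radius_nm / r_nm)
  if (include_ambient) dt <- dt + source$ambient_rise_c
  dt
}

#' Radius of the zone heated above a threshold
#'
#' Inverts the 1/r field: the temperature rise equals `threshold_c` at
#' \eqn{r^\ast = a \, \Delta T_s / \mathrm{threshold}}. A threshold equal to
#' \eqn{\Delta T_s} gives the particle radius itself; half of it gives
#' \eqn{2a} — heating above any sizeable fraction of the surface rise is
#' confined to a region comparable to the particle diameter.
#'
#' @param source A [np_heat_source()].
#' @param threshold_c Temperature-rise threshold in degC, > 0.
#' @return Radius in nm where the rise first falls to the threshold, or
#'   `NA_real_` when the threshold exceeds the surface rise (no hot zone).
#' @export
hot_zone_extent <- function(source, threshold_c) {
  stopifnot(inherits(source, "np_heat_source"), is.numeric(threshold_c))
  if (threshold_c <= 0) {
    stop("threshold must be > 0 (the 1/r field never reaches 0)",
         call. = FALSE)
  }
  dts <- surface_temperature_rise(source)
  if (threshold_c > dts) return(NA_real_)
  source$np_radius_nm * dts / threshold_c
}
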