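#' Saturation vapour pressure (Tetens formula)
#'
#' Saturation vapour pressure of water over a flat surface at air temperature
#' `temp_c`, using the Tetens approximation
#' \eqn{e_s(T) = 0.6108 \exp(17.27 T / (T + 237.3))} (kPa, T in degrees C).
#' This single formula backs every vapour-pressure-deficit computation in the
#' package so that simulated and recomputed deficits agree exactly.
#'
#' @param temp_c Temperature in degrees Celsius (vectorised).
#' @return Saturation vapour pressure in kPa.
#' @examples
#' es_tetens(25) # about 3.17 kPa
#' @export
es_tetens <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Leaf-to-air vapour pressure deficit
#'
#' Computes the vapour pressure deficit driving leaf transpiration,
#' \eqn{D = e_s(T_{leaf}) - RH \cdot e_s(T_{air})} (kPa). Leaf temperature is
#' the more precise driver when available (e.g. from gas-exchange cuvette
#' readings); where `tleaf_c` is `NA` the air-to-air deficit
#' \eqn{e_s(T_{air})(1 - RH)} is used instead. Negative results (supersaturated
#' cuvette, condensation) are floored at zero with a warning.
#'
#' @param tleaf_c Leaf temperature, degrees C. May contain `NA` (falls back to
#'   air-to-air deficit for those elements).
#' @param tair_c Air temperature, degrees C.
#' @param rh Relative humidity as a fraction in (0, 1].
#' @return Vapour pressure deficit in kPa, same length as the inputs.
#' @examples
#' leaf_vpd(25, 25, 0.5) # half of es(25)
#' @export
leaf_vpd <- function(tleaf_c, tair_c, rh) {
  if (any(rh <= 0 | rh > 1, na.rm = TRUE)) {
    abort("`rh` must be a fraction in (0, 1].")
  }
  tleaf_c <- ifelse(is.na(tleaf_c), tair_c, tleaf_c)
  d <- es_tetens(tleaf_c) - rh * es_tetens(tair_c)
  if (any(d < 0, na.rm = TRUE)) {
    warn(sprintf("%d negative deficit value(s) floored at 0 kPa.",
                 sum(d < 0, na.rm = TRUE)))
    d <- pmax(d, 0)
  }
  d
}

# Conversion factors owned in one place. Seconds<->hours, cm<->m, and the
# water/air constants used to map sap flux density to a molar vapour flux.
.hydro_units <- list(
  s_per_h        = 3600,
  m_per_cm       = 0.01,
  rho_water      = 998.2,    # kg m-3 at 20 degC
  eta_water      = 1.002e-9, # MPa s at 20 degC
  r_gas          = 8.31446,  # J mol-1 K-1
  um2_per_m2     = 1e12,
  mm2_per_m2     = 1e6,
  kpa_per_pa     = 1e-3
)

#' Unit conversion factors used across the package
#'
#' Returns the named list of physical constants and conversion factors shared
#' by the simulator and the trait calculators (water density and viscosity at
#' 20 degrees C, gas constant, length/time factors). Exposed so the exact
#' values entering each trait are inspectable.
#'
#' @return Named list of conversion constants.
#' @export
hydro_units <- function() .hydro_units

#' Convert sap flux density from cm per hour to a mass flux
#'
#' Sap flux density expressed volumetrically (cm3 cm-2 h-1, i.e. cm h-1)
#' converted to the equivalent mass flux of liquid water (kg m-2 s-1), using
#' water density at 20 degrees C.
#'
#' @param js_cm_h Sap flux density in cm h-1.
#' @return Mass flux in kg m-2 s-1.
#' @export
js_cmh_to_kg_m2_s <- function(js_cm_h) {
  js_cm_h * .hydro_units$m_per_cm / .hydro_units$s_per_h * .hydro_units$rho_water
}

#' Molar volume of air
#'
#' Ideal-gas molar volume at a given temperature and pressure,
#' \eqn{v = RT/P} (m3 mol-1).
#'
#' @param tair_c Air temperature, degrees C.
#' @param pressure_kpa Atmospheric pressure, kPa.
#' @return Molar volume in m3 mol-1.
#' @export
molar_volume_air <- function(tair_c = 20, pressure_kpa = 101.3) {
  .hydro_units$r_gas * (tair_c + 273.15) / (pressure_kpa * 1000)
}
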