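#' Map Hounsfield units to acoustic properties
#'
#' Converts a skull slice to co-registered density, sound-speed, and
#' attenuation grids. Density follows the standard CT piecewise-linear
#' calibration: air (-1000 HU) maps to 1.293 kg/m^3, water (0 HU) to the
#' water density, and a linear bone segment reaches `bone_density` at
#' `bone_hu`. The result is clipped below at 997 kg/m^3 so everything
#' outside the skull behaves as water. Sound speed is the linear map
#' c = 1.33 rho + 166.67 (m/s); attenuation is a constant
#' 13.3 dB/(MHz cm) on the skull mask and 0 elsewhere.
#'
#' @param slice A [skull_slice()].
#' @param density_floor Lower density clip, kg/m^3.
#' @param air_density Density at -1000 HU.
#' @param water_density Density at 0 HU (pre-clip).
#' @param bone_hu,bone_density Upper anchor of the bone segment.
#' @param speed_slope,speed_intercept Coefficients of the density-to-speed
#'   map, m/s per (kg/m^3) and m/s.
#' @param attenuation_db_mhz_cm Attenuation applied on the skull mask.
#' @return Object of class `acoustic_medium` with `density`, `speed`,
#'   `attenuation_coeff`, `pixel_spacing_mm`, `skull_mask`.
#' @export
map_hu_to_medium <- function(slice,
                             density_floor = 997,
                             air_density = 1.293,
                             water_density = 997,
                             bone_hu = 1600,
                             bone_density = 2000,
                             speed_slope = 1.33,
                             speed_intercept = 166.67,
                             attenuation_db_mhz_cm = 13.3) {
  if (!inherits(slice, "skull_slice")) stop("`slice` must be a skull_slice")
  hu <- slice$hu_grid
  if (any(!is.finite(hu))) stop("non-finite HU", call. = FALSE)
  rho <- ifelse(hu <= 0,
                water_density + hu * (water_density - air_density) / 1000,
                water_density + hu * (bone_density - water_density) / bone_hu)
  rho <- pmax(rho, density_floor)
  structure(list(
    density = rho,
    speed = speed_slope * rho + speed_intercept,
    attenuation_coeff = attenuation_db_mhz_cm * slice$skull_mask,
    pixel_spacing_mm = slice$pixel_spacing_mm,
    skull_mask = slice$skull_mask
  ), class = "acoustic_medium")
}

#' Homogeneous water medium
#'
#' Convenience constructor for an all-water scene of the given size.
#'
#' @param n Grid size (square), pixels.
#' @param pixel_spacing_mm Pixel spacing, mm.
#' @return An `acoustic_medium`.
#' @export
water_medium <- function(n, pixel_spacing_mm) {
  map_hu_to_medium(skull_slice(matrix(0, n, n), pixel_spacing_mm))
}
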