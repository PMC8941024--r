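## Solar geometry and extraterrestrial irradiance.
## All angles are handled in degrees at the interface; conversion to radians
## happens only inside the trigonometric calls.

.deg2rad <- function(x) x * pi / 180

#' Solar constant used for extraterrestrial irradiance
#'
#' Mean top-of-atmosphere solar irradiance at one astronomical unit, in W/m2.
#' @export
SOLAR_CONSTANT <- 1361

#' Angular fraction of the year
#'
#' Maps a day of the year onto its angular position along Earth's orbit,
#' `F = 360 * D / 365` degrees. This angle drives both the solar declination
#' and the Earth-Sun distance ratio.
#'
#' @param day_of_year integer day of the year, 1 to 365.
#' @return Angle in degrees (0, 360].
#' @examples
#' angular_fraction(365) # 360
#' @export
angular_fraction <- function(day_of_year) {
  if (!is.numeric(day_of_year) || anyNA(day_of_year)) {
    stop("`day_of_year` must be numeric with no missing values")
  }
  if (any(day_of_year < 1 | day_of_year > 365)) {
    stop("`day_of_year` must lie in [1, 365]")
  }
  360 * day_of_year / 365
}

#' Solar declination
#'
#' Angle between the sun's rays and the Earth's equatorial plane, evaluated
#' from a truncated Fourier series in the angular fraction of the year.
#' Varies between roughly -23.1 deg (southern summer solstice) and +23.1 deg.
#'
#' @param F angular fraction of the year in degrees (periodic; any real value).
#' @return Declination in degrees.
#' @export
solar_declination <- function(F) {
  f <- .deg2rad(F)
  0.3964 +
    3.631 * sin(f) - 22.97 * cos(f) +
    0.03838 * sin(2 * f) - 0.3885 * cos(2 * f) +
    0.07659 * sin(3 * f) - 0.1587 * cos(3 * f) -
    0.01021 * cos(4 * f)
}

#' Hour angle of the sun
#'
#' Angular displacement of the sun from local solar noon: `(12 - Hd) * 15`
#' degrees, 15 degrees per hour, positive in the morning. `Hd` is the decimal
#' clock hour of the moment of interest (no equation-of-time or longitude
#' correction is applied).
#'
#' @param decimal_hour hour of day with decimal fraction, in [0, 24).
#' @return Hour angle in degrees.
#' @export
hour_angle <- function(decimal_hour) {
  if (any(decimal_hour < 0 | decimal_hour >= 24)) {
    stop("`decimal_hour` must lie in [0, 24)")
  }
  (12 - decimal_hour) * 15
}

#' Earth-Sun distance ratio
#'
#' Dimensionless ratio of the mean to the instantaneous Earth-Sun distance,
#' evaluated from a truncated Fourier series in the angular fraction of the
#' year. Stays within (0.96, 1.04) for all dates.
#'
#' Note the `2F` term: the series alternates sine and cosine harmonics, and
#' the second harmonic is taken as `sin(2F)` to preserve that alternation.
#'
#' @param F angular fraction of the year in degrees (periodic; any real value).
#' @return Dimensionless distance ratio.
#' @export
earth_sun_distance_ratio <- function(F) {
  f <- .deg2rad(F)
  1 -
    0.0009467 * sin(f) -
    0.01671 * cos(f) -
    0.0001489 * sin(2 * f) -
    0.00002917 * sin(3 * f) -
    0.0003438 * cos(4 * f)
}

#' Cosine of the solar zenith angle
#'
#' Standard spherical-astronomy identity
#' `cos Z = sin(delta) sin(phi) + cos(delta) cos(phi) cos(omega)`.
#' Negative values mean the sun is below the horizon.
#'
#' @param delta solar declination, degrees.
#' @param phi signed geographic latitude, degrees (southern hemisphere
#'   negative, e.g. -22.85 for a site at 22.85 deg S).
#' @param omega hour angle, degrees.
#' @return cos of the zenith angle, in [-1, 1].
#' @export
cos_zenith <- function(delta, phi, omega) {
  d <- .deg2rad(delta)
  p <- .deg2rad(phi)
  w <- .deg2rad(omega)
  sin(d) * sin(p) + cos(d) * cos(p) * cos(w)
}

#' Extraterrestrial irradiance
#'
#' Solar irradiance on a horizontal surface at the top of the atmosphere,
#' `I_E = 1361 * (1/R) * cos Z` W/m2. When the sun is below the horizon
#' (`cos Z < 0`) the value is floored at 0 rather than going negative, so the
#' result can serve directly as a physical upper bound for ground
#' measurements.
#'
#' @param R Earth-Sun distance ratio (dimensionless, > 0).
#' @param cos_z cosine of the solar zenith angle.
#' @return Irradiance in W/m2, >= 0.
#' @examples
#' extraterrestrial_irradiance(1, 1) # the solar constant, 1361
#' @export
extraterrestrial_irradiance <- function(R, cos_z) {
  if (any(R <= 0)) stop("`R` must be strictly positive")
  pmax(0, SOLAR_CONSTANT * (1 / R) * cos_z)
}

#' Extraterrestrial irradiance at a site and instant
#'
#' Convenience wrapper chaining the angular fraction, declination, hour angle,
#' distance ratio and zenith cosine for a given latitude, day of year and
#' decimal clock hour. Vectorised over `day_of_year` and `decimal_hour`.
#'
#' @param day_of_year integer day of the year, 1 to 365.
#' @param decimal_hour decimal clock hour in [0, 24).
#' @param latitude signed latitude in degrees (default -22.85, the study
#'   site's southern-hemisphere latitude).
#' @return Irradiance in W/m2, >= 0 (0 at night).
#' @export
solar_toa_irradiance <- function(day_of_year, decimal_hour, latitude = -22.85) {
  F <- angular_fraction(day_of_year)
  cz <- cos_zenith(solar_declination(F), latitude, hour_angle(decimal_hour))
  extraterrestrial_irradiance(earth_sun_distance_ratio(F), cz)
}
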