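## Solar position (NOAA low-accuracy formulas). Sufficient for diel-phase
## classification at mid latitudes: agreement with reference almanacs is
## within ~1-2 minutes.

## fractional-year angle (radians) at a given UTC datetime
.solarGamma <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  2 * pi / 365 * (lt$yday + (lt$hour - 12) / 24)
}

## equation of time (minutes) and solar declination (radians)
.solarEqDecl <- function(gamma) {
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma)
                      - 0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- (0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma)
           - 0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma)
           - 0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma))
  list(eqtime = eqtime, decl = decl)
}

#' Sunrise and sunset times (UTC)
#'
#' NOAA solar-position formulas with the standard refraction-corrected
#' zenith of 90.833 degrees. Valid for |lat| < 66 degrees; polar latitudes
#' (where the day/night cycle can vanish) are rejected.
#'
#' @param date Date (interpreted in UTC)
#' @param lon,lat position, decimal degrees (lon positive east)
#' @return list with POSIXct `sunrise` and `sunset` (UTC)
#' @export
sunriseSunset <- function(date, lon, lat) {
  if (abs(lat) >= 66) stop("polar latitudes not supported (|lat| must be < 66)")
  noon0 <- as.POSIXct(paste(as.Date(date), "12:00:00"), tz = "UTC")
  sd <- .solarEqDecl(.solarGamma(noon0))
  zen <- 90.833 * pi / 180
  latr <- lat * pi / 180
  cosha <- cos(zen) / (cos(latr) * cos(sd$decl)) - tan(latr) * tan(sd$decl)
  cosha <- pmin(1, pmax(-1, cosha))
  ha <- acos(cosha) * 180 / pi
  sunrise_min <- 720 - 4 * (lon + ha) - sd$eqtime
  sunset_min <- 720 - 4 * (lon - ha) - sd$eqtime
  day0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  list(sunrise = day0 + sunrise_min * 60, sunset = day0 + sunset_min * 60)
}

#' Diel phase of a timestamp
#'
#' Classifies a UTC timestamp as `"day"` iff sunrise <= t < sunset at the
#' given position (sunrise/sunset from [sunriseSunset()]), else `"night"`.
#'
#' @param timestamp POSIXct (UTC), vectorised
#' @param lon,lat position, decimal degrees
#' @return character vector of `"day"` / `"night"`
#' @export
dielPhase <- function(timestamp, lon, lat) {
  vapply(seq_along(timestamp), function(i) {
    ss <- sunriseSunset(as.Date(timestamp[i], tz = "UTC"), lon, lat)
    if (timestamp[i] >= ss$sunrise && timestamp[i] < ss$sunset) "day" else "night"
  }, character(1))
}

#' Reproductive season of a date
#'
#' `"spawning"` for dates whose month falls in the configured spawning
#' season (default March-August), `"resting"` otherwise.
#'
#' @param date Date, vectorised
#' @param spawning_months integer months of the spawning season
#' @return character vector of `"spawning"` / `"resting"`
#' @export
seasonLabel <- function(date, spawning_months = 3:8) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m %in% spawning_months, "spawning", "resting")
}
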