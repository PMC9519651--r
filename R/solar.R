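#' Solar events for a calendar day
#'
#' Sunrise, sunset, nautical dawn and nautical dusk from standard solar
#' geometry (NOAA solar-calculation formulas): the equation of time and solar
#' declination are evaluated from a Fourier expansion in the fractional year,
#' and event times follow from the hour angle at the event's solar zenith.
#' Sunrise/sunset use zenith 90.833 deg (elevation -0.833 deg, accounting for
#' refraction and the solar disc); nautical events use zenith 102 deg
#' (elevation -12 deg).
#'
#' At high latitudes an event may not exist (midnight sun / polar night);
#' such events are returned as `NA`.
#'
#' @param date a `Date` (or coercible).
#' @param lat,lon geographic coordinates in degrees (lon positive east).
#' @return list with `date` and POSIXct (UTC) `nautical_dawn`, `sunrise`,
#'   `sunset`, `nautical_dusk`.
#' @export
solar_events <- function(date, lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon) || abs(lat) > 90 || abs(lon) > 180) {
    stop("invalid latitude/longitude")
  }
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  # fractional year (radians) at local solar noon
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lat_r <- lat * pi / 180
  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  ha_deg <- function(zenith_deg) {
    z <- zenith_deg * pi / 180
    cos_ha <- cos(z) / (cos(lat_r) * cos(decl)) - tan(lat_r) * tan(decl)
    ifelse(abs(cos_ha) > 1, NA_real_, acos(cos_ha) * 180 / pi)
  }
  ev <- function(ha, rising) {
    minutes <- 720 - 4 * (lon + ifelse(rising, ha, -ha)) - eqtime
    midnight + minutes * 60
  }
  ha_sun <- ha_deg(90.833)
  ha_naut <- ha_deg(102)
  list(
    date = date,
    nautical_dawn = ev(ha_naut, TRUE),
    sunrise = ev(ha_sun, TRUE),
    sunset = ev(ha_sun, FALSE),
    nautical_dusk = ev(ha_naut, FALSE)
  )
}

#' Classify timestamps into day, night and twilight
#'
#' Day is `[sunrise, sunset)`; twilight is `[nautical_dawn, sunrise)` union
#' `[sunset, nautical_dusk)`; night is the remainder. The three classes
#' partition the 24 h of every mid-latitude day; ties at an exact event
#' instant fall into the later class.
#'
#' @param timestamps POSIXct vector (UTC).
#' @param lat,lon reference coordinates in degrees.
#' @return factor with levels day, night, twilight.
#' @export
classify_time_of_day <- function(timestamps, lat, lon) {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  dates <- as.Date(timestamps, tz = "UTC")
  out <- rep(NA_character_, length(timestamps))
  for (d in unique(dates)) {
    idx <- which(dates == d)
    ev <- solar_events(as.Date(d, origin = "1970-01-01"), lat, lon)
    t <- timestamps[idx]
    cls <- rep("night", length(t))
    if (!is.na(ev$sunrise) && !is.na(ev$sunset)) {
      cls[t >= ev$sunrise & t < ev$sunset] <- "day"
      if (!is.na(ev$nautical_dawn)) {
        cls[t >= ev$nautical_dawn & t < ev$sunrise] <- "twilight"
      }
      if (!is.na(ev$nautical_dusk)) {
        cls[t >= ev$sunset & t < ev$nautical_dusk] <- "twilight"
      }
    } else if (!is.na(ev$nautical_dawn)) {
      # sun never reaches -0.833 deg but crosses -12 deg: all twilight between
      cls[t >= ev$nautical_dawn & t < ev$nautical_dusk] <- "twilight"
    }
    out[idx] <- cls
  }
  factor(out, levels = .tod_levels)
}
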