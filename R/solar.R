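#' Sunrise and sunset times for a date and location
#'
#' Computes apparent sunrise and sunset (solar zenith 90.833 degrees, i.e.
#' standard refraction plus the solar semi-diameter) with the NOAA solar
#' position algorithm (Meeus low-precision series). Events are returned as
#' UTC timestamps falling on the requested UTC calendar date; agreement with
#' published almanacs is within about one minute at mid-latitudes.
#'
#' @param date `Date` vector (or coercible).
#' @param lat,lon Location in decimal degrees (recycled against `date`).
#' @return `data.frame` with columns `date`, `sunrise_utc`, `sunset_utc`
#'   (POSIXct, UTC).
#' @examples
#' sun_events(as.Date("2018-03-20"), 54.1821, 7.8925)
#' @export
sun_events <- function(date, lat, lon) {
  date <- as.Date(date)
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(date, n)
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)
  check_coords(lat, lon)
  # polar day/night errors out via the hour-angle test below.
  # Events of neighbouring *local* days can fall on the requested *UTC*
  # date at extreme longitudes, so compute candidates for local days
  # d-1, d, d+1 and keep the one inside the requested UTC date.
  day0 <- as.numeric(as.POSIXct(as.character(date), tz = "UTC"))
  pick <- function(event) {
    cand <- vapply(c(-1, 0, 1), function(off) {
      solar_event_abs(unclass(date) + off, lat, lon, event)
    }, numeric(length(date)))
    cand <- matrix(cand, nrow = length(date))
    out <- rep(NA_real_, length(date))
    for (i in seq_along(date)) {
      hit <- cand[i, cand[i, ] >= day0[i] & cand[i, ] < day0[i] + 86400]
      out[i] <- if (length(hit)) hit[1] else NA_real_
    }
    if (anyNA(out)) stop("no sunrise/sunset on requested UTC date")
    out
  }
  data.frame(
    date = date,
    sunrise_utc = as.POSIXct(pick("sunrise"), origin = "1970-01-01", tz = "UTC"),
    sunset_utc = as.POSIXct(pick("sunset"), origin = "1970-01-01", tz = "UTC")
  )
}

# absolute POSIX time (seconds) of the event belonging to local day `dnum`
# (days since epoch); two-pass: evaluate solar quantities at approximate
# local noon, then refine at the first-pass event time
solar_event_abs <- function(dnum, lat, lon, event) {
  sgn <- if (event == "sunrise") -1 else 1
  noon_guess <- 12 - lon / 15
  sq <- noaa_solar(dnum + 2440587.5 + noon_guess / 24)
  m <- (720 - 4 * lon - sq$eqtime) + sgn * 4 * hour_angle_deg(lat, sq$decl)
  sq2 <- noaa_solar(dnum + 2440587.5 + m / 1440)
  m <- (720 - 4 * lon - sq2$eqtime) + sgn * 4 * hour_angle_deg(lat, sq2$decl)
  dnum * 86400 + m * 60
}

# cosine of zenith-crossing hour angle; errors on polar day/night
hour_angle_deg <- function(lat, decl) {
  phi <- lat * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(phi) * cos(decl)) - tan(phi) * tan(decl)
  if (any(cos_ha < -1 | cos_ha > 1)) {
    stop("no sunrise/sunset at this latitude and date (polar day or night)")
  }
  acos(cos_ha) * 180 / pi
}

# NOAA solar declination (rad) and equation of time (min) at a Julian day
noaa_solar <- function(jd) {
  jc <- (jd - 2451545) / 36525
  deg2rad <- pi / 180
  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(m * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * m * deg2rad) * 0.000289
  true_long <- l0 + ctr
  app_long <- true_long - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * deg2rad)
  obl0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obl <- obl0 + 0.00256 * cos((125.04 - 1934.136 * jc) * deg2rad)
  decl <- asin(sin(obl * deg2rad) * sin(app_long * deg2rad))
  y <- tan(obl * deg2rad / 2)^2
  eqtime <- 4 / deg2rad * (
    y * sin(2 * l0 * deg2rad) - 2 * ecc * sin(m * deg2rad) +
      4 * ecc * y * sin(m * deg2rad) * cos(2 * l0 * deg2rad) -
      0.5 * y^2 * sin(4 * l0 * deg2rad) - 1.25 * ecc^2 * sin(2 * m * deg2rad)
  )
  list(decl = decl, eqtime = eqtime)
}

#' Night-fraction time axis
#'
#' Rescales a timestamp onto a per-night axis on which 0 is the most recent
#' sunset and 1 the following sunrise, linear in between, so that flight
#' start times are comparable across dates and night lengths. Daytime
#' timestamps are extended continuously on the same axis: times after
#' sunrise map above 1 (scaled by the length of the night just ended) and
#' times approaching the coming sunset map below 0 (scaled by the coming
#' night's length); a daytime instant is attached to whichever night
#' boundary (previous sunrise or next sunset) is closer.
#'
#' @param t POSIXct timestamp(s), UTC.
#' @param lat,lon Location in decimal degrees.
#' @return Numeric vector of night fractions.
#' @export
night_fraction <- function(t, lat, lon) {
  stopifnot(inherits(t, "POSIXct"))
  vapply(as.numeric(t), function(tt) {
    d <- as.Date(as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"))
    ev <- sun_events(seq(d - 2, d + 2, by = 1), lat, lon)
    ss <- sort(as.numeric(ev$sunset_utc))
    sr <- sort(as.numeric(ev$sunrise_utc))
    # pair each sunset with the first following sunrise -> nights
    nights <- lapply(ss, function(s) {
      nxt <- sr[sr > s]
      if (!length(nxt)) return(NULL)
      c(s, nxt[1])
    })
    nights <- do.call(rbind, nights[!vapply(nights, is.null, TRUE)])
    inside <- which(nights[, 1] <= tt & tt <= nights[, 2])
    if (length(inside)) {
      nb <- nights[inside[1], ]
      return((tt - nb[1]) / (nb[2] - nb[1]))
    }
    prev <- nights[nights[, 2] < tt, , drop = FALSE]
    nxt <- nights[nights[, 1] > tt, , drop = FALSE]
    if (!nrow(prev) || !nrow(nxt)) stop("timestamp outside resolvable nights")
    pn <- prev[nrow(prev), ]
    nn <- nxt[1, ]
    if (tt - pn[2] <= nn[1] - tt) {
      (tt - pn[1]) / (pn[2] - pn[1]) # morning: > 1 on the ended night's scale
    } else {
      (tt - nn[1]) / (nn[2] - nn[1]) # evening: < 0 on the coming night's scale
    }
  }, numeric(1))
}
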