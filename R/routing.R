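#' Classify a heading as progress or detour
#'
#' A heading is a progress track when it falls inside the season's
#' migratory sector: 315 through north to 90 degrees in spring, 135 to 270
#' degrees in autumn (boundaries inclusive). All other headings, including
#' reverse migration, are detour tracks.
#'
#' @param bearing_deg Bearing(s) in degrees, `[0, 360)`.
#' @param season `"spring"` or `"autumn"`.
#' @param cfg A [routing_config()].
#' @return Character vector, `"progress"` or `"detour"`.
#' @export
classify_heading <- function(bearing_deg, season, cfg = routing_config()) {
  stopifnot(all(bearing_deg >= 0 & bearing_deg < 360))
  season <- match.arg(season, c("spring", "autumn"))
  sector <- if (season == "spring") cfg$progress_sector_spring else cfg$progress_sector_autumn
  inside <- if (sector[1] <= sector[2]) {
    bearing_deg >= sector[1] & bearing_deg <= sector[2]
  } else { # sector wraps through north
    bearing_deg >= sector[1] | bearing_deg <= sector[2]
  }
  ifelse(inside, "progress", "detour")
}

#' Cumulative progress and detour track lengths
#'
#' Accumulates the great-circle length of every non-simultaneous
#' inter-receiver transition into a progress or detour total according to
#' the heading of the transition and the season's migratory sector.
#'
#' @param transitions Output of [track_transitions()].
#' @param season `"spring"` or `"autumn"`.
#' @param cfg A [routing_config()].
#' @return One-row `data.frame`: `progress_km`, `detour_km`, `took_detour`.
#' @export
route_lengths <- function(transitions, season, cfg = routing_config()) {
  tr <- transitions[!transitions$simultaneous, , drop = FALSE]
  if (!nrow(tr)) {
    return(data.frame(progress_km = 0, detour_km = 0, took_detour = FALSE))
  }
  cls <- classify_heading(tr$bearing_deg, season, cfg)
  progress <- sum(tr$distance_km[cls == "progress"])
  detour <- sum(tr$distance_km[cls == "detour"])
  data.frame(progress_km = progress, detour_km = detour, took_detour = detour > 0)
}

#' Extract sustained flights
#'
#' Splits a track at detection gaps of `sustained_gap_max_h` hours or more;
#' each remaining window of continuous recordings qualifies as a sustained
#' flight when it involves (a) at least `sustained_min_receivers` distinct
#' receivers that are pairwise more than `sustained_receiver_spacing_km`
#' apart (a maximal mutually-spaced subset is selected greedily in order of
#' first detection), or (b) two receivers at least
#' `sustained_pair_distance_km` apart.
#'
#' The flight's start time is the departure from its first receiver (the
#' last detection of the window's initial single-receiver run), the
#' quantity summarised on the night-fraction axis.
#'
#' @param track A `coasttrack_track` (full track).
#' @param receivers Receiver registry.
#' @param cfg A [routing_config()].
#' @return List of `coasttrack_sustained_flight` objects (possibly empty),
#'   in time order; each has `tag_id`, `detections`, `receiver_ids`,
#'   `start_t`, `start_receiver`, `max_pair_km`.
#' @export
extract_sustained_flights <- function(track, receivers, cfg = routing_config()) {
  det <- track$detections
  if (nrow(det) < 2) return(list())
  gap <- c(0, diff(as.numeric(det$t)))
  win_id <- cumsum(gap >= cfg$sustained_gap_max_h * 3600)
  out <- list()
  for (w in split(seq_len(nrow(det)), win_id)) {
    d <- det[w, , drop = FALSE]
    if (nrow(d) < 2) next
    recs <- unique(d$receiver_id)
    if (length(recs) < 2) next
    loc <- receiver_loc(receivers, recs)
    dm <- outer(seq_along(recs), seq_along(recs), function(i, j) {
      gc_distance(loc$lat[i], loc$lon[i], loc$lat[j], loc$lon[j])
    })
    max_pair <- max(dm)
    # greedy maximal subset of mutually spaced receivers, in detection order
    kept <- integer()
    for (i in seq_along(recs)) {
      if (all(dm[i, kept] > cfg$sustained_receiver_spacing_km)) kept <- c(kept, i)
    }
    qualifies <- length(kept) >= cfg$sustained_min_receivers ||
      max_pair >= cfg$sustained_pair_distance_km
    if (!qualifies) next
    first_rec <- d$receiver_id[1]
    leave <- which(d$receiver_id != first_rec)[1]
    start_t <- d$t[leave - 1L]
    out[[length(out) + 1L]] <- structure(list(
      tag_id = track$tag_id, detections = d, receiver_ids = recs,
      start_t = start_t, start_receiver = first_rec, max_pair_km = max_pair
    ), class = "coasttrack_sustained_flight")
  }
  out
}

#' First sustained flight of an individual
#'
#' Earliest sustained flight by start time; `NULL` when none, so each
#' individual contributes at most one flight to routing comparisons.
#'
#' @param flights List from [extract_sustained_flights()].
#' @return A `coasttrack_sustained_flight` or `NULL`.
#' @export
first_sustained_flight <- function(flights) {
  if (!length(flights)) return(NULL)
  flights[[which.min(vapply(flights, function(f) as.numeric(f$start_t), numeric(1)))]]
}

#' Classify a sustained flight as offshore or alongshore
#'
#' A flight is offshore when it includes a recording at an island receiver,
#' or when it crosses the split latitude over open water: in autumn
#' (southbound) the last recording receiver above the split latitude must
#' lie above `offshore_lat_min` and the first recording receiver below the
#' split must lie west of `offshore_lon_threshold`; in spring (northbound)
#' the temporal roles mirror, i.e. the *first* receiver above the split
#' takes the latitude test and the *last* receiver below it the longitude
#' test. Flights never crossing the split latitude and touching no island
#' receiver are alongshore.
#'
#' @param flight A `coasttrack_sustained_flight`.
#' @param season `"spring"` or `"autumn"`.
#' @param receivers Receiver registry.
#' @param cfg A [routing_config()].
#' @return `"offshore"` or `"alongshore"`.
#' @export
classify_offshore <- function(flight, season, receivers, cfg = routing_config()) {
  season <- match.arg(season, c("spring", "autumn"))
  d <- flight$detections
  loc <- receiver_loc(receivers, d$receiver_id)
  if (any(loc$is_island_site)) return("offshore")
  above <- which(loc$lat > cfg$lat_split)
  below <- which(loc$lat < cfg$lat_split)
  if (!length(above) || !length(below)) return("alongshore")
  if (season == "autumn") {
    lat_ref <- loc$lat[above[length(above)]] # last receiver above the split
    lon_ref <- loc$lon[below[1]]             # first receiver below the split
  } else {
    lat_ref <- loc$lat[above[1]]             # first receiver above the split
    lon_ref <- loc$lon[below[length(below)]] # last receiver below the split
  }
  if (lat_ref > cfg$offshore_lat_min && lon_ref < cfg$offshore_lon_threshold) {
    "offshore"
  } else {
    "alongshore"
  }
}
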