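#' Initial stopover at the deployment site
#'
#' Identifies the first receiver that detected the bird, provided it lies
#' within `initial_radius_km` of the release site; that receiver plus all
#' registry receivers within `cluster_radius_km` of it form the deployment
#' cluster. The initial stopover lasts from release until the first
#' detection at any receiver outside the cluster. Birds never detected
#' outside the cluster get the time from release to their last detection,
#' flagged as a minimum estimate. If the first detection is farther than
#' `initial_radius_km` from the release site no initial stopover is
#' recorded (`duration_days` is `NA`).
#'
#' @param track A `coasttrack_track`.
#' @param receivers Receiver registry.
#' @param cfg A [segmentation_config()].
#' @return List with `duration_days`, `minimum_estimate`, `cluster`
#'   (receiver ids), and `last_initial_idx` (index of the last detection
#'   belonging to the initial stopover; 0 when absent), `end_t`.
#' @export
initial_stopover <- function(track, receivers, cfg = segmentation_config()) {
  det <- track$detections
  dep <- track$deployment
  if (nrow(det) == 0) {
    return(list(duration_days = NA_real_, minimum_estimate = FALSE,
                cluster = character(), last_initial_idx = 0L, end_t = NULL))
  }
  first_rec <- receiver_loc(receivers, det$receiver_id[1])
  if (gc_distance(dep$lat, dep$lon, first_rec$lat, first_rec$lon) > cfg$initial_radius_km) {
    return(list(duration_days = NA_real_, minimum_estimate = FALSE,
                cluster = character(), last_initial_idx = 0L, end_t = NULL))
  }
  d_to_first <- gc_distance(receivers$lat, receivers$lon, first_rec$lat, first_rec$lon)
  cluster <- receivers$receiver_id[d_to_first <= cfg$cluster_radius_km]
  outside <- which(!(det$receiver_id %in% cluster))
  if (length(outside)) {
    idx <- outside[1]
    list(duration_days = as.numeric(det$t[idx] - dep$release_t, units = "days"),
         minimum_estimate = FALSE, cluster = cluster,
         last_initial_idx = idx - 1L, end_t = det$t[idx])
  } else {
    list(duration_days = as.numeric(det$t[nrow(det)] - dep$release_t, units = "days"),
         minimum_estimate = TRUE, cluster = cluster,
         last_initial_idx = nrow(det), end_t = det$t[nrow(det)])
  }
}

#' Behavioural segmentation of a track
#'
#' Classifies the detections of a track (after excision of the initial
#' stopover window, see [initial_stopover()]) into `along_track_stopover`,
#' `flight` and `unknown`:
#'
#' * a single-receiver dwell of more than `stop_dwell_min_h` hours is
#'   along-track stopover; a dwell of less than `short_visit_max_min`
#'   minutes is flight (a bird passing through); dwells between the two
#'   thresholds are not covered by either rule and fall to unknown;
#' * a movement between receivers at 5-26 m/s over ground, or a
#'   simultaneous detection (implied speed above 26 m/s), is flight;
#' * a slow movement (below 5 m/s) whose next detection comes within
#'   `stop_gap_max_days` days and `stop_dist_max_km` km is along-track
#'   stopover; remaining slow movements are unknown (discontinuous
#'   recordings with gaps in space and/or time).
#'
#' Adjacent pieces with equal labels merge, so a stopover composed of a
#' dwell, a slow local move and another dwell is one segment. Every
#' detection belongs to exactly one segment (its dwell run); movement
#' pieces only extend segment time spans.
#'
#' @param track A `coasttrack_track` whose `detections` are the
#'   post-initial-stopover detections.
#' @param receivers Receiver registry.
#' @param cfg A [segmentation_config()].
#' @return `data.frame` of segments (`tag_id`, `label`, `t_start`, `t_end`,
#'   `receiver_ids`, `n_detections`), with attributes `detection_labels`
#'   (label of every input detection) and `pieces` (the unmerged dwell and
#'   movement pieces, used by [daily_mean_speed()]).
#' @export
classify_segments <- function(track, receivers, cfg = segmentation_config()) {
  det <- track$detections
  empty <- data.frame(tag_id = character(), label = character(),
                      t_start = as.POSIXct(character(), tz = "UTC"),
                      t_end = as.POSIXct(character(), tz = "UTC"),
                      receiver_ids = character(), n_detections = integer())
  if (nrow(det) == 0) {
    attr(empty, "detection_labels") <- character()
    attr(empty, "pieces") <- data.frame()
    return(empty)
  }
  change <- c(TRUE, det$receiver_id[-1] != det$receiver_id[-nrow(det)])
  run_id <- cumsum(change)
  n_runs <- max(run_id)
  i_first <- match(seq_len(n_runs), run_id)
  i_last <- nrow(det) + 1 - match(seq_len(n_runs), rev(run_id))
  run_receiver <- det$receiver_id[i_first]
  run_t0 <- det$t[i_first]
  run_t1 <- det$t[i_last]
  dwell_s <- as.numeric(run_t1) - as.numeric(run_t0)
  run_label <- ifelse(dwell_s > cfg$stop_dwell_min_h * 3600, "along_track_stopover",
               ifelse(dwell_s < cfg$short_visit_max_min * 60, "flight", "unknown"))

  pieces <- data.frame(
    kind = "dwell", label = run_label,
    t_start = run_t0, t_end = run_t1,
    receivers = run_receiver, distance_km = 0,
    duration_s = dwell_s, ground_speed_ms = NA_real_,
    simultaneous = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_runs >= 2) {
    from <- run_receiver[-n_runs]
    to <- run_receiver[-1]
    t0 <- run_t1[-n_runs]
    t1 <- run_t0[-1]
    loc_f <- receiver_loc(receivers, from)
    loc_t <- receiver_loc(receivers, to)
    dist <- gc_distance(loc_f$lat, loc_f$lon, loc_t$lat, loc_t$lon)
    dt <- as.numeric(t1) - as.numeric(t0)
    speed <- ifelse(dt > 0, dist * 1000 / dt, Inf)
    mv_label <- classify_movement(speed, dt, dist, cfg)
    mv <- data.frame(kind = "move", label = mv_label,
                     t_start = t0, t_end = t1,
                     receivers = paste(from, to, sep = ";"),
                     distance_km = dist, duration_s = dt,
                     ground_speed_ms = speed,
                     simultaneous = speed > cfg$flight_speed_max_ms,
                     stringsAsFactors = FALSE)
    # interleave dwell and movement pieces in time order
    ord <- order(c(seq_len(n_runs) * 2 - 1, seq_len(n_runs - 1) * 2))
    pieces <- rbind(pieces, mv)[ord, , drop = FALSE]
    rownames(pieces) <- NULL
  }

  grp <- cumsum(c(TRUE, pieces$label[-1] != pieces$label[-nrow(pieces)]))
  segs <- do.call(rbind, lapply(split(seq_len(nrow(pieces)), grp), function(ix) {
    p <- pieces[ix, , drop = FALSE]
    recs <- unique(unlist(strsplit(p$receivers, ";", fixed = TRUE)))
    data.frame(tag_id = track$tag_id, label = p$label[1],
               t_start = p$t_start[1], t_end = p$t_end[nrow(p)],
               receiver_ids = paste(recs, collapse = ";"),
               n_detections = sum(p$kind == "dwell") * NA_integer_,
               stringsAsFactors = FALSE)
  }))
  # count detections per segment from run membership
  seg_of_piece <- grp
  run_piece_idx <- which(pieces$kind == "dwell")
  run_seg <- seg_of_piece[run_piece_idx]
  det_seg <- run_seg[run_id]
  segs$n_detections <- as.integer(tabulate(det_seg, nbins = nrow(segs)))
  rownames(segs) <- NULL
  attr(segs, "detection_labels") <- run_label[run_id]
  attr(segs, "pieces") <- pieces
  segs
}

# movement-piece label from ground speed, time gap and distance
classify_movement <- function(speed, dt, dist, cfg) {
  ifelse(speed >= cfg$flight_speed_min_ms, "flight",
  ifelse(dt <= cfg$stop_gap_max_days * 86400 & dist < cfg$stop_dist_max_km,
         "along_track_stopover", "unknown"))
}

#' Total along-track stopover duration
#'
#' Sum of all along-track stopover segment durations of one individual, in
#' days; `NA` when the track has no such segment.
#'
#' @param segments Output of [classify_segments()].
#' @return Duration in days or `NA`.
#' @export
along_track_stopover_days <- function(segments) {
  s <- segments[segments$label == "along_track_stopover", , drop = FALSE]
  if (!nrow(s)) return(NA_real_)
  sum(as.numeric(s$t_end) - as.numeric(s$t_start)) / 86400
}

#' Days spent in the study area
#'
#' Whole-day calendar difference between the date of tag deployment and the
#' date of the last recording.
#'
#' @param track A `coasttrack_track` (full, unexcised).
#' @return Integer number of days.
#' @export
days_at_study_area <- function(track) {
  if (nrow(track$detections) == 0) return(NA_integer_)
  as.integer(as.Date(max(track$detections$t)) - as.Date(track$deployment$release_t))
}

#' Daily mean movement speed
#'
#' Total great-circle distance over movement pieces labelled flight or
#' along-track stopover (slow stopover movements), divided by the summed
#' duration of those recordings in whole days (ceiling, minimum one day).
#' Simultaneous detections (implied speed above the flight band) are
#' detection artefacts, not movement, and are excluded from the distance
#' sum. `NA` when the track has no qualifying movement.
#'
#' @param segments Output of [classify_segments()].
#' @return Speed in km/day or `NA`.
#' @export
daily_mean_speed <- function(segments) {
  p <- attr(segments, "pieces")
  if (is.null(p) || !nrow(p)) return(NA_real_)
  q <- p[p$kind == "move" & !p$simultaneous &
           p$label %in% c("flight", "along_track_stopover"), , drop = FALSE]
  if (!nrow(q)) return(NA_real_)
  days <- max(1, ceiling(sum(q$duration_s) / 86400))
  sum(q$distance_km) / days
}

#' Night-fraction start phase of flight segments
#'
#' Maps the start time of each flight segment onto the night-fraction axis
#' (0 = most recent sunset, 1 = following sunrise) at the location of the
#' segment's first receiver, for comparing diurnal and nocturnal flight
#' scheduling.
#'
#' @param segments Output of [classify_segments()] (or any data.frame with
#'   `label`, `t_start`, `receiver_ids`).
#' @param receivers Receiver registry.
#' @return Numeric vector, one value per flight segment (named by segment
#'   row index).
#' @export
flight_start_phase <- function(segments, receivers) {
  fl <- which(segments$label == "flight")
  out <- vapply(fl, function(i) {
    rec <- strsplit(segments$receiver_ids[i], ";", fixed = TRUE)[[1]][1]
    loc <- receiver_loc(receivers, rec)
    night_fraction(segments$t_start[i], loc$lat, loc$lon)
  }, numeric(1))
  names(out) <- fl
  out
}

#' Excise the initial-stopover window from a track
#'
#' Returns a copy of the track containing only detections after the
#' initial stopover (see [initial_stopover()]); the full track when no
#' initial stopover was recorded.
#'
#' @param track A `coasttrack_track`.
#' @param init Result of [initial_stopover()].
#' @return A `coasttrack_track`.
#' @export
excise_initial <- function(track, init) {
  if (init$last_initial_idx > 0) {
    track$detections <- track$detections[
      seq_len(nrow(track$detections)) > init$last_initial_idx, , drop = FALSE]
    rownames(track$detections) <- NULL
  }
  track
}
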