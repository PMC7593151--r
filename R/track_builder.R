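#' Assemble per-individual tracks
#'
#' Combines all detections of each tagged bird into a time-ordered track
#' bound to its deployment metadata. Detections with identical timestamp at
#' the same receiver are deduplicated (first kept); equal timestamps at
#' different receivers are retained as simultaneous detections. Tags with a
#' deployment but no detection yield no track; a tag with detections but no
#' deployment is an error.
#'
#' @param detections Filtered detection `data.frame` (see
#'   [filter_false_positives()]).
#' @param deployments Deployment `data.frame` from [read_deployments()].
#' @return Named list of `coasttrack_track` objects, each a list with
#'   `tag_id`, `deployment` (one-row data.frame) and `detections`.
#' @export
build_tracks <- function(detections, deployments) {
  orphan <- setdiff(unique(detections$tag_id), deployments$tag_id)
  if (length(orphan)) {
    stop("detections without deployment for tag(s): ", paste(orphan, collapse = ", "))
  }
  split_det <- split(detections, detections$tag_id)
  tracks <- lapply(names(split_det), function(tag) {
    det <- split_det[[tag]]
    det <- det[order(det$t, det$receiver_id), , drop = FALSE]
    dup <- duplicated(det[c("t", "receiver_id")])
    det <- det[!dup, , drop = FALSE]
    rownames(det) <- NULL
    structure(list(
      tag_id = tag,
      deployment = deployments[deployments$tag_id == tag, , drop = FALSE],
      detections = det
    ), class = "coasttrack_track")
  })
  names(tracks) <- names(split_det)
  tracks
}

#' @export
print.coasttrack_track <- function(x, ...) {
  cat("<coasttrack_track> tag", x$tag_id, "-", x$deployment$species,
      x$deployment$season, "-", nrow(x$detections), "detections\n")
  invisible(x)
}

#' Inter-receiver transitions of a track
#'
#' One row per consecutive pair of detections at *different* receivers;
#' runs of detections at the same receiver collapse into their boundary
#' detections (dwell is handled by segmentation). Ground speed is
#' displacement over elapsed time; a transition whose implied speed exceeds
#' `simultaneous_speed_ms` (detections registered by two receivers at
#' essentially the same instant) is flagged `simultaneous` and its speed
#' retained as computed (`Inf` for a zero time gap).
#'
#' @param track A `coasttrack_track`.
#' @param receivers Receiver registry.
#' @param simultaneous_speed_ms Implied-speed cutoff flagging simultaneous
#'   detections (m/s).
#' @return `data.frame` with columns `from_receiver`, `to_receiver`,
#'   `t_start`, `t_end`, `distance_km`, `ground_speed_ms`, `bearing_deg`,
#'   `simultaneous`. Zero rows for single-receiver tracks.
#' @export
track_transitions <- function(track, receivers, simultaneous_speed_ms = 26) {
  det <- track$detections
  empty <- data.frame(from_receiver = character(), to_receiver = character(),
                      t_start = as.POSIXct(character(), tz = "UTC"),
                      t_end = as.POSIXct(character(), tz = "UTC"),
                      distance_km = numeric(), ground_speed_ms = numeric(),
                      bearing_deg = numeric(), simultaneous = logical())
  if (nrow(det) < 2) return(empty)
  change <- c(TRUE, det$receiver_id[-1] != det$receiver_id[-nrow(det)])
  run_id <- cumsum(change)
  n_runs <- max(run_id)
  if (n_runs < 2) return(empty)
  first_idx <- match(seq_len(n_runs), run_id)
  last_idx <- nrow(det) + 1 - match(seq_len(n_runs), rev(run_id))
  from <- det$receiver_id[last_idx[-n_runs]]
  to <- det$receiver_id[first_idx[-1]]
  t_start <- det$t[last_idx[-n_runs]]
  t_end <- det$t[first_idx[-1]]
  loc <- receiver_loc(receivers, c(from, to))
  k <- length(from)
  dist <- gc_distance(loc$lat[seq_len(k)], loc$lon[seq_len(k)],
                      loc$lat[k + seq_len(k)], loc$lon[k + seq_len(k)])
  bear <- initial_bearing(loc$lat[seq_len(k)], loc$lon[seq_len(k)],
                          loc$lat[k + seq_len(k)], loc$lon[k + seq_len(k)])
  dt <- as.numeric(t_end) - as.numeric(t_start)
  speed <- ifelse(dt > 0, dist * 1000 / dt, Inf)
  data.frame(from_receiver = from, to_receiver = to,
             t_start = t_start, t_end = t_end,
             distance_km = dist, ground_speed_ms = speed, bearing_deg = bear,
             simultaneous = speed > simultaneous_speed_ms)
}

receiver_loc <- function(receivers, ids) {
  i <- match(ids, receivers$receiver_id)
  if (anyNA(i)) stop("unknown receiver id(s): ", paste(unique(ids[is.na(i)]), collapse = ", "))
  data.frame(lat = receivers$lat[i], lon = receivers$lon[i],
             is_island_site = receivers$is_island_site[i])
}
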