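#' Configuration objects
#'
#' All numeric thresholds of the analysis live in three small config
#' objects so every assumption is auditable and adjustable in one place.
#' Defaults are the study values used throughout: a 0.67 false-positive
#' probability cut, a 20 km deployment radius with 2.6 km receiver
#' clusters, the 1 h / 35 min dwell rules, the 5-26 m/s flight-speed band,
#' the 3 day / 32 km slow-movement stopover rule, seasonal progress
#' sectors (315-90 degrees in spring, 135-270 in autumn), and the
#' sustained-flight and offshore criteria (>3 receivers spaced >2.6 km or
#' two receivers >=35 km apart, gaps <7 h; latitude split 54 with
#' thresholds 54.135 / 8.08 east).
#'
#' @param fp_threshold Detections with a false-positive probability score at
#'   or above this value are dropped (recaptures are always kept).
#' @return A named list with class `coasttrack_config`.
#' @name configs
NULL

#' @rdname configs
#' @export
filter_config <- function(fp_threshold = 0.67) {
  stopifnot(is.numeric(fp_threshold), length(fp_threshold) == 1,
            fp_threshold >= 0, fp_threshold <= 1)
  structure(list(fp_threshold = fp_threshold),
            class = c("coasttrack_filter_config", "coasttrack_config"))
}

#' @rdname configs
#' @param initial_radius_km Deployment-site radius defining where an initial
#'   stopover can start (km).
#' @param cluster_radius_km Radius around the first-detecting receiver whose
#'   receivers form the initial-stopover cluster (km).
#' @param stop_dwell_min_h Single-receiver dwell longer than this is an
#'   along-track stopover (hours).
#' @param slow_speed_max_ms Upper bound of "slow movement" ground speed (m/s).
#' @param flight_speed_min_ms,flight_speed_max_ms Plausible flight ground
#'   speed band (m/s); implied speeds above the maximum are treated as
#'   simultaneous detections.
#' @param short_visit_max_min Single-receiver dwell shorter than this counts
#'   as flight (minutes).
#' @param stop_gap_max_days,stop_dist_max_km Slow movements with subsequent
#'   detections within this many days and below this range are along-track
#'   stopover.
#' @export
segmentation_config <- function(initial_radius_km = 20,
                                cluster_radius_km = 2.6,
                                stop_dwell_min_h = 1,
                                slow_speed_max_ms = 5,
                                flight_speed_min_ms = 5,
                                flight_speed_max_ms = 26,
                                short_visit_max_min = 35,
                                stop_gap_max_days = 3,
                                stop_dist_max_km = 32) {
  cfg <- list(initial_radius_km = initial_radius_km,
              cluster_radius_km = cluster_radius_km,
              stop_dwell_min_h = stop_dwell_min_h,
              slow_speed_max_ms = slow_speed_max_ms,
              flight_speed_min_ms = flight_speed_min_ms,
              flight_speed_max_ms = flight_speed_max_ms,
              short_visit_max_min = short_visit_max_min,
              stop_gap_max_days = stop_gap_max_days,
              stop_dist_max_km = stop_dist_max_km)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1 || x <= 0, TRUE))) {
    stop("all segmentation thresholds must be single positive numbers")
  }
  if (cfg$flight_speed_min_ms != cfg$slow_speed_max_ms) {
    stop("flight_speed_min_ms must equal slow_speed_max_ms (contiguous speed classes)")
  }
  if (cfg$cluster_radius_km >= cfg$initial_radius_km) {
    stop("cluster_radius_km must be smaller than initial_radius_km")
  }
  structure(cfg, class = c("coasttrack_segmentation_config", "coasttrack_config"))
}

#' @rdname configs
#' @param progress_sector_spring,progress_sector_autumn Numeric length-2
#'   vectors `c(from, to)` in degrees, clockwise from `from` to `to`; the
#'   spring default wraps through north.
#' @param sustained_min_receivers Minimum count of mutually spaced receivers
#'   for a sustained flight ("more than 3" = 4).
#' @param sustained_receiver_spacing_km Minimum pairwise spacing of those
#'   receivers (km).
#' @param sustained_pair_distance_km Alternative criterion: two receivers at
#'   least this far apart (km).
#' @param sustained_gap_max_h Maximum gap between subsequent detections
#'   within a sustained flight (hours).
#' @param lat_split Latitude separating the two coastline legs (degrees).
#' @param offshore_lat_min Offshore criterion threshold on the
#'   above-split receiver latitude (degrees).
#' @param offshore_lon_threshold Offshore criterion threshold on the
#'   below-split receiver longitude (degrees east).
#' @export
routing_config <- function(progress_sector_spring = c(315, 90),
                           progress_sector_autumn = c(135, 270),
                           sustained_min_receivers = 4,
                           sustained_receiver_spacing_km = 2.6,
                           sustained_pair_distance_km = 35,
                           sustained_gap_max_h = 7,
                           lat_split = 54,
                           offshore_lat_min = 54.135,
                           offshore_lon_threshold = 8.08) {
  stopifnot(length(progress_sector_spring) == 2, length(progress_sector_autumn) == 2,
            sustained_min_receivers >= 2, sustained_receiver_spacing_km > 0,
            sustained_pair_distance_km > 0, sustained_gap_max_h > 0)
  structure(list(progress_sector_spring = progress_sector_spring,
                 progress_sector_autumn = progress_sector_autumn,
                 sustained_min_receivers = sustained_min_receivers,
                 sustained_receiver_spacing_km = sustained_receiver_spacing_km,
                 sustained_pair_distance_km = sustained_pair_distance_km,
                 sustained_gap_max_h = sustained_gap_max_h,
                 lat_split = lat_split,
                 offshore_lat_min = offshore_lat_min,
                 offshore_lon_threshold = offshore_lon_threshold),
            class = c("coasttrack_routing_config", "coasttrack_config"))
}

#' @export
print.coasttrack_config <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  for (nm in names(x)) cat(" ", nm, ": ", paste(format(x[[nm]]), collapse = " "), "\n", sep = "")
  invisible(x)
}
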