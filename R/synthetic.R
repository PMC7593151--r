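#' Simulation configuration
#'
#' Defines the stated world of the synthetic study: a coastal receiver
#' array with two coastline legs (a meridional north-south leg and a zonal
#' east-west leg meeting at the inner corner of a bight) plus one offshore
#' island receiver; two species archetypes (a diurnal migrant that starts
#' flights around sunrise, up to ~3 h before and extending into the
#' morning, and a nocturnal migrant that departs in the first quarter of
#' the night and lands strictly before sunrise); release at a coastal
#' receiver followed by an initial stopover, optional along-track
#' stopovers and detours, and an offshore bight crossing with the
#' configured probability. Default group medians (initial stopover,
#' stopover and detour probabilities, offshore probability) follow the
#' field study the generator emulates: diurnal birds stop over long
#' (median ~5 d spring, ~10 d autumn) and nocturnal birds leave around the
#' next night (~0.6-0.9 d); roughly a third of sustained flights cross
#' offshore.
#'
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @param n_per_group Birds per species x season group.
#' @param seasons Subset of `c("autumn", "spring")`.
#' @param p_detect Per-sample detection probability within range.
#' @param p_detect_island Detection probability at island receivers.
#' @param fp_rate False positives injected per true detection; their
#'   fp-scores are drawn at or above 0.67 so the standard filter removes
#'   them all.
#' @param range_flight_km Detection range for a flying bird (km).
#' @param range_ground_km Detection range for a bird on the ground (km).
#' @param step_s Flight sampling step (seconds).
#' @param ground_sample_s Stopover sampling step (seconds).
#' @param species_params Named list of archetype parameter lists; see
#'   defaults.
#' @return A `coasttrack_sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_per_group = 30L,
                       seasons = "autumn",
                       p_detect = 0.9,
                       p_detect_island = 1.0,
                       fp_rate = 0.02,
                       range_flight_km = 12,
                       range_ground_km = 2,
                       step_s = 120,
                       ground_sample_s = 1800,
                       species_params = NULL) {
  stopifnot(all(seasons %in% c("autumn", "spring")), n_per_group >= 1,
            p_detect >= 0, p_detect <= 1, fp_rate >= 0)
  if (is.null(species_params)) {
    species_params <- list(
      dunnock = list(
        archetype = "diurnal",
        initial_stop_median_days = c(spring = 4.9, autumn = 10.5),
        initial_stop_sdlog = 0.6,
        p_stopover = 0.45, stop_median_days = 1.0, stop_sdlog = 1.0,
        p_offshore = 0.31, p_detour = 0.5, p_recapture = 0.05,
        speed_ms = c(8, 14), fat_mean = 3.0, fat_sd = 0.7
      ),
      blackcap = list(
        archetype = "nocturnal",
        initial_stop_median_days = c(spring = 0.6, autumn = 0.9),
        initial_stop_sdlog = 0.5,
        p_stopover = 0.2, stop_median_days = 1.0, stop_sdlog = 1.0,
        p_offshore = 0.32, p_detour = 0.4, p_recapture = 0.05,
        speed_ms = c(9, 16), fat_mean = 3.75, fat_sd = 1.0
      )
    )
  }
  structure(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                 seasons = seasons, p_detect = p_detect,
                 p_detect_island = p_detect_island, fp_rate = fp_rate,
                 range_flight_km = range_flight_km,
                 range_ground_km = range_ground_km,
                 step_s = step_s, ground_sample_s = ground_sample_s,
                 species_params = species_params,
                 geometry = default_geometry()),
            class = c("coasttrack_sim_config", "coasttrack_config"))
}

# two coastline legs meeting at the inner bight corner, one island;
# receiver spacing ~10-13 km so flight-range coverage is continuous
default_geometry <- function() {
  list(
    leg_a = list(from = c(55.05, 8.45), to = c(53.75, 8.25), n = 12),
    leg_b = list(from = c(53.73, 8.10), to = c(53.55, 6.55), n = 11),
    island = c(54.1821, 7.8925),
    release_autumn_idx = 6L,  # receiver on leg A
    release_spring_idx = 8L,  # receiver on leg B
    offshore_landing_autumn_idx = 6L, # leg B receiver west of the lon threshold
    offshore_landing_spring_idx = 5L  # leg A receiver north of the lat threshold
  )
}

#' Build the synthetic receiver registry
#'
#' Receivers are placed evenly along the two coastline legs; the island
#' receiver is flagged `is_island_site`.
#'
#' @param cfg A [sim_config()].
#' @return Receiver registry `data.frame` (same schema as
#'   [read_receivers()]).
#' @export
make_receiver_array <- function(cfg = sim_config()) {
  g <- cfg$geometry
  if (g$leg_a$n < 1 || g$leg_b$n < 1) stop("empty receiver layout")
  leg <- function(l, prefix) {
    data.frame(receiver_id = sprintf("%s%02d", prefix, seq_len(l$n)),
               lat = seq(l$from[1], l$to[1], length.out = l$n),
               lon = seq(l$from[2], l$to[2], length.out = l$n),
               is_island_site = FALSE)
  }
  rbind(leg(g$leg_a, "A"), leg(g$leg_b, "B"),
        data.frame(receiver_id = "HEL", lat = g$island[1], lon = g$island[2],
                   is_island_site = TRUE))
}

# next archetype-consistent flight start at or after t_min (POSIXct, UTC);
# returns the start and, for nocturnal birds, the limiting sunrise
next_flight_start <- function(archetype, t_min, lat, lon) {
  d <- as.Date(t_min) - 1
  for (k in 0:13) {
    ev0 <- sun_events(d + k, lat, lon)
    ev1 <- sun_events(d + k + 1, lat, lon)
    sunset <- ev0$sunset_utc
    sunrise <- ev1$sunrise_utc
    night_len <- as.numeric(sunrise) - as.numeric(sunset)
    cand <- if (archetype == "nocturnal") {
      sunset + stats::runif(1, 0.05, 0.30) * night_len
    } else {
      sunrise + stats::runif(1, -2, 2) * 3600
    }
    if (cand >= t_min) {
      return(list(t0 = cand, night_end = sunrise))
    }
  }
  stop("no flight start found within two weeks") # nocov
}

# step grid along a waypoint polyline at constant ground speed
make_bout_track <- function(way, t0, v_ms, step_s) {
  seg_km <- gc_distance(way[-nrow(way), 1], way[-nrow(way), 2],
                        way[-1, 1], way[-1, 2])
  cum_km <- c(0, cumsum(seg_km))
  total_s <- cum_km[length(cum_km)] * 1000 / v_ms
  ts <- unique(c(seq(0, total_s, by = step_s), total_s))
  dist_km <- pmin(ts * v_ms / 1000, cum_km[length(cum_km)])
  seg <- pmin(findInterval(dist_km, cum_km, rightmost.closed = TRUE),
              nrow(way) - 1L)
  frac <- (dist_km - cum_km[seg]) / pmax(seg_km[seg], 1e-9)
  data.frame(t = t0 + ts,
             lat = way[seg, 1] + frac * (way[seg + 1, 1] - way[seg, 1]),
             lon = way[seg, 2] + frac * (way[seg + 1, 2] - way[seg, 2]))
}

#' Simulate latent bird trajectories with ground truth
#'
#' Draws, for every bird, a release time, an initial stopover duration, a
#' route (offshore crossing with the archetype's probability, otherwise
#' coastal), optional detour and along-track stopover, and flight bouts
#' scheduled in the archetype's diel window at the current location's
#' solar times; nocturnal bouts are speed-adjusted so they end before
#' sunrise. Movement is straight waypoint-to-waypoint flight at constant
#' ground speed, which is all a receiver-bound pipeline can resolve.
#'
#' @param cfg A [sim_config()].
#' @return List with `birds` (per-bird latent data: bouts as step grids,
#'   stopovers, deployment fields) and `truth` (`data.frame`s `birds` and
#'   `intervals`).
#' @export
simulate_tracks <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  receivers <- make_receiver_array(cfg)
  g <- cfg$geometry
  a_idx <- seq_len(g$leg_a$n)
  b_idx <- g$leg_a$n + seq_len(g$leg_b$n)
  coast <- receivers[c(a_idx, b_idx), ] # ordered N -> S -> W
  island <- g$island
  birds <- list()
  truth_rows <- list()
  interval_rows <- list()
  for (season in cfg$seasons) {
    for (sp in names(cfg$species_params)) {
      par <- cfg$species_params[[sp]]
      for (i in seq_len(cfg$n_per_group)) {
        tag <- sprintf("%s-%s-%03d", toupper(substr(sp, 1, 2)), substr(season, 1, 2), i)
        rel <- release_time(season, sp)
        if (season == "autumn") {
          rel_row <- g$release_autumn_idx # index into coast (leg A part)
          fwd <- seq(rel_row, nrow(coast)) # southbound then westbound
          land_row <- g$leg_a$n + g$offshore_landing_autumn_idx
        } else {
          rel_row <- g$leg_a$n + g$release_spring_idx
          fwd <- seq(rel_row, 1) # eastbound then northbound
          land_row <- g$offshore_landing_spring_idx
        }
        offshore <- stats::runif(1) < par$p_offshore
        detour <- stats::runif(1) < par$p_detour
        stopover <- stats::runif(1) < par$p_stopover
        d_init <- stats::rlnorm(1, log(par$initial_stop_median_days[[season]]),
                                par$initial_stop_sdlog)
        # waypoint rows (into `coast`) for the main journey
        if (offshore) {
          post <- fwd[which(fwd == land_row):length(fwd)]
          main <- list(rbind(as.matrix(coast[rel_row, c("lat", "lon")]),
                             island,
                             as.matrix(coast[post, c("lat", "lon")])))
        } else {
          main <- list(as.matrix(coast[fwd, c("lat", "lon")]))
        }
        # optional split with an along-track stopover (after any crossing)
        stop_dur <- NULL
        if (stopover) {
          wp <- main[[1]]
          n_wp <- nrow(wp)
          lo <- if (offshore) 4L else 3L # past release / crossing
          if (n_wp - lo >= 2) {
            s <- sample(seq(lo, n_wp - 1), 1)
            main <- list(wp[1:s, , drop = FALSE], wp[s:n_wp, , drop = FALSE])
            stop_dur <- stats::rlnorm(1, log(par$stop_median_days), par$stop_sdlog)
          }
        }
        # optional detour: one leg backward from the release receiver,
        # a short rest, then the journey (re-entered from the neighbour)
        bouts_way <- main
        did_detour <- FALSE
        if (detour) {
          back_row <- if (season == "autumn") rel_row - 1L else rel_row + 1L
          if (back_row >= 1 && back_row <= nrow(coast)) {
            back <- as.matrix(coast[c(rel_row, back_row), c("lat", "lon")])
            first <- rbind(as.matrix(coast[back_row, c("lat", "lon"), drop = FALSE]),
                           main[[1]])
            bouts_way <- c(list(back, first), if (length(main) > 1) main[-1])
            did_detour <- TRUE
          }
        }
        # schedule the bouts
        arch <- par$archetype
        loc <- unname(as.matrix(coast[rel_row, c("lat", "lon")]))[1, ]
        t_avail <- rel + d_init * 86400
        bouts <- list()
        stopovers <- data.frame(lat = loc[1], lon = loc[2],
                                t_start = rel, t_end = rel) # initial; end set below
        dep1 <- NULL
        for (b in seq_along(bouts_way)) {
          st <- next_flight_start(arch, t_avail, loc[1], loc[2])
          v <- stats::runif(1, par$speed_ms[1], par$speed_ms[2])
          way <- bouts_way[[b]]
          total_km <- sum(gc_distance(way[-nrow(way), 1], way[-nrow(way), 2],
                                      way[-1, 1], way[-1, 2]))
          if (arch == "nocturnal") {
            avail_s <- as.numeric(st$night_end) - as.numeric(st$t0)
            v <- max(v, total_km * 1000 / (0.95 * avail_s))
          }
          tr <- make_bout_track(way, st$t0, v, cfg$step_s)
          bouts[[b]] <- tr
          if (b == 1) {
            dep1 <- st$t0
            stopovers$t_end[1] <- st$t0
          } else {
            stopovers <- rbind(stopovers,
                               data.frame(lat = loc[1], lon = loc[2],
                                          t_start = t_arr, t_end = st$t0))
          }
          t_arr <- tr$t[nrow(tr)]
          loc <- c(tr$lat[nrow(tr)], tr$lon[nrow(tr)])
          rest <- if (b == 1 && did_detour) {
            stats::runif(1, 0.1, 0.3) # short rest after the backward leg
          } else if (!is.null(stop_dur)) stop_dur else stats::runif(1, 0.1, 0.3)
          t_avail <- t_arr + rest * 86400
        }
        birds[[tag]] <- list(
          tag_id = tag, species = sp, season = season, archetype = arch,
          release_t = rel, release_lat = coast$lat[rel_row],
          release_lon = coast$lon[rel_row],
          fat_score = pmin(8, pmax(0, round(stats::rnorm(1, par$fat_mean, par$fat_sd) * 4) / 4)),
          recapture = stats::runif(1) < par$p_recapture,
          bouts = bouts, stopovers = stopovers
        )
        rest_days <- if (nrow(stopovers) > 1) {
          sum(as.numeric(stopovers$t_end[-1]) - as.numeric(stopovers$t_start[-1])) / 86400
        } else NA_real_
        truth_rows[[tag]] <- data.frame(
          tag_id = tag, species = sp, season = season,
          release_t = rel, departure_t = dep1,
          initial_stopover_days = as.numeric(dep1 - rel, units = "days"),
          route = if (offshore) "offshore" else "alongshore",
          n_detour_legs = as.integer(did_detour),
          has_along_track_stop = nrow(stopovers) > 1,
          along_track_stop_days = rest_days
        )
        iv <- rbind(
          data.frame(tag_id = tag, behavior = "stopover",
                     t_start = stopovers$t_start, t_end = stopovers$t_end),
          do.call(rbind, lapply(bouts, function(tr) {
            data.frame(tag_id = tag, behavior = "flight",
                       t_start = tr$t[1], t_end = tr$t[nrow(tr)])
          }))
        )
        interval_rows[[tag]] <- iv
      }
    }
  }
  list(birds = birds,
       truth = list(birds = do.call(rbind, c(truth_rows, make.row.names = FALSE)),
                    intervals = do.call(rbind, c(interval_rows, make.row.names = FALSE))))
}

# release timestamps follow the species' catching windows
release_time <- function(season, species) {
  win <- if (season == "autumn") {
    c("2018-09-27", "2018-10-14")
  } else if (species == "dunnock") {
    c("2018-03-20", "2018-03-27")
  } else {
    c("2018-04-08", "2018-04-21")
  }
  d0 <- as.numeric(as.POSIXct(paste(win[1], "00:00:00"), tz = "UTC"))
  d1 <- as.numeric(as.POSIXct(paste(win[2], "00:00:00"), tz = "UTC"))
  day <- d0 + floor(stats::runif(1) * ((d1 - d0) / 86400 + 1)) * 86400
  as.POSIXct(day + stats::runif(1, 8 * 3600, 14 * 3600),
             origin = "1970-01-01", tz = "UTC")
}

#' Thin latent trajectories into a detection table
#'
#' A flying bird is detected by every receiver within `range_flight_km`
#' at each flight sampling step with probability `p_detect`
#' (`p_detect_island` at island receivers); a bird on the ground is
#' sampled every `ground_sample_s` seconds by receivers within the much
#' shorter `range_ground_km`. False positives are injected at random
#' receivers and times with fp-scores drawn in `[0.67, 1]`; true
#' detections get scores in `[0, 0.5]` (one in five missing). Recaptures
#' at the deployment site are added for a small fraction of birds.
#'
#' @param sim Output of [simulate_tracks()].
#' @param receivers Registry from [make_receiver_array()].
#' @param cfg The same [sim_config()].
#' @return Detection `data.frame` (schema of [read_detections()]) with
#'   attribute `is_false_positive` (logical, per row).
#' @export
emit_detections <- function(sim, receivers, cfg = sim_config()) {
  set.seed(cfg$seed + 104729L)
  p_rec <- ifelse(receivers$is_island_site, cfg$p_detect_island, cfg$p_detect)
  rows <- list()
  for (bird in sim$birds) {
    for (tr in bird$bouts) {
      hit <- proximity_hits(tr, receivers, cfg$range_flight_km, p_rec)
      if (nrow(hit)) rows[[length(rows) + 1L]] <- cbind(tag_id = bird$tag_id, hit)
    }
    so <- bird$stopovers
    for (k in seq_len(nrow(so))) {
      ts <- seq(as.numeric(so$t_start[k]), as.numeric(so$t_end[k]),
                by = cfg$ground_sample_s)
      if (!length(ts)) next
      grid <- data.frame(t = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
                         lat = so$lat[k], lon = so$lon[k])
      hit <- proximity_hits(grid, receivers, cfg$range_ground_km, p_rec)
      if (nrow(hit)) rows[[length(rows) + 1L]] <- cbind(tag_id = bird$tag_id, hit)
    }
  }
  det <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  if (is.null(det)) {
    det <- data.frame(tag_id = character(), t = as.POSIXct(character(), tz = "UTC"),
                      receiver_id = character())
  }
  det$source <- rep("network", nrow(det))
  # recaptures at the deployment site during the initial stopover
  recap <- Filter(function(b) b$recapture, sim$birds)
  if (length(recap)) {
    rc <- do.call(rbind, lapply(recap, function(b) {
      t0 <- as.numeric(b$stopovers$t_start[1])
      t1 <- as.numeric(b$stopovers$t_end[1])
      data.frame(tag_id = b$tag_id,
                 t = as.POSIXct(stats::runif(1, t0, t1), origin = "1970-01-01", tz = "UTC"),
                 receiver_id = nearest_receiver(b$release_lat, b$release_lon, receivers),
                 source = "recapture")
    }))
    det <- rbind(det, rc)
  }
  n_true <- nrow(det)
  det$fp_score <- stats::runif(n_true, 0, 0.5)
  det$fp_score[stats::runif(n_true) < 0.2] <- NA_real_
  det$fp_score[det$source == "recapture"] <- NA_real_
  is_fp <- rep(FALSE, n_true)
  n_fp <- round(cfg$fp_rate * n_true)
  if (n_fp > 0) {
    span <- range(as.numeric(det$t))
    fp <- data.frame(
      tag_id = sample(names(sim$birds), n_fp, replace = TRUE),
      t = as.POSIXct(stats::runif(n_fp, span[1], span[2]),
                     origin = "1970-01-01", tz = "UTC"),
      receiver_id = sample(receivers$receiver_id, n_fp, replace = TRUE),
      source = "network",
      fp_score = stats::runif(n_fp, 0.67, 1)
    )
    det <- rbind(det, fp)
    is_fp <- c(is_fp, rep(TRUE, n_fp))
  }
  ord <- order(det$tag_id, det$t, det$receiver_id)
  det <- det[ord, c("tag_id", "t", "receiver_id", "fp_score", "source")]
  rownames(det) <- NULL
  attr(det, "is_false_positive") <- is_fp[ord]
  det
}

# detections of a position grid by receivers within range, Bernoulli thinned
proximity_hits <- function(grid, receivers, range_km, p_rec) {
  res <- list()
  for (j in seq_len(nrow(receivers))) {
    d <- gc_distance(grid$lat, grid$lon, receivers$lat[j], receivers$lon[j])
    in_range <- which(d <= range_km)
    if (!length(in_range)) next
    keep <- in_range[stats::runif(length(in_range)) < p_rec[j]]
    if (!length(keep)) next
    res[[length(res) + 1L]] <- data.frame(t = grid$t[keep],
                                          receiver_id = receivers$receiver_id[j])
  }
  if (!length(res)) {
    return(data.frame(t = as.POSIXct(character(), tz = "UTC"),
                      receiver_id = character()))
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}

nearest_receiver <- function(lat, lon, receivers) {
  receivers$receiver_id[which.min(gc_distance(lat, lon, receivers$lat, receivers$lon))]
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing the three canonical input tables plus
#' ground truth, optionally written as CSV files (`receivers.csv`,
#' `deployments.csv`, `detections.csv`, `truth_birds.csv`,
#' `truth_intervals.csv`).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `receivers`, `deployments`, `detections`, `truth`,
#'   and (when `dir` is given) `paths`.
#' @export
simulate_study <- function(cfg = sim_config(), dir = NULL) {
  receivers <- make_receiver_array(cfg)
  sim <- simulate_tracks(cfg)
  detections <- emit_detections(sim, receivers, cfg)
  deployments <- do.call(rbind, lapply(sim$birds, function(b) {
    data.frame(tag_id = b$tag_id, species = b$species, season = b$season,
               release_t = b$release_t, lat = b$release_lat, lon = b$release_lon,
               fat_score = b$fat_score)
  }))
  rownames(deployments) <- NULL
  out <- list(receivers = receivers, deployments = deployments,
              detections = detections, truth = sim$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(receivers = file.path(dir, "receivers.csv"),
               deployments = file.path(dir, "deployments.csv"),
               detections = file.path(dir, "detections.csv"),
               truth_birds = file.path(dir, "truth_birds.csv"),
               truth_intervals = file.path(dir, "truth_intervals.csv"))
    utils::write.csv(receivers, paths["receivers"], row.names = FALSE, quote = FALSE)
    dep_out <- deployments
    dep_out$release_ts_utc <- format(dep_out$release_t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    dep_out$release_t <- NULL
    utils::write.csv(dep_out[c("tag_id", "species", "season", "release_ts_utc",
                               "lat", "lon", "fat_score")],
                     paths["deployments"], row.names = FALSE, quote = FALSE)
    write_detections(detections, paths["detections"])
    tb <- sim$truth$birds
    tb$release_t <- format(tb$release_t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    tb$departure_t <- format(tb$departure_t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(tb, paths["truth_birds"], row.names = FALSE, quote = FALSE)
    ti <- sim$truth$intervals
    ti$t_start <- format(ti$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ti$t_end <- format(ti$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(ti, paths["truth_intervals"], row.names = FALSE, quote = FALSE)
    out$paths <- paths
  }
  out
}
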