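#' Summarise one individual track
#'
#' Runs the full per-individual analysis: initial stopover, behavioural
#' segmentation of the remaining detections, study-area residence, daily
#' mean movement speed, cumulative progress/detour lengths, and the first
#' sustained flight with its offshore/alongshore label and night-fraction
#' start phase.
#'
#' @param track A `coasttrack_track`.
#' @param receivers Receiver registry.
#' @param seg_cfg A [segmentation_config()].
#' @param rt_cfg A [routing_config()].
#' @return One-row `data.frame`.
#' @export
summarize_individual <- function(track, receivers,
                                 seg_cfg = segmentation_config(),
                                 rt_cfg = routing_config()) {
  dep <- track$deployment
  init <- initial_stopover(track, receivers, seg_cfg)
  post <- excise_initial(track, init)
  segs <- classify_segments(post, receivers, seg_cfg)
  trans <- track_transitions(track, receivers, seg_cfg$flight_speed_max_ms)
  route <- route_lengths(trans, dep$season, rt_cfg)
  flights <- extract_sustained_flights(track, receivers, rt_cfg)
  ff <- first_sustained_flight(flights)
  ats <- along_track_stopover_days(segs)
  sf_label <- sf_phase <- NA
  sf_start <- as.POSIXct(NA)
  if (!is.null(ff)) {
    sf_label <- classify_offshore(ff, dep$season, receivers, rt_cfg)
    loc <- receiver_loc(receivers, ff$start_receiver)
    sf_phase <- night_fraction(ff$start_t, loc$lat, loc$lon)
    sf_start <- ff$start_t
  }
  data.frame(
    tag_id = track$tag_id, species = dep$species, season = dep$season,
    n_detections = nrow(track$detections),
    initial_stopover_days = init$duration_days,
    initial_minimum_estimate = init$minimum_estimate,
    along_track_stopover_days = ats,
    has_along_track_stop = !is.na(ats),
    days_at_study_area = days_at_study_area(track),
    daily_mean_speed_km_day = daily_mean_speed(segs),
    progress_km = route$progress_km, detour_km = route$detour_km,
    took_detour = route$took_detour,
    n_sustained_flights = length(flights),
    sustained_label = if (is.na(sf_label)) NA_character_ else sf_label,
    sustained_start_t = sf_start,
    sustained_start_phase = as.numeric(sf_phase)
  )
}

#' Run the full analysis pipeline
#'
#' Filter, track assembly, segmentation, routing and group statistics,
#' end to end. Inputs may be the three canonical CSV paths or already
#' loaded `data.frame`s. When `out_dir` is given, writes
#' `individual_summary.csv`, `group_summary.csv` (per species x season x
#' variable medians/quartiles with Kruskal-Wallis species comparisons),
#' `group_tests.csv` (proportion comparisons), `routing_contingency.csv`
#' (species x season x alongshore/offshore), `segments.csv`,
#' `sustained_flights.csv`, and `manifest.json` (configs, versions, input
#' hashes) so a run is reproducible.
#'
#' @param detections,receivers,deployments Paths or `data.frame`s.
#' @param out_dir Optional output directory.
#' @param filter_cfg,seg_cfg,rt_cfg Configuration objects.
#' @return Invisibly, a list with all result tables.
#' @export
run_pipeline <- function(detections, receivers, deployments, out_dir = NULL,
                         filter_cfg = filter_config(),
                         seg_cfg = segmentation_config(),
                         rt_cfg = routing_config()) {
  input_hashes <- list()
  if (is.character(receivers)) {
    input_hashes$receivers <- unname(tools::md5sum(receivers))
    receivers <- read_receivers(receivers)
  }
  if (is.character(deployments)) {
    input_hashes$deployments <- unname(tools::md5sum(deployments))
    deployments <- read_deployments(deployments)
  }
  if (is.character(detections)) {
    input_hashes$detections <- unname(tools::md5sum(detections))
    detections <- read_detections(detections, receivers)
  }
  n_raw <- nrow(detections)
  detections <- filter_false_positives(detections, filter_cfg)
  message("detections: ", n_raw, " raw, ", nrow(detections), " after false-positive filter")
  if (nrow(detections) == 0) {
    warning("no detections after filtering; summaries are empty")
    res <- list(individual = data.frame(), groups = data.frame(),
                tests = data.frame(), contingency = data.frame(),
                segments = data.frame(), sustained = data.frame())
    if (!is.null(out_dir)) write_outputs(res, out_dir, filter_cfg, seg_cfg, rt_cfg, input_hashes)
    return(invisible(res))
  }
  tracks <- build_tracks(detections, deployments)
  message("tracks: ", length(tracks), " individuals detected of ",
          nrow(deployments), " deployed")
  indiv <- do.call(rbind, lapply(tracks, summarize_individual, receivers = receivers,
                                 seg_cfg = seg_cfg, rt_cfg = rt_cfg))
  rownames(indiv) <- NULL
  segments <- do.call(rbind, lapply(tracks, function(tr) {
    init <- initial_stopover(tr, receivers, seg_cfg)
    classify_segments(excise_initial(tr, init), receivers, seg_cfg)
  }))
  rownames(segments) <- NULL
  sustained <- do.call(rbind, lapply(tracks, function(tr) {
    fl <- extract_sustained_flights(tr, receivers, rt_cfg)
    if (!length(fl)) return(NULL)
    do.call(rbind, lapply(fl, function(f) {
      data.frame(tag_id = f$tag_id, start_ts = f$start_t,
                 n_receivers = length(f$receiver_ids),
                 max_pair_km = f$max_pair_km,
                 label = classify_offshore(f, tr$deployment$season, receivers, rt_cfg))
    }))
  }))
  if (is.null(sustained)) sustained <- data.frame()
  rownames(sustained) <- NULL
  groups <- group_summary(indiv)
  tests <- group_tests(indiv)
  contingency <- routing_contingency(indiv)
  res <- list(individual = indiv, groups = groups, tests = tests,
              contingency = contingency, segments = segments, sustained = sustained)
  if (!is.null(out_dir)) write_outputs(res, out_dir, filter_cfg, seg_cfg, rt_cfg, input_hashes)
  invisible(res)
}

# per species x season x variable: median (25%, 75%), n, and the
# between-species Kruskal-Wallis test within each season
group_summary <- function(indiv) {
  vars <- c("initial_stopover_days", "along_track_stopover_days",
            "days_at_study_area", "progress_km", "detour_km",
            "daily_mean_speed_km_day")
  rows <- list()
  for (season in unique(indiv$season)) {
    sdat <- indiv[indiv$season == season, , drop = FALSE]
    species <- sort(unique(sdat$species))
    for (v in vars) {
      vals <- sdat[[v]]
      if (v %in% c("progress_km", "detour_km")) vals[vals <= 0] <- NA
      by_sp <- lapply(species, function(sp) vals[sdat$species == sp & !is.na(vals)])
      names(by_sp) <- species
      kw <- tryCatch(kruskal_wallis(by_sp[lengths(by_sp) > 0]),
                     error = function(e) list(statistic = NA_real_, p = NA_real_))
      for (sp in species) {
        x <- by_sp[[sp]]
        mq <- if (length(x)) median_quartiles(x) else c(NA, NA, NA)
        rows[[length(rows) + 1L]] <- data.frame(
          season = season, variable = v, species = sp, n = length(x),
          median = mq[[1]], q25 = mq[[2]], q75 = mq[[3]],
          kw_chisq = kw$statistic, kw_p = kw$p)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# proportion comparisons mirroring the study's reporting: between species
# within season (initial stopover recorded, along-track stopover), and
# between seasons within species (detour taken, offshore flight), plus the
# overall between-species offshore comparison
group_tests <- function(indiv) {
  rows <- list()
  add <- function(comparison, ga, gb, k1, n1, k2, n2) {
    tst <- tryCatch(proportion_test(k1, n1, k2, n2),
                    error = function(e) list(statistic = NA_real_, df = NA, p = NA_real_))
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, group_a = ga, group_b = gb,
      k1 = k1, n1 = n1, k2 = k2, n2 = n2,
      statistic = tst$statistic, df = 1L, p = tst$p)
  }
  count <- function(mask, flag) c(sum(flag & mask, na.rm = TRUE), sum(mask))
  for (season in unique(indiv$season)) {
    species <- sort(unique(indiv$species[indiv$season == season]))
    if (length(species) == 2) {
      m1 <- indiv$season == season & indiv$species == species[1]
      m2 <- indiv$season == season & indiv$species == species[2]
      a <- count(m1, !is.na(indiv$initial_stopover_days))
      b <- count(m2, !is.na(indiv$initial_stopover_days))
      add(paste0(season, ": initial stopover recorded"), species[1], species[2],
          a[1], a[2], b[1], b[2])
      a <- count(m1, indiv$has_along_track_stop)
      b <- count(m2, indiv$has_along_track_stop)
      add(paste0(season, ": along-track stopover"), species[1], species[2],
          a[1], a[2], b[1], b[2])
    }
  }
  with_sf <- !is.na(indiv$sustained_label)
  for (sp in unique(indiv$species)) {
    seasons <- sort(unique(indiv$season[indiv$species == sp]), decreasing = TRUE)
    if (length(seasons) == 2) {
      m1 <- indiv$species == sp & indiv$season == seasons[1]
      m2 <- indiv$species == sp & indiv$season == seasons[2]
      a <- count(m1 & indiv$progress_km + indiv$detour_km > 0, indiv$took_detour)
      b <- count(m2 & indiv$progress_km + indiv$detour_km > 0, indiv$took_detour)
      add(paste0(sp, ": detour, ", seasons[1], " vs ", seasons[2]),
          seasons[1], seasons[2], a[1], a[2], b[1], b[2])
      a <- count(m1 & with_sf, indiv$sustained_label == "offshore")
      b <- count(m2 & with_sf, indiv$sustained_label == "offshore")
      add(paste0(sp, ": offshore, ", seasons[1], " vs ", seasons[2]),
          seasons[1], seasons[2], a[1], a[2], b[1], b[2])
    }
  }
  species <- sort(unique(indiv$species))
  if (length(species) == 2) {
    a <- count(indiv$species == species[1] & with_sf, indiv$sustained_label == "offshore")
    b <- count(indiv$species == species[2] & with_sf, indiv$sustained_label == "offshore")
    add("offshore: species comparison", species[1], species[2],
        a[1], a[2], b[1], b[2])
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) data.frame() else out
}

# species x season x alongshore/offshore counts of first sustained flights
routing_contingency <- function(indiv) {
  sf <- indiv[!is.na(indiv$sustained_label), , drop = FALSE]
  if (!nrow(sf)) return(data.frame())
  tab <- as.data.frame(table(species = sf$species, season = sf$season,
                             label = sf$sustained_label))
  names(tab)[4] <- "n"
  tab
}

write_outputs <- function(res, out_dir, filter_cfg, seg_cfg, rt_cfg, input_hashes) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  wr(res$individual, "individual_summary.csv")
  wr(res$groups, "group_summary.csv")
  wr(res$tests, "group_tests.csv")
  wr(res$contingency, "routing_contingency.csv")
  wr(res$segments, "segments.csv")
  wr(res$sustained, "sustained_flights.csv")
  manifest <- list(
    package = "coasttrack",
    version = as.character(utils::packageVersion("coasttrack")),
    r_version = as.character(getRversion()),
    configs = list(filter = unclass(filter_cfg), segmentation = unclass(seg_cfg),
                   routing = unclass(rt_cfg)),
    input_md5 = input_hashes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
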