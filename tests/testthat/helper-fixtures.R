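# shared fixture builders: everything is constructed in code, no binary data

utc <- function(x) as.POSIXct(x, tz = "UTC")

# registry of receivers on a ~13 km north-south line plus a tight 2 km
# cluster mate of R1 and one distant island site
tiny_registry <- function() {
  data.frame(
    receiver_id = c("R1", "R1b", "R2", "R3", "ISL"),
    lat = c(54.00, 54.018, 54.118, 54.236, 54.1821),
    lon = c(8.00, 8.000, 8.000, 8.000, 7.8925),
    is_island_site = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

# build a track object from vectors; deployment defaults to release at R1
make_track <- function(t, receiver_id, tag_id = "T1",
                       release_t = utc("2018-04-01 10:00:00"),
                       release_lat = 54.0, release_lon = 8.0,
                       species = "dunnock", season = "spring") {
  det <- data.frame(tag_id = tag_id, t = t, receiver_id = receiver_id,
                    fp_score = NA_real_, source = "network")
  det <- det[order(det$t, det$receiver_id), , drop = FALSE]
  rownames(det) <- NULL
  structure(list(
    tag_id = tag_id,
    deployment = data.frame(tag_id = tag_id, species = species, season = season,
                            release_t = release_t, lat = release_lat,
                            lon = release_lon, fat_score = 3),
    detections = det
  ), class = "coasttrack_track")
}

# random small registry + track for property/oracle tests
random_track <- function(n_receivers = 6, n_det = 30) {
  reg <- data.frame(
    receiver_id = sprintf("S%02d", seq_len(n_receivers)),
    lat = 53.5 + runif(n_receivers, 0, 1.2),
    lon = 6.8 + runif(n_receivers, 0, 1.8),
    is_island_site = FALSE
  )
  t0 <- utc("2018-09-01 00:00:00")
  gaps <- rexp(n_det, rate = 1 / 3600) * sample(c(0.01, 1, 10), n_det, replace = TRUE)
  t <- t0 + cumsum(pmax(1, gaps))
  det <- data.frame(tag_id = "RT", t = t,
                    receiver_id = sample(reg$receiver_id, n_det, replace = TRUE),
                    fp_score = NA_real_, source = "network")
  det <- det[!duplicated(det[c("t", "receiver_id")]), , drop = FALSE]
  det <- det[order(det$t, det$receiver_id), , drop = FALSE]
  rownames(det) <- NULL
  tr <- structure(list(tag_id = "RT", deployment = NULL, detections = det),
                  class = "coasttrack_track")
  list(track = tr, registry = reg)
}

read_almanac <- function() {
  alm <- read.csv(test_path("almanac-astral.csv"), stringsAsFactors = FALSE)
  alm$sunrise <- as.POSIXct(alm$sunrise_utc, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  alm$sunset <- as.POSIXct(alm$sunset_utc, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  alm
}
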