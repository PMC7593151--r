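test_that("heading classification matches the seasonal sectors", {
  expect_equal(classify_heading(0, "spring"), "progress")
  expect_equal(classify_heading(200, "autumn"), "progress")
  expect_equal(classify_heading(200, "spring"), "detour")
  expect_equal(classify_heading(100, "spring"), "detour")
  # inclusive boundaries
  expect_equal(classify_heading(c(315, 90), "spring"), c("progress", "progress"))
  expect_equal(classify_heading(c(135, 270), "autumn"), c("progress", "progress"))
  # totality: the two classes partition the circle in each season
  b <- seq(0, 359.75, by = 0.25)
  for (season in c("spring", "autumn")) {
    cls <- classify_heading(b, season)
    expect_true(all(cls %in% c("progress", "detour")))
  }
  expect_equal(sum(classify_heading(b, "spring") == "progress"),
               sum(b >= 315 | b <= 90))
})

test_that("route lengths accumulate by heading and exclude simultaneous", {
  tt <- data.frame(
    from_receiver = "A", to_receiver = "B",
    t_start = utc("2018-04-01 00:00:00"), t_end = utc("2018-04-01 01:00:00"),
    distance_km = c(50, 50, 20, 10),
    ground_speed_ms = c(10, 10, 10, 100),
    bearing_deg = c(10, 350, 180, 20),
    simultaneous = c(FALSE, FALSE, FALSE, TRUE)
  )
  rs <- route_lengths(tt, "spring")
  expect_equal(rs$progress_km, 100)
  expect_equal(rs$detour_km, 20)
  expect_true(rs$took_detour)
  # conservation: progress + detour = total non-simultaneous length
  expect_equal(rs$progress_km + rs$detour_km, sum(tt$distance_km[!tt$simultaneous]))
  rs0 <- route_lengths(tt[tt$simultaneous, ], "spring")
  expect_equal(rs0$progress_km + rs0$detour_km, 0)
  expect_false(rs0$took_detour)
})

test_that("route length conservation holds on random tracks", {
  set.seed(41)
  for (rep in 1:20) {
    rt <- random_track(6, 25)
    tt <- track_transitions(rt$track, rt$registry)
    for (season in c("spring", "autumn")) {
      rs <- route_lengths(tt, season)
      expect_equal(rs$progress_km + rs$detour_km,
                   sum(tt$distance_km[!tt$simultaneous]))
    }
  }
})

# four receivers ~10 km apart on a line, plus a far pair for criterion (b)
sf_registry <- function() {
  data.frame(receiver_id = c("G1", "G2", "G3", "G4", "F1", "F2", "N1", "N2"),
             lat = c(54.0, 54.09, 54.18, 54.27, 54.0, 54.36, 54.0, 54.18),
             lon = c(8, 8, 8, 8, 8.5, 8.5, 9, 9),
             is_island_site = FALSE)
}

test_that("sustained flight extraction applies both criteria and the gap rule", {
  reg <- sf_registry()
  t0 <- utc("2018-04-01 00:00:00")
  # (a) four receivers spaced ~10 km, 1 h gaps
  tr <- make_track(t0 + (0:3) * 3600, c("G1", "G2", "G3", "G4"))
  fl <- extract_sustained_flights(tr, reg)
  expect_length(fl, 1)
  expect_setequal(fl[[1]]$receiver_ids, c("G1", "G2", "G3", "G4"))
  # (b) two receivers 40 km apart, 2 h gap
  tr <- make_track(t0 + c(0, 7200), c("F1", "F2"))
  expect_length(extract_sustained_flights(tr, reg), 1)
  # two receivers 20 km apart fail both criteria
  tr <- make_track(t0 + c(0, 7200), c("N1", "N2"))
  expect_length(extract_sustained_flights(tr, reg), 0)
  # an 8 h gap splits an otherwise qualifying run into two failing halves
  tr <- make_track(t0 + c(0, 3600, 3600 + 8 * 3600, 3600 + 9 * 3600),
                   c("G1", "G2", "G3", "G4"))
  expect_length(extract_sustained_flights(tr, reg), 0)
  # start time is the departure from the first receiver
  tr <- make_track(t0 + c(0, 1800, 3600, 5400, 7200),
                   c("G1", "G1", "G2", "G3", "G4"))
  fl <- extract_sustained_flights(tr, reg)
  expect_equal(fl[[1]]$start_t, t0 + 1800)
  expect_equal(fl[[1]]$start_receiver, "G1")
})

test_that("first sustained flight picks the earliest", {
  reg <- sf_registry()
  t0 <- utc("2018-04-01 00:00:00")
  tr <- make_track(c(t0, t0 + 7200, t0 + 3 * 86400, t0 + 3 * 86400 + 7200),
                   c("F1", "F2", "F1", "F2"))
  fl <- extract_sustained_flights(tr, reg)
  expect_length(fl, 2)
  expect_equal(first_sustained_flight(fl)$start_t, t0)
  expect_null(first_sustained_flight(list()))
  expect_equal(first_sustained_flight(fl[2])$start_t, fl[[2]]$start_t)
})

test_that("offshore classification: island rule, thresholds, seasonal mirror", {
  reg <- data.frame(
    receiver_id = c("HI", "LO_W", "LO_E", "HEL", "MID"),
    lat = c(54.30, 53.90, 53.90, 54.1821, 54.05),
    lon = c(8.40, 7.90, 8.40, 7.8925, 8.40),
    is_island_site = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  t0 <- utc("2018-10-01 00:00:00")
  mk <- function(recs) {
    tr <- make_track(t0 + seq_along(recs) * 3600, recs, season = "autumn")
    structure(list(tag_id = "T1", detections = tr$detections,
                   receiver_ids = unique(recs), start_t = t0,
                   start_receiver = recs[1], max_pair_km = 50),
              class = "coasttrack_sustained_flight")
  }
  # island recording alone makes it offshore
  expect_equal(classify_offshore(mk(c("HI", "HEL", "LO_E")), "autumn", reg), "offshore")
  # autumn: last above-54 at 54.30 > 54.135 and first below-54 at 7.90 < 8.08
  expect_equal(classify_offshore(mk(c("HI", "LO_W")), "autumn", reg), "offshore")
  # latitude criterion fails (last above-54 receiver at 54.05)
  expect_equal(classify_offshore(mk(c("HI", "MID", "LO_W")), "autumn", reg), "alongshore")
  # longitude criterion fails
  expect_equal(classify_offshore(mk(c("HI", "LO_E")), "autumn", reg), "alongshore")
  # spring mirror: first above-54 takes the latitude test, last below-54 the longitude
  expect_equal(classify_offshore(mk(c("LO_W", "HI")), "spring", reg), "offshore")
  expect_equal(classify_offshore(mk(c("LO_E", "HI")), "spring", reg), "alongshore")
  expect_equal(classify_offshore(mk(c("LO_W", "MID", "HI")), "spring", reg), "alongshore")
  # never crossing the split latitude -> alongshore
  expect_equal(classify_offshore(mk(c("LO_W", "LO_E")), "autumn", reg), "alongshore")
})

test_that("extracted sustained flights always satisfy the internal gap bound", {
  set.seed(42)
  cfg <- routing_config()
  for (rep in 1:20) {
    rt <- random_track(6, 30)
    for (f in extract_sustained_flights(rt$track, rt$registry, cfg)) {
      expect_true(all(diff(as.numeric(f$detections$t)) < cfg$sustained_gap_max_h * 3600))
    }
  }
})
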