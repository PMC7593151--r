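test_that("initial stopover follows the cluster rule", {
  reg <- tiny_registry()
  rel <- utc("2018-04-01 10:00:00")
  # detections at R1 and its 2 km mate R1b for 2.5 days, then R2
  tr <- make_track(rel + c(0, 3600, 86400, 2.5 * 86400) ,
                   c("R1", "R1b", "R1", "R2"), release_t = rel)
  init <- initial_stopover(tr, reg)
  expect_equal(init$duration_days, 2.5)
  expect_false(init$minimum_estimate)
  expect_setequal(init$cluster, c("R1", "R1b"))
  # never detected outside the cluster -> minimum estimate to last detection
  tr2 <- make_track(rel + c(0, 4 * 86400), c("R1", "R1b"), release_t = rel)
  init2 <- initial_stopover(tr2, reg)
  expect_equal(init2$duration_days, 4)
  expect_true(init2$minimum_estimate)
  # first detection beyond 20 km of release -> no initial stopover
  tr3 <- make_track(rel + c(0, 3600), c("R3", "R3"), release_t = rel,
                    release_lat = 53.75, release_lon = 8.0) # R3 is ~54 km away
  expect_true(is.na(initial_stopover(tr3, reg)$duration_days))
})

test_that("initial stopover ignores detections after the first outside-cluster one", {
  reg <- tiny_registry()
  rel <- utc("2018-04-01 10:00:00")
  base <- make_track(rel + c(0, 86400, 1.5 * 86400), c("R1", "R1", "R2"), release_t = rel)
  more <- make_track(rel + c(0, 86400, 1.5 * 86400, 2 * 86400, 3 * 86400),
                     c("R1", "R1", "R2", "R1", "R3"), release_t = rel)
  expect_equal(initial_stopover(base, reg)$duration_days,
               initial_stopover(more, reg)$duration_days)
})

test_that("segment labels follow the dwell and speed rules", {
  reg <- tiny_registry()
  t0 <- utc("2018-04-02 00:00:00")
  cfg <- segmentation_config()
  # 90 min at one receiver -> along-track stopover
  s <- classify_segments(make_track(t0 + c(0, 2700, 5400), rep("R2", 3)), reg, cfg)
  expect_equal(s$label, "along_track_stopover")
  # two receivers 13.1 km apart crossed in 20 min (~11 m/s) -> flight
  s <- classify_segments(make_track(t0 + c(0, 1200), c("R1", "R2")), reg, cfg)
  expect_true(all(s$label == "flight"))
  # slow transition (0.1 m/s over 13.1 km) but within 3 d / 32 km -> stopover move
  s <- classify_segments(make_track(t0 + c(0, 36.4 * 3600), c("R1", "R2")), reg, cfg)
  p <- attr(s, "pieces")
  expect_equal(p$label[p$kind == "move"], "along_track_stopover")
  # slow transition to a receiver beyond 32 km -> unknown
  reg_far <- rbind(reg, data.frame(receiver_id = "FAR", lat = 54.40, lon = 8.0,
                                   is_island_site = FALSE)) # ~44 km from R1
  s <- classify_segments(make_track(t0 + c(0, 72 * 3600), c("R1", "FAR")), reg_far, cfg)
  p <- attr(s, "pieces")
  expect_equal(p$label[p$kind == "move"], "unknown")
  # 20-min single-receiver visit between two flights -> flight throughout
  tr <- make_track(t0 + c(0, 1200, 2400, 3600, 4800),
                   c("R1", "R2", "R2", "R3", "R3"))
  s <- classify_segments(tr, reg, cfg)
  expect_equal(unique(s$label), "flight")
  # dwell in the 35 min - 1 h gap -> unknown
  s <- classify_segments(make_track(t0 + c(0, 45 * 60), c("R2", "R2")), reg, cfg)
  expect_equal(s$label, "unknown")
})

test_that("segments partition the detections exactly once", {
  set.seed(31)
  for (rep in 1:20) {
    rt <- random_track(6, sample(5:40, 1))
    s <- classify_segments(rt$track, rt$registry)
    lab <- attr(s, "detection_labels")
    det <- rt$track$detections
    expect_length(lab, nrow(det))
    # every detection's timestamp is covered by exactly one segment run
    expect_equal(sum(s$n_detections), nrow(det))
    expect_true(all(s$t_start <= s$t_end))
    expect_true(all(diff(as.numeric(s$t_start)) >= 0))
  }
})

test_that("classification equals the brute-force oracle on random tracks", {
  set.seed(32)
  cfg <- segmentation_config()
  for (rep in 1:100) {
    rt <- random_track(sample(3:8, 1), sample(2:50, 1))
    s <- classify_segments(rt$track, rt$registry, cfg)
    expect_identical(attr(s, "detection_labels"),
                     oracle_detection_labels(rt$track$detections, cfg))
    mv <- attr(s, "pieces")
    mv <- mv[mv$kind == "move", , drop = FALSE]
    orc <- oracle_movement_labels(rt$track$detections, rt$registry, cfg)
    expect_identical(mv$label, orc$label)
  }
})

test_that("per-individual duration metrics follow their conventions", {
  reg <- tiny_registry()
  rel <- utc("2018-03-20 10:00:00")
  # along-track stopover additivity
  t0 <- utc("2018-04-02 00:00:00")
  tr <- make_track(t0 + c(0, 2 * 3600, 30 * 3600, 32 * 3600, 33 * 3600),
                   c("R1", "R1", "R3", "R3", "R3"))
  s <- classify_segments(tr, reg)
  stops <- s[s$label == "along_track_stopover", ]
  expect_equal(along_track_stopover_days(s),
               sum(as.numeric(stops$t_end) - as.numeric(stops$t_start)) / 86400)
  expect_true(is.na(along_track_stopover_days(
    classify_segments(make_track(t0 + c(0, 600), c("R1", "R2")), reg))))
  # study-area days are calendar-date differences
  tr <- make_track(c(rel + 3600, utc("2018-04-04 02:00:00")), c("R1", "R2"),
                   release_t = rel)
  expect_equal(days_at_study_area(tr), 15)
  tr <- make_track(rel + 2 * 3600, "R1", release_t = rel)
  expect_equal(days_at_study_area(tr), 0)
  tr <- make_track(utc("2018-03-21 00:30:00"), "R1", release_t = rel)
  expect_equal(days_at_study_area(tr), 1)
})

test_that("daily mean speed uses whole-day ceiling and qualifying moves only", {
  reg <- tiny_registry()
  t0 <- utc("2018-04-02 00:00:00")
  d12 <- gc_distance(54.00, 8.00, 54.118, 8.00)
  d23 <- gc_distance(54.118, 8.00, 54.236, 8.00)
  # two flight hops spanning 0.5 h each with a 47 h stopover between
  tr <- make_track(t0 + c(0, 1800, 1800 + 47 * 3600, 3600 + 47 * 3600),
                   c("R1", "R2", "R2", "R3"))
  s <- classify_segments(tr, reg)
  # qualifying time = 2 * 0.5 h plus the 47 h stopover dwell is *not* a move
  expect_equal(daily_mean_speed(s), (d12 + d23) / 1)
  # no qualifying movement -> NA
  expect_true(is.na(daily_mean_speed(
    classify_segments(make_track(t0 + c(0, 7200), c("R1", "R1")), reg))))
})

test_that("flight start phase maps to the night-fraction axis", {
  reg <- tiny_registry()
  ev0 <- sun_events(as.Date("2018-04-10"), reg$lat[2], reg$lon[2])
  ev1 <- sun_events(as.Date("2018-04-11"), reg$lat[2], reg$lon[2])
  night <- as.numeric(ev1$sunrise_utc) - as.numeric(ev0$sunset_utc)
  for (frac in c(0, 0.5, 1)) {
    start <- ev0$sunset_utc + frac * night
    tr <- make_track(c(start, start + 1200), c("R1b", "R2"))
    s <- classify_segments(tr, reg)
    ph <- flight_start_phase(s, reg)
    expect_equal(unname(ph[1]), frac, tolerance = 1e-6)
  }
})
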