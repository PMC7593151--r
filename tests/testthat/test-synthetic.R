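small_cfg <- function(...) {
  sim_config(seed = 99, n_per_group = 3, seasons = "autumn", ...)
}

test_that("receiver array has the configured layout and island flag", {
  reg <- make_receiver_array(sim_config())
  expect_equal(nrow(reg), 12 + 11 + 1)
  expect_equal(sum(reg$is_island_site), 1)
  expect_false(anyDuplicated(reg$receiver_id) > 0)
  # receivers are mutually farther apart than the cluster radius
  d <- outer(seq_len(nrow(reg)), seq_len(nrow(reg)), function(i, j) {
    gc_distance(reg$lat[i], reg$lon[i], reg$lat[j], reg$lon[j])
  })
  expect_gt(min(d[upper.tri(d)]), 2.6)
  bad <- sim_config()
  bad$geometry$leg_a$n <- 0
  expect_error(make_receiver_array(bad), "empty")
})

test_that("simulation is deterministic: same seed, byte-identical output", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(small_cfg(), dir = d1)
  simulate_study(small_cfg(), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("nocturnal flights stay strictly within the night", {
  cfg <- sim_config(seed = 13, n_per_group = 4, seasons = c("autumn", "spring"))
  sim <- simulate_tracks(cfg)
  for (bird in sim$birds) {
    if (bird$archetype != "nocturnal") next
    for (tr in bird$bouts) {
      t0 <- tr$t[1]
      t1 <- tr$t[nrow(tr)]
      ev0 <- sun_events(as.Date(t0) - 1, tr$lat[1], tr$lon[1])
      ev1 <- sun_events(as.Date(t0), tr$lat[1], tr$lon[1])
      ev2 <- sun_events(as.Date(t0) + 1, tr$lat[1], tr$lon[1])
      sunsets <- c(ev0$sunset_utc, ev1$sunset_utc, ev2$sunset_utc)
      last_sunset <- max(sunsets[sunsets <= t0])
      sunrises <- c(ev1$sunrise_utc, ev2$sunrise_utc)
      next_sunrise <- min(sunrises[sunrises > last_sunset])
      expect_gte(as.numeric(t0), as.numeric(last_sunset))
      expect_lte(as.numeric(t1), as.numeric(next_sunrise))
    }
  }
})

test_that("diurnal flights start within the dawn window", {
  cfg <- sim_config(seed = 14, n_per_group = 6, seasons = "autumn")
  sim <- simulate_tracks(cfg)
  for (bird in sim$birds) {
    if (bird$archetype != "diurnal") next
    for (tr in bird$bouts) {
      ph <- night_fraction(tr$t[1], tr$lat[1], tr$lon[1])
      expect_gt(ph, 0.6) # late night through morning, never early night
    }
  }
})

test_that("offshore probability zero produces no offshore truth", {
  cfg <- small_cfg()
  for (sp in names(cfg$species_params)) cfg$species_params[[sp]]$p_offshore <- 0
  sim <- simulate_tracks(cfg)
  expect_true(all(sim$truth$birds$route == "alongshore"))
})

test_that("detection emission honours probability and false-positive construction", {
  cfg <- small_cfg(fp_rate = 0.1)
  reg <- make_receiver_array(cfg)
  sim <- simulate_tracks(cfg)
  det <- emit_detections(sim, reg, cfg)
  is_fp <- attr(det, "is_false_positive")
  expect_equal(length(is_fp), nrow(det))
  expect_true(all(det$fp_score[is_fp] >= 0.67))
  # the standard filter removes exactly the injected false positives
  kept <- filter_false_positives(det, filter_config())
  expect_equal(nrow(kept), sum(!is_fp))
  # p_detect = 0 silences the network entirely (recaptures may remain)
  cfg0 <- small_cfg(p_detect = 0, p_detect_island = 0, fp_rate = 0)
  for (sp in names(cfg0$species_params)) cfg0$species_params[[sp]]$p_recapture <- 0
  det0 <- emit_detections(simulate_tracks(cfg0), reg, cfg0)
  expect_equal(nrow(det0), 0)
  # emitted table is valid pipeline input: write, read, identical instants
  dir <- withr::local_tempdir()
  p <- file.path(dir, "det.csv")
  write_detections(det, p)
  rt <- read_detections(p, reg)
  expect_equal(nrow(rt), nrow(det))
  expect_equal(rt$t, det$t)
})

test_that("a bird overflying the array is caught by multiple distinct receivers", {
  cfg <- small_cfg(p_detect = 1, fp_rate = 0)
  reg <- make_receiver_array(cfg)
  sim <- simulate_tracks(cfg)
  det <- emit_detections(sim, reg, cfg)
  per_bird <- tapply(det$receiver_id, det$tag_id, function(x) length(unique(x)))
  expect_true(all(per_bird >= 4))
})
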