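# independent brute-force oracles, deliberately unoptimised: plain loops
# applying each rule per detection (or per detection pair), no run-length
# encoding, no vectorisation

# per-detection behavioural label: scan outward for the maximal
# same-receiver window containing detection i, then apply the dwell rules
oracle_detection_labels <- function(det, cfg) {
  n <- nrow(det)
  out <- character(n)
  for (i in seq_len(n)) {
    j <- i
    while (j > 1 && det$receiver_id[j - 1] == det$receiver_id[i]) j <- j - 1
    k <- i
    while (k < n && det$receiver_id[k + 1] == det$receiver_id[i]) k <- k + 1
    dwell <- as.numeric(det$t[k]) - as.numeric(det$t[j])
    out[i] <- if (dwell > cfg$stop_dwell_min_h * 3600) {
      "along_track_stopover"
    } else if (dwell < cfg$short_visit_max_min * 60) {
      "flight"
    } else {
      "unknown"
    }
  }
  out
}

# per-pair movement label for each consecutive detection pair at distinct
# receivers
oracle_movement_labels <- function(det, registry, cfg) {
  out <- data.frame(i = integer(), label = character())
  for (i in seq_len(nrow(det) - 1)) {
    if (det$receiver_id[i] == det$receiver_id[i + 1]) next
    a <- registry[registry$receiver_id == det$receiver_id[i], ]
    b <- registry[registry$receiver_id == det$receiver_id[i + 1], ]
    dist <- gc_distance(a$lat, a$lon, b$lat, b$lon)
    dt <- as.numeric(det$t[i + 1]) - as.numeric(det$t[i])
    speed <- if (dt > 0) dist * 1000 / dt else Inf
    lab <- if (speed >= cfg$flight_speed_min_ms) {
      "flight"
    } else if (dt <= cfg$stop_gap_max_days * 86400 && dist < cfg$stop_dist_max_km) {
      "along_track_stopover"
    } else {
      "unknown"
    }
    out <- rbind(out, data.frame(i = i, label = lab))
  }
  out
}

# closed-form Kruskal-Wallis H without tie correction
oracle_kw_closed_form <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  off <- 0
  s <- 0
  for (g in groups) {
    rbar <- mean(r[off + seq_along(g)])
    s <- s + length(g) * rbar^2
    off <- off + length(g)
  }
  12 / (N * (N + 1)) * s - 3 * (N + 1)
}
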