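---
title: "coasttrack: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coasttrack: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coasttrack)
```

# Scope and data model

`coasttrack` analyses individually radio-tagged songbird migrants
recorded by a coastal array of automated receivers. The atomic datum is a
*detection* — tag, UTC timestamp, receiver — optionally carrying an
estimated false-positive probability from an upstream classifier. The
package never models the radio layer itself: it starts from a detection
table, a receiver registry (with an island flag for offshore sites) and a
deployment table, and produces per-individual behavioural metrics, routing
classifications and group statistics. All timestamps are handled in UTC
throughout; local time is presentation only.

# Filtering

Detections with a false-positive score at or above `fp_threshold`
(default 0.67) are removed. The direction of the threshold — drop at or
above, keep below — is a documented choice: the upstream score estimates
the probability of *being* a false positive, and a conservative cut at
0.67 removes most radio-noise artefacts while keeping genuine tracks
intact. Unscored detections and physical recaptures at the deployment
site are always kept; the filter is idempotent and its output is a strict
subset of its input.

# Initial stopover

The release site is matched to the first receiver that detected the bird,
provided that receiver is within `initial_radius_km` (20 km). The
deployment *cluster* is that receiver plus all registry receivers within
`cluster_radius_km` (2.6 km) of it; cluster membership is computed once
from the first-detecting receiver, without transitive chaining of 2.6 km
links — chains could silently grow the cluster along a dense coastline
and bias durations upward. The initial stopover runs from *release* (not
first detection) to the first detection outside the cluster, consistent
with nocturnal migrants showing sub-day durations (release one morning,
departure the following night). Birds never detected outside the cluster
get a *minimum estimate* ending at their last detection. If the first
detection is beyond 20 km no initial stopover is recorded; we anchor the
rule to the first detection and do not re-open it if the bird later
returns to the deployment area, so the estimate cannot be inflated by
late revisits.

# Behavioural segmentation

After excising the initial-stopover window, a track decomposes into
single-receiver *dwell runs* and *movements* between consecutive runs.
The rules, all thresholds in `segmentation_config()`:

| piece | condition | label |
|---|---|---|
| dwell | > 1 h at one receiver | along-track stopover |
| dwell | < 35 min at one receiver | flight (bird passing through) |
| dwell | 35 min – 1 h | unknown |
| movement | 5–26 m/s over ground | flight |
| movement | implied speed > 26 m/s | flight (simultaneous detections) |
| movement | < 5 m/s, next detection ≤ 3 d and < 32 km | along-track stopover |
| movement | other slow movement | unknown |

The 35 min–1 h dwell band is not covered by either published rule; it
falls to `unknown` rather than being absorbed into a neighbouring class,
which keeps the mapping total and honest. Adjacent pieces with equal
labels merge into segments, so every detection belongs to exactly one
segment (its dwell run) and movement pieces only extend segment spans.
The same rules are re-implemented as a deliberately unoptimised
per-detection evaluator in the test helpers, and the two routes must
agree exactly on randomised tracks.

*Simultaneous* detections are operationalised as implied ground speed
above 26 m/s rather than exact time equality, so clock-skewed
near-simultaneous registrations at two receivers are handled identically.

## Durations and speeds

Along-track stopover duration is the summed span of such segments
(fractional days). Time at the study area is a whole-day calendar
difference between release date and last-detection date. Daily mean
movement speed divides summed movement distance over flight and
slow-stopover movements by their summed duration in whole days (ceiling,
minimum one day — avoiding division by zero for sub-day recordings). Two
choices here were genuinely open:

* the denominator uses the *union of qualifying movement intervals*, not
  the release-to-last-detection span, because the metric describes speed
  while moving, not residence;
* simultaneous detections are excluded from the distance sum. They are
  detection artefacts of overlapping coverage, not movement; under dense
  synthetic coverage including them inflates the metric several-fold
  (alternating registrations between two receivers 13 km apart each count
  13 km). Real sparse arrays suffer less, but the exclusion makes the
  metric stable across detection densities.

# Routing

Receiver-to-receiver headings (initial great-circle bearing) inside the
seasonal sector — 315° through north to 90° in spring, 135°–270° in
autumn, boundaries inclusive — accumulate into progress length, all
others (including reverse migration) into detour length; simultaneous
transitions are excluded. Progress plus detour equals total
non-simultaneous transition length by construction, and this conservation
is property-tested.

Sustained flights are windows of continuous recording (all gaps < 7 h —
the only continuity notion used) that span either ≥ 4 distinct receivers
pairwise > 2.6 km apart or two receivers ≥ 35 km apart. The mutually
spaced subset is selected greedily in order of first detection; a greedy
maximal set is deterministic and can only undercount, never overcount,
the criterion. Only the first sustained flight per bird enters group
comparisons, to avoid multiple sampling. Its *start time* is the
departure from the window's first receiver (last detection there before
the first receiver change): windows often begin with a long stopover
dwell, and the time of interest is when the flight began, not when the
recording began.

A sustained flight is offshore when it includes an island receiver, or
when it crosses latitude 54° meeting both threshold tests: in autumn
(southbound) the last receiver above 54° must lie above 54.135° N and the
first receiver below 54° west of 8.08° E. In spring the temporal roles
mirror (first above-54 receiver takes the latitude test, last below-54
receiver the longitude test) — the compressed "vice versa" in the source
material is read as a temporal mirror because the bird traverses the
split in the opposite direction; both thresholds are configurable.

# Solar events and the night-fraction axis

Sunrise and sunset use the NOAA solar position algorithm (Meeus
low-precision series) at zenith 90.833°, two-pass refined at the
first-pass event time; agreement with an independently generated
reference almanac (python-astral, frozen as a plain-text fixture) is
within 0.4 min over random mid-latitude date/location pairs, against a
2-minute acceptance tolerance. Events are reported for the requested UTC
calendar date; at extreme longitudes the event of a neighbouring local
day is selected when it is the one falling on that UTC date. Polar
day/night raises an error rather than returning fabricated times.

The night-fraction axis maps a timestamp to 0 at the most recent sunset
and 1 at the next sunrise, linear in between, making flight start times
comparable across dates and night lengths. Daytime instants extend the
axis continuously (> 1 after sunrise, < 0 before sunset), attached to
whichever night boundary is closer; a diurnal migrant departing 2 h after
sunrise in a 12 h night maps to ≈ 1.17.

# Statistics

Group summaries are medians with 25 %/75 % quantiles using
linear-interpolation (type 7) quantiles — the convention that produces
fractional quartiles from integer-valued day counts. Species comparisons
use the tie-corrected Kruskal–Wallis H against χ²(k−1); when every value
is identical the statistic is 0 with p = 1. Proportion comparisons use
the two-sample equal-proportions χ² with continuity correction
min(0.5, |O−E|) and df = 1 — with this correction, tables whose cells sit
within 0.5 of expectation give exactly 0, which is why near-identical
proportions report "χ² < 0.01". This operationalisation was verified
against all nine published proportion statistics before implementation
and is pinned by the acceptance suite. Fat scores are summarised as
median ± mean absolute deviation from the median. Two-sided p-values
throughout; no multiple-testing correction is applied.

# The synthetic world

The generator (`sim_config()`, `simulate_tracks()`, `emit_detections()`)
states a world rather than tuning one:

* **Geometry.** Twelve receivers down a meridional coastline leg
  (55.05° N → 53.75° N), eleven along a zonal leg (8.10° E → 6.55° E),
  spacing ≈ 10–13 km, plus one island receiver at 54.1821° N, 7.8925° E.
  Releases happen at a coastal receiver on each leg (autumn on the
  meridional leg, spring on the zonal one), within the species' real
  catching windows (late September–mid October; late March for the
  diurnal species and April for the nocturnal one).
* **Archetypes.** The diurnal archetype starts flights uniformly within
  ±2 h of sunrise; the nocturnal one in the first 5–30 % of the night,
  with ground speed raised if needed so the bout lands before sunrise —
  nocturnal flights are strictly night-bounded by construction. Ground
  speeds are drawn from 8–14 m/s (diurnal) and 9–16 m/s (nocturnal),
  inside the 5–26 m/s plausibility band.
* **Behaviour.** Initial stopover durations are log-normal with medians
  at the published group values (diurnal 4.9 d spring / 10.5 d autumn;
  nocturnal 0.6 / 0.9 d; σ~log~ 0.6/0.5). Roughly a third of birds cross
  the bight offshore via the island; about 45 % (diurnal) / 20 %
  (nocturnal) insert an along-track stopover (log-normal, median 1 d);
  about half / 40 % fly one backward detour leg first. A small fraction
  is "recaptured" at the deployment site.
* **Detection.** A flying bird is sampled every 120 s and detected by
  every receiver within 12 km with probability `p_detect` (default 0.9; 1
  at the island); a grounded bird every 30 min within 2 km. The short
  ground range reflects the physics of a perched transmitter and is what
  keeps the deployment cluster from leaking into neighbouring receivers.
  False positives are injected at 2 % of true detections with scores
  drawn in [0.67, 1], so the standard filter removes exactly them.

What the generator does *not* emulate: wind, variable airspeeds, antenna
beam patterns, signal strength, mortality, and real landscape choice. A
green recovery test therefore establishes that the pipeline's rules
invert the generator's stated world — not that they are unbiased on real
radio data. Two known consequences of dense synthetic coverage are
documented rather than patched: short backward detour legs largely
disappear into simultaneous-detection exclusion (both receivers see the
bird at once), so detour lengths are not a recovery target; and segment
labels at stopover/flight boundaries misclassify the one or two
detections where a run straddles the transition, bounding label agreement
near, not at, 100 %.

# Numerical conventions

Distances use the haversine on a 6371 km sphere (sub-0.5 % error at array
scale, far below any threshold's granularity). Speed-class boundaries are
closed on the flight side (exactly 5 m/s is flight); sector boundaries
are inclusive (ties at 90°/135°/270°/315° are progress) — both
measure-zero choices on continuous data. The dwell rules use strict
inequalities as published (> 1 h, < 35 min). Equal timestamps at one
receiver deduplicate to the first row; equal timestamps at different
receivers are kept as simultaneous detections. Degenerate inputs (empty
tracks, single-receiver tracks, empty detection tables) return empty or
`NA` results, never errors, except where a contract is violated (unknown
receiver ids, tags without deployments, invalid coordinates).

# Limitations

* The pipeline is receiver-bound: it cannot see movement between
  receivers, so all durations at the array edge are minimum estimates.
* The 0.67 filter direction, the 35 min–1 h unknown band, the
  union-of-intervals speed denominator and the spring offshore mirror are
  documented interpretations of compressed method descriptions; each is a
  single configurable parameter or rule.
* Kruskal–Wallis p-values rely on the χ² approximation, questionable for
  the smallest groups; the package reports the statistic either way and
  applies no post-hoc procedure.
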