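---
title: "Quantifying electrolocation motor patterns from EOD-triggered tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying electrolocation motor patterns from EOD-triggered tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eodkin)
```

## The measurement model

Pulse-type weakly electric fish such as *Gnathonemus petersii* probe their
surroundings by emitting brief electric organ discharges (EODs) and reading
the object-induced distortions of the resulting field. Because each EOD is a
discrete sensory acquisition, a camera triggered on the EODs samples the
animal's pose exactly at the moments sensory input arrives: one frame per
pulse, at a variable rate of roughly 25 Hz, while the fish swims at roughly
10 cm/s. At that rate and speed, successive frames are about 0.4 cm of travel
apart — the natural spatial resolution of this sampling scheme.

`eodkin` analyses such recordings as a table of frames (time, head position
in cm, heading in degrees) per session. All stages downstream are:

1. **Egocentric kinematics.** For each inter-frame interval the head
   displacement is rotated into the body frame of the leading frame, giving
   thrust (along the heading), slip (positive to the animal's left) and yaw
   (wrapped heading change, counterclockwise positive), each divided by the
   realized inter-pulse interval. Velocities attach to the leading frame;
   the last frame of a contiguous segment carries none, and no velocity ever
   spans a tracking gap.
2. **Prototypical movements (PMs).** The velocity triples are z-scored —
   thrust and slip jointly with one pooled mean and SD, yaw on its own — so
   that translational and rotational channels become comparable, and
   clustered with k-means. The cluster count is chosen by scanning
   k = 2..50: per k, replicate fits must induce the same partition
   (stability) and the partition must be compact (silhouette quality).
3. **Homogeneous chains.** Maximal runs of at least 10 consecutive frames
   sharing one PM label. Runs of the backward-capable PM 01 are split by
   mean thrust at −2 cm/s into *backwards swimming* (below) and *stationary
   behavior* (at or above; the boundary is inclusive on the stationary side,
   a choice this package documents because the rule itself does not decide
   it). Onset-triggered averages (nearest-frame resampling onto a 0.04 s
   grid, t-based 95% CIs, bins with fewer than two contributions masked)
   characterize the kinematics and EOD frequency around chain starts.
4. **Super-prototypical movements (SPMs).** Labels are run-collapsed to
   transitions only; a first-order Markov model supplies P(next | current)
   and token stationary frequencies. Every 5-transition chain has overall
   probability stationary(s0) × Π P(s(i+1) | s(i)); the 100 most probable
   chains are found by best-first search with an exact dynamic-programming
   bound (provably identical to exhaustive enumeration, which the tests
   verify on small alphabets). Mirror-image PM pairs are then pooled and
   sequences of equal token composition merged, yielding the reduced SPM
   catalog whose occurrence frequencies are contrasted between the object
   and no-object conditions.
5. **Spatial conditionals and electromotor analytics.** An SPM occurrence is
   an *object approach* if it ends within 4 cm of the object (head-to-cube
   distance, measured to the cube centre by default; a surface-distance
   option exists) with the final distance smaller than the initial one; the
   inverted conditional defines *object departure* — the two sets are
   disjoint by construction. The instantaneous EOD frequency is the
   reciprocal of the preceding inter-pulse interval, z-scored per recording
   night to absorb drifts in basal rate. Occupancy and mean-frequency maps
   use 1 cm² bins; distance profiles use 1 cm distance bins and report both
   the per-bin conditional fraction and the whole-dataset-relative fraction,
   because either normalisation is defensible and they answer slightly
   different questions. Post-chain transition shifts are tested against a
   permutation null (windows placed uniformly at random, 999 draws,
   two-sided empirical p, Holm-corrected). Group comparisons use the
   Wilcoxon rank-sum test for two groups and Kruskal-Wallis with
   tie-corrected Dunn post-hoc z-statistics (Holm-adjusted) otherwise.

## Choosing the cluster count

The scan's concrete criteria are deliberately explicit, since "stability and
quality" admit many formalisations:

- **Stability** of a candidate k is the mean pairwise adjusted Rand index
  between `n_replicates = 20` partitions of the *full* dataset, each induced
  by a k-means fit on its own seeded subsample of at most 10,000 points
  (nearest-centroid prediction extends a fit to all frames). This is
  resampling-based stability: a genuine cluster structure reappears whatever
  subsample it is estimated from, whereas arbitrary splits of a continuum
  land differently each time.
- **Quality** is the mean silhouette width on one fixed seeded subsample of
  2,000 points (silhouette is O(n²) and needs no more than this to rank
  candidate k).
- **Selection** takes the largest k whose stability is at least 0.9 *and*
  whose quality lies within 5% of the running maximum over the k scanned so
  far. Preferring larger k resolves the finest stable, near-optimal
  partition; the quality margin protects against stable but worthless
  refinements (a consistent bisection of one elongated cluster is stable yet
  measurably less compact).

Each k-means fit uses greedy k-means++ seeding (several candidate centers
per step, keeping the potential-minimizing one) with `n_init = 10`
independent seedings for final fits and `n_init = 5` within the scan,
keeping the lowest-cost solution. Plain single-seed k-means++ reaches the
global optimum on this kind of mixture only a minority of the time, which
would make replicate disagreement measure seeding luck rather than cluster
structure. Lloyd iterations stop when the cost change falls below 1e−8 or
assignments stop changing (at most 300 iterations); ties in assignment go
to the lowest centroid index; a cluster that empties is re-seeded at the
point farthest from its assigned centroid. The Ward pre-scan
(`hierarchical_k_range`, 5,000-point seeded subsample, top-decile relative
merge-cost jumps) motivates the plausible k interval and is reported in the
model, but does not constrain the k-means scan.

After fitting, PMs are renumbered canonically: unpaired prototypes first by
increasing thrust (so the backward prototype is always PM 01), then mirror
pairs by increasing rotational amplitude with the positive-slip member
first. Mirror pairs are detected greedily by the score
|Δthrust| + |slip_i + slip_j| + |yaw_i + yaw_j| (accepted below 0.5),
computed on SD-normalised raw centroids rather than z-scored ones: the joint
translational z-shift moves the slip channel off zero, which would offset
the antisymmetry the score looks for.

Whether z-scoring should pool all data or work per fish and night is not
decidable from the method itself; the package pools by default (the cluster
model is a property of the pooled dataset) and exposes per-night
z-scoring for the EOD frequency, where nightly drifts in basal rate are a
documented phenomenon.

## The synthetic session generator

No tracking data are distributed with this package; the generator
(`generator_config()`, `generate_session()`) produces sessions with the
statistical structure the analysis assumes, plus per-frame ground truth, so
every stage is testable end to end.

What it emulates, with defaults chosen once as study conditions:

- **Geometry.** An 80 × 80 cm arena viewed through a centred 64 × 48 cm
  camera window, origin at the arena centre where a metal cube of 1–3 cm
  edge sits in the object condition; two shelters at (±28, 0) cm.
  Coordinates: x rightward, y upward, heading 0° along +x, counterclockwise
  positive — with the object at the origin, object distance is simply the
  Euclidean norm.
- **Prototypes.** Ten emission prototypes in (thrust, slip, yaw): one
  backward singleton PM 01 at (−3, 0, 0) cm/s, one forward singleton PM 02
  at (8, 0, 0), and four mirror pairs at (16, ±4, ±40), (12, ±6, ±90),
  (8, ±6, ±160), (5, ±4, ±240) (cm/s, cm/s, deg/s), spanning the continuum
  from maximal translation to maximal rotation. Emission SDs are 1 cm/s and
  10 deg/s (PM 01 thrust: 1.5 cm/s). These are free parameters of the
  generator — published prototypes for such recordings exist only in
  normalised form — and are flagged as such.
- **Behavior scripting.** Macro-behaviors (cruise, object approach,
  stationary probing, backwards swimming, object departure) are drawn with
  weights (0.55, 0.12, 0.10, 0.10, 0.13) and log-normal durations (medians
  2.5, 1.1, 0.8, 1.1, 1.1 s). Within a behavior, per-frame PM labels follow
  a first-order Markov chain over that behavior's prototype pool; approach
  and departure use the PM 02 / PM 07/08 alternation, steering by choosing
  the mirror member that turns toward (or away from) the object. Stationary
  and backwards probing are pure PM 01 runs distinguished by a thrust-mean
  override (−0.8 and −2.8 cm/s): together they reproduce the two-mode PM 01
  thrust distribution that motivates the −2 cm/s split, while keeping PM 01
  one cluster — the modes sit 1.3 emission SDs apart, wide enough for chain
  means (SE ≤ 0.5 cm/s at the 10-frame minimum length) to classify reliably,
  and too close for the cluster scan to resolve a spurious eleventh
  prototype. An approach is defined by reaching the object, so approach
  segments run until the head is within 2.5 cm (up to four times the drawn
  duration); within 10 cm the approach thrust mean ramps down linearly to a
  floor of 60%, producing the distance-referenced deceleration that the
  distance-referenced averages must recover. Scripts never place stationary
  and backwards segments back to back (their PM 01 runs would fuse into one
  chain of mixed thrust), probing phases are often followed by departures,
  and approaches by probing.
- **EOD trains.** Inter-pulse intervals are gamma distributed (shape 10 —
  strictly positive and regular-but-variable, as real pulse trains are)
  with mean 1/rate; the rate is a per-PM base rate (23.2, 22.8, 35.4, 35.4,
  27, 27, 25.5, 25.5, 32.4, 32.4 Hz — per-PM median rates reported for
  such recordings where available, interpolated for the middle pairs) times
  a gain of 1.3 within 5 cm of the object. The behavior mix makes the
  realized session mean rate ≈ 25 Hz and mean speed ≈ 10 cm/s.
- **Boundaries.** Near the view boundary the fish turns inward
  (thigmotactic wall avoidance); in the rare case integration still leaves
  the view, the position is reflected and the event is recorded as a frame
  gap — mirroring a heading in place is not a motion any fish performs, and
  the emulated recordings likewise excluded frames at the view edge, so the
  kinematic series is split there rather than polluted with impossible yaw
  values. Reflections are counted and reported, never silently clipped.
  In the no-object condition the script is cruising only, waypoints are
  biased toward the shelters and walls, and the empty centre is avoided —
  the condition differs from the object condition in exactly the ways the
  condition contrast is meant to detect.

All randomness flows through one generator seeded at session start, so equal
seeds give identical sessions; derived seeds (replicates, stages) come from
fixed integer offsets of the master seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: no body bending or midline curvature (heading is a
rigid pose), no tracking noise or misdetections, no social signalling
context, no object-size dependence of behavior, no electric-image physics,
and emission distributions are diagonal Gaussians, whereas real
within-cluster spread is heavier-tailed and correlated. Recovery rates
measured on synthetic sessions are therefore upper bounds on what identical
settings would achieve on video-tracked data.

## Numerical choices and degenerate inputs

- Angles live in (−180, 180]; wrapped differences make a +10° turn across
  the ±180 discontinuity read as +10°, never −350°.
- Frame indices and intervals are 1-based and inclusive throughout, the R
  convention; chains, tokens and occurrences all index rows of the
  kinematic record table.
- A constant kinematic channel makes z-scoring impossible and errors,
  naming the channel. Empty chain sets summarise to a count of zero, not
  NaN. Triggered averages mask grid points with fewer than two
  contributions; distance-referenced averages mask the spread of
  single-frame bins. Transition-matrix rows without outgoing transitions
  are flagged and excluded from enumeration. The SPM search breaks
  probability ties lexicographically, so rankings are reproducible.
- Transition weighting — "the frequency of a transition relative to the
  target PM's overall frequency" admits several readings — is implemented
  as the row-conditional P(next | current), the only choice under which
  chain probabilities define a proper Markov measure; the enrichment ratio
  P(i→j)/stationary(j) is retained descriptively. Chain probability includes
  the start token's stationary frequency. An SPM's occurrence frequency
  counts covered *frames* (union over overlapping occurrences) over total
  frames; occurrence-count normalisation is a one-line variant the catalog
  supports.

## Problem sizes

The test suite and the acceptance script size their simulations as the
package's own defaults: four sessions of 13,000 frames (≈ 52,000 kinematic
records, comparable to one experimental condition of such a study)
for the cluster-count scan, single 12,000–15,000-frame sessions for
recovery checks, and ≤ 9-point or ≤ 6-token instances wherever an
exhaustive oracle verifies a search-based operation exactly.

## Known limitations

The selection rule's 0.9 stability threshold and 5% quality margin are
conventions, not estimates; data with genuinely hierarchical structure can
defensibly support several k, and the full scan trace is retained so users
can inspect the trade-off rather than trust the argmax. Occurrence matching
uses each catalog entry's canonical token sequence; member sequences merged
by composition contribute probability mass but are not matched separately.
The permutation null for post-chain shifts treats window placements as
exchangeable, which ignores long-range nonstationarity in real sessions.
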