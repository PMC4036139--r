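# eodkin

Quantitative motor-pattern analysis for EOD-triggered tracking of pulse-type
weakly electric fish.

Pulse-type electric fish (e.g. *Gnathonemus petersii*) emit discrete electric
organ discharges (EODs) and sense the world through the object-induced
distortions of each pulse's field. Recording one video frame per EOD samples
the animal's pose exactly at its own sensory sampling times. `eodkin` turns
such recordings — and, in place of unavailable raw video data, faithful
synthetic sessions with ground truth — into a quantitative ethogram of
electrolocation behavior:

- **Egocentric kinematics**: per-interval thrust, slip and yaw velocities
  (`compute_kinematics()`), z-scored with joint translational scaling
  (`fit_scaler()`).
- **Prototypical movements (PMs)**: k-means clustering of the velocity
  triples with a Ward pre-scan (`hierarchical_k_range()`), greedy k-means++
  / Lloyd fits (`kmeans_fit()`), replicate-stability and silhouette-quality
  selection of the cluster count over k = 2..50 (`evaluate_k_scan()`), and
  mirror-pair detection (`find_mirror_pairs()`); all wrapped by
  `fit_pm_model()`. For a PM with label sequence probability
  P(s0…s5) = π(s0)·∏ P(s(i+1)|s(i)).
- **Homogeneous chains**: maximal PM runs of ≥ 10 frames
  (`extract_runs()`), the −2 cm/s split of PM 01 chains into stationary vs
  backwards swimming (`split_pm01()`), and onset-triggered averages with
  t-based 95% CIs (`triggered_average()`).
- **Super-prototypical movements (SPMs)**: a run-collapsed Markov
  transition model (`transition_matrix()`), exact best-first enumeration of
  the 100 most probable 5-transition chains (`enumerate_top_spms()`),
  mirror/composition merging into a reduced catalog (`reduce_spms()`),
  occurrence matching and condition contrasts (`condition_contrast()`).
- **Spatial conditionals and EOD analytics**: the 4-cm object-approach /
  departure filters (`approach_filter()`), occupancy and mean-fEOD maps at
  1 cm² (`occupancy_and_value_maps()`), distance profiles
  (`distance_profile()`), distance-referenced averages, post-chain
  transition shifts with a permutation null, and rank-based group tests
  (`group_compare()`).
- **Synthetic sessions**: `generator_config()` / `generate_session()`
  emulate EOD-triggered sampling at ~25 Hz, ~10 cm/s swim speed, an
  80×80 cm arena with 64×48 cm camera view, a central metal cube, scripted
  macro-behaviors with mirror-paired Gaussian PM emissions, and gamma
  inter-pulse intervals whose rate depends on the active PM and object
  distance — with per-frame ground truth.

The methods vignette (`vignettes/motor-pattern-analysis.Rmd`) documents the
model, every tunable parameter and the design decisions.

## Worked example

```r
library(eodkin)

cfg <- generator_config(n_frames_target = 6000)
bundle <- run_pipeline(cfg, seed = 5, n_sessions = 2, n_control = 1,
                       k = 10, n_replicates = 5)
s <- bundle$summary
s$pm_table
#>  pm thrust  slip     yaw fraction
#>   1  -2.02  0.00   -0.32   0.0688
#>   2   7.69 -0.01    0.31   0.2362
#>   3  15.97  4.03   40.01   0.0648
#>   4  16.00 -4.01  -39.91   0.0623
#>   5  11.95  5.97   89.91   0.0593
#>   6  11.95 -6.01  -90.29   0.0562
#>   7   7.91  5.99  160.03   0.1735
#>   8   7.91 -5.99 -160.20   0.1671
#>   9   5.02  4.10  238.78   0.0532
#>  10   5.02 -4.01 -239.45   0.0586

unlist(s[c("selected_k", "n_mirror_pairs", "catalog_size",
           "n_approach_chains", "n_approach_chains_control")])
#>               selected_k            n_mirror_pairs              catalog_size
#>                       10                         4                         5
#>        n_approach_chains n_approach_chains_control
#>                       13                         0

round(unlist(s[c("mean_rate_hz", "mean_speed_cms")]), 2)
#>   mean_rate_hz mean_speed_cms
#>          26.68           9.78

s$chain_counts
#> backwards stationary
#>        27         22
```

Reading the output: the ten fitted centroids reproduce the generator's
prototype table (PM 01 backward-capable, PM 02 low-velocity forward, four
mirror pairs with sign-opposed slip and yaw); mirror and composition
merging reduces the 100 most probable transition chains to 5 catalog
entries on this small run; the approach-bearing SPM yields 13
object-approach chains in the object condition and - because the 4-cm
conditional is object-specific - none in the control condition. Chain
counts are the >= 10-frame PM 01 runs split at -2 cm/s, and the realized
sampling statistics sit near the emulated 25 Hz and 10 cm/s.

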