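# floorplate

Analytics for multi-animal home-cage tracking with RFID floor plates.

Group-housed mice can be tracked continuously, without handling, by a grid
of RFID antennas under the cage floor: each detection is a
`(time, antenna ID, tag ID)` triple from a board of 96 tiles (12 × 8, each
5 cm × 5 cm). This package turns those raw logs into quantitative group
behavior for behavioral neuroscientists: per-second multi-animal
trajectories, circadian locomotor activity, pairwise social proximity, the
**close contact ratio (CCR)** sociability statistic, Cytoscape-ready social
networks, and group-level phenotyping by PCA and clustering. A built-in,
seeded home-cage simulator generates realistic raw logs with known ground
truth, so the entire pipeline is testable without animal data.

## The model in brief

- **Preprocessing.** Timestamps are truncated to whole seconds; within one
  animal-second only the first detection is kept; silent seconds inherit
  the last observed position (forward fill, no back-fill). The result is
  one row per animal per second with grid coordinates.
- **Activity.** Step distance `D[t+1] = 5·sqrt(dX² + dY²)` cm, summed over
  windows (`T = 7,200` samples for 2 h, `43,200` for 12 h); per-animal
  normalization to the maximum 2-h bin gives relative activity in
  [0, 100].
- **Proximity.** Pair distance `L[t]` is classified into Same (`L = 0`),
  Close (`L = 5` or `5√2` cm), Intermediate (`L = 10`, `5√5`, `10√2` cm)
  or Away (`L > 10√2` cm) — Chebyshev rings 0/1/2/≥3 on the tile grid. The
  CCR of a pair over a window is

  ```
  CCR = 100/T · Σ_t δ(L[t] ≤ 5√2)   (%)
  ```

  the percentage of time spent at Same or Close proximity.
- **Networks.** One edge per pair with weight `CCR/10`, exported as the
  tab-delimited `Source / Target / Edge betweenness` table Cytoscape
  imports.
- **Phenotyping.** Per animal: normalized activity in light (AL) and dark
  (AD), per-animal CCR in light (SL) and dark (SD); PCA on the four
  features, k-means with the cluster count chosen by maximum mean
  silhouette (inertia curve reported for elbow inspection). Chi-square on
  pooled category-seconds and step-down Holm–Šidák adjustment round out
  the statistics.

## Worked example

Simulate a 4-mouse, 24-h cage, recover trajectories from the noisy
detections, and compute activity and sociability:

```r
library(floorplate)
library(data.table)

sim  <- simulate_cohort(sim_params(n_mice = 4, hours = 24, seed = 42))
traj <- preprocess(sim$detections, sim$config)
traj[1:3]
#>    tag_id     second antenna_id     x     y observed
#> 1: TAG_01 1673337600         13     1     2     TRUE
#> 2: TAG_01 1673337601         13     1     2     TRUE
#> 3: TAG_01 1673337602         13     1     2     TRUE

steps <- step_distances(traj)
dcast(light_dark_totals(steps, sim$config), tag_id ~ label,
      value.var = "distance_cm")
#>    tag_id day 1 dark day 1 light
#> 1: TAG_01   194369.7    50621.16
#> 2: TAG_02   192659.2    49787.87
#> 3: TAG_03   193618.5    49474.58
#> 4: TAG_04   194540.8    49522.96
```

Every animal travels ~4× farther in the dark half-day than in the light —
the simulator's planted nocturnal movement contrast (0.8 vs 0.2 per-second
move probability), recovered through the full detection → preprocessing →
metric chain.

```r
st <- pair_window_stats(traj, phase_windows(sim$config))
st[1:2, .(tag_i, tag_j, label, ccr_pct, p_same, p_away)]
#>     tag_i  tag_j       label ccr_pct p_same p_away
#> 1: TAG_01 TAG_02 day 1 light    31.1  0.074  0.482
#> 2: TAG_01 TAG_02  day 1 dark    28.5  0.049  0.501

per_animal_ccr(ccr_matrix(st, window_id = 1L))
#> TAG_01 TAG_02 TAG_03 TAG_04
#>   29.9   29.7   29.6   29.6

edges <- build_edge_table(st[window_id == 1L])
write_edge_tsv(edges, "edges_day1_light.tsv")   # Cytoscape-ready
```

Each pair spends ~30% of the light period at Same/Close proximity (the
default moderate social attraction), and the per-animal score is the mean
over partners. `extract_features()`, `pca_embed()` and `select_k()` take
it from here to group phenotypes; see the methods vignette
(`vignettes/floorplate-methods.Rmd`) for the full model, parameter
meanings and validation design.

A command-line front end over the same functions is installed at
`inst/cli/floorplate` (subcommands `simulate`, `preprocess`, `locomotion`,
`proximity`, `network`, `phenotype`).

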