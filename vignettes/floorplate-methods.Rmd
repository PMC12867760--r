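---
title: "Methods: from RFID floor-plate logs to group behavioral phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from RFID floor-plate logs to group behavioral phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floorplate)
library(data.table)
```

## The measurement model

An RFID floor plate is a grid of antenna tiles under a home cage; each tile
reports which subcutaneously tagged animal sits above it. The default board
in `grid_geometry()` has 96 tiles (antenna IDs 1–96) in 12 columns × 8 rows
of 5 cm × 5 cm. A raw log is a stream of `(timestamp, antenna ID, tag ID)`
events with sub-second timestamps; several events can fall within one
second (re-reads, or a spurious read on a neighboring tile), and seconds can
be silent for an animal that sits still over a tile edge or is briefly
shielded.

Position is therefore a *tile index*, not a continuous coordinate: every
distance this package reports is a multiple of the 5 cm pitch, and no
sub-tile interpolation is attempted. Antenna numbering is mapped to
coordinates row-major (antenna 1 → (1,1), antenna 13 → (1,2)); the
convention is isolated in `antenna_to_xy()` / `xy_to_antenna()` so an
alternative board layout is a one-line change.

## Preprocessing

`preprocess()` chains four steps, each exported for testing and reuse:

1. **Parse** (`parse_raw_log()`): tolerant reader for tab- or
   whitespace-delimited lines; `#` comments and blank lines are skipped,
   malformed lines are counted and reported (or abort under
   `strict = TRUE`). Timestamps are wall-clock local time and assumed
   monotone; if not, detections are stably re-sorted with a warning.
2. **Truncate** (`truncate_to_seconds()`): fractional seconds are
   *removed* (floor), not rounded — the per-second grid is the analysis
   clock.
3. **Deduplicate** (`dedupe_first_wins()`): within one animal-second only
   the first event by file order survives. After truncation sub-second
   order is gone, so file order is the only defensible tie-break.
4. **Forward fill** (`forward_fill()`): silent seconds inherit the last
   observed position (`observed = FALSE` marks them). There is no
   back-fill: seconds before an animal's first detection have no preceding
   value and are absent, and downstream code must not assume coverage
   there. By default the fill extends to the end of the configured session
   (`fill_to = "session"`); `fill_to = "last"` stops at the last detection,
   and `max_fill_gap` caps how long a stale position may be carried —
   the guard for a detached transponder, whose last position would
   otherwise be propagated for days. A `drop_tags` argument excludes such
   an animal entirely, which is how the dropped-animal analysis of a
   16-animal cohort with one detached tag is reproduced.

The resulting trajectory table has exactly one row per animal-second with
in-bounds integer coordinates — the substrate every metric builds on.

## Locomotor activity

Step distance between consecutive seconds is
$D_{t+1} = p\sqrt{(X_{t+1}-X_t)^2 + (Y_{t+1}-Y_t)^2}$ with $p$ the pitch in
cm, and windowed travel distance is the sum of steps whose *arrival*
second falls in the window. Attribution by arrival second makes window
sums additive over any partition of the session and gives an isolated
window of $T$ samples exactly $T-1$ steps (7,199 for a 2-h window), the
form of the printed summation bound. Forward-filled spans contribute zero
distance by construction — a consequence worth remembering when dropout is
heavy: heavy `p_miss` biases distance downward, never upward.

Windows come from `make_windows()` (fixed-width bins, 2 h by default) and
`phase_windows()` (successive 12-h light/dark half-days), both anchored at
the lighting schedule in `session_config()` (12:12, lights on 08:00 by
default; animals are introduced at lights-on, so a session normally starts
on a boundary — if not, windows anchor to the next lights-on with a
warning). `normalize_activity()` rescales each animal by its own maximum
windowed distance over the whole recording (the 2-h bin width of the
heatmaps; configurable), so `relative_activity` is 100 in at least one bin
for every animal that moved: this removes between-animal absolute-speed
differences and leaves the temporal *pattern*, which is what the
activity heatmaps and the AL/AD features consume.

## Pairwise proximity and the CCR

For each unordered pair the interindividual distance
$L_t = p\sqrt{(X^{(i)}_t-X^{(j)}_t)^2+(Y^{(i)}_t-Y^{(j)}_t)^2}$ is
classified into four concentric categories: **Same** ($L=0$), **Close**
(adjacent tiles, $L \in \{5, 5\sqrt2\}$ cm), **Intermediate** (second ring,
$L \in \{10, 5\sqrt5, 10\sqrt2\}$ cm), **Away** ($L > 10\sqrt2$ cm). On the
integer grid these rings coincide with Chebyshev distance 0/1/2/≥3, so the
implementation classifies on squared grid-index distance with exact integer
comparisons — there are no floating-point boundary questions, and the
equivalence is verified by brute force over all 96² coordinate pairs in the
test suite.

The **close contact ratio** of a pair over a window of $T$ seconds is

$$\mathrm{CCR} = \frac{100}{T}\sum_{t=1}^{T}\delta(L_t \le 5\sqrt2),$$

the percentage of time at Same or Close proximity. The formula assumes a
fully covered window; with partial coverage (an animal introduced late, a
tag lost) the divisor becomes the number of covered seconds — both animals
present — and the coverage fraction is always reported, so CCR stays a
proportion and the detached-tag scenario stays well defined. A window with
zero covered seconds yields a missing value, never NaN arithmetic.

Group-level category proportions pool *seconds* across pairs rather than
averaging per-pair ratios; the two differ only under unequal coverage, and
pooled counts are also the correct input for the light/dark chi-square
test. Per-animal sociability (`per_animal_ccr()`) is the mean of an
animal's pairwise CCRs over partners — the aggregation behind CCR heatmaps
and the SL/SD features; it is isolated in one function because other
aggregations (e.g. maximum over partners) are defensible too.

## Social networks

`build_edge_table()` turns one window's pairwise CCRs into an edge list
with `weight = CCR/10`, and `write_edge_tsv()` writes the tab-delimited
`Source / Target / Edge betweenness` table that Cytoscape imports for
spring-embedded layouts. The third column's name is kept verbatim for
import compatibility although the quantity is a scaled contact ratio, not
graph-theoretic betweenness; internally the field is simply `weight`.
Zero-weight edges are emitted by default (dropping them is a flag), and
the conventional windows for network snapshots are day-1 light and day-3
dark. `network_summary()` adds per-node strength and mean-weight density
for light/dark comparisons.

## Phenotyping

Four per-animal features: **AL**/**AD**, normalized activity averaged over
light / dark time points (bin time-of-day profiles are first averaged
across days, then across each phase's time points), and **SL**/**SD**,
per-animal CCR over the pooled light / dark seconds. All four live on a
0–100 scale. `pca_embed()` centers and (by default) z-scores them —
scaling is a flag because the shared scale makes it mostly a
loading-balance choice — and fixes component signs deterministically
(largest-magnitude loading positive). `select_k()` runs k-means (50
restarts, fixed seed) on the PC scores for each candidate k and chooses
the k with maximal mean silhouette width, exporting the inertia curve for
a manual elbow reading: an automated, reproducible stand-in for the usual
elbow-plus-silhouette inspection. Degenerate inputs (all points identical,
a zero-variance feature, k beyond n−1) are errors, not silent results.

Supporting statistics: `coefficient_of_variation()` (sample sd / mean,
for variability comparisons across groups), `chi_square_light_dark()`
(Pearson chi-square on pooled category-seconds, conditions × categories),
and `holm_sidak_adjust()` (step-down Šidák:
$\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$, monotonized and capped at 1).
The omnibus two-way ANOVA that typically precedes the adjustment is
deliberately out of scope — any standard statistics tool fits it from the
tidy activity/CCR tables this package writes — only the adjustment layer,
which is easy to get subtly wrong, is implemented and tested here.

## The simulator

`simulate_cohort()` generates ground-truth trajectories plus a noisy raw
log so every pipeline stage is testable without animal data. The movement
model is deliberately the simplest kernel whose statistics the proximity
layer can predict: each second, mouse $m$ attempts a move with a
phase-dependent probability (`p_move_light` / `p_move_dark`, scalars or
per-animal vectors); an attempted move is, with probability `p_social`, a
single Chebyshev-reducing step toward the nearest conspecific (ties broken
uniformly), otherwise a uniform draw from the 8-neighborhood, clipped to
the board. Updates are synchronous from the previous second, animals
processed in index order, all randomness from R's seeded stream — so runs
are bit-reproducible across platforms, including the emitted log bytes.
The detection channel then drops each second's read with probability
`p_miss`, adds a spurious same-second read at an adjacent tile with
probability `p_dup` (always later within the second than the true read,
which is what makes first-wins deduplication the correct recovery), and
can silence a tag from a given second on (`tag_loss`), emulating a
detached transponder.

Defaults are fixed once as the study conditions: 8 mice, 72 h, movement
probability 0.2 (light) / 0.8 (dark) — a 4:1 nocturnal contrast typical of
mouse circadian activity and the planted value the parameter-recovery
checks measure against — `p_social = 0.3`, `p_miss = 0.05`,
`p_dup = 0.01`, session starting at lights-on. None of these rates are
observable in the source recordings (live animals, hardware detections);
they are modeling choices, and the validation suite treats them as planted
truth to be *recovered* by the pipeline, not as empirical claims.

What the simulator does **not** emulate: walls and nest sites (no
wall-following or preferred corners), huddling as a persistent state (social
attraction is memoryless), feeding/drinking bouts, body orientation, and
identity swaps (RFID has none). Passing tests therefore show that the
pipeline computes its statistics correctly on data with the right *format*
and controllable circadian/social structure — they do not validate
biological realism of any particular rate.

## Validation design and problem sizes

The test suite runs the pipeline at the full study scale where the checks
are about scale, and small fixtures where they are about arithmetic:

- structural constants (96 tiles, 5 cm pitch, 7,200-sample 2-h and
  43,200-sample 12-h windows) fall out of geometry and windowing;
- proximity classification is checked against an independent Chebyshev
  ring oracle on all 96² antenna pairs;
- on a full 72-h, 16-mouse simulated recording with default sensor noise,
  category proportions sum to 1 and CCR equals 100·(p_same+p_close) in
  every covered pair-window;
- with a noiseless channel, simulate → write log → parse → preprocess
  reproduces ground truth *identically*, 4.1 million rows;
- planted parameters are recovered: the per-animal dark/light travel
  ratio under 0.8/0.2 movement probabilities lies within 15% of 4.0 over
  24 h, and group CCR is monotone in `p_social` over {0, 0.3, 0.6, 0.9}
  with paired seeds;
- two planted phenotypes — high-social arrhythmic movers vs asocial
  strongly nocturnal movers, 8 + 8 animals over 72 h with per-animal
  parameter variation within each cohort — are recovered by
  silhouette-selected k-means as k = 2 with full label agreement. Each
  phenotype draws per-animal rates from a range (a phenotype is a
  distribution, not a point); the arrhythmic cohort uses one rate per
  animal for both phases, since independent light/dark draws would plant a
  circadian axis and a genuine third cluster;
- chi-square and Holm–Šidák match hand-computed closed forms exactly.

`scripts/acceptance.R` re-runs this battery from scratch against the
installed package and writes the measured quantities as JSON.

## Known limitations

Resolution is the 5 cm tile: two animals in one tile are "Same" whatever
their orientation, and fine social acts (sniffing, mounting, grooming)
are not distinguishable from co-occupancy. CCR is a proximity proxy:
huddling for warmth, shared nest sites and low mobility all raise it
without implying affiliative behavior, so it should be read alongside
activity. Forward fill is a modeling choice — a silent animal is assumed
stationary, which under heavy dropout is optimistic. The parser's dialect
is one reasonable reading of "time, antenna, tag" plain-text logs; a
hardware variant with a different layout needs only `parse_raw_log()`
adapted.
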