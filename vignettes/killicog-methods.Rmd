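---
title: "Models and numerical conventions in killicog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical conventions in killicog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(killicog)
```

killicog turns raw pose-estimation tracks from an automated-feeder
conditioning assay into latency, learning, survival and enrichment
statistics. This vignette is the package's account of its models: what is
computed, under which assumptions, which knobs matter, and where the
design was genuinely open.

## Coordinate and timing conventions

Tracks are in image pixel space: origin top-left, y increasing downward.
All "upward" logic converts once, at the velocity step: upward displacement
is −Δy, so upward velocity `v_up[i] = -(y[i] - y[i-1]) * fps` is positive
when the fish moves toward the water surface, and displacement angles are
reported on upward-positive axes (0° rightward, 90° toward the surface).
Frames are indexed from 0; frame *i* maps to time *i*/fps with fps stored
on each track (default 20 frames/s). The trial schedule is light on at
2 s, food nominally at 9 s, analysis window 18 s (`trial_timing()`); real
food arrival varied up to 11 s, which is why the success window [2, 9] is
conservative. Missing coordinates are always `NA` — never sentinel values.

## The three-step prefilter

1. **Likelihood gate** (`likelihood_gate()`, threshold 0.999): coordinates
   of frames whose pose confidence is below threshold are masked;
   likelihoods are retained for audit.
2. **Jump filter** (`jump_filter()`, quantile 0.05): Euclidean distances
   between consecutive *non-missing* observations of each track — gated
   frames are skipped over, not treated as barriers — are pooled across
   every track of the dataset; distances strictly greater than the pooled
   95th percentile (linear-interpolation sample quantile, ties not
   flagged) mark the second frame of the pair as an anomaly, in a single
   pass over distances computed up front. Comparing across gaps is a
   deliberate choice: when roughly half the frames fail the 0.999 gate, an
   adjacency rule would discard most of the distance pool, and — decisive
   for correctness — a jump artifact immediately following a gated frame
   could never be flagged, after which the spline would interpolate
   through the rogue point and manufacture velocity spikes that inflate
   the per-animal burst threshold.
3. **Spline fill** (`spline_interpolate()`): interior missing values are
   replaced by a natural cubic spline (second derivative zero at the end
   knots) through the observed (frame, coordinate) points. Natural
   boundaries are the package's choice among cubic-spline variants; they
   avoid the endpoint oscillation of not-a-knot fits on noisy tracks.
   Leading and trailing missing runs are never extrapolated. Tracks with
   fewer than four observations pass through with a warning.

The stages are monotone (nothing ever un-masks), the pipeline is the
identity on clean tracks, and per-track counts satisfy
`n_interpolated + n_residual_missing = n_gated + n_anomalies` on complete
input.

## Kinematics and t1

Rolling velocity uses a centred 20-frame window; for even windows the
extra frame is taken forward in time, and any missing input or incomplete
window yields `NA`. Centred alignment is the package convention
(configurable), chosen because it keeps burst timing unbiased rather than
systematically late.

Per animal, the burst threshold is `v_min + 0.75 (v_max − v_min)` over the
rolled velocities pooled across all trials; bursts are maximal runs
strictly above it. The food-drop site is the mean over videos of the
coordinate at maximum food-drop likelihood; arrivals are frames within the
surface radius (default 125 px; the assay convention allows 100–150 per
animal, and per-animal overrides are logged in the output rather than
silently applied). t1 rules, in order: at surface on the first defined
frame → 0; no arrival → 18 s; otherwise the start of the burst nearest in
time to the *first* arrival (gap 0 if the arrival is inside a burst; ties
to the earlier burst — conservative, earlier initiation). Trials without
bursts fall back to the arrival time.

Success is `2 ≤ t1 ≤ 9` inclusive. The learning index for run length *k*
is the reciprocal of the first trial number beginning *k* consecutive
successes, and 0 when no run exists — "never associated" extends "slower
association = smaller index" to its natural limit, and keeps the index
numeric for effect-size work. Session summaries average t1 over trials
1–7 ("early") and 11–17 ("late"); a trial with undefined t1 is dropped
from the mean with the count reported, while percent success keeps 7 as
its denominator (both the count and denominator are in the output, so
either convention can be recomputed). Fish eating in fewer than three
trials are flagged `included = FALSE` rather than removed.

Manual score sheets are per-second `upward`/`at_surface` flags; manual t1
backtracks from the first surface second through the unbroken run of
upward seconds leading into it, so a pause of ≥1 s restarts the run and
the post-pause ascent is reported.

## Statistics

* Wilcoxon tests wrap `stats::wilcox.test` with explicit exactness rules:
  exact when ≤25 nonzero pairs (signed-rank) or pooled n ≤ 20 (rank-sum)
  and no ties, otherwise the tie-corrected normal approximation with
  continuity correction; the `exact` flag is always reported.
* Cohen's d uses the pooled (df-weighted) SD without small-sample
  correction, and the interval
  `d ± t_{(1+c)/2, n1+n2−2} √((n1+n2)/(n1 n2) + d²/(2(n1+n2)))` — the
  convention that reproduces published killifish effect-size intervals to
  printed precision.
* `wmw_sample_size()` implements the A.R.E. method: the WMW test at *n*
  observations per group is treated as a two-sample t test at effective
  sizes `ARE × n` (normal parent: 3/π ≈ 0.955; also min-ARE 0.864,
  logistic, Laplace, uniform), and the smallest integer *n* whose
  effective-size noncentral-t power reaches the target is returned. The
  alternative reading — find the integer t-test n first, then inflate and
  round — gives systematically larger answers and does not reproduce the
  published 28/27/132 triple; the effective-size rule does.
* Feeding precision is `1/sd_boot²` with `sd_boot` the mean over B
  (default 1000) ordinary bootstrap resamples of the sample SD — the
  point-estimate convention is the plain mean of replicate SDs, seed
  always recorded. Percent fields in fidelity summaries are rounded half
  away from zero to one decimal, with raw values retained.

## Survival

Lifespans are treated as exact daily observations; censored animals
(feeder failures) carry `observed = 0`. The KM median is the earliest time
with S(t) ≤ 0.5 — on plateaus at exactly 0.5 this differs from the
midpoint convention some software uses, and it makes the median invariant
to censored observations appended after the last event. The Gompertz
hazard h(t) = a·e^{bt} is fitted by maximising
Σ_deaths ln h(t) − Σ_all H(t), H(t) = (a/b)(e^{bt}−1) with the limit a·t
as b→0, with log-parameterised rate, analytic gradients, BFGS from the
exponential fit (b = 0.01/unit), and Wald intervals from the observed
information (rate interval on the log scale). Parameters scale with the
time unit, so the unit is explicit (`time_unit = 27` days reproduces the
scale on which published killifish rate-of-aging estimates are printed;
the printed parameters' underlying unit is not stated in full, so the
package also reports day-scale values, and the unit-invariant comparison
between groups is the one to rely on). Binned hazards use the discrete
life-table convention — deaths in the bin over the number at risk at bin
start, censored animals at risk through their censoring bin.

## Expression-matched bootstrap enrichment

Genes with missing adjusted p in either table are removed first; strict
`padj < 0.05` classifies each remaining gene into both/sex-only/diet-only/
neither. Enrichment is g1/(g1+g3); significance is the exact two-tailed
Fisher rule. The bootstrap null draws, per diet DEG, one non-diet-DEG from
the genes within ±2% *relative* mean expression (expression spans orders
of magnitude, so the window is read as relative); draws are independent
across pools, duplicates are collapsed when the control set is formed and
the effective size logged. Each of the B = 1000 control sets is tested by
the identical contingency/Fisher construction with set membership in place
of diet-DEG status, over the same filtered universe; medians of the
enrichment and p distributions summarise the null. An empty matching pool
is an error naming the gene — the remedy is widening the tolerance, which
is exactly how the 2% convention arose from an initial 1%.

## The synthetic-data generators

`simulate_tracks()` emulates the assay: per trial the fish wanders near
the tank bottom of a 640×480 px frame, then at the true latency executes a
ballistic ascent to just below the food-drop site, then hovers at the
surface. The ascent is the decelerating half of a constant-acceleration
profile (velocity maximal at launch, zero at the surface) lasting 0.9 s —
a sub-second feeding dash, chosen once so that the rolled-velocity
threshold crossing lands at the true launch time rather than trailing it;
with this profile the pipeline recovers every clean-trial latency within
0.25 s and ≥95% of noisy-trial latencies (σ ≤ 5 px noise, 5% dropouts, 1%
teleports) within 0.25 s. The default latency curve decays geometrically
from ~12 s to ~3 s over the 17 trials with 0.5 s jitter, producing the
early-failure/late-success structure a learning animal shows. Dropout
frames draw likelihood below the 0.999 gate, others above it; teleport
displacement is 10× the 99th percentile of the session's normal step
lengths, guaranteeing pooled-quantile detectability.

What the generator does *not* emulate: occlusions with correlated
multi-frame drift, reflections, tank-wall interactions, identity swaps, or
fish that approach the surface without feeding motivation. Passing
recovery tests therefore demonstrates the pipeline's numerics and edge
rules, not robustness to every real-world tracking failure — the
per-animal override mechanism exists precisely because real sessions
occasionally need a manually chosen threshold.

`simulate_deg_tables()` plants a 2×2 joint distribution of sex/diet DEG
status over a log-normal expression distribution. Planted DEGs are
restricted to the central expression band (within 2 SD of the log-mean),
as differential expression is only callable with adequate counts — the
same reason DE pipelines report missing adjusted p for low-count genes —
and `enrichment_lift = 1` gives exact conditional independence of the two
statuses among callable genes, the meaningful null for calibrating the
matched bootstrap. Lifespans use the inverse-CDF of the Gompertz law,
`t = (1/b) ln(1 − (b/a) ln U)`; feeder logs are per-day binomial misses.
All generators are pure functions of (config, seed).

## Problem sizes used in the test suite

Module tests use the smallest sessions that exercise each rule (1–6 fish).
The end-to-end checks use 16 fish × 17 trials × 10 generator seeds for
latency recovery, 100 replicates of n = 500 for Gompertz coverage, 20
generator seeds × 1000 bootstrap iterations over a 10,000-gene universe
for enrichment calibration, and 1000 random instances for the Wilcoxon
enumeration property — sizes chosen so each check is decisively powered
while the whole suite stays interactive.

## Known limitations

* t1 inherits the onset-localisation granularity of a centred 20-frame
  rolling average: onsets are resolved to roughly 2–3 frames, not 1.
* The range-based burst threshold is sensitive to a single spiky trial;
  the jump filter removes the dominant source (interpolation through
  unflagged artifacts), and per-animal overrides handle the remainder.
* Gompertz Wald intervals are asymptotic; at very few events (< ~20) their
  coverage degrades, and the fit refuses to run below 5 events.
* The control-set contingency keeps true diet DEGs in the "not in control
  set" margin; whether to exclude them is configurable reasoning left
  open, and at realistic DEG fractions the difference is negligible.
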