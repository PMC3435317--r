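# woundkinetics

Quantitative, fully automated analysis of bright-field (DIC) scratch
wound-healing time-lapse movies in R.

In a scratch assay a strip of cells is removed from a confluent monolayer
and the collective migration that refills the gap is imaged for many
hours. Standard read-outs (wound area over time) discard almost all of
the spatiotemporal structure. `woundkinetics` extracts it:

- **Segmentation** of each frame into monolayer and wound by local
  texture variance (DIC monolayers are highly textured, the void is
  flat), with frame-to-frame wound tracking.
- **Patch-level motion estimation** by normalized cross-correlation
  (NCC) block matching on ~18.5 µm sub-cellular patches, with sub-pixel
  parabolic refinement and validity gating (variance floor, minimum NCC).
- **Velocity magnitude maps** `M[t, d]` — the mean speed (µm/h) of all
  cells in the strip at distance `d` from the wound edge at time `t` —
  the central compact representation of a whole experiment.
- **Healing phases**: Phase 1 (scratch → first contact of the opposing
  fronts, detected as loss of separation by the wound region), Phase 2
  (→ full closure, wound area below 1% of initial), Phase 3 (after).
- **"Average-cell" kinetics**: cumulative toward-wound displacement
  `R(t)` and smoothed velocity profiles at chosen anchor distances.
- **Multi-cellular texture**: per-frame histograms of the ten
  rotation-invariant uniform local binary pattern (LBP, 8 neighbours,
  radius 1) codes over cellular pixels — an implicit, gray-scale
  invariant morphology measure.
- **Treatment classification**: phase × distance-interval descriptor
  vectors (6 intervals × 3 phases = length 18, or × 2 phases = 12),
  optional norm-1 normalization to isolate the motility *pattern* from
  its magnitude, leave-one-out linear-SVM validation, exact Wilcoxon
  rank-sum p-values (full permutation null, tie-aware), and 2-component
  PCA.
- **Morphometrics**: trajectory estimation by integrating the motion
  fields, cell area/eccentricity from label images, density from mean
  cell area, and Spearman density–speed correlation with exact small-n
  permutation p-values.
- **A synthetic movie generator** with complete ground truth (prescribed
  velocity law `v(d, t)`, wound geometry, phase times, tracks, morphology
  program) emulating untreated, growth-factor-treated (a backward
  activation wave recruits distant cells layer by layer) and
  motility-inhibited regimes — the validation harness for everything
  above.

## Worked example

```r
library(woundkinetics)

sc  <- synthetic_scenario("treated", rng_seed = 42)
gm  <- generate_movie(sc)                    # movie + ground truth
run <- run_experiment(gm$movie, cohort_config())
print(run)
round(run$descriptors$velocity, 1)
```

```
wound_run 'synthetic-treated-seed42': 59 frame pairs, map 59 x 18 bins
phases: contact at frame 19, closure at frame 22 (of 60)

p1.i1 p1.i2 p1.i3 p1.i4 p1.i5 p1.i6 p2.i1 p2.i2 p2.i3 p2.i4 p2.i5 p2.i6 p3.i1
 28.1  29.0  27.8  24.9  21.0  18.8  32.6  33.9  33.7  35.7  37.0  36.6  12.0
p3.i2 p3.i3 p3.i4 p3.i5 p3.i6
 12.6  13.2  12.9  12.8  12.9
```

Each entry is the mean speed (µm/h) in one distance interval (i1 =
0–16 µm from the wound edge … i6 = 80–96 µm) during one healing phase.
The treated signature is visible directly: in Phase 1 the front moves
fastest (28 vs 19 µm/h), in Phase 2 distant cells have accelerated past
the front (37 vs 33 µm/h, the layer-by-layer recruitment wave), and in
Phase 3 the front has halted while distant cells still move. An
untreated movie instead decays monotonically with distance in every
phase. `plot_velocity_map(run$map, run$phases)` renders the map with the
two phase-boundary lines.

A labelled cohort is classified end to end with

```r
report <- run_cohort(cohort_scenarios(base_seed = 1), config = cohort_config())
print(report)
#> cohort of 11 movies (treated: 5, untreated: 6)
#>   descriptors: length 18 (3 phases x 6 intervals)
#>   LOOCV accuracy: raw 100.0%, normalized 100.0%
#>   rank-sum p (decision scores): 0.004329 (exact)
```

A thin command-line front end wraps the same functions:

```sh
inst/cli/wound-kinetics simulate --regime treated --seed 3 --out movie.tif
inst/cli/wound-kinetics run-all --movie movie.tif --pixel-size 2 --interval 14.5 --out-dir results/
```

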