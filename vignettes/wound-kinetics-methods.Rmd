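---
title: "Morpho-kinetic analysis of wound-healing movies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morpho-kinetic analysis of wound-healing movies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundkinetics)
```

# The measurement problem

A scratch wound-healing assay images a monolayer of cells refilling a
~300 µm gap over many hours (here: one frame every 14.5 minutes,
roughly a day of imaging). Bright-field/DIC imaging gives no labels to
track, but the inner-cellular texture is rich enough that *local* image
motion is measurable. The package turns such a movie into:

1. a per-frame cellular/wound partition,
2. per-patch velocity vectors,
3. a *velocity magnitude map* `M[t, d]` — mean cell speed at distance
   `d` from the wound edge at time `t`,
4. phase-partitioned descriptor vectors and texture histograms that a
   classifier can act on.

The working assumption throughout is that the average over all pixels
of a distance strip is a better-behaved kinetic observable than any
individual cell track: estimation noise is isotropic and averages out,
while systematic spatial structure (who moves, where, when) survives.

# Pipeline components

## Segmentation

A monolayer pixel sits in a high-variance neighbourhood; a wound pixel
does not. Each frame is scored by the standard deviation of intensities
in a sliding window (`seg_window_um`, default half a patch ≈ 9 µm; for
the bundled 2 µm/px synthetic geometry the cohort configuration uses
14 µm, i.e. a 7 px window, which we found gives a steadier variance
image at that sampling). The threshold is chosen by Otsu's method on
the variance image of **frame 1** and reused for the whole movie: frame
1 always contains both classes, whereas after closure the low-variance
class disappears and a per-frame Otsu would split the monolayer texture
itself. The binary mask is closed with a small disc, specks and holes
below one patch area are removed, and the wound is the background
component that (frame 1) is largest, or (later) overlaps the previous
wound — this overlap tracking keeps the wound identity stable when
first contact fragments it.

Known bias: the variance window blurs the boundary by ~half a window,
so the detected wound is slightly eroded; the wound area error is a
fixed few pixels of perimeter. Relative area error is therefore small
while the wound is open (<10% down to half the initial area on the
synthetic benchmark) but diverges as the true area approaches zero, and
contact/closure are detected one or two frames early. The phase
detection tolerance used in testing (±2 frames for closure) reflects
this.

## Motion estimation

Frames are tiled with non-overlapping square patches (`patch_size_um`,
default 18.5 µm; at least 8 px). Each patch of frame *t* is matched in
frame *t+1* within an integer search radius by normalized
cross-correlation; NCC makes the estimate exactly invariant to affine
intensity changes. The radius defaults to the expected per-frame
displacement (`expected_max_speed_um_hr` × frame interval) plus a 2 px
margin. Ties in the NCC maximum break toward the smallest displacement
(bias to stillness), and the integer optimum is refined by independent
1-D parabolic fits along each axis (clamped to ±0.5 px, skipped at a
perfect match where it would only echo neighbour asymmetry). A patch is
invalid if its centre is background, its variance falls below
`variance_floor_frac` (default 10%) of the movie's median patch
variance, its best NCC is below `min_ncc` (default 0.5), or its search
window leaves the frame. Displacements convert to µm/h via
`px/frame × pixel_size_um × 60 / frame_interval_min`.

On rigid integer translations of textured frames the estimator is
accurate to <0.25 px; identical frames give exactly zero.

## Strips, maps and phases

Distance from the wound is the exact Euclidean distance transform of
the wound mask, evaluated on cellular pixels and scaled to µm. After
closure there is no wound to measure from; distances are then taken to
the **last non-empty wound mask** (frames flagged `dist_frozen`). This
keeps Phase-3 map columns defined — post-closure kinetics are indexed
by distance from the former wound, which is also how the phase-3 third
of the descriptor vector is meaningful.

Each valid patch contributes its speed to the half-open distance bin
`[d, d+w)` (strip width `strip_width_um`, default one patch) holding
its centre, weighted by the number of cellular pixels it covers; the
bin mean is `M[t, d]`. Empty bins are missing, not zero.

Phases: first contact is detected as *loss of separation* — by planar
duality, an 8-connected cellular path joins the two fronts exactly when
no 4-connected wound component spans the frame along the wound axis.
Closure is the first frame with wound area below
`closure_area_fraction` (default 1%) of the initial area; a movie that
starts closed has both at frame 1. Undefined phases are `NA` flags, and
descriptor construction then requires manual phase frames.

"Average-cell" displacement accumulates the strip-mean toward-wound
velocity into `R(t)`. By default anchors *advect*: each frame the
anchor's strip is re-selected at its remaining distance `d0 − R(t)`
(floored at zero), tracking the average cell as it approaches the
wound; `anchor_mode = "fixed"` keeps the initial strip. The toward-wound
component at a patch is the projection on the negative distance-map
gradient, so speed is preserved (`dx² + dy² = |v|²`) and patches on
distance plateaus are flagged.

## Texture

With 8 neighbours on the unit ring (diagonals bilinearly interpolated)
and the tie rule "neighbour ≥ centre", the rotation-invariant uniform
LBP has exactly ten codes: uniform patterns (≤2 circular transitions)
map to their count of ones (0–8; a constant region gives 8), everything
else to 9. Histograms over cellular pixels (border excluded) are
L1-normalized, exactly invariant to positive affine intensity maps, and
invariant to 90° rotations. The Phase-2 mean histogram is the texture
descriptor: the contact-to-closure window is where the morphological
program (spreading, elongation) acts most strongly.

## Descriptors and statistics

The distance axis is cut into `n_distance_intervals` (default 6) equal
intervals over `[0, max_distance_um]`; the descriptor is the mean of
`M` over each interval × phase rectangle, phase-major — length 18 with
three phases, 12 with Phases 1–2 only (used when part of a cohort never
closes). Norm-1 (Euclidean) normalization removes the overall motility
scale, leaving the spatial pattern.

Classification is leave-one-out: a linear SVM (cost 1, features
standardized per training fold — kernel and cost are deliberately the
minimal-assumption baseline for an 11-sample cohort) predicts each
held-out movie. Group separation of the held-out decision scores is
tested with an exact two-sided Wilcoxon rank-sum p-value: the
permutation null over all `choose(nA+nB, nA)` assignments is computed
by a subset-sum dynamic program over doubled (hence integer,
tie-averaged) ranks, the smaller tail is doubled and capped at 1. At
complete separation this gives 2/462 ≈ 0.0043 for 6 vs 5 and
2/924 ≈ 0.0022 for 6 vs 6. Above 25 observations a tie-corrected
normal approximation is used and flagged. PCA uses a deterministic sign
convention (largest-magnitude loading positive).

## Morphometrics

Trajectories integrate the per-frame fields by forward Euler with
bilinear interpolation between patch centres; an invalid patch is
patched from the nearest valid neighbour within one patch radius, else
the track terminates with a status. Cell area is pixel count × pixel
area; eccentricity comes from the second-moment ellipse
(`sqrt(1 − (b/a)²)`; a 1/12 pixel-footprint term stabilises one-pixel-
thin masks), making it scale- and rotation-invariant. Density is
`packing_fraction / mean cell area` (default packing 0.9 — a confluent
monolayer is not perfectly covered; the choice scales absolute density
only, never correlations). The density–speed association uses
Spearman's rank correlation with average ranks; p-values are exact by
permutation enumeration for n ≤ 8, else the t approximation.

# The synthetic benchmark

No imaging data ships with the package, so validation runs on a
generator whose defaults encode the study conditions: 128 × 256 px at
2 µm/px (the long axis perpendicular to the wound; pixel size chosen so
the 300 µm scratch plus ~100 µm of monolayer on each side fit the
frame), 60 frames at 14.5 min (14.5 h of healing), a vertical 300 µm
wound with ±20 µm smooth edge perturbations. The two edges use
different spatial frequencies, which guarantees the gap profile varies
by at least twice the perturbation amplitude — first contact then
strictly precedes closure whatever the random phases.

The prescribed speed toward the wound is:

* untreated: `v(d) = v_front · exp(−d/λ)` with `v_front = 20 µm/h`,
  `λ = 50 µm`, constant in time until closure;
* treated: `v_front = 30 µm/h`, `λ = 40 µm`, plus a logistic activation
  wave travelling backward at 50 µm/h (onset 0.5 h, ramp 0.5 h) that
  lifts activated cells toward `1.25 · v_front` scaled by
  `1 − exp(−d/λ)`, so the front stays at `v_front` while distant cells
  overtake it before closure;
* inhibited: `v_front = 10 µm/h`, `λ = 25 µm` — the steepest
  front/distant ratio, and slow enough that the wound does not close
  within the movie (matching the use of Phases 1–2 descriptors for such
  cohorts);
* after closure, speeds relax exponentially (time constant 1.5 h;
  0.75 h at the front for the treated regime, growing with distance, so
  the front halts first).

These functional forms (exponential decay, logistic wave) are the
simplest fields reproducing the qualitative map structure of the three
regimes; they are configuration-exposed, not claims about mechanism.

Rendering uses Gaussian-blob pseudo-cells (diameter 16 µm) on a
jittered grid, advected as particles toward the nearest wound-edge
point at the prescribed speed. Bright/dark blob signs alternate in a
checkerboard so neither same-sign plateaus nor cancellation pools
produce spurious low-variance patches. Because the untreated flow
stretches the sheet (the front outruns the interior — the origin of the
fan-like displacement gap), grid nodes whose nearest particle is
farther than one grid step are re-seeded each frame
(pseudo-proliferation), keeping the monolayer confluent; a mechanistic
cell simulation is explicitly out of scope. The wound carries only a
static sensor-noise field (σ = 0.02), so cellular texture variance
exceeds wound variance many-fold and a zero-velocity scenario renders
bit-identical frames. The morphology program scales blob size and
elongation with distance and phase (front cells spread; treated distant
cells grow once the wave arrives), which is what the texture descriptor
and the density–speed correlation see. Everything is a pure function of
the scenario, including its RNG seed.

What passing on this benchmark does *not* show: robustness to uneven
illumination, debris, stage drift, out-of-focus frames, cell division
figures, or segmentation-hostile cell lines; the generator's texture is
statistically far cleaner than real DIC. The end-to-end recovery
criterion — mean absolute error of `M[t, d]` against the prescribed
`v(d, t)` below 15% of the peak speed — was budgeted before tuning from
the known error sources (±0.25 px matching error ≈ 2 µm/h at this
sampling, strip-averaging of a curved profile, edge-localisation bias)
and the measured errors on the default regimes are 4–9%.

# Numerical and design choices

* Intensities are min-max scaled to [0, 1] once per movie (not per
  frame): LBP is gray-scale invariant but the segmentation threshold is
  not, and per-frame scaling would make thresholds drift.
* Coordinates are row-major with origin at top-left; all distance bins
  are half-open `[d, d+w)`. Multi-channel input is rejected — the
  method is defined on a single bright-field channel.
* The cohort configuration (`cohort_config()`) sets the strip width to
  16 µm equal to the descriptor interval width over `[0, 96 µm]`, so
  strips align with descriptor intervals exactly on the synthetic
  geometry; with the general defaults (18.5 µm strips, 350 µm range)
  intervals simply average the strips they contain.
* Whether displacement anchors should advect with their accumulated
  displacement or stay in their initial strip is genuinely open; the
  advecting interpretation is the default (it "tracks" the average
  cell), the fixed-strip variant is a configuration switch
  (`anchor_mode`).
* Problem sizes in tests and the acceptance run: movies of 128 × 256 px
  × 60 frames and an 11-movie cohort; these reproduce every qualitative
  regime feature at interactive runtimes (~10 s per movie through the
  full pipeline).
* Determinism: the pipeline contains no randomness; the generator and
  classifiers are seeded. Manifests record configuration, phase frames
  and output checksums, so a run is reproducible from its manifest.

# Limitations

Segmentation substitutes a local-variance thresholder for a trained
multi-cellular segmenter; it is adequate where texture contrast is
strong, and the wound-edge bias noted above is its main artefact.
Block matching assumes locally rigid translation between consecutive
frames — strong rotation or deformation within a patch lowers NCC and
drops the patch rather than biasing it. Single-cell morphology requires
label images (from ground truth or external instance segmentation);
the package deliberately does not segment individual cells from
bright-field. Proliferation, 3-D motion and finger/leader-cell
morphologies are out of scope.
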