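---
title: "Methods: viability calling, expression quantification and cooling kinetics in viacool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viability calling, expression quantification and cooling kinetics in viacool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viacool)
```

## Scope

`viacool` packages the computational half of a 3D in-vitro neurotrauma /
therapeutic-hypothermia workflow: neural cells cultured in collagen hydrogels
are imaged as multi-channel confocal z-stacks (Hoechst/DAPI nuclei, calcein AM
for live cells, ethidium homodimer-1 for dead nuclei, plus a marker channel —
a caspase-3/7 or ROS reporter, or a calpastatin immunostain), and the stacks
are reduced to per-sample outcomes: population viability, percent
marker-positive cells, or per-cell expression in arbitrary units (AU). A
companion thermal model quantifies how quickly a submerged gel reaches a
hypothermic target temperature, and rank-based statistics compare treatment
groups.

Because no raw stacks are publicly deposited for this class of experiment,
the package is organised around a synthetic scene generator with exhaustive
ground truth: every analysis stage is validated against scenes whose true
cell positions, labels and intensities are known by construction.

## The synthetic scene generator

`scene_spec()` / `generate_scene()` render each cell as a nucleus sphere
inside a concentric soma sphere and emit five co-registered channels:

* `nuclei` — every nucleus;
* `live` — somata of live cells (calcein-like);
* `dead` — nuclei of dead cells (EthD-1-like);
* `marker` — somata of marker-positive live cells, each at a per-cell true
  mean intensity (recorded in the ground-truth table);
* `brightfield` — all somata, darker than a mid-grey transmitted background.

Rendered volumes are blurred with an anisotropic Gaussian point-spread
function, offset by a uniform background, corrupted by signal-dependent
Gaussian noise (variance proportional to the signal, the usual Gaussian
approximation to shot noise, avoiding an integer Poisson dependency in the
contract) plus additive read noise, clipped to the bit depth, and finally
distorted by the bidirectional scan-line mismatch: every odd-indexed y line
is translated along x by an integer pixel shift, as happens when the two
scan directions of a resonant scanner are mis-phased.

Defaults were chosen once, as conditions representative of live imaging of
dissociated 3D cortical cultures, and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| voxel pitch | 1.24 µm isotropic | native pixel pitch of a 20×/0.45 long-working-distance objective, with z-step matched |
| stack shape | 60 × 192 × 192 voxels (z, y, x) | a full acquisition is 200 × 512 × 512; the default is the same pitch scaled down so suites run in seconds, and large enough to hold 25 cells at the default spacing |
| bit depth | 12 | typical photomultiplier digitisation |
| nucleus radius | 3–4.5 µm | cortical neuron nuclei |
| soma radius | 5–7 µm | cortical neuron somata |
| minimum center spacing | 20 µm | moderate seeding density; also the regime the bounding-box colocalization rule assumes (well-separated somata) |
| PSF σ (z, y, x) | 1.0, 0.5, 0.5 µm | axial elongation of a mid-NA confocal PSF |
| background | 2% of range | detector offset + autofluorescence |
| shot-noise scale | 1 DN | variance per digital number of signal |
| read noise | 15 DN | ~0.4% of the 12-bit range |
| mismatch shift | 1 px | a typical uncorrected bidirectional offset |

Cell centers are placed by rejection sampling with the minimum spacing and a
one-soma-radius margin from every face (so no object is clipped); a bounded
number of attempts guards against infeasible densities and raises a "scene
too crowded" error rather than looping forever. Dead cells are drawn
exactly: `round(fraction_dead × n)` cells are dead, and
`round(fraction_marker_positive × live count)` of the live cells are
marker-positive — positivity is *defined* only among live cells, so the
truth table never marks a dead cell positive. With the same spec and seed
the generator is bit-identical; the RNG state of the caller is left
untouched.

**What the generator does not emulate.** Neurites and astrocyte morphology
(cells are blobs, which is exactly what the bounding-box calling rule
assumes); spectral bleed-through; depth-dependent attenuation; optical
sectioning beyond a Gaussian PSF. Passing ground-truth recovery on these
scenes therefore demonstrates that the calling machinery is correct for
blob-like, well-separated cells — not that it would segment densely
interwoven neuritic cultures.

## Image conditioning

The conditioning chain mirrors standard confocal practice, in order:

1. **Mismatch correction** (`correct_bidirectional_mismatch`): the inverse
   integer shift on odd lines. The `|s|` border columns of shifted lines
   are unrecoverable and take the fill value; all tests of the round-trip
   therefore exclude the x-borders. The shift is a configuration input —
   estimating it from line cross-correlation is out of scope.
2. **3D median filter** (`denoise_median`): `(2r+1)³` neighborhood with
   edge replication, default radius 1 (3×3×3) — the smallest kernel that
   removes isolated hot voxels without eroding 5–10 voxel-wide objects.
3. **Histogram binarization** (`binarize_histogram`): Otsu's criterion —
   the threshold maximizing between-class variance over the full-depth
   integer histogram. "Based on its histogram of intensities" names no
   specific method; Otsu is the standard parameter-free choice and the
   threshold is overridable per channel. Ties (a plateau of thresholds
   inducing the same partition) are broken by the plateau midpoint, so a
   two-valued image is cut midway between its modes. A constant image has
   no separable foreground: the mask is all-false and flagged degenerate.
4. **De-speckling** (`despeckle`): removal of connected components below a
   minimum voxel count, default 27 (≈ a 3×3×3 blob, well below any real
   nucleus at 1.24 µm pitch), 26-connectivity by default (6/18/26
   configurable). Idempotent by construction.

## Cell calling

`detect_objects` labels components and screens them for "semi-spherical"
blobs: minimum size (default 30 voxels) and minimum extent ratio
(voxel count / bounding-box volume, default 0.3; a digitized sphere sits
near π/6 ≈ 0.52 for large radii, somewhat lower for small ones because the
half-open box width is 2r + 1). Extent alone passes axis-aligned filaments
(a 1×1×40 line has extent 1), so an optional principal-axis elongation cap
(`max_elongation`, e.g. 3) is available as a second screen.

Bounding boxes are half-open on every axis; boxes sharing only a face do
not overlap. `call_cells` applies the colocalization rule per nucleus:
overlap with any dead-channel box ⇒ dead; otherwise overlap with any
marker box ⇒ marker-positive. A nucleus overlapping both is dead, not
positive, and multiple marker overlaps count once. `percent_positive`
divides by live nuclei by default (the rule defines positivity only there);
a total-nuclei denominator is available via `denominator = "all"`.
`viability` counts live-channel objects with no dead overlap against
dead-channel objects — an automation of, not a replica of, the manual
counting these assays traditionally use.

## Expression quantification (AU)

For immunostained sections the per-cell readout is built in four steps:

1. **Outline** (`segment_cell_levelset`): two-phase piecewise-constant
   (Chan–Vese-type) segmentation of a brightfield plane, evolved from a
   seed by discrete energy minimization — boundary pixels flip to the phase
   whose squared deviation from the phase mean (plus `mu` × the perimeter
   change) is lower; convergence when fewer than 0.1% of mask pixels flip.
   `mu` defaults to 0 because the plane is median-filtered first; an exact
   two-phase cover is a fixed point, and a contrast-free image returns the
   seed with a degenerate flag rather than a spurious contour.
2. **3D mask** (`build_cell_mask_3d`): the outline extruded over the
   contiguous z-range of the DAPI component that overlaps it (ties broken
   by the largest overlap); empty + flagged when nothing overlaps.
3. **Noise floor**: mean and SD of the marker channel over a background
   region — by default the complement of all detected objects eroded by
   two voxels (`background_from_objects`), so PSF tails do not contaminate
   the floor; an explicit background mask can be supplied instead.
4. **Gate and normalize** (`quantify_au`): mask voxels strictly more than
   two background SDs above the floor are averaged and divided by
   `2^bit_depth − 1`, giving AU ∈ [0, 1]. The gate is applied per voxel
   (the most literal reading of a per-pixel signal-to-noise requirement),
   strictly — so in the degenerate zero-noise case, voxels *at* the floor
   are excluded and a flat image scores 0. Normalization applies to the
   final mean, not the floor. The aggregate is the mean by default
   (median/sum available); under the mean, AU is monotone in mask
   intensity and blind to sub-gate voxels.

The procedure is exposed both as per-cell building blocks (interactive
seeding) and as the automatic path in `analyze_scene(..., "calpastatin")`,
which seeds from each detected nucleus, outlines on the brightfield slice
at the nucleus centroid within a local window (1.5 soma radii), and
averages AU over cells.

## Thermal model

Cooling of a submerged gel is modeled as transient conduction in a finite
cylinder, uniform initial temperature, all surfaces stepped to the bath at
`t = 0` (Dirichlet: convective resistance of stirred, pre-equilibrated
media is neglected). The separable solution is the product of an
infinite-cylinder radial series over Bessel-J0 eigenfunctions and a slab
sine series in z, each truncated at `n_terms` (default 50); a conservative
truncation bound is attached to every evaluation. At `t = 0` the
eigenseries of the discontinuous initial state suffers Gibbs oscillation,
so the exact initial/boundary values are returned directly — they are known
in closed form and the series limit agrees with them pointwise in the
interior.

`fraction_equilibrated` integrates the indicator of "within
`tol_fraction` of the step" over an r-weighted midpoint quadrature grid
(default 96 × 96); `time_to_fraction` bisects to 0.1 s, which is
well-posed because each point's excess decays monotonically. Geometry and
diffusivity are *assumptions*, prominently so: a 5 mm × 2 mm disc with the
diffusivity of water (1.4 × 10⁻⁷ m²/s), every one overridable. "Reaches
the target" is quantified as within 5% of the step — 0.2 °C for a
37 → 33 °C protocol. Under these defaults the whole volume is inside the
band long before 60 s (the slab Fourier number at 60 s is ≈ 2.1 based on
half-thickness, so the slowest mode has decayed by e⁻²⁰); the
sub-minute claim is insensitive to factor-of-two changes in geometry or
diffusivity.

The series implementation is verified against an explicit finite-difference
solver in (r, z) on a 101 × 101 grid (a test-side oracle sharing no code
with the series), agreeing to better than 0.05 °C at Fourier number 0.2.

## Group statistics

Outcomes are compared with ANOVA on ranks: a tie-corrected Kruskal–Wallis
omnibus (`stats::kruskal.test` behind `kruskal_wallis`; the all-identical
corner returns H = 0, p = 1 as the tie-correction limit). The post-hoc
method follows per-group Shapiro–Wilk normality at α = 0.05: Tukey's HSD
on group means when every group passes, Dunn's rank z-test with tie
correction otherwise (groups of n < 3 are untestable ⇒ Dunn, with a
warning). Running a rank omnibus and then Tukey on raw means is an unusual
pairing, but it is implemented as stated by the source protocol rather than
"fixed". P-values are unadjusted beyond what each post-hoc method itself
does, and α is fixed at 0.05 for the compact letter display, produced by
insert-and-absorb: groups share a letter exactly when their pairwise
p ≥ α. Calibration is property-tested: under a 5-group global null the
omnibus rejects at 5% ± 1.5% over 2,000 simulations, and a single 2-SD
shifted group is detected with > 80% power at n = 8.

## Pipeline and determinism

`experiment_config` + `run_experiment` orchestrate simulate → condition →
call → compare. All randomness descends from one top-level seed;
per-sample seeds are derived deterministically from (seed, group index,
sample index), so a rerun of the same config is bit-identical, including
the CSV/JSON artifacts. Per-sample and group-level tables, a JSON report
(omnibus, pairwise p, letters) and a parameter log are written when an
output directory is given. A thin command-line wrapper
(`inst/cli/viacool.R`; subcommands `simulate`, `thermal`, `compare`,
`run-all`) exposes the same functions from a shell.

## Problem sizes used in validation

Routine tests run on 40–60 slice stacks of 128–192 px laterally with 5–25
cells — seconds each. Ground-truth recovery is additionally exercised on a
100 × 448 × 448 scene with 250 cells at realistic noise, where called
viability and percent-positive land within 3 percentage points of truth
(exactly equal, in practice, at the default spacing); the statistical
calibration uses 2,000 null simulations. These sizes were chosen so the
full validation completes in minutes on one CPU while still exercising
every stage at realistic density.

## Known limitations

* Blob morphology only; neuritic or confluent cultures would defeat the
  extent screen and the bounding-box rule alike.
* The bounding-box colocalization rule over-calls when somata pack closer
  than about the sum of box half-widths along a diagonal; the generator's
  default spacing keeps scenes in the regime the rule assumes.
* The mismatch shift is supplied, not estimated; subpixel mismatch is out
  of scope.
* The thermal model ignores convective boundary resistance and gel/media
  property contrast; its geometry and diffusivity defaults are documented
  assumptions, not measurements.
* Level-set seeding assumes each cell's nucleus is detected; undetected
  nuclei are silently skipped in the automatic expression path.
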