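---
title: "Holotomographic freezability analysis of sperm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holotomographic freezability analysis of sperm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermHT)
```

## Scientific background

Holotomography (HT) reconstructs the three-dimensional refractive index
(RI) of an unstained cell. Because the RI of biological material scales
with local dry-mass concentration, an RI tomogram is simultaneously a
structural image and a quantitative map: volumes, surface areas and dry
mass can be read off without fixation or fluorescent labels.

Cryopreservation dehydrates spermatozoa and contracts their
compartments. The analysis implemented here quantifies that damage per
cell compartment and summarises it as the **HT Freezability Index**:

\[
\mathrm{FI_{HT}} =
  \frac{\bar V_{\text{freezing extender}}}{\bar V_{\text{fresh reference}}}
  \times 100,
\]

the mean post-thaw regional volume as a percentage of the mean volume in
the same donor's fresh reference sample (extended in INRA96). An index
of 100% means no structural change; values below 100% indicate volume
loss, and values above 100% (swelling) are legal. The ratio is taken
between **sample means**, not per cell: different spermatozoa are imaged
fresh and frozen, so no per-cell pairing exists.

`spermHT` re-implements this pipeline end to end and validates it on
synthetic phantoms whose ground truth is known analytically:

1. a 3D phantom generator with the statistical structure of a
   donor x extender cryopreservation study,
2. RI-window segmentation into compartments,
3. per-region morphometry (volume, surface area, sphericity, projection
   area, dry mass, concentration),
4. CASA-style kinematics from 2D tracks,
5. the freezability indices and donor classification,
6. the statistical comparison (assumption checks, ANOVA on
   arcsine-transformed percentages, Bonferroni pairwise tests).

## Segmentation: RI windows

Compartments are defined purely by RI thresholds, mirroring commercial
HT analysis software:

| region      | RI window        |
|-------------|------------------|
| whole cell  | [1.348, 1.44)    |
| midpiece    | [1.37, 1.39)     |
| nucleus     | [1.39, 1.44)     |

Windows are **half-open**: a voxel exactly at 1.39 belongs to the
nucleus, not the midpiece, so the two sub-windows partition
[1.37, 1.44) without overlap or gap. The tail (and any cytoplasm below
1.37) appears in the whole-cell window only. After thresholding, each
mask is optionally reduced to its largest 26-connected component to
strip isolated noise voxels (`segment_cell()`); with the default noise
level this changes nothing on phantoms but is the safe default for real
data. Connected components and the component tie-break (smallest
flattened voxel index wins among equal sizes) are implemented in C++
because no installed R package provides 3D labelling.

## The phantom generator

`phantom_spec()` describes an idealised spermatozoon in a homogeneous
medium (RI 1.337, safely below the 1.348 window floor):

* **nucleus / head** — ellipsoid, semi-axes (1.1, 0.8, 0.45) µm,
  RI 1.415;
* **midpiece** — cylinder along the head axis, length 1.8 µm, radius
  0.35 µm, RI 1.380;
* **tail segment** — cylinder, length 1.8 µm, radius 0.20 µm, RI 1.360;
* Gaussian RI noise, sd 0.002.

The default voxel pitch is (0.11, 0.11, 0.22) µm — the instrument's
stated lateral and axial resolution used as sampling pitch — on a 64^3
grid. Compartment RIs sit at least 3 noise standard deviations inside
their windows (`check_spec_windows()`), so window purity is effectively
exact.

Two rendering details matter for unbiased volumetry:

* **Junction neck.** Where the midpiece cylinder would overlap the
  nuclear ellipsoid, the overlap sliver is rendered at the *tail* RI
  (visible in the whole-cell window only). This keeps the whole cell one
  connected component while leaving the midpiece window an unbiased
  sample of an exact cylinder — rendering the sliver at midpiece RI
  inflates that compartment by several percent.
* **Sub-voxel jitter.** A phantom at a fixed alignment relative to the
  voxel grid has a systematic voxelisation bias of up to several percent
  in thin compartments. `simulate_study()` jitters every cell's centre
  uniformly within ±0.5 voxel, so sample-mean volumes are unbiased and
  the freezability ratio converges to the generative factor.

Cryo-damage is modelled by `apply_cryo_effect()`: a per-region volume
factor `f` scales the region's linear dimensions by `f^(1/3)`.
`study_design()` draws those factors per cell from per-extender Gaussian
distributions; defaults emulate an 11-stallion, four-freezing-extender
study in which the midpiece is the most affected compartment (mean
factors 0.55–0.78), the nucleus is nearly stable (0.95–0.98), and two
donors are "good coolers" whose susceptibility `s = 0.1` attenuates
any factor towards 1 via `f_eff = 1 - s (1 - f)`.

## Morphometry

* **Volume** is voxel count x voxel volume.
* **Surface area** comes from a marching-tetrahedra iso-surface (level
  0.5) of the mask after Gaussian smoothing (sd = 1 finest-pitch unit,
  applied isotropically in physical space so anisotropic grids are not
  over-smoothed along their coarse axis). Smoothing is essential:
  meshing the raw binary staircase overestimates a sphere's area by
  ~27%, while the smoothed mesh is accurate to well under 1%. Regions
  thinner than the smoothing scale fall back to the unsmoothed mesh so
  they never report a zero surface. Marching tetrahedra are
  hand-implemented in C++ for the same reason as the component
  labelling.
* **Sphericity** is \(\pi^{1/3} (6V)^{2/3} / A\), 1 for a perfect
  sphere; discretisation can push estimates ~1–2% above 1.
* **Dry mass** uses the standard linear RI–concentration relation with
  specific refractive increment \(\alpha = 0.185\) µm³/pg:
  \(m = \sum_v (\mathrm{RI}_v - \mathrm{RI}_{\text{medium}})
  \cdot V_{\text{voxel}} / \alpha\). Noise can push single voxels below
  the medium RI; negative contributions are clipped to zero and counted
  in an attribute rather than silently subtracted.
* **Concentration** is dry mass / volume, so
  concentration x volume = dry mass by construction.

## Kinematics

Tracks are ordered 2D positions at a uniform frame rate. VCL is the
mean frame-to-frame speed along the raw track; VSL the net
start-to-finish displacement over the duration; VAP the speed along a
smoothed average path. The smoother is a centred moving average
(default 5 frames) whose half-width shrinks symmetrically at the track
ends; the endpoints are therefore preserved and a straight track has
VAP exactly equal to VCL and VSL. Straightness is STR = VSL/VAP x 100.

Motility classes use the conventional CASA thresholds: **immotile** when
the average velocity is below 10 µm/s, **progressive** when VAP exceeds
30 µm/s with STR above 80%, otherwise **motile**. "Average velocity" is
read as VAP (the SCA convention) but is configurable, since published
descriptions do not disambiguate. Sample summaries report total
motility TM (% non-immotile), progressive motility PM, and mean
velocities over motile tracks. `simulate_tracks()` generates labelled
mixtures of the three classes for calibration; the classifier recovers
well-separated generative labels at ≥95% (n = 1000).

## Freezability and statistics

`aggregate_freezability()` computes FI_HT per donor x extender x region
from a morphometry table; `classify_cooler()` calls donors good
(all regions ≥ 90%), poor (any region < 80%) or intermediate, either on
extender-pooled indices or per extender. Post-thaw motility is related
to the fresh value as a ratio by default, with a difference form
available because conventions vary.

Percentages are arcsine square-root transformed
(\(\arcsin\sqrt{p/100}\)) before ANOVA. `check_assumptions()` runs
Shapiro–Wilk on within-group-centred values and the Brown–Forsythe
(median-centred) Levene test. `ht_anova()` fits one or two fixed
factors (additive by default, since donor x extender interactions are
weakly identified with one sample per cell) and produces
Bonferroni-corrected pairwise comparisons: pooled-SD t-tests with raw p
multiplied by the number of comparisons, capped at 1. The type-I error
of the fitted model is verified at 5% ± 2% over 1000 simulated nulls.

## Storage formats

Tomograms are multi-page 32-bit TIFF stacks (one page per z-slice)
with a JSON sidecar carrying voxel size, medium RI and metadata. The
TIFF payload stores RI − 1.0 because the writer requires samples in
[0, 1]; the offset is recorded in the sidecar. The 32-bit sample grid
quantises RI at ~2 x 10^-10 — finer than single-precision float; the
writer truncates to that grid, so each write/read cycle can shift a
value by at most one quantisation step, far below the imaging noise. Masks are 8-bit
TIFFs; tracks are CSV with a `# fps=` header line. Malformed track
files (duplicate frames, gaps, missing frame rate) are hard errors.

## Limitations

* Phantoms are idealised solids of revolution; real sperm heads are
  asymmetric paddles and the flagellum is much longer than the rendered
  segment. The generator is built for calibrating the measurement
  pipeline, not for morphological realism.
* Segmentation is purely intensity-based; compartments with overlapping
  RI distributions (severe noise, RI > ~0.01 sd) cannot be separated
  and `check_spec_windows()` refuses such specs.
* Kinematics are 2D projections at a fixed frame rate; fine-scale beat
  parameters (ALH, BCF) are out of scope.
* Fixed-effects ANOVA treats donor as a factor of interest, matching
  the "individual variability" question; no mixed-model machinery is
  provided.
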