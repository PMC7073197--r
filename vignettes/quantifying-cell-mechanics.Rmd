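---
title: "Quantifying cell mechanics and basement-membrane invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell mechanics and basement-membrane invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoinvade)
```

This vignette explains the models behind the package's four pipelines, the
parameters that matter, what the synthetic phantoms emulate, and the
numerical choices made where the methods left room for design.

## 1. Volumetric invasion (Q-Pi)

A cell invading a basement membrane is imaged as a two-channel confocal
z-stack: an actin (cell) channel and a laminin (membrane) channel, acquired
every 0.2 µm in z. Throughout the package slice 1 is the lowest physical z
(the substrate side below the membrane); cells sit on top of the membrane
and invade toward decreasing z.

The pipeline (`run_qpi()`):

1. **Membrane localisation.** The laminin sheet is treated as a horizontal
   plane at a single z position. `locate_membrane()` takes the per-slice
   mean intensity profile of the membrane channel and returns the highest-z
   local maximum exceeding background + 3 robust SDs (median/MAD of the
   profile). The membrane of interest is a *bilayer*; the higher-z peak is
   the upper laminin layer, the surface a cell must cross first, and ties
   resolve upward. Tilt correction is out of scope.
2. **Segmentation.** Each cell-channel slice passes through Gaussian
   smoothing (σ = 1 px), a threshold, morphological closing (3 px disc),
   connected components and boundary tracing (`segment_slice()`, built on
   EBImage). Inside `run_qpi()` the Otsu threshold is computed once over
   the whole 3D channel: a per-slice Otsu threshold would hallucinate
   foreground in slices containing no cell. Standalone `segment_slice()`
   keeps per-slice Otsu but rejects slices whose Otsu separability
   (between-class variance fraction) is below 0.75 — a unimodal noise-only
   image scores ≈ 0.63, a slice with a real object ≥ 0.9.
3. **3D linking.** Regions in adjacent slices belong to the same cell when
   their masks overlap (union-find over slice components). This avoids
   fragile per-slice centroid matching.
4. **Contour reduction.** Every boundary is reduced to its Teh–Chin
   dominant points: each point's region of support grows while the chord
   through its two arms lengthens and the perpendicular-distance ratio
   shrinks; significance is the k-cosine at the support arms, and three
   non-maxima-suppression passes leave the dominant points. On a rasterised
   square exactly the 4 corners survive; on smooth contours the polygon
   stays within 1.5 px of the chain. Regression ellipses are fitted to each
   contour (stable direct least-squares conic fit) for QC; by default the
   hull is built from dominant points, not ellipse outlines
   (`hull_source = "ellipse"` switches), because the volumetric model is
   the hull and the ellipses' role is descriptive.
5. **Reconstruction and clipping.** Dominant points are lifted to physical
   coordinates (voxel centre = index × voxel size) and their 3D convex hull
   (`convex_hull_3d()`, an incremental beneath-beyond implementation) is
   the cell model. The invasion readout is the exact fraction of hull
   volume below the membrane plane: the hull is decomposed into tetrahedra
   (centroid + facets) and each tetrahedron is clipped against the
   half-space analytically (`hull_volume_below()`); the 2-below/2-above
   case is resolved by an exact prism decomposition. No sampling is
   involved; a Monte-Carlo point-in-hull oracle is kept in the package
   (`mc_fraction_below()`) purely as an independent cross-check.

Cells touching the lateral image border are excluded by default (their
volume would be truncated); cells spanning a single slice have no 3D extent
and are skipped with a reason.

For multi-day assays where transmigrated cells detach and fall to the well
bottom, `cumulative_invaded_count()` implements the companion count:
per-ROI daily means divided by the number of mesenteries in the well, with
daily means and standard errors both accumulated as running sums.

## 2. Micropillar traction forces

An elastic micropillar bends like a cantilever under a lateral tip load, so
its stiffness is `k = 3EI/L³` with `I = πd⁴/64`
(`compute_spring_constant()`, reported in nN/µm). For the 2 MPa PDMS
pillars of 5 µm height and 1 µm diameter this gives 2.356 nN/µm.

Tracking (`detect_pillars()`, `track_pillars()`) fits a 2D Gaussian to the
intensity spot of each pillar top — amplitude and offset are profiled out
linearly, leaving a 3-parameter optimisation per window — in a window of
2/3 pitch centred on the previous frame's position. The frame-1 position is
taken as the zero-force rest position; this is the convention of the assay,
with the documented limitation that a cell already pulling at frame 1
biases that pillar's baseline. A pillar whose fit diverges is flagged and
falls back to an intensity centroid rather than aborting the set.

Stage drift is the per-frame mean (optionally median) displacement of
user-chosen cell-free reference pillars and is subtracted from everything
(`correct_drift()`); a reference pillar still moving > 50 nm afterwards
triggers a contamination warning. Forces are `k·|displacement|` per frame;
each pillar's maximum over frames is its peak force. The per-cell aggregate
is the mean of per-pillar peaks by default, with max-of-per-frame-means
exposed as an option — the two conventions circulating for this assay
("mean maximum force" vs "maximum mean force") cannot be reconciled on
paper, and the per-pillar-peak reading matches how peak-force heat maps are
drawn.

## 3. Magnetic-tweezers mechanosensing

The assay applies 12 force pulses of 1 nN (3 s on, 4 s rest) to a
fibronectin-coated bead bound to the cell; a stiffening (mechanosensing)
cell displaces less on later pulses. `segment_pulses()` places one window
per pulse arithmetically from the onset; an unknown onset is estimated by
correlating the displacement derivative with the regime's on/off square
template (exact to one sample on clean traces). Amplitudes are
`Aᵢ = max − start` within each window (`pulse_amplitudes()`): subtracting
the per-pulse start absorbs slow bead drift without detrending, making the
statistic invariant under offsets and rescaling. The headline statistic
(`mechanosensing_metric()`) uses pulses 1 and 12 only — intermediate pulses
are reported for QC — and a bead enters a cohort only when `A₁₂ < A₁`;
beads with negative amplitudes are excluded with a reason code, and a bead
whose `A₁` does not exceed 3× the MAD of its pre-onset baseline (the
package's noise threshold; the assay literature states none) errors as
having no initial response. Cohorts average per-bead ratios rather than
taking the ratio of averaged amplitudes; the alternative would weight
strongly-responding beads more.

## 4. AFM compliance

A spherical indenter of radius R pressed a depth δ into an elastic
half-space experiences `F = (4/3)·E/(1−ν²)·√R·δ^{3/2}` (`hertz_force()`).
`fit_hertz()` estimates E over the contact region of the approach curve up
to a maximum force above baseline (default 1 nN, the usual set force),
with:

* **Contact point** by minimising the joint residual of a flat baseline
  before and the Hertz law after the candidate point (coarse grid +
  golden-section refinement, `estimate_contact_point()`).
* **Deflection correction** `δ = (z − z_c) − F/k`: the cantilever bends as
  it loads, so piezo travel overstates indentation. Whether vendor software
  applies this correction is instrument-dependent; this package does, and
  says so.
* **Baseline re-estimation** from the pre-contact segment, which makes the
  fitted modulus exactly invariant under a constant force offset.
* Poisson ratio ν = 0.5 by default (incompressible cell), exposed as an
  argument. Only approach curves are analysed.

`fit_hertz()` returns a classed model object with `print`, `coef`,
`predict`, `residuals` and `plot` methods; `fit_hertz_batch()` reports
per-curve moduli plus both cohort mean and median, since cohort moduli are
variously summarised either way.

## The phantoms: what they emulate, and what they do not

Each generator is a pure function of its spec (seed included): identical
specs give bit-identical output, and every phantom carries analytic ground
truth.

* **Invasion stacks** (`generate_invasion_stack()`): ellipsoidal cells
  (default intensity 1000) over a membrane bilayer rendered as two
  Gaussian-profile planes 0.8 µm apart (σ_z = 0.2 µm), blurred with an
  isotropic Gaussian PSF (σ = 0.2 µm) and carrying additive Gaussian noise
  (SD 30, clipped at zero) — noise and layer separation are not stated by
  the assay protocols, so these are the package's choices, exposed as
  parameters. Truth comes from the ellipsoid-cap closed form
  `h²(3−h)/4` (`ellipsoid_fraction_below()`). Default stack geometry:
  76 × 128 × 128 voxels at (0.2, 0.1, 0.1) µm.
* **Pillar sequences** (`generate_pillar_sequence()`): Gaussian spots
  (σ = 0.3 µm, amplitude 1000, camera noise SD 20) on an 8 × 8 lattice of
  2 µm pitch at 0.1 µm/px, 60 frames at 1 frame/s, with programmed
  per-pillar displacements plus a global drift series as truth.
* **Bead traces** (`generate_bead_trace()`): 12 × (3 s on / 4 s rest) at
  50 Hz with exponential rise (τ = 0.3 s), a normalised inter-pulse
  relaxation that retains 20% of each pulse permanently (so pulse start
  points creep upward, as real beads drift), 1 nm/s baseline drift and 2 nm
  noise. Truth amplitudes are measured on the noiseless trace with the same
  max−start convention the analysis uses.
* **Force curves** (`generate_force_curve()`): zero-force baseline, then
  the Hertz law solved self-consistently with cantilever deflection at each
  piezo position (R = 7.5 µm, k = 0.03 N/m, 1 nN set force, 5 µm/s, 5 nm
  sampling, 20 pN noise).

They do **not** emulate: realistic confocal optics (anisotropic PSF,
spectral bleed-through, photobleaching), Poisson photon statistics,
non-ellipsoidal or touching cells, membrane tilt or deformation by the
invading cell, pillar bending shapes beyond a linear spring, viscoelastic
(power-law) bead creep, or AFM tip contamination and adhesion. Passing
tests therefore demonstrate that the *computational* chain — segmentation,
geometry, tracking, fitting — is correct at realistic noise levels, not
that the methods are robust to every artefact of real microscopy.

## Numerical choices and problem sizes

* Hull construction uses a relative tolerance of 1e-10 × cloud extent for
  facet visibility; clipped volumes are clamped to `[0, V]` against
  rounding. Degenerate inputs (coplanar, collinear, < 4 distinct points)
  are errors, and ellipse fits flag degeneracy instead of erroring inside
  the pipeline.
* Peak-detection ties in the membrane profile resolve to higher z;
  equal-curvature runs of survivors in the dominant-point suppression
  collapse to the member with the largest support.
* TIFF round trips: integer stacks in [0, 65535] are stored as 16-bit
  pages and recovered exactly; non-integral stacks are stored as 32-bit
  fixed point with a power-of-two scale recorded in the JSON sidecar
  (worst-case error scale/2³², far below fluorescence noise), because the
  TIFF writer available to R has no float sample format.
* The validation suite runs 20 invasion phantoms spanning 0–100% truth
  (mean absolute error observed ≈ 0.2 pp, bound asserted at 3 pp), an
  8 × 8 × 60-frame pillar phantom with 12 loaded pillars, a 30-trace
  tweezer cohort, and Hertz round trips over 50–5000 Pa — sizes chosen to
  mirror one field of view, one dish and one cohort of the corresponding
  experiments while keeping the whole suite in a few minutes on one CPU.

## Known limitations

The hull is convex by construction, so concave cell shapes are
overestimated — the method is explicitly a convex-hull volumetry. Rest
positions equal frame-1 positions, biasing pillars already under load.
Percent invasion cannot see cells that have fully transmigrated and
detached (they leave the stack); the cumulative well-bottom count exists
for exactly that reason, and no censoring correction is applied to the
volumetric readout.
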