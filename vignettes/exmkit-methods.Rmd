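---
title: "Calibrated quantification for 3D expansion microscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated quantification for 3D expansion microscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmkit)
```

# The measurement problem

Expansion microscopy (ExM) embeds a specimen in a swellable hydrogel and
physically inflates it, multiplying the effective optical resolution by the
linear expansion factor (EF). Every quantity measured on an expanded sample
is then conditioned on two calibrations that are themselves measurements:

1. **How much did this region actually expand?** The macroscopic EF (post/pre
   gel dimensions) is a bulk property; locally, small compartments such as
   endosomes can under-expand relative to the bulk gel, which both distorts
   their ultrastructure and biases size estimates.
2. **How faithful is the expanded geometry?** Even after a global similarity
   (scale, rotation, translation) is removed, residual deformation remains
   and must be mapped, not assumed away.

`exmkit` implements the quantitative machinery for both questions and for
the downstream biology (endosomal surface reconstruction, nanodomain
statistics), together with a synthetic-scene generator that gives every
algorithm a ground truth to be tested against.

# Coordinate conventions

All physical quantities are in nm (areas nm², volumes nm³). A volume is a 3D
array indexed `[ix, iy, iz]` with a per-axis voxel size; the centre of voxel
`(i, j, k)` (1-based) is `origin + (c(i,j,k) - 0.5) * voxel`. Pixel units
never cross an I/O boundary.

# Synthetic scenes and what they do (and do not) emulate

`build_scene()` draws:

* **Membrane puncta** on an ellipsoidal shell, area-uniform (by rejection on
  the sphere-to-ellipsoid map) or gathered into `n_clusters` nanoclusters by
  a von Mises–Fisher draw around random axes with concentration kappa. This
  reproduces the punctate, nanoclustered decoration of endosomal membranes
  seen after 10x expansion without committing to a biological clustering
  model; cluster count and concentration are free parameters because the
  source imagery does not constrain them.
* **Interior puncta** uniform in the lumen (strictly inside), emulating
  internalised cargo.
* **Nanocages**: sparse cytoplasmic point sources whose true diameters are
  drawn from Normal(28.3, 1.6) nm — the size distribution of the 60-meric
  protein nanocage used as an in-cell size standard. At generation time they
  are ideal points (fluorescence) or annuli (TEM); blur belongs to the
  renderer.
* **Distortion**: a global isotropic factor plus local radial Gaussian bumps
  `u(q) = a * exp(-|q - c|^2 / (2 f^2)) * (q - c)` applied after the global
  scaling. Negative `a` produces the radially inward shift field
  characteristic of compartment under-expansion. `|a| >= 1` is rejected
  (fold-over), `|a| >= 0.5` warns (invertibility is only guaranteed below
  0.5). The analytic field is available at any point, so flow estimates can
  be scored exactly.

The renderer integrates an anisotropic Gaussian PSF exactly over voxels
(separable CDF differences), conserving intensity to better than 1% for
interior sources, and applies the standard detector model — Poisson on
gain-scaled intensities, then additive Gaussian read noise — both optional so
zero-noise contracts stay exact.

What the generator does **not** emulate: Airyscan detector-array physics and
pixel-reassignment artefacts, gel mechanics (our distortions are imposed, not
emergent), membrane tubules or intraluminal vesicles (deliberately — see the
surface section), and spatially varying background. Tests passing on these
scenes therefore validate the estimators' correctness, not their robustness
to every property of real micrographs.

# Registration (similarity only, on purpose)

`estimate_transform()` registers a pre-expansion volume to its post-expansion
partner with iterative block matching: initialise with the macroscopic EF and
intensity-centroid alignment; per iteration, resample the pre volume through
the current transform, match blocks of the post volume by FFT-accelerated
normalized cross-correlation with parabolic sub-voxel refinement, reject
outliers at 2.5x MAD, and update with the closed-form (Umeyama) least-squares
similarity fit. Iterations stop at the residual tolerance, the iteration cap,
or as soon as the residual stops improving, so the recorded residual sequence
is non-increasing.

Only a similarity is fitted because the residual deformation *is the
measurand*: an anisotropic affine (or any deformable model) would absorb the
distortion signal the next stage is supposed to map.

Implementation notes that matter:

* Blocks whose search window would be clipped by the volume border are
  skipped; clipped windows cannot represent all candidate shifts and bias
  matches toward zero.
* Flat blocks (zero variance) are excluded; fewer than 4 surviving
  correspondences is an error, not a silent fallback.
* Defaults (32³ blocks, stride 16, ±8 search, correlation cutoff 0.3, 5
  iterations, 0.5 nm tolerance) are package choices, exposed in
  `block_match_config()`.

On synthetic pairs the recovered scale is accurate to ~0.1% at 4x and 9.4x
expansion. The registration fixtures render the post volume with the PSF
scaled by the same factor as the coordinates, so the pair differs by exactly
a similarity; with realistic *unscaled* post-ExM PSFs, sparse point scenes
change appearance (pre-expansion blur merges points that expansion resolves)
and no rigid answer exists to recover — real specimens provide the multiscale
texture that makes the method work, and the fixture must, too.

# Distortion mapping

Registered volumes are resectioned into every x–y and x–z plane and a dense
2D displacement field is estimated per plane with a polynomial-expansion
optical flow (quadratic local model under a Gaussian applicability, Gaussian
window accumulation, warping iterations, coarse-to-fine pyramid). The x
component is measured by both plane families and averaged; y comes from x–y
planes, z from x–z planes; a voxel is valid only where both families see
signal (background is excluded below a fraction of the Otsu floor of the
fixed image).

Flow parameters default to 3 pyramid levels, a 7 px polynomial neighbourhood
(`poly_n = 3` half-size), 5 iterations and a 15 px window. For distortion
*mapping* on the 20 nm-voxel fixtures the analysis uses a 39 px window
(Gaussian sigma ~200 nm) and mask-normalised 3D smoothing of the fused field
at sigma 100 nm (`smooth_sigma_nm`): the per-voxel noise tail otherwise
dominates extreme-value read-outs such as the minimum of the radial map,
while the smoothing kernel remains several times smaller than the 400 nm
falloff of the distortion being measured, so the bump amplitude is preserved
(recovered minimum within ~4% of the analytic value on the reference
fixture). Optical flow remains a smoother: magnitudes are reproduced within
tens of percent, not exactly, and the documented end-to-end tolerances
(median angular error < 30°, magnitude within a factor of two) reflect that.

Error versus length scale follows the pair-differential definition:
`RMSE(L) = sqrt(mean |u(p) - u(q)|^2)` over random valid voxel pairs with
`|p - q|` within ±10% of L, and `percent(L) = 100 * RMSE(L) / L`. A uniform
residual shift (registration residue) contributes nothing, which is the
point of the pair-differential form; the raw-magnitude variant is available
behind `method = "magnitude"`. Scales are reported on the post-expansion
physical scale. A scale with fewer than 10 valid pairs is flagged, never
fabricated. For a linear radial field `u = 0.03 (p - c)` the read-out is 3.0%
at every scale, which is the closed-form check the implementation must pass.

`radial_component_map()` projects the field onto unit radial directions from
a centroid; negative values point inward (under-expansion).

# Expansion-factor calibration

* **TEM reference**: nanocage widths from negative-stain-like images. The
  manual path passes through (major, minor) ellipse axes; the automatic path
  thresholds (Otsu refined to the half-max contour between the class
  levels), labels components, fills the annulus hole, and reads axes as
  `4 * sqrt(eigenvalues)` of the mask covariance — exactly the diameter for
  a filled disk (a pixel-footprint variance of 1/12 px² is included).
  Components with axis ratio above 1.2 are rejected as overlapping cages or
  debris; the generator's ellipticity jitter keeps genuine singles below
  ~1.13. Width is `(major + minor) / 2` in both paths.
* **Fluorescence spots**: difference-of-Gaussians detection at a stated
  physical scale, robust MAD seeding, per-spot circular 2D Gaussian fit on
  the in-focus plane, `FWHM = 2 sqrt(2 ln 2) sigma`. Spots failing R² >= 0.8
  or the width range [0.5x, 3x] of the detection scale are flagged, not
  dropped — post-expansion cage widths are genuinely heterogeneous, so
  filters must be loose and visible.
* **Intrinsic EF** = mean accepted spot width / reference diameter. No PSF
  deconvolution by default: the operational definition divides the raw
  fluorescence width by the physical reference, conflating PSF broadening
  with expansion, and the package reproduces that definition; a quadrature
  correction `sqrt(w² - FWHM_psf²)` exists behind an argument and warns,
  because it changes EF values. Both the pooled per-spot EFs and the
  summary are returned, so per-cell or per-gel aggregation is the caller's
  choice.
* **Macroscopic EF** = mean of per-dimension post/pre gel-dimension ratios
  (5 mm -> 47 mm gives 9.4).
* **calibrate_scale()** divides voxel sizes by the EF and records which EF
  (macroscopic or intrinsic) was used; intensities are untouched, the
  operation is exactly invertible, and because the intrinsic EF is typically
  a few percent smaller than the macroscopic one, intrinsically calibrated
  objects come out larger by exactly `ef_macro / ef_intr`.
* **PSF**: bead stacks are centroid-aligned (sub-voxel, trilinear), averaged
  and fitted with 1D Gaussians along each axis; the effective PSF under
  expansion is `FWHM / EF` (170 nm lateral at EF 10 gives 17 nm).

# Endosome surface tracing

The limiting membrane is reconstructed from membrane-marker puncta by an
iterated, averaged Delaunay-hull procedure on a star-shaped radial
parameterisation:

1. centroid := intensity-weighted punctum mean (a manual override exists);
2. per iteration, subsample a fraction (default 0.7) of the puncta, build
   the convex hull of the subsample, and intersect rays from the centroid
   along a fixed icosphere direction set (level 3, 642 directions / 1280
   faces) with the hull;
3. average the per-direction radii over iterations (default 25);
4. smooth the *radial field* on the icosphere neighbour graph (2 Laplacian
   passes, lambda 0.5) and mesh it.

Smoothing the radial field rather than the mesh vertices is deliberate:
vertex-space Laplacian smoothing contracts curved surfaces (about 2% area on
a sphere at this mesh resolution, compounding with the hull's inherent
chord-sag underestimate), whereas the radial field of a sphere is constant
and exactly invariant. With 500 puncta on a 150 nm sphere the traced area
and volume land within ~2–4% of the closed forms.

The star-shaped parameterisation (checked up front: every direction must
have a punctum within 60°) cannot represent concave topologies — tubules,
invaginations, intraluminal vesicles. That is a stated scope limit, not an
accident; such structures require a different representation.

Projection assigns each punctum within ±40 nm (the default band, exposed per
channel) of the surface to its nearest face (ties to the lowest face index)
with a footprint disk of radius width/2; puncta outside the band (e.g.
luminal cargo) are listed separately. A face is occupied if it is an
assigned face or its incenter falls inside a footprint (Euclidean
approximation of the geodesic disk), which makes occupancy monotone under
punctum addition and resolution-controlled by the icosphere level.
Cross-sectional occupancy is a straight pixel ratio over an ROI.

# Puncta statistics

Segmentation works on EF-calibrated volumes so every size filter is in nm:
Gaussian high-pass background subtraction (5x the detection scale — a
rolling-ball equivalent for these scenes), MAD-robust seeding with
non-maximum suppression at 0.75x the detection scale, 3D connected
components (slice labelling + union-find), nearest-seed splitting of
multi-seed regions, and a physical volume filter. Each punctum records an
intensity-weighted centroid, the in-focus-plane fitted FWHM width (fitted on
the unsmoothed background-subtracted signal; fitting the smoothed image
would inflate widths in quadrature), voxel-count volume, integrated
intensity, and a `flagged_merge` elongation flag (in-plane covariance axis
ratio > 1.25) marking regions that may be unresolved pairs — two equal spots
merged at the seed-suppression separation reach ~1.35 while isolated spots
stay near 1.0.

Nearest-neighbour distances are asymmetric (source -> target) centroid
distances; volume/count ratios are totals; the moment-preserving (Tsai)
threshold is computed on the 8-bit min–max-quantized histogram and equals an
exhaustive 256-level moment-matching search by construction (the tests
assert exact agreement); Manders percentages are direct mask-overlap counts
with the moment threshold per channel (3D by default, per-plane behind a
flag, masks stored so results are exactly recomputable); chord tables
normalise per-marker occupancies into arc fractions and demand every
directed pair. Hypothesis testing is out of scope: the toolkit emits tidy
per-observation tables for external statistics software.

# Numerical choices and degenerate inputs

* Zero-variance images refuse flow ("no structure to track"); empty volumes
  segment to empty sets with a message; empty Manders masks make that
  direction NA (undefined), never 0.
* All stochastic operations take a `seed` and restore the caller's RNG
  state; identical spec + seed is bit-identical for point sets and
  voxel-identical for renders.
* The distortion-field sampler rejects voxel pairs whose *actual* rounded
  separation leaves the ±10% band, so lattice rounding cannot bias small
  scales.
* Renders clip sources outside the grid only when `allow_clip = TRUE`;
  silent truncation of signal is otherwise an error.
* Volumes are stored as 32-bit-float multi-page TIFF with a JSON side-car
  carrying voxel size, origin and channel; a volume without a discoverable
  voxel size is an error — 1 nm is never assumed.

# Problem sizes used by the test-suite

The shipped tests run the full pipeline at reduced but non-trivial sizes
chosen to exercise every code path with clear margins: 96³ voxels at 20 nm
for the end-to-end distortion recovery, 104³–120³ post volumes for the 4x
and 9.4x registration recoveries, 500-punctum spheres for surface tracing,
55 rendered nanocages for the calibration chain, and a 2 µm x 2 µm TEM
field (0.5 nm/px) with 138 cages for the width-estimator benchmark. Larger
volumes change runtimes, not conclusions, since every operator is scale-free
in physical units.

# Known limitations

* The block matcher assumes the pre/post pair shares structure at the block
  scale; specimens whose content changes between imaging rounds (bleaching,
  loss) degrade correspondence quality, visible in the diagnostics.
* Optical flow underestimates sharp, small-support displacements and cannot
  see displacement where there is no signal; the validity mask is the
  honest boundary of the measurement.
* The surface tracer is star-shaped by construction (no tubules, no ILVs)
  and assumes the membrane marker outlines the compartment from the
  cytoplasmic side.
* The intrinsic EF inherits PSF broadening by definition; comparisons
  between microscopes with different PSFs should use the quadrature option
  consistently, or not at all.
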