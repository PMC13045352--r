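# exmkit — calibrated quantification for 3D expansion microscopy

Expansion microscopy (ExM) physically inflates a hydrogel-embedded specimen
by a linear expansion factor (EF), multiplying effective optical resolution.
Every nanometre measured on an expanded sample therefore depends on two
calibrations that are themselves measurements: *how much did this region
expand* (the bulk gel EF is not the local EF — small compartments such as
endosomes can under-expand), and *how faithfully* (residual deformation
remains after the global scale and pose are removed). `exmkit` is an R
toolkit for both, plus the downstream endosome quantification, aimed at
microscopists and image analysts working with pre/post-ExM volume pairs.

## What it computes

**Spatial-error analysis.** Pre- and post-ExM volumes of the same region are
registered with an iterative block-matching similarity fit (FFT-accelerated
normalized cross-correlation, sub-voxel refinement, MAD outlier rejection,
closed-form Umeyama update). Only scale s, rotation R and translation t are
fitted — `y = s R x + t` — because the residual deformation is the
measurand. The registered pair is resectioned into x–y and x–z planes, a
dense polynomial-expansion optical flow estimates 2D shift vectors per
plane, and the orthogonal components are fused into a 3D distortion field
u(p) in nm. Error versus length scale L uses the pair-differential form

    RMSE(L) = sqrt( E |u(p) − u(q)|² ),   |p − q| ≈ L,
    percent(L) = 100 · RMSE(L) / L,

which is invariant to uniform registration residue; a signed radial map
u·r̂ exposes compartment under-expansion as negative (inward) values.

**Intrinsic EF calibration.** A 60-meric protein nanocage of known diameter
(~28 nm by negative-stain TEM) serves as an in-cell size standard. The
toolkit measures cage widths in TEM-like images (ellipse axes, width =
(major + minor)/2), fits post-ExM fluorescence spot FWHMs
(FWHM = 2√(2 ln 2)·σ), and reports

    EF_intrinsic = mean spot width / mean TEM width,

alongside the macroscopic EF (gel-dimension ratios), PSF FWHM from averaged
bead stacks, the effective PSF FWHM/EF, and voxel-size recalibration by
either EF.

**Endosome surfaces and nanodomains.** The limiting membrane is traced from
membrane-marker puncta by iterated, averaged Delaunay-hull radial sampling
on an icosphere, giving a watertight mesh with area and volume; puncta
within ±40 nm of the surface are projected onto it and per-channel surface
occupancy, cross-sectional occupancy, nearest-neighbour distances,
volume/count ratios, Manders colocalization with moment-preserving (Tsai)
auto-thresholds, and chord-diagram tables are computed.

**Synthetic scenes.** A first-class generator builds endosome shells with
clustered membrane puncta, luminal puncta, nanocage fields with known true
diameters, anisotropic Gaussian PSF rendering with exact intensity
conservation, Poisson + Gaussian noise, and analytic ground-truth distortion
fields — so the whole pipeline is testable without microscope data.

## Worked example

```r
library(exmkit)

# TEM reference width from a synthetic negative-stain field (truth 28.3 nm)
field <- render_tem_nanocages(nanocage_field_spec(138, 28.3, 1.6),
                              dims = c(4000, 4000), pixel_size = 0.5, seed = 1)
tem <- measure_tem_widths(field$image, pixel_size = 0.5)

# post-ExM nanocage spots rendered at 263.7 nm FWHM, detected and fitted
spots <- detect_spots(vol, scale = 263.7)     # vol: calibratable image_volume
ef <- intrinsic_ef(spots, mean(tem$width))

macroscopic_ef(5, 47)       # gel 5 mm -> 47 mm
effective_psf(170, 10)      # 170 nm lateral PSF under 10x expansion

# trace an endosome from 500 membrane puncta on a 150 nm sphere
mesh <- trace_endosome_surface(puncta, seed = 7)
c(mesh_area(mesh), mesh_volume(mesh))
```

Output from this session:

```
TEM reference: 28.4 +/- 1.6 nm over 133 cages
intrinsic EF: 9.27 +/- 0.02 from 60 accepted spots
macroscopic EF: 9.4
effective lateral PSF at EF 10: 17.0 nm
traced endosome: area 2.75e+05 nm^2 (sphere: 2.83e+05), volume 1.35e+07 nm^3 (sphere: 1.41e+07)
```

The TEM estimator recovers the simulated 28.3 nm population within its
standard error; dividing the 263.7 nm mean spot width by it gives an
intrinsic EF near 9.3, a few percent below the macroscopic 9.4 — the
signature of local under-expansion that motivates intrinsic calibration.
The traced sphere lands within ~3–4% of the closed-form area and volume.

## Command line

A thin CLI wraps the package functions:

```sh
exmkit simulate --seed 3 --out scene/ --n-membrane 400 --radius 150 --render
exmkit register --pre pre.tif --post post.tif --init-scale 9.4 --out t.json
exmkit distort-map --pre pre.tif --post post.tif --transform t.json --out map/
exmkit calibrate --tem tem.csv --spots vol.tif --scale 263.7 --out ef.json
exmkit trace-surface --puncta endofin.csv --band 40 --out endo.ply
exmkit puncta-stats --vol egf.tif --vol2 egfr.tif --out stats/
```

Every run writes a `config.json` echo and a checksummed `manifest.json`
next to its outputs, so identical configs and seeds reproduce identical
artifacts.

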