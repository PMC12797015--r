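---
title: "Fusing histopathological and MRI tumor models in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing histopathological and MRI tumor models in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TumorFusion3D)
```

TumorFusion3D reconstructs a resected soft-tissue tumor twice — from the
pathologist's grossing-slide outlines and from the radiologist's MRI
segmentation — and superimposes both bodies into the scanned specimen's
frame so that volumes, directional extents and diameters can be compared
per case and per cohort. This vignette documents the models and
procedures, the parameters that matter, the synthetic phantom generator
the tests rely on, and the design choices taken where the workflow the
package automates was originally manual CAD work.

## Coordinate conventions

Everything is expressed in one right-handed anatomical frame in mm:
axis 1 is left(+)/right(-), axis 2 posterior(+)/anterior(-), axis 3
cranial(+)/caudal(-) — an LPS-style convention. NIfTI affines (RAS-native)
and NRRD `space` metadata are converted into this frame on load, which
confines sign conventions to the two readers and keeps the measurement
code free of per-format special cases. Volumes are reported in cm^3 and
lengths in cm, the units of the clinical tables the report mirrors;
internal geometry stays in mm to keep coordinates at a comfortable float
scale.

## Surface reconstruction from grossing outlines

The pathologist grosses the specimen into slabs along a freely chosen
direction and outlines tumor on the slides of interest, so the raw
histological representation is an *irregular* stack: closed 2D polygons
(possibly several per slab, possibly with holes for lumina or ulcer pits)
at strictly increasing positions, with gaps where no slide was made.

Reconstruction is shape-based interpolation:

1. each slab's contour set is rasterized to a signed-distance field
   (negative inside; outer polygons combine by union, holes by
   subtraction);
2. between adjacent slab planes the field is interpolated linearly in the
   grossing coordinate — this bridges unsampled gaps smoothly rather than
   fragmenting the body, matching the interpolation framing of the
   original workflow;
3. beyond the first and last slab planes the end-slab field is extruded
   with a linear inflation of 0.5 mm per mm of overhang and closed by a
   far positive plane at half a slab thickness, i.e. a slide proves tumor
   through its own slab and the closure tapers instead of inventing
   tissue;
4. the zero iso-surface of the resulting 3D field is extracted with
   marching tetrahedra.

Explicit contour stitching was rejected because it needs correspondence
heuristics that break on branching or multifocal tumors; the implicit
route handles both for free (two disjoint contours per slab reconstruct
to a two-component mesh whose total volume matches the sum of
single-focus reconstructions to well under 1%).

The iso-surfacer uses the Kuhn (Freudenthal) 6-tetrahedron decomposition
of each grid cell. That decomposition is translation-consistent, so
neighbouring cells share face diagonals, and triangle orientation follows
a fixed combinatorial table per tetrahedron parity — the extracted
surface is therefore watertight with consistent outward normals by
construction, never by numerical luck. Grid samples exactly at the iso
level are nudged by 1e-9 of the field range so every classification is
strict.

**Parameters.** `spacing` (default 0.5 mm, used in-plane and along the
grossing axis) gives at least four samples across the smallest tumor axis
a cohort of this kind contains (3 mm); halving it quadruples runtime for
well under 1% volume change on cohort-scale bodies. Slab `thickness`
defaults to 4 mm when a file omits it, a typical grossing slab.

## MRI mask to mesh

The package consumes the radiologist's segmentation as a binary label
volume; segmentation itself (ADC thresholds, sequence choice) is out of
scope. The mesh is the 0.5-level iso-surface of the binary field sampled
at voxel centers, computed in index-mm space scaled per-axis by the voxel
spacing — anisotropy (3-4 mm slices against ~1 mm in-plane) is handled by
physical-space scaling, not by resampling, which would bias volume
through interpolation. Optional Gaussian pre-smoothing (`smoothSigma`, in
voxels) is exposed but off by default: reproducibility is preferred over
cosmetics. On smooth bodies spanning at least ~5 voxels per axis the mesh
volume stays within ~10% of the voxel-count volume; the residual is the
price of 3-4 mm slices and shrinks with resolution.

## Landmark registration

Pins placed at named anatomy in the operating room and the corresponding
fiducials marked on the MRI model give two small point sets matched *by
name only* — there is deliberately no automatic correspondence search.
The rigid transform minimizing the sum of squared residuals is closed
form (Kabsch via SVD of the cross-covariance; reflections excluded by
forcing det = +1). A similarity variant (Umeyama's scale estimator) is
opt-in for exploring formalin shrinkage (about 4%-6% linear), but rigid
is the default: the workflow being automated superimposes without
scaling. Midlines are represented as two endpoint landmarks to keep the
solver point-based. Exactly collinear configurations are refused rather
than regularized — an under-determined roll should surface as an error,
not a silent guess. Registration quality is reported as the fiducial
registration error (RMS residual); no pass/fail threshold is asserted
because the workflow defines none.

## Measurement and report

Volume is the divergence-theorem sum of signed tetrahedra over faces,
refused (not warned) on non-watertight input, since the integral is
meaningless on an open surface. Directional extents are bounding-box
widths along the three anatomical axes; both bodies are measured in the
specimen frame after registration (the source workflow does not state the
frame; measuring post-fusion is documented here as the package's choice).
The greatest surface diameter is the exact maximum pairwise distance,
computed on convex-hull vertices (quickhull, with a brute-force fallback
for small or degenerate sets) because the maximum is attained there.

Derived columns use half-up rounding (volumes to 2 decimals, lengths and
percentages to 1), the only rounding rule consistent with the published
cohort table this report format mirrors. Two provenance paths exist and
are kept explicit: from meshes, derived columns come from full-precision
measurements; from an ingested table, they come from printed-precision
inputs. The distinction matters because published per-axis percent cells
in such tables can derive from unrounded source measurements and then
disagree with their own printed inputs by one unit in the last digit.

## The phantom generator

`generatePhantom()` builds a fully synthetic case per seed: a star-shaped
tumor (ellipsoid radially modulated by a low-order harmonic mix, amplitude
at most 0.3 so cross-sections stay simple polygons), a specimen as a
radial offset surface, landmarks as pins on the specimen surface, a random
rigid MRI-to-specimen displacement, the tumor rasterized at (1, 1, 3) mm
in the MRI frame, and grossing contours of the (optionally shrunk) tumor.
Defaults are the cohort conditions the package targets: volumes
log-uniform over 0.4-12.6 cm^3, 7-21 grossing slabs with spacing at most
~2.5 mm, MRI slice thickness 3 mm (in-plane pixel size is not reported
for such protocols; 1 mm is assumed and configurable), shrinkage in
[0.94, 1.00]. Truth values (volume, extents, diameter, transform) are
computed from the ground-truth mesh, never from pipeline outputs.

What the phantoms do *not* emulate — and what passing tests therefore do
not show about real data: MRI intensities and segmentation ambiguity
(masks are clean rasterizations), slide-to-slide deformation, tissue
folds, specimen sag during scanning, and landmark placement error (pins
are noiseless, so FRE near 0 is expected, not impressive). Phantom
results bound the *geometric* pipeline error, not observer effects.

## Numerical choices and degenerate inputs

* Half-up decimal rounding everywhere a value is reported; ties away from
  zero.
* STL is a float32 format: coordinates are quantized to float32 on write
  (both encodings) and on ASCII read, so binary and ASCII round-trips load
  bit-identically; vertices are deduplicated by exact coordinate match to
  restore topology from the triangle soup.
* Watertightness is the directed-edge criterion (every edge appears once
  in each direction); it gates volume computation, voxelization and
  cross-sectioning.
* Voxelization labels a voxel iff its center is inside (parity of ray
  crossings), with a sub-voxel irrational ray jitter so rays never hit
  mesh edges exactly.
* Cross-section polygons are chained topologically through shared mesh
  edges (never by floating-point point matching), so loops close exactly;
  cutting planes that would pass through a vertex are nudged by 1e-6 mm.
* Empty meshes, empty masks, all-empty stacks, non-binary label volumes
  and sub-3-landmark registrations are errors with specific messages, not
  silent defaults.

## Problem sizes

The test suite and the acceptance script run cohorts of 20 seeded
phantoms per property (registration recovery uses 100 random transforms),
with reconstruction at the default 0.5 mm grid — sizes chosen because
recovery statistics stabilize well below them while the full suite stays
around a minute on one CPU. All quantitative statements in this vignette
(volume recovery within 5% for convex and 10% for perturbed bodies,
Cavalieri agreement within 15%, ratio tracking 100 x shrinkage^3 within a
few points) are the properties the suite itself computes and asserts.

## Known limitations

* The reconstruction bridges grossing gaps linearly; a pathologist
  skipping a large tumor-free region would be interpolated across unless
  an explicitly empty slice marks it (empty slices are treated as
  unsampled, with a validation warning).
* No deformable registration: specimen deformation between scanning and
  imaging is not corrected, matching the rigid scope of the automated
  workflow.
* No mesh repair: defective input meshes are rejected, not fixed.
* Shrinkage correction is a single isotropic scale; differential
  shrinkage across tissue types is out of scope.
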