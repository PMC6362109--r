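---
title: "Quantifying lung tumor burden from stained micro-CT volumes: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lung tumor burden from stained micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungburden)
```

## Background

Ex vivo micro-CT of iodine-in-ethanol (I2E) stained mouse lungs resolves
tumors, vessels and airways at voxel sizes around 12–13 μm. Because the
iodine stain raises the X-ray absorption of soft tissue, tumorous lesions
appear bright against parenchyma, while air-filled airway lumina stay dark;
the organ itself sits in an ethanol bath of intermediate gray. Tumor burden
can then be measured volumetrically — the fraction of organ voxels occupied
by segmented tumor — rather than from a single stained section.

`lungburden` packages that workflow and, because real stained-lung scans
are rarely shareable, validates every estimator against synthetic phantoms
with exact voxel-level ground truth.

## The segmentation model

### Static-mode seeded region growing

The core operation is a seeded flood fill with a *static* acceptance rule:
a voxel $v$ joins the region grown from seed $s$ when

$$|g(v) - g(s)| \le \tfrac{1}{2}\,\text{tolerance},$$

where $g(\cdot)$ is the gray value and the reference $g(s)$ is the seed
voxel's value, **fixed for the whole growth**. The growth proceeds
breadth-first over a 6-, 18- or 26-neighborhood (default 26), optionally
restricted to a sphere of radius $r$ (in μm, converted through the voxel
size) around the seed and to a domain mask. Regions grown from several
seeds are computed independently and unioned.

Three design choices deserve comment:

* *Seed-fixed reference.* An alternative "dynamic" rule would compare each
  candidate against a running regional mean. We use the seed's value
  because it makes the operator deterministic, independent of visit order,
  and **monotone**: enlarging the tolerance, the radius, or the
  connectivity can only enlarge the mask. These monotonicity properties
  are tested explicitly; a running-mean rule satisfies none of them. The
  commercial tool that inspired the rule does not document its reference
  convention, so the seed-fixed choice is declared here as this package's
  convention, not as a claim about any other implementation.
* *Exclusions restrict the domain, not the output.* An exclusion mask
  (e.g. segmented airways) is removed from the domain *before* growth, so
  a region cannot tunnel through excluded voxels and reappear behind them.
* *Determinism.* For fixed inputs the mask is reproducible bit for bit;
  the breadth-first order never influences membership, only discovery
  order.

The flood fill, together with the 3D ball morphology, connected-component
labelling and cavity filling used below, is implemented in C++ (via Rcpp);
each is verified against exhaustive plain-R reference implementations on
small random volumes (set equality, hundreds of randomized cases).

### Organ mask

The burden denominator is the *entire specimen*: `compute_lung_mask()`
thresholds above the background (ethanol) gray level, applies a
morphological closing with a ball of configurable radius, keeps the largest
26-connected component, and fills enclosed cavities. Cavity filling makes
air-filled airway lumina count as organ volume, which matches the
whole-organ reading of the denominator; a `fill_airways` flag exposes the
alternative. One practical subtlety: the trachea opens at the organ
surface, so the lumina are only *enclosed* after a closing whose radius is
at least the trachea radius. The closing radius therefore defaults to one
voxel above the phantom's trachea radius in the bundled study protocols.

### Airways and tumors

`segment_airways()` region-grows over the dark air voxels from a seed in
the trachea (warning heuristically if the seed looks too bright for air),
restricted to the organ mask. `segment_tumors()` grows from one seed per
lesion — with optional per-seed tolerance/radius overrides, since real
lesions need individual settings — inside the organ mask minus any
exclusion masks, and records per-seed parameters as provenance.

## Quantification

* `volume_fraction(part, whole)` $= 100\,|P \cap W|/|W|$ — the 3D burden.
* `slice_burden(part, whole, axis, index)` — the same ratio on one virtual
  slice (axis 1, the first array axis, is the slicing axis by default).
  The lung-area-weighted mean of `slice_burden` over *all* slices equals
  `volume_fraction` exactly; this conservation identity is tested to
  1e-9 and anchors the 2D-vs-3D comparison.
* `histogram_split(vol, whole, part)` — aligned gray-value histograms of
  the whole organ and the segmented part over identical bin edges; its
  `segmented_fraction_percent` is consistent with `volume_fraction` by
  construction.
* `build_report()` — the three-method comparison per sample: a 2D
  *histology surrogate* (ground-truth tumor label restricted to one
  slice), the segmentation-based area fraction on the same virtual slice,
  and the segmentation-based 3D volume fraction, plus signed errors
  against the label-derived truth when labels exist. CSV output rounds to
  one decimal place; the R object keeps full precision.

The histology surrogate deliberately counts **only the tumor label, never
the halo label**: a pathologist reading an H&E section excludes inflamed
or necrotic tissue that merely stains darker, whereas intensity-based 3D
segmentation cannot. This asymmetry, not pathologist modelling, is what
the surrogate is for — it reproduces the sign structure of the
histology-vs-micro-CT comparison (3D intensity-based estimates run high;
single sections miss out-of-plane tumor in either direction).

## The phantom generator

`generate_phantom()` emulates a reconstructed I2E-stained lung scan, never
the physics of acquisition (no projections, no reconstruction artifacts):

* an ellipsoidal organ (default semi-axes 40 % of each grid axis) of
  parenchyma in an ethanol background;
* a deterministic recursively bifurcating airway tree (default depth 3,
  trachea radius 2.5 voxels, per-generation radius and length decay 0.7,
  branching half-angle 40°) of air-filled lumina with one-voxel
  stain-enhanced walls — deterministic rather than stochastic growth, so
  geometry is reproducible and airway ground truth is exact;
* random vessel segments (default 6, radius 1–2 voxels);
* spherical tumors with optional smooth radial irregularity, either sharp
  or diffuse boundaries, which may overlap (merged lesions);
* an optional *halo* shell per tumor — the morphological dilation of the
  tumor by the halo thickness, clipped to the organ — standing in for
  inflamed/dead tissue; its gray class **defaults to the tumor mean**,
  encoding the stain's non-specificity;
* additive zero-mean Gaussian noise, clipped to the 16-bit range.

Labels (0 background, 1 parenchyma, 2 tumor, 3 airway lumen, 4 halo,
5 vessel/wall) partition the grid exactly. For diffuse boundaries the
intensity ramps linearly from the tumor mean to the parenchyma mean over
the stated ramp width and the label boundary sits at the 50 % intensity
point, giving an unambiguous truth for bias studies.

### Default intensity model

No absolute gray values are reported for any tissue class in this kind of
experiment, so the defaults are free parameters of the phantom — chosen
once to give the contrast *ordering* seen in stained-lung tomograms, and
documented rather than presented as measurements (16-bit scale):

| class | mean gray | rationale |
|---|---|---|
| air (lumen) | 2000 | darkest: no absorber |
| ethanol background | 9000 | bath absorbs less than stained tissue |
| parenchyma | 22000 | stained soft tissue |
| vessel / airway wall | 30000 | denser stained structures |
| tumor | 42000 | strongest stain uptake |
| halo | 42000 (= tumor) | non-specific staining |

Default noise σ = 800 gray units (a conservative noise-to-contrast ratio
of 4 % of the tumor–parenchyma gap); a `well_separated` flag enforces
pairwise class-mean gaps of at least 4σ when requested. Default voxel size
13 μm; grids of at least 32³.

All randomness (vessel placement, tumor surface irregularity, noise) flows
from the spec's single `rng_seed`; identical specs produce bit-identical
volumes. Coordinates are 1-based `(z, y, x)` as usual in R, with axis 1
the virtual-slice axis.

### What the phantom does *not* emulate

Reconstruction streaks, beam hardening, partial-volume blur beyond the
explicit diffuse ramp, Poisson noise statistics, anatomically faithful
murine lobe anatomy, and vascular contrast kinetics. Passing the phantom
studies therefore demonstrates correctness of the *estimators under the
stated contrast model*, not segmentation accuracy on any particular real
scan — on real data, tolerance and seeds remain operator choices.

## Validation studies

The test suite runs four study families (sizes chosen to keep the full
suite in the low minutes on one core):

1. **Oracle equivalence.** The C++ flood fill equals an exhaustive
   plain-R set-expansion reference on >200 random volumes up to 8³ across
   tolerances, radii and connectivities (exact set equality).
2. **Order properties.** Tolerance monotonicity, radius containment and
   monotonicity, and 6 ⊆ 18 ⊆ 26 connectivity nesting on >50 random
   instances each.
3. **Conservation.** Lung-area-weighted slice burdens reproduce the
   volume fraction to 1e-9 on segmented phantom runs.
4. **Parameter recovery.** Twenty sharp-contrast, halo-free phantoms
   (64³–128³, 1–10 tumors of radius 3–15 voxels, noise σ drawn up to 1/8
   of the tumor–parenchyma gap, fixed per-replicate seeds), segmented with
   tolerance equal to the tumor–parenchyma gap, organ threshold midway
   between background and parenchyma, closing radius 4: the absolute
   burden error stays below 1 percentage point in at least 95 % of
   replicates.
5. **Halo bias.** On phantoms with a 2-voxel halo at tumor gray, the 3D
   estimate strictly exceeds the true burden in every replicate (the
   growth cannot distinguish identical gray values), while the histology
   surrogate never counts halo — reproducing the direction intensity-based
   3D estimates deviate from histology.
6. **End-to-end determinism.** The demo pipeline re-run with the same
   configuration is byte-identical.

`scripts/acceptance.R` recomputes these quantities from scratch under a
caller-supplied seed.

### Numerical choices and degenerate inputs

* Ties/tie-breaks: none exist — membership is a pure predicate, so visit
  order is irrelevant.
* The radius restriction compares Euclidean distance between voxel
  centers in μm; anisotropic voxels are out of scope (the target data are
  isotropic).
* Region growth from zero seeds returns an empty mask; an empty organ
  mask, an empty histogram domain, or a virtual slice without lung tissue
  raise descriptive errors rather than NaNs.
* Erosion treats out-of-grid as foreground so masks touching the grid
  border are not eaten by the closing; cavity filling floods the
  background 6-connectedly from the grid border.
* 16-bit TIFF IO is lossless (verified against range edges 0 and 65535);
  voxel size travels in a YAML sidecar because TIFF resolution tags are
  unreliable across writers.

### Known limitations

* At the top of the studied noise range (σ = 1/8 of the class gap) the
  static rule's single-voxel reference makes the growth sensitive to the
  seed's own noise: an unluckily low seed value can let the region
  percolate into the vessel class (only 60 % of the tumor–parenchyma gap
  away), and background noise specks near the organ surface can be
  bridged into the organ mask by the closing. Both effects stay within
  ~1 pp on the studied families but grow with noise. `smooth_volume()`
  (separable 3³ box mean) suppresses both; it is deliberately *opt-in*
  (`bias_study(presmooth_radius = 1)`, pipeline `presmooth_radius`)
  because smoothing in turn under-segments tumors clipped at the organ
  surface by roughly the same magnitude. Real workflows resolve this
  interactively by adjusting per-lesion tolerances.
* Tumor seeds in the bundled studies sit at the true tumor centers — a
  stand-in for the operator's interactive clicks, which makes the
  recovery studies a best-case for seed placement.
* The halo study fixes the overestimation *direction*, not its magnitude,
  which depends entirely on the assumed halo thickness.
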