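# lungburden

Tumor burden quantification in contrast-stained lung micro-CT volumes.

## The problem

Pulmonary tumor burden in mouse models is traditionally scored on a handful
of H&E-stained histological sections: a pathologist outlines the lesions on
one 2D slice and reports the tumor area fraction. A physical section,
however, samples a single plane of a three-dimensional organ — tumors above
and below the plane are invisible, so 2D burden systematically
misrepresents the volumetric disease load. Ex vivo micro-CT of
iodine-in-ethanol (I2E) stained lungs images the whole organ at ~13 μm
voxels without sectioning: tumors and airway lumina can be segmented in 3D
and the burden expressed as a voxel volume fraction. The catch is that the
iodine stain is non-specific — inflamed and dead tissue takes up the stain
like tumor does, so intensity-based 3D segmentation tends to run slightly
high.

`lungburden` implements this whole workflow as tested, scriptable code for
imaging scientists and preclinical oncology labs:

* **seeded 3D region growing** with the *static-mode* gray-value rule: a
  voxel `v` joins the region grown from seed `s` when

  `|g(v) − g(s)| ≤ tolerance / 2`,

  subject to 6/18/26-connectivity, an optional spherical restriction
  `‖x(v) − x(s)‖ ≤ radius` (useful to keep a growth out of the trachea),
  and an optional domain mask;
* **whole-organ mask extraction** (threshold → morphological closing →
  largest 3D component → cavity fill, so air-filled airway lumina count as
  part of the specimen);
* **burden quantification**: 3D volume fraction
  `burden = 100 · |T ∩ L| / |L|`, per-slice 2D area fraction, and the
  gray-value histogram of the whole organ split by the segmented part;
* a **synthetic stained-lung phantom generator** with exact voxel-level
  ground-truth labels (parenchyma, tumor, airway lumen, vessel/wall,
  halo), used to validate the estimators and to quantify the 2D-vs-3D and
  halo biases;
* a reproducible **end-to-end pipeline** and a thin command-line front end.

## Worked example

```r
library(lungburden)

# a 64^3 stained-lung phantom: 3 tumors, airway tree, vessels, noise
res <- run_pipeline(demo_config(rng_seed = 1), "demo_out")
#> [lungburden] phantom: 262144 voxels, 2881 tumor voxels (truth)
#> [lungburden] lung mask: 70308 voxels
#> [lungburden] airways: 435 voxels
#> [lungburden] tumors: 3000 voxels from 3 seed(s)
#> [lungburden] burden: 3D 4.27 %, 2D slice 8.22 % (slice 32)

res$report
#> <lb_burden_report>
#>  sample burden_2d_truth_percent burden_2d_microct_percent
#>    demo                   8.268                      8.22
#>  burden_3d_microct_percent true_3d_percent error_2d_microct error_3d_microct
#>                      4.267           4.097            4.123             0.17
#>  slice_axis slice_index
#>           1          32
```

Reading the numbers: the segmentation recovers the 3D burden (4.27 %
estimated vs 4.10 % true from the labels — the diffuse-boundary tumor adds
a small positive bias). The central virtual slice happens to cut through
the tumors, so both the histology surrogate (8.3 %) and the 2D micro-CT
estimate (8.2 %) are nearly double the volumetric burden — a single 2D
section is a poor proxy for 3D disease load in either direction.
`demo_out/report.csv` holds the three-method comparison
(`he_histological_slice`, `microct_virtual_slice`,
`microct_volumetric_image`), `histogram.csv` the organ/tumor gray-value
histograms, and `provenance.yaml` the full configuration echo.

The same stages are available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lungburden.R", package = "lungburden"))')
Rscript $CLI demo    --out demo_out --seed 1
Rscript $CLI phantom --config spec.yaml --out phantom_dir
Rscript $CLI segment --volume v.tif --config seg.yaml --out masks
Rscript $CLI quantify --volume v.tif --masks masks --labels l.tif \
        --slice axis1:32 --out report.csv
```

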