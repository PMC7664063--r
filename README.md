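# kneemorph

Fully automatic quantification of knee cartilage and meniscus morphology
from labeled 3D MRI volumes, with a synthetic knee-phantom generator that
carries analytic ground truth for every measurement the package produces.

Quantitative knee MRI studies of osteoarthritis need more than cartilage
thickness and volume: both scale with body size, which confounds
cross-sectional comparisons. The measurement at the core of this package is
the **projected cartilage area ratio (PCAR)** — the fraction of a
bone-derived region of interest (the "ideal" cartilage area predicted from
bone morphology) that is actually covered by cartilage thicker than a
threshold *t*:

```
PCAR_t = #{ ROI cells : thickness > t mm } / #{ ROI cells },   t in {0.0, 0.5, 1.0, 1.5}
```

PCAR is dimensionless (1 = full coverage, 0 = none) and, unlike mean
thickness (ThC) or volume (VC), largely independent of stature. Alongside
it the package quantifies medial meniscus extrusion from the same
projection geometry: the **MME area** (projected meniscal area outside the
tibial plateau ROI), the **MME volume** (meniscal volume over those cells),
and the **MMCR** (fraction of the plateau ROI covered by the meniscus).

The pipeline, given a labeled volume (femur, tibia, femoral/tibial
cartilage, menisci):

1. **Projection frames from bone morphology** — a planar frame on the
   tibial plateau (vertical projection) and a least-squares cylinder
   fitted to the femoral condylar surface (cylindrical projection, which
   removes the 1/cos(slope) thickness inflation a flat projection
   suffers on curved cartilage).
2. **ROIs and subregions** — MT/LT plateau ROIs and a three-region femoral
   ROI (MF, Trochlea, LF), each divided 3 x 3 at equal intervals; the
   centre subregion of MT is the mcMT reported in regional analyses.
3. **Thickness maps and morphometry** — ray-based thickness per 2D cell,
   then ThC, VC and PCAR per region and subregion, as a tidy table.
4. **Meniscus extrusion metrics** — cell-level set arithmetic between the
   meniscus footprint and the plateau ROI.
5. **Segmentation** — a 3D U-Net encoder-decoder (two 3x3x3 convolutions +
   batch norm + ReLU per block, max-pool encoder, fusion-by-concatenation
   decoder, softmax probability maps including background) trained by
   soft-Dice maximization with Adam, plus a repeated hold-out Dice
   validation harness and Spearman correlation reporting.

Everything is verified against phantoms (elliptical tibial plateau with a
configurable cartilage plate and C-shaped meniscal wedge; femoral cylinder
sector with a cartilage shell) whose PCAR/ThC/VC/MMCR truths are computed
analytically or by an independent 2D indicator-integration oracle.

## Worked example

```r
library(kneemorph)

spec <- tibial_phantom_spec(
  coverage_fraction  = 0.85,
  cartilage_profile  = thickness_profile("radial", from = 2.8, to = 0.8),
  extrusion_offset_mm = 1.5,
  spacing_mm = c(0.29, 0.29, 0.3))
ph    <- generate_tibial_phantom(spec)
frame <- estimate_tibial_frame(ph$volume)
roi   <- build_tibial_rois(ph$volume, frame)$MT
map   <- project_planar_thickness(ph$volume, frame, roi)
map
#> thickness_map on MT: 6576 ROI cells, covered 85.1%, mean covered 1.47 mm

subset(measure_region(map, subdivide(roi)), subregion == 0)
#>  region subregion metric threshold_mm       value
#>      MT         0    ThC           NA   1.4674414
#>      MT         0     VC           NA 690.2423400
#>      MT         0   PCAR          0.0   0.8505170
#>      MT         0   PCAR          0.5   0.8505170
#>      MT         0   PCAR          1.0   0.6502433
#>      MT         0   PCAR          1.5   0.2804136

fp <- project_footprint(ph$volume, "medial_meniscus", frame)
compute_meniscus_metrics(fp, roi)
#> medial meniscus: MME area 79.39 mm^2, MME volume 309.62 mm^3, MMCR 0.2181
```

Reading the output: 85.1% of the plateau ROI bears cartilage (PCAR0.0 =
0.8505 against the planted coverage 0.85); the radially tapered plate means
progressively less area survives the 1.0 and 1.5 mm thickness thresholds;
VC recovers the analytic plate volume (689.3 mm^3) to 0.1%; and the 1.5 mm
extruded meniscal wedge covers 21.8% of the plateau ROI (analytic overlap
truth 0.2184), with 79.4 mm^2 of meniscus outside the ROI.

A command-line wrapper is installed at `inst/cli/kneemorph`
(`kneemorph demo --out out/ --seed 1` runs the whole chain and writes
`results.csv`, a synthetic cohort, correlation tables and a thickness-map
PNG; `kneemorph validate` runs the scaled-down hold-out segmentation
experiment).

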