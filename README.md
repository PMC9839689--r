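# woundarea

Automatic wound-area measurement from RGB-D captures, for clinicians and
imaging researchers who need contact-free planimetry of pressure injuries
and other chronic wounds. A LiDAR-equipped phone or tablet delivers a
segmentation mask (or a LabelMe polygon) together with a co-registered
per-pixel depth map; this package turns that pair into a wound area in
cm², and provides the evaluation statistics and a synthetic-scene
validation harness around it.

## The method

Given the wound border pixels (u, v) and their depths z, each border
vertex is back-projected through the pinhole camera model

    x = (u − o_x) z / f_x,   y = (v − o_y) z / f_y,

optionally transformed into a world frame by the camera extrinsics
[R | t]. The wound surface is modelled as the least-squares plane

    z = a x + b y + c,

fitted to the 3D border by the regression B = A·(a, b, c)ᵀ with design
matrix rows (xᵢ, yᵢ, 1). The border points are projected orthogonally
onto that plane, and the area is the shoelace (cyclic 2×2 determinant)
sum of the projected vertices' xy-shadow, rescaled by the plane's tilt:

    area = |Σᵢ det[(x'ᵢ, x'ᵢ₊₁); (y'ᵢ, y'ᵢ₊₁)]| / (2 cos θ),

where cos θ = 1/√(a² + b² + 1) is the cosine of the angle between the
fitted plane and the image plane. Quality-control rules flag wounds that
fill less than 20 % of the frame and refuse planes steeper than the
configured guard, where the 1/cos θ rescaling amplifies depth noise
without bound.

Around this core the package implements:

* **Mask handling** — largest-8-connected-component selection,
  Moore-neighbour boundary tracing, even-odd polygon rasterization,
  LabelMe JSON parsing, 512×512 standardization.
* **Segmentation metrics** — Dice, IoU, precision, recall, accuracy and
  the ε-smoothed Dice loss on pixel confusion counts, with macro/micro
  batch aggregation.
* **Area-agreement statistics** — per-wound relative error
  |A* − A| / A, mean relative error (percent) and its n−1 standard
  deviation (fraction), with outlier exclusion; a 20-wound clinical
  reference table is bundled (`clinical_wound_areas()`).
* **Synthetic scenes** — exact planar-polygon renders with known area,
  tilt and frame fill (`tilted_wound_scene()`, `render_scene()`), used
  to validate the full pipeline at sub-percent accuracy.
* **File formats** — 16-bit millimetre-encoded depth PNG (own encoder;
  `png::writePNG` is 8-bit) or plain-text depth matrices, mask PNGs,
  JSON camera configs, JSON/CSV reports, plus a command-line wrapper in
  `inst/cli/woundtool.R`.

## Worked example

Render a synthetic 20 cm² wound on a plane tilted 30° and measure it
back:

```r
library(woundarea)

spec  <- tilted_wound_scene(area_cm2 = 20, tilt_deg = 30,
                            fill_fraction = 0.4)
scene <- render_scene(spec)
scene
#> Synthetic scene: truth area 20.00 cm^2, mask fill 40.0%, 512 x 512 px

m <- measure_wound_area(scene$mask, scene$depth, spec$intrinsics)
summary(m)
#> Wound area: 20.00 cm^2
#>   plane tilt 30.0 deg (cos theta = 0.8660), 1284 border vertices
#>   frame fill: 40.0%, dropped vertices: 0
#>   boundary correction factor: 1.0062
#> Least-squares plane: z = -1.05255e-17 x + 0.57735 y + 0.1274  (n = 1284)
#> Tilt: 30.00 deg from the image plane (cos theta = 0.86603)
```

The measured area agrees with the ground truth to 0.02 %, the fitted
plane recovers the 30° tilt, and the boundary-correction factor shows
the small rasterization adjustment applied to the traced pixel-centre
contour.

Evaluating the bundled clinical comparison (20 wounds, manual
planimetry vs the automatic pipeline driven by a U-Net segmentation),
after excluding the two flagged outliers:

```r
evaluate_area_measurements(area_records("unet"), exclude = c(16, 20))
#> Area measurement evaluation over 18 wound(s) (excluded: 16, 20)
#>   Mean relative error: 26.6%
#>   SD of relative error: 0.23
```

From the shell, the same operations are available via the bundled CLI:

```sh
TOOL=$(Rscript -e 'cat(system.file("cli/woundtool.R", package="woundarea"))')
Rscript "$TOOL" simulate --out-dir scene --area 20 --tilt 30 --fill 0.4
Rscript "$TOOL" measure --mask scene/mask.png --depth scene/depth.png \
        --camera scene/camera.json --out report.json
```

## Vignette

`vignettes/wound-area-measurement.Rmd` documents the measurement model
and its assumptions, the configuration parameters and their defaults,
the synthetic-scene generator's design, the numerical choices
(boundary correction, steep-plane guard, orientation handling), and the
known limitations.
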