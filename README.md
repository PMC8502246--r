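# uavstand

Counting sorghum plants and heads in breeding plots from raw multispectral
UAV captures — without stitching an orthomosaic.

## Why

Plant breeders need per-plot counts of emerged plants (stand) and of grain
heads across hundreds of small plots. Stitched orthomosaics blur leaves and
heads ("ghosting"), which is fatal for counting. `uavstand` instead derives
one high-quality *nadir* reflectance image per plot directly from the raw
captures and counts on that:

1. **Calibration** — raw 16-bit DN → radiance via the vendor model
   `L = V(x,y) · (a1/g) · (p − p_BL) / (t_e + a2·y − a3·t_e·y)` → surface
   reflectance via a calibrated reference panel (`F_i = ρ_i / avg(L_i)`).
2. **Band alignment** — per-band homographies to the green band, estimated
   by enhanced-correlation-coefficient optimisation on gradient images.
3. **Reverse calculation** — world plot/row boundaries lifted through the
   DSM and projected into every capture with the 3×4 `P` matrix
   (`u = x/z`, `v = y/z`); row lines are buffered ±10 cm to keep weeds out.
4. **Nadir selection** — the capture whose view of the plot is closest to
   the image centre.
5. **Counting** — plants: OSAVI → per-image OTSU → open/close → blob
   count. Heads: GEMI-OTSU soil mask → `NDVI_RE < 0.3` head mask →
   contour circularity (`4πA/P²`) → Gaussian-KDE local minima split
   clusters into single/double/triple → `n = s + 2d + 3t`.

A first-class synthetic-flight generator renders a complete trial (raw DN
bands, panel capture, camera solutions, DSM, layout, ground truth) so the
whole pipeline is testable end to end with no field data.

## Worked example

```r
library(uavstand)

# a small synthetic head-stage flight: 2 x 3 plots, known truth
fl  <- generate_flight(2, 3, heads_config = list(), seed = 7)
res <- run_pipeline(fl)
m   <- merge(res$counts, fl$truth$plots, by = "plot_id")
m[1:3, c("plot_id", "n_heads", "true_n_heads")]
#   plot_id n_heads true_n_heads
# 1   P0101      26           26
# 2   P0102      69           69
# 3   P0103      14           15
r_squared(m$n_heads, m$true_n_heads)   # 0.983 on this 6-plot flight
rmse(m$n_heads, m$true_n_heads)        # 2.65 heads per plot
```

`n_heads` is the declustered head count for the plot's nadir image;
`true_n_heads` is what the renderer actually drew. Counts disagree mostly
when the kernel-density valley between double and triple clusters is
shallow and a triple is read as a double — the same drift the field method
shows.

For plant counting, omit `heads_config`; `res$counts$n_plants` is then the
per-plot stand count (sum of the two data rows) and `res$coverage` reports
how many captures fully contain each plot.

## CLI

```sh
Rscript inst/cli/uavstand.R simulate --out flight/ --stage heads --seed 3
Rscript inst/cli/uavstand.R run-all  --flight flight/ --out results/
```

Interchange formats are plain text: ESRI ASCII grids for rasters, GeoJSON
for layouts, CSV for camera solutions and counts, YAML for capture
metadata and configuration.

See `vignettes/uavstand-methods.Rmd` for the model details, the synthetic
world's assumptions, and known limitations.
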