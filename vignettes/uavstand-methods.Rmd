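---
title: "Counting sorghum plants and heads from single UAV captures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting sorghum plants and heads from single UAV captures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breeding trials need per-plot counts of emerged plants and of grain heads
across hundreds to thousands of small plots. Orthomosaics stitched from
overlapping UAV captures blur exactly the features these counts depend on
("ghosting" around leaves and heads), so `uavstand` works on *single raw
captures*: each plot is counted in the one capture that views it closest
to straight overhead (its nadir capture), at the sensor's native spatial
and spectral resolution.

The pipeline has five stages, each exposed as ordinary functions and glued
together by `run_pipeline()`:

1. **Radiometric calibration** (`dn_to_radiance()`, `panel_factor()`,
   `radiance_to_reflectance()`). Raw digital numbers are converted to
   spectral radiance with the vendor model

   $$L = V(x, y)\,\frac{a_1}{g}\,
       \frac{p - p_{BL}}{t_e + a_2 y - a_3 t_e y},$$

   where $p$ is the DN normalised by $2^{\text{bit depth}}$, $p_{BL}$ the
   normalised black level, $t_e$ exposure, $g$ gain, $y$ the 0-based row
   index, and $V$ a radial vignette polynomial
   $V = 1/(1 + \sum_{i=1}^{6} k_i r^i)$ around a metadata-supplied centre.
   Radiance becomes reflectance through the calibrated reference panel:
   $F_i = \rho_i / \overline{L_i}$ per band, applied flight-wide.
   Reflectance is *not* clipped to $[0,1]$; a warning is raised when more
   than 5 % of pixels exceed 1, because specular pixels are useful QA
   signals.

2. **Band alignment** (`estimate_homography()`, `align_capture()`). The
   five lenses are not hardware-registered. A homography per band is
   estimated against the green band by iteratively maximising the enhanced
   correlation coefficient, computed on lightly smoothed gradient-magnitude
   images because raw intensities are not comparable across bands. A
   brute-force integer-shift search at half resolution initialises the
   optimiser (iteration cap 200, stop when the correlation increment falls
   below 1e-6). Because lens geometry is stable within a flight, the
   default mode estimates on five captures spread through the flight and
   applies the element-wise median matrix everywhere.

3. **Reverse calculation** (`buffer_row()`, `lift_polygon()`,
   `project_point()`). Plot polygons and row lines are digitised once in
   world coordinates. Row lines are buffered by 0.10 m on both sides, so
   weeds between rows stay outside the counted area. Vertices take their
   height from the DSM cell that contains them (nearest cell — vertices
   are metres apart, interpolation would add nothing) and are projected
   into every capture with the 3x4 matrix:
   $(x, y, z)^t = P\,(X, Y, Z, 1)^t$, $u = x/z$, $v = y/z$.

4. **Nadir selection and extraction** (`select_nadir()`,
   `extract_plot_image()`). Among captures that contain the full boundary
   (border-inclusive, 0 px margin), the one with the smallest
   centroid-to-image-centre distance wins; ties break to the smallest
   capture id. Plots with no fully containing capture are reported, not
   silently dropped. Pixels are assigned to the plot by
   pixel-centre-in-polygon membership.

5. **Detection.**
   *Plants* (`count_plants()`): OSAVI
   $= 1.16\,(\mathrm{NIR}-\mathrm{Red})/(\mathrm{NIR}+\mathrm{Red}+0.16)$
   is thresholded per row image with OTSU (256 uniform bins over the
   observed range, ties to the lowest edge), opened then closed with a 3x3
   cross, and 8-connected components of at least 4 px are counted. A
   plot's count is the sum over its two data rows. OTSU runs per image, so
   changing light between captures needs no manual thresholds.
   *Heads* (`count_heads()`): a two-step mask — OTSU on GEMI removes soil,
   then within the canopy, pixels with
   $\mathrm{NDVI_{RE}} = (\mathrm{RE}-\mathrm{Red})/(\mathrm{RE}+\mathrm{Red}) < 0.3$
   are heads (leaves score high on red-edge/red contrast; red and white
   heads score low, so one threshold covers both colours). Clusters of at
   least 10 px are contoured (Moore tracing); circularity $4\pi A / P^2$
   is close to 1 for a single round head and drops as heads merge. A
   Gaussian kernel on every circularity value, aggregated on a 512-point
   grid over $[0, 1.3]$, gives a smooth density whose interior local
   minima (the two lowest, at most) split clusters into single, double and
   triple heads, capped at three. The plot total is
   $n = s + 2d + 3t$.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `ndvi_re_threshold` | 0.3 | fixed head/leaf split; transfers across head colours |
| `row_buffer_m` | 0.10 m | half-width of the counted row strip; excludes inter-row weeds |
| `min_area_plants` / `min_area_heads` | 4 / 10 px | below these, specks are noise; few-pixel seedlings are a documented miss mode |
| OTSU bins | 256 | candidate thresholds = bin edges; ties to the lowest |
| `eta_min` | 0.75 | OTSU separability (between/total variance) under which an image counts as single-class; a unimodal Gaussian tops out near 0.64, real vegetation/soil splits sit above 0.9 |
| KDE bandwidth | Silverman's rule, floor 0.02 | the floor prevents a handful of identical circularities from fragmenting the density |
| KDE skip | < 4 clusters | density estimation on 3 points is meaningless; all-single is the dominant class |
| alignment mode | per-flight median of 5 | lens geometry is stable within a flight |

## The synthetic world

`generate_flight()` renders a complete flight so that every stage can be
tested against known truth with no field data. The stated world follows
the trial the method was built for: plots of four 4 m rows (0.6 m between
the two internal data rows, 0.75 m to the guard rows), 5–30 plants per
row in the default, a 20 m flight. The sensor flies at the real
altitude-equivalent ground sampling distance (0.87 cm: focal 2300 px at
20 m) with an 800x600 frame; plants are 3–8 px discs, heads 8–14 px discs.
Plants spread along the full row (drill-sown rows do) and squeeze into
overlap only when the drawn count physically cannot fit — at 100 plants
per plot some neighbours merge, which is the method's documented
undercount mode, not a renderer artefact.

Double and triple head clusters are rendered at centre spacings of 1.6–1.9
head radii, i.e. near-tangent. At closer spacings (under ~1.2 radii) the
union of two discs is analytically almost as circular as a single disc
(circularity 0.86–0.91 versus 0.91), and no shape descriptor could
separate the classes; near-tangency gives ~0.71 (double) and ~0.55
(triple), separable but still overlapping across plots.

Soil carries a band-correlated multiplicative albedo texture (4 cm grain,
sd 0.06) plus per-pixel log-normal noise (sd 0.02) that is independent per
band. The texture matters: without it the only cross-band structure is
sparse plant edges and the intensity-based aligner has nothing to lock
onto — real soil is textured. Ratio indices are invariant to the common
factor by construction, so the detectors are essentially unaffected.

Captures are synthesized by inverting the reflectance and radiance models
with known metadata (non-trivial vignette, per-band exposure and gain),
quantizing to 16-bit DN, and rendering each band through its own injected
similarity warp (up to 4 px translation, 0.5 degree rotation, 0.4 % scale)
that the alignment stage must recover. Rasters are exchanged as ESRI
ASCII grids, layouts as GeoJSON, cameras as CSV, metadata as YAML.

**What a green test does and does not establish.** The renderer draws
discs in class-pure spectra on flat terrain: no shadows, no BRDF, no wind
blur, no open/loose panicles, no oblique head shapes, no green heads in
the default world (their red-edge contrast puts them above the 0.3
threshold — the documented missed-detection mode, available as a spectra
class for stress tests). Passing the synthetic acceptance bounds shows the
pipeline machinery is correct and self-consistent at realistic geometry
and noise; it does not certify accuracy on field imagery.

## Numerical choices and edge cases

- Pixel convention everywhere: `u` = column, `v` = row, 0-based, origin at
  the top-left pixel centre; the renderer and the projector share it.
- DN normalisation base is $2^{\text{bit depth}}$ (16 by default); the
  row-dependent calibration terms act on the raw (unflipped) row axis,
  with a `row_axis` flag since vendor documentation leaves it open.
- Contour perimeter is the traced 8-connected path length (diagonal steps
  $\sqrt 2$); digital circularity of a disc is ~0.91, and very small
  blobs can exceed 1 — they classify as singles, which is the right
  failure direction.
- Bare-soil images: OTSU on a unimodal histogram would split noise, so a
  separability guard (`eta_min`) returns zero plants / an empty head mask
  with a `degenerate_histogram` QC flag instead of an error.
- The per-plot validation statistic is the squared Pearson correlation
  between estimated and true counts, the quantity conventionally reported
  for estimated-versus-observed scatter; RMSE is reported in heads per
  plot.
- `select_nadir()` ties break lexicographically; reruns of the whole
  pipeline on identical inputs are bit-identical (the only RNG use is in
  the generator, which restores the caller's RNG state).

## Known limitations

- Heads piled four or more deep are classified as triples (cap 3).
- The KDE bandwidth occasionally blurs the double/triple valley in plots
  where one class is rare; those triples count as doubles (an undercount
  of one head each). The same drift is described for the field method.
- Oblique (non-nadir) views elongate heads and depress circularity; only
  the nadir capture should be counted.
- The aligner assumes a global homography per band pair: true for rigid
  multi-lens rigs, wrong for rolling-shutter distortion, which is not
  modelled.
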