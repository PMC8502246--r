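#' Count emerged plants in one row (or plot) image
#'
#' OSAVI is computed from the masked nadir sub-image, thresholded with OTSU
#' (vegetation = index above threshold), the binary mask is refined by
#' morphological opening then closing, and 8-connected components of at
#' least `min_area_px` pixels are counted as plants. The threshold is
#' computed per image, so lighting differences between captures need no
#' manual tuning.
#'
#' A bare-soil image yields a unimodal OSAVI histogram; OTSU separability
#' (between-class over total variance) below `eta_min` is treated as
#' degenerate and returns zero plants with a `degenerate_histogram` QC flag
#' rather than an error.
#'
#' @param plot_image a `plot_image` from [extract_plot_image()].
#' @param min_area_px minimum component area (default 4; emerging plants of
#'   only a couple of pixels are a documented miss mode).
#' @param eta_min OTSU separability below which the image counts as
#'   vegetation-free (default 0.75; a unimodal Gaussian tops out near
#'   0.64).
#' @param struct_element structuring element for [refine_mask()].
#' @return A `plant_count`: list with `plot_id`, `capture_id`, `n_plants`,
#'   `component_centroids` (n x 2, capture pixel coordinates), `qc_flags`.
#' @export
count_plants <- function(plot_image, min_area_px = 4L, eta_min = 0.75,
                         struct_element = default_struct_element()) {
  qc <- character()
  osavi <- compute_index(plot_image, "OSAVI")
  thr <- tryCatch(otsu_threshold(osavi),
                  degenerate_histogram_error = function(e) NULL)
  degenerate <- is.null(thr) || attr(thr, "eta") < eta_min
  if (degenerate) {
    return(structure(list(plot_id = plot_image$plot_id,
                          capture_id = plot_image$capture_id,
                          n_plants = 0L,
                          component_centroids = matrix(0, 0, 2),
                          qc_flags = c(qc, "degenerate_histogram")),
                     class = "plant_count"))
  }
  veg <- binary_mask(osavi$values > as.numeric(thr), "osavi_otsu")
  veg <- refine_mask(veg, struct_element = struct_element)
  comp <- connected_components(veg, min_area_px = min_area_px)
  removed <- max(cpp_label_components(veg$values, 8L)) - nrow(comp$components)
  if (removed > 0) qc <- c(qc, "tiny_components_removed")
  centroids <- cbind(comp$components$centroid_u + plot_image$offset[1],
                     comp$components$centroid_v + plot_image$offset[2])
  structure(list(plot_id = plot_image$plot_id,
                 capture_id = plot_image$capture_id,
                 n_plants = nrow(comp$components),
                 component_centroids = centroids,
                 qc_flags = qc),
            class = "plant_count")
}

#' @export
print.plant_count <- function(x, ...) {
  cat(sprintf("<plant_count> plot %s / %s: %d plants%s\n", x$plot_id,
              x$capture_id, x$n_plants,
              if (length(x$qc_flags))
                paste0(" [", paste(x$qc_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
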