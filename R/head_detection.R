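#' Two-step head pixel mask
#'
#' Progressive background masking: (1) OTSU on GEMI removes the soil
#' background, keeping the canopy (leaves plus heads); (2) within the
#' canopy, head pixels are those with `NDVI_RE` below the threshold —
#' green leaves score high on the red-edge/red contrast, heads of any
#' colour score low. Morphological opening and closing then clean the
#' mask. The fixed 0.3 threshold transfers across head colours without
#' re-tuning.
#'
#' @param plot_image a `plot_image` from [extract_plot_image()].
#' @param ndvi_re_threshold head/leaf separation threshold (default 0.3).
#' @param eta_min GEMI OTSU separability under which the image is treated
#'   as having no canopy: returns an empty mask with a QC flag.
#' @param struct_element structuring element for [refine_mask()].
#' @return A [binary_mask()]; attribute `qc_flags` lists degeneracies.
#' @export
head_mask <- function(plot_image, ndvi_re_threshold = 0.3, eta_min = 0.75,
                      struct_element = default_struct_element()) {
  gemi <- compute_index(plot_image, "GEMI")
  thr <- tryCatch(otsu_threshold(gemi),
                  degenerate_histogram_error = function(e) NULL)
  if (is.null(thr) || attr(thr, "eta") < eta_min) {
    empty <- binary_mask(matrix(FALSE, nrow(plot_image$mask),
                                ncol(plot_image$mask)),
                         "gemi_degenerate")
    attr(empty, "qc_flags") <- "degenerate_histogram"
    return(empty)
  }
  canopy <- gemi$values > as.numeric(thr)
  ndvi_re <- compute_index(plot_image, "NDVI_RE")
  heads <- canopy & ndvi_re$values < ndvi_re_threshold
  out <- refine_mask(binary_mask(heads, c("gemi_otsu", "ndvi_re_lt")),
                     struct_element = struct_element)
  attr(out, "qc_flags") <- character()
  out
}

#' Contours and circularity of head clusters
#'
#' Finds 8-connected clusters of at least `min_area_px` pixels, traces the
#' outer boundary of each (Moore neighbourhood tracing) and scores the
#' shape with circularity `4 * pi * area / perimeter^2`: close to one for a
#' single near-circular head and decreasing as heads merge into clusters.
#'
#' @param mask a [binary_mask()] of head pixels.
#' @param min_area_px minimum cluster area (default 10).
#' @return A data.frame of class `head_clusters` with `id`, `area_px`,
#'   `perimeter_px`, `circularity`, `centroid_u`, `centroid_v` and
#'   `multiplicity` (`NA` until classified); the ordered boundary rings sit
#'   in `attr(, "contours")`.
#' @export
cluster_shapes <- function(mask, min_area_px = 10L) {
  comp <- connected_components(mask, min_area_px = min_area_px)
  n <- nrow(comp$components)
  contours <- vector("list", n)
  perim <- numeric(n)
  for (i in seq_len(n)) {
    tr <- cpp_trace_contour(comp$labels, i)
    contours[[i]] <- tr$contour
    perim[i] <- tr$perimeter
  }
  out <- data.frame(id = comp$components$id,
                    area_px = as.numeric(comp$components$area),
                    perimeter_px = perim,
                    circularity = ifelse(perim > 0,
                                         4 * pi * comp$components$area /
                                           perim^2, NA_real_),
                    centroid_u = comp$components$centroid_u,
                    centroid_v = comp$components$centroid_v,
                    multiplicity = NA_integer_)
  attr(out, "contours") <- contours
  class(out) <- c("head_clusters", "data.frame")
  out
}

#' Kernel-density thresholds over cluster circularities
#'
#' Places a Gaussian kernel on every circularity value, aggregates them
#' into a density on a fixed grid, and returns the interior local minima as
#' class boundaries. At most the two lowest-density minima are kept, so
#' clusters split into at most three groups (single/double/triple). A
#' unimodal density yields no thresholds. Unlike a histogram, the smooth
#' estimator does not depend on a bin-count choice.
#'
#' @param circularities numeric vector (>= 1 value).
#' @param bandwidth kernel bandwidth; default Silverman's rule-of-thumb
#'   ([stats::bw.nrd0()]) floored at `bw_floor`.
#' @param bw_floor bandwidth floor (default 0.02).
#' @param grid_n,grid_range evaluation grid (default 512 points over
#'   \[0, 1.3\]).
#' @return Numeric vector of 0, 1 or 2 thresholds, sorted decreasing.
#' @export
kde_circularity_thresholds <- function(circularities, bandwidth = NULL,
                                       bw_floor = 0.02, grid_n = 512L,
                                       grid_range = c(0, 1.3)) {
  x <- circularities[is.finite(circularities)]
  assert_that(length(x) >= 1, "contract_error",
              "need at least one circularity value")
  if (length(x) < 2 || sd(x) == 0) return(numeric())
  if (is.null(bandwidth)) bandwidth <- max(bw.nrd0(x), bw_floor)
  grid <- seq(grid_range[1], grid_range[2], length.out = grid_n)
  dens <- rowMeans(outer(grid, x, function(g, xi)
    dnorm(g, mean = xi, sd = bandwidth)))
  i <- 2:(grid_n - 1)
  is_min <- dens[i] < dens[i - 1] & dens[i] < dens[i + 1]
  mins <- grid[i][is_min]
  if (!length(mins)) return(numeric())
  # keep minima inside the data range, then the two with lowest density
  inside <- mins > min(x) & mins < max(x)
  mins <- mins[inside]
  if (!length(mins)) return(numeric())
  dmin <- dens[match(mins, grid)]
  keep <- mins[order(dmin)][seq_len(min(2L, length(mins)))]
  sort(keep, decreasing = TRUE)
}

#' Classify clusters as single/double/triple heads and count
#'
#' With thresholds `t1 > t2`: circularity `>= t1` is a single head,
#' `[t2, t1)` a double, `< t2` a triple. With one threshold only
#' single/double are assigned; with none every cluster is a single head.
#' The cap of three reflects that larger pile-ups are rare enough to hurt
#' more than help. The head count follows the identity
#' `n_heads = n_single + 2 * n_double + 3 * n_triple`.
#'
#' @param clusters a `head_clusters` data.frame from [cluster_shapes()].
#' @param thresholds numeric vector of 0–2 circularity thresholds, sorted
#'   decreasing.
#' @param plot_id,capture_id identifiers carried into the result.
#' @param qc_flags QC flags carried through.
#' @return A `head_count`: list with `n_single`, `n_double`, `n_triple`,
#'   `n_heads`, `thresholds`, `clusters` (with `multiplicity` filled),
#'   `qc_flags`.
#' @export
classify_and_count <- function(clusters, thresholds = numeric(),
                               plot_id = "plot", capture_id = "capture",
                               qc_flags = character()) {
  assert_that(length(thresholds) <= 2, "contract_error",
              "at most two thresholds")
  if (length(thresholds) > 1)
    assert_that(thresholds[1] > thresholds[2], "contract_error",
                "thresholds must be sorted decreasing")
  circ <- clusters$circularity
  mult <- rep(1L, length(circ))
  if (length(thresholds) >= 1) mult[circ < thresholds[1]] <- 2L
  if (length(thresholds) == 2) mult[circ < thresholds[2]] <- 3L
  clusters$multiplicity <- mult
  n_single <- sum(mult == 1L); n_double <- sum(mult == 2L)
  n_triple <- sum(mult == 3L)
  structure(list(plot_id = plot_id, capture_id = capture_id,
                 n_single = n_single, n_double = n_double,
                 n_triple = n_triple,
                 n_heads = n_single + 2L * n_double + 3L * n_triple,
                 thresholds = thresholds, clusters = clusters,
                 qc_flags = qc_flags),
            class = "head_count")
}

#' @export
print.head_count <- function(x, ...) {
  cat(sprintf(
    "<head_count> plot %s / %s: %d heads (%d single, %d double, %d triple)\n",
    x$plot_id, x$capture_id, x$n_heads, x$n_single, x$n_double, x$n_triple))
  invisible(x)
}

#' Full head-counting pipeline for one plot image
#'
#' [head_mask()] then [cluster_shapes()] then [kde_circularity_thresholds()]
#' then [classify_and_count()]. Plots with fewer than `min_clusters_for_kde`
#' clusters skip the density estimation (meaningless at that sample size)
#' and classify everything as single heads.
#'
#' @param plot_image a `plot_image` from [extract_plot_image()].
#' @param ndvi_re_threshold passed to [head_mask()].
#' @param min_area_px passed to [cluster_shapes()] (default 10).
#' @param min_clusters_for_kde below this, no KDE (default 4).
#' @param bandwidth,bw_floor passed to [kde_circularity_thresholds()].
#' @return A `head_count`.
#' @export
count_heads <- function(plot_image, ndvi_re_threshold = 0.3,
                        min_area_px = 10L, min_clusters_for_kde = 4L,
                        bandwidth = NULL, bw_floor = 0.02) {
  mask <- head_mask(plot_image, ndvi_re_threshold = ndvi_re_threshold)
  qc <- attr(mask, "qc_flags") %||% character()
  clusters <- cluster_shapes(mask, min_area_px = min_area_px)
  thr <- if (nrow(clusters) >= min_clusters_for_kde)
    kde_circularity_thresholds(clusters$circularity, bandwidth = bandwidth,
                               bw_floor = bw_floor)
  else numeric()
  classify_and_count(clusters, thr, plot_id = plot_image$plot_id,
                     capture_id = plot_image$capture_id, qc_flags = qc)
}

#' Tiller ratio per plot
#'
#' Heads divided by plants approximates the number of head-bearing tillers
#' per plant, a trait in its own right.
#'
#' @param n_heads,n_plants non-negative counts (vectors recycle).
#' @return `n_heads / n_plants`, `NA` where `n_plants` is zero.
#' @export
tiller_ratio <- function(n_heads, n_plants) {
  out <- n_heads / n_plants
  out[n_plants == 0] <- NA_real_
  out
}
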