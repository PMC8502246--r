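#' Vegetation indices used by the plant and head detectors
#'
#' Computes one of four indices from a five-band reflectance source:
#' \describe{
#'   \item{OSAVI}{`1.16 * (NIR - Red) / (NIR + Red + 0.16)` — soil-adjusted
#'     index driving plant-pixel thresholding.}
#'   \item{NDVI}{`(NIR - Red) / (NIR + Red)`.}
#'   \item{NDVI_RE}{`(RE - Red) / (RE + Red)` — green leaves (low red, high
#'     red-edge) score high, sorghum heads score low; the 0.3 default
#'     threshold of the head detector keeps pixels below it.}
#'   \item{GEMI}{`eta * (1 - 0.25 * eta) - (Red - 0.125) / (1 - Red)` with
#'     `eta = (2 * (NIR^2 - Red^2) + 1.5 * NIR + 0.5 * Red) /
#'     (NIR + Red + 0.5)` — masks the soil background before head
#'     detection.}
#' }
#' Pixels with a zero denominator, a non-finite input band, or outside the
#' source's valid mask become invalid (`NA`).
#'
#' @param x a [reflectance_stack()] or a `plot_image` from
#'   [extract_plot_image()].
#' @param index_name one of `"OSAVI"`, `"GEMI"`, `"NDVI"`, `"NDVI_RE"`.
#' @return An `index_image`: list with `values` matrix, `index_name`,
#'   `valid_mask`.
#' @export
compute_index <- function(x, index_name) {
  assert_that(index_name %in% c("OSAVI", "GEMI", "NDVI", "NDVI_RE"),
              "configuration_error", "unknown index '%s'", index_name)
  bands <- x$bands
  red <- bands$red; nir <- bands$nir; re <- bands$red_edge
  vals <- switch(index_name,
    OSAVI = 1.16 * (nir - red) / (nir + red + 0.16),
    NDVI = (nir - red) / (nir + red),
    NDVI_RE = (re - red) / (re + red),
    GEMI = {
      eta <- (2 * (nir^2 - red^2) + 1.5 * nir + 0.5 * red) /
        (nir + red + 0.5)
      eta * (1 - 0.25 * eta) - (red - 0.125) / (1 - red)
    })
  vals[!is.finite(vals)] <- NA_real_
  structure(list(values = vals, index_name = index_name,
                 valid_mask = is.finite(vals)),
            class = "index_image")
}

#' OTSU automatic threshold
#'
#' Quantizes the valid values into 256 uniform bins over their observed
#' range and returns the bin-edge threshold minimising the within-class
#' variance (equivalently maximising the between-class variance) between
#' the two sides. Ties resolve to the lowest threshold, so the result is
#' deterministic for a fixed input.
#'
#' @param index an `index_image` or a numeric vector/matrix.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold value, with attributes `eta` (between-class over
#'   total variance at the optimum, a separability score in \[0, 1\]) and
#'   `n_valid`.
#' @export
otsu_threshold <- function(index, n_bins = 256L) {
  vals <- if (inherits(index, "index_image")) index$values else index
  vals <- as.numeric(vals)
  vals <- vals[is.finite(vals)]
  rng <- range(vals)
  if (length(vals) < 2 || diff(rng) == 0)
    uav_error("degenerate_histogram_error",
              "need >= 2 distinct finite values for OTSU")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(vals, edges,
                                            rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)
  cmu <- cumsum(w * mids)
  mu <- cmu[n_bins]
  # between-class variance with threshold after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1L)
  w0 <- cw[k]; m0 <- cmu[k]
  valid <- w0 > 0 & w0 < 1
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (mu * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  best <- which.max(sb)  # which.max takes the first (lowest) maximiser
  thr <- edges[best + 1L]
  tot <- sum(w * (mids - mu)^2)
  structure(thr, eta = if (tot > 0) sb[best] / tot else 0,
            n_valid = length(vals))
}

#' Binary mask with provenance
#' @param values logical matrix (`NA` treated as background).
#' @param provenance character vector of applied processing steps.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, provenance = character()) {
  assert_that(is.matrix(values), "contract_error", "values must be a matrix")
  values[is.na(values)] <- FALSE
  storage.mode(values) <- "logical"
  structure(list(values = values, provenance = provenance),
            class = "binary_mask")
}

# default 3x3 "elliptical" structuring element (cross)
default_struct_element <- function() {
  matrix(c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), 3, 3)
}

shift_mat <- function(m, dv, du, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dv):min(nr, nr + dv)
  cs <- max(1, 1 + du):min(nc, nc + du)
  out[rs, cs] <- m[rs - dv, cs - du, drop = FALSE]
  out
}

erode_mask <- function(m, se) {
  off <- which(se, arr.ind = TRUE) - (dim(se) + 1) / 2
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mat(m, -off[i, 1], -off[i, 2], FALSE)
  out
}

dilate_mask <- function(m, se) {
  off <- which(se, arr.ind = TRUE) - (dim(se) + 1) / 2
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mat(m, off[i, 1], off[i, 2], FALSE)
  out
}

#' Morphological opening followed by closing
#'
#' Opening (erosion then dilation) removes the small noise specks produced
#' by thresholding; closing (dilation then erosion) fills interior holes.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param open_then_close apply opening before closing (default). `FALSE`
#'   swaps the order.
#' @param struct_element logical matrix structuring element (default 3x3
#'   cross, the discrete ellipse of radius 1).
#' @param iterations erosions/dilations per operation.
#' @return A [binary_mask()] with extended provenance.
#' @export
refine_mask <- function(mask, open_then_close = TRUE,
                        struct_element = default_struct_element(),
                        iterations = 1L) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  m <- mask$values
  open_op <- function(m) {
    for (i in seq_len(iterations)) m <- erode_mask(m, struct_element)
    for (i in seq_len(iterations)) m <- dilate_mask(m, struct_element)
    m
  }
  close_op <- function(m) {
    for (i in seq_len(iterations)) m <- dilate_mask(m, struct_element)
    for (i in seq_len(iterations)) m <- erode_mask(m, struct_element)
    m
  }
  m <- if (open_then_close) close_op(open_op(m)) else open_op(close_op(m))
  binary_mask(m, c(mask$provenance,
                   if (open_then_close) c("open", "close")
                   else c("close", "open")))
}

#' Connected pixel clusters of a binary mask
#'
#' 8-connected component labelling with a minimum-area filter; the blob
#' detector behind both the plant and the head counters.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param min_area_px keep components with at least this many pixels.
#' @param connectivity 8 (default) or 4.
#' @return List with `labels` (integer matrix, 0 = background, components
#'   renumbered 1..n after filtering) and `components`, a data.frame with
#'   `id`, `area`, `centroid_u`, `centroid_v` (0-based pixel coordinates).
#' @export
connected_components <- function(mask, min_area_px = 1L, connectivity = 8L) {
  assert_that(min_area_px >= 1, "contract_error", "min_area_px must be >= 1")
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  lab <- cpp_label_components(mask$values, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) {
    return(list(labels = lab,
                components = data.frame(id = integer(), area = integer(),
                                        centroid_u = numeric(),
                                        centroid_v = numeric())))
  }
  area <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(area >= min_area_px)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[idx]
  comp <- data.frame(
    id = seq_along(keep),
    area = area[keep],
    centroid_u = as.numeric(tapply(idx[, 2] - 1, ids, mean)),
    centroid_v = as.numeric(tapply(idx[, 1] - 1, ids, mean)))
  if (!nrow(comp))
    comp <- data.frame(id = integer(), area = integer(),
                       centroid_u = numeric(), centroid_v = numeric())
  list(labels = lab, components = comp)
}
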