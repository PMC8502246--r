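#' Per-capture radiometric and geometric metadata
#'
#' Houses the symbols of the vendor calibration model that converts raw
#' digital numbers (DN) to spectral radiance: radiometric coefficients
#' `a1`–`a3`, the sensor black level, exposure time, gain, and the radial
#' vignette polynomial.
#'
#' @param a1,a2,a3 radiometric calibration coefficients (dimensionless).
#' @param black_level black level in raw DN counts.
#' @param exposure_s exposure time in seconds (> 0).
#' @param gain sensor gain (> 0).
#' @param vignette_center length-2 `(cx, cy)` pixel coordinates (0-based
#'   column, row) of the vignette centre.
#' @param vignette_coeffs six radial polynomial coefficients `k1..k6`.
#' @param bit_depth sensor bit depth; one of 8, 10, 12, 16.
#' @param band_id one of `"blue"`, `"green"`, `"red"`, `"red_edge"`, `"nir"`.
#' @param capture_id capture identifier string.
#' @param row_axis whether the row-dependent terms of the calibration model
#'   act on the raw (`"raw"`, top row = 0) or vertically flipped
#'   (`"flipped"`) row axis. The vendor documentation is silent; exposed as
#'   a flag, default `"raw"`.
#' @return An object of class `capture_meta`.
#' @export
capture_meta <- function(a1, a2 = 0, a3 = 0, black_level = 0,
                         exposure_s, gain = 1,
                         vignette_center = c(0, 0),
                         vignette_coeffs = rep(0, 6),
                         bit_depth = 16L,
                         band_id, capture_id = "capture",
                         row_axis = c("raw", "flipped")) {
  row_axis <- match.arg(row_axis)
  assert_that(all(is.finite(c(a1, a2, a3, black_level))), "invalid_metadata",
              "radiometric coefficients must be finite")
  assert_that(is.finite(exposure_s) && exposure_s > 0, "invalid_metadata",
              "exposure_s must be > 0")
  assert_that(is.finite(gain) && gain > 0, "invalid_metadata",
              "gain must be > 0")
  assert_that(length(vignette_coeffs) == 6 && all(is.finite(vignette_coeffs)),
              "invalid_metadata", "vignette_coeffs must be 6 finite values")
  assert_that(length(vignette_center) == 2 && all(is.finite(vignette_center)),
              "invalid_metadata", "vignette_center must be 2 finite values")
  assert_that(bit_depth %in% c(8L, 10L, 12L, 16L), "invalid_metadata",
              "bit_depth must be one of 8, 10, 12, 16")
  assert_that(band_id %in% .uavstand_bands, "invalid_metadata",
              "unknown band_id '%s'", band_id)
  structure(list(a1 = a1, a2 = a2, a3 = a3, black_level = black_level,
                 exposure_s = exposure_s, gain = gain,
                 vignette_center = as.numeric(vignette_center),
                 vignette_coeffs = as.numeric(vignette_coeffs),
                 bit_depth = as.integer(bit_depth),
                 band_id = band_id, capture_id = capture_id,
                 row_axis = row_axis),
            class = "capture_meta")
}

#' @export
print.capture_meta <- function(x, ...) {
  cat(sprintf("<capture_meta> %s / %s: a1=%g a2=%g a3=%g t_e=%gs g=%g BL=%g\n",
              x$capture_id, x$band_id, x$a1, x$a2, x$a3,
              x$exposure_s, x$gain, x$black_level))
  invisible(x)
}

#' Vignette correction factor per pixel
#'
#' Radial polynomial vignette model
#' `V(x, y) = 1 / (1 + sum_{i=1..6} k_i r^i)` with `r` the Euclidean pixel
#' distance to the vignette centre. Multiplying raw intensities by `V`
#' compensates the radial brightness falloff of the lens.
#'
#' @param meta a [capture_meta()].
#' @param shape integer `(rows, cols)` of the image.
#' @return A `rows x cols` matrix of positive correction factors; exactly 1
#'   at the vignette centre and wherever all coefficients are zero.
#' @export
vignette_factor <- function(meta, shape) {
  assert_that(inherits(meta, "capture_meta"), "contract_error",
              "meta must be a capture_meta")
  assert_that(length(shape) == 2 && all(shape >= 1), "contract_error",
              "shape must be positive (rows, cols)")
  k <- meta$vignette_coeffs
  assert_that(all(is.finite(k)), "invalid_metadata",
              "non-finite vignette coefficients")
  rows <- shape[1]; cols <- shape[2]
  u <- matrix(0:(cols - 1), rows, cols, byrow = TRUE)
  v <- matrix(0:(rows - 1), rows, cols)
  r <- sqrt((u - meta$vignette_center[1])^2 + (v - meta$vignette_center[2])^2)
  poly <- 1 + k[1] * r + k[2] * r^2 + k[3] * r^3 +
    k[4] * r^4 + k[5] * r^5 + k[6] * r^6
  assert_that(all(poly > 0), "invalid_metadata",
              "vignette polynomial non-positive somewhere in the frame")
  1 / poly
}

#' Convert raw digital numbers to spectral radiance
#'
#' Vendor calibration model
#' `L = V(x,y) * (a1/g) * (p - p_BL) / (t_e + a2*y - a3*t_e*y)` where
#' `p = DN / 2^bit_depth` is the normalised DN, `p_BL` the normalised black
#' level and `y` the 0-based pixel row index (rolling-shutter row
#' correction).
#'
#' @param raw matrix of raw DN in `[0, 2^bit_depth - 1]`.
#' @param meta a [capture_meta()].
#' @return A `radiance_image`: list with `values` (W/m^2/sr/nm matrix),
#'   `band_id`, `capture_id`.
#' @export
dn_to_radiance <- function(raw, meta) {
  assert_that(inherits(meta, "capture_meta"), "contract_error",
              "meta must be a capture_meta")
  assert_that(is.matrix(raw), "contract_error", "raw must be a matrix")
  scale <- 2^meta$bit_depth
  p <- raw / scale
  p_bl <- meta$black_level / scale
  rows <- nrow(raw)
  y <- 0:(rows - 1)
  if (meta$row_axis == "flipped") y <- rev(y)
  denom <- meta$exposure_s + meta$a2 * y - meta$a3 * meta$exposure_s * y
  bad <- which(denom <= 0)
  if (length(bad))
    uav_error("calibration_metadata_error",
              "calibration denominator <= 0 at image row %d", bad[1] - 1L)
  V <- vignette_factor(meta, dim(raw))
  L <- V * (meta$a1 / meta$gain) * (p - p_bl) / denom  # denom recycles by row
  structure(list(values = L, band_id = meta$band_id,
                 capture_id = meta$capture_id),
            class = "radiance_image")
}

#' Known reflectance panel used for radiance-to-reflectance conversion
#'
#' @param known_reflectance named numeric vector, one entry per band, each
#'   strictly inside (0, 1).
#' @param panel_polygon `n x 2` matrix of `(u, v)` pixel vertices (n >= 3)
#'   enclosing a region strictly inside the panel.
#' @return An object of class `panel_reference`.
#' @export
panel_reference <- function(known_reflectance, panel_polygon) {
  assert_that(all(known_reflectance > 0 & known_reflectance < 1),
              "invalid_metadata", "panel reflectances must be in (0, 1)")
  assert_that(is.matrix(panel_polygon) && nrow(panel_polygon) >= 3,
              "geometry_error", "panel polygon needs >= 3 vertices")
  structure(list(known_reflectance = known_reflectance,
                 panel_polygon = panel_polygon),
            class = "panel_reference")
}

#' Reflectance calibration factor from a panel capture
#'
#' `F_i = rho_i / avg(L_i)` where the average runs over the pixels whose
#' centres fall inside the panel polygon.
#'
#' @param panel_radiance a `radiance_image` of the panel capture.
#' @param ref a [panel_reference()].
#' @return Positive scalar factor for the image's band.
#' @export
panel_factor <- function(panel_radiance, ref) {
  assert_that(inherits(ref, "panel_reference"), "contract_error",
              "ref must be a panel_reference")
  L <- panel_radiance$values
  rho <- ref$known_reflectance[[panel_radiance$band_id]]
  assert_that(!is.null(rho), "invalid_metadata",
              "no panel reflectance for band '%s'", panel_radiance$band_id)
  uv <- expand.grid(u = 0:(ncol(L) - 1), v = 0:(nrow(L) - 1))
  inside <- point_in_polygon(uv$u, uv$v, ref$panel_polygon)
  if (!any(inside)) uav_error("geometry_error", "panel polygon interior empty")
  mL <- mean(L[cbind(uv$v[inside] + 1, uv$u[inside] + 1)], na.rm = TRUE)
  if (!is.finite(mL) || mL <= 0)
    uav_error("degenerate_panel_error",
              "mean panel radiance %.4g is not positive", mL)
  rho / mL
}

#' Scale radiance to surface reflectance
#'
#' Applies the per-band panel factor: `reflectance = F_i * L`. Values are
#' deliberately not clipped to \[0, 1\]; specular pixels above 1 are
#' informative for QA, and a warning is raised when more than 5% of pixels
#' exceed 1.
#'
#' @param rad a `radiance_image`.
#' @param factor positive scalar from [panel_factor()].
#' @return Matrix of dimensionless reflectance.
#' @export
radiance_to_reflectance <- function(rad, factor) {
  assert_that(is.finite(factor) && factor > 0, "contract_error",
              "panel factor must be > 0")
  refl <- factor * rad$values
  frac_over <- mean(refl > 1, na.rm = TRUE)
  if (is.finite(frac_over) && frac_over > 0.05)
    warning(sprintf("%.1f%% of pixels exceed reflectance 1 (band %s)",
                    100 * frac_over, rad$band_id))
  refl
}

#' Five-band reflectance stack for one capture
#'
#' @param bands named list of equally sized reflectance matrices; all of
#'   blue, green, red, red_edge, nir must be present.
#' @param capture_id capture identifier.
#' @param aligned whether the bands have already been registered to the
#'   green band.
#' @return An object of class `reflectance_stack`.
#' @export
reflectance_stack <- function(bands, capture_id = "capture",
                              aligned = FALSE) {
  assert_that(all(.uavstand_bands %in% names(bands)), "contract_error",
              "all five bands must be present")
  dims <- vapply(bands, dim, integer(2))
  assert_that(all(dims == dims[, 1]), "contract_error",
              "all bands must share one shape")
  structure(list(bands = bands[.uavstand_bands], capture_id = capture_id,
                 aligned = isTRUE(aligned)),
            class = "reflectance_stack")
}

#' @export
print.reflectance_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<reflectance_stack> %s: %d x %d x 5 bands, %saligned\n",
              x$capture_id, d[1], d[2], if (x$aligned) "" else "not "))
  invisible(x)
}
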