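#' Camera solution for one capture
#'
#' @param capture_id capture identifier.
#' @param P 3x4 projection matrix mapping homogeneous world `(X, Y, Z, 1)`
#'   to homogeneous image `(x, y, z)`; must have rank 3.
#' @param position `(X, Y, Z)` camera position in world metres.
#' @param image_size integer `(rows, cols)`.
#' @return An object of class `camera_solution`.
#' @export
camera_solution <- function(capture_id, P, position, image_size) {
  assert_that(is.matrix(P) && all(dim(P) == c(3, 4)), "contract_error",
              "P must be 3x4")
  assert_that(qr(P)$rank == 3, "contract_error", "P must have rank 3")
  structure(list(capture_id = capture_id, P = P,
                 position = as.numeric(position),
                 image_size = as.integer(image_size)),
            class = "camera_solution")
}

#' Digital surface model on a regular north-up grid
#'
#' @param elevations matrix of elevations in metres (row 1 = northern edge).
#' @param xll,yll world coordinates of the lower-left corner of the grid.
#' @param cellsize cell size in metres.
#' @param nodata value marking missing cells.
#' @return An object of class `dsm_grid`.
#' @export
dsm_grid <- function(elevations, xll, yll, cellsize, nodata = -9999) {
  assert_that(is.matrix(elevations) && cellsize > 0, "contract_error",
              "elevations must be a matrix with positive cellsize")
  structure(list(elevations = elevations, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "dsm_grid")
}

#' Plot or row boundary in world coordinates
#'
#' @param plot_id plot identifier.
#' @param kind `"row"` or `"plot"`.
#' @param vertices `n x 2` matrix of `(X, Y)` world metres forming a
#'   non-self-intersecting ring (first vertex not repeated), n >= 3.
#' @return An object of class `world_boundary`.
#' @export
world_boundary <- function(plot_id, kind = c("plot", "row"), vertices) {
  kind <- match.arg(kind)
  assert_that(is.matrix(vertices) && nrow(vertices) >= 3, "geometry_error",
              "boundary ring needs >= 3 vertices")
  assert_that(!ring_self_intersects(vertices), "geometry_error",
              "boundary ring is self-intersecting (plot %s)", plot_id)
  structure(list(plot_id = plot_id, kind = kind,
                 vertices = unname(vertices)),
            class = "world_boundary")
}

#' Buffer a row line into a rectangular row boundary
#'
#' Plant rows are digitised as straight 2-point lines; buffering by 10 cm
#' on both sides creates the row boundary used for plant counting, keeping
#' weeds between the rows out of the counts.
#'
#' @param line 2x2 matrix: rows are the `(X, Y)` endpoints in world metres.
#' @param half_width_m perpendicular buffer distance (default 0.10 m).
#' @param plot_id plot identifier attached to the boundary.
#' @return A [world_boundary()] of kind `"row"` with 4 vertices.
#' @export
buffer_row <- function(line, half_width_m = 0.10, plot_id = "row") {
  assert_that(is.matrix(line) && all(dim(line) == c(2, 2)), "contract_error",
              "line must be a 2x2 matrix of endpoints")
  d <- line[2, ] - line[1, ]
  len <- sqrt(sum(d^2))
  if (len <= 0) uav_error("geometry_error", "zero-length row line")
  n <- c(d[2], -d[1]) / len
  ring <- rbind(line[1, ] + half_width_m * n,
                line[2, ] + half_width_m * n,
                line[2, ] - half_width_m * n,
                line[1, ] - half_width_m * n)
  world_boundary(plot_id, "row", ring)
}

#' Lift a 2-D boundary onto the surface model
#'
#' Samples the elevation of the DSM cell containing each vertex
#' (nearest-cell; vertices are metres apart so interpolation is not
#' warranted).
#'
#' @param boundary a [world_boundary()].
#' @param dsm a [dsm_grid()].
#' @return `n x 3` matrix of `(X, Y, Z)`.
#' @export
lift_polygon <- function(boundary, dsm) {
  v <- boundary$vertices
  nr <- nrow(dsm$elevations); nc <- ncol(dsm$elevations)
  col <- floor((v[, 1] - dsm$xll) / dsm$cellsize) + 1L
  row <- nr - floor((v[, 2] - dsm$yll) / dsm$cellsize)
  for (i in seq_len(nrow(v))) {
    if (col[i] < 1 || col[i] > nc || row[i] < 1 || row[i] > nr)
      uav_error("out_of_extent_error",
                "vertex %d (%.2f, %.2f) outside DSM extent",
                i, v[i, 1], v[i, 2])
    if (dsm$elevations[row[i], col[i]] == dsm$nodata)
      uav_error("out_of_extent_error", "vertex %d on DSM nodata cell", i)
  }
  cbind(v, Z = dsm$elevations[cbind(row, col)])
}

#' Project world points into a capture
#'
#' `(x, y, z)^t = P (X, Y, Z, 1)^t`, `u = x/z`, `v = y/z`; `u` is the
#' 0-based image column and `v` the 0-based row, origin at the top-left
#' pixel centre.
#'
#' @param P 3x4 projection matrix.
#' @param world `(X, Y, Z)` vector or `n x 3` matrix.
#' @return `n x 2` matrix of `(u, v)` pixel coordinates.
#' @export
project_point <- function(P, world) {
  if (!is.matrix(world)) world <- matrix(world, nrow = 1)
  h <- P %*% rbind(t(world), 1)
  z <- h[3, ]
  if (any(z == 0)) uav_error("point_at_infinity_error",
                             "projected point at infinity (z = 0)")
  if (any(z < 0)) uav_error("behind_camera_error",
                            "world point behind the camera (z < 0)")
  cbind(u = h[1, ] / z, v = h[2, ] / z)
}

#' One plot boundary as seen in one capture
#'
#' @param plot_id,capture_id identifiers.
#' @param pixel_polygon `n x 2` matrix of `(u, v)` vertices.
#' @param image_size `(rows, cols)` of the capture.
#' @param kind boundary kind, carried through from the world boundary.
#' @return A `plot_view` with `fully_contained` (every vertex inside the
#'   pixel-centre grid, border inclusive) and `center_distance` (pixels
#'   from the polygon centroid to the image centre).
#' @export
plot_view <- function(plot_id, capture_id, pixel_polygon, image_size,
                      kind = "plot") {
  rows <- image_size[1]; cols <- image_size[2]
  contained <- all(pixel_polygon[, 1] >= 0 & pixel_polygon[, 1] <= cols - 1 &
                   pixel_polygon[, 2] >= 0 & pixel_polygon[, 2] <= rows - 1)
  ctr <- polygon_centroid(pixel_polygon)
  dist <- sqrt((ctr[1] - (cols - 1) / 2)^2 + (ctr[2] - (rows - 1) / 2)^2)
  structure(list(plot_id = plot_id, capture_id = capture_id,
                 pixel_polygon = pixel_polygon, kind = kind,
                 fully_contained = contained, center_distance = dist),
            class = "plot_view")
}

#' Project a world boundary into every capture
#'
#' @param boundary a [world_boundary()].
#' @param cameras list of [camera_solution()]s.
#' @param dsm a [dsm_grid()].
#' @return List of `plot_view`s, one per capture in which the projection
#'   succeeded (captures for which the boundary falls behind the camera are
#'   skipped).
#' @export
project_boundary <- function(boundary, cameras, dsm) {
  xyz <- lift_polygon(boundary, dsm)
  views <- list()
  for (cam in cameras) {
    uv <- tryCatch(project_point(cam$P, xyz), uavstand_error = function(e) NULL)
    if (is.null(uv)) next
    views[[length(views) + 1L]] <-
      plot_view(boundary$plot_id, cam$capture_id, uv, cam$image_size,
                kind = boundary$kind)
  }
  views
}

#' Select the nadir view of a plot
#'
#' Among the fully contained views the one whose polygon centroid is
#' closest to the image centre; ties break to the lexicographically
#' smallest capture id. `NULL` when no view is fully contained (the plot is
#' then reported as not fully captured).
#'
#' @param views list of `plot_view`s sharing one `plot_id`.
#' @return A `plot_view` or `NULL`.
#' @export
select_nadir <- function(views) {
  if (!length(views)) return(NULL)
  ids <- unique(vapply(views, `[[`, "", "plot_id"))
  assert_that(length(ids) == 1, "contract_error",
              "select_nadir: views span several plot_ids (%s)",
              paste(ids, collapse = ", "))
  full <- Filter(function(v) v$fully_contained, views)
  if (!length(full)) return(NULL)
  dist <- vapply(full, `[[`, 0, "center_distance")
  cap <- vapply(full, `[[`, "", "capture_id")
  full[[order(dist, cap)[1]]]
}

#' Extract the masked plot sub-image from an aligned capture
#'
#' Crops the bounding box of the pixel polygon from all five bands and
#' marks pixels whose centres fall outside the polygon as invalid (`NA`).
#'
#' @param stack an aligned [reflectance_stack()].
#' @param view a fully contained `plot_view`.
#' @return A `plot_image`: list with `bands` (masked crops), `mask`
#'   (logical), `offset` (`(u0, v0)` of the crop origin in capture pixels),
#'   `plot_id`, `capture_id`, `kind`.
#' @export
extract_plot_image <- function(stack, view) {
  assert_that(stack$aligned, "contract_error",
              "stack must be aligned before plot extraction")
  assert_that(view$fully_contained, "contract_error",
              "view is not fully contained in the capture")
  poly <- view$pixel_polygon
  if (polygon_area(poly) <= 0)
    uav_error("empty_extraction_error", "pixel polygon has zero area")
  d <- dim(stack$bands[[1]])
  u0 <- max(0L, floor(min(poly[, 1]))); u1 <- min(d[2] - 1L, ceiling(max(poly[, 1])))
  v0 <- max(0L, floor(min(poly[, 2]))); v1 <- min(d[1] - 1L, ceiling(max(poly[, 2])))
  us <- u0:u1; vs <- v0:v1
  grid_u <- matrix(us, length(vs), length(us), byrow = TRUE)
  grid_v <- matrix(vs, length(vs), length(us))
  mask <- matrix(point_in_polygon(as.numeric(grid_u), as.numeric(grid_v),
                                  poly),
                 length(vs), length(us))
  if (!any(mask))
    uav_error("empty_extraction_error", "no pixel centres inside polygon")
  bands <- lapply(stack$bands, function(b) {
    crop <- b[vs + 1L, us + 1L, drop = FALSE]
    crop[!mask] <- NA_real_
    crop
  })
  structure(list(bands = bands, mask = mask, offset = c(u0, v0),
                 plot_id = view$plot_id, capture_id = view$capture_id,
                 kind = view$kind),
            class = "plot_image")
}
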