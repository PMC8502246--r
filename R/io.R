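## Plain-text interchange formats. Rasters use the ESRI ASCII grid, which
## carries the same geotransform information as a single-band GeoTIFF in a
## text container; layouts are GeoJSON; camera solutions are CSV; capture
## metadata are YAML sidecars mirroring the calibration-model symbols.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values numeric matrix (row 1 = northern edge).
#' @param path output file.
#' @param xll,yll lower-left corner world coordinates.
#' @param cellsize cell size in metres (rasters) or pixels.
#' @param nodata nodata marker.
#' @export
write_ascii_grid <- function(values, path, xll = 0, yll = 0, cellsize = 1,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(values)),
               sprintf("nrows %d", nrow(values)),
               sprintf("xllcorner %.10g", xll),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", cellsize),
               sprintf("NODATA_value %.10g", nodata)), con)
  vals <- values
  vals[is.na(vals)] <- nodata
  write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file written by [write_ascii_grid()] (or any ESRI .asc).
#' @return A [dsm_grid()]; the raw matrix sits in `$elevations`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[[`, "", 1))
  val <- as.numeric(vapply(kv, `[[`, "", 2))
  names(val) <- key
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == val[["nodata_value"]]] <- NA
  dsm_grid(m, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
           cellsize = val[["cellsize"]], nodata = val[["nodata_value"]])
}

#' Write a plot/row layout as GeoJSON
#'
#' Plots are written as Polygon features, rows as 2-point LineString
#' features; both carry `plot_id` and `kind` properties.
#'
#' @param layout list with `plots` (list of [world_boundary()]) and `rows`
#'   (list of `list(plot_id, row_index, line)`).
#' @param path output file.
#' @export
write_layout <- function(layout, path) {
  feats <- list()
  for (p in layout$plots) {
    ring <- rbind(p$vertices, p$vertices[1, ])
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(plot_id = p$plot_id, kind = "plot"),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(split(ring, row(ring))))))
  }
  for (r in layout$rows) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(plot_id = r$plot_id, kind = "row",
                        row_index = r$row_index),
      geometry = list(type = "LineString",
                      coordinates = unname(split(r$line, row(r$line)))))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON plot/row layout
#' @param path GeoJSON file with Polygon (plot) and LineString (row)
#'   features carrying a `plot_id` property.
#' @return List with `plots` and `rows` as in [write_layout()].
#' @export
read_layout <- function(path) {
  gj <- jsonlite::read_json(path)
  plots <- list(); rows <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    pid <- f$properties$plot_id
    if (is.null(pid))
      uav_error("schema_error", "feature %d has no plot_id property", i)
    ty <- f$geometry$type
    coords_to_mat <- function(cc)
      do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p))))
    if (ty == "Polygon") {
      ring <- coords_to_mat(f$geometry$coordinates[[1]])
      if (all(ring[1, ] == ring[nrow(ring), ]))
        ring <- ring[-nrow(ring), , drop = FALSE]
      plots[[pid]] <- world_boundary(pid, "plot", ring)
    } else if (ty == "LineString") {
      rows[[length(rows) + 1L]] <- list(
        plot_id = pid, row_index = f$properties$row_index %||% NA_integer_,
        line = coords_to_mat(f$geometry$coordinates))
    } else {
      uav_error("schema_error", "feature %d: unsupported geometry %s", i, ty)
    }
  }
  list(plots = plots, rows = rows)
}

#' Write camera solutions as CSV
#'
#' One row per capture: `capture_id`, the 12 projection-matrix entries
#' row-major (`p11..p34`), camera `X, Y, Z` and the image size.
#'
#' @param cameras list of [camera_solution()]s.
#' @param path output file.
#' @export
write_cameras_csv <- function(cameras, path) {
  df <- do.call(rbind, lapply(cameras, function(cm) {
    p <- as.numeric(t(cm$P))
    d <- data.frame(capture_id = cm$capture_id)
    for (i in 1:12) d[[sprintf("p%d%d", (i - 1) %/% 4 + 1,
                               (i - 1) %% 4 + 1)]] <- p[i]
    d$X <- cm$position[1]; d$Y <- cm$position[2]; d$Z <- cm$position[3]
    d$rows <- cm$image_size[1]; d$cols <- cm$image_size[2]
    d
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read camera solutions from CSV
#' @param path file written by [write_cameras_csv()].
#' @return List of [camera_solution()]s.
#' @export
read_cameras_csv <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    P <- matrix(as.numeric(df[i, sprintf("p%d%d", rep(1:3, each = 4),
                                         rep(1:4, 3))]),
                3, 4, byrow = TRUE)
    camera_solution(df$capture_id[i], P,
                    c(df$X[i], df$Y[i], df$Z[i]),
                    c(df$rows[i], df$cols[i]))
  })
}

#' Write per-capture radiometric metadata as a YAML sidecar
#' @param meta named list (by band) of [capture_meta()] for one capture.
#' @param path output file.
#' @export
write_capture_meta <- function(meta, path) {
  yaml::write_yaml(lapply(meta, function(m) unclass(m)), path)
  invisible(path)
}

#' Read a YAML capture-metadata sidecar
#' @param path file written by [write_capture_meta()].
#' @return Named list (by band) of [capture_meta()].
#' @export
read_capture_meta <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(m)
    capture_meta(a1 = m$a1, a2 = m$a2, a3 = m$a3,
                 black_level = m$black_level, exposure_s = m$exposure_s,
                 gain = m$gain, vignette_center = unlist(m$vignette_center),
                 vignette_coeffs = unlist(m$vignette_coeffs),
                 bit_depth = m$bit_depth, band_id = m$band_id,
                 capture_id = m$capture_id, row_axis = m$row_axis))
}

#' Serialise per-band homographies as row-major CSV
#' @param homographies named list of [band_homography()] or 3x3 matrices.
#' @param path output file.
#' @export
write_homographies_csv <- function(homographies, path) {
  df <- do.call(rbind, lapply(names(homographies), function(b) {
    M <- homographies[[b]]
    if (inherits(M, "band_homography")) M <- M$matrix
    out <- data.frame(band = b)
    vals <- as.numeric(t(M))
    for (i in 1:9) out[[sprintf("h%d%d", (i - 1) %/% 3 + 1,
                                (i - 1) %% 3 + 1)]] <- vals[i]
    out
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read per-band homographies from CSV
#' @param path file written by [write_homographies_csv()].
#' @return Named list of 3x3 matrices.
#' @export
read_homographies_csv <- function(path) {
  df <- read.csv(path)
  out <- lapply(seq_len(nrow(df)), function(i)
    matrix(as.numeric(df[i, sprintf("h%d%d", rep(1:3, each = 3),
                                    rep(1:3, 3))]), 3, 3, byrow = TRUE))
  names(out) <- df$band
  out
}

#' Write a synthetic flight to a directory of interchange files
#'
#' Produces exactly the formats the pipeline reads: per-band DN rasters
#' (`captures/<id>_<band>.asc`), YAML metadata sidecars, a camera CSV, the
#' DSM, the GeoJSON layout, the panel capture, injected homographies, and
#' the ground truth CSV.
#'
#' @param flight a `uav_flight` from [generate_flight()].
#' @param dir output directory (created).
#' @export
write_flight <- function(flight, dir) {
  dir.create(file.path(dir, "captures"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "meta"), showWarnings = FALSE)
  dir.create(file.path(dir, "panel"), showWarnings = FALSE)
  for (cap in flight$captures) {
    for (b in names(cap$dn))
      write_ascii_grid(cap$dn[[b]],
                       file.path(dir, "captures",
                                 sprintf("%s_%s.asc", cap$capture_id, b)))
    write_capture_meta(cap$meta,
                       file.path(dir, "meta",
                                 sprintf("%s.yaml", cap$capture_id)))
  }
  write_cameras_csv(flight$cameras, file.path(dir, "cameras.csv"))
  write_ascii_grid(flight$dsm$elevations, file.path(dir, "dsm.asc"),
                   xll = flight$dsm$xll, yll = flight$dsm$yll,
                   cellsize = flight$dsm$cellsize,
                   nodata = flight$dsm$nodata)
  write_layout(flight$layout, file.path(dir, "layout.geojson"))
  for (b in names(flight$panel$dn))
    write_ascii_grid(flight$panel$dn[[b]],
                     file.path(dir, "panel", sprintf("panel_%s.asc", b)))
  write_capture_meta(flight$panel$meta, file.path(dir, "panel",
                                                  "panel_meta.yaml"))
  yaml::write_yaml(list(
    known_reflectance = as.list(flight$panel$reference$known_reflectance),
    panel_polygon = unname(split(flight$panel$reference$panel_polygon,
                                 row(flight$panel$reference$panel_polygon)))),
    file.path(dir, "panel", "panel_reference.yaml"))
  write_homographies_csv(flight$truth$homographies,
                         file.path(dir, "true_homographies.csv"))
  write.csv(flight$truth$plots, file.path(dir, "truth.csv"),
            row.names = FALSE)
  yaml::write_yaml(flight$params, file.path(dir, "flight.yaml"))
  invisible(dir)
}

#' Read a flight directory written by [write_flight()]
#' @param dir flight directory.
#' @return A `uav_flight`.
#' @export
read_flight <- function(dir) {
  params <- yaml::read_yaml(file.path(dir, "flight.yaml"))
  cameras <- read_cameras_csv(file.path(dir, "cameras.csv"))
  captures <- lapply(cameras, function(cm) {
    dn <- list()
    for (b in .uavstand_bands) {
      g <- read_ascii_grid(file.path(dir, "captures",
                                     sprintf("%s_%s.asc", cm$capture_id, b)))
      dn[[b]] <- g$elevations
    }
    list(capture_id = cm$capture_id, dn = dn,
         meta = read_capture_meta(file.path(dir, "meta",
                                            sprintf("%s.yaml",
                                                    cm$capture_id))),
         image_size = cm$image_size)
  })
  pref <- yaml::read_yaml(file.path(dir, "panel", "panel_reference.yaml"))
  pdn <- list()
  for (b in .uavstand_bands)
    pdn[[b]] <- read_ascii_grid(file.path(dir, "panel",
                                          sprintf("panel_%s.asc",
                                                  b)))$elevations
  panel <- list(
    dn = pdn,
    meta = read_capture_meta(file.path(dir, "panel", "panel_meta.yaml")),
    reference = panel_reference(
      unlist(pref$known_reflectance),
      do.call(rbind, lapply(pref$panel_polygon, as.numeric))),
    image_size = dim(pdn[[1]]))
  truth_path <- file.path(dir, "truth.csv")
  truth <- list(
    plots = if (file.exists(truth_path)) read.csv(truth_path) else NULL,
    homographies = read_homographies_csv(file.path(dir,
                                                   "true_homographies.csv")))
  params$image_size <- cameras[[1]]$image_size
  structure(list(captures = captures, cameras = cameras,
                 dsm = read_ascii_grid(file.path(dir, "dsm.asc")),
                 layout = read_layout(file.path(dir, "layout.geojson")),
                 panel = panel, truth = truth, params = params),
            class = "uav_flight")
}
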