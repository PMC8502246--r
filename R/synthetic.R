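#' Per-class reflectance spectra for the scene renderer
#'
#' Five-band reflectance for soil, leaves and red/white/green sorghum
#' heads, plus the multiplicative noise level. The defaults are chosen so
#' that the index-based separations the detectors rely on hold by
#' construction: leaves sit above the 0.3 red-edge/red threshold, red and
#' white heads below it, green heads above it (the documented missed-head
#' mode), and soil scores below all vegetation on both OSAVI and GEMI.
#'
#' @param noise_sd standard deviation of the per-pixel multiplicative
#'   log-normal noise (default 0.02).
#' @param ... named per-class overrides, e.g.
#'   `soil = c(blue = .08, green = .10, red = .12, red_edge = .13, nir = .14)`.
#' @return A `class_spectra` list; invalid overrides error.
#' @export
class_spectra <- function(noise_sd = 0.02, ...) {
  sp <- list(
    soil       = c(blue = .08, green = .10, red = .12, red_edge = .13, nir = .14),
    leaf       = c(blue = .03, green = .14, red = .04, red_edge = .30, nir = .50),
    red_head   = c(blue = .10, green = .09, red = .20, red_edge = .25, nir = .55),
    white_head = c(blue = .35, green = .38, red = .25, red_edge = .27, nir = .65),
    green_head = c(blue = .04, green = .09, red = .12, red_edge = .30, nir = .50))
  over <- list(...)
  for (nm in names(over)) sp[[nm]] <- over[[nm]]
  ndvi_re <- function(s) (s["red_edge"] - s["red"]) / (s["red_edge"] + s["red"])
  osavi <- function(s) 1.16 * (s["nir"] - s["red"]) / (s["nir"] + s["red"] + .16)
  gemi <- function(s) {
    eta <- (2 * (s["nir"]^2 - s["red"]^2) + 1.5 * s["nir"] + .5 * s["red"]) /
      (s["nir"] + s["red"] + .5)
    unname(eta * (1 - .25 * eta) - (s["red"] - .125) / (1 - s["red"]))
  }
  assert_that(ndvi_re(sp$leaf) > 0.3, "configuration_error",
              "leaf NDVI_RE must exceed 0.3")
  assert_that(ndvi_re(sp$red_head) < 0.3 && ndvi_re(sp$white_head) < 0.3,
              "configuration_error", "red/white head NDVI_RE must be < 0.3")
  veg <- c("leaf", "red_head", "white_head")
  assert_that(all(osavi(sp$soil) < vapply(sp[veg], osavi, 0)) &&
                all(gemi(sp$soil) < vapply(sp[veg], gemi, 0)),
              "configuration_error",
              "soil OSAVI and GEMI must sit below vegetation")
  structure(c(sp, list(noise_sd = noise_sd)), class = "class_spectra")
}

# scene labels in the world raster
.lab <- c(soil = 0L, leaf = 1L, red_head = 2L, white_head = 3L,
          green_head = 4L, plant = 5L, weed = 6L, panel = 7L)

# label -> per-band reflectance lookup (index = label + 1)
label_reflectance <- function(spectra, band, panel_rho = 0.49) {
  c(spectra$soil[band], spectra$leaf[band], spectra$red_head[band],
    spectra$white_head[band], spectra$green_head[band],
    spectra$leaf[band], spectra$leaf[band], panel_rho)
}

# default per-band acquisition metadata for the synthetic sensor
default_sensor <- function() {
  list(a1 = c(blue = 1.00, green = 1.05, red = 0.98, red_edge = 1.02,
              nir = 1.10),
       a2 = 2e-6, a3 = 1e-4, black_level = 4096, gain = 1,
       exposure_s = c(blue = .010, green = .009, red = .011,
                      red_edge = .010, nir = .008),
       vignette_coeffs = c(1.2e-4, 2e-8, 0, 0, 0, 0),
       irradiance = c(blue = 55, green = 60, red = 65, red_edge = 60,
                      nir = 50),
       panel_rho = 0.49)
}

# homography for rotation th (rad) + scale s about centre c + translation t
make_similarity_h <- function(theta, s, t, centre) {
  R <- s * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  M <- diag(3)
  M[1:2, 1:2] <- R
  M[1:2, 3] <- centre - R %*% centre + t
  M
}

# invert the radiance model and quantize to DN
reflectance_to_dn <- function(refl, meta, irradiance, quantize = TRUE) {
  L <- irradiance * refl
  scale <- 2^meta$bit_depth
  rows <- nrow(refl)
  y <- 0:(rows - 1)
  denom <- meta$exposure_s + meta$a2 * y - meta$a3 * meta$exposure_s * y
  V <- vignette_factor(meta, dim(refl))
  p <- meta$black_level / scale + L * denom * meta$gain / (meta$a1 * V)
  dn <- matrix(p * scale, rows, ncol(refl))
  if (quantize) {
    dn <- pmin(pmax(round(dn), 0), scale - 1)
    storage.mode(dn) <- "integer"  # halves the memory of a stored flight
  }
  dn
}

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a complete synthetic flight with known ground truth
#'
#' Builds a flat-terrain breeding trial (plots of four 4 m rows, 0.6 m
#' between the two internal data rows, 0.75 m to the outer rows), renders
#' plants (plant stage) or canopy plus head clusters (head stage) into a
#' world raster at the flight's ground sampling distance, and synthesizes
#' per-capture raw DN imagery by projecting each capture's pixel grid into
#' the world and inverting the reflectance and radiance calibration models
#' with known metadata — including a non-trivial vignette and per-band
#' misregistration homographies. Everything the pipeline consumes (camera
#' solutions, DSM, layout, panel capture) is produced alongside per-plot
#' truth.
#'
#' @param n_plot_rows,n_plot_cols plot grid dimensions.
#' @param plants_per_row_range integer range of plants per 4 m data row
#'   (default 5–30, the variability seen in a real trial).
#' @param plants_per_plot_range optional integer range for the *total*
#'   plant count per plot (split across the two data rows); overrides
#'   `plants_per_row_range`.
#' @param heads_config `NULL` for a plant-stage flight, or a list for a
#'   head-stage flight: `n_single_range`, `n_double_range`,
#'   `n_triple_range` (cluster counts per plot), `head_radius_px` (default
#'   4–7), `spacing_radii` (centre spacing of merged heads in units of the
#'   head radius, default 1.6–1.9: near-tangent, so circularity classes are
#'   separable but not trivial), `colours` (subset of red/white/green).
#' @param overlap_fraction forward/side overlap of the serpentine capture
#'   grid (only used when `capture_layout = "grid"`).
#' @param flight_height_m flight height above ground (default 20).
#' @param seed integer seed; the flight is deterministic given the seed.
#' @param spectra a [class_spectra()].
#' @param weed_density expected number of between-row weeds per plot
#'   (default 0).
#' @param image_size capture `(rows, cols)` in pixels.
#' @param focal_px focal length in pixels; with the default 1500 px and
#'   20 m height the ground sampling distance is 1.33 cm.
#' @param elevation_m terrain elevation (flat).
#' @param capture_layout `"per_plot"` (one jittered capture above each
#'   plot) or `"grid"` (serpentine grid with `overlap_fraction`).
#' @param band_misregistration inject per-band similarity warps
#'   (translation up to 4 px, rotation up to 0.5 degrees, scale within
#'   0.4%) for the alignment stage to recover.
#' @return A `uav_flight` list: `captures` (raw DN bands + metadata),
#'   `cameras`, `dsm`, `layout`, `panel`, `truth` (per-plot counts,
#'   injected homographies, seed), `params`.
#' @export
generate_flight <- function(n_plot_rows, n_plot_cols,
                            plants_per_row_range = c(5L, 30L),
                            heads_config = NULL,
                            overlap_fraction = 0,
                            flight_height_m = 20,
                            seed = 1L,
                            spectra = class_spectra(),
                            plants_per_plot_range = NULL,
                            weed_density = 0,
                            image_size = c(600L, 800L),
                            focal_px = 2300,
                            elevation_m = 300,
                            capture_layout = c("per_plot", "per_pair",
                                               "grid"),
                            band_misregistration = TRUE,
                            albedo_sd = 0.06) {
  capture_layout <- match.arg(capture_layout)
  assert_that(n_plot_rows >= 1 && n_plot_cols >= 1, "configuration_error",
              "plot grid dimensions must be positive")
  assert_that(overlap_fraction >= 0 && overlap_fraction < 1,
              "configuration_error", "overlap_fraction must be in [0, 1)")
  assert_that(inherits(spectra, "class_spectra"), "configuration_error",
              "spectra must be a class_spectra object")
  run_with_seed(seed, {
    gsd <- flight_height_m / focal_px
    rows_px <- image_size[1]; cols_px <- image_size[2]
    sensor <- default_sensor()
    stage <- if (is.null(heads_config)) "plants" else "heads"

    ## field geometry (metres; origin at the SW field corner) -------------
    cell_x <- 2.9; cell_y <- 5.0
    row_off <- c(0.40, 1.15, 1.75, 2.50)   # 0.75 / 0.60 / 0.75 m spacings
    data_rows <- c(2L, 3L)
    row_y <- c(0.5, 4.5)                   # 4 m row length inside the cell
    field_x <- n_plot_cols * cell_x; field_y <- n_plot_rows * cell_y

    ## world label raster -------------------------------------------------
    margin <- max(cols_px, rows_px) * gsd / 2 + 1
    wx0 <- -margin; wy1 <- field_y + margin
    wnc <- ceiling((field_x + 2 * margin) / gsd)
    wnr <- ceiling((field_y + 2 * margin) / gsd)
    world <- matrix(.lab["soil"], wnr, wnc)
    w_col <- function(X) (X - wx0) / gsd + 0.5   # fractional 1-based col
    w_row <- function(Y) (wy1 - Y) / gsd + 0.5
    ## band-correlated surface albedo texture (soil clods, residue) on a
    ## 4 cm grid; multiplies all bands alike, so ratio indices barely move
    acell <- 0.04
    anc <- ceiling((field_x + 2 * margin) / acell)
    anr <- ceiling((field_y + 2 * margin) / acell)
    alb <- box_blur3(matrix(rnorm(anr * anc), anr, anc), passes = 2L)
    alb <- exp(albedo_sd * alb / sd(alb))
    paint <- function(X, Y, r_m, value) {
      if (!length(X)) return(invisible())
      cpp_fill_discs(world, w_col(X) - 1, w_row(Y) - 1, r_m / gsd,
                     as.integer(value))
    }

    ## layout + per-plot truth -------------------------------------------
    plots <- list(); row_lines <- list(); truth_rows <- list()
    hc <- NULL
    if (stage == "heads") {
      hc <- utils::modifyList(
        list(n_single_range = c(5L, 40L), n_double_range = c(2L, 12L),
             n_triple_range = c(0L, 8L), head_radius_px = c(4, 7),
             spacing_radii = c(1.6, 1.9), colours = c("red", "white")),
        heads_config)
    }
    rint <- function(rng) if (rng[1] >= rng[2]) as.integer(rng[1]) else
      sample(rng[1]:rng[2], 1L)
    k <- 0L
    for (pr in seq_len(n_plot_rows)) {
      for (pc in seq_len(n_plot_cols)) {
        k <- k + 1L
        pid <- sprintf("P%02d%02d", pr, pc)
        x0 <- (pc - 1) * cell_x; y0 <- (pr - 1) * cell_y
        ring <- rbind(c(x0 + 0.1, y0 + 0.2), c(x0 + 2.8, y0 + 0.2),
                      c(x0 + 2.8, y0 + 4.8), c(x0 + 0.1, y0 + 4.8))
        plots[[pid]] <- world_boundary(pid, "plot", ring)
        for (dr in data_rows) {
          row_lines[[length(row_lines) + 1L]] <- list(
            plot_id = pid, row_index = match(dr, data_rows),
            line = rbind(c(x0 + row_off[dr], y0 + row_y[1]),
                         c(x0 + row_off[dr], y0 + row_y[2])))
        }
        tr <- list(plot_id = pid, centre_x = x0 + cell_x / 2,
                   centre_y = y0 + cell_y / 2)

        if (stage == "plants") {
          if (!is.null(plants_per_plot_range)) {
            total <- rint(plants_per_plot_range)
            n_per <- c(ceiling(total / 2), floor(total / 2))
          } else {
            n_per <- c(rint(plants_per_row_range), rint(plants_per_row_range))
          }
          for (j in 1:2) {
            n <- n_per[j]
            if (n > 0) {
              # seedlings emerge along the row essentially without
              # overlap; pack greedily with a small gap and compress only
              # when the count physically cannot fit in the row
              r_px <- runif(n, 3, 8) / 2
              gap_px <- 2.5
              pitch <- 2 * r_px + gap_px            # centre-to-centre need
              need <- sum(pitch) - pitch[1] / 2 - pitch[n] / 2
              avail <- (row_y[2] - row_y[1] - 0.2) / gsd
              # spread over the whole row when it fits (drill-sown rows
              # fill their length); squeeze into overlap only when the
              # count physically cannot fit
              scale <- avail / max(need, 1e-9)
              ys_px <- cumsum(c(0, (pitch[-n] + pitch[-1]) / 2)) * scale
              ys_px <- ys_px + runif(n, -0.3, 0.3) * gap_px * min(scale, 1)
              ys <- y0 + row_y[1] + 0.1 +
                (avail - max(ys_px)) / 2 * gsd + ys_px * gsd
              xs <- x0 + row_off[data_rows[j]] + runif(n, -0.03, 0.03)
              paint(xs, ys, r_px * gsd, .lab["plant"])
            }
          }
          # uncounted outer guard rows
          for (orow in c(1L, 4L)) {
            n <- rint(plants_per_row_range)
            ys <- y0 + runif(n, row_y[1], row_y[2])
            xs <- x0 + row_off[orow] + runif(n, -0.03, 0.03)
            paint(xs, ys, runif(n, 3, 8) / 2 * gsd, .lab["plant"])
          }
          if (weed_density > 0) {
            nw <- stats::rpois(1, weed_density)
            if (nw > 0) {
              gaps <- c(mean(row_off[1:2]), mean(row_off[3:4]))
              xs <- x0 + sample(gaps, nw, replace = TRUE) +
                runif(nw, -0.05, 0.05)
              ys <- y0 + runif(nw, row_y[1], row_y[2])
              paint(xs, ys, runif(nw, 3, 8) / 2 * gsd, .lab["weed"])
            }
          }
          tr$true_n_plants <- sum(n_per)
          tr$n_single <- tr$n_double <- tr$n_triple <- NA_integer_
          tr$true_n_heads <- NA_integer_
          tr$head_colour <- NA_character_
        } else {
          ## head stage: leafy canopy along all four rows ----------------
          for (orow in 1:4) {
            ys <- seq(y0 + row_y[1], y0 + row_y[2], by = 0.12)
            xs <- x0 + row_off[orow] + runif(length(ys), -0.06, 0.06)
            paint(xs, ys, runif(length(ys), 0.08, 0.14), .lab["leaf"])
          }
          n_s <- rint(hc$n_single_range); n_d <- rint(hc$n_double_range)
          n_t <- rint(hc$n_triple_range)
          colour <- sample(hc$colours, 1L)
          lab_head <- .lab[paste0(colour, "_head")]
          mult <- sample(rep(c(1L, 2L, 3L), c(n_s, n_d, n_t)))
          n_cl <- length(mult)
          host <- rep_len(1:4, n_cl)[sample.int(n_cl)]
          for (orow in 1:4) {
            on_row <- which(host == orow)
            m <- length(on_row)
            if (!m) next
            step <- (row_y[2] - row_y[1]) / m
            ys <- y0 + row_y[1] + (seq_len(m) - 0.5) * step +
              runif(m, -0.08, 0.08) * step
            xs <- x0 + row_off[orow] + runif(m, -0.04, 0.04)
            for (q in seq_len(m)) {
              r_px <- runif(1, hc$head_radius_px[1], hc$head_radius_px[2])
              r_m <- r_px * gsd
              d_m <- runif(1, hc$spacing_radii[1], hc$spacing_radii[2]) * r_m
              ang <- runif(1, -25, 25) * pi / 180  # near across-row
              dx <- cos(ang) * d_m; dy <- sin(ang) * d_m
              mm <- mult[on_row[q]]
              cx <- xs[q] + (seq_len(mm) - (mm + 1) / 2) * dx
              cy <- ys[q] + (seq_len(mm) - (mm + 1) / 2) * dy
              paint(cx, cy, rep(r_m, mm), lab_head)
            }
          }
          tr$true_n_plants <- NA_integer_
          tr$n_single <- n_s; tr$n_double <- n_d; tr$n_triple <- n_t
          tr$true_n_heads <- n_s + 2L * n_d + 3L * n_t
          tr$head_colour <- colour
        }
        truth_rows[[k]] <- tr
      }
    }
    truth <- do.call(rbind, lapply(truth_rows, as.data.frame))

    ## cameras -------------------------------------------------------------
    cam_z <- elevation_m + flight_height_m
    cx <- (cols_px - 1) / 2; cy <- (rows_px - 1) / 2
    if (capture_layout == "per_plot") {
      cam_xy <- cbind(truth$centre_x + runif(nrow(truth), -0.2, 0.2),
                      truth$centre_y + runif(nrow(truth), -0.15, 0.15))
    } else if (capture_layout == "per_pair") {
      # one capture per 1x2 block of plot columns (the frame footprint
      # holds two neighbouring plots); an odd last column gets its own
      pair_x <- c(); pair_y <- c()
      for (pr in seq_len(n_plot_rows)) {
        pc <- 1L
        while (pc <= n_plot_cols) {
          wide <- pc + 1L <= n_plot_cols
          pair_x <- c(pair_x, (pc - 1) * cell_x +
                        if (wide) cell_x else cell_x / 2)
          pair_y <- c(pair_y, (pr - 0.5) * cell_y)
          pc <- pc + (if (wide) 2L else 1L)
        }
      }
      cam_xy <- cbind(pair_x + runif(length(pair_x), -0.2, 0.2),
                      pair_y + runif(length(pair_y), -0.15, 0.15))
    } else {
      foot_w <- cols_px * gsd; foot_h <- rows_px * gsd
      xs <- seq(foot_w / 2, field_x + foot_w / 2 - 1e-9,
                by = max(foot_w * (1 - overlap_fraction), 0.5))
      ys <- seq(foot_h / 2, field_y + foot_h / 2 - 1e-9,
                by = max(foot_h * (1 - overlap_fraction), 0.5))
      cam_xy <- as.matrix(expand.grid(xs, ys))
    }
    cameras <- vector("list", nrow(cam_xy))
    K <- matrix(c(focal_px, 0, 0, 0, focal_px, 0, cx, cy, 1), 3, 3)
    R <- diag(c(1, -1, -1))
    for (i in seq_len(nrow(cam_xy))) {
      C <- c(cam_xy[i, 1], cam_xy[i, 2], cam_z)
      P <- K %*% cbind(R, -R %*% C)
      cameras[[i]] <- camera_solution(sprintf("C%04d", i), P, C, image_size)
    }

    ## per-band misregistration -------------------------------------------
    centre_px <- c(cx, cy)
    homs <- list(green = diag(3))
    for (b in setdiff(.uavstand_bands, "green")) {
      homs[[b]] <- if (band_misregistration)
        make_similarity_h(runif(1, -0.5, 0.5) * pi / 180,
                          runif(1, 0.996, 1.004),
                          runif(2, -4, 4), centre_px)
      else diag(3)
    }

    ## render captures ------------------------------------------------------
    u <- matrix(0:(cols_px - 1), rows_px, cols_px, byrow = TRUE)
    v <- matrix(0:(rows_px - 1), rows_px, cols_px)
    captures <- vector("list", length(cameras))
    for (i in seq_along(cameras)) {
      cam <- cameras[[i]]
      dn <- list(); meta <- list()
      for (b in .uavstand_bands) {
        M <- homs[[b]]
        # band pixel -> green-frame pixel (the injected misregistration)
        ug <- M[1, 1] * u + M[1, 2] * v + M[1, 3]
        vg <- M[2, 1] * u + M[2, 2] * v + M[2, 3]
        X <- cam$position[1] + (ug - cx) * gsd
        Y <- cam$position[2] - (vg - cy) * gsd
        lut <- label_reflectance(spectra, b, sensor$panel_rho)
        base <- cpp_sample_lut_bilinear(world, lut, w_row(Y), w_col(X))
        texture <- cpp_sample_bilinear(alb, (wy1 - Y) / acell + 0.5,
                                       (X - wx0) / acell + 0.5)
        refl <- matrix(base * texture, rows_px, cols_px) *
          rlnorm(length(base), 0, spectra$noise_sd)
        m <- capture_meta(a1 = sensor$a1[[b]], a2 = sensor$a2,
                          a3 = sensor$a3, black_level = sensor$black_level,
                          exposure_s = sensor$exposure_s[[b]],
                          gain = sensor$gain,
                          vignette_center = centre_px,
                          vignette_coeffs = sensor$vignette_coeffs,
                          band_id = b, capture_id = cam$capture_id)
        dn[[b]] <- reflectance_to_dn(refl, m, sensor$irradiance[[b]])
        meta[[b]] <- m
      }
      captures[[i]] <- list(capture_id = cam$capture_id, dn = dn,
                            meta = meta, image_size = image_size)
    }

    ## panel capture --------------------------------------------------------
    pn <- 200L
    plab <- matrix(.lab["soil"], pn, pn)
    plab[61:140, 61:140] <- .lab["panel"]
    pdn <- list(); pmeta <- list()
    for (b in .uavstand_bands) {
      lut <- label_reflectance(spectra, b, sensor$panel_rho)
      refl <- matrix(lut[plab + 1L], pn, pn) *
        rlnorm(pn * pn, 0, spectra$noise_sd)
      m <- capture_meta(a1 = sensor$a1[[b]], a2 = sensor$a2, a3 = sensor$a3,
                        black_level = sensor$black_level,
                        exposure_s = sensor$exposure_s[[b]],
                        gain = sensor$gain,
                        vignette_center = c((pn - 1) / 2, (pn - 1) / 2),
                        vignette_coeffs = sensor$vignette_coeffs,
                        band_id = b, capture_id = "PANEL")
      pdn[[b]] <- reflectance_to_dn(refl, m, sensor$irradiance[[b]])
      pmeta[[b]] <- m
    }
    panel_poly <- rbind(c(75, 75), c(124, 75), c(124, 124), c(75, 124))
    panel <- list(dn = pdn, meta = pmeta,
                  reference = panel_reference(
                    known_reflectance = stats::setNames(
                      rep(sensor$panel_rho, 5), .uavstand_bands),
                    panel_polygon = panel_poly),
                  image_size = c(pn, pn))

    ## DSM ------------------------------------------------------------------
    dcell <- 0.5
    dnc <- ceiling((field_x + 2 * margin) / dcell)
    dnr <- ceiling((field_y + 2 * margin) / dcell)
    dsm <- dsm_grid(matrix(elevation_m, dnr, dnc), xll = wx0,
                    yll = field_y + margin - dnr * dcell, cellsize = dcell)

    structure(list(
      captures = captures, cameras = cameras, dsm = dsm,
      layout = list(plots = plots, rows = row_lines),
      panel = panel,
      truth = list(plots = truth, homographies = homs, seed = seed,
                   sensor = sensor, spectra = spectra),
      params = list(stage = stage, gsd = gsd, image_size = image_size,
                    focal_px = focal_px, flight_height_m = flight_height_m,
                    elevation_m = elevation_m, n_plot_rows = n_plot_rows,
                    n_plot_cols = n_plot_cols, heads_config = hc,
                    capture_layout = capture_layout,
                    overlap_fraction = overlap_fraction)),
      class = "uav_flight")
  })
}

#' @export
print.uav_flight <- function(x, ...) {
  cat(sprintf("<uav_flight> %s stage: %d plots, %d captures (%d x %d px)\n",
              x$params$stage, nrow(x$truth$plots), length(x$captures),
              x$params$image_size[1], x$params$image_size[2]))
  invisible(x)
}

#' Apply a controlled degradation to a flight's captures
#'
#' Stress fixtures for the calibration and alignment stages. `magnitude`
#' zero is the identity for every mode.
#' \describe{
#'   \item{band_shift}{shifts every non-green band's content by
#'     `magnitude` pixels in the column direction (truth homographies are
#'     updated accordingly).}
#'   \item{vignette}{injects an extra radial falloff of strength
#'     `magnitude` (per pixel of radius) into the DN above black level and
#'     updates the metadata coefficients consistently, so calibration
#'     undoes it exactly.}
#'   \item{exposure_jitter}{rescales each capture's exposure by a random
#'     log-normal factor of spread `magnitude`, consistently in DN and
#'     metadata.}
#' }
#'
#' @param flight a `uav_flight`.
#' @param mode one of `"band_shift"`, `"vignette"`, `"exposure_jitter"`.
#' @param magnitude degradation strength (>= 0).
#' @param seed RNG seed for the stochastic modes.
#' @return The degraded `uav_flight`.
#' @export
render_degradation <- function(flight, mode, magnitude, seed = 1L) {
  assert_that(mode %in% c("band_shift", "vignette", "exposure_jitter"),
              "configuration_error", "unknown degradation mode '%s'", mode)
  assert_that(magnitude >= 0, "configuration_error",
              "magnitude must be >= 0")
  if (magnitude == 0) return(flight)
  run_with_seed(seed, {
    if (mode == "band_shift") {
      shift <- diag(3); shift[1, 3] <- -magnitude
      for (i in seq_along(flight$captures)) {
        for (b in setdiff(.uavstand_bands, "green")) {
          dn <- flight$captures[[i]]$dn[[b]]
          bl <- flight$captures[[i]]$meta[[b]]$black_level
          out <- cpp_warp_bilinear(dn, shift, nrow(dn), ncol(dn))
          out[is.na(out)] <- bl
          flight$captures[[i]]$dn[[b]] <- round(out)
        }
      }
      tshift <- diag(3); tshift[1, 3] <- -magnitude
      for (b in setdiff(.uavstand_bands, "green"))
        flight$truth$homographies[[b]] <-
          normalize_h(flight$truth$homographies[[b]] %*% tshift)
    } else if (mode == "vignette") {
      # extra radial falloff, injected consistently in DN and metadata so
      # that the calibration model inverts it exactly
      for (i in seq_along(flight$captures)) {
        for (b in .uavstand_bands) {
          m <- flight$captures[[i]]$meta[[b]]
          dn <- flight$captures[[i]]$dn[[b]]
          uu <- matrix(0:(ncol(dn) - 1), nrow(dn), ncol(dn), byrow = TRUE)
          vv <- matrix(0:(nrow(dn) - 1), nrow(dn), ncol(dn))
          r <- sqrt((uu - m$vignette_center[1])^2 +
                    (vv - m$vignette_center[2])^2)
          k <- m$vignette_coeffs
          poly_old <- 1 + k[1] * r + k[2] * r^2 + k[3] * r^3 +
            k[4] * r^4 + k[5] * r^5 + k[6] * r^6
          k[1] <- k[1] - magnitude
          poly_new <- poly_old - magnitude * r
          assert_that(all(poly_new > 0), "configuration_error",
                      "vignette magnitude too strong for the frame size")
          dn2 <- m$black_level + (dn - m$black_level) * poly_new / poly_old
          flight$captures[[i]]$dn[[b]] <- round(dn2)
          m$vignette_coeffs <- k
          flight$captures[[i]]$meta[[b]] <- m
        }
      }
    } else {  # exposure_jitter
      for (i in seq_along(flight$captures)) {
        fac <- rlnorm(1, 0, magnitude)
        for (b in .uavstand_bands) {
          m <- flight$captures[[i]]$meta[[b]]
          dn <- flight$captures[[i]]$dn[[b]]
          y <- 0:(nrow(dn) - 1)
          te2 <- m$exposure_s * fac
          ratio <- (te2 + m$a2 * y - m$a3 * te2 * y) /
            (m$exposure_s + m$a2 * y - m$a3 * m$exposure_s * y)
          dn2 <- m$black_level + (dn - m$black_level) * ratio
          flight$captures[[i]]$dn[[b]] <- round(dn2)
          m$exposure_s <- te2
          flight$captures[[i]]$meta[[b]] <- m
        }
      }
    }
    flight
  })
}
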