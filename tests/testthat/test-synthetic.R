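test_that("class spectra enforce the separability invariants", {
  sp <- class_spectra()
  ndvi_re <- function(s) (s[["red_edge"]] - s[["red"]]) /
    (s[["red_edge"]] + s[["red"]])
  expect_gt(ndvi_re(sp$leaf), 0.3)
  expect_lt(ndvi_re(sp$red_head), 0.3)
  expect_lt(ndvi_re(sp$white_head), 0.3)
  # a leaf override violating the threshold is rejected
  expect_error(class_spectra(leaf = c(blue = .03, green = .08, red = .2,
                                      red_edge = .25, nir = .5)),
               class = "configuration_error")
})

test_that("flights are deterministic per seed", {
  f1 <- generate_flight(1, 1, seed = 9, image_size = c(200L, 260L),
                        focal_px = 760)
  f2 <- generate_flight(1, 1, seed = 9, image_size = c(200L, 260L),
                        focal_px = 760)
  expect_identical(f1$captures[[1]]$dn, f2$captures[[1]]$dn)
  expect_identical(f1$truth$plots, f2$truth$plots)
  f3 <- generate_flight(1, 1, seed = 10, image_size = c(200L, 260L),
                        focal_px = 760)
  expect_false(identical(f1$captures[[1]]$dn$green,
                         f3$captures[[1]]$dn$green))
})

test_that("zero-plant plots render no vegetation pixels", {
  fl <- generate_flight(1, 1, plants_per_plot_range = c(0, 0), seed = 3,
                        plants_per_row_range = c(0, 0),
                        image_size = c(240L, 320L), focal_px = 920)
  expect_equal(fl$truth$plots$true_n_plants, 0)
  st <- uavstand:::calibrate_capture(fl$captures[[1]],
                                     flight_panel_factors(fl))
  osavi <- compute_index(
    reflectance_stack(st$bands, aligned = TRUE), "OSAVI")
  # nothing but soil: no pixel reaches leaf-level OSAVI
  expect_lt(max(osavi$values, na.rm = TRUE), 0.4)
})

test_that("projection is consistent with the renderer", {
  fl <- cached_flight("tiny_plants", function()
    generate_flight(1, 2, plants_per_plot_range = c(30, 40), seed = 5,
                    image_size = c(240L, 320L), focal_px = 920))
  # pixel -> world (renderer convention) must invert Eq.-style projection
  for (cam in fl$cameras) {
    gsd <- fl$params$gsd
    ctr <- c((320 - 1) / 2, (240 - 1) / 2)
    set.seed(1)
    uv <- cbind(runif(20, 0, 319), runif(20, 0, 239))
    world <- cbind(cam$position[1] + (uv[, 1] - ctr[1]) * gsd,
                   cam$position[2] - (uv[, 2] - ctr[2]) * gsd,
                   fl$params$elevation_m)
    back <- project_point(cam$P, world)
    expect_lt(max(abs(back - uv)), 0.5)
  }
})

test_that("nadir selection matches the world-space footprint oracle", {
  fl <- cached_flight("tiny_plants", function()
    generate_flight(1, 2, plants_per_plot_range = c(30, 40), seed = 5,
                    image_size = c(240L, 320L), focal_px = 920))
  for (b in fl$layout$plots) {
    views <- project_boundary(b, fl$cameras, fl$dsm)
    pick <- select_nadir(views)
    centroid <- colMeans(b$vertices)
    d <- vapply(fl$cameras, function(cm)
      sqrt(sum((cm$position[1:2] - centroid)^2)), 0)
    contained <- vapply(views, `[[`, TRUE, "fully_contained")
    oracle <- fl$cameras[[which.min(replace(d, !contained, Inf))]]$capture_id
    expect_equal(pick$capture_id, oracle)
  }
})

test_that("coverage accounting partitions the plots", {
  # a sparse serpentine grid leaves gaps: captured + missed = all plots
  fl <- generate_flight(2, 2, plants_per_row_range = c(5, 8), seed = 6,
                        image_size = c(200L, 260L), focal_px = 760,
                        capture_layout = "grid", overlap_fraction = 0)
  res <- run_pipeline(fl)
  expect_equal(sum(res$coverage$captured) + length(res$not_captured),
               nrow(fl$truth$plots))
  # per-plot full-view counts agree with a direct containment oracle
  for (i in seq_len(nrow(res$coverage))) {
    pid <- res$coverage$plot_id[i]
    rows <- Filter(function(r) r$plot_id == pid, fl$layout$rows)
    n_oracle <- min(vapply(rows, function(r) {
      vs <- project_boundary(buffer_row(r$line, 0.10, pid), fl$cameras,
                             fl$dsm)
      sum(vapply(vs, `[[`, TRUE, "fully_contained"))
    }, 0L))
    expect_equal(res$coverage$n_full_views[i], n_oracle)
  }
})

test_that("degradations are identity at magnitude zero and act as named", {
  fl <- cached_flight("tiny_plants", function()
    generate_flight(1, 2, plants_per_plot_range = c(30, 40), seed = 5,
                    image_size = c(240L, 320L), focal_px = 920))
  expect_identical(render_degradation(fl, "band_shift", 0), fl)
  expect_error(render_degradation(fl, "warp9000", 1),
               class = "configuration_error")
  # band_shift: the estimated homography moves by exactly the injected
  # translation relative to the pre-degradation estimate (comparing
  # estimate to estimate cancels the shared rendering quantization)
  sh <- render_degradation(fl, "band_shift", 4)
  factors <- flight_panel_factors(sh)
  est_before <- flight_homographies(fl, flight_panel_factors(fl))
  est_after <- flight_homographies(sh, factors)
  tshift <- diag(3); tshift[1, 3] <- -4
  for (b in c("red", "nir"))
    expect_lt(corner_error(est_after[[b]]$matrix,
                           est_before[[b]]$matrix %*% tshift,
                           c(240, 320)), 0.5)
  # vignette: corners of a flat region fall off, calibration flattens them
  vg <- render_degradation(fl, "vignette", 0.002)
  dn <- vg$captures[[1]]$dn$green
  m <- vg$captures[[1]]$meta$green
  corner_ratio <- mean(dn[1:10, 1:10]) / mean(dn[115:125, 155:165])
  expect_lt(corner_ratio, 0.9)  # > 10% raw corner falloff
  L <- dn_to_radiance(dn, m)$values
  flat_ratio <- mean(L[1:10, 1:10]) / mean(L[115:125, 155:165])
  expect_equal(flat_ratio, 1, tolerance = 0.05)
})
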