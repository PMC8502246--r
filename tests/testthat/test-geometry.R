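test_that("buffer_row builds the perpendicular rectangle", {
  b <- buffer_row(rbind(c(0, 0), c(4, 0)), 0.10)
  expect_equal(b$vertices,
               rbind(c(0, -0.1), c(4, -0.1), c(4, 0.1), c(0, 0.1)),
               tolerance = 1e-12)
  expect_equal(b$kind, "row")
  # vertical line: same ring up to cyclic order
  b2 <- buffer_row(rbind(c(0, 0), c(0, 4)), 0.10)
  expect_setequal(apply(round(b2$vertices, 9), 1, paste, collapse = ","),
                  c("-0.1,0", "0.1,0", "0.1,4", "-0.1,4"))
  # diagonal 3-4-5 line: unit normal (0.8, -0.6), offsets (+-0.4, -+0.3)
  b3 <- buffer_row(rbind(c(0, 0), c(3, 4)), 0.5)
  expect_equal(b3$vertices[1, ], c(0.4, -0.3), tolerance = 1e-12)
  expect_equal(b3$vertices[4, ], c(-0.4, 0.3), tolerance = 1e-12)
  expect_error(buffer_row(rbind(c(1, 1), c(1, 1))), class = "geometry_error")
})

test_that("lift_polygon samples the containing DSM cell", {
  flat <- dsm_grid(matrix(100, 10, 10), xll = 0, yll = 0, cellsize = 1)
  ring <- rbind(c(1.2, 1.2), c(8.3, 1.7), c(5.1, 8.9))
  expect_equal(lift_polygon(world_boundary("p", "plot", ring), flat)[, 3],
               rep(100, 3))
  # two distinct cells
  two <- dsm_grid(cbind(c(100), c(102)), xll = 0, yll = 0, cellsize = 1)
  got <- lift_polygon(world_boundary("p", "plot",
                                     rbind(c(0.5, 0.5), c(1.5, 0.5),
                                           c(1.5, 0.9))), two)
  expect_equal(got[, 3], c(100, 102, 102))
  # ramp Z = X on a 1 m grid: nearest-cell oracle gives the cell's column
  ramp <- dsm_grid(matrix(rep(0:9 + 0.5, each = 10), 10, 10),
                   xll = 0, yll = 0, cellsize = 1)
  got2 <- lift_polygon(world_boundary("p", "plot",
                                      rbind(c(3.2, 5), c(7.9, 5),
                                            c(5, 2.5))), ramp)
  expect_equal(got2[, 3], c(3.5, 7.5, 5.5))
  expect_error(lift_polygon(world_boundary("p", "plot",
                                           rbind(c(-5, 0), c(1, 0),
                                                 c(1, 1))), flat),
               class = "out_of_extent_error")
})

test_that("project_point applies the homogeneous projection", {
  P <- cbind(diag(3), c(0, 0, 0))
  expect_equal(project_point(P, c(3, -2, 4)), cbind(u = 0.75, v = -0.5))
  P2 <- cbind(diag(3), c(0, 0, 1))
  expect_equal(project_point(P2, c(0, 0, 1)), cbind(u = 0, v = 0))
  # pinhole built from K[R|t]: a point straight below the camera maps to
  # the principal point
  K <- matrix(c(1000, 0, 0, 0, 1000, 0, 640, 480, 1), 3, 3)
  R <- diag(c(1, -1, -1))
  C <- c(5, 7, 20)
  P3 <- K %*% cbind(R, -R %*% C)
  expect_equal(project_point(P3, c(5, 7, 0)),
               cbind(u = 640, v = 480), tolerance = 1e-9)
  # one metre east at 20 m depth moves 50 px in +u
  expect_equal(project_point(P3, c(6, 7, 0))[1, "u"], c(u = 690),
               tolerance = 1e-9)
  expect_error(project_point(P, c(1, 1, 0)),
               class = "point_at_infinity_error")
  expect_error(project_point(P, c(1, 1, -2)), class = "behind_camera_error")
})

test_that("select_nadir picks the closest fully contained view", {
  mk <- function(cap, dist, contained, pid = "p1") {
    structure(list(plot_id = pid, capture_id = cap,
                   pixel_polygon = rbind(c(0, 0), c(1, 0), c(1, 1)),
                   kind = "plot", fully_contained = contained,
                   center_distance = dist), class = "plot_view")
  }
  views <- list(mk("c1", 812.4, TRUE), mk("c2", 95.1, TRUE),
                mk("c3", 410.0, TRUE))
  expect_equal(select_nadir(views)$capture_id, "c2")
  expect_equal(select_nadir(list(mk("c9", 10, TRUE)))$capture_id, "c9")
  # no fully contained view: NULL (plot reported as not fully captured)
  expect_null(select_nadir(list(mk("c1", 5, FALSE), mk("c2", 7, FALSE))))
  # ties break to the lexicographically smallest capture id
  expect_equal(select_nadir(list(mk("cb", 5, TRUE),
                                 mk("ca", 5, TRUE)))$capture_id, "ca")
  expect_error(select_nadir(list(mk("c1", 1, TRUE),
                                 mk("c2", 1, TRUE, pid = "p2"))),
               class = "contract_error")
})

test_that("plot_view containment includes the border", {
  pv <- plot_view("p", "c", rbind(c(0, 0), c(99, 0), c(99, 49), c(0, 49)),
                  image_size = c(50, 100))
  expect_true(pv$fully_contained)
  pv2 <- plot_view("p", "c", rbind(c(0, 0), c(100, 0), c(100, 49)),
                   image_size = c(50, 100))
  expect_false(pv2$fully_contained)
})

test_that("extract_plot_image masks by pixel-centre membership", {
  bands <- lapply(bands5, function(b) matrix(runif(900), 30, 30))
  names(bands) <- bands5
  st <- reflectance_stack(bands, aligned = TRUE)
  # grid-aligned rectangle: clean crop, no interior invalids
  rect <- plot_view("p", "T", rbind(c(5, 5), c(14, 5), c(14, 12), c(5, 12)),
                    image_size = c(30, 30))
  img <- extract_plot_image(st, rect)
  expect_equal(dim(img$bands$red), c(8, 10))
  expect_true(all(img$mask))
  expect_equal(img$bands$green, bands$green[6:13, 6:15])
  # triangle: invalid count complements a brute-force point-in-polygon scan
  tri_ring <- rbind(c(5, 5), c(14, 5), c(5, 14))
  tri <- plot_view("p", "T", tri_ring, image_size = c(30, 30))
  img2 <- extract_plot_image(st, tri)
  inside <- 0
  for (u in 5:14) for (v in 5:14) {
    s <- 0; on_edge <- FALSE
    # ray casting oracle with explicit boundary membership, implemented
    # independently (crossing count plus point-on-segment test)
    n <- nrow(tri_ring); j <- n
    for (i in 1:n) {
      yi <- tri_ring[i, 2]; yj <- tri_ring[j, 2]
      xi <- tri_ring[i, 1]; xj <- tri_ring[j, 1]
      if ((yi > v) != (yj > v) && u < (xj - xi) * (v - yi) / (yj - yi) + xi)
        s <- s + 1
      cross <- (xj - xi) * (v - yi) - (yj - yi) * (u - xi)
      dot <- (u - xi) * (xj - xi) + (v - yi) * (yj - yi)
      len2 <- (xj - xi)^2 + (yj - yi)^2
      if (abs(cross) < 1e-9 && dot >= 0 && dot <= len2) on_edge <- TRUE
      j <- i
    }
    if (s %% 2 == 1 || on_edge) inside <- inside + 1
  }
  expect_equal(sum(img2$mask), inside)
  expect_true(all(is.na(img2$bands$nir[!img2$mask])))
  # contract errors
  expect_error(extract_plot_image(
    reflectance_stack(bands, aligned = FALSE), rect),
    class = "contract_error")
  degenerate <- plot_view("p", "T", rbind(c(5, 5), c(9, 5), c(7, 5)),
                          image_size = c(30, 30))
  expect_error(extract_plot_image(st, degenerate),
               class = "empty_extraction_error")
})

test_that("world boundaries reject self-intersecting rings", {
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(world_boundary("p", "plot", bow), class = "geometry_error")
  ok <- world_boundary("p", "plot", rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_s3_class(ok, "world_boundary")
})
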