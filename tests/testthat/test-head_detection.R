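# head-stage plot image: soil, leaf canopy band, head discs of a colour
render_head_image <- function(head_centres, r, colour = "red_head",
                              nr = 120, nc = 160, seed = 1,
                              canopy = TRUE) {
  set.seed(seed)
  sp <- class_spectra()
  lab <- matrix("soil", nr, nc)
  if (canopy) {
    canopy_mask <- disc_mask(nr, nc, seq(5, nc - 5, by = 6), rep(30, 27),
                             rep(9, 27)) |
      disc_mask(nr, nc, seq(5, nc - 5, by = 6), rep(85, 27), rep(9, 27))
    lab[canopy_mask] <- "leaf"
  }
  if (length(head_centres))
    lab[disc_mask(nr, nc, head_centres[, 1], head_centres[, 2],
                  rep(r, nrow(head_centres)))] <- colour
  bands <- lapply(bands5, function(b) {
    m <- matrix(0, nr, nc)
    for (cl in c("soil", "leaf", colour)) m[lab == cl] <- sp[[cl]][[b]]
    m * rlnorm(nr * nc, 0, sp$noise_sd)
  })
  names(bands) <- bands5
  fake_plot_image(bands)
}

test_that("head_mask keeps head pixels and drops soil and leaves", {
  centres <- cbind(c(30, 70, 110, 140), c(30, 85, 30, 85))
  img <- render_head_image(centres, r = 6)
  mask <- head_mask(img)
  truth <- disc_mask(120, 160, centres[, 1], centres[, 2], rep(6, 4))
  # morphology erodes a boundary ring; interiors must match
  interior <- disc_mask(120, 160, centres[, 1], centres[, 2], rep(4, 4))
  expect_true(all(mask$values[interior]))
  outside <- !disc_mask(120, 160, centres[, 1], centres[, 2], rep(8, 4))
  expect_lt(mean(mask$values[outside]), 0.001)
  expect_equal(sum(mask$values & !truth), 0)
})

test_that("white heads are caught by the same 0.3 threshold", {
  centres <- cbind(c(30, 70, 110), c(30, 85, 30))
  img <- render_head_image(centres, r = 6, colour = "white_head", seed = 2)
  cl <- cluster_shapes(head_mask(img), 10)
  expect_equal(nrow(cl), 3)
})

test_that("an all-leaf canopy produces an empty mask", {
  img <- render_head_image(matrix(numeric(), 0, 2), r = 6, seed = 3)
  expect_false(any(head_mask(img)$values))
})

test_that("bare soil gives an empty mask with a qc flag", {
  img <- render_head_image(matrix(numeric(), 0, 2), r = 6, seed = 4,
                           canopy = FALSE)
  mask <- head_mask(img)
  expect_false(any(mask$values))
  expect_true("degenerate_histogram" %in% attr(mask, "qc_flags"))
})

test_that("circularity ranks discs above dumbbells above chains", {
  disc1 <- disc_mask(80, 80, 40, 40, 20)
  two <- disc_mask(80, 140, c(45, 79), c(40, 40), c(20, 20))  # d = 1.7 r
  three <- disc_mask(80, 180, c(40, 74, 108), c(40, 40, 40), rep(20, 3))
  c1 <- cluster_shapes(binary_mask(disc1), 10)$circularity
  c2 <- cluster_shapes(binary_mask(two), 10)$circularity
  c3 <- cluster_shapes(binary_mask(three), 10)$circularity
  expect_gt(c1, 0.85); expect_lt(c1, 1.05)
  expect_gt(c1, c2); expect_gt(c2, c3)
  # analytic square: the closed form gives pi / 4
  s <- 21
  expect_equal(4 * pi * s^2 / (4 * s)^2, pi / 4, tolerance = 1e-12)
})

test_that("kde thresholds fall in the density valleys", {
  # one valley: matches a dense closed-form mixture scan within a step
  vals <- c(0.9, 0.88, 0.91, 0.6, 0.58)
  thr <- kde_circularity_thresholds(vals, bandwidth = 0.05)
  expect_length(thr, 1)
  expect_gt(thr, 0.6); expect_lt(thr, 0.88)
  grid <- seq(0, 1.3, length.out = 4096)
  dens <- rowMeans(outer(grid, vals, function(g, x) dnorm(g, x, 0.05)))
  i <- 2:4095
  mins <- grid[i][dens[i] < dens[i - 1] & dens[i] < dens[i + 1]]
  expect_equal(thr, mins[1], tolerance = 1.3 / 511)
  # no spread: no thresholds
  expect_length(kde_circularity_thresholds(rep(0.8, 10)), 0)
  expect_length(kde_circularity_thresholds(0.7), 0)
  # three clumps: two thresholds, one per gap
  set.seed(8)
  v3 <- c(rnorm(5, 0.9, 0.01), rnorm(5, 0.65, 0.01), rnorm(5, 0.45, 0.01))
  t3 <- kde_circularity_thresholds(v3, bandwidth = 0.03)
  expect_length(t3, 2)
  expect_gt(t3[1], 0.66); expect_lt(t3[1], 0.89)
  expect_gt(t3[2], 0.46); expect_lt(t3[2], 0.64)
})

test_that("classification and the head-count identity", {
  cl <- data.frame(id = 1:8, area_px = 100, perimeter_px = 40,
                   circularity = c(0.95, 0.93, 0.70, 0.40, 0.9, 0.6, 0.3,
                                   0.85),
                   centroid_u = 0, centroid_v = 0,
                   multiplicity = NA_integer_)
  hc <- classify_and_count(cl, c(0.80, 0.55))
  expect_equal(hc$n_single, 4); expect_equal(hc$n_double, 2)
  expect_equal(hc$n_triple, 2)
  expect_equal(hc$n_heads, hc$n_single + 2 * hc$n_double + 3 * hc$n_triple)
  expect_true(all(hc$clusters$multiplicity <= 3))
  # no thresholds: all single
  hc0 <- classify_and_count(cl, numeric())
  expect_equal(hc0$n_heads, 8)
  # one threshold: single/double only
  hc1 <- classify_and_count(cl, 0.80)
  expect_equal(hc1$n_triple, 0)
  expect_equal(hc1$n_heads, hc1$n_single + 2 * hc1$n_double)
  expect_error(classify_and_count(cl, c(0.5, 0.8)), class = "contract_error")
})

test_that("count_heads separates mixed compositions on a rendered plot", {
  # 6 singles, 4 doubles (d = 1.7 r), 3 triples, r = 6
  set.seed(12)
  singles <- cbind(seq(15, 145, length.out = 6), rep(25, 6))
  doubles <- lapply(seq(25, 135, length.out = 4), function(u)
    cbind(c(u - 5.1, u + 5.1), c(60, 60)))
  triples <- lapply(seq(30, 130, length.out = 3), function(u)
    cbind(c(u - 10.2, u, u + 10.2), c(95, 95, 95)))
  centres <- rbind(singles, do.call(rbind, doubles), do.call(rbind, triples))
  img <- render_head_image(centres, r = 6, canopy = FALSE, seed = 13)
  hc <- count_heads(img)
  expect_equal(hc$n_single, 6)
  expect_equal(hc$n_double, 4)
  expect_equal(hc$n_triple, 3)
  expect_equal(hc$n_heads, 6 + 8 + 9)
  # identical geometry in white yields the identical count
  img_w <- render_head_image(centres, r = 6, colour = "white_head",
                             canopy = FALSE, seed = 13)
  hc_w <- count_heads(img_w)
  expect_equal(hc_w$n_heads, hc$n_heads)
  expect_equal(hc_w$n_triple, hc$n_triple)
})

test_that("fewer than four clusters skip the KDE and count as singles", {
  centres <- cbind(c(40, 100), c(40, 80))
  img <- render_head_image(centres, r = 6, canopy = FALSE, seed = 14)
  hc <- count_heads(img)
  expect_equal(hc$n_heads, 2)
  expect_length(hc$thresholds, 0)
})

test_that("tiller ratio guards zero plant counts", {
  expect_equal(tiller_ratio(c(10, 0, 6), c(5, 4, 0)), c(2, 0, NA))
})
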