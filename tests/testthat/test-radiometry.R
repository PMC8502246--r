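test_that("vignette factor follows the radial polynomial", {
  # zero coefficients: identity everywhere
  m <- simple_meta(vignette_center = c(7, 3), vignette_coeffs = rep(0, 6))
  expect_equal(vignette_factor(m, c(10, 12)),
               matrix(1, 10, 12))
  # hand evaluation: k1 = 0.01, centre (0,0), pixel (u=3, v=4) -> r = 5
  m2 <- simple_meta(vignette_coeffs = c(0.01, 0, 0, 0, 0, 0))
  V <- vignette_factor(m2, c(6, 6))
  expect_equal(V[5, 4], 1 / 1.05, tolerance = 1e-12)
  # exactly 1 at the centre for any coefficients
  m3 <- simple_meta(vignette_center = c(2, 3),
                    vignette_coeffs = c(.3, .2, .1, .05, .01, .001))
  expect_equal(vignette_factor(m3, c(8, 8))[4, 3], 1)
  expect_error(vignette_factor(m3, c(0, 5)), class = "contract_error")
})

test_that("dn_to_radiance implements the calibration model", {
  raw <- matrix(32768, 6, 6)
  m <- simple_meta()  # a1=1, g=1, a2=a3=0, BL=0, t_e=0.01 -> L = 0.5/0.01
  expect_equal(dn_to_radiance(raw, m)$values, matrix(50, 6, 6))
  # direct evaluation with black level and scaled coefficients
  m2 <- simple_meta(a1 = 2, gain = 2, black_level = 0.1 * 2^16,
                    exposure_s = 0.001)
  expect_equal(dn_to_radiance(raw, m2)$values[1, 1], 400, tolerance = 1e-9)
  # DN at black level gives exactly zero radiance
  m3 <- simple_meta(black_level = 1200)
  expect_equal(dn_to_radiance(matrix(1200, 4, 4), m3)$values,
               matrix(0, 4, 4))
  # homogeneity: scaling (p - p_BL) scales L linearly
  L1 <- dn_to_radiance(matrix(8000, 4, 4), m)$values[1, 1]
  L3 <- dn_to_radiance(matrix(24000, 4, 4), m)$values[1, 1]
  expect_equal(L3, 3 * L1, tolerance = 1e-12)
  # row-dependent denominator <= 0 reports the offending row
  bad <- simple_meta(exposure_s = 0.001, a2 = -1e-3)
  expect_error(dn_to_radiance(raw, bad), class = "calibration_metadata_error")
})

test_that("row-dependent terms act on the configured row axis", {
  m_raw <- simple_meta(a2 = 1e-4)
  m_flip <- simple_meta(a2 = 1e-4, row_axis = "flipped")
  raw <- matrix(32768, 6, 6)
  Lr <- dn_to_radiance(raw, m_raw)$values
  Lf <- dn_to_radiance(raw, m_flip)$values
  expect_equal(Lr[1, ], Lf[6, ])
  expect_false(isTRUE(all.equal(Lr[1, 1], Lr[6, 1])))
})

test_that("panel factor averages radiance inside the polygon", {
  poly <- rbind(c(1, 1), c(8, 1), c(8, 8), c(1, 8))
  ref <- panel_reference(c(red = 0.49), poly)
  rad <- structure(list(values = matrix(98, 10, 10), band_id = "red",
                        capture_id = "c"), class = "radiance_image")
  expect_equal(panel_factor(rad, ref), 0.005)
  # non-uniform panel: mean over the interior
  vals <- matrix(90, 10, 10); vals[, 6:10] <- 110
  rad2 <- structure(list(values = vals, band_id = "red", capture_id = "c"),
                    class = "radiance_image")
  expect_equal(panel_factor(rad2, ref), 0.49 / 100, tolerance = 1e-3)
  # degenerate panel radiance
  rad3 <- structure(list(values = matrix(0, 10, 10), band_id = "red",
                         capture_id = "c"), class = "radiance_image")
  expect_error(panel_factor(rad3, ref), class = "degenerate_panel_error")
  expect_error(panel_reference(c(red = 1.2), poly),
               class = "invalid_metadata")
})

test_that("radiance-to-reflectance round trip closes on the panel", {
  poly <- rbind(c(1, 1), c(8, 1), c(8, 8), c(1, 8))
  ref <- panel_reference(c(red = 0.5), poly)
  rad <- structure(list(values = matrix(1, 10, 10), band_id = "red",
                        capture_id = "c"), class = "radiance_image")
  f <- panel_factor(rad, ref)
  expect_equal(f, 0.5)
  refl <- radiance_to_reflectance(rad, f)
  expect_equal(mean(refl), 0.5, tolerance = 1e-9)
  expect_equal(radiance_to_reflectance(
    structure(list(values = matrix(100, 3, 3), band_id = "red"),
              class = "radiance_image"), 0.005),
    matrix(0.5, 3, 3))
  expect_warning(radiance_to_reflectance(
    structure(list(values = matrix(300, 3, 3), band_id = "red"),
              class = "radiance_image"), 0.005),
    "exceed reflectance 1")
})

test_that("full DN round trip recovers a synthetic reflectance field", {
  set.seed(11)
  target <- matrix(runif(40 * 50, 0.05, 0.7), 40, 50)
  m <- simple_meta(a1 = 1.05, a2 = 2e-6, a3 = 1e-4, black_level = 4096,
                   exposure_s = 0.009, vignette_center = c(24.5, 19.5),
                   vignette_coeffs = c(1.2e-4, 2e-8, 0, 0, 0, 0))
  irr <- 60
  # inversion oracle from the synthetic module, unquantized
  dn <- uavstand:::reflectance_to_dn(target, m, irr, quantize = FALSE)
  L <- dn_to_radiance(dn, m)
  refl <- radiance_to_reflectance(L, 1 / irr)
  expect_lt(max(abs(refl - target) / target), 1e-6)
  # quantized DN stays within the half-DN quantization band
  dnq <- uavstand:::reflectance_to_dn(target, m, irr, quantize = TRUE)
  reflq <- radiance_to_reflectance(dn_to_radiance(dnq, m), 1 / irr)
  expect_lt(max(abs(reflq - target)), 1e-3)
})
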