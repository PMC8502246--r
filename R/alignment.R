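#' Band-to-band homography
#'
#' @param matrix 3x3 homography mapping target-band pixel coordinates into
#'   the reference (green) frame, normalised so element (3,3) = 1.
#' @param source_band band being aligned.
#' @param reference_band always `"green"`.
#' @param converged whether the optimiser converged.
#' @param correlation enhanced correlation coefficient at the optimum.
#' @return An object of class `band_homography`.
#' @export
band_homography <- function(matrix, source_band = "unknown",
                            reference_band = "green",
                            converged = TRUE, correlation = NA_real_) {
  matrix <- normalize_h(matrix)
  assert_that(abs(det(matrix)) > 1e-12, "contract_error",
              "homography must be invertible")
  structure(list(matrix = matrix, source_band = source_band,
                 reference_band = reference_band,
                 converged = converged, correlation = correlation),
            class = "band_homography")
}

#' @export
print.band_homography <- function(x, ...) {
  cat(sprintf("<band_homography> %s -> %s (rho = %.4f, %s)\n",
              x$source_band, x$reference_band, x$correlation,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$matrix, 5))
  invisible(x)
}

# gradient magnitude via central differences; cross-band intensities are
# not comparable, edges are
gradient_magnitude <- function(img) {
  img[!is.finite(img)] <- 0
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  sqrt(gx^2 + gy^2)
}

box_blur3 <- function(img, passes = 2L) {
  nr <- nrow(img); nc <- ncol(img)
  for (p in seq_len(passes)) {
    img <- (img +
            rbind(img[1, , drop = FALSE], img[-nr, , drop = FALSE]) +
            rbind(img[-1, , drop = FALSE], img[nr, , drop = FALSE])) / 3
    img <- (img +
            cbind(img[, 1, drop = FALSE], img[, -nc, drop = FALSE]) +
            cbind(img[, -1, drop = FALSE], img[, nc, drop = FALSE])) / 3
  }
  img
}

downsample2 <- function(img) {
  nr <- 2 * (nrow(img) %/% 2); nc <- 2 * (ncol(img) %/% 2)
  img <- img[1:nr, 1:nc]
  (img[seq(1, nr, 2), seq(1, nc, 2)] + img[seq(2, nr, 2), seq(1, nc, 2)] +
   img[seq(1, nr, 2), seq(2, nc, 2)] + img[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

# brute-force integer translation maximising correlation, search +/- radius
best_shift <- function(ref, tgt, radius = 8L) {
  nr <- nrow(ref); nc <- ncol(ref)
  best <- c(0L, 0L); best_cor <- -Inf
  m <- radius + 1L
  rr <- m:(nr - m); cc <- m:(nc - m)
  ref_c <- ref[rr, cc]
  for (dv in -radius:radius) {
    for (du in -radius:radius) {
      tc <- tgt[rr + dv, cc + du]
      cr <- suppressWarnings(cor(as.numeric(ref_c), as.numeric(tc)))
      if (is.finite(cr) && cr > best_cor) {
        best_cor <- cr; best <- c(du, dv)
      }
    }
  }
  best
}

# Forward-additive ECC refinement of the sampling warp V (output pixel ->
# target pixel). Returns list(V, rho, converged).
ecc_refine <- function(ref, tgt, V, max_iter = 200L, eps = 1e-6,
                       margin = 8L) {
  nr <- nrow(ref); nc <- ncol(ref)
  tx <- matrix(0, nr, nc); ty <- matrix(0, nr, nc)
  tx[, 2:(nc - 1)] <- (tgt[, 3:nc] - tgt[, 1:(nc - 2)]) / 2
  ty[2:(nr - 1), ] <- (tgt[3:nr, ] - tgt[1:(nr - 2), ]) / 2
  u <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  v <- matrix(0:(nr - 1), nr, nc)
  interior <- u >= margin & u < nc - margin & v >= margin & v < nr - margin
  rho_prev <- -Inf; rho <- -Inf
  for (iter in seq_len(max_iter)) {
    Iw <- cpp_warp_bilinear(tgt, V, nr, nc)
    Ix <- cpp_warp_bilinear(tx, V, nr, nc)
    Iy <- cpp_warp_bilinear(ty, V, nr, nc)
    valid <- interior & is.finite(Iw)
    n <- sum(valid)
    if (n < 64) return(list(V = V, rho = rho, converged = FALSE))
    r <- ref[valid]; r <- r - mean(r)
    iw <- Iw[valid]; iw <- iw - mean(iw)
    D <- V[3, 1] * u[valid] + V[3, 2] * v[valid] + V[3, 3]
    uw <- (V[1, 1] * u[valid] + V[1, 2] * v[valid] + V[1, 3]) / D
    vw <- (V[2, 1] * u[valid] + V[2, 2] * v[valid] + V[2, 3]) / D
    ix <- Ix[valid]; iy <- Iy[valid]
    uu <- u[valid]; vv <- v[valid]
    G <- cbind(ix * uu, iy * uu, ix * vv, iy * vv, ix, iy,
               -(ix * uw + iy * vw) * uu,
               -(ix * uw + iy * vw) * vv) / D
    G <- sweep(G, 2, colMeans(G))
    H <- crossprod(G)
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Hi)) return(list(V = V, rho = rho, converged = FALSE))
    Gw <- crossprod(G, iw); Gr <- crossprod(G, r)
    rho <- sum(r * iw) / sqrt(sum(r^2) * sum(iw^2))
    num <- sum(iw^2) - t(Gw) %*% Hi %*% Gw
    den <- sum(r * iw) - t(Gr) %*% Hi %*% Gw
    lambda <- if (den > 0) as.numeric(num / den) else 1
    err <- lambda * r - iw
    dp <- as.numeric(Hi %*% crossprod(G, err))
    V <- V + matrix(c(dp[1], dp[3], dp[5],
                      dp[2], dp[4], dp[6],
                      dp[7], dp[8], 0), 3, 3, byrow = TRUE)
    if (is.finite(rho_prev) && abs(rho - rho_prev) < eps) break
    rho_prev <- rho
  }
  list(V = V, rho = rho, converged = is.finite(rho) && rho > 0.5)
}

#' Estimate the homography aligning one band to the reference band
#'
#' Intensity-based iterative maximisation of the enhanced correlation
#' coefficient between the gradient-magnitude images (cross-band raw
#' intensities are not comparable; their edge structure is). A coarse
#' integer-translation search initialises a two-level pyramid of ECC
#' refinements. On failure the identity matrix is returned with
#' `converged = FALSE`.
#'
#' @param reference 2-D reference band image (green).
#' @param target 2-D target band image, same shape.
#' @param max_iter iteration cap per pyramid level (default 200).
#' @param eps termination threshold on the correlation increment.
#' @param source_band label carried into the result.
#' @return A [band_homography()] whose `matrix` maps target pixels into the
#'   reference frame.
#' @export
estimate_homography <- function(reference, target, max_iter = 200L,
                                eps = 1e-6, source_band = "unknown") {
  assert_that(all(dim(reference) == dim(target)), "contract_error",
              "reference and target must share one shape")
  if (length(unique(as.numeric(reference[is.finite(reference)]))) < 2 ||
      length(unique(as.numeric(target[is.finite(target)]))) < 2)
    uav_error("degenerate_input_error", "constant image cannot be aligned")
  # light blur suppresses per-band-independent pixel noise, whose gradients
  # would otherwise dominate the (band-correlated) edge structure
  gr <- box_blur3(gradient_magnitude(reference))
  gt <- box_blur3(gradient_magnitude(target))
  gr2 <- downsample2(gr); gt2 <- downsample2(gt)
  s <- best_shift(gr2, gt2, radius = 8L)
  # V samples target at output+shift when target content sits at +shift
  V2 <- diag(3); V2[1, 3] <- s[1]; V2[2, 3] <- s[2]
  fit2 <- ecc_refine(gr2, gt2, V2, max_iter = max_iter, eps = eps,
                     margin = 6L)
  S <- diag(c(2, 2, 1))
  V1 <- S %*% fit2$V %*% solve(S)
  fit1 <- ecc_refine(gr, gt, V1, max_iter = min(max_iter, 60L), eps = eps,
                     margin = 10L)
  if (!fit1$converged)
    return(band_homography(diag(3), source_band = source_band,
                           converged = FALSE, correlation = fit1$rho))
  M <- normalize_h(solve(fit1$V))
  band_homography(M, source_band = source_band, converged = TRUE,
                  correlation = fit1$rho)
}

#' Element-wise median of several homographies
#'
#' The registration between lenses is stable within a flight, so a single
#' median matrix over a handful of sampled captures can serve a whole
#' flight. The median is taken element-wise and then renormalised so that
#' element (3,3) = 1.
#'
#' @param homographies list of [band_homography()]s for one band.
#' @return A [band_homography()].
#' @export
median_homography <- function(homographies) {
  assert_that(length(homographies) >= 1, "contract_error",
              "need at least one homography")
  mats <- lapply(homographies, `[[`, "matrix")
  med <- apply(simplify2array(mats), c(1, 2), median)
  band_homography(normalize_h(med),
                  source_band = homographies[[1]]$source_band,
                  converged = all(vapply(homographies, `[[`, TRUE,
                                         "converged")),
                  correlation = median(vapply(homographies, `[[`, 0,
                                              "correlation")))
}

#' Register all bands of a capture to the green band
#'
#' Warps each non-green band by its homography with bilinear resampling;
#' pixels that fall outside the source frame become invalid (`NA`). The
#' green band passes through untouched.
#'
#' @param stack a [reflectance_stack()].
#' @param homographies named list of [band_homography()]s for the four
#'   non-green bands.
#' @return The aligned [reflectance_stack()] (`aligned = TRUE`).
#' @export
align_capture <- function(stack, homographies) {
  need <- setdiff(.uavstand_bands, "green")
  missing <- setdiff(need, names(homographies))
  assert_that(length(missing) == 0, "configuration_error",
              "missing homography for band(s): %s",
              paste(missing, collapse = ", "))
  d <- dim(stack$bands$green)
  bands <- stack$bands
  for (b in need) {
    M <- homographies[[b]]$matrix
    bands[[b]] <- cpp_warp_bilinear(stack$bands[[b]], solve(M), d[1], d[2])
  }
  reflectance_stack(bands, capture_id = stack$capture_id, aligned = TRUE)
}
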