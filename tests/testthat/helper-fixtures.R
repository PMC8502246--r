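# Shared fixtures, built in code at test time.

bands5 <- c("blue", "green", "red", "red_edge", "nir")

# a plain capture_meta with identity-ish radiometry
simple_meta <- function(band = "red", ...) {
  args <- utils::modifyList(
    list(a1 = 1, a2 = 0, a3 = 0, black_level = 0, exposure_s = 0.01,
         gain = 1, band_id = band),
    list(...))
  do.call(capture_meta, args)
}

# constant five-band stack
const_stack <- function(vals, nr = 8, nc = 8, aligned = TRUE) {
  bands <- lapply(bands5, function(b) matrix(vals[[b]], nr, nc))
  names(bands) <- bands5
  reflectance_stack(bands, capture_id = "T", aligned = aligned)
}

# plot_image wrapper around raw band matrices
fake_plot_image <- function(bands, plot_id = "P", capture_id = "C") {
  structure(list(bands = bands,
                 mask = matrix(TRUE, nrow(bands[[1]]), ncol(bands[[1]])),
                 offset = c(0, 0), plot_id = plot_id,
                 capture_id = capture_id, kind = "plot"),
            class = "plot_image")
}

# smooth random texture for alignment tests
smooth_texture <- function(nr, nc, seed = 7, passes = 6) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) {
    m <- (m + rbind(m[1, ], m[-nr, ]) + rbind(m[-1, ], m[nr, ])) / 3
    m <- (m + cbind(m[, 1], m[, -nc]) + cbind(m[, -1], m[, nc])) / 3
  }
  m
}

# rasterize a disc mask
disc_mask <- function(nr, nc, cu, cv, r) {
  u <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  v <- matrix(0:(nr - 1), nr, nc)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_along(cu)) out <- out | ((u - cu[i])^2 + (v - cv[i])^2 <= r[i]^2)
  out
}

# independent brute-force OTSU oracle: quantize to the 256-bin histogram
# (quantization is part of the operation's definition), then scan every
# candidate bin edge minimising the within-class variance directly
otsu_oracle <- function(vals, n_bins = 256L) {
  vals <- vals[is.finite(vals)]
  rng <- range(vals)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(vals, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  q <- ((edges[-1] + edges[-(n_bins + 1L)]) / 2)[bin]  # bin midpoints
  wcv <- vapply(seq_len(n_bins - 1L), function(i) {
    lo <- q[bin <= i]; hi <- q[bin > i]
    if (!length(lo) || !length(hi)) return(Inf)
    (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) / length(q)
  }, 0)
  edges[which.min(wcv) + 1L]
}

# flood-fill component-count oracle (8-connected), recursive-free
floodfill_count <- function(mask, min_area = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (v0 in seq_len(nr)) for (u0 in seq_len(nc)) {
    if (!mask[v0, u0] || seen[v0, u0]) next
    stack <- list(c(v0, u0)); seen[v0, u0] <- TRUE; area <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (dv in -1:1) for (du in -1:1) {
        v <- p[1] + dv; u <- p[2] + du
        if (v >= 1 && u >= 1 && v <= nr && u <= nc &&
            mask[v, u] && !seen[v, u]) {
          seen[v, u] <- TRUE
          stack[[length(stack) + 1L]] <- c(v, u)
        }
      }
    }
    if (area >= min_area) count <- count + 1L
  }
  count
}

# corner reprojection error between two homographies on an image frame
corner_error <- function(H1, H2, image_size) {
  nr <- image_size[1]; nc <- image_size[2]
  corners <- cbind(c(0, nc - 1, nc - 1, 0), c(0, 0, nr - 1, nr - 1), 1)
  a <- corners %*% t(H1); a <- a[, 1:2] / a[, 3]
  b <- corners %*% t(H2); b <- b[, 1:2] / b[, 3]
  max(sqrt(rowSums((a - b)^2)))
}

# small cached flights shared across test files (built once per run)
.test_cache <- new.env(parent = emptyenv())
cached_flight <- function(key, builder) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- builder()
  .test_cache[[key]]
}
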