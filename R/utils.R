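uav_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "uavstand_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) uav_error(class, msg, ...)
  invisible(TRUE)
}

#' Squared Pearson correlation between estimates and reference values
#'
#' The coefficient of determination conventionally reported for
#' estimated-versus-observed scatter in phenotyping validation studies.
#'
#' @param estimated,observed numeric vectors of equal length.
#' @return A single number in \[0, 1\].
#' @export
r_squared <- function(estimated, observed) {
  keep <- is.finite(estimated) & is.finite(observed)
  cor(estimated[keep], observed[keep])^2
}

#' Root-mean-square error
#' @param estimated,observed numeric vectors of equal length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(estimated, observed) {
  keep <- is.finite(estimated) & is.finite(observed)
  sqrt(mean((estimated[keep] - observed[keep])^2))
}

## polygon helpers ------------------------------------------------------

# area-weighted centroid of a closed ring given as n x 2 (not repeated)
polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(ring))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# vectorised even-odd ray casting; points on an edge count as inside
point_in_polygon <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    ex <- xj - xi; ey <- yj - yi
    len2 <- ex^2 + ey^2
    if (len2 > 0) {
      t <- pmin(pmax(((px - xi) * ex + (py - yi) * ey) / len2, 0), 1)
      d2 <- (px - (xi + t * ex))^2 + (py - (yi + t * ey))^2
      on_edge <- on_edge | d2 <= eps
    }
    j <- i
  }
  inside | on_edge
}

# TRUE when any two non-adjacent edges of the ring properly intersect
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  seg <- function(i) rbind(ring[i, ], ring[if (i == n) 1 else i + 1, ])
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  intersects <- function(p, q) {
    ccw(p[1, ], q[1, ], q[2, ]) != ccw(p[2, ], q[1, ], q[2, ]) &&
      ccw(p[1, ], p[2, ], q[1, ]) != ccw(p[1, ], p[2, ], q[2, ])
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      if (intersects(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# normalize a 3x3 homography so element (3,3) = 1
normalize_h <- function(H) {
  assert_that(is.matrix(H) && all(dim(H) == c(3, 3)), "contract_error",
              "homography must be a 3x3 matrix")
  H / H[3, 3]
}
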