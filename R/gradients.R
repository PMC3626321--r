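# Sobel gradient approximation and gradient-angle image.

#' Sobel gradient field of a CT slice
#'
#' Convolves the slice with the standard 3x3 Sobel masks to approximate the
#' intensity gradient. `gx` uses the mask
#' `[[-1,0,1],[-2,0,2],[-1,0,1]]` (positive where HU increases with
#' increasing column, i.e. image x) and `gy` its transpose (positive where
#' HU increases with increasing row, image y), so the gradient vector
#' points from darker toward brighter tissue. Border pixels are handled by
#' edge replication. The per-pixel gradient angle is the full-quadrant
#' arctangent of `(gy, gx)` in degrees `[0, 360)`; pixels with
#' `gx == gy == 0` have no defined direction and carry `NA`.
#'
#' @param slice A [make_slice()] object (at least 3x3 pixels).
#' @return An object of class `gradient_field`: matrices `gx`, `gy`,
#'   `gtheta` of the slice's shape.
#' @examples
#' s <- make_slice(matrix(rep(c(0, 400), each = 12), 4, 6), 0)
#' f <- sobel_field(s)
#' f$gx[2, 3]  # positive across the vertical step edge
#' @export
sobel_field <- function(slice) {
  stopifnot(inherits(slice, "ct_slice"))
  p <- slice$pixels
  if (nrow(p) < 3L || ncol(p) < 3L) stop("slice must be at least 3x3 pixels")
  pp <- pad_replicate(p)
  n <- nrow(p); m <- ncol(p)
  # shifted views of the padded image: s(dr, dc) = neighborhood at offset
  sh <- function(dr, dc) pp[(2L + dr):(n + 1L + dr), (2L + dc):(m + 1L + dc)]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  structure(list(gx = gx, gy = gy, gtheta = gradient_angle(gx, gy)),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %d x %d, %d px with undefined angle\n",
              nrow(x$gx), ncol(x$gx), sum(is.na(x$gtheta))))
  invisible(x)
}

pad_replicate <- function(p) {
  n <- nrow(p); m <- ncol(p)
  ri <- c(1L, seq_len(n), n)
  ci <- c(1L, seq_len(m), m)
  p[ri, ci, drop = FALSE]
}

#' Gradient angle in degrees
#'
#' Full-quadrant arctangent of `(gy, gx)` mapped to `[0, 360)`. The printed
#' one-argument form `atan(gy/gx)` cannot distinguish opposite directions,
#' which the opposed-pair condition of the circle test requires, so the
#' two-argument form is used. Where `gx == gy == 0` the direction is
#' undefined and `NA` is returned; such pixels never participate in pair
#' conditions. Vectorized.
#'
#' @param gx,gy Numeric (scalars or equal-shape arrays), HU change per
#'   pixel along image x (col) and y (row).
#' @return Angle(s) in degrees in `[0, 360)`, `NA` where undefined.
#' @examples
#' gradient_angle(1, 0)   # 0
#' gradient_angle(0, 1)   # 90
#' gradient_angle(0, 0)   # NA (undefined)
#' @export
gradient_angle <- function(gx, gy) {
  ang <- (atan2(gy, gx) * 180 / pi) %% 360
  ang[gx == 0 & gy == 0] <- NA_real_
  ang
}

# Absolute circular difference of two angle sets, result in [0, 180].
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Absolute difference of two undirected-line angles, result in [0, 90].
circ_diff180 <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}
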