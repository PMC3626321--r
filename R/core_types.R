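#' aortacad: aortic disease CAD for contrast-enhanced CT
#'
#' Detects candidates for aortic dissection (non-circular aortic
#' cross-sections, via a gradient-pair circle test) and penetrating aortic
#' ulcer (hyperintense components inside the aortic boundary) on axial
#' contrast-enhanced CT slices, with a synthetic phantom generator and a
#' sensitivity/specificity evaluation layer.
#'
#' Coordinate convention, used uniformly by every function in the package:
#' pixel positions are 0-based `(row, col)` pairs; `row` increases downward
#' (image y), `col` increases rightward (image x). Wherever the classical
#' gradient/centroid formulas speak of "x" and "y", x maps to `col` and y to
#' `row`. Gradient angles are degrees in `[0, 360)`.
#'
#' @keywords internal
#' @aliases aortacad-package
"_PACKAGE"

# ---- CTSlice -----------------------------------------------------------

#' Construct a CT slice
#'
#' Wraps a rectangular integer matrix of Hounsfield units (HU) with its
#' ordinal position in the axial series (0-based, superior to inferior) and
#' optional pixel spacing metadata.
#'
#' @param pixels Numeric matrix of HU values. Values must lie in the
#'   plausible CT range \[-2048, 4096\] and are rounded to integer HU.
#' @param slice_index Non-negative integer ordinal of the slice.
#' @param pixel_spacing_mm Optional numeric length-2 vector, physical
#'   (row, col) spacing in millimetres.
#' @return An object of class `ct_slice` with elements `pixels`,
#'   `slice_index`, `pixel_spacing_mm`.
#' @examples
#' s <- make_slice(matrix(300L, 3, 3), slice_index = 7)
#' s$slice_index
#' @export
make_slice <- function(pixels, slice_index, pixel_spacing_mm = NULL) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix (ragged or empty input?)")
  }
  if (nrow(pixels) == 0L || ncol(pixels) == 0L) {
    stop("`pixels` must be non-empty")
  }
  if (anyNA(pixels)) stop("`pixels` contains missing values")
  rng <- range(pixels)
  if (rng[1] < -2048 || rng[2] > 4096) {
    stop("HU values outside plausible CT range [-2048, 4096]")
  }
  # HU is an integer scale; round and store as integer
  pixels <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  slice_index <- as.integer(slice_index)
  if (length(slice_index) != 1L || is.na(slice_index) || slice_index < 0L) {
    stop("`slice_index` must be a single non-negative integer")
  }
  if (!is.null(pixel_spacing_mm)) {
    stopifnot(is.numeric(pixel_spacing_mm), length(pixel_spacing_mm) == 2L,
              all(pixel_spacing_mm > 0))
  }
  structure(
    list(pixels = pixels, slice_index = slice_index,
         pixel_spacing_mm = pixel_spacing_mm),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> index %d, %d x %d px, HU [%d, %d]\n",
              x$slice_index, nrow(x$pixels), ncol(x$pixels),
              round(min(x$pixels)), round(max(x$pixels))))
  invisible(x)
}

# ---- HURange -----------------------------------------------------------

#' Hounsfield-unit range of the contrast-enhanced lumen
#'
#' The HU window that defines the opacified aortic lumen. The default
#' 200--500 HU is the average range observed for contrast-enhanced aortic
#' blood. Thresholding of the lumen is inclusive at both bounds; the PAU
#' stage uses strictly-greater-than `upper`, so the two stages partition
#' intensities with no overlap.
#'
#' @param lower,upper Numeric scalars, `lower < upper`.
#' @return An object of class `hu_range`.
#' @examples
#' hu_range()          # default 200-500 HU
#' hu_range(150, 600)
#' @export
hu_range <- function(lower = 200, upper = 500) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (!(lower < upper)) stop("`lower` must be strictly below `upper`")
  structure(list(lower = lower, upper = upper), class = "hu_range")
}

#' @export
print.hu_range <- function(x, ...) {
  cat(sprintf("<hu_range> [%g, %g] HU\n", x$lower, x$upper))
  invisible(x)
}

# ---- AortaObject -------------------------------------------------------

#' Construct an aortic cross-section object from a pixel set
#'
#' An `aorta_object` is one labeled connected pixel region on one slice:
#' its pixel set, centroid `(C_x, C_y)` (the arithmetic mean of the pixel
#' positions), ordered boundary pixel list, and an anatomy label. The
#' boundary is the set of object pixels with at least one 4-neighbor
#' outside the object (pixels on the image edge count their out-of-image
#' neighbors as outside); it is ordered row-major for determinism.
#'
#' @param pixel_coords Integer matrix with columns `row`, `col` (0-based).
#' @param slice_index Slice ordinal the object lives on.
#' @param anatomy_label One of `"ascending"`, `"descending"`, `"unlinked"`.
#' @param image_shape Optional `c(nrow, ncol)` of the host image, used only
#'   to treat out-of-image neighbors as exterior; if omitted, pixels are
#'   assumed interior to an unbounded grid.
#' @return An `aorta_object` with elements `slice_index`, `pixel_coords`,
#'   `n`, `centroid` (named `c(row, col)`), `boundary`, `anatomy_label`.
#' @export
aorta_object <- function(pixel_coords, slice_index = 0L,
                         anatomy_label = c("unlinked", "ascending", "descending"),
                         image_shape = NULL) {
  anatomy_label <- match.arg(anatomy_label)
  pixel_coords <- coerce_coords(pixel_coords)
  if (nrow(pixel_coords) == 0L) stop("`pixel_coords` must be non-empty")
  if (anyDuplicated(paste(pixel_coords[, 1], pixel_coords[, 2]))) {
    stop("`pixel_coords` contains duplicate positions")
  }
  centroid <- c(row = mean(pixel_coords[, 1]), col = mean(pixel_coords[, 2]))
  boundary <- boundary_pixels(pixel_coords, image_shape)
  structure(
    list(slice_index = as.integer(slice_index),
         pixel_coords = pixel_coords,
         n = nrow(pixel_coords),
         centroid = centroid,
         boundary = boundary,
         anatomy_label = anatomy_label),
    class = "aorta_object"
  )
}

#' @export
print.aorta_object <- function(x, ...) {
  cat(sprintf(
    "<aorta_object> slice %d, %s: %d px, centroid (%.1f, %.1f), %d boundary px\n",
    x$slice_index, x$anatomy_label, x$n,
    x$centroid[["row"]], x$centroid[["col"]], nrow(x$boundary)))
  invisible(x)
}

coerce_coords <- function(pixel_coords) {
  if (is.data.frame(pixel_coords)) pixel_coords <- as.matrix(pixel_coords)
  if (is.vector(pixel_coords) && length(pixel_coords) == 2L) {
    pixel_coords <- matrix(pixel_coords, 1L, 2L)
  }
  if (!is.matrix(pixel_coords) || ncol(pixel_coords) != 2L) {
    stop("pixel coordinates must be a 2-column (row, col) matrix")
  }
  storage.mode(pixel_coords) <- "integer"
  colnames(pixel_coords) <- c("row", "col")
  pixel_coords
}

# Boundary = object pixels with >= 1 four-neighbor outside the set.
# Returned in row-major scan order.
boundary_pixels <- function(pixel_coords, image_shape = NULL) {
  key <- function(r, c) r * 1e6 + c   # rows/cols < 1e6 always hold for CT
  inside <- key(pixel_coords[, 1], pixel_coords[, 2])
  is_member <- function(r, c) key(r, c) %in% inside
  r <- pixel_coords[, 1]; c <- pixel_coords[, 2]
  ext <- !is_member(r - 1L, c) | !is_member(r + 1L, c) |
         !is_member(r, c - 1L) | !is_member(r, c + 1L)
  if (!is.null(image_shape)) {
    # out-of-image neighbors already count as exterior via is_member
    stopifnot(length(image_shape) == 2L)
  }
  b <- pixel_coords[ext, , drop = FALSE]
  b[order(b[, 1], b[, 2]), , drop = FALSE]
}

# Logical mask (nrow x ncol) from 0-based coords, and back.
coords_to_mask <- function(pixel_coords, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[cbind(pixel_coords[, 1] + 1L, pixel_coords[, 2] + 1L)] <- TRUE
  m
}

mask_to_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  cbind(row = w[, 1] - 1L, col = w[, 2] - 1L)
}

# ---- CircleDecision ----------------------------------------------------

circle_decision <- function(score, threshold) {
  stopifnot(score >= 0, score <= 1, threshold >= 0, threshold <= 1)
  structure(
    list(score = score, threshold = threshold,
         label = if (score >= threshold) "circle_like" else "dissection_candidate"),
    class = "circle_decision"
  )
}

#' @export
print.circle_decision <- function(x, ...) {
  cat(sprintf("<circle_decision> score %.4f (threshold %.2f): %s\n",
              x$score, x$threshold, x$label))
  invisible(x)
}
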