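# PAU detection: hyperintense connected components inside the aortic
# boundary. PAU pouches trap contrast medium, and the calcified plaque
# that causes them is radiodense, so their HU exceeds the lumen window;
# the lumen threshold therefore carves them out of the segmented lumen as
# holes, and they are recovered by intersecting the above-range mask with
# the filled interior of the aortic object.

#' Mask of pixels above the lumen HU range
#'
#' `TRUE` exactly where `HU > hu_range$upper` (strict; the lumen threshold
#' is inclusive at `upper`, so the two masks never overlap).
#'
#' @param slice A [make_slice()] object.
#' @param hu_range The lumen [hu_range()].
#' @return Logical matrix of the slice's shape.
#' @export
hyperintense_mask <- function(slice, hu_range = aortacad::hu_range()) {
  stopifnot(inherits(slice, "ct_slice"), inherits(hu_range, "hu_range"))
  slice$pixels > hu_range$upper
}

#' Restrict a mask to the filled interior of an aortic object
#'
#' Keeps only mask pixels lying within the filled interior of the object's
#' outer contour. The filled interior is the object's pixel set plus any
#' enclosed holes (computed by flood-filling the background from the image
#' border on the object's bounding box); holes are exactly where PAU and
#' calcification pixels end up after lumen thresholding. If the object
#' encloses no interior beyond its own pixels, the mask is simply clipped
#' to the pixel set.
#'
#' @param mask Logical matrix matching the object's host slice shape.
#' @param obj An [aorta_object()].
#' @return Logical matrix: `mask & filled_interior(obj)`.
#' @export
inside_aorta <- function(mask, obj) {
  stopifnot(is.logical(mask), is.matrix(mask), inherits(obj, "aorta_object"))
  mask & filled_interior(obj, dim(mask))
}

#' Filled interior of an aortic object
#'
#' Logical mask of the object's pixels together with any fully enclosed
#' holes.
#'
#' @param obj An [aorta_object()].
#' @param shape `c(nrow, ncol)` of the host image.
#' @return Logical matrix.
#' @export
filled_interior <- function(obj, shape) {
  m <- coords_to_mask(obj$pixel_coords, shape)
  fill_holes(m)
}

# Flood the complement 4-connectedly from a border ring; complement pixels
# not reached are enclosed holes. Cropping to the object's bounding box
# (padded by one) keeps the fill O(object area) rather than O(image area).
fill_holes <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(mask)
  r0 <- max(1L, min(w[, 1]) - 1L); r1 <- min(nrow(mask), max(w[, 1]) + 1L)
  c0 <- max(1L, min(w[, 2]) - 1L); c1 <- min(ncol(mask), max(w[, 2]) + 1L)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  n <- nrow(sub); m <- ncol(sub)
  outside <- matrix(FALSE, n, m)
  queue <- unique(c(which(!sub & (row(sub) %in% c(1L, n) |
                                  col(sub) %in% c(1L, m)))))
  outside[queue] <- TRUE
  while (length(queue) > 0L) {
    cur <- queue
    queue <- integer()
    r <- ((cur - 1L) %% n) + 1L
    c <- ((cur - 1L) %/% n) + 1L
    for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rn <- r + o[1]; cn <- c + o[2]
      ok <- rn >= 1L & rn <= n & cn >= 1L & cn <= m
      nb <- (cn[ok] - 1L) * n + rn[ok]
      new <- nb[!sub[nb] & !outside[nb]]
      if (length(new) > 0L) {
        outside[new] <- TRUE
        queue <- c(queue, new)
      }
    }
    queue <- unique(queue)
  }
  filled <- mask
  filled[r0:r1, c0:c1] <- sub | !outside
  filled
}

#' Detect PAU candidates inside an aortic object
#'
#' Intersects the above-range [hyperintense_mask()] with the object's
#' filled interior and groups the surviving pixels into 8-connected
#' components. Components of at least `min_size` pixels are returned as
#' PAU candidates with their peak HU; an empty list means the aortic
#' object as a whole is labeled healthy with respect to PAU.
#'
#' @param slice A [make_slice()] object.
#' @param obj An [aorta_object()] on that slice.
#' @param hu_range The lumen [hu_range()].
#' @param min_size Minimum candidate size in pixels (default 3, to
#'   suppress single-pixel artifact hits slightly above the lumen range).
#' @return List of `pau_candidate` objects, each with `pixel_coords`,
#'   `host_slice_index`, `host_anatomy`, `n`, `peak_hu`.
#' @export
detect_pau <- function(slice, obj, hu_range = aortacad::hu_range(),
                       min_size = 3L) {
  stopifnot(inherits(slice, "ct_slice"), inherits(obj, "aorta_object"),
            slice$slice_index == obj$slice_index)
  m <- inside_aorta(hyperintense_mask(slice, hu_range), obj)
  lab <- label_mask8(m)
  if (is.null(lab)) return(list())
  sizes <- tabulate(lab$labels)
  keep <- which(sizes >= min_size)
  lapply(keep, function(k) {
    px <- lab$coords[lab$labels == k, , drop = FALSE]
    structure(
      list(pixel_coords = px,
           host_slice_index = obj$slice_index,
           host_anatomy = obj$anatomy_label,
           n = nrow(px),
           peak_hu = max(slice$pixels[cbind(px[, 1] + 1L, px[, 2] + 1L)])),
      class = "pau_candidate")
  })
}

#' @export
print.pau_candidate <- function(x, ...) {
  cat(sprintf("<pau_candidate> slice %d (%s): %d px, peak %g HU\n",
              x$host_slice_index, x$host_anatomy, x$n, x$peak_hu))
  invisible(x)
}
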