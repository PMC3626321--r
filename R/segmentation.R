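# Lumen segmentation: HU thresholding, connected components, seeded
# slice-to-slice tracking of the ascending and descending aorta.

#' Seed position for vessel tracking
#'
#' The starting position of the ascending or descending aorta on the first
#' slice, supplied by the operator.
#'
#' @param position Length-2 `(row, col)` 0-based pixel position.
#' @param anatomy_label `"ascending"` or `"descending"`.
#' @return A `seed_point` object.
#' @export
seed_point <- function(position, anatomy_label = c("descending", "ascending")) {
  anatomy_label <- match.arg(anatomy_label)
  stopifnot(is.numeric(position), length(position) == 2L, all(position >= 0))
  structure(list(position = c(row = position[1], col = position[2]),
                 anatomy_label = anatomy_label),
            class = "seed_point")
}

#' Threshold the contrast-enhanced lumen
#'
#' @param slice A [make_slice()] object.
#' @param hu_range A [hu_range()]; the mask is `TRUE` exactly where
#'   `lower <= HU <= upper` (inclusive at both bounds).
#' @return Logical matrix of the slice's shape.
#' @examples
#' s <- make_slice(matrix(c(150, 200, 500, 501), 2, 2), 0)
#' threshold_lumen(s, hu_range(200, 500))
#' @export
threshold_lumen <- function(slice, hu_range = aortacad::hu_range()) {
  stopifnot(inherits(slice, "ct_slice"), inherits(hu_range, "hu_range"))
  slice$pixels >= hu_range$lower & slice$pixels <= hu_range$upper
}

#' Label connected components of a binary mask
#'
#' Groups `TRUE` pixels into 8-connected components and returns each
#' component of at least `min_size` pixels as an [aorta_object()] candidate
#' (with centroid and boundary computed). Smaller components are discarded.
#'
#' @param mask Logical matrix.
#' @param min_size Minimum component size in pixels (default 50; intended
#'   to reject contrast-filled vessels much smaller than the aorta).
#' @param slice_index Slice ordinal recorded on the candidates.
#' @return List of `aorta_object` candidates (possibly empty), ordered by
#'   their first pixel in row-major scan order.
#' @export
label_components <- function(mask, min_size = 50L, slice_index = 0L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label_mask8(mask)
  if (is.null(lab)) return(list())
  sizes <- tabulate(lab$labels)
  keep <- which(sizes >= min_size)
  shape <- dim(mask)
  out <- lapply(keep, function(k) {
    aorta_object(lab$coords[lab$labels == k, , drop = FALSE],
                 slice_index = slice_index, image_shape = shape)
  })
  if (length(out) > 1L) {
    first <- vapply(out, function(o) {
      min(o$pixel_coords[, 1] * ncol(mask) + o$pixel_coords[, 2])
    }, numeric(1))
    out <- out[order(first)]
  }
  out
}

# 8-connected labeling of TRUE pixels via an igraph components pass.
# Returns NULL for an all-FALSE mask, else list(coords = 0-based (row,col)
# matrix, labels = integer component id per row of coords).
label_mask8 <- function(mask) {
  idx <- which(mask)                       # column-major linear indices
  if (length(idx) == 0L) return(NULL)
  n <- nrow(mask); m <- ncol(mask)
  id <- integer(n * m); id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% n) + 1L
  c <- ((idx - 1L) %/% n) + 1L
  edges <- list()
  # half the 8-neighborhood; the other half is implied by undirectedness
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    rn <- r + o[1]; cn <- c + o[2]
    ok <- rn >= 1L & rn <= n & cn >= 1L & cn <= m
    if (!any(ok)) next
    nb <- (cn[ok] - 1L) * n + rn[ok]
    hit <- mask[nb]
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <- rbind(id[idx[ok][hit]], id[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  comp <- igraph::components(g)
  list(coords = cbind(row = r - 1L, col = c - 1L),
       labels = as.integer(comp$membership))
}

#' Select the aortic candidate continuing a tracked vessel
#'
#' Among candidate objects on the current slice, returns the one whose
#' centroid is nearest the previous object's centroid (or the seed
#' position on the first slice), provided that distance is below the
#' continuity limit; `NULL` if no candidate qualifies.
#'
#' @param candidates List of [aorta_object()]s.
#' @param previous An `aorta_object` or [seed_point()].
#' @param continuity_limit_px Maximum allowed centroid displacement
#'   between consecutive slices, in pixels (default 20).
#' @return The selected `aorta_object`, or `NULL`.
#' @export
select_aorta <- function(candidates, previous, continuity_limit_px = 20) {
  if (length(candidates) == 0L) return(NULL)
  ref <- if (inherits(previous, "seed_point")) previous$position
         else previous$centroid
  d <- vapply(candidates, function(o) {
    sqrt(sum((o$centroid - ref)^2))
  }, numeric(1))
  i <- which.min(d)
  if (d[i] > continuity_limit_px) return(NULL)
  candidates[[i]]
}

#' Segment and track the aorta through a slice series
#'
#' For each seeded vessel, thresholds every slice to the lumen HU range,
#' labels connected components, and links the nearest candidate slice to
#' slice starting from the seed. Slices where no candidate lies within the
#' continuity limit are reported as gaps (tracking resumes from the last
#' linked centroid rather than silently dropping the vessel).
#'
#' @param slices List of [make_slice()] objects ordered by `slice_index`.
#' @param hu_range Lumen [hu_range()].
#' @param seeds List of [seed_point()]s, one per tracked vessel.
#' @param min_size,continuity_limit_px Passed to [label_components()] and
#'   [select_aorta()].
#' @return A list with one element per seed, each a list with
#'   `anatomy_label`, `objects` (list of linked `aorta_object`s carrying
#'   that label), and `gaps` (integer vector of slice indices where
#'   tracking failed).
#' @export
segment_series <- function(slices, hu_range = aortacad::hu_range(), seeds,
                           min_size = 50L, continuity_limit_px = 20) {
  stopifnot(length(slices) > 0L, length(seeds) > 0L)
  shape <- dim(slices[[1]]$pixels)
  for (sd in seeds) {
    if (!inherits(sd, "seed_point")) stop("`seeds` must be seed_point objects")
    if (sd$position[1] >= shape[1] || sd$position[2] >= shape[2]) {
      stop(sprintf("seed (%g, %g) outside image bounds",
                   sd$position[1], sd$position[2]))
    }
  }
  ord <- order(vapply(slices, `[[`, integer(1), "slice_index"))
  slices <- slices[ord]
  # component labeling is per slice, shared across vessels
  per_slice <- lapply(slices, function(s) {
    label_components(threshold_lumen(s, hu_range), min_size = min_size,
                     slice_index = s$slice_index)
  })
  lapply(seeds, function(sd) {
    prev <- sd
    objects <- list()
    gaps <- integer()
    for (i in seq_along(slices)) {
      hit <- select_aorta(per_slice[[i]], prev, continuity_limit_px)
      if (is.null(hit)) {
        gaps <- c(gaps, slices[[i]]$slice_index)
      } else {
        hit$anatomy_label <- sd$anatomy_label
        objects[[length(objects) + 1L]] <- hit
        prev <- hit
      }
    }
    list(anatomy_label = sd$anatomy_label, objects = objects, gaps = gaps)
  })
}
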