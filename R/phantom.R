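# Synthetic CT phantom generator with ground truth: healthy circular
# aortae, dissection-distorted cross-sections (flap-split or elongated),
# and hyperintense PAU blobs at the lumen wall, on a soft-tissue
# background with additive Gaussian noise.

#' Specification of a synthetic phantom study
#'
#' Describes a stack of axial slices containing one tracked vessel. Class
#' means are soft tissue ~40 HU, contrast-enhanced lumen ~350 HU and PAU
#' blobs ~800 HU, placed so that with the default additive noise
#' (`noise_sd = 10` HU) every class stays on its own side of the 200--500
#' HU lumen window by a wide margin; the spec validates the 3-sigma
#' separation and refuses inconsistent settings. `noise_sd = 0` yields
#' deterministic class-constant images (the "noise-free" phantom).
#'
#' @param shape `c(nrow, ncol)` image dimensions (default 128 x 128; the
#'   geometry is resolution-agnostic, so tests run at reduced size).
#' @param n_slices Number of slices in the stack.
#' @param hu_range Lumen [hu_range()] the phantom is built against.
#' @param lumen_hu,background_hu,pau_hu Class mean HU values.
#' @param vessel List: `center` `(row, col)` on slice 0, `radius` px,
#'   `drift` `(row, col)` px per slice.
#' @param noise_sd Additive Gaussian noise standard deviation in HU.
#' @param seed Integer seed; each slice derives its own stream from it, so
#'   generation is deterministic and independent of call order.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(128L, 128L), n_slices = 10L,
                         hu_range = aortacad::hu_range(),
                         lumen_hu = 350, background_hu = 40, pau_hu = 800,
                         vessel = list(center = c(64, 64), radius = 20,
                                       drift = c(0, 0)),
                         noise_sd = 10, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 8L), n_slices >= 1L,
            inherits(hu_range, "hu_range"), noise_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (lumen_hu - 3 * noise_sd < hu_range$lower ||
      lumen_hu + 3 * noise_sd > hu_range$upper) {
    stop("lumen mean +- 3 sd must stay inside the lumen HU range")
  }
  if (background_hu + 3 * noise_sd >= hu_range$lower) {
    stop("background mean + 3 sd must stay below the lumen HU range")
  }
  if (pau_hu - 3 * noise_sd <= hu_range$upper) {
    stop("PAU mean - 3 sd must stay above the lumen HU range")
  }
  ctr <- vessel$center; rad <- vessel$radius
  drift <- if (is.null(vessel$drift)) c(0, 0) else vessel$drift
  end <- ctr + (n_slices - 1L) * drift
  for (p in list(ctr, end)) {
    if (p[1] - rad < 1 || p[1] + rad > shape[1] - 2 ||
        p[2] - rad < 1 || p[2] + rad > shape[2] - 2) {
      stop("vessel does not fit inside the image over the whole stack")
    }
  }
  structure(
    list(shape = as.integer(shape), n_slices = as.integer(n_slices),
         hu_range = hu_range, lumen_hu = lumen_hu,
         background_hu = background_hu, pau_hu = pau_hu,
         vessel = list(center = ctr, radius = rad, drift = drift),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Per-slice RNG stream derived from the study seed; global RNG state is
# restored on exit. Multiplier keeps the derived seed well under 2^31.
with_slice_seed <- function(spec, slice_index, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((spec$seed * 10007L + slice_index) %% 1000000007L)
  force(code)
}

vessel_center <- function(spec, slice_index) {
  spec$vessel$center + slice_index * spec$vessel$drift
}

disk_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]) - 1L, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1L, shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

ellipse_mask <- function(shape, center, a_row, a_col, angle_deg = 0) {
  r <- matrix(seq_len(shape[1]) - 1L, shape[1], shape[2]) - center[1]
  c <- matrix(seq_len(shape[2]) - 1L, shape[1], shape[2], byrow = TRUE) - center[2]
  th <- angle_deg * pi / 180
  u <- r * cos(th) + c * sin(th)
  v <- -r * sin(th) + c * cos(th)
  (u / a_row)^2 + (v / a_col)^2 <= 1
}

render_slice <- function(spec, slice_index, lumen_mask, extra = NULL) {
  px <- matrix(spec$background_hu, spec$shape[1], spec$shape[2])
  px[lumen_mask] <- spec$lumen_hu
  if (!is.null(extra)) px[extra$mask] <- extra$hu
  if (spec$noise_sd > 0) {
    px <- with_slice_seed(spec, slice_index, {
      px + matrix(stats::rnorm(length(px), 0, spec$noise_sd),
                  nrow(px), ncol(px))
    })
  }
  make_slice(round(px), slice_index)
}

#' Generate a healthy phantom slice
#'
#' A circular lumen at the lumen mean HU on soft-tissue background, plus
#' additive noise; the truth mask is the rasterized disk.
#'
#' @param spec A [phantom_spec()].
#' @param slice_index Slice ordinal (drift applies per slice).
#' @return List: `slice` ([make_slice()]), `truth_mask` (logical matrix),
#'   `truth_label = "healthy"`.
#' @export
make_healthy_slice <- function(spec, slice_index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  ctr <- vessel_center(spec, slice_index)
  m <- disk_mask(spec$shape, ctr, spec$vessel$radius)
  list(slice = render_slice(spec, slice_index, m),
       truth_mask = m, truth_label = "healthy")
}

#' Generate a dissection phantom slice
#'
#' Two distortion models of the aortic cross-section are offered. In a
#' dissection the lumen is split in two by the intimal flap and the
#' pressure difference between true and false lumen distorts their
#' shapes; `kind = "flap"` renders the disk minus a dark flap band through
#' its middle (two crescent sub-lumens), `kind = "ellipse"` renders a
#' single elongated lumen of the same area as the reference disk with the
#' given axis ratio. A flap of width 0 degenerates to the healthy slice.
#'
#' @param spec A [phantom_spec()].
#' @param slice_index Slice ordinal.
#' @param kind `"flap"` or `"ellipse"`.
#' @param flap_width_px Width of the dark flap band in pixels (flap kind).
#' @param flap_angle_deg Orientation of the flap band (flap kind).
#' @param axis_ratio Major/minor axis ratio `>= 2` (ellipse kind).
#' @return List: `slice`, `truth_mask` (lumen pixels),
#'   `truth_label = "dissection"`.
#' @export
make_dissection_slice <- function(spec, slice_index = 0L,
                                  kind = c("flap", "ellipse"),
                                  flap_width_px = 4, flap_angle_deg = 0,
                                  axis_ratio = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  kind <- match.arg(kind)
  ctr <- vessel_center(spec, slice_index)
  rad <- spec$vessel$radius
  if (kind == "flap") {
    m <- disk_mask(spec$shape, ctr, rad)
    if (flap_width_px > 0) {
      r <- matrix(seq_len(spec$shape[1]) - 1L, spec$shape[1], spec$shape[2]) - ctr[1]
      c <- matrix(seq_len(spec$shape[2]) - 1L, spec$shape[1], spec$shape[2],
                  byrow = TRUE) - ctr[2]
      th <- flap_angle_deg * pi / 180
      band <- abs(r * cos(th) + c * sin(th)) <= flap_width_px / 2
      m <- m & !band
    }
  } else {
    if (axis_ratio < 2) stop("`axis_ratio` must be >= 2 for a dissection phantom")
    a <- rad * sqrt(axis_ratio)   # same area as the reference disk
    b <- rad / sqrt(axis_ratio)
    if (ctr[1] - a < 1 || ctr[1] + a > spec$shape[1] - 2) {
      stop("ellipse does not fit inside the image")
    }
    m <- ellipse_mask(spec$shape, ctr, a, b)
  }
  list(slice = render_slice(spec, slice_index, m),
       truth_mask = m,
       truth_label = if (kind == "flap" && flap_width_px == 0) "healthy"
                     else "dissection")
}

#' Generate a PAU phantom slice
#'
#' A healthy circular lumen with one or more hyperintense blobs planted
#' just inside the lumen wall (contrast trapped in an ulcer pouch or
#' calcified plaque). Blobs sit fully inside the disk with a small margin
#' from the wall so that, after lumen thresholding, each becomes a closed
#' hole recoverable by interior filling.
#'
#' @param spec A [phantom_spec()].
#' @param slice_index Slice ordinal.
#' @param blobs List of blob descriptors, each a list with `angle_deg`
#'   (position around the wall), `radius` (blob radius in px, default 2),
#'   optional `hu` (default `spec$pau_hu`), optional `margin_px` distance
#'   from the wall (default 2), or an explicit `pixels` matrix of 0-based
#'   `(row, col)` offsets from the blob center overriding the disk shape.
#' @return List: `slice`, `truth_mask` (lumen pixels excluding blobs),
#'   `truth_blobs` (list of 0-based `(row, col)` matrices),
#'   `truth_label = "pau"`.
#' @export
make_pau_slice <- function(spec, slice_index = 0L,
                           blobs = list(list(angle_deg = 0))) {
  stopifnot(inherits(spec, "phantom_spec"), length(blobs) >= 1L)
  ctr <- vessel_center(spec, slice_index)
  rad <- spec$vessel$radius
  lumen <- disk_mask(spec$shape, ctr, rad)
  blob_mask <- matrix(FALSE, spec$shape[1], spec$shape[2])
  truth_blobs <- list()
  hu <- spec$pau_hu
  for (b in blobs) {
    br <- if (is.null(b$radius)) 2 else b$radius
    margin <- if (is.null(b$margin_px)) 2 else b$margin_px
    if (!is.null(b$hu)) hu <- b$hu
    th <- (if (is.null(b$angle_deg)) 0 else b$angle_deg) * pi / 180
    d <- rad - br - margin
    if (d <= 0) stop("blob too large to fit inside the lumen wall")
    bc <- round(ctr + d * c(sin(th), cos(th)))
    bm <- if (!is.null(b$pixels)) {
      px <- coerce_coords(b$pixels)
      coords_to_mask(cbind(px[, 1] + bc[1], px[, 2] + bc[2]), spec$shape)
    } else {
      disk_mask(spec$shape, bc, br)
    }
    bm <- bm & lumen
    if (!any(bm)) stop("blob specification produced no pixels inside the lumen")
    truth_blobs[[length(truth_blobs) + 1L]] <- mask_to_coords(bm)
    blob_mask <- blob_mask | bm
  }
  list(slice = render_slice(spec, slice_index, lumen & !blob_mask,
                            extra = list(mask = blob_mask, hu = hu)),
       truth_mask = lumen & !blob_mask,
       truth_blobs = truth_blobs,
       truth_label = "pau")
}

#' Generate a full phantom study with truth table
#'
#' Builds a slice stack mixing healthy, dissection and PAU slices in the
#' given order and returns the slices together with a per-slice truth
#' table suitable for the evaluation stage.
#'
#' @param spec A [phantom_spec()].
#' @param labels Character vector of per-slice truth labels drawn from
#'   `"healthy"`, `"dissection"`, `"pau"`; its length overrides
#'   `spec$n_slices`. Defaults to all healthy.
#' @param ... Passed on to [make_dissection_slice()] / [make_pau_slice()]
#'   for the matching slices.
#' @return List: `slices` (list of [make_slice()]), `truth`
#'   (`data.frame` with `slice_index`, `truth_label`, `n_truth_blobs`),
#'   `details` (per-slice generator output).
#' @export
make_phantom_study <- function(spec, labels = rep("healthy", spec$n_slices),
                               ...) {
  stopifnot(inherits(spec, "phantom_spec"),
            all(labels %in% c("healthy", "dissection", "pau")))
  details <- lapply(seq_along(labels) - 1L, function(i) {
    switch(labels[i + 1L],
           healthy = make_healthy_slice(spec, i),
           dissection = make_dissection_slice(spec, i, ...),
           pau = make_pau_slice(spec, i, ...))
  })
  truth <- data.frame(
    slice_index = seq_along(labels) - 1L,
    truth_label = labels,
    n_truth_blobs = vapply(details, function(d) {
      if (is.null(d$truth_blobs)) 0L else length(d$truth_blobs)
    }, integer(1))
  )
  list(slices = lapply(details, `[[`, "slice"), truth = truth,
       details = details)
}

#' Write a phantom study to a directory of plain array files
#'
#' One headerless CSV of integer HU values per slice
#' (`slice_0000.csv`, ...) plus `truth.csv`. The inverse of
#' [read_slice_dir()].
#'
#' @param study Output of [make_phantom_study()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dir <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in study$slices) {
    f <- file.path(dir, sprintf("slice_%04d.csv", s$slice_index))
    data.table::fwrite(data.table::as.data.table(s$pixels), f,
                       col.names = FALSE)
  }
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a directory of plain array slice files
#'
#' Reads every `slice_*.csv` (headerless CSV of HU values, one file per
#' slice; the four-digit suffix is the slice index) into a list of
#' [make_slice()] objects ordered by index.
#'
#' @param dir Directory path.
#' @return List of `ct_slice` objects.
#' @export
read_slice_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("no slice_*.csv files found in '%s'", dir))
  }
  lapply(files, function(f) {
    idx <- as.integer(sub("^slice_0*(\\d+)\\.csv$", "\\1", basename(f)))
    px <- as.matrix(data.table::fread(f, header = FALSE))
    dimnames(px) <- NULL
    make_slice(px, idx)
  })
}
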