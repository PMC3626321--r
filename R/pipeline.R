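# Pipeline front end: wires segmentation, circle detection and PAU
# detection into one run over a slice directory, with config handling,
# logging, CSV reports, overlay images and (when truth is available)
# confusion summaries.

#' Default pipeline configuration
#'
#' Every tunable of the diagnostic process with its standard value:
#' lumen HU window 200--500, circle-likeness threshold 0.60, pair
#' tolerances 10 degrees / 2 px, minimum aortic object 50 px, minimum PAU
#' component 3 px, slice-to-slice continuity limit 20 px. `seeds` must be
#' supplied by the operator (a list of `list(row =, col =, anatomy =)`).
#'
#' @return Named list of settings.
#' @export
default_config <- function() {
  list(
    hu_range = list(lower = 200, upper = 500),
    threshold = 0.60,
    angle_tol_deg = 10,
    line_tol_px = 2,
    min_object_px = 50,
    min_pau_px = 3,
    continuity_limit_px = 20,
    seeds = NULL
  )
}

#' Read a pipeline configuration file
#'
#' YAML file with any subset of the [default_config()] keys; missing keys
#' fall back to the documented defaults (an omitted `hu_range` falls back
#' to 200--500 HU with a logged warning).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

config_seeds <- function(config) {
  if (is.null(config$seeds) || length(config$seeds) == 0L) {
    stop("config must supply at least one seed (list(row=, col=, anatomy=))")
  }
  lapply(config$seeds, function(s) {
    seed_point(c(s$row, s$col), anatomy_label = s$anatomy)
  })
}

#' Run the diagnostic pipeline over a slice directory
#'
#' Reads the slice series, tracks the seeded vessels, classifies every
#' tracked aortic object as circle-like or dissection candidate, detects
#' PAU candidates inside it, and writes to `output_dir`:
#' `report.csv` (one row per tracked object: slice index, anatomy, size,
#' centroid, circle score, shape label, PAU candidate count, peak HU),
#' `log.txt` (all parameter values and per-stage counts), overlay PNGs
#' for flagged slices, and, when `truth.csv` is present in `input_dir`,
#' `dissection_summary.csv` and `pau_summary.csv` confusion tables.
#'
#' @param input_dir Directory of `slice_*.csv` files (see
#'   [read_slice_dir()]), optionally holding a `truth.csv`.
#' @param config Config list (see [default_config()]) or path to a YAML
#'   config file. Must supply `seeds`. An omitted `hu_range` falls back
#'   to the 200--500 HU default with a logged warning.
#' @param output_dir Directory for reports (created if needed).
#' @param stages Character subset of `c("dissection", "pau")`.
#' @param overlays Write overlay PNGs for flagged slices (default TRUE).
#' @return Invisibly, a list with `report` (`data.frame`), `tracks`,
#'   `summaries` (possibly NULL), `log` (character vector).
#' @export
run_pipeline <- function(input_dir, config = default_config(),
                         output_dir = file.path(input_dir, "cad_output"),
                         stages = c("dissection", "pau"),
                         overlays = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(config)) config <- read_config(config)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  full <- default_config()
  hu_missing <- is.null(config$hu_range)
  for (k in setdiff(names(full), "seeds")) {
    if (is.null(config[[k]])) config[[k]] <- full[[k]]
  }
  if (hu_missing) {
    warning("config omitted hu_range; using default 200-500 HU")
    note("WARNING: config omitted hu_range; using default 200-500 HU")
  }
  rng <- hu_range(config$hu_range$lower, config$hu_range$upper)
  tol <- pair_tolerances(config$angle_tol_deg, config$line_tol_px)
  seeds <- config_seeds(config)

  slices <- read_slice_dir(input_dir)
  note("read %d slices from %s", length(slices), input_dir)
  note("hu_range [%g, %g]; threshold %g; angle_tol %g deg; line_tol %g px",
       rng$lower, rng$upper, config$threshold, tol$angle_tol_deg,
       tol$line_tol_px)
  note("min_object_px %d; min_pau_px %d; continuity_limit_px %g",
       config$min_object_px, config$min_pau_px, config$continuity_limit_px)

  tracks <- segment_series(slices, rng, seeds,
                           min_size = config$min_object_px,
                           continuity_limit_px = config$continuity_limit_px)
  by_index <- stats::setNames(slices,
                              vapply(slices, `[[`, integer(1), "slice_index"))
  field_cache <- new.env(parent = emptyenv())
  get_field <- function(s) {
    key <- as.character(s$slice_index)
    if (is.null(field_cache[[key]])) field_cache[[key]] <- sobel_field(s)
    field_cache[[key]]
  }

  rows <- list()
  flagged <- list()
  for (tr in tracks) {
    note("vessel %s: %d objects linked, %d gaps (%s)", tr$anatomy_label,
         length(tr$objects), length(tr$gaps),
         paste(tr$gaps, collapse = " "))
    for (obj in tr$objects) {
      s <- by_index[[as.character(obj$slice_index)]]
      score <- NA_real_; shape <- NA_character_
      if ("dissection" %in% stages) {
        dec <- tryCatch(classify_shape(obj, get_field(s), config$threshold, tol),
                        error = function(e) NULL)
        if (is.null(dec)) {
          shape <- "degenerate"
        } else {
          score <- dec$score; shape <- dec$label
        }
      }
      pau <- list()
      if ("pau" %in% stages) {
        pau <- detect_pau(s, obj, rng, min_size = config$min_pau_px)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        slice_index = obj$slice_index,
        anatomy = obj$anatomy_label,
        n_pixels = obj$n,
        centroid_row = round(obj$centroid[["row"]], 3),
        centroid_col = round(obj$centroid[["col"]], 3),
        circle_score = round(score, 4),
        shape_label = shape,
        pau_count = length(pau),
        peak_hu = if (length(pau) > 0) {
          max(vapply(pau, `[[`, numeric(1), "peak_hu"))
        } else NA_real_
      )
      if (identical(shape, "dissection_candidate") || length(pau) > 0L) {
        flagged[[length(flagged) + 1L]] <-
          list(slice = s, obj = obj, pau = pau)
      }
    }
  }
  report <- if (length(rows) > 0) do.call(rbind, rows) else data.frame()
  note("%d objects reported; %d slices flagged", nrow(report), length(flagged))

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report, file.path(output_dir, "report.csv"),
                   row.names = FALSE)
  if (overlays) {
    for (fl in flagged) write_overlay(fl, output_dir)
  }

  summaries <- NULL
  truth_path <- file.path(input_dir, "truth.csv")
  if (file.exists(truth_path) && nrow(report) > 0) {
    truth <- utils::read.csv(truth_path)
    summaries <- evaluate_report(report, truth)
    if ("dissection" %in% stages) {
      utils::write.csv(summaries$dissection,
                       file.path(output_dir, "dissection_summary.csv"),
                       row.names = FALSE)
    }
    if ("pau" %in% stages) {
      utils::write.csv(summaries$pau,
                       file.path(output_dir, "pau_summary.csv"),
                       row.names = FALSE)
    }
    note("truth available: confusion summaries written")
  }
  writeLines(log, file.path(output_dir, "log.txt"))
  invisible(list(report = report, tracks = tracks, summaries = summaries,
                 log = log))
}

#' Confusion summaries from a pipeline report and a truth table
#'
#' Joins the per-object report with a per-slice truth table
#' (`slice_index`, `truth_label` in healthy/dissection/pau) and tallies
#' both diagnostic tasks per anatomical region.
#'
#' @param report `data.frame` as produced by [run_pipeline()].
#' @param truth `data.frame` with `slice_index` and `truth_label`.
#' @return List of two [confusion_summary()] tables, `dissection` and
#'   `pau`.
#' @export
evaluate_report <- function(report, truth) {
  stopifnot(all(c("slice_index", "truth_label") %in% names(truth)))
  tl <- truth$truth_label[match(report$slice_index, truth$slice_index)]
  per_task <- function(pred_candidate, diseased_label) {
    regions <- lapply(split(seq_len(nrow(report)), report$anatomy),
                      function(i) {
      tally(ifelse(pred_candidate[i], "candidate", "healthy"),
            ifelse(tl[i] == diseased_label, "diseased", "healthy"))
    })
    confusion_summary(regions)
  }
  list(
    dissection = per_task(report$shape_label %in% "dissection_candidate",
                          "dissection"),
    pau = per_task(report$pau_count > 0, "pau")
  )
}

# Grayscale overlay PNG with candidate pixels highlighted: the aortic
# boundary in green, PAU candidate pixels in red.
write_overlay <- function(fl, output_dir) {
  p <- fl$slice$pixels
  g <- (p - min(p)) / max(1e-9, diff(range(p)))
  img <- array(g, dim = c(nrow(p), ncol(p), 3L))
  b <- fl$obj$boundary
  img[cbind(b[, 1] + 1L, b[, 2] + 1L, 1L)] <- 0
  img[cbind(b[, 1] + 1L, b[, 2] + 1L, 2L)] <- 1
  img[cbind(b[, 1] + 1L, b[, 2] + 1L, 3L)] <- 0
  for (cand in fl$pau) {
    px <- cand$pixel_coords
    img[cbind(px[, 1] + 1L, px[, 2] + 1L, 1L)] <- 1
    img[cbind(px[, 1] + 1L, px[, 2] + 1L, 2L)] <- 0
    img[cbind(px[, 1] + 1L, px[, 2] + 1L, 3L)] <- 0
  }
  png::writePNG(img, file.path(output_dir,
      sprintf("overlay_%04d_%s.png", fl$slice$slice_index,
              fl$obj$anatomy_label)))
}
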