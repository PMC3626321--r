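# Per-object diagnostic evaluation: confusion counts, sensitivity,
# specificity. The unit of evaluation is the aortic object per slice
# (ascending and descending counted separately); "positive" means the
# system flagged a disease candidate.

#' Construct confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts of aortic objects.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, tn = 0L, fn = 0L) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers")
  }
  v <- as.integer(v)
  structure(list(tp = v[1], fp = v[2], tn = v[3], fn = v[4]),
            class = "confusion_counts")
}

#' Tally predicted/truth label pairs into confusion counts
#'
#' A true positive is a diseased aortic object labeled a candidate by the
#' system; a false positive a healthy object labeled a candidate; a true
#' negative a healthy object labeled healthy; a false negative a diseased
#' object labeled healthy.
#'
#' @param predicted Character vector, each `"candidate"` or `"healthy"`.
#' @param truth Character vector (same length), each `"diseased"` or
#'   `"healthy"`.
#' @return A [confusion_counts()] object; entries always sum to
#'   `length(predicted)`.
#' @examples
#' tally(c("candidate", "healthy"), c("diseased", "healthy"))
#' @export
tally <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have the same length")
  }
  if (!all(predicted %in% c("candidate", "healthy"))) {
    stop("unknown predicted label (use 'candidate' or 'healthy')")
  }
  if (!all(truth %in% c("diseased", "healthy"))) {
    stop("unknown truth label (use 'diseased' or 'healthy')")
  }
  pos <- predicted == "candidate"
  dis <- truth == "diseased"
  confusion_counts(tp = sum(pos & dis), fp = sum(pos & !dis),
                   tn = sum(!pos & !dis), fn = sum(!pos & dis))
}

#' Sensitivity (true positive rate)
#'
#' `tp / (tp + fn)`; `NA` when no diseased objects exist. Summaries
#' display 4 decimal places (round half to even).
#'
#' @param c A [confusion_counts()] object.
#' @return Fraction in `[0, 1]`, or `NA` if undefined.
#' @examples
#' sensitivity(confusion_counts(tp = 83, fn = 18))  # 0.8218...
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0L) return(NA_real_)
  c$tp / (c$tp + c$fn)
}

#' Specificity (true negative rate)
#'
#' `tn / (tn + fp)`; `NA` when no healthy objects exist.
#'
#' @param c A [confusion_counts()] object.
#' @return Fraction in `[0, 1]`, or `NA` if undefined.
#' @examples
#' specificity(confusion_counts(tn = 534, fp = 5))  # 0.9907...
#' @export
specificity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tn + c$fp == 0L) return(NA_real_)
  c$tn / (c$tn + c$fp)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d, fp %d, tn %d, fn %d\n",
              x$tp, x$fp, x$tn, x$fn))
  se <- sensitivity(x); sp <- specificity(x)
  cat(sprintf("  sensitivity %s  specificity %s\n",
              if (is.na(se)) "undefined" else sprintf("%.4f", round(se, 4)),
              if (is.na(sp)) "undefined" else sprintf("%.4f", round(sp, 4))))
  invisible(x)
}

#' Per-region evaluation summary table
#'
#' Builds the standard summary: one row per region (all / ascending /
#' descending) with tp, fp, tn, fn and 4-decimal sensitivity and
#' specificity, the "all" row being the sum of the regions.
#'
#' @param by_region Named list of [confusion_counts()], names
#'   `"ascending"` and/or `"descending"`.
#' @return `data.frame` with columns `data_type`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`.
#' @export
confusion_summary <- function(by_region) {
  stopifnot(length(by_region) >= 1L, !is.null(names(by_region)))
  total <- confusion_counts(
    tp = sum(vapply(by_region, `[[`, integer(1), "tp")),
    fp = sum(vapply(by_region, `[[`, integer(1), "fp")),
    tn = sum(vapply(by_region, `[[`, integer(1), "tn")),
    fn = sum(vapply(by_region, `[[`, integer(1), "fn")))
  rows <- c(list(all = total), by_region)
  data.frame(
    data_type = names(rows),
    tp = vapply(rows, `[[`, integer(1), "tp"),
    fp = vapply(rows, `[[`, integer(1), "fp"),
    tn = vapply(rows, `[[`, integer(1), "tn"),
    fn = vapply(rows, `[[`, integer(1), "fn"),
    sensitivity = round(vapply(rows, sensitivity, numeric(1)), 4),
    specificity = round(vapply(rows, specificity, numeric(1)), 4),
    row.names = NULL
  )
}
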