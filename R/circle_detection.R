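# Fast circle detection: classifies an aortic cross-section as circle-like
# (healthy) or a dissection candidate from gradient-angle pair conditions
# on its boundary pixels.
#
# A boundary pixel pair (P1, P2) is "satisfying" when
#   (1) their gradient angles are opposed: |Gtheta1 - Gtheta2| is within
#       angle_tol_deg of 180 degrees (circular difference);
#   (2) Gtheta1 is aligned with the chord through P1 and P2, modulo 180
#       degrees (a chord is undirected while a gradient is directed);
#   (3) the chord passes within line_tol_px of the object centroid.
# The score is the fraction of boundary pixels belonging to at least one
# satisfying pair; each pixel counts once however many partners it has.

#' Tolerances for the circle-detection pair conditions
#'
#' The pair conditions are exact equalities in the idealised continuous
#' statement; on a discrete pixel grid they are measure-zero events, so
#' explicit tolerances are required.
#'
#' @param angle_tol_deg Angular tolerance in degrees, in `(0, 45]`
#'   (default 10).
#' @param line_tol_px Maximum perpendicular distance of the centroid from
#'   the chord, in pixels, `>= 0` (default 2).
#' @return A `pair_tolerances` object.
#' @export
pair_tolerances <- function(angle_tol_deg = 10, line_tol_px = 2) {
  stopifnot(is.numeric(angle_tol_deg), length(angle_tol_deg) == 1L,
            is.numeric(line_tol_px), length(line_tol_px) == 1L)
  if (angle_tol_deg <= 0 || angle_tol_deg > 45) {
    stop("`angle_tol_deg` must lie in (0, 45]")
  }
  if (line_tol_px < 0) stop("`line_tol_px` must be >= 0")
  structure(list(angle_tol_deg = angle_tol_deg, line_tol_px = line_tol_px),
            class = "pair_tolerances")
}

#' Pair condition 1: opposed gradient angles
#'
#' `TRUE` iff the circular difference `|Gtheta1 - Gtheta2|` is within
#' `angle_tol_deg` of 180 degrees. An undefined (`NA`) angle at either
#' pixel yields `FALSE`. Vectorized over the angle arguments.
#'
#' @param gtheta1,gtheta2 Gradient angles in degrees.
#' @param tol A [pair_tolerances()].
#' @return Logical.
#' @export
opposed_gradients <- function(gtheta1, gtheta2, tol = pair_tolerances()) {
  d <- circ_diff(gtheta1, gtheta2)
  ok <- abs(d - 180) <= tol$angle_tol_deg
  ok & !is.na(ok)
}

#' Pair condition 2: gradient aligned with the chord
#'
#' `TRUE` iff the gradient angle at `p1` matches the angle of the
#' (undirected) line through `p1` and `p2`, modulo 180 degrees, within
#' `angle_tol_deg`. `NA` gradient angle yields `FALSE`.
#'
#' @param p1,p2 Length-2 `(row, col)` positions, `p1 != p2`.
#' @param gtheta1 Gradient angle at `p1` in degrees.
#' @param tol A [pair_tolerances()].
#' @return Logical scalar.
#' @export
gradient_aligned_with_chord <- function(p1, p2, gtheta1,
                                        tol = pair_tolerances()) {
  if (all(p1 == p2)) stop("`p1` and `p2` must differ")
  if (is.na(gtheta1)) return(FALSE)
  chord <- (atan2(p2[1] - p1[1], p2[2] - p1[2]) * 180 / pi) %% 180
  circ_diff180(gtheta1, chord) <= tol$angle_tol_deg
}

#' Pair condition 3: chord passes through the centroid
#'
#' `TRUE` iff the perpendicular distance from the centroid to the infinite
#' line through `p1` and `p2` is at most `line_tol_px` (inclusive).
#'
#' @param p1,p2 Length-2 `(row, col)` positions, `p1 != p2`.
#' @param centroid Length-2 `(row, col)` centroid.
#' @param tol A [pair_tolerances()].
#' @return Logical scalar.
#' @export
chord_through_centroid <- function(p1, p2, centroid,
                                   tol = pair_tolerances()) {
  if (all(p1 == p2)) stop("`p1` and `p2` must differ")
  point_line_distance(centroid, p1, p2) <= tol$line_tol_px
}

point_line_distance <- function(pt, a, b) {
  d <- b - a
  abs(d[2] * (pt[1] - a[1]) - d[1] * (pt[2] - a[2])) / sqrt(sum(d^2))
}

#' Circle-likeness score of an aortic object
#'
#' For every boundary pixel, searches the remaining boundary pixels for a
#' partner such that all three pair conditions hold, and returns the
#' fraction of boundary pixels that belong to at least one satisfying
#' pair. The pair search is a full O(B^2) scan (aortic boundaries here
#' have at most a few hundred pixels).
#'
#' @param obj An [aorta_object()] with at least 8 boundary pixels.
#' @param field A [sobel_field()] of the host slice.
#' @param tol A [pair_tolerances()].
#' @return Score in `[0, 1]`.
#' @export
circle_score <- function(obj, field, tol = pair_tolerances()) {
  stopifnot(inherits(obj, "aorta_object"), inherits(field, "gradient_field"))
  b <- obj$boundary
  nb <- nrow(b)
  if (nb < 8L) stop("degenerate object: fewer than 8 boundary pixels")
  th <- field$gtheta[cbind(b[, 1] + 1L, b[, 2] + 1L)]
  r <- as.numeric(b[, 1]); c <- as.numeric(b[, 2])
  cr <- obj$centroid[["row"]]; cc <- obj$centroid[["col"]]

  # pairwise condition matrices (B x B); entry [i, j] tests P1 = i, P2 = j
  dth <- circ_diff(outer(th, th, "-") %% 360, 0)
  cond1 <- !is.na(dth) & abs(dth - 180) <= tol$angle_tol_deg

  dr <- outer(r, r, function(a, b) b - a)
  dc <- outer(c, c, function(a, b) b - a)
  chord <- (atan2(dr, dc) * 180 / pi) %% 180
  cond2 <- !is.na(th) & circ_diff180(matrix(th, nb, nb), chord) <= tol$angle_tol_deg

  # perpendicular distance from centroid to line through (i, j)
  num <- abs(dc * (cr - r) - dr * (cc - c))  # recycled by column i
  len <- sqrt(dr^2 + dc^2)
  cond3 <- num <= tol$line_tol_px * len      # avoids 0/0 on the diagonal

  sat <- cond1 & cond2 & cond3
  diag(sat) <- FALSE
  mean(rowSums(sat) > 0L)
}

#' Classify an aortic cross-section as circle-like or dissection candidate
#'
#' Applies [circle_score()] and compares against the decision threshold:
#' an object whose score reaches the threshold (inclusive) is labeled
#' `circle_like` (healthy in this respect), otherwise
#' `dissection_candidate`. The default threshold is 0.60, i.e. 60% of
#' boundary pixels must participate in a satisfying gradient pair.
#'
#' @inheritParams circle_score
#' @param threshold Decision threshold in `[0, 1]` (default 0.60).
#' @return A `circle_decision` with elements `score`, `threshold`, `label`.
#' @export
classify_shape <- function(obj, field, threshold = 0.60,
                           tol = pair_tolerances()) {
  circle_decision(circle_score(obj, field, tol), threshold)
}
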