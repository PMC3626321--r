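# Independent brute-force oracle for the circle-likeness score, plus small
# fixture builders. The oracle is coded scalar-wise, pair by pair, with no
# shared code with the package's vectorized implementation.

oracle_circle_score <- function(boundary, angles, centroid,
                                angle_tol = 10, line_tol = 2) {
  nb <- nrow(boundary)
  satisfied <- logical(nb)
  for (i in seq_len(nb)) {
    if (is.na(angles[i])) next
    for (j in seq_len(nb)) {
      if (j == i || is.na(angles[j])) next
      # (1) opposed gradient angles
      d1 <- abs(angles[i] - angles[j]) %% 360
      d1 <- min(d1, 360 - d1)
      if (abs(d1 - 180) > angle_tol) next
      # (2) gradient at P1 aligned with the undirected chord
      chord <- atan2(boundary[j, 1] - boundary[i, 1],
                     boundary[j, 2] - boundary[i, 2]) * 180 / pi
      d2 <- abs(angles[i] - chord) %% 180
      d2 <- min(d2, 180 - d2)
      if (d2 > angle_tol) next
      # (3) chord passes near the centroid
      vr <- boundary[j, 1] - boundary[i, 1]
      vc <- boundary[j, 2] - boundary[i, 2]
      dist <- abs(vc * (centroid[1] - boundary[i, 1]) -
                  vr * (centroid[2] - boundary[i, 2])) / sqrt(vr^2 + vc^2)
      if (dist > line_tol) next
      satisfied[i] <- TRUE
      break
    }
  }
  mean(satisfied)
}

# Gradient field with exact radial angles about `center` (pointing
# outward); magnitude 1 everywhere except the centre pixel (undefined).
ideal_radial_field <- function(shape, center) {
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2]) - center[1]
  c <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE) - center[2]
  len <- sqrt(r^2 + c^2)
  gx <- ifelse(len > 0, c / len, 0)
  gy <- ifelse(len > 0, r / len, 0)
  structure(list(gx = gx, gy = gy, gtheta = gradient_angle(gx, gy)),
            class = "gradient_field")
}

# Random connected blob (union of a few disks) rendered as a lumen-HU
# slice; returns the segmented object and its Sobel field. Boundary sizes
# stay well under 200 px for the oracle-equivalence checks.
random_blob_case <- function(shape = c(48L, 48L), n_disks = 3L) {
  base <- c(shape[1] / 2, shape[2] / 2)
  m <- matrix(FALSE, shape[1], shape[2])
  ctr <- base
  for (k in seq_len(n_disks)) {
    rad <- sample(4:8, 1)
    rr <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
    cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
    m <- m | ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2)
    ctr <- pmin(pmax(ctr + sample(-6:6, 2), 12), shape - 12)
  }
  px <- matrix(40, shape[1], shape[2])
  px[m] <- 350
  slice <- make_slice(px, 0L)
  objs <- label_components(threshold_lumen(slice), min_size = 20L)
  stopifnot(length(objs) >= 1L)
  obj <- objs[[which.max(vapply(objs, `[[`, integer(1), "n"))]]
  list(obj = obj, field = sobel_field(slice))
}

# Boundary angles of an object looked up in a gradient field (1-based
# indexing into the field arrays).
boundary_angles <- function(obj, field) {
  b <- obj$boundary
  field$gtheta[cbind(b[, 1] + 1L, b[, 2] + 1L)]
}
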