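test_that("pair_tolerances validates its ranges", {
  t <- pair_tolerances()
  expect_equal(c(t$angle_tol_deg, t$line_tol_px), c(10, 2))
  expect_error(pair_tolerances(angle_tol_deg = 0))
  expect_error(pair_tolerances(angle_tol_deg = 50))
  expect_error(pair_tolerances(line_tol_px = -1))
})

test_that("opposed_gradients uses circular difference about 180 degrees", {
  tol <- pair_tolerances(angle_tol_deg = 10)
  expect_true(opposed_gradients(10, 190, tol))
  expect_true(opposed_gradients(10, 185, tol))   # difference 175
  expect_false(opposed_gradients(10, 100, tol))  # orthogonal
  expect_true(opposed_gradients(355, 170, tol))  # wraps through 0
  expect_false(opposed_gradients(NA, 190, tol))
  expect_false(opposed_gradients(10, NA, tol))
})

test_that("gradient_aligned_with_chord treats the chord as undirected", {
  tol <- pair_tolerances(angle_tol_deg = 10)
  expect_true(gradient_aligned_with_chord(c(0, 0), c(0, 10), 0, tol))
  expect_false(gradient_aligned_with_chord(c(0, 0), c(10, 0), 0, tol))
  expect_true(gradient_aligned_with_chord(c(0, 0), c(7, 7), 45, tol))
  # reversed gradient polarity still aligns (modulo 180)
  expect_true(gradient_aligned_with_chord(c(0, 0), c(0, 10), 180, tol))
  expect_false(gradient_aligned_with_chord(c(0, 0), c(0, 10), NA, tol))
  expect_error(gradient_aligned_with_chord(c(1, 1), c(1, 1), 0, tol))
})

test_that("chord_through_centroid uses inclusive perpendicular distance", {
  tol <- pair_tolerances(line_tol_px = 1)
  expect_true(chord_through_centroid(c(0, 5), c(10, 5), c(5, 5), tol))
  expect_false(chord_through_centroid(c(0, 0), c(0, 10), c(5, 5), tol))
  # centroid exactly tol away: inclusive
  expect_true(chord_through_centroid(c(0, 0), c(0, 10), c(1, 5), tol))
  expect_error(chord_through_centroid(c(2, 2), c(2, 2), c(0, 0), tol))
})

test_that("circle_score is high on a disk with an ideal radial field", {
  spec <- phantom_spec(noise_sd = 0)
  h <- make_healthy_slice(spec, 0)
  obj <- label_components(threshold_lumen(h$slice))[[1]]
  f <- ideal_radial_field(spec$shape, spec$vessel$center)
  sc <- circle_score(obj, f)
  expect_gte(sc, 0.9)
  # and the independent oracle agrees exactly
  expect_equal(sc, oracle_circle_score(obj$boundary,
                                       boundary_angles(obj, f),
                                       obj$centroid))
})

test_that("a flat edge (all gradient angles equal) scores zero", {
  sq <- as.matrix(expand.grid(row = 2:11, col = 2:11))
  obj <- aorta_object(sq)
  f <- structure(list(gx = matrix(1, 20, 20), gy = matrix(0, 20, 20),
                      gtheta = matrix(0, 20, 20)),
                 class = "gradient_field")
  expect_equal(circle_score(obj, f), 0)
})

test_that("degenerate objects with fewer than 8 boundary pixels error", {
  obj <- aorta_object(rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)))
  f <- structure(list(gx = matrix(1, 5, 5), gy = matrix(0, 5, 5),
                      gtheta = matrix(0, 5, 5)), class = "gradient_field")
  expect_error(circle_score(obj, f), "degenerate")
})

test_that("circle_score matches the brute-force oracle on random blobs", {
  set.seed(31)
  for (k in 1:8) {
    case <- random_blob_case()
    expect_lte(nrow(case$obj$boundary), 200)
    sc <- circle_score(case$obj, case$field)
    expect_equal(sc, oracle_circle_score(case$obj$boundary,
                                         boundary_angles(case$obj, case$field),
                                         case$obj$centroid))
  }
})

test_that("score is invariant under translation and 90-degree rotation", {
  spec <- phantom_spec(noise_sd = 0)
  h <- make_healthy_slice(spec, 0)
  obj <- label_components(threshold_lumen(h$slice))[[1]]
  sc <- circle_score(obj, sobel_field(h$slice))

  spec_t <- phantom_spec(noise_sd = 0,
                         vessel = list(center = c(50, 78), radius = 20,
                                       drift = c(0, 0)))
  ht <- make_healthy_slice(spec_t, 0)
  objt <- label_components(threshold_lumen(ht$slice))[[1]]
  expect_equal(circle_score(objt, sobel_field(ht$slice)), sc)

  # 90-degree rotation of the pixel grid
  pr <- t(h$slice$pixels[nrow(h$slice$pixels):1, ])
  sr <- make_slice(pr, 0)
  objr <- label_components(threshold_lumen(sr))[[1]]
  expect_equal(circle_score(objr, sobel_field(sr)), sc)
})

test_that("classify_shape thresholds inclusively at 0.60", {
  # synthetic decisions around the threshold
  d1 <- aortacad:::circle_decision(0.95, 0.60)
  expect_identical(d1$label, "circle_like")
  d2 <- aortacad:::circle_decision(0.30, 0.60)
  expect_identical(d2$label, "dissection_candidate")
  d3 <- aortacad:::circle_decision(0.60, 0.60)
  expect_identical(d3$label, "circle_like")   # "reaches" is inclusive

  # end to end: disk healthy, 3:1 ellipse candidate
  spec <- phantom_spec(noise_sd = 0)
  h <- make_healthy_slice(spec, 0)
  obj <- label_components(threshold_lumen(h$slice))[[1]]
  expect_identical(classify_shape(obj, sobel_field(h$slice))$label,
                   "circle_like")
  e <- make_dissection_slice(spec, 0, kind = "ellipse", axis_ratio = 3)
  oe <- label_components(threshold_lumen(e$slice))[[1]]
  expect_identical(classify_shape(oe, sobel_field(e$slice))$label,
                   "dissection_candidate")
})
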