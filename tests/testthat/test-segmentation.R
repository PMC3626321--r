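test_that("threshold_lumen is inclusive at both bounds", {
  s <- make_slice(matrix(c(150, 200, 500, 501), 2, 2), 0)
  m <- threshold_lumen(s, hu_range(200, 500))
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(threshold_lumen(make_slice(matrix(300, 4, 4), 0))))
  expect_false(any(threshold_lumen(make_slice(matrix(100, 4, 4), 0))))
})

test_that("label_components applies 8-connectivity and the size filter", {
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:11] <- TRUE        # 100 px blob
  m[25:34, 25:34] <- TRUE      # second 100 px blob
  expect_length(label_components(m, min_size = 50), 2)

  m2 <- matrix(FALSE, 20, 20)
  m2[3, 3:12] <- TRUE          # 10 px blob
  expect_length(label_components(m2, min_size = 50), 0)

  # diagonal-touching pixels form one component under 8-connectivity
  m3 <- matrix(FALSE, 5, 5)
  m3[2, 2] <- TRUE; m3[3, 3] <- TRUE
  cand <- label_components(m3, min_size = 1)
  expect_length(cand, 1)
  expect_identical(cand[[1]]$n, 2L)
})

test_that("select_aorta picks the nearest candidate within the limit", {
  mk <- function(center) {
    aorta_object(as.matrix(expand.grid(row = center[1] + (-2:2),
                                       col = center[2] + (-2:2))))
  }
  prev <- mk(c(50, 50))
  near <- mk(c(53, 50))   # 3 px away
  far <- mk(c(90, 50))    # 40 px away
  expect_identical(select_aorta(list(far, near), prev)$centroid,
                   near$centroid)
  expect_null(select_aorta(list(far), prev, continuity_limit_px = 20))
  expect_null(select_aorta(list(), prev))
  # seed on a candidate selects it
  sd <- seed_point(c(53, 50))
  expect_identical(select_aorta(list(near, far), sd)$centroid, near$centroid)
})

test_that("segment_series tracks stationary, drifting and vanishing disks", {
  # stationary disk over 10 slices
  spec <- phantom_spec(n_slices = 10, noise_sd = 0)
  study <- make_phantom_study(spec)
  sd <- seed_point(spec$vessel$center, "descending")
  tr <- segment_series(study$slices, hu_range(), list(sd))[[1]]
  expect_length(tr$objects, 10)
  expect_length(tr$gaps, 0)
  expect_true(all(vapply(tr$objects, `[[`, character(1), "anatomy_label")
                  == "descending"))

  # drift 2 px/slice stays under the 20 px continuity limit
  spec2 <- phantom_spec(n_slices = 10, noise_sd = 0,
                        vessel = list(center = c(40, 40), radius = 15,
                                      drift = c(2, 2)))
  study2 <- make_phantom_study(spec2)
  tr2 <- segment_series(study2$slices, hu_range(),
                        list(seed_point(c(40, 40))))[[1]]
  expect_length(tr2$objects, 10)
  expect_length(tr2$gaps, 0)
  # the tracked centroid follows the drift
  last <- tr2$objects[[10]]$centroid
  expect_equal(unname(last), c(40 + 9 * 2, 40 + 9 * 2), tolerance = 0.1)

  # disk missing on two slices is reported as two gaps
  spec3 <- phantom_spec(n_slices = 6, noise_sd = 0)
  study3 <- make_phantom_study(spec3)
  blank <- make_slice(matrix(40, 128, 128), 2L)
  study3$slices[[3]] <- blank
  study3$slices[[5]] <- make_slice(matrix(40, 128, 128), 4L)
  tr3 <- segment_series(study3$slices, hu_range(),
                        list(seed_point(spec3$vessel$center)))[[1]]
  expect_length(tr3$objects, 4)
  expect_identical(tr3$gaps, c(2L, 4L))

  expect_error(
    segment_series(study$slices, hu_range(),
                   list(seed_point(c(500, 500)))),
    "outside image")
})

test_that("segmented object pixels all lie within the HU range", {
  spec <- phantom_spec(noise_sd = 10, seed = 7)
  h <- make_healthy_slice(spec, 0)
  rng <- hu_range()
  obj <- label_components(threshold_lumen(h$slice, rng))[[1]]
  vals <- h$slice$pixels[cbind(obj$pixel_coords[, 1] + 1L,
                               obj$pixel_coords[, 2] + 1L)]
  expect_true(all(vals >= rng$lower & vals <= rng$upper))
})

test_that("segmentation is deterministic and exact on noise-free phantoms", {
  spec <- phantom_spec(noise_sd = 0)
  h <- make_healthy_slice(spec, 0)
  m <- threshold_lumen(h$slice)
  expect_identical(m, h$truth_mask)
  o1 <- label_components(m)
  o2 <- label_components(threshold_lumen(make_healthy_slice(spec, 0)$slice))
  expect_identical(o1, o2)
  # recovered pixel set equals the rasterized disk exactly
  expect_identical(coords_to_mask(o1[[1]]$pixel_coords, spec$shape),
                   h$truth_mask)
})
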