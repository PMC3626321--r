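test_that("phantom generation is deterministic for a fixed seed", {
  spec <- phantom_spec(noise_sd = 10, seed = 42)
  a <- make_healthy_slice(spec, 3)
  b <- make_healthy_slice(spec, 3)
  expect_identical(a$slice$pixels, b$slice$pixels)
  # different slices of the stack get independent noise
  c <- make_healthy_slice(spec, 4)
  expect_false(identical(a$slice$pixels, c$slice$pixels))
  # and a different seed changes the noise
  spec2 <- phantom_spec(noise_sd = 10, seed = 43)
  expect_false(identical(make_healthy_slice(spec2, 3)$slice$pixels,
                         a$slice$pixels))
})

test_that("class separation holds under noise at the 3-sigma level", {
  spec <- phantom_spec(noise_sd = 10, seed = 9)
  h <- make_healthy_slice(spec, 0)
  rng <- hu_range()
  in_range <- h$slice$pixels >= rng$lower & h$slice$pixels <= rng$upper
  expect_gte(mean(in_range[h$truth_mask]), 0.99)
  expect_lte(mean(in_range[!h$truth_mask]), 0.01)
  # spec constructor refuses settings that break the 3-sigma margins
  expect_error(phantom_spec(noise_sd = 60), "3 sd")
  expect_error(phantom_spec(lumen_hu = 210, noise_sd = 10), "3 sd")
  expect_error(phantom_spec(background_hu = 180, noise_sd = 10), "3 sd")
  expect_error(phantom_spec(pau_hu = 520, noise_sd = 10), "3 sd")
})

test_that("vessel must fit inside the image over the whole stack", {
  expect_error(phantom_spec(vessel = list(center = c(10, 64), radius = 20,
                                          drift = c(0, 0))), "fit")
  expect_error(phantom_spec(n_slices = 30,
                            vessel = list(center = c(64, 64), radius = 20,
                                          drift = c(2, 0))), "fit")
})

test_that("a flap of width zero degenerates to the healthy slice", {
  spec <- phantom_spec(noise_sd = 0)
  h <- make_healthy_slice(spec, 0)
  d0 <- make_dissection_slice(spec, 0, kind = "flap", flap_width_px = 0)
  expect_identical(d0$slice$pixels, h$slice$pixels)
  expect_identical(d0$truth_label, "healthy")
  d4 <- make_dissection_slice(spec, 0, kind = "flap", flap_width_px = 4)
  expect_identical(d4$truth_label, "dissection")
  expect_lt(sum(d4$truth_mask), sum(h$truth_mask))
})

test_that("pau blobs are carved from the lumen and sit inside the wall", {
  spec <- phantom_spec(noise_sd = 0)
  p <- make_pau_slice(spec, 0, blobs = list(list(angle_deg = 90, radius = 2)))
  blob <- p$truth_blobs[[1]]
  # blob pixels are at pau HU (strictly above the window)
  idx <- cbind(blob[, 1] + 1L, blob[, 2] + 1L)
  expect_true(all(p$slice$pixels[idx] == spec$pau_hu))
  # blob pixels are not part of the lumen truth mask
  expect_false(any(p$truth_mask[idx]))
  # blob lies strictly inside the disk (near the wall but not on it)
  ctr <- spec$vessel$center
  d <- sqrt((blob[, 1] - ctr[1])^2 + (blob[, 2] - ctr[2])^2)
  expect_true(all(d < spec$vessel$radius))
  expect_gt(max(d), spec$vessel$radius - 6)   # adjacent to the wall
})

test_that("make_phantom_study assembles slices and a truth table", {
  spec <- phantom_spec(n_slices = 6, noise_sd = 0)
  labels <- c("healthy", "healthy", "dissection", "healthy", "pau", "pau")
  study <- make_phantom_study(spec, labels)
  expect_length(study$slices, 6)
  expect_identical(study$truth$truth_label, labels)
  expect_identical(study$truth$n_truth_blobs, c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_identical(vapply(study$slices, `[[`, integer(1), "slice_index"),
                   0:5)
})

test_that("phantom directories round-trip through write and read", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(n_slices = 3, noise_sd = 10, seed = 2)
  study <- make_phantom_study(spec)
  write_phantom_dir(study, dir)
  back <- read_slice_dir(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$pixels, study$slices[[i]]$pixels)
    expect_identical(back[[i]]$slice_index, study$slices[[i]]$slice_index)
  }
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_identical(truth$slice_index, study$truth$slice_index)
  expect_error(read_slice_dir(file.path(dir, "nope")), "no slice")
})
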