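test_that("write_cine / read_cine round-trips volumes, labels and sidecar", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  write_cine(ph$series, dir, labels = ph$labels)
  back <- read_cine(dir)

  expect_equal(n_frames(back$series), n_frames(ph$series))
  expect_equal(back$series$ed_index, ph$series$ed_index)
  expect_equal(back$series$es_index, ph$series$es_index)
  expect_equal(back$series$spacing_mm, ph$series$spacing_mm)
  # float volumes within tolerance, integer labels bit-identical
  expect_equal(back$series$frames[[1]], ph$series$frames[[1]],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(as.integer(back$labels[[3]]), as.integer(ph$labels[[3]]))
})

test_that("read_cine refuses to guess ED/ES and validates shapes", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  write_cine(ph$series, dir)
  file.remove(file.path(dir, "sidecar.yaml"))
  expect_error(read_cine(dir), "ed_index")

  # corrupt one frame's shape
  bad <- array(0, c(4, 4, 4))
  RNifti::writeNifti(RNifti::asNifti(bad), file.path(dir, "frame_02.nii.gz"))
  expect_error(read_cine(dir, sidecar = list(ed_index = 0, es_index = 3)),
               "inconsistent")
})

test_that("a 4D NIfTI file reads back as a full series", {
  ph <- small_phantom()
  arr <- array(0, c(16, 16, 16, 4))
  for (t in 1:4) arr[, , , t] <- ph$series$frames[[t]]
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(1, 1, 1, 1)), f)
  back <- read_cine(f, sidecar = list(ed_index = 0, es_index = 2))
  expect_equal(n_frames(back$series), 4)
  expect_equal(back$series$frames[[2]], ph$series$frames[[2]],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("crop_series applies one box to every frame and label", {
  ph <- small_phantom()
  box <- bounding_box(c(2, 2, 2), c(14, 14, 14))
  out <- crop_series(ph$series, box, labels = ph$labels)
  expect_equal(dim(out$series$frames[[1]]), c(12, 12, 12))
  expect_equal(length(out$series$frames), n_frames(ph$series))
  expect_equal(out$series$spacing_mm, ph$series$spacing_mm)
  # label values are untouched, just windowed
  expect_identical(out$labels[[1]], ph$labels[[1]][3:14, 3:14, 3:14])

  # identity box
  full <- crop_series(ph$series, bounding_box(c(0, 0, 0), c(16, 16, 16)))
  expect_identical(full$frames, ph$series$frames)

  expect_error(bounding_box(c(2, 2, 2), c(2, 14, 14)), "positive extent")
  expect_error(crop_series(ph$series, bounding_box(c(0, 0, 0), c(20, 16, 16))),
               "exceeds")
})

test_that("normalize_intensity maps lung/blood anchors to exactly 0 and 1", {
  ph <- small_phantom()
  norm <- normalize_intensity(ph$series)
  for (t in c(1, 5)) {
    q <- quantile(norm$frames[[t]], c(0.05, 0.95), names = FALSE)
    expect_equal(q[1], 0, tolerance = 1e-12)
    expect_equal(q[2], 1, tolerance = 1e-12)
  }
  # linear map: a voxel halfway between the anchors lands at 0.5
  f <- ph$series$frames[[1]]
  q <- quantile(f, c(0.05, 0.95), names = FALSE)
  mid <- (q[1] + q[2]) / 2
  i <- which.min(abs(f - mid))
  expect_equal(norm$frames[[1]][i], (f[i] - q[1]) / (q[2] - q[1]))

  # idempotent once anchors are 0/1
  twice <- normalize_intensity(norm)
  expect_equal(twice$frames[[1]], norm$frames[[1]], tolerance = 1e-10)
})

test_that("normalization recovers the anchors of a two-Gaussian mixture", {
  # lung-like and blood-like intensity populations
  set.seed(21)
  n <- 10000
  vals <- c(rnorm(0.9 * n, 60, 10), rnorm(0.1 * n, 480, 20))
  dims <- c(20, 25, 20)
  series <- cine_series(list(array(vals, dims), array(vals, dims)),
                        c(1, 1, 1), ed_index = 0, es_index = 1)
  norm <- normalize_intensity(series)
  q <- quantile(norm$frames[[1]], c(0.05, 0.95), names = FALSE)
  expect_equal(q, c(0, 1), tolerance = 1e-12)

  # constant frame has coincident anchors
  flat <- cine_series(list(array(7, c(4, 4, 4)), array(7, c(4, 4, 4))),
                      c(1, 1, 1), 0, 1)
  expect_error(normalize_intensity(flat), "degenerate")
})

test_that("crop commutes with in-box normalization", {
  ph <- small_phantom()
  box <- bounding_box(c(1, 1, 1), c(15, 15, 15))
  a <- normalize_intensity(crop_series(ph$series, box))
  b <- crop_series(normalize_intensity(ph$series), box)
  # not identical in general (different percentile pools), but cropping the
  # normalized series then re-normalizing equals normalizing the crop
  b2 <- normalize_intensity(b)
  expect_equal(a$frames[[1]], b2$frames[[1]], tolerance = 1e-10)
})

test_that("cine_series enforces its invariants", {
  f <- list(array(0:7, c(2, 2, 2)), array(0:7, c(2, 2, 2)))
  expect_error(cine_series(f, c(1, 1, 1), 0, 0), "differ")
  expect_error(cine_series(f, c(1, 1, 1), 0, 5), "range")
  expect_error(cine_series(list(f[[1]]), c(1, 1, 1), 0, 1))
  expect_error(cine_series(list(f[[1]], array(0, c(3, 2, 2))),
                           c(1, 1, 1), 0, 1), "identical shape")
})
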