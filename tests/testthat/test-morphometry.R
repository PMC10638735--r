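make_stack <- function(labels, thickness = 0.4, pixel = 0.0234,
                       map = c(ABDH = 1L)) {
  segmented_stack(labels, thickness, pixel, map)
}

test_that("ACSA is labelled pixel count times squared pixel size", {
  labels <- array(0L, dim = c(3, 20, 20))
  labels[1, 1:10, 1:10] <- 1L # 100 pixels
  stack <- make_stack(labels)
  acsa <- extract_acsa(stack)
  expect_equal(acsa$acsa_cm2[acsa$slice_index == 0], 100 * 0.0234^2)
  expect_equal(acsa$acsa_cm2[acsa$slice_index == 1], 0) # empty slice -> 0
  expect_equal(nrow(acsa), 3) # every slice recorded for every mapped muscle
})

test_that("unmapped positive labels are rejected by name", {
  labels <- array(0L, dim = c(2, 4, 4))
  labels[1, 1, 1] <- 7L
  expect_error(make_stack(labels), "7")
})

test_that("volume sums ACSAs times slice thickness", {
  acsa <- data.frame(slice_index = c(0, 1), muscle = "ABDH",
                     acsa_cm2 = c(3, 3))
  expect_equal(compute_volume(acsa, "ABDH", 0.4), 2.4)
  one <- data.frame(slice_index = 0, muscle = "QP", acsa_cm2 = 5)
  expect_equal(compute_volume(one, "QP", 0.35), 1.75)
  expect_error(compute_volume(acsa, "QP", 0.4), "no positive ACSA")
})

test_that("volume is additive over slice partitions and order-invariant", {
  set.seed(3)
  acsa <- data.frame(slice_index = 0:9, muscle = "FDB",
                     acsa_cm2 = runif(10, 0, 4))
  v <- compute_volume(acsa, "FDB", 0.35)
  shuffled <- acsa[sample(10), ]
  expect_equal(compute_volume(shuffled, "FDB", 0.35), v)
  top <- acsa[1:4, ]; bottom <- acsa[5:10, ]
  expect_equal(compute_volume(top, "FDB", 0.35) +
                 compute_volume(bottom, "FDB", 0.35), v)
})

test_that("length is the inclusive visible-slice span times thickness", {
  acsa <- data.frame(slice_index = c(5, 10:41, 50), muscle = "ABDH",
                     acsa_cm2 = c(0, rep(1, 32), 0))
  expect_equal(compute_length(acsa, "ABDH", 0.35), 32 * 0.35)
  single <- data.frame(slice_index = 3, muscle = "ABDH", acsa_cm2 = 2)
  expect_equal(compute_length(single, "ABDH", 0.4), 0.4)
  none <- data.frame(slice_index = 1, muscle = "ABDH", acsa_cm2 = 0)
  expect_error(compute_length(none, "ABDH", 0.4), "not visible")
})

test_that("length grows monotonically as visibility extends", {
  for (span in 1:6) {
    acsa <- data.frame(slice_index = seq_len(span) - 1, muscle = "QP",
                       acsa_cm2 = 1)
    expect_equal(compute_length(acsa, "QP", 0.4), span * 0.4)
  }
})

test_that("transverse-head length uses the in-plane medial-lateral extent", {
  labels <- array(0L, dim = c(3, 10, 256))
  labels[1, 4, 101:220] <- 1L # columns 101..220 -> 120-pixel span
  labels[2, 5, 150:180] <- 1L
  stack <- segmented_stack(labels, 0.4, 0.0234, c(ADDH_TH = 1L))
  acsa <- extract_acsa(stack)
  expect_equal(compute_length(acsa, "ADDH_TH", 0.4, stack = stack),
               120 * 0.0234)
  # without the stack the in-plane rule cannot be applied
  expect_error(compute_length(acsa, "ADDH_TH", 0.4), "stack")
  # the same table under the slice rule would give a very different answer
  expect_equal(compute_length(acsa, "ADDH_TH", 0.4, in_plane = FALSE),
               2 * 0.4)
})

test_that("voxelized cylinders reproduce analytic volume and length", {
  geom <- data.frame(muscle = c("ABDH", "QP"),
                     center_row_cm = c(1.6, 4.2), center_col_cm = c(1.6, 4.2),
                     radius_row_cm = c(1.0, 0.9), radius_col_cm = c(0.5, 0.9),
                     first_slice = c(2L, 0L), n_slices = c(20L, 29L))
  phantom <- generate_label_stack(geom, n_slices = 30, grid_cm = 6,
                                  slice_thickness_cm = 0.35,
                                  in_plane_pixel_cm = 0.05)
  morpho <- compute_morphometry(phantom$stack)
  for (m in geom$muscle) {
    got <- morpho[morpho$muscle == m, ]
    want <- phantom$truth[phantom$truth$muscle == m, ]
    expect_lt(abs(got$volume_cm3 - want$volume_cm3) / want$volume_cm3, 0.02)
    expect_lte(abs(got$length_cm - want$length_cm), 0.35)
  }
  # circle of radius 1 -> per-slice ACSA ~ pi within 2%
  acsa <- extract_acsa(phantom$stack)
  mid <- acsa$acsa_cm2[acsa$muscle == "ABDH" & acsa$slice_index == 10]
  expect_lt(abs(mid - pi * 1.0 * 0.5) / (pi * 0.5), 0.02)
})

test_that("NIfTI label volumes round-trip with cm geometry", {
  arr <- array(0L, dim = c(16, 16, 6))
  arr[4:9, 4:9, 2:4] <- 1L
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(2.34, 2.34, 3.5)) # mm
  tmp <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, tmp)
  stack <- read_label_stack(tmp, c(FHB = 1L), slice_axis = 3)
  expect_s3_class(stack, "pifm_stack")
  # header pixdims are float32; compare at single precision
  expect_equal(stack$slice_thickness_cm, 0.35, tolerance = 1e-6)
  expect_equal(stack$in_plane_pixel_cm, 0.234, tolerance = 1e-6)
  acsa <- extract_acsa(stack)
  expect_equal(compute_length(acsa, "FHB", stack$slice_thickness_cm),
               3 * 0.35, tolerance = 1e-6)
  expect_equal(compute_volume(acsa, "FHB", stack$slice_thickness_cm),
               36 * 0.234^2 * 3 * 0.35, tolerance = 1e-6)
})

test_that("non-integer NIfTI volumes are rejected", {
  arr <- array(0, dim = c(4, 4, 3))
  arr[1, 1, 1] <- 0.5
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 4))
  tmp <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, tmp)
  expect_error(read_label_stack(tmp, c(ABDH = 1L)), "non-integer")
})

test_that("the ACSA CSV route loads validated tables", {
  tab <- data.frame(participant = "P01", slice_index = 0:2,
                    muscle = "ABDM", acsa_cm2 = c(1.5, 2.0, 0.5))
  tmp <- tempfile(fileext = ".csv")
  write.csv(tab, tmp, row.names = FALSE)
  got <- read_acsa_csv(tmp)
  expect_equal(compute_volume(got, "ABDM", 0.4), 4 * 0.4)
  bad <- tab
  bad$acsa_cm2[1] <- -1
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_acsa_csv(tmp), "non-negative")
})
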