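test_that("air threshold includes the boundary and morphology cleans speckle", {
  cfg <- preprocess_config()
  ct <- volume3d(array(0, c(20, 20, 20)), c(1, 1, 1))
  ct$values[5, 5, 5] <- -500
  ct$values[6, 5, 5] <- -400    # boundary value counts as air
  ct$values[7, 5, 5] <- -300
  raw <- segment_air(ct, cfg, morphology = FALSE)
  expect_equal(raw[5, 5, 5], 1L)
  expect_equal(raw[6, 5, 5], 1L)
  expect_equal(raw[7, 5, 5], 0L)
  # all-soft-tissue volume -> empty mask
  expect_equal(sum(segment_air(volume3d(array(0, c(10, 10, 10)),
                                        c(1, 1, 1)), cfg)), 0)
  # a single isolated air voxel cannot survive a 7-iteration opening
  expect_equal(sum(segment_air(ct, cfg)), 0)
})

test_that("closing/opening equal brute-force dilation-erosion composition", {
  cfg <- preprocess_config()
  set.seed(21)
  for (rep in 1:3) {
    m <- array(as.integer(runif(20^3) < 0.45), c(20, 20, 20))
    expect_identical(mediastinet:::binary_closing(m, cfg$closing_iters),
                     oracle_morph(oracle_morph(m, 2, TRUE), 2, FALSE))
    expect_identical(mediastinet:::binary_opening(m, 3),
                     oracle_morph(oracle_morph(m, 3, FALSE), 3, TRUE))
  }
})

test_that("border components are removed by x/y margin only", {
  d <- c(60, 60, 30)
  m <- array(0L, d)
  m[1:3, 30:32, 10:12] <- 1L              # touches x border -> deleted
  m[30:32, 30:32, 1:3] <- 1L              # touches z border only -> kept
  m[28:31, 28:31, 14:16] <- 1L            # interior -> kept
  m[26, 26, 26] <- 1L                     # 0-based index 25 == margin -> kept
  out <- remove_border_components(m, 25)
  expect_equal(sum(out[1:3, , ]), 0)
  expect_equal(sum(out[30:32, 30:32, 1:3]), 27)
  expect_equal(out[26, 26, 26], 1L)
  # oracle: a component is deleted iff its minimum border distance < margin
  set.seed(31)
  mm <- array(0L, c(40, 40, 20))
  for (b in 1:6) {
    at <- c(sample(3:38, 2), sample(3:18, 1))
    mm[at[1] + (-1:1), at[2] + (-1:1), at[3] + (-1:1)] <- 1L
  }
  margin <- 10L
  lab <- oracle_components(mm)
  keep_oracle <- array(0L, dim(mm))
  for (l in seq_len(attr(lab, "n_components"))) {
    vox <- arrayInd(which(lab == l), dim(mm))
    bd <- min(vox[, 1] - 1, vox[, 2] - 1,
              dim(mm)[1] - vox[, 1], dim(mm)[2] - vox[, 2])
    if (bd >= margin) keep_oracle[lab == l] <- 1L
  }
  expect_identical(remove_border_components(mm, margin), keep_oracle)
})

test_that("largest air component is selected with scan-order tie-break", {
  m <- array(0L, c(30, 30, 10))
  m[2:11, 2:11, 2:4] <- 1L    # 300 voxels
  m[20:23, 20:23, 2:6] <- 1L  # 80 voxels
  out <- select_lungs(m)
  expect_equal(sum(out), 300)
  expect_equal(sum(out[2:11, 2:11, 2:4]), 300)
  # exact size tie: the component met first in scan order wins
  t2 <- array(0L, c(20, 20, 6))
  t2[2:4, 2:4, 2:4] <- 1L
  t2[10:12, 10:12, 2:4] <- 1L
  sel <- select_lungs(t2)
  expect_equal(sum(sel), 27)
  expect_equal(sel[2, 2, 2], 1L)
  expect_equal(sel[10, 10, 2], 0L)
  expect_error(select_lungs(array(0L, c(5, 5, 5))), "segmentation failure")
})

test_that("thorax crop keeps the lung z-range and centres the xy window", {
  mk_scan <- function(d) {
    list(patient_id = "p", nodes = empty_nodes(),
         ct = volume3d(array(100, d), c(1, 1, 1)),
         pet = volume3d(array(1, d), c(1, 1, 1), modality = "PET_SUV"))
  }
  d <- c(300L, 300L, 200L)
  lungs <- array(0L, d)
  lungs[140:160, 140:160, 40:160] <- 1L
  crop <- crop_thorax(mk_scan(d), lungs)
  expect_equal(dim(crop$ct$values), c(256L, 256L, 121L))
  expect_equal(crop$z_range, c(40L, 160L))
  expect_equal(crop$xy_offset, c(22L, 22L))
  expect_equal(crop$ct$origin, c(22, 22, 39))

  # smaller slices are padded symmetrically with air-equivalent values
  d2 <- c(200L, 200L, 60L)
  lungs2 <- array(0L, d2)
  lungs2[90:110, 90:110, 10:50] <- 1L
  crop2 <- crop_thorax(mk_scan(d2), lungs2)
  expect_equal(dim(crop2$ct$values), c(256L, 256L, 41L))
  expect_equal(crop2$xy_offset, c(-28L, -28L))
  expect_equal(crop2$ct$values[1, 1, 1], -1000)
  expect_equal(crop2$pet$values[1, 1, 1], 0)
  expect_equal(crop2$ct$values[29, 29, 1], 100)

  expect_error(crop_thorax(mk_scan(d), array(0L, d)),
               "segmentation failure")
})

test_that("intensity clipping applies the published bounds", {
  crop <- make_test_crop(c(8, 8, 4))
  crop$ct$values[1:4] <- c(1500, -1500, 350, -400)
  crop$pet$values[1:4] <- c(10, 7.9, 0, 3)
  out <- clip_intensities(crop)
  expect_equal(out$ct$values[1:4], c(1000, -1000, 350, -400))
  expect_equal(out$pet$values[1:4], c(8, 7.9, 0, 3))
})

test_that("dataset-level standardisation pools training voxels and inverts", {
  c1 <- make_test_crop(c(6, 6, 4), seed = 1)
  c2 <- make_test_crop(c(6, 6, 4), seed = 2)
  c1$ct$values[] <- 0; c2$ct$values[] <- 2
  c1$pet$values[] <- 1; c2$pet$values[] <- 3
  expect_error(fit_normalization(list(c1)), "degenerate")
  st <- fit_normalization(list(c1, c2))
  expect_equal(st$ct_mean, 1)
  expect_equal(st$pet_mean, 2)

  set.seed(8)
  crops <- list(make_test_crop(c(10, 10, 6), seed = 3),
                make_test_crop(c(10, 10, 6), seed = 4))
  st2 <- fit_normalization(crops)
  normed <- lapply(crops, apply_normalization, stats = st2)
  pooled_ct <- unlist(lapply(normed, function(cr) cr$ct$values))
  expect_equal(mean(pooled_ct), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean((pooled_ct - mean(pooled_ct))^2)), 1,
               tolerance = 1e-6)
  # affine and order preserving: differences scale by 1/sd
  delta <- crops[[2]]$ct$values[1] - crops[[1]]$ct$values[1]
  expect_equal(normed[[2]]$ct$values[1] - normed[[1]]$ct$values[1],
               delta / st2$ct_sd)
  # exact inverse round trip
  back <- apply_normalization(normed[[1]], st2, invert = TRUE)
  expect_equal(back$ct$values, crops[[1]]$ct$values, tolerance = 1e-9)
  expect_error(apply_normalization(crops[[1]], NULL), "missing")
})

test_that("normalization stats survive a JSON round trip", {
  st <- structure(list(ct_mean = -312.5, ct_sd = 481.25, pet_mean = 0.82,
                       pet_sd = 1.13, fitted_on = "train"),
                  class = "norm_stats")
  f <- tempfile(fileext = ".json")
  write_normalization(st, f)
  expect_equal(read_normalization(f)[1:4], unclass(st)[1:4])
})
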