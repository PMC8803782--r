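test_that("NIfTI round trip preserves values and physical metadata", {
  set.seed(11)
  vol <- volume3d(array(rnorm(10 * 10 * 10), c(10, 10, 10)),
                  spacing = c(2, 1, 1), origin = c(3.5, -2, 10),
                  modality = "CT_HU")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, "CT_HU")
  expect_equal(back$values, vol$values)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)
})

test_that("voxel/physical coordinate round trip is the identity", {
  vol <- volume3d(array(0, c(7, 9, 11)), spacing = c(0.58, 1.05, 2.8),
                  origin = c(-10, 4, 2))
  set.seed(2)
  idx <- cbind(sample(7, 20, TRUE), sample(9, 20, TRUE),
               sample(11, 20, TRUE))
  mm <- voxel_to_physical(vol, idx)
  expect_equal(physical_to_voxel(vol, mm), idx, ignore_attr = TRUE)
  # any point within half a voxel of a centre maps back to it
  jitter <- mm + sweep(matrix(runif(60, -0.49, 0.49), ncol = 3), 2,
                       vol$spacing, "*")
  expect_equal(physical_to_voxel(vol, jitter), idx, ignore_attr = TRUE)
})

test_that("volume3d rejects invalid geometry", {
  expect_error(volume3d(array(0, c(4, 4, 4)), spacing = c(0, 1, 1)),
               "spacing")
  expect_error(volume3d(matrix(0, 3, 3), c(1, 1, 1)), "3D")
})

test_that("DICOM series reads with slices ordered by physical position", {
  set.seed(3)
  arr <- array(sample(-500:500, 8 * 6 * 5, TRUE), c(8, 6, 5))
  dir <- tempfile("dcm")
  # files written in scrambled z order; reader must sort by slice position
  write_test_dicom_series(dir, arr, spacing = c(0.8, 0.8, 2.5))
  vol <- read_volume(dir, "CT_HU")
  expect_equal(vol$values, array(as.numeric(arr), dim(arr)))
  expect_equal(vol$spacing, c(0.8, 0.8, 2.5))
  # rescale slope/intercept applied
  f2 <- tempfile("dcm2")
  dir.create(f2)
  write_test_dicom(file.path(f2, "a.dcm"), matrix(100L, 4, 4),
                   position = c(0, 0, 0), slope = 2, intercept = -1000)
  write_test_dicom(file.path(f2, "b.dcm"), matrix(100L, 4, 4),
                   position = c(0, 0, 3), slope = 2, intercept = -1000)
  v2 <- read_volume(f2, "CT_HU")
  expect_equal(unique(as.vector(v2$values)), -800)
  expect_equal(v2$spacing[3], 3)
})

test_that("missing pixel-spacing metadata is a format error", {
  dir <- tempfile("dcm")
  dir.create(dir)
  write_test_dicom(file.path(dir, "a.dcm"), matrix(0L, 4, 4),
                   omit_spacing = TRUE)
  expect_error(read_volume(dir, "CT_HU"), "pixel-spacing")
})

test_that("resampling preserves constants, ramps and is idempotent at 1 mm", {
  cv <- resample_isotropic(volume3d(array(7, c(6, 6, 6)), c(3, 2, 1.5)))
  expect_equal(max(abs(cv$values - 7)), 0, tolerance = 1e-12)
  expect_equal(cv$spacing, c(1, 1, 1))
  expect_equal(dim(cv$values), c(18L, 12L, 9L))

  # linear ramp along z, 2-mm spacing: per-voxel increment halves exactly
  ramp <- volume3d(array(rep(seq(0, 18, by = 2), each = 25), c(5, 5, 10)),
                   c(1, 1, 2))
  r <- resample_isotropic(ramp)
  expect_equal(dim(r$values)[3], 20L)
  expect_equal(r$values[3, 3, 5:15], as.numeric(4:14), tolerance = 1e-12)

  # scanner-1 PET grid: 4-mm voxels -> axis lengths x4
  pet <- volume3d(array(1.5, c(10, 10, 10)), c(4, 4, 4),
                  modality = "PET_SUV")
  rp <- resample_isotropic(pet)
  expect_true(all(abs(dim(rp$values) - 40L) <= 1L))

  v1 <- volume3d(array(rnorm(5 * 5 * 5), c(5, 5, 5)), c(1, 1, 1))
  expect_equal(resample_isotropic(v1)$values, v1$values, tolerance = 1e-6)

  expect_error(resample_isotropic(volume3d(array(0, c(5, 5, 1)),
                                           c(1, 1, 1))), "degenerate")
})

test_that("node annotation tables read, validate and round trip", {
  f <- tempfile(fileext = ".csv")
  writeLines("patient_id,x_mm,y_mm,z_mm,source", f)
  expect_equal(nrow(read_nodes(f)), 0L)

  nodes <- nodes_df("p1", rbind(c(10, 20, 30), c(11, 21, 31), c(1, 2, 3)))
  write_nodes(nodes, f)
  back <- read_nodes(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$x_mm, nodes$x_mm)

  writeLines(c("patient_id,x_mm,y_mm", "p1,1,2"), f)
  expect_error(read_nodes(f), "missing column")
  writeLines(c("patient_id,x_mm,y_mm,z_mm", "p1,1,2,oops"), f)
  expect_error(read_nodes(f), "non-numeric")

  # unknown patients are accepted at read time but flagged on cross-check
  write_nodes(nodes_df(c("p1", "ghost"), rbind(c(1, 2, 3), c(4, 5, 6))), f)
  expect_warning(out <- check_node_inventory(read_nodes(f), "p1"),
                 "ghost")
  expect_equal(out$known_patient, c(TRUE, FALSE))
})

test_that("detection label maps round trip voxel sets exactly", {
  geom <- volume3d(array(0, c(12, 12, 8)), c(1, 1, 1), origin = c(5, 5, 0))
  r1 <- mediastinet:::candidate_region(cbind(2:4, 2:4, 2:4), "p1")
  r2 <- mediastinet:::candidate_region(rbind(c(10, 10, 6), c(10, 11, 6)),
                                       "p1")
  stem <- tempfile()
  out <- write_detections(list(r1, r2), geom, stem)
  lab <- read_volume(out$label_map)
  expect_setequal(unique(as.vector(lab$values)), c(0, 1, 2))
  back <- read_detections(out$label_map)
  expect_equal(lapply(back, function(r) unname(r$voxels)),
               list(unname(r1$voxels), unname(r2$voxels)))
  tab <- read.csv(out$table)
  expect_equal(tab$volume_voxels, c(3L, 2L))
  # no regions -> all-zero map, empty table
  out0 <- write_detections(list(), geom, tempfile())
  expect_true(all(read_volume(out0$label_map)$values == 0))
  expect_equal(nrow(read.csv(out0$table)), 0L)
  # region outside grid -> consistency error
  bad <- mediastinet:::candidate_region(rbind(c(13, 1, 1)), "p1")
  expect_error(write_detections(list(bad), geom, tempfile()), "outside")
})
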