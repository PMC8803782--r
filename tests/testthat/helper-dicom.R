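# Writes minimal explicit-VR little-endian DICOM slices for reader tests.

dcm_element <- function(group, elem, vr, data_raw) {
  if (length(data_raw) %% 2L) data_raw <- c(data_raw, as.raw(0))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(data_raw), raw(), size = 4, endian = "little"),
      data_raw)
  } else {
    c(head, writeBin(length(data_raw), raw(), size = 2, endian = "little"),
      data_raw)
  }
}

dcm_ds <- function(...) charToRaw(paste(sprintf("%g", c(...)),
                                        collapse = "\\"))
dcm_us <- function(v) writeBin(as.integer(v), raw(), size = 2,
                               endian = "little")

# one axial slice; values: integer matrix [x, y] stored before rescale
write_test_dicom <- function(path, values, pixel_spacing = c(1, 1),
                             position = c(0, 0, 0), slope = 1,
                             intercept = 0, omit_spacing = FALSE) {
  rows <- ncol(values)   # y
  cols <- nrow(values)   # x
  # PixelData is row-major with the column (our x) index fastest, which is
  # exactly the R column-major order of the [x, y] matrix
  px <- writeBin(as.integer(as.vector(values)), raw(), size = 2,
                 endian = "little")
  body <- c(
    dcm_element(0x0020, 0x0032, "DS",
                charToRaw(paste(sprintf("%g", position), collapse = "\\"))),
    dcm_element(0x0028, 0x0010, "US", dcm_us(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_us(cols)),
    if (!omit_spacing)
      dcm_element(0x0028, 0x0030, "DS",
                  dcm_ds(pixel_spacing[2], pixel_spacing[1])) else raw(),
    dcm_element(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_us(1)),
    dcm_element(0x0028, 0x1052, "DS", dcm_ds(intercept)),
    dcm_element(0x0028, 0x1053, "DS", dcm_ds(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# write a whole series with slices in a scrambled file order
write_test_dicom_series <- function(dir, arr, spacing = c(1, 1, 2),
                                    scramble = TRUE, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(arr)[3]
  ord <- if (scramble) withr_seed_sample(nz, seed) else seq_len(nz)
  for (fi in seq_len(nz)) {
    z <- ord[fi]
    write_test_dicom(file.path(dir, sprintf("slice_%03d.dcm", fi)),
                     arr[, , z],
                     pixel_spacing = spacing[1:2],
                     position = c(0, 0, (z - 1) * spacing[3]))
  }
  invisible(dir)
}

withr_seed_sample <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  sample.int(n)
}
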