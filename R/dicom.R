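# Minimal DICOM series reader: uncompressed single-frame slices in explicit
# VR little endian (the flavour exported by scanners for axial CT/PET). Only
# the tags the pipeline needs are parsed; slices are stacked in order of
# physical slice position, whatever the file order on disk.

DCM_TAGS <- list(
  rows              = c(0x0028, 0x0010),
  cols              = c(0x0028, 0x0011),
  bits_allocated    = c(0x0028, 0x0100),
  pixel_rep         = c(0x0028, 0x0103),
  pixel_spacing     = c(0x0028, 0x0030),
  position          = c(0x0020, 0x0032),
  slope             = c(0x0028, 0x1053),
  intercept         = c(0x0028, 0x1052),
  pixel_data        = c(0x7FE0, 0x0010)
)

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # 128-byte preamble + "DICM"
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("read_volume: not a DICOM file (missing DICM magic): ", path,
         call. = FALSE)
  pos <- 133L
  out <- list()
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      data_at <- pos + 8L
    }
    if (len < 0) stop("read_volume: undefined-length element unsupported: ",
                      path, call. = FALSE)
    bytes <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, bytes = bytes)
    pos <- data_at + len
  }
  out
}

dcm_get <- function(elems, tag, path, required = TRUE) {
  key <- sprintf("%04X,%04X", tag[1], tag[2])
  el <- elems[[key]]
  if (is.null(el) && required)
    stop("read_volume: DICOM tag (", key, ") missing in ", path,
         call. = FALSE)
  el
}

dcm_num <- function(el) as.numeric(strsplit(trimws(rawToChar(el$bytes)),
                                            "\\\\")[[1]])
dcm_u16 <- function(el) readBin(el$bytes, "integer", size = 2,
                                endian = "little", signed = FALSE)

read_dicom_series <- function(dir, modality) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files))
    stop("read_volume: no files in DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, function(f) {
    el <- read_dicom_file(f)
    rows <- dcm_u16(dcm_get(el, DCM_TAGS$rows, f))
    cols <- dcm_u16(dcm_get(el, DCM_TAGS$cols, f))
    sp_el <- dcm_get(el, DCM_TAGS$pixel_spacing, f, required = FALSE)
    if (is.null(sp_el))
      stop("read_volume: missing pixel-spacing metadata in ", f,
           call. = FALSE)
    spacing <- dcm_num(sp_el)          # row spacing, column spacing
    ipp <- dcm_num(dcm_get(el, DCM_TAGS$position, f))
    bits <- dcm_u16(dcm_get(el, DCM_TAGS$bits_allocated, f))
    if (bits != 16L)
      stop("read_volume: only 16-bit DICOM pixel data supported", call. = FALSE)
    rep_el <- dcm_get(el, DCM_TAGS$pixel_rep, f, required = FALSE)
    signed <- !is.null(rep_el) && dcm_u16(rep_el) == 1L
    slope_el <- dcm_get(el, DCM_TAGS$slope, f, required = FALSE)
    inter_el <- dcm_get(el, DCM_TAGS$intercept, f, required = FALSE)
    slope <- if (is.null(slope_el)) 1 else dcm_num(slope_el)
    inter <- if (is.null(inter_el)) 0 else dcm_num(inter_el)
    px_el <- dcm_get(el, DCM_TAGS$pixel_data, f)
    px <- readBin(px_el$bytes, "integer", n = rows * cols, size = 2,
                  endian = "little", signed = signed)
    # PixelData is row-major (column index fastest); our x axis is the column
    mat <- matrix(px, nrow = cols, ncol = rows)      # -> [x=col, y=row]
    list(values = mat * slope + inter,
         spacing = c(spacing[2], spacing[1]),        # col, row spacing
         position = ipp)
  })
  z <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  d2 <- dim(slices[[1]]$values)
  if (!all(vapply(slices, function(s) identical(dim(s$values), d2),
                  logical(1))))
    stop("read_volume: inconsistent slice dimensions in series", call. = FALSE)
  dz <- if (length(z) > 1) diff(z) else NA_real_
  if (length(z) > 1 && (any(dz <= 0) || diff(range(dz)) > 1e-3))
    stop("read_volume: non-uniform or duplicate slice positions", call. = FALSE)
  zsp <- if (length(z) > 1) dz[1] else 1
  arr <- array(0, c(d2[1], d2[2], length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]$values
  volume3d(arr, c(slices[[1]]$spacing, zsp),
           origin = c(slices[[1]]$position[1], slices[[1]]$position[2], z[1]),
           modality = modality)
}
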