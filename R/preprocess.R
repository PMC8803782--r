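#' Preprocessing configuration
#'
#' Defaults are the published pipeline settings: air threshold -400 HU,
#' 2-iteration binary closing then 7-iteration binary opening
#' (face-connected element), exterior-air rejection within 25 voxels of the
#' x/y border, 256 x 256 in-plane crop, CT clipped to +/-1000 HU and PET to
#' 8 SUV, all on the 1-mm isotropic grid.
#'
#' @param hu_air_threshold HU at or below which a voxel counts as air.
#' @param closing_iters,opening_iters morphology iteration counts.
#' @param border_margin_voxels exterior-air border margin (x/y only).
#' @param crop_xy in-plane crop size, voxels.
#' @param ct_clip symmetric CT clip bound, HU.
#' @param suv_clip upper PET clip bound, SUV.
#' @param target_spacing isotropic working spacing, mm.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(hu_air_threshold = -400, closing_iters = 2L,
                              opening_iters = 7L, border_margin_voxels = 25L,
                              crop_xy = 256L, ct_clip = 1000, suv_clip = 8,
                              target_spacing = 1.0) {
  stopifnot(closing_iters >= 0, opening_iters >= 0,
            border_margin_voxels >= 0, crop_xy >= 1,
            ct_clip > 0, suv_clip > 0, abs(hu_air_threshold) <= ct_clip)
  structure(as.list(environment()), class = "preprocess_config")
}

# ---- binary morphology (face-connected structuring element, 3D) ---------

binary_dilate <- function(mask, iters = 1L) {
  storage.mode(mask) <- "integer"
  array(.morph_cpp(mask, dim(mask), as.integer(iters), TRUE), dim(mask))
}

binary_erode <- function(mask, iters = 1L) {
  storage.mode(mask) <- "integer"
  array(.morph_cpp(mask, dim(mask), as.integer(iters), FALSE), dim(mask))
}

binary_closing <- function(mask, iters = 1L)
  binary_erode(binary_dilate(mask, iters), iters)

binary_opening <- function(mask, iters = 1L)
  binary_dilate(binary_erode(mask, iters), iters)

# 26-connected component labelling (the package-wide convention);
# components are numbered in scan order of their first voxel.
label_components <- function(mask, connectivity = 26L) {
  storage.mode(mask) <- "integer"
  lab <- .label_components_cpp(mask, dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim(mask))
  attr(lab, "n_components") <- n
  lab
}

#' Segment air-filled regions of a CT
#'
#' Thresholds the CT (air: HU at or below the threshold; the boundary value
#' itself counts as air), then applies a 2-iteration binary closing followed
#' by a 7-iteration binary opening, both with the face-connected
#' (connectivity-one) element in 3D. The morphology removes very small air
#' pockets and nodules within the lungs.
#'
#' @param ct a [volume3d] in HU on the 1-mm working grid.
#' @param cfg a [preprocess_config()].
#' @param morphology set `FALSE` to return the raw threshold mask.
#' @return integer 0/1 array of the CT's dimensions.
#' @export
segment_air <- function(ct, cfg = preprocess_config(), morphology = TRUE) {
  vals <- if (inherits(ct, "volume3d")) ct$values else ct
  mask <- .threshold_leq_cpp(vals, cfg$hu_air_threshold)
  if (!morphology) return(mask)
  mask <- binary_closing(mask, cfg$closing_iters)
  binary_opening(mask, cfg$opening_iters)
}

#' Delete air components touching the x/y image border zone
#'
#' Any connected component containing a voxel within `margin` voxels of the
#' x or y border is exterior air (outside the patient) and is removed. The z
#' axis is exempt: a whole-body scan necessarily reaches the first and last
#' slices.
#'
#' @param mask 0/1 array.
#' @param margin border margin in voxels (default 25).
#' @return 0/1 array with border components removed.
#' @export
remove_border_components <- function(mask, margin = 25L) {
  storage.mode(mask) <- "integer"
  array(.remove_border_components_cpp(mask, dim(mask), as.integer(margin)),
        dim(mask))
}

#' Select the lungs from an air mask
#'
#' Returns the largest 26-connected component by voxel count; size ties go
#' to the component first encountered in scan order.
#'
#' @param mask 0/1 array after border-component removal.
#' @return 0/1 array containing a single component.
#' @export
select_lungs <- function(mask) {
  lab <- label_components(mask)
  n <- attr(lab, "n_components")
  if (n == 0L)
    stop("select_lungs: segmentation failure, no air component found",
         call. = FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  best <- which.max(sizes)   # ties: lowest label = first in scan order
  array(as.integer(lab == best), dim(mask))
}

#' Crop both modalities to the thorax
#'
#' Keeps only z slices within the min/max slice range of the lung mask, then
#' symmetrically centre-crops each slice to `crop_xy` x `crop_xy` (padding
#' symmetrically with air-equivalent values, -1000 HU / 0 SUV, if a slice is
#' smaller). Physical origins are updated so node coordinates remain valid.
#'
#' @param scan a `patient_scan` whose `ct`/`pet` are on an identical 1-mm
#'   grid.
#' @param lungs lung mask from [select_lungs()] on the same grid.
#' @param cfg a [preprocess_config()].
#' @return A `thorax_crop`: cropped `ct` and `pet` [volume3d]s, `z_range`
#'   (1-based slice bounds in the input grid), `xy_offset` (voxels removed
#'   at the low x/y side; negative when padded), `patient_id`, `nodes`.
#' @export
crop_thorax <- function(scan, lungs, cfg = preprocess_config()) {
  if (!any(lungs > 0))
    stop("crop_thorax: segmentation failure, empty lung mask", call. = FALSE)
  d <- dim(scan$ct$values)
  if (!identical(dim(scan$pet$values), d) ||
      any(abs(scan$ct$spacing - scan$pet$spacing) > 1e-9))
    stop("crop_thorax: CT and PET must share one grid", call. = FALSE)
  zs <- which(apply(lungs, 3, function(s) any(s > 0)))
  z_range <- c(min(zs), max(zs))
  crop1 <- function(vol, fill) {
    arr <- vol$values[, , z_range[1]:z_range[2], drop = FALSE]
    cp <- crop_or_pad_xy(arr, cfg$crop_xy, fill)
    volume3d(cp$values, vol$spacing,
             vol$origin + c(cp$offset[1], cp$offset[2], z_range[1] - 1) *
               vol$spacing,
             vol$modality)
  }
  ct <- crop1(scan$ct, -1000)
  pet <- crop1(scan$pet, 0)
  structure(list(ct = ct, pet = pet, z_range = z_range,
                 xy_offset = c(floor((d[1] - cfg$crop_xy) / 2),
                               floor((d[2] - cfg$crop_xy) / 2)),
                 patient_id = scan$patient_id, nodes = scan$nodes,
                 standardised = FALSE),
            class = "thorax_crop")
}

crop_or_pad_xy <- function(arr, size, fill) {
  d <- dim(arr)
  take <- function(n) {
    off <- floor((n - size) / 2)           # negative => pad
    idx <- (off + 1):(off + size)
    list(off = off, idx = idx)
  }
  tx <- take(d[1]); ty <- take(d[2])
  out <- array(fill, c(size, size, d[3]))
  sx <- pmax(tx$idx, 1L); sx <- sx[sx <= d[1]]
  sy <- pmax(ty$idx, 1L); sy <- sy[sy <= d[2]]
  sx <- sx[sx >= 1]; sy <- sy[sy >= 1]
  dest_x <- which(tx$idx >= 1 & tx$idx <= d[1])
  dest_y <- which(ty$idx >= 1 & ty$idx <= d[2])
  out[dest_x, dest_y, ] <- arr[tx$idx[dest_x], ty$idx[dest_y], , drop = FALSE]
  list(values = out, offset = c(tx$off, ty$off))
}

#' Clip CT and PET intensities
#'
#' CT to `[-ct_clip, ct_clip]` HU; PET to `[0, suv_clip]` SUV.
#'
#' @param crop a `thorax_crop`.
#' @param cfg a [preprocess_config()].
#' @return The crop with clipped intensities.
#' @export
clip_intensities <- function(crop, cfg = preprocess_config()) {
  crop$ct$values <- pmin(pmax(crop$ct$values, -cfg$ct_clip), cfg$ct_clip)
  crop$pet$values <- pmin(pmax(crop$pet$values, 0), cfg$suv_clip)
  crop
}

#' Fit dataset-level standardisation statistics
#'
#' Per-modality mean and standard deviation pooled over every voxel of every
#' training crop. One set of statistics is fitted on the training data and
#' reused unchanged at inference: the rescaling is dataset-level, so
#' absolute differences between patients are preserved.
#'
#' @param crops list of clipped `thorax_crop`s (training set).
#' @param fitted_on identifier recorded with the statistics.
#' @return A `norm_stats` list: `ct_mean`, `ct_sd`, `pet_mean`, `pet_sd`,
#'   `fitted_on`.
#' @export
fit_normalization <- function(crops, fitted_on = "training") {
  if (!length(crops)) stop("fit_normalization: no crops", call. = FALSE)
  pooled <- function(field) {
    n <- 0; s <- 0; s2 <- 0
    for (cr in crops) {
      v <- cr[[field]]$values
      n <- n + length(v); s <- s + sum(v); s2 <- s2 + sum(v * v)
    }
    m <- s / n
    var <- s2 / n - m * m
    c(mean = m, sd = sqrt(max(var, 0)))
  }
  ct <- pooled("ct"); pet <- pooled("pet")
  if (ct["sd"] <= 0 || pet["sd"] <= 0)
    stop("fit_normalization: degenerate data (zero variance)", call. = FALSE)
  structure(list(ct_mean = unname(ct["mean"]), ct_sd = unname(ct["sd"]),
                 pet_mean = unname(pet["mean"]), pet_sd = unname(pet["sd"]),
                 fitted_on = fitted_on),
            class = "norm_stats")
}

#' Apply (or invert) dataset-level standardisation
#'
#' The affine map `(value - mean) / sd` per modality; order-preserving, and
#' exactly invertible with `invert = TRUE`.
#'
#' @param crop a `thorax_crop`.
#' @param stats a `norm_stats` from [fit_normalization()].
#' @param invert undo the standardisation.
#' @return The transformed crop (`standardised` flag updated).
#' @export
apply_normalization <- function(crop, stats, invert = FALSE) {
  if (is.null(stats) || !inherits(stats, "norm_stats"))
    stop("apply_normalization: normalization statistics missing",
         call. = FALSE)
  if (invert) {
    crop$ct$values <- crop$ct$values * stats$ct_sd + stats$ct_mean
    crop$pet$values <- crop$pet$values * stats$pet_sd + stats$pet_mean
    crop$standardised <- FALSE
  } else {
    crop$ct$values <- (crop$ct$values - stats$ct_mean) / stats$ct_sd
    crop$pet$values <- (crop$pet$values - stats$pet_mean) / stats$pet_sd
    crop$standardised <- TRUE
  }
  crop
}

#' @rdname fit_normalization
#' @param stats a `norm_stats`.
#' @param path JSON file path.
#' @export
write_normalization <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_normalization
#' @export
read_normalization <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "norm_stats")
}

# Pad/crop a volume at the grid edges so its array matches `ref`'s dims
# (same spacing assumed); replicates edge values, consistent with the
# resampler's edge policy.
conform_to_grid <- function(vol, ref) {
  d <- dim(vol$values); rd <- dim(ref$values)
  if (identical(d, rd)) return(vol)
  arr <- vol$values
  for (axis in 1:3) {
    n <- dim(arr)[axis]
    idx <- pmin(pmax(seq_len(rd[axis]), 1L), n)
    arr <- switch(axis,
                  arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
  }
  volume3d(arr, vol$spacing, ref$origin, vol$modality)
}

#' Run the full automated preprocessing for one scan
#'
#' Resample both modalities to the isotropic working grid, conform the PET
#' onto the CT grid, segment the air regions, discard exterior air, select
#' the lungs, crop to the thorax, and clip intensities. Standardisation is a
#' separate step because its statistics come from the training set only.
#'
#' @param scan a `patient_scan` (native grids).
#' @param cfg a [preprocess_config()].
#' @return list with the clipped `crop` and the selected `lungs` mask (on
#'   the working grid).
#' @export
preprocess_scan <- function(scan, cfg = preprocess_config()) {
  ct <- resample_isotropic(scan$ct, cfg$target_spacing)
  pet <- resample_isotropic(scan$pet, cfg$target_spacing)
  pet <- conform_to_grid(pet, ct)
  air <- segment_air(ct, cfg)
  air <- remove_border_components(air, cfg$border_margin_voxels)
  lungs <- select_lungs(air)
  rescaled <- scan
  rescaled$ct <- ct; rescaled$pet <- pet
  crop <- crop_thorax(rescaled, lungs, cfg)
  crop <- clip_intensities(crop, cfg)
  list(crop = crop, lungs = lungs)
}
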