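#' 3D scalar volume with physical geometry
#'
#' Container for a volumetric scan: a numeric array indexed `[x, y, z]`
#' together with its voxel spacing (mm per axis), the physical position of
#' voxel `(1,1,1)` (voxel-centre convention) and a modality tag.
#'
#' @param values numeric 3D array, axis order x, y, z.
#' @param spacing numeric length-3, mm per axis; strictly positive.
#' @param origin numeric length-3, physical mm coordinate of the first voxel
#'   centre.
#' @param modality `"CT_HU"` or `"PET_SUV"`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, spacing, origin = c(0, 0, 0),
                     modality = c("CT_HU", "PET_SUV")) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3L)
    stop("volume3d: `values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: spacing must be three strictly positive values",
         call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume3d: origin must be three finite values", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         modality = modality, axis_order = c("x", "y", "z")),
    class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d %s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Convert between voxel indices and physical coordinates
#'
#' Voxel-centre convention: the physical coordinate of 1-based voxel index
#' `(i,j,k)` is `origin + (c(i,j,k) - 1) * spacing`. The two functions are
#' exact inverses on the lattice; `physical_to_voxel()` rounds to the nearest
#' voxel, so any point within half a voxel of a centre maps back to it.
#'
#' @param vol a [volume3d].
#' @param index numeric matrix (n x 3) or length-3 vector of 1-based indices.
#' @param coord numeric matrix (n x 3) or length-3 vector of physical mm.
#' @return A matrix (n x 3) of coordinates or indices.
#' @export
voxel_to_physical <- function(vol, index) {
  index <- rbind_coords(index)
  sweep(sweep(index - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname voxel_to_physical
#' @export
physical_to_voxel <- function(vol, coord) {
  coord <- rbind_coords(coord)
  round(sweep(sweep(coord, 2, vol$origin, "-"), 2, vol$spacing, "/")) + 1
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  x
}

#' Read a volumetric scan
#'
#' Reads a NIfTI file or a DICOM series directory into a [volume3d],
#' preserving spacing and origin. The caller declares the modality; values
#' are taken as stored (after DICOM rescale slope/intercept), i.e. HU for CT
#' and SUV for PET.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param modality `"CT_HU"` or `"PET_SUV"`.
#' @param format `"auto"`, `"nifti"` or `"dicom"`.
#' @return A [volume3d].
#' @export
read_volume <- function(path, modality = c("CT_HU", "PET_SUV"),
                        format = c("auto", "nifti", "dicom")) {
  modality <- match.arg(modality)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "dicom") return(read_dicom_series(path, modality))
  if (!file.exists(path)) stop("read_volume: file not found: ", path,
                               call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("read_volume: image is not 3D (dims: ",
         paste(dim(arr), collapse = "x"), ")", call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("read_volume: missing or invalid spacing metadata", call. = FALSE)
  ext <- RNifti::extension(img, 40L, "character")
  orig <- if (length(ext)) as.numeric(strsplit(ext[[1]], ",")[[1]]) else c(0, 0, 0)
  if (length(orig) != 3L || any(!is.finite(orig))) orig <- c(0, 0, 0)
  volume3d(array(as.numeric(arr), dim(arr)), pd, orig, modality)
}

#' Write a volume to NIfTI
#'
#' Spacing goes into `pixdim`; the origin is stored in a NIfTI extension so
#' that [read_volume()] round-trips the full geometry.
#'
#' @param vol a [volume3d] (or plain 3D array for label maps).
#' @param path output `.nii` / `.nii.gz` path.
#' @param datatype NIfTI storage type (`"double"` preserves values exactly;
#'   `"float"` halves size for large intermediate crops).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  if (is.array(vol)) vol <- volume3d(vol, c(1, 1, 1))
  img <- RNifti::asNifti(vol$values, datatype = datatype)
  img$pixdim <- c(-1, vol$spacing, 0, 0, 0, 0)
  RNifti::extension(img, 40L) <- paste(sprintf("%.9g", vol$origin),
                                       collapse = ",")
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Resample a volume to an isotropic grid
#'
#' Separable cubic-spline (Catmull-Rom) interpolation onto `target_spacing`
#' mm isotropic voxels. The physical slab extent `n * spacing` is preserved
#' to within one voxel per axis (`n_out = round(n * spacing / target)`); the
#' origin is unchanged and samples beyond the first/last input voxel centre
#' take edge values.
#'
#' @param vol a [volume3d].
#' @param target_spacing isotropic target spacing in mm (default 1).
#' @return A [volume3d] with spacing `(target, target, target)`.
#' @export
resample_isotropic <- function(vol, target_spacing = 1.0) {
  stopifnot(inherits(vol, "volume3d"), target_spacing > 0)
  d <- dim(vol$values)
  if (any(d < 2L))
    stop("resample_isotropic: degenerate axis (fewer than 2 voxels)",
         call. = FALSE)
  arr <- vol$values
  for (axis in 1:3) {
    n_out <- max(2L, as.integer(round(d[axis] * vol$spacing[axis] /
                                        target_spacing)))
    if (n_out == d[axis] && isTRUE(all.equal(vol$spacing[axis],
                                             target_spacing))) next
    arr <- .resample_axis_cpp(arr, dim(arr), axis - 1L, n_out,
                              target_spacing / vol$spacing[axis])
  }
  volume3d(arr, rep(target_spacing, 3), vol$origin, vol$modality)
}

#' Read node annotations from CSV
#'
#' Expected columns: `patient_id, x_mm, y_mm, z_mm` and optionally `source`
#' (`reference_reader`, `second_reader` or `ground_truth`; default
#' `ground_truth`).
#'
#' @param path CSV file.
#' @return A data.frame of class `node_annotations`, one row per node, in
#'   file order.
#' @export
read_nodes <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("read_nodes: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (nrow(tab) && anyNA(v))
      stop("read_nodes: non-numeric coordinate in column ", cc, call. = FALSE)
    tab[[cc]] <- v
  }
  if (is.null(tab$source)) tab$source <- rep("ground_truth", nrow(tab))
  tab <- tab[, c("patient_id", "x_mm", "y_mm", "z_mm", "source")]
  class(tab) <- c("node_annotations", "data.frame")
  tab
}

#' @rdname read_nodes
#' @param nodes a `node_annotations` data.frame.
#' @export
write_nodes <- function(nodes, path) {
  write.csv(as.data.frame(nodes), path, row.names = FALSE)
  invisible(path)
}

#' Cross-check annotations against a scan inventory
#'
#' Annotations whose patient is absent from the scan set are accepted at read
#' time but flagged here.
#'
#' @param nodes annotations from [read_nodes()].
#' @param patient_ids character vector of known patients.
#' @return `nodes` with a logical `known_patient` column; warns on orphans.
#' @export
check_node_inventory <- function(nodes, patient_ids) {
  nodes$known_patient <- nodes$patient_id %in% patient_ids
  if (any(!nodes$known_patient))
    warning("annotations reference unknown patient(s): ",
            paste(unique(nodes$patient_id[!nodes$known_patient]),
                  collapse = ", "))
  nodes
}

#' Write detections as a label map and a centroid table
#'
#' Emits a NIfTI label map (region index per voxel, 0 background) plus a CSV
#' of region centroids (physical mm) and voxel volumes.
#'
#' @param regions list of `candidate_region` objects (see
#'   [predict_candidates()]).
#' @param geometry a [volume3d] (or object with `$spacing`, `$origin` and
#'   values dims) defining the grid; a `scoremap` from [aggregate_scores()]
#'   also works.
#' @param path output stem; writes `<path>.nii.gz` and `<path>.csv`.
#' @return Invisible list with the two file paths.
#' @export
write_detections <- function(regions, geometry, path) {
  d <- geometry$dim %||% dim(geometry$values)
  spacing <- geometry$spacing
  origin <- geometry$origin
  lab <- array(0L, d)
  rows <- list()
  for (i in seq_along(regions)) {
    vox <- regions[[i]]$voxels
    if (any(vox < 1L) || any(vox[, 1] > d[1]) || any(vox[, 2] > d[2]) ||
        any(vox[, 3] > d[3]))
      stop("write_detections: region ", i, " has voxels outside the grid",
           call. = FALSE)
    lab[vox] <- i
    cen <- origin + (colMeans(vox) - 1) * spacing
    rows[[i]] <- data.frame(region = i, x_mm = cen[1], y_mm = cen[2],
                            z_mm = cen[3], volume_voxels = nrow(vox))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = integer(), x_mm = numeric(), y_mm = numeric(),
               z_mm = numeric(), volume_voxels = integer())
  nii <- paste0(path, ".nii.gz")
  csv <- paste0(path, ".csv")
  write_volume(volume3d(lab, spacing, origin), nii)
  write.csv(tab, csv, row.names = FALSE)
  invisible(list(label_map = nii, table = csv))
}

#' Read a detection label map back into regions
#'
#' @param path the `<path>.nii.gz` written by [write_detections()].
#' @return list of `candidate_region` objects.
#' @export
read_detections <- function(path) {
  vol <- read_volume(path)
  lab <- vol$values
  labels_to_regions(array(as.integer(round(lab)), dim(lab)),
                    patient_id = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
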