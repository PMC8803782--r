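#' Scanner acquisition profiles
#'
#' Two profiles emulating the acquisition differences between an older
#' time-of-flight PET/CT (scanner 1: 4 x 4 x 4 mm PET voxels) and a newer
#' digital system (scanner 2: 2.34-2.73 mm in-plane / 2.8 mm inter-plane PET
#' voxels, improved contrast and lower noise). Contrast enters the phantom as
#' a single multiplicative gain on node uptake; noise as the SD of additive
#' Gaussian SUV noise.
#'
#' @param id `"scanner1"` or `"scanner2"`.
#' @param pet_spacing,ct_spacing mm triples (defaults per profile).
#' @param pet_noise_sd SUV noise standard deviation.
#' @param contrast_gain multiplier on node uptake above background.
#' @return A `scanner_profile` list.
#' @export
scanner_profile <- function(id = c("scanner1", "scanner2"),
                            pet_spacing = NULL, ct_spacing = c(2, 2, 2),
                            pet_noise_sd = NULL, contrast_gain = NULL) {
  id <- match.arg(id)
  defaults <- list(
    scanner1 = list(pet_spacing = c(4, 4, 4), pet_noise_sd = 0.20,
                    contrast_gain = 1.0),
    scanner2 = list(pet_spacing = c(2.5, 2.5, 2.8), pet_noise_sd = 0.15,
                    contrast_gain = 1.4))[[id]]
  structure(list(
    id = id,
    pet_spacing = pet_spacing %||% defaults$pet_spacing,
    ct_spacing = ct_spacing,
    pet_noise_sd = pet_noise_sd %||% defaults$pet_noise_sd,
    contrast_gain = contrast_gain %||% defaults$contrast_gain),
    class = "scanner_profile")
}

#' Phantom generation parameters
#'
#' Tissue intensities, node characteristics and the per-patient node-count
#' distribution. The default node-count distribution follows the pooled
#' patient split by number of nodes across the study cohorts
#' (P(0), P(1), P(2), P(3), P(4+)) with the 4+ band drawn as
#' `4 + Poisson(extra_pois_lambda)`.
#'
#' @param body_hu,lung_hu,air_hu,node_hu tissue CT intensities (HU).
#' @param node_diameter_range node diameter range, mm.
#' @param node_suv_range node uptake above background, SUV (pre contrast
#'   gain).
#' @param background_suv_range per-patient soft-tissue background SUV range.
#' @param lung_suv lung background SUV.
#' @param ct_noise_sd CT Gaussian noise SD, HU.
#' @param node_count_probs probabilities for 0,1,2,3,4+ nodes per patient.
#' @param extra_pois_lambda Poisson mean added on top of 4 in the 4+ band.
#' @param n_nodes fixed node count (overrides sampling) or `NULL`.
#' @param n_distractors number of extra-mediastinal hot spots (thyroid /
#'   inflammation analogues); `NULL` draws 1-2.
#' @param grid_dim,grid_spacing CT native grid (default 192 x 192 x 160
#'   voxels at 2 mm).
#' @param min_separation minimum surface-to-surface node gap, mm.
#' @param seed integer RNG seed for the phantom.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(body_hu = 0, lung_hu = -800, air_hu = -1000,
                           node_hu = 50,
                           node_diameter_range = c(8, 30),
                           node_suv_range = c(3, 8),
                           background_suv_range = c(1, 2),
                           lung_suv = 0.5, ct_noise_sd = 15,
                           node_count_probs = c(96, 26, 26, 13, 23) / 184,
                           extra_pois_lambda = 1.3,
                           n_nodes = NULL, n_distractors = NULL,
                           grid_dim = c(192L, 192L, 160L),
                           grid_spacing = c(2, 2, 2),
                           min_separation = 4, seed = 1L) {
  stopifnot(length(node_count_probs) == 5L,
            abs(sum(node_count_probs) - 1) < 1e-8,
            node_hu > lung_hu, all(grid_spacing > 0), all(grid_dim >= 8))
  structure(as.list(environment()), class = "phantom_params")
}

#' Draw a per-patient node count
#'
#' Samples from the 0/1/2/3/4+ distribution in [phantom_params()]; the 4+
#' band adds a Poisson-distributed excess, matching the heavy per-patient
#' node totals implied by the cohort table.
#'
#' @param params a [phantom_params()].
#' @return integer node count.
#' @export
sample_node_count <- function(params) {
  band <- sample.int(5L, 1L, prob = params$node_count_probs) - 1L
  if (band < 4L) band else 4L + rpois(1L, params$extra_pois_lambda)
}

# Analytic phantom geometry in physical mm, scaled to the grid extent so the
# same proportions hold on small test grids.
phantom_geometry <- function(params) {
  ext <- params$grid_dim * params$grid_spacing
  cen <- (params$grid_dim - 1) * params$grid_spacing / 2
  lung_off <- 0.16 * ext[1]
  lung_semi <- c(0.125 * ext[1], 0.17 * ext[2], 0.27 * ext[3])
  list(
    extent = ext, centre = cen,
    body_semi = c(0.40 * ext[1], 0.27 * ext[2]),
    body_z = c(0.05, 0.95) * ext[3],
    lung_centres = rbind(c(cen[1] - lung_off, cen[2], cen[3]),
                         c(cen[1] + lung_off, cen[2], cen[3])),
    lung_semi = lung_semi,
    bronchi = list(y = cen[2], z = cen[3] + 0.17 * ext[3],
                   half_len = lung_off, radius = 12),
    # mediastinum: between the lungs, interior z sub-range of the thorax
    med_half = c(max(8, 0.9 * (lung_off - lung_semi[1])),
                 0.10 * ext[2], 0.14 * ext[3]))
}

# value field helpers: per-axis vectors combined into a full 3D array
field3 <- function(A, B, C) {
  nx <- length(A); ny <- length(B); nz <- length(C)
  array(rep(A, times = ny * nz) +
          rep(rep(B, each = nx), times = nz) +
          rep(C, each = nx * ny), c(nx, ny, nz))
}

axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

ellipsoid_mask <- function(xs, ys, zs, centre, semi) {
  field3(((xs - centre[1]) / semi[1])^2,
         ((ys - centre[2]) / semi[2])^2,
         ((zs - centre[3]) / semi[3])^2) <= 1
}

# paint a sphere into arr (bounding-box restricted)
paint_sphere <- function(arr, xs, ys, zs, centre, radius, value,
                         mode = c("set", "add")) {
  mode <- match.arg(mode)
  ix <- which(abs(xs - centre[1]) <= radius)
  iy <- which(abs(ys - centre[2]) <= radius)
  iz <- which(abs(zs - centre[3]) <= radius)
  if (!length(ix) || !length(iy) || !length(iz)) return(arr)
  sub <- field3((xs[ix] - centre[1])^2, (ys[iy] - centre[2])^2,
                (zs[iz] - centre[3])^2) <= radius^2
  block <- arr[ix, iy, iz, drop = FALSE]
  if (mode == "set") block[sub] <- value else block[sub] <- block[sub] + value
  arr[ix, iy, iz] <- block
  arr
}

place_nodes <- function(n, geom, params) {
  if (n == 0) return(list(centres = matrix(numeric(), 0, 3),
                          diam = numeric()))
  centres <- matrix(NA_real_, n, 3)
  diam <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in 1:400) {
      d <- runif(1, params$node_diameter_range[1],
                 params$node_diameter_range[2])
      p <- geom$centre + runif(3, -1, 1) * geom$med_half
      # keep clear of the bronchial air bar
      dyz <- sqrt((p[2] - geom$bronchi$y)^2 + (p[3] - geom$bronchi$z)^2)
      if (dyz < d / 2 + geom$bronchi$radius + 2) next
      if (i > 1) {
        dd <- sqrt(rowSums(sweep(centres[seq_len(i - 1), , drop = FALSE],
                                 2, p)^2))
        if (any(dd < (diam[seq_len(i - 1)] + d) / 2 + params$min_separation))
          next
      }
      centres[i, ] <- p; diam[i] <- d; ok <- TRUE
      break
    }
    if (!ok)
      stop("generate_phantom: cannot place ", n,
           " nodes in the mediastinal compartment at the requested ",
           "separation", call. = FALSE)
  }
  list(centres = centres, diam = diam)
}

#' Generate one synthetic thoracic PET/CT phantom
#'
#' Builds a whole-body-like CT (air background, soft-tissue body, two
#' air-filled lung ellipsoids joined by a bronchial air bar, the thorax a
#' strict interior z sub-range) and a co-registered PET (per-patient
#' soft-tissue background, hot spherical nodes planted in the mediastinum,
#' at least one distractor hot spot outside the mediastinum, additive
#' Gaussian noise), each on its native grid per the scanner profile.
#'
#' @param params a [phantom_params()] (its `seed` drives all randomness).
#' @param profile a [scanner_profile()].
#' @param patient_id identifier string.
#' @return A `patient_scan`: `ct`, `pet` ([volume3d]s), `nodes`
#'   (ground-truth annotations), `scanner_id` and the analytic `geometry`.
#' @export
generate_phantom <- function(params, profile, patient_id = "p001") {
  stopifnot(inherits(params, "phantom_params"),
            inherits(profile, "scanner_profile"))
  with_seed(params$seed, {
    geom <- phantom_geometry(params)
    n_nodes <- params$n_nodes %||% sample_node_count(params)
    nodes <- place_nodes(n_nodes, geom, params)
    suv <- if (n_nodes) runif(n_nodes, params$node_suv_range[1],
                              params$node_suv_range[2]) else numeric()
    n_dis <- params$n_distractors %||% sample(1:2, 1)
    dis <- distractor_sites(n_dis, geom)
    dis_suv <- runif(n_dis, 3, 6)
    bg <- runif(1, params$background_suv_range[1],
                params$background_suv_range[2])

    ## ---- CT on its native grid -------------------------------------
    cd <- params$grid_dim
    cs <- profile$ct_spacing
    xs <- axis_coords(cd[1], cs[1]); ys <- axis_coords(cd[2], cs[2])
    zs <- axis_coords(cd[3], cs[3])
    ct <- array(params$air_hu, cd)
    body <- body_mask(xs, ys, zs, geom)
    ct[body] <- params$body_hu
    for (l in 1:2)
      ct[ellipsoid_mask(xs, ys, zs, geom$lung_centres[l, ], geom$lung_semi)] <-
        params$lung_hu
    ct[bronchi_mask(xs, ys, zs, geom)] <- params$lung_hu
    for (i in seq_len(n_nodes))
      ct <- paint_sphere(ct, xs, ys, zs, nodes$centres[i, ],
                         nodes$diam[i] / 2, params$node_hu)
    for (i in seq_len(n_dis))
      ct <- paint_sphere(ct, xs, ys, zs, dis$centres[i, ], dis$diam[i] / 2,
                         params$node_hu)
    ct <- ct + array(rnorm(length(ct), 0, params$ct_noise_sd), dim(ct))

    ## ---- PET on its native grid ------------------------------------
    ps <- profile$pet_spacing
    pd <- pmax(8L, as.integer(round(cd * cs / ps)))
    pxs <- axis_coords(pd[1], ps[1]); pys <- axis_coords(pd[2], ps[2])
    pzs <- axis_coords(pd[3], ps[3])
    pet <- array(0, pd)
    pet[body_mask(pxs, pys, pzs, geom)] <- bg
    for (l in 1:2)
      pet[ellipsoid_mask(pxs, pys, pzs, geom$lung_centres[l, ],
                         geom$lung_semi)] <- params$lung_suv
    pet[bronchi_mask(pxs, pys, pzs, geom)] <- params$lung_suv
    for (i in seq_len(n_nodes))
      pet <- paint_sphere(pet, pxs, pys, pzs, nodes$centres[i, ],
                          nodes$diam[i] / 2,
                          bg + suv[i] * profile$contrast_gain)
    for (i in seq_len(n_dis))
      pet <- paint_sphere(pet, pxs, pys, pzs, dis$centres[i, ],
                          dis$diam[i] / 2,
                          bg + dis_suv[i] * profile$contrast_gain)
    pet <- pet + array(rnorm(length(pet), 0, profile$pet_noise_sd), dim(pet))
    pet[pet < 0] <- 0

    ann <- data.frame(
      patient_id = rep(patient_id, n_nodes),
      x_mm = nodes$centres[, 1], y_mm = nodes$centres[, 2],
      z_mm = nodes$centres[, 3],
      source = rep("ground_truth", n_nodes))
    class(ann) <- c("node_annotations", "data.frame")

    structure(list(
      patient_id = patient_id,
      scanner_id = profile$id,
      ct = volume3d(ct, cs, modality = "CT_HU"),
      pet = volume3d(pet, ps, modality = "PET_SUV"),
      nodes = ann,
      node_diameters = nodes$diam,
      background_suv = bg,
      distractors = dis,
      geometry = geom),
      class = "patient_scan")
  })
}

body_mask <- function(xs, ys, zs, geom) {
  m <- field3(((xs - geom$centre[1]) / geom$body_semi[1])^2,
              ((ys - geom$centre[2]) / geom$body_semi[2])^2,
              rep(0, length(zs))) <= 1
  inz <- zs >= geom$body_z[1] & zs <= geom$body_z[2]
  m & rep(inz, each = length(xs) * length(ys))
}

bronchi_mask <- function(xs, ys, zs, geom) {
  b <- geom$bronchi
  r2 <- field3(rep(0, length(xs)), (ys - b$y)^2, (zs - b$z)^2) <= b$radius^2
  inx <- abs(xs - geom$centre[1]) <= b$half_len
  r2 & rep(inx, times = length(ys) * length(zs))
}

distractor_sites <- function(n, geom) {
  if (n == 0) return(list(centres = matrix(numeric(), 0, 3),
                          diam = numeric()))
  centres <- matrix(NA_real_, n, 3)
  diam <- runif(n, 8, 16)
  for (i in seq_len(n)) {
    side <- sample(c(-1, 1), 1)
    centres[i, ] <- c(
      geom$centre[1] + runif(1, -40, 40),
      # anterior/posterior chest wall: inside the body, outside lungs and
      # mediastinum, still within the 256-mm central crop window
      geom$centre[2] + side * (geom$lung_semi[2] + runif(1, 12, 20)),
      geom$centre[3] + runif(1, -0.18, 0.18) * geom$extent[3])
  }
  list(centres = centres, diam = diam)
}

#' Generate a cohort of phantoms
#'
#' Per-patient seeds are derived deterministically from the cohort seed, so a
#' cohort is reproducible run-to-run and any patient can be regenerated in
#' isolation.
#'
#' @param n_patients number of phantoms (>= 1).
#' @param params a [phantom_params()]; its `seed` field is overridden per
#'   patient.
#' @param profile a [scanner_profile()].
#' @param seed cohort seed.
#' @param id_prefix prefix for patient identifiers.
#' @return A `phantom_cohort`: list with `scans`, `profile`, `params`,
#'   `seed`.
#' @export
generate_cohort <- function(n_patients, params, profile, seed = 1L,
                            id_prefix = NULL) {
  if (n_patients < 1) stop("generate_cohort: n_patients must be >= 1",
                           call. = FALSE)
  id_prefix <- id_prefix %||% profile$id
  patient_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                              n_patients))
  scans <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    p <- params
    p$seed <- patient_seeds[i]
    scans[[i]] <- generate_phantom(p, profile,
                                   sprintf("%s_p%03d", id_prefix, i))
  }
  structure(list(scans = scans, profile = profile, params = params,
                 seed = seed), class = "phantom_cohort")
}

#' Write a cohort to disk
#'
#' NIfTI pair per patient, one ground-truth node CSV, and a JSON manifest
#' recording parameters, profile and seed.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_nodes <- list()
  for (scan in cohort$scans) {
    write_volume(scan$ct, file.path(dir, paste0(scan$patient_id, "_ct.nii")),
                 datatype = "float")
    write_volume(scan$pet, file.path(dir, paste0(scan$patient_id, "_pet.nii")),
                 datatype = "float")
    all_nodes[[scan$patient_id]] <- as.data.frame(scan$nodes)
  }
  nodes <- do.call(rbind, c(all_nodes, list(make.row.names = FALSE)))
  write.csv(nodes, file.path(dir, "ground_truth_nodes.csv"),
            row.names = FALSE)
  manifest <- list(
    n_patients = length(cohort$scans),
    patient_ids = vapply(cohort$scans, `[[`, "", "patient_id"),
    seed = cohort$seed,
    profile = unclass(cohort$profile),
    params = unclass(cohort$params)[setdiff(names(cohort$params),
                                            c("n_nodes", "n_distractors"))])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
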