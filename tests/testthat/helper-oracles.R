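# Brute-force reference implementations, independent of the package's
# optimised code paths.

# one morphology pass with the face-connected element; outside = background
oracle_morph_pass <- function(mask, dilate) {
  d <- dim(mask)
  out <- array(0L, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    nb <- c(mask[i, j, k],
            if (i > 1) mask[i - 1, j, k] else 0L,
            if (i < d[1]) mask[i + 1, j, k] else 0L,
            if (j > 1) mask[i, j - 1, k] else 0L,
            if (j < d[2]) mask[i, j + 1, k] else 0L,
            if (k > 1) mask[i, j, k - 1] else 0L,
            if (k < d[3]) mask[i, j, k + 1] else 0L)
    if (length(nb) < 7L) nb <- c(nb, 0L)   # clipped neighbours = background
    out[i, j, k] <- if (dilate) max(nb) else min(nb)
  }
  out
}

oracle_morph <- function(mask, iters, dilate) {
  for (t in seq_len(iters)) mask <- oracle_morph_pass(mask, dilate)
  mask
}

# lattice count of a sphere: voxels of a spacing-1 grid within r of `centre`
# (voxel coordinates, possibly fractional)
oracle_sphere_count <- function(centre, r) {
  cnt <- 0L
  for (i in floor(centre[1] - r):ceiling(centre[1] + r))
    for (j in floor(centre[2] - r):ceiling(centre[2] + r))
      for (k in floor(centre[3] - r):ceiling(centre[3] + r))
        if ((i - centre[1])^2 + (j - centre[2])^2 + (k - centre[3])^2 <= r^2)
          cnt <- cnt + 1L
  cnt
}

# Clopper-Pearson by direct bisection of the binomial tails
oracle_clopper_pearson <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) > alpha / 2,
           0, 1)
  upper <- if (x == n) 1 else
    bisect(function(p) pbinom(x, n, p) < alpha / 2, 0, 1)
  c(lower = lower, upper = upper)
}

# textbook two-rater kappa from the 2x2 contingency table
oracle_kappa <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# connected components by repeated neighbour expansion (26-connectivity)
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextl <- 0L
  idx <- which(mask > 0L)
  for (start in idx) {
    if (lab[start] > 0L) next
    nextl <- nextl + 1L
    frontier <- start
    lab[start] <- nextl
    while (length(frontier)) {
      newf <- integer()
      for (v in frontier) {
        ai <- arrayInd(v, d)
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
          if (!di && !dj && !dk) next
          p <- ai + c(di, dj, dk)
          if (any(p < 1) || any(p > d)) next
          li <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
          if (mask[li] > 0L && lab[li] == 0L) {
            lab[li] <- nextl
            newf <- c(newf, li)
          }
        }
      }
      frontier <- newf
    }
  }
  attr(lab, "n_components") <- nextl
  lab
}

# small standardised crop with both modalities, for unit tests
make_test_crop <- function(dims = c(32L, 32L, 24L), patient_id = "tp01",
                           seed = 1) {
  set.seed(seed)
  structure(list(
    ct = volume3d(array(rnorm(prod(dims)), dims), c(1, 1, 1),
                  modality = "CT_HU"),
    pet = volume3d(array(abs(rnorm(prod(dims))), dims), c(1, 1, 1),
                   modality = "PET_SUV"),
    z_range = c(1L, dims[3]), xy_offset = c(0L, 0L),
    patient_id = patient_id, nodes = NULL, standardised = TRUE),
    class = "thorax_crop")
}

empty_nodes <- function() {
  df <- data.frame(patient_id = character(), x_mm = numeric(),
                   y_mm = numeric(), z_mm = numeric(), source = character())
  class(df) <- c("node_annotations", "data.frame")
  df
}

nodes_df <- function(patient_id, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  df <- data.frame(patient_id = rep_len(patient_id, nrow(xyz)),
                   x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
                   source = rep("ground_truth", nrow(xyz)))
  class(df) <- c("node_annotations", "data.frame")
  df
}

# small phantom parameters so unit tests run in seconds; proportions match
# the full-size generator
small_phantom_params <- function(seed = 1L, ...) {
  phantom_params(grid_dim = c(64L, 64L, 48L), grid_spacing = c(2, 2, 2),
                 node_diameter_range = c(6, 10),
                 node_count_probs = c(0.3, 0.3, 0.3, 0.1, 0),
                 seed = seed, ...)
}
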