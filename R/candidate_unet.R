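#' Phase-one (candidate generation) configuration
#'
#' Published defaults: 15-mm spherical surrogate labels, Dice loss, Adam at
#' learning rate 1e-5 for 20 epochs, regions under 300 voxels removed,
#' 3-iteration face-connected dilation of the survivors. The U-Net depth and
#' width are configurable so that desk-scale runs can shrink the network
#' without changing pipeline semantics.
#'
#' @param sphere_radius surrogate label radius, mm.
#' @param min_region_voxels region volume filter (voxel count).
#' @param dilation_iters dilation iterations (connectivity-one element).
#' @param epochs,learning_rate training schedule.
#' @param mask_threshold probability cut binarising the U-Net output.
#' @param base_width channels of the first encoder level (doubled per
#'   level).
#' @param levels number of down/up-sampling levels.
#' @param max_train_slices cap on training slices (evenly subsampled when
#'   exceeded); `Inf` keeps all.
#' @return A `candidate_config` list.
#' @export
candidate_config <- function(sphere_radius = 15, min_region_voxels = 300L,
                             dilation_iters = 3L, epochs = 20L,
                             learning_rate = 1e-5, mask_threshold = 0.5,
                             base_width = 64L, levels = 4L,
                             max_train_slices = Inf) {
  stopifnot(sphere_radius > 0, min_region_voxels >= 1, dilation_iters >= 0,
            epochs >= 1, learning_rate > 0, mask_threshold > 0,
            mask_threshold < 1, base_width >= 1, levels >= 1)
  structure(c(as.list(environment()),
              list(loss = "dice", optimiser = "adam")),
            class = "candidate_config")
}

#' Spherical surrogate labels for point-annotated nodes
#'
#' The union over nodes of all voxels whose centre lies within
#' `radius` mm (Euclidean, physical coordinates) of the node position;
#' spheres are truncated at the grid borders. Nodes are point positions, not
#' contours, so a generous sphere stands in for the unknown node extent.
#'
#' @param nodes `node_annotations` (physical mm).
#' @param grid a [volume3d] defining the label grid (typically the crop CT).
#' @param radius sphere radius, mm.
#' @return integer 0/1 array of the grid's dimensions.
#' @export
make_sphere_labels <- function(nodes, grid, radius = 15) {
  d <- dim(grid$values)
  mask <- array(0L, d)
  if (!nrow(nodes)) return(mask)
  for (r in seq_len(nrow(nodes))) {
    p <- c(nodes$x_mm[r], nodes$y_mm[r], nodes$z_mm[r])
    idx <- (p - grid$origin) / grid$spacing + 1   # fractional voxel index
    if (any(idx < 0.5) || any(idx > d + 0.5))
      stop("make_sphere_labels: node ", r, " (patient ",
           nodes$patient_id[r], ") lies outside the grid", call. = FALSE)
    lo <- pmax(1L, ceiling(idx - radius / grid$spacing))
    hi <- pmin(d, floor(idx + radius / grid$spacing))
    if (any(lo > hi)) next
    ax <- (grid$origin[1] + (seq(lo[1], hi[1]) - 1) * grid$spacing[1] - p[1])^2
    ay <- (grid$origin[2] + (seq(lo[2], hi[2]) - 1) * grid$spacing[2] - p[2])^2
    az <- (grid$origin[3] + (seq(lo[3], hi[3]) - 1) * grid$spacing[3] - p[3])^2
    sub <- field3(ax, ay, az) <= radius^2
    block <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    block[sub] <- 1L
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- block
  }
  mask
}

# ---- U-Net --------------------------------------------------------------

unet_widths <- function(cfg) cfg$base_width * 2^(seq_len(cfg$levels) - 1)

#' Initialise a 2D U-Net
#'
#' Standard encoder-decoder: `levels` encoder levels of two 3x3
#' convolutions + ReLU and 2x2 max pooling, a two-convolution bottleneck,
#' and a mirrored decoder using nearest-neighbour upsampling, a
#' channel-halving convolution and skip concatenation, ending in a 1x1
#' convolution with a sigmoid head.
#'
#' @param cfg a [candidate_config()].
#' @param in_ch input channels (2: CT and PET).
#' @param seed RNG seed for He initialisation.
#' @return An untrained `unet_model`.
#' @export
unet_init <- function(cfg = candidate_config(), in_ch = 2L, seed = 1L) {
  w <- unet_widths(cfg)
  L <- cfg$levels
  params <- list()
  with_seed(seed, {
    cin <- in_ch
    for (l in seq_len(L)) {
      params[[sprintf("e%dc1_w", l)]] <- he_weights(c(3, 3, cin, w[l]),
                                                    9 * cin)
      params[[sprintf("e%dc1_b", l)]] <- numeric(w[l])
      params[[sprintf("e%dc2_w", l)]] <- he_weights(c(3, 3, w[l], w[l]),
                                                    9 * w[l])
      params[[sprintf("e%dc2_b", l)]] <- numeric(w[l])
      cin <- w[l]
    }
    wb <- 2 * w[L]
    params$b_c1_w <- he_weights(c(3, 3, w[L], wb), 9 * w[L])
    params$b_c1_b <- numeric(wb)
    params$b_c2_w <- he_weights(c(3, 3, wb, wb), 9 * wb)
    params$b_c2_b <- numeric(wb)
    cabove <- wb
    for (l in rev(seq_len(L))) {
      params[[sprintf("d%dup_w", l)]] <- he_weights(c(3, 3, cabove, w[l]),
                                                    9 * cabove)
      params[[sprintf("d%dup_b", l)]] <- numeric(w[l])
      params[[sprintf("d%dc1_w", l)]] <- he_weights(c(3, 3, 2 * w[l], w[l]),
                                                    9 * 2 * w[l])
      params[[sprintf("d%dc1_b", l)]] <- numeric(w[l])
      params[[sprintf("d%dc2_w", l)]] <- he_weights(c(3, 3, w[l], w[l]),
                                                    9 * w[l])
      params[[sprintf("d%dc2_b", l)]] <- numeric(w[l])
      cabove <- w[l]
    }
    params$head_w <- he_weights(c(1, 1, w[1], 1), w[1])
    params$head_b <- numeric(1)
  })
  structure(list(params = params, cfg = cfg, in_ch = in_ch,
                 trained = FALSE, loss_trace = numeric(), type = "unet"),
            class = "unet_model")
}

unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  L <- model$cfg$levels
  cache <- list(x = x, skip = vector("list", L), pool = vector("list", L),
                enc = vector("list", L), dec = list())
  cur <- x
  for (l in seq_len(L)) {
    a1 <- relu(conv2d(cur, p[[sprintf("e%dc1_w", l)]],
                      p[[sprintf("e%dc1_b", l)]]))
    a2 <- relu(conv2d(a1, p[[sprintf("e%dc2_w", l)]],
                      p[[sprintf("e%dc2_b", l)]]))
    mp <- .maxpool2d_fw_cpp(a2)
    cache$enc[[l]] <- list(input = cur, a1 = a1, a2 = a2, idx = mp$idx)
    cache$skip[[l]] <- a2
    cur <- mp$y
  }
  b1 <- relu(conv2d(cur, p$b_c1_w, p$b_c1_b))
  b2 <- relu(conv2d(b1, p$b_c2_w, p$b_c2_b))
  cache$bott <- list(input = cur, b1 = b1, b2 = b2)
  cur <- b2
  for (l in rev(seq_len(L))) {
    up <- upsample2x(cur)
    u <- relu(conv2d(up, p[[sprintf("d%dup_w", l)]],
                     p[[sprintf("d%dup_b", l)]]))
    cat_ <- concat_ch(u, cache$skip[[l]])
    c1 <- relu(conv2d(cat_, p[[sprintf("d%dc1_w", l)]],
                      p[[sprintf("d%dc1_b", l)]]))
    c2 <- relu(conv2d(c1, p[[sprintf("d%dc2_w", l)]],
                      p[[sprintf("d%dc2_b", l)]]))
    cache$dec[[as.character(l)]] <- list(input = cur, up = up, u = u,
                                         cat = cat_, c1 = c1, c2 = c2)
    cur <- c2
  }
  logits <- conv2d(cur, p$head_w, p$head_b)
  prob <- sigmoid(logits)
  cache$logits <- logits
  cache$prob <- prob
  if (keep_cache) list(prob = prob, cache = cache) else list(prob = prob)
}

unet_backward <- function(model, cache, dlogits) {
  p <- model$params
  L <- model$cfg$levels
  g <- list()
  dec_last <- cache$dec[[as.character(1L)]]
  bw <- conv2d_bw(dec_last$c2, p$head_w, dlogits)
  g$head_w <- bw$dw; g$head_b <- bw$db
  dcur <- bw$dx
  dskip <- vector("list", L)
  for (l in seq_len(L)) {       # reverse of decoder execution order (L..1)
    dc <- cache$dec[[as.character(l)]]
    dcur <- relu_bw(dcur, dc$c2)
    bw <- conv2d_bw(dc$c1, p[[sprintf("d%dc2_w", l)]], dcur)
    g[[sprintf("d%dc2_w", l)]] <- bw$dw
    g[[sprintf("d%dc2_b", l)]] <- bw$db
    dc1 <- relu_bw(bw$dx, dc$c1)
    bw <- conv2d_bw(dc$cat, p[[sprintf("d%dc1_w", l)]], dc1)
    g[[sprintf("d%dc1_w", l)]] <- bw$dw
    g[[sprintf("d%dc1_b", l)]] <- bw$db
    wl <- dim(dc$u)[3]
    du <- bw$dx[, , seq_len(wl), drop = FALSE]
    dskip[[l]] <- bw$dx[, , wl + seq_len(dim(dc$cat)[3] - wl), drop = FALSE]
    du <- relu_bw(du, dc$u)
    bw <- conv2d_bw(dc$up, p[[sprintf("d%dup_w", l)]], du)
    g[[sprintf("d%dup_w", l)]] <- bw$dw
    g[[sprintf("d%dup_b", l)]] <- bw$db
    dcur <- upsample2x_bw(bw$dx)
  }
  bo <- cache$bott
  db2 <- relu_bw(dcur, bo$b2)
  bw <- conv2d_bw(bo$b1, p$b_c2_w, db2)
  g$b_c2_w <- bw$dw; g$b_c2_b <- bw$db
  db1 <- relu_bw(bw$dx, bo$b1)
  bw <- conv2d_bw(bo$input, p$b_c1_w, db1)
  g$b_c1_w <- bw$dw; g$b_c1_b <- bw$db
  dcur <- bw$dx
  for (l in rev(seq_len(L))) {
    en <- cache$enc[[l]]
    da2 <- .maxpool2d_bw_cpp(dcur, en$idx, dim(en$a2)) + dskip[[l]]
    da2 <- relu_bw(da2, en$a2)
    bw <- conv2d_bw(en$a1, p[[sprintf("e%dc2_w", l)]], da2)
    g[[sprintf("e%dc2_w", l)]] <- bw$dw
    g[[sprintf("e%dc2_b", l)]] <- bw$db
    da1 <- relu_bw(bw$dx, en$a1)
    bw <- conv2d_bw(en$input, p[[sprintf("e%dc1_w", l)]], da1)
    g[[sprintf("e%dc1_w", l)]] <- bw$dw
    g[[sprintf("e%dc1_b", l)]] <- bw$db
    dcur <- bw$dx
  }
  g
}

crop_slice_input <- function(crop, z) {
  d <- dim(crop$ct$values)
  array(c(crop$ct$values[, , z], crop$pet$values[, , z]), c(d[1], d[2], 2L))
}

#' Train the phase-one U-Net
#'
#' Trains slice-by-slice with a Dice loss and Adam. Only slices containing
#' at least one positive label voxel are used. All randomness (weight
#' initialisation, slice shuffling) derives from `seed`.
#'
#' @param crops list of standardised `thorax_crop`s.
#' @param labels list of 0/1 label arrays aligned with `crops` (see
#'   [make_sphere_labels()]).
#' @param cfg a [candidate_config()].
#' @param seed RNG seed.
#' @param model optionally, an existing `unet_model` to continue training.
#' @return A trained `unet_model` with a per-epoch `loss_trace`.
#' @export
train_unet <- function(crops, labels, cfg = candidate_config(), seed = 1L,
                       model = NULL) {
  stopifnot(length(crops) == length(labels), length(crops) >= 1)
  slices <- list()
  for (i in seq_along(crops)) {
    pos_z <- which(apply(labels[[i]], 3, function(s) any(s > 0)))
    for (z in pos_z)
      slices[[length(slices) + 1L]] <-
        list(x = crop_slice_input(crops[[i]], z), g = labels[[i]][, , z])
  }
  train_unet_slices(slices, cfg, seed, model)
}

# Slice-level trainer: `slices` is a list of list(x = [H,W,2] input,
# g = [H,W] label); used directly by the pipeline so whole crops need not
# stay resident.
train_unet_slices <- function(slices, cfg = candidate_config(), seed = 1L,
                              model = NULL) {
  if (!length(slices))
    stop("train_unet: no slices with positive labels in the training set",
         call. = FALSE)
  if (is.finite(cfg$max_train_slices) &&
      length(slices) > cfg$max_train_slices)
    slices <- slices[unique(round(seq(1, length(slices),
                                      length.out = cfg$max_train_slices)))]
  if (is.null(model)) model <- unet_init(cfg, in_ch = 2L, seed = seed)
  adam <- adam_init(model$params)
  trace <- numeric(cfg$epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(slices))
      ep_loss <- 0
      for (it in ord) {
        x <- slices[[it]]$x
        gtruth <- slices[[it]]$g
        fwd <- unet_forward(model, x, keep_cache = TRUE)
        pr <- fwd$prob[, , 1]
        dl <- dice_loss(pr, gtruth)
        ep_loss <- ep_loss + dl$loss
        dlogits <- array(dl$dp * pr * (1 - pr), dim(fwd$prob))
        grads <- unet_backward(model, fwd$cache, dlogits)
        upd <- adam_step(model$params, grads, adam, cfg$learning_rate)
        model$params <- upd$params
        adam <- upd$state
      }
      trace[ep] <- ep_loss / length(slices)
    }
  })
  model$loss_trace <- c(model$loss_trace, trace)
  model$trained <- TRUE
  model$cfg <- cfg
  model
}

#' Predict candidate regions for one patient
#'
#' Runs every slice of the crop through the U-Net (not only labelled ones),
#' binarises the per-slice probability maps at the mask threshold, stacks
#' them to 3D and extracts 26-connected components.
#'
#' @param crop a standardised `thorax_crop`.
#' @param model a trained `unet_model`.
#' @param cfg a [candidate_config()]; defaults to the model's.
#' @return list of `candidate_region`s (unfiltered, pre-dilation).
#' @export
predict_candidates <- function(crop, model, cfg = NULL) {
  if (is.null(model) || !isTRUE(model$trained))
    stop("predict_candidates: model is untrained", call. = FALSE)
  cfg <- cfg %||% model$cfg
  d <- dim(crop$ct$values)
  mask <- array(0L, d)
  for (z in seq_len(d[3])) {
    pr <- unet_forward(model, crop_slice_input(crop, z))$prob
    mask[, , z] <- as.integer(pr[, , 1] > cfg$mask_threshold)
  }
  labels_to_regions(label_components(mask), crop$patient_id)
}

candidate_region <- function(voxels, patient_id = NA_character_) {
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, volume = nrow(voxels),
                 bounding_box = rbind(min = apply(voxels, 2, min),
                                      max = apply(voxels, 2, max)),
                 patient_id = patient_id),
            class = "candidate_region")
}

labels_to_regions <- function(lab, patient_id = NA_character_) {
  n <- attr(lab, "n_components") %||% max(lab)
  if (n == 0L) return(list())
  vox <- which(lab > 0L)
  d <- dim(lab)
  ind <- arrayInd(vox, d)
  by_lab <- split(seq_along(vox), lab[vox])
  unname(lapply(by_lab[order(as.integer(names(by_lab)))], function(rows)
    candidate_region(ind[rows, , drop = FALSE], patient_id)))
}

regions_to_mask <- function(regions, d) {
  mask <- array(0L, d)
  for (r in regions) mask[r$voxels] <- 1L
  mask
}

#' Filter small candidate regions and dilate the survivors
#'
#' Regions under `min_region_voxels` voxels are removed (too small to be
#' node candidates); the survivors are dilated `dilation_iters` iterations
#' with the face-connected element, and dilated regions that touch are
#' merged into single 26-connected components.
#'
#' @param regions list of `candidate_region`s on one grid.
#' @param grid_dim dimensions of that grid.
#' @param cfg a [candidate_config()].
#' @return list of post-dilation `candidate_region`s.
#' @export
filter_and_dilate <- function(regions, grid_dim,
                              cfg = candidate_config()) {
  keep <- Filter(function(r) r$volume >= cfg$min_region_voxels, regions)
  if (!length(keep)) return(list())
  pid <- keep[[1]]$patient_id
  mask <- regions_to_mask(keep, grid_dim)
  mask <- binary_dilate(mask, cfg$dilation_iters)
  labels_to_regions(label_components(mask), pid)
}

#' Phase-one candidate sensitivity
#'
#' Fraction of ground-truth nodes whose centre voxel lies inside at least
#' one (post-dilation) candidate region.
#'
#' @param regions list of `candidate_region`s on the crop grid.
#' @param nodes `node_annotations` (physical mm).
#' @param geometry a [volume3d] giving the crop grid (e.g. `crop$ct`).
#' @return fraction in `[0, 1]`; `NaN` with a warning when there are no
#'   nodes.
#' @export
candidate_sensitivity <- function(regions, nodes, geometry) {
  if (!nrow(nodes)) {
    warning("candidate_sensitivity: no ground-truth nodes; returning NaN")
    return(NaN)
  }
  d <- dim(geometry$values)
  mask <- regions_to_mask(regions, d)
  covered <- vapply(seq_len(nrow(nodes)), function(r) {
    v <- physical_to_voxel(geometry,
                           c(nodes$x_mm[r], nodes$y_mm[r], nodes$z_mm[r]))
    if (any(v < 1) || any(v > d)) return(FALSE)
    mask[v] > 0L
  }, logical(1))
  mean(covered)
}
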