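#' Phase-two (false-positive reduction) configuration
#'
#' Published defaults: 64-mm cubes on an 8-mm lattice, positive when a node
#' lies within 16 mm of the cube centre (inclusive), negatives undersampled
#' by eight, a 50-layer 3D residual network (bottleneck blocks 3-4-6-3)
#' trained 20 epochs with batch size 32, Adam at 1e-5 and cross-entropy,
#' fine-tuned at 1e-8, and a summed-score threshold of 18. Network depth and
#' width are configurable downward for CPU-scale runs without changing any
#' pipeline semantics.
#'
#' @param cube_side cube side length, mm (divisible by `grid_stride`).
#' @param grid_stride lattice interval, mm.
#' @param positive_radius node-to-centre distance defining a positive cube,
#'   mm.
#' @param undersample_factor negative undersampling factor.
#' @param epochs,batch_size,learning_rate training schedule.
#' @param finetune_learning_rate learning rate for transfer learning.
#' @param agg_threshold summed-score positivity threshold (strictly above).
#' @param block `"bottleneck"` (1-3-1 convolutions) or `"basic"` (3-3).
#' @param blocks residual blocks per stage.
#' @param widths output channels per stage.
#' @param stem_width channels of the stride-2 stem convolution.
#' @return A `cube_config` list with the derived `resnet_depth`.
#' @export
cube_config <- function(cube_side = 64, grid_stride = 8,
                        positive_radius = 16, undersample_factor = 8L,
                        epochs = 20L, batch_size = 32L,
                        learning_rate = 1e-5, finetune_learning_rate = 1e-8,
                        agg_threshold = 18,
                        block = c("bottleneck", "basic"),
                        blocks = c(3L, 4L, 6L, 3L),
                        widths = c(256L, 512L, 1024L, 2048L),
                        stem_width = 64L) {
  block <- match.arg(block)
  stopifnot(cube_side %% grid_stride == 0, positive_radius < cube_side / 2,
            undersample_factor >= 1, length(blocks) == length(widths),
            epochs >= 1, batch_size >= 1)
  cfg <- structure(c(as.list(environment()), list(loss = "cross-entropy")),
                   class = "cube_config")
  cfg$resnet_depth <- 2L + sum(blocks) * if (block == "bottleneck") 3L else 2L
  cfg
}

#' Enumerate cube centres over candidate regions
#'
#' Centres are the points of a regular `grid_stride`-mm lattice anchored at
#' the crop origin whose voxel lies inside any candidate region; each centre
#' is listed once even where regions overlap.
#'
#' @param regions list of `candidate_region`s on the crop grid.
#' @param geometry a [volume3d] for that grid.
#' @param cfg a [cube_config()].
#' @return integer matrix (n x 3) of 1-based voxel indices, with the
#'   physical mm coordinates in `attr(, "mm")`.
#' @export
enumerate_cubes <- function(regions, geometry, cfg = cube_config()) {
  d <- dim(geometry$values)
  step <- round(cfg$grid_stride / geometry$spacing)
  stopifnot(all(step >= 1))
  mask <- regions_to_mask(regions, d)
  gx <- seq(1L, d[1], by = step[1])
  gy <- seq(1L, d[2], by = step[2])
  gz <- seq(1L, d[3], by = step[3])
  sub <- mask[gx, gy, gz, drop = FALSE]
  hits <- which(sub > 0L)
  ind <- arrayInd(hits, dim(sub))
  centres <- cbind(gx[ind[, 1]], gy[ind[, 2]], gz[ind[, 3]])
  storage.mode(centres) <- "integer"
  attr(centres, "mm") <- voxel_to_physical(geometry, centres)
  centres
}

#' Label cubes by proximity to pathological nodes
#'
#' Positive iff some node lies within `positive_radius` mm (Euclidean,
#' inclusive at the boundary) of the cube centre.
#'
#' @param centres_mm numeric matrix (n x 3) of centre coordinates, mm (e.g.
#'   `attr(enumerate_cubes(...), "mm")`).
#' @param nodes `node_annotations`.
#' @param cfg a [cube_config()].
#' @return integer vector of 0/1 labels.
#' @export
label_cubes <- function(centres_mm, nodes, cfg = cube_config()) {
  if (!nrow(centres_mm)) return(integer())
  if (!nrow(nodes)) return(integer(nrow(centres_mm)))
  nd <- as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")])
  lab <- integer(nrow(centres_mm))
  for (i in seq_len(nrow(centres_mm))) {
    d2 <- rowSums(sweep(nd, 2, centres_mm[i, ])^2)
    lab[i] <- as.integer(min(d2) <= cfg$positive_radius^2)
  }
  lab
}

#' Undersample negative cubes
#'
#' Keeps every positive and a uniform random subset of
#' `round(n_neg / factor)` negatives, drawn once, without replacement,
#' reproducibly from `seed`.
#'
#' @param labels 0/1 cube labels.
#' @param factor undersampling factor (>= 1).
#' @param seed RNG seed.
#' @return sorted integer indices of the retained cubes.
#' @export
undersample_negatives <- function(labels, factor = 8, seed = 1L) {
  if (factor < 1) stop("undersample_negatives: factor must be >= 1",
                       call. = FALSE)
  neg <- which(labels == 0L)
  n_keep <- round_half_up(length(neg) / factor, 0)
  kept_neg <- with_seed(seed, sample(neg, min(n_keep, length(neg))))
  sort(c(which(labels == 1L), kept_neg))
}

#' Extract a two-channel cube patch
#'
#' A `cube_side`-mm cube (64^3 voxels at 1 mm) centred on a lattice voxel,
#' channels (CT, PET). Voxels outside the crop are filled with the
#' standardised equivalents of -1000 HU / 0 SUV.
#'
#' @param crop a standardised `thorax_crop`.
#' @param centre length-3 1-based voxel index of the cube centre.
#' @param cfg a [cube_config()].
#' @param stats the `norm_stats` used to standardise the crop (defines the
#'   fill values).
#' @return numeric array `[side, side, side, 2]`.
#' @export
extract_cube <- function(crop, centre, cfg = cube_config(), stats = NULL) {
  d <- dim(crop$ct$values)
  if (any(centre < 1) || any(centre > d))
    stop("extract_cube: centre outside the crop", call. = FALSE)
  side <- round(cfg$cube_side / crop$ct$spacing[1])
  half <- side %/% 2
  fill_ct <- if (!is.null(stats)) (-1000 - stats$ct_mean) / stats$ct_sd else -1000
  fill_pet <- if (!is.null(stats)) (0 - stats$pet_mean) / stats$pet_sd else 0
  out <- array(0, c(side, side, side, 2L))
  rng <- lapply(1:3, function(a) (centre[a] - half + 1L):(centre[a] + half))
  inside <- lapply(1:3, function(a) which(rng[[a]] >= 1L & rng[[a]] <= d[a]))
  src <- lapply(1:3, function(a) rng[[a]][inside[[a]]])
  ctp <- array(fill_ct, c(side, side, side))
  petp <- array(fill_pet, c(side, side, side))
  ctp[inside[[1]], inside[[2]], inside[[3]]] <-
    crop$ct$values[src[[1]], src[[2]], src[[3]], drop = FALSE]
  petp[inside[[1]], inside[[2]], inside[[3]]] <-
    crop$pet$values[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out[, , , 1] <- ctp
  out[, , , 2] <- petp
  out
}

# ---- cube dataset -------------------------------------------------------

#' Assemble a cube dataset over several patients
#'
#' Patches are extracted lazily from the stored crops at training time, so
#' only centre tables are materialised here.
#'
#' @param crops named list of standardised `thorax_crop`s (names =
#'   patient ids).
#' @param regions_by_patient named list of candidate-region lists.
#' @param nodes_by_patient named list of `node_annotations` (crop frame).
#' @param cfg a [cube_config()].
#' @param stats `norm_stats` for fill values.
#' @return A `cube_dataset`: `crops`, `items` (data.frame with patient,
#'   voxel centre, mm centre, label), `cfg`, `stats`.
#' @export
cube_dataset <- function(crops, regions_by_patient, nodes_by_patient,
                         cfg = cube_config(), stats = NULL) {
  items <- list()
  for (pid in names(crops)) {
    centres <- enumerate_cubes(regions_by_patient[[pid]], crops[[pid]]$ct,
                               cfg)
    if (!nrow(centres)) next
    mm <- attr(centres, "mm")
    lab <- label_cubes(mm, nodes_by_patient[[pid]], cfg)
    items[[pid]] <- data.frame(
      patient_id = pid, vx = centres[, 1], vy = centres[, 2],
      vz = centres[, 3], x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3],
      label = lab)
  }
  items <- if (length(items)) do.call(rbind, c(items, list(make.row.names = FALSE)))
    else data.frame(patient_id = character(), vx = integer(),
                    vy = integer(), vz = integer(), x_mm = numeric(),
                    y_mm = numeric(), z_mm = numeric(), label = integer())
  structure(list(crops = crops, items = items, cfg = cfg, stats = stats),
            class = "cube_dataset")
}

dataset_cube <- function(ds, row) {
  it <- ds$items[row, ]
  extract_cube(ds$crops[[it$patient_id]], c(it$vx, it$vy, it$vz), ds$cfg,
               ds$stats)
}

# ---- augmentation: random axis flips and right-angle rotations ----------

flip_axis4 <- function(x, a) {
  idx <- rep(list(quote(expr = )), 4)
  idx[[a]] <- rev(seq_len(dim(x)[a]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# 90-degree rotation in the plane of axes (a1, a2), k times
rot90_axes4 <- function(x, a1, a2, k) {
  k <- k %% 4
  if (k == 0) return(x)
  for (i in seq_len(k)) {
    perm <- 1:4
    perm[c(a1, a2)] <- c(a2, a1)
    x <- flip_axis4(aperm(x, perm), a1)
  }
  x
}

augment_cube <- function(x) {
  for (a in 1:3) if (runif(1) < 0.5) x <- flip_axis4(x, a)
  planes <- list(c(1, 2), c(2, 3), c(1, 3))
  for (pl in planes) {
    k <- sample(0:3, 1)
    if (k) x <- rot90_axes4(x, pl[1], pl[2], k)
  }
  x
}

# ---- 3D residual network ------------------------------------------------

#' Initialise the 3D residual network
#'
#' Stride-2 stem convolution, then stages of residual blocks (basic or
#' bottleneck), each stage downsampling by 2 via its first block; global
#' average pooling and a single-logit head.
#'
#' @param cfg a [cube_config()].
#' @param in_ch input channels.
#' @param seed RNG seed for He initialisation.
#' @return An untrained `resnet_model`.
#' @export
resnet_init <- function(cfg = cube_config(), in_ch = 2L, seed = 1L) {
  params <- list()
  with_seed(seed, {
    params$stem_w <- he_weights(c(3, 3, 3, in_ch, cfg$stem_width),
                                27 * in_ch)
    params$stem_b <- numeric(cfg$stem_width)
    cin <- cfg$stem_width
    for (s in seq_along(cfg$blocks)) {
      cout <- cfg$widths[s]
      cmid <- if (cfg$block == "bottleneck") max(1L, cout %/% 4L) else cout
      for (b in seq_len(cfg$blocks[s])) {
        key <- function(part) sprintf("s%db%d_%s", s, b, part)
        if (cfg$block == "bottleneck") {
          params[[key("c1_w")]] <- he_weights(c(1, 1, 1, cin, cmid), cin)
          params[[key("c1_b")]] <- numeric(cmid)
          params[[key("c2_w")]] <- he_weights(c(3, 3, 3, cmid, cmid),
                                              27 * cmid)
          params[[key("c2_b")]] <- numeric(cmid)
          params[[key("c3_w")]] <- he_weights(c(1, 1, 1, cmid, cout), cmid)
          params[[key("c3_b")]] <- numeric(cout)
        } else {
          params[[key("c1_w")]] <- he_weights(c(3, 3, 3, cin, cout),
                                              27 * cin)
          params[[key("c1_b")]] <- numeric(cout)
          params[[key("c2_w")]] <- he_weights(c(3, 3, 3, cout, cout),
                                              27 * cout)
          params[[key("c2_b")]] <- numeric(cout)
        }
        if (b == 1L || cin != cout) {
          params[[key("proj_w")]] <- he_weights(c(1, 1, 1, cin, cout), cin)
          params[[key("proj_b")]] <- numeric(cout)
        }
        cin <- cout
      }
    }
    # zero-initialised head: the network starts at probability 0.5 and the
    # residual trunk learns before the logit saturates
    params$fc_w <- numeric(cin)
    params$fc_b <- 0
  })
  structure(list(params = params, cfg = cfg, in_ch = in_ch,
                 trained = FALSE, loss_trace = numeric(), type = "resnet3d"),
            class = "resnet_model")
}

resnet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$cfg
  cache <- list(x = x, blocks = list())
  stem <- relu(conv3d(x, p$stem_w, p$stem_b, stride = 2L))
  cache$stem <- stem
  cur <- stem
  for (s in seq_along(cfg$blocks)) {
    for (b in seq_len(cfg$blocks[s])) {
      key <- function(part) sprintf("s%db%d_%s", s, b, part)
      stride <- if (b == 1L) 2L else 1L
      has_proj <- !is.null(p[[key("proj_w")]])
      skip <- if (has_proj)
        conv3d(cur, p[[key("proj_w")]], p[[key("proj_b")]], stride) else cur
      if (cfg$block == "bottleneck") {
        h1 <- relu(conv3d(cur, p[[key("c1_w")]], p[[key("c1_b")]]))
        h2 <- relu(conv3d(h1, p[[key("c2_w")]], p[[key("c2_b")]], stride))
        h3 <- conv3d(h2, p[[key("c3_w")]], p[[key("c3_b")]])
        y <- relu(h3 + skip)
        cache$blocks[[key("")]] <- list(input = cur, h1 = h1, h2 = h2,
                                        h3 = h3, skip = skip, y = y,
                                        stride = stride,
                                        has_proj = has_proj)
      } else {
        h1 <- relu(conv3d(cur, p[[key("c1_w")]], p[[key("c1_b")]], stride))
        h2 <- conv3d(h1, p[[key("c2_w")]], p[[key("c2_b")]])
        y <- relu(h2 + skip)
        cache$blocks[[key("")]] <- list(input = cur, h1 = h1, h2 = h2,
                                        skip = skip, y = y, stride = stride,
                                        has_proj = has_proj)
      }
      cur <- y
    }
  }
  d <- dim(cur)
  nspace <- prod(d[1:3])
  feat <- colMeans(matrix(cur, nrow = nspace, ncol = d[4]))
  logit <- sum(feat * p$fc_w) + p$fc_b
  cache$last <- cur
  cache$feat <- feat
  if (keep_cache) list(logit = logit, cache = cache)
  else list(logit = logit)
}

resnet_backward <- function(model, cache, dlogit) {
  p <- model$params
  cfg <- model$cfg
  g <- list()
  feat <- cache$feat
  g$fc_w <- dlogit * feat
  g$fc_b <- dlogit
  d <- dim(cache$last)
  nspace <- prod(d[1:3])
  dfeat <- dlogit * as.numeric(p$fc_w)
  dcur <- array(rep(dfeat / nspace, each = nspace), d)
  for (s in rev(seq_along(cfg$blocks))) {
    for (b in rev(seq_len(cfg$blocks[s]))) {
      key <- function(part) sprintf("s%db%d_%s", s, b, part)
      bc <- cache$blocks[[key("")]]
      dy <- relu_bw(dcur, bc$y)
      dskip <- dy
      if (cfg$block == "bottleneck") {
        bw <- conv3d_bw(bc$h2, p[[key("c3_w")]], dy)
        g[[key("c3_w")]] <- bw$dw; g[[key("c3_b")]] <- bw$db
        dh2 <- relu_bw(bw$dx, bc$h2)
        bw <- conv3d_bw(bc$h1, p[[key("c2_w")]], dh2, bc$stride)
        g[[key("c2_w")]] <- bw$dw; g[[key("c2_b")]] <- bw$db
        dh1 <- relu_bw(bw$dx, bc$h1)
        bw <- conv3d_bw(bc$input, p[[key("c1_w")]], dh1)
        g[[key("c1_w")]] <- bw$dw; g[[key("c1_b")]] <- bw$db
        dinput <- bw$dx
      } else {
        bw <- conv3d_bw(bc$h1, p[[key("c2_w")]], dy)
        g[[key("c2_w")]] <- bw$dw; g[[key("c2_b")]] <- bw$db
        dh1 <- relu_bw(bw$dx, bc$h1)
        bw <- conv3d_bw(bc$input, p[[key("c1_w")]], dh1, bc$stride)
        g[[key("c1_w")]] <- bw$dw; g[[key("c1_b")]] <- bw$db
        dinput <- bw$dx
      }
      if (bc$has_proj) {
        bw <- conv3d_bw(bc$input, p[[key("proj_w")]], dskip, bc$stride)
        g[[key("proj_w")]] <- bw$dw; g[[key("proj_b")]] <- bw$db
        dinput <- dinput + bw$dx
      } else {
        dinput <- dinput + dskip
      }
      dcur <- dinput
    }
  }
  dstem <- relu_bw(dcur, cache$stem)
  bw <- conv3d_bw(cache$x, p$stem_w, dstem, 2L)
  g$stem_w <- bw$dw; g$stem_b <- bw$db
  g
}

#' Train the phase-two cube classifier
#'
#' Mini-batch Adam with binary cross-entropy on a single logit, and
#' on-the-fly augmentation (random axis flips and right-angle rotations in
#' x, y and z — rotations are right-angle so no interpolation is needed).
#' All randomness derives from `seed`.
#'
#' @param dataset a [cube_dataset()] (after undersampling).
#' @param cfg a [cube_config()].
#' @param seed RNG seed.
#' @param model optionally an existing model to continue training (used by
#'   [fine_tune()]).
#' @param learning_rate overrides `cfg$learning_rate` when given.
#' @param augment apply augmentation (default `TRUE`).
#' @return A trained `resnet_model` with a per-epoch `loss_trace`.
#' @export
train_resnet <- function(dataset, cfg = cube_config(), seed = 1L,
                         model = NULL, learning_rate = NULL,
                         augment = TRUE) {
  items <- dataset$items
  if (!nrow(items) || length(unique(items$label)) < 2L)
    stop("train_resnet: need at least one positive and one negative cube",
         call. = FALSE)
  lr <- learning_rate %||% cfg$learning_rate
  if (is.null(model)) model <- resnet_init(cfg, in_ch = 2L, seed = seed)
  adam <- adam_init(model$params)
  trace <- numeric(cfg$epochs)
  n <- nrow(items)
  with_seed(seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1, n)]
        total <- NULL
        for (row in batch) {
          x <- dataset_cube(dataset, row)
          if (augment) x <- augment_cube(x)
          fwd <- resnet_forward(model, x, keep_cache = TRUE)
          lo <- bce_logit_loss(fwd$logit, items$label[row])
          ep_loss <- ep_loss + lo$loss
          total <- accumulate_grads(total,
                                    resnet_backward(model, fwd$cache,
                                                    lo$dlogit))
        }
        upd <- adam_step(model$params, scale_grads(total, 1 / length(batch)),
                         adam, lr)
        model$params <- upd$params
        adam <- upd$state
      }
      trace[ep] <- ep_loss / n
    }
  })
  model$loss_trace <- c(model$loss_trace, trace)
  model$trained <- TRUE
  model$cfg <- cfg
  model
}

#' Predict pathological probabilities for cubes
#'
#' One probability in `[0, 1]` per cube; no augmentation at inference, so
#' predictions are deterministic.
#'
#' @param dataset a [cube_dataset()].
#' @param model a trained `resnet_model`.
#' @return numeric vector of probabilities aligned with `dataset$items`.
#' @export
predict_cubes <- function(dataset, model) {
  if (is.null(model) || !isTRUE(model$trained))
    stop("predict_cubes: model is untrained", call. = FALSE)
  n <- nrow(dataset$items)
  probs <- numeric(n)
  for (row in seq_len(n)) {
    x <- dataset_cube(dataset, row)
    probs[row] <- sigmoid(resnet_forward(model, x)$logit)
  }
  probs
}

#' Aggregate overlapping cube predictions into a score map
#'
#' For every voxel, `summed_score` is the sum of the probabilities of all
#' cubes whose 64-mm extent contains it, and `coverage` counts those cubes
#' (bounded by `(cube_side/grid_stride)^3 = 512` on the full interior
#' lattice).
#'
#' @param centres integer matrix of cube-centre voxel indices (crop grid).
#' @param probs probabilities aligned with `centres`.
#' @param geometry a [volume3d] for the crop grid.
#' @param cfg a [cube_config()].
#' @return A `scoremap`: `summed_score`, `coverage`, `dim`, `spacing`,
#'   `origin`.
#' @export
aggregate_scores <- function(centres, probs, geometry, cfg = cube_config()) {
  if (nrow(centres) != length(probs))
    stop("aggregate_scores: centres and probabilities differ in length",
         call. = FALSE)
  d <- dim(geometry$values)
  side <- as.integer(round(cfg$cube_side / geometry$spacing[1]))
  agg <- .aggregate_scores_cpp(as.integer(d),
                               matrix(as.integer(centres), ncol = 3),
                               as.numeric(probs), side)
  structure(list(summed_score = agg$summed_score, coverage = agg$coverage,
                 dim = d, spacing = geometry$spacing,
                 origin = geometry$origin),
            class = "scoremap")
}

#' Threshold a score map into predicted node regions
#'
#' Voxels with summed score strictly above the threshold form the positive
#' set; its 26-connected components are the predicted nodes. The threshold
#' defaults to the published value and can be re-tuned on a validation
#' cohort with [tune_threshold()].
#'
#' @param scoremap from [aggregate_scores()].
#' @param cfg a [cube_config()] (uses `agg_threshold`).
#' @param threshold optional override of `cfg$agg_threshold`.
#' @param patient_id attached to the returned regions.
#' @return list of `candidate_region`s (predicted nodes).
#' @export
positive_regions <- function(scoremap, cfg = cube_config(),
                             threshold = NULL, patient_id = NA_character_) {
  thr <- threshold %||% cfg$agg_threshold
  mask <- array(as.integer(scoremap$summed_score > thr), scoremap$dim)
  labels_to_regions(label_components(mask), patient_id)
}

#' Fine-tune the cube classifier on second-scanner data
#'
#' Continues training of an existing phase-two model with the identical
#' loop at the (much smaller) fine-tune learning rate. Phase one is not
#' touched: candidate cubes must come from the frozen U-Net.
#'
#' @param model a trained `resnet_model`.
#' @param dataset a [cube_dataset()] of second-scanner cubes.
#' @param cfg a [cube_config()] (uses `finetune_learning_rate`, `epochs`).
#' @param seed RNG seed.
#' @return The fine-tuned `resnet_model`.
#' @export
fine_tune <- function(model, dataset, cfg = cube_config(), seed = 1L) {
  if (is.null(model) || !isTRUE(model$trained))
    stop("fine_tune: no trained base model", call. = FALSE)
  train_resnet(dataset, cfg, seed = seed, model = model,
               learning_rate = cfg$finetune_learning_rate)
}
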