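test_that("cube enumeration matches brute-force lattice membership", {
  cfg <- cube_config()
  geom <- volume3d(array(0, c(64, 64, 64)), c(1, 1, 1))
  # empty regions -> no centres
  expect_equal(nrow(enumerate_cubes(list(), geom, cfg)), 0L)
  # single-voxel region on a lattice point (1-based index 1+8k)
  r1 <- mediastinet:::candidate_region(rbind(c(17L, 9L, 25L)), "p")
  cen <- enumerate_cubes(list(r1), geom, cfg)
  expect_equal(nrow(cen), 1L)
  expect_equal(cen[1, ], c(17L, 9L, 25L), ignore_attr = TRUE)
  expect_equal(attr(cen, "mm")[1, ], c(16, 8, 24), ignore_attr = TRUE)

  # 24^3 region aligned to the lattice vs triple-loop oracle
  reg <- mediastinet:::candidate_region(
    as.matrix(expand.grid(9:32, 9:32, 9:32)), "p")
  cen2 <- enumerate_cubes(list(reg), geom, cfg)
  oracle <- 0L
  for (i in seq(1, 64, by = 8)) for (j in seq(1, 64, by = 8))
    for (k in seq(1, 64, by = 8))
      if (i >= 9 && i <= 32 && j >= 9 && j <= 32 && k >= 9 && k <= 32)
        oracle <- oracle + 1L
  expect_equal(nrow(cen2), oracle)

  # overlapping regions do not duplicate centres
  cen3 <- enumerate_cubes(list(reg, reg), geom, cfg)
  expect_equal(nrow(cen3), oracle)
})

test_that("cube labels use an inclusive 16-mm centre distance", {
  cfg <- cube_config()
  centres <- rbind(c(0, 0, 0), c(0, 0, 0), c(100, 0, 0))
  nodes <- nodes_df("p", c(15.9, 0, 0))
  expect_equal(label_cubes(centres[1, , drop = FALSE], nodes, cfg), 1L)
  expect_equal(label_cubes(rbind(c(-0.2, 0, 0)),
                           nodes_df("p", c(15.9, 0, 0)), cfg), 0L)
  expect_equal(label_cubes(rbind(c(0, 0, 0)),
                           nodes_df("p", c(16, 0, 0)), cfg), 1L)  # boundary
  expect_equal(label_cubes(rbind(c(0, 0, 0)),
                           nodes_df("p", c(16.1, 0, 0)), cfg), 0L)
  expect_equal(label_cubes(centres, empty_nodes(), cfg), c(0L, 0L, 0L))

  # random configuration vs all-pairs oracle
  set.seed(23)
  cen <- matrix(runif(60, 0, 100), ncol = 3)
  nds <- nodes_df("p", matrix(runif(15, 0, 100), ncol = 3))
  lab <- label_cubes(cen, nds, cfg)
  oracle <- vapply(seq_len(nrow(cen)), function(i) {
    d <- sqrt(colSums((t(as.matrix(nds[, 2:4])) - cen[i, ])^2))
    as.integer(any(d <= 16))
  }, integer(1))
  expect_equal(lab, oracle)
})

test_that("negative undersampling keeps positives and is reproducible", {
  labels <- c(rep(1L, 5), rep(0L, 80))
  k1 <- undersample_negatives(labels, 8, seed = 3)
  k2 <- undersample_negatives(labels, 8, seed = 3)
  expect_identical(k1, k2)
  expect_equal(sum(labels[k1] == 1L), 5L)
  expect_equal(sum(labels[k1] == 0L), 10L)   # 80 / 8
  expect_error(undersample_negatives(labels, 0.5), "factor")
  # retained ratio on larger draws stays near 1/8 of negatives
  labels2 <- c(rep(1L, 40), rep(0L, 423))
  k3 <- undersample_negatives(labels2, 8, seed = 9)
  expect_equal(sum(labels2[k3] == 0L), round(423 / 8))
})

test_that("cube extraction pads outside the crop with standardised air", {
  crop <- make_test_crop(c(80, 80, 80))
  cfg <- cube_config()
  st <- structure(list(ct_mean = 10, ct_sd = 2, pet_mean = 1, pet_sd = 0.5,
                       fitted_on = "t"), class = "norm_stats")
  patch <- extract_cube(crop, c(41L, 41L, 41L), cfg, st)
  expect_equal(dim(patch), c(64L, 64L, 64L, 2L))
  expect_equal(patch[1, 1, 1, 1], crop$ct$values[10, 10, 10])
  expect_equal(patch[, , , 2][2, 3, 4], crop$pet$values[11, 12, 13])

  # centre 10 voxels from the low x face: padded slab thickness 22
  p2 <- extract_cube(crop, c(10L, 41L, 41L), cfg, st)
  fill_ct <- (-1000 - st$ct_mean) / st$ct_sd
  fill_pet <- (0 - st$pet_mean) / st$pet_sd
  expect_true(all(p2[1:22, , , 1] == fill_ct))
  expect_true(all(p2[1:22, , , 2] == fill_pet))
  expect_equal(p2[23, 32, 32, 1], crop$ct$values[1, 41, 41])

  # constant volume -> constant patch; channel order (CT, PET) kept
  cc <- make_test_crop(c(80, 80, 80))
  cc$ct$values[] <- -3; cc$pet$values[] <- 4
  p3 <- extract_cube(cc, c(41L, 41L, 41L), cfg, st)
  expect_true(all(p3[, , , 1] == -3))
  expect_true(all(p3[, , , 2] == 4))

  expect_error(extract_cube(crop, c(0L, 5L, 5L), cfg, st), "outside")
})

test_that("augmentation flips and right-angle rotations preserve content", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 6 * 2), c(6, 6, 6, 2))
  for (rep in 1:5) {
    a <- mediastinet:::augment_cube(x)
    expect_equal(dim(a), dim(x))
    expect_equal(sort(as.vector(a)), sort(as.vector(x)))
  }
  # a rotation by 4 quarter turns is the identity
  expect_equal(mediastinet:::rot90_axes4(x, 1, 2, 4), x)
  r1 <- mediastinet:::rot90_axes4(x, 2, 3, 1)
  expect_equal(mediastinet:::rot90_axes4(r1, 2, 3, 3), x)
})

test_that("ResNet training is deterministic and discriminates hot cubes", {
  cfg <- cube_config(block = "basic", blocks = c(1L, 1L),
                     widths = c(4L, 8L), stem_width = 2L, epochs = 2L,
                     batch_size = 4L, learning_rate = 1e-3,
                     cube_side = 16, grid_stride = 8, positive_radius = 6)
  # synthetic 16-mm cubes: positives carry a hot PET blob
  mk_ds <- function(n, seed) {
    set.seed(seed)
    crops <- list(); items <- list()
    crop <- make_test_crop(c(48, 48, 48), seed = seed)
    labs <- integer(n)
    for (i in seq_len(n)) labs[i] <- i %% 2L
    centres <- cbind(sample(seq(9, 41, by = 8), n, TRUE),
                     sample(seq(9, 41, by = 8), n, TRUE),
                     sample(seq(9, 41, by = 8), n, TRUE))
    for (i in seq_len(n)) if (labs[i])
      crop$pet$values[centres[i, 1] + (-2:2), centres[i, 2] + (-2:2),
                      centres[i, 3] + (-2:2)] <- 6
    structure(list(crops = list(tp01 = crop),
                   items = data.frame(patient_id = "tp01",
                                      vx = centres[, 1], vy = centres[, 2],
                                      vz = centres[, 3],
                                      x_mm = centres[, 1] - 1,
                                      y_mm = centres[, 2] - 1,
                                      z_mm = centres[, 3] - 1,
                                      label = labs),
                   cfg = cfg, stats = NULL), class = "cube_dataset")
  }
  ds <- mk_ds(24, 31)
  m1 <- train_resnet(ds, cfg, seed = 11)
  m2 <- train_resnet(ds, cfg, seed = 11)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(model_hash(m1), model_hash(m2))

  cfg10 <- cfg; cfg10$epochs <- 20L; cfg10$learning_rate <- 1e-2
  m3 <- train_resnet(ds, cfg10, seed = 11)
  expect_lt(tail(m3$loss_trace, 1), m3$loss_trace[1])
  held <- mk_ds(20, 77)
  pr <- predict_cubes(held, m3)
  expect_true(all(pr >= 0 & pr <= 1))
  # deterministic inference
  expect_identical(pr, predict_cubes(held, m3))
  auc <- mean(outer(pr[held$items$label == 1L],
                    pr[held$items$label == 0L], ">")) +
    0.5 * mean(outer(pr[held$items$label == 1L],
                     pr[held$items$label == 0L], "=="))
  expect_gt(auc, 0.7)

  # single-class data is an error; untrained prediction is a state error
  ds1 <- ds; ds1$items$label <- 1L
  expect_error(train_resnet(ds1, cfg), "positive and one negative")
  expect_error(predict_cubes(ds, resnet_init(cfg)), "untrained")
})

test_that("fine-tuning updates only phase two and a zero rate is a no-op", {
  cfg <- cube_config(block = "basic", blocks = c(1L), widths = c(4L),
                     stem_width = 2L, epochs = 2L, batch_size = 4L,
                     learning_rate = 1e-3, finetune_learning_rate = 0,
                     cube_side = 16, grid_stride = 8, positive_radius = 6)
  set.seed(44)
  crop <- make_test_crop(c(32, 32, 32), seed = 4)
  items <- data.frame(patient_id = "tp01",
                      vx = c(9L, 17L, 9L, 17L), vy = c(9L, 9L, 17L, 17L),
                      vz = c(9L, 17L, 17L, 9L),
                      x_mm = 0, y_mm = 0, z_mm = 0,
                      label = c(1L, 0L, 1L, 0L))
  ds <- structure(list(crops = list(tp01 = crop), items = items,
                       cfg = cfg, stats = NULL), class = "cube_dataset")
  base <- train_resnet(ds, cfg, seed = 2)
  pr_before <- predict_cubes(ds, base)
  # learning rate 0: parameters and predictions unchanged
  ft0 <- fine_tune(base, ds, cfg, seed = 3)
  expect_identical(model_hash(ft0), model_hash(base))
  expect_identical(predict_cubes(ds, ft0), pr_before)
  # the phase-one model is untouched by construction: fine_tune never sees
  # it; assert the frozen-contract on a stored hash
  unet <- unet_init(candidate_config(base_width = 2L, levels = 1L), seed = 1)
  h <- model_hash(unet)
  cfg2 <- cfg; cfg2$finetune_learning_rate <- 1e-3
  ft <- fine_tune(base, ds, cfg2, seed = 3)
  expect_identical(model_hash(unet), h)
  expect_false(identical(model_hash(ft), model_hash(base)))
  expect_error(fine_tune(NULL, ds, cfg), "trained")
})

test_that("score aggregation matches the containment oracle", {
  cfg <- cube_config()
  geom <- volume3d(array(0, c(120, 120, 120)), c(1, 1, 1))
  # full interior lattice at probability 1 -> interior summed score 512
  lat <- as.matrix(expand.grid(seq(1, 113, by = 8), seq(1, 113, by = 8),
                               seq(1, 113, by = 8)))
  storage.mode(lat) <- "integer"
  sm <- aggregate_scores(lat, rep(1, nrow(lat)), geom, cfg)
  centre <- c(60, 60, 60)
  # oracle: count lattice cubes whose 64-mm window contains the voxel
  contains <- function(c0, v) all(v >= c0 - 31 & v <= c0 + 32)
  cnt <- sum(apply(lat, 1, contains, v = centre))
  expect_equal(cnt, 512)
  expect_equal(sm$summed_score[centre[1], centre[2], centre[3]], 512)
  expect_equal(sm$coverage[centre[1], centre[2], centre[3]], 512L)
  # coverage bound holds everywhere; scores never exceed coverage
  expect_lte(max(sm$coverage), 512L)
  expect_true(all(sm$summed_score <= sm$coverage + 1e-9))

  # single cube with probability p: p inside the extent, 0 outside
  one <- matrix(c(60L, 60L, 60L), 1)
  s1 <- aggregate_scores(one, 0.37, geom, cfg)
  expect_equal(s1$summed_score[60, 60, 60], 0.37)
  expect_equal(s1$summed_score[60 - 31, 60 - 31, 60 - 31], 0.37)
  expect_equal(s1$summed_score[60 + 32, 60, 60], 0.37)
  expect_equal(s1$summed_score[60 + 33, 60, 60], 0)
  expect_equal(s1$summed_score[60 - 32, 60, 60], 0)

  # aggregation is additive over disjoint cube sets
  a <- lat[1:40, , drop = FALSE]
  b <- lat[41:80, , drop = FALSE]
  set.seed(3)
  pa <- runif(40); pb <- runif(40)
  s_ab <- aggregate_scores(rbind(a, b), c(pa, pb), geom, cfg)
  s_a <- aggregate_scores(a, pa, geom, cfg)
  s_b <- aggregate_scores(b, pb, geom, cfg)
  expect_equal(s_ab$summed_score, s_a$summed_score + s_b$summed_score)

  expect_error(aggregate_scores(one, c(0.1, 0.2), geom, cfg), "length")
})

test_that("positive regions threshold strictly above the cut", {
  cfg <- cube_config()
  geom <- volume3d(array(0, c(30, 30, 30)), c(1, 1, 1))
  sm <- structure(list(summed_score = array(17.9, c(30, 30, 30)),
                       coverage = NULL, dim = c(30L, 30L, 30L),
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                  class = "scoremap")
  expect_length(positive_regions(sm, cfg), 0L)
  sm$summed_score[10:14, 10:14, 10:14] <- 25
  regs <- positive_regions(sm, cfg)
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$volume, 125L)
  # exactly 18 is not positive ("above" the threshold)
  sm2 <- sm; sm2$summed_score[] <- 18
  expect_length(positive_regions(sm2, cfg), 0L)
})
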