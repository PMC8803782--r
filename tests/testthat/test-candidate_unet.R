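test_that("sphere labels equal brute-force lattice enumeration", {
  grid <- volume3d(array(0, c(40, 40, 40)), c(1, 1, 1))
  # an interior 15-mm sphere on the 1-mm lattice: frozen oracle count
  nodes <- nodes_df("p", c(19, 19, 19))
  mask <- make_sphere_labels(nodes, grid, radius = 15)
  expect_equal(sum(mask), 14147)
  expect_equal(sum(mask), oracle_sphere_count(c(20, 20, 20), 15))

  # random centres and radii <= 20 mm (fractional centres included)
  set.seed(17)
  for (rep in 1:4) {
    cen <- runif(3, 12, 27)
    r <- runif(1, 3, 12)
    m <- make_sphere_labels(nodes_df("p", cen - 1), grid, radius = r)
    expect_equal(sum(m), oracle_sphere_count(cen, r))
  }

  # no nodes -> empty mask; union of close spheres is smaller than 2x one
  expect_equal(sum(make_sphere_labels(empty_nodes(), grid)), 0)
  two <- make_sphere_labels(nodes_df("p", rbind(c(15, 19, 19),
                                                c(25, 19, 19))),
                            grid, radius = 15)
  one <- make_sphere_labels(nodes_df("p", c(15, 19, 19)), grid, radius = 15)
  m1 <- make_sphere_labels(nodes_df("p", c(15, 19, 19)), grid, 15)
  m2 <- make_sphere_labels(nodes_df("p", c(25, 19, 19)), grid, 15)
  expect_identical(two, pmax(m1, m2))   # exact set union
  expect_lt(sum(two), 2 * sum(one))

  # node outside the grid is an annotation error naming the node
  expect_error(make_sphere_labels(nodes_df("pX", c(100, 10, 10)), grid),
               "pX")
})

test_that("spheres are truncated at grid borders", {
  grid <- volume3d(array(0, c(30, 30, 12)), c(1, 1, 1))
  m <- make_sphere_labels(nodes_df("p", c(14, 14, 1)), grid, radius = 8)
  # oracle restricted to lattice points inside the grid
  cnt <- 0L
  for (i in 7:23) for (j in 7:23) for (k in 1:12)
    if ((i - 15)^2 + (j - 15)^2 + (k - 2)^2 <= 64) cnt <- cnt + 1L
  expect_equal(sum(m), cnt)
})

test_that("region filtering and dilation follow the published rules", {
  cfg <- candidate_config()
  d <- c(40L, 40L, 40L)
  # 299 voxels removed, 300 kept: build a 300-voxel bar and drop one voxel
  bar <- as.matrix(expand.grid(6:25, 6:20, 6))  # 20 x 15 x 1 = 300
  r300 <- mediastinet:::candidate_region(bar, "p")
  r299 <- mediastinet:::candidate_region(bar[-1, ], "p")
  expect_length(filter_and_dilate(list(r299), d, cfg), 0L)
  out <- filter_and_dilate(list(r300), d, cfg)
  expect_length(out, 1L)
  # dilation only grows: every input voxel survives
  mask_out <- mediastinet:::regions_to_mask(out, d)
  expect_true(all(mask_out[bar] == 1L))

  # 10^3 cube dilated 3 face-connected iterations: frozen oracle volume
  cube <- as.matrix(expand.grid(16:25, 16:25, 16:25))
  big <- mediastinet:::candidate_region(cube, "p")
  dil <- filter_and_dilate(list(big), d, cfg)
  expect_equal(dil[[1]]$volume, 3168)
  expect_equal(dil[[1]]$volume,
               sum(oracle_morph(mediastinet:::regions_to_mask(list(big), d),
                                3, TRUE)))
  expect_length(filter_and_dilate(list(), d, cfg), 0L)
})

test_that("touching dilated regions merge into one component", {
  cfg <- candidate_config(min_region_voxels = 10L, dilation_iters = 3L)
  d <- c(30L, 30L, 10L)
  a <- as.matrix(expand.grid(5:8, 5:8, 4:6))    # 48 voxels
  b <- as.matrix(expand.grid(13:16, 5:8, 4:6))  # gap of 4 -> bridged by 3+3
  out <- filter_and_dilate(list(mediastinet:::candidate_region(a, "p"),
                                mediastinet:::candidate_region(b, "p")),
                           d, cfg)
  expect_length(out, 1L)
})

test_that("U-Net training is deterministic and fits a simple segmentation", {
  cfg <- candidate_config(base_width = 4L, levels = 1L, epochs = 2L,
                          learning_rate = 2e-3)
  set.seed(5)
  mk_slices <- function() {
    lapply(1:6, function(i) {
      x <- array(rnorm(32 * 32 * 2, sd = 0.1), c(32, 32, 2))
      g <- matrix(0, 32, 32)
      at <- 8 + (i %% 3) * 5
      g[at:(at + 6), at:(at + 6)] <- 1
      x[, , 2] <- x[, , 2] + 3 * g
      list(x = x, g = g)
    })
  }
  s <- mk_slices()
  m1 <- mediastinet:::train_unet_slices(s, cfg, seed = 42L)
  m2 <- mediastinet:::train_unet_slices(s, cfg, seed = 42L)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(model_hash(m1), model_hash(m2))

  # longer training separates hot foreground from background
  cfg$epochs <- 25L
  m3 <- mediastinet:::train_unet_slices(s, cfg, seed = 42L)
  expect_lt(mean(tail(m3$loss_trace, 3)), m3$loss_trace[1])
  dice <- function(p, g) 2 * sum(p * g) / (sum(p) + sum(g))
  f <- mediastinet:::unet_forward(m3, s[[1]]$x)$prob[, , 1] > 0.5
  expect_gt(dice(f, s[[1]]$g), 0.5)

  expect_error(mediastinet:::train_unet_slices(list(), cfg), "positive")
})

test_that("candidate prediction binarises, stacks and partitions foreground", {
  cfg <- candidate_config(base_width = 2L, levels = 1L)
  model <- unet_init(cfg, seed = 1)
  # zero all weights: sigmoid(0) = 0.5 is not > 0.5 -> empty prediction
  model$params <- lapply(model$params, function(p) { p[] <- 0; p })
  model$trained <- TRUE
  crop <- make_test_crop(c(32, 32, 8))
  expect_length(predict_candidates(crop, model, cfg), 0L)

  # untrained model is a state error
  expect_error(predict_candidates(crop, unet_init(cfg), cfg), "untrained")

  # regions partition the binarised foreground exactly: force the head
  # bias positive so every voxel is foreground
  model$params$head_b[] <- 10
  regs <- predict_candidates(crop, model, cfg)
  expect_equal(sum(vapply(regs, `[[`, integer(1), "volume")),
               prod(dim(crop$ct$values)))
})

test_that("candidate sensitivity counts covered node centres", {
  geom <- volume3d(array(0, c(40, 40, 20)), c(1, 1, 1))
  reg <- mediastinet:::candidate_region(
    as.matrix(expand.grid(10:20, 10:20, 5:10)), "p")
  nodes_in <- nodes_df("p", rbind(c(14, 14, 7), c(11, 12, 6)))
  expect_equal(candidate_sensitivity(list(reg), nodes_in, geom), 1.0)
  mixed <- nodes_df("p", rbind(c(14, 14, 7), c(35, 35, 15)))
  expect_equal(candidate_sensitivity(list(reg), mixed, geom), 0.5)
  expect_equal(candidate_sensitivity(list(), nodes_in, geom), 0.0)
  expect_warning(s <- candidate_sensitivity(list(reg), empty_nodes(), geom),
                 "NaN")
  expect_true(is.nan(s))
  # the published phase-one arithmetic: 32 of 34 nodes covered -> 94%
  expect_equal(round(32 / 34, 2), 0.94)
})
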