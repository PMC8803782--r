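# Minimal deterministic CNN engine: hand-written forward/backward passes
# over im2col convolutions (see src/nnops.cpp), ReLU/sigmoid, 2x2 max
# pooling, nearest-neighbour upsampling and Adam. Everything is seeded
# through R's RNG and runs single-threaded, so identical seeds and data give
# identical parameter trajectories.

he_weights <- function(dims, fan_in)
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

relu <- function(x) .relu_fw_cpp(x)
relu_bw <- function(dy, y) .relu_bw_cpp(dy, y)
sigmoid <- function(x) 1 / (1 + exp(-x))

conv2d <- function(x, w, b, stride = 1L)
  .conv2d_fw_cpp(x, w, b, as.integer(stride))
conv2d_bw <- function(x, w, dy, stride = 1L)
  .conv2d_bw_cpp(x, w, dy, as.integer(stride))
conv3d <- function(x, w, b, stride = 1L)
  .conv3d_fw_cpp(x, w, b, as.integer(stride))
conv3d_bw <- function(x, w, dy, stride = 1L)
  .conv3d_bw_cpp(x, w, dy, as.integer(stride))

upsample2x <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

# gradient of nearest-neighbour 2x upsampling: sum each 2x2 block
upsample2x_bw <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(2, d[1], by = 2)
  p1 <- seq(1, d[2], by = 2); p2 <- seq(2, d[2], by = 2)
  dy[o1, p1, , drop = FALSE] + dy[o2, p1, , drop = FALSE] +
    dy[o1, p2, , drop = FALSE] + dy[o2, p2, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# ---- Adam ---------------------------------------------------------------

zero_like <- function(p)
  if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))

adam_init <- function(params)
  list(t = 0L, m = lapply(params, zero_like),
       v = lapply(params, zero_like))

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

scale_grads <- function(g, f) lapply(g, function(x) x * f)

# ---- losses -------------------------------------------------------------

# soft Dice loss on probabilities; returns loss and d(loss)/d(prob)
dice_loss <- function(p, g, smooth = 1) {
  inter <- sum(p * g)
  denom <- sum(p) + sum(g) + smooth
  loss <- 1 - (2 * inter + smooth) / denom
  dp <- -(2 * g * denom - (2 * inter + smooth)) / denom^2
  list(loss = loss, dp = dp)
}

# binary cross-entropy on a single logit; returns loss and d(loss)/d(logit)
bce_logit_loss <- function(logit, y) {
  p <- sigmoid(logit)
  pc <- min(max(p, 1e-12), 1 - 1e-12)
  list(loss = -(y * log(pc) + (1 - y) * log(1 - pc)), dlogit = p - y)
}

#' Hash of a model's parameters
#'
#' MD5 over the serialised parameter list; used to assert that a model was
#' (or was not) modified, e.g. that phase one stays frozen during phase-two
#' fine-tuning.
#'
#' @param model a model object with a `params` element.
#' @return character MD5 hash.
#' @export
model_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model$params, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
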