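# Layer primitives for the two-branch SE CNN. Feature maps are dense
# arrays (H, W, C, N); convolution weights are K x Cout matrices with
# K = kh*kw*Cin (row order: kernel row fastest, then kernel column, then
# input channel), matching the C++ im2col layout. Broadcast-heavy steps
# (ReLU, channel scaling, spatial reductions, feature-map resize) run in
# C++ to avoid large intermediate copies.

conv_fw <- function(x, wmat, b, kh, kw, relu = FALSE, single = FALSE) {
  if (single) {
    cpp_conv2d_forward_f32(x, dim(x), wmat, b, kh, kw, relu)
  } else {
    cpp_conv2d_forward(x, dim(x), wmat, b, kh, kw, relu)
  }
}

conv_bw <- function(x, wmat, dout, kh, kw, single = FALSE) {
  if (single) {
    cpp_conv2d_backward_f32(x, dim(x), wmat, dout, kh, kw)
  } else {
    cpp_conv2d_backward(x, dim(x), wmat, dout, kh, kw)
  }
}

relu <- function(x) cpp_relu(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- squeeze-and-excitation ------------------------------------------------
# Global average pool per channel, two fully connected layers
# (ReLU then sigmoid), channel-wise rescaling. Gates lie in (0, 1), so the
# block never increases channel magnitude.

se_fw <- function(a, par) {
  d <- dim(a)
  s <- cpp_channel_means(a, d)
  nb <- d[4]
  h <- pmax(par$W1 %*% s + par$b1[, rep(1, nb), drop = FALSE], 0)
  z <- sigmoid(par$W2 %*% h + par$b2[, rep(1, nb), drop = FALSE])
  zero <- matrix(0, d[3], nb)
  out <- cpp_chan_scale_shift(a, d, z, zero)
  list(out = out, s = s, h = h, z = z)
}

se_bw <- function(dout, a, cache, par) {
  d <- dim(a)
  zero <- matrix(0, d[3], d[4])
  dz <- cpp_channel_dot(dout, a, d)
  dp2 <- dz * cache$z * (1 - cache$z)
  dW2 <- dp2 %*% t(cache$h)
  db2 <- rowSums(dp2)
  dh <- t(par$W2) %*% dp2
  dp1 <- dh * (cache$h > 0)
  dW1 <- dp1 %*% t(cache$s)
  db1 <- rowSums(dp1)
  ds <- t(par$W1) %*% dp1
  da <- cpp_chan_scale_shift(dout, d, cache$z, zero)
  da <- cpp_chan_scale_shift(da, d, matrix(1, d[3], d[4]),
                             ds / (d[1] * d[2]))
  list(dx = da, dW1 = dW1, db1 = matrix(db1), dW2 = dW2, db2 = matrix(db2))
}

# --- separable bicubic resize of feature maps ------------------------------
# Spatial resize of an (H, W, C, N) map with precomputed row/column
# cubic-convolution weight matrices (see cubic_resize_matrix); linear in
# the input, so the backward pass is the transposed resize:
# resize_maps(dY, t(Rr), t(Rc)).

resize_maps <- function(x, Rr, Rc) {
  cpp_slice_gemm(x, dim(x), Rr, t(Rc))
}

# --- per-channel instance normalization ------------------------------------
# Post-fusion feature normalization: standardize each (channel, sample)
# over its spatial extent, then apply a trainable per-channel affine map.

inorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  mu <- cpp_channel_means(x, d)
  ex2 <- cpp_channel_dot(x, x, d) / hw
  sd_ <- sqrt(pmax(ex2 - mu^2, 0) + eps)
  xhat <- cpp_chan_scale_shift(x, d, 1 / sd_, -mu / sd_)
  gm <- matrix(gamma, d[3], d[4])
  bm <- matrix(beta, d[3], d[4])
  list(out = cpp_chan_scale_shift(xhat, d, gm, bm), xhat = xhat, sd = sd_)
}

inorm_bw <- function(dout, cache, gamma, dims) {
  hw <- dims[1] * dims[2]
  gm <- matrix(gamma, dims[3], dims[4])
  zero <- matrix(0, dims[3], dims[4])
  dxhat <- cpp_chan_scale_shift(dout, dims, gm, zero)
  xhat <- cache$xhat
  # d/dx of (x - mu)/sd with mu, sd functions of x
  m1 <- cpp_channel_means(dxhat, dims)
  m2 <- cpp_channel_dot(dxhat, xhat, dims) / hw
  tmp <- dxhat - cpp_chan_scale_shift(xhat, dims, m2, zero)
  dx <- cpp_chan_scale_shift(tmp, dims, 1 / cache$sd, -m1 / cache$sd)
  dgamma <- rowSums(cpp_channel_dot(dout, xhat, dims))
  dbeta <- rowSums(cpp_channel_means(dout, dims)) * hw
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# global gradient-norm clipping: rescale the whole gradient so its L2
# norm does not exceed max_norm (stabilises the first Adam steps on small
# batches).
clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) grads <- lapply(grads, `*`, max_norm / total)
  grads
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

he_mat <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}
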