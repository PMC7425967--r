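# CSAM: parallel channel + spatial attention with residual aggregation.
#
# Channel branch:  M_C = sigmoid(MLP(avg_pool_C(F)) + MLP(max_pool_C(F)))
#                  with a shared one-hidden-layer MLP (reduction ratio r,
#                  ReLU hidden activation).
# Spatial branch:  M_S = sigmoid(f([avg_pool_S(F); max_pool_S(F)])) where f is
#                  1x1 (2->1 channels), then 7x1, then 1x7 convolution, all
#                  same-padded, no nonlinearity in between.
# Aggregation:     F' = (F + F (*) M_C) + (F + F (*) M_S)
#                     = 2F + F (*) M_C + F (*) M_S,
#                  (*) denoting elementwise product with broadcasting.

#' Create CSAM parameters
#'
#' Allocates the learnable weights of the channel/spatial attention module for
#' feature maps with `C` channels: the shared channel MLP (`W0` of shape
#' `[C/r, C]`, `W1` of shape `[C, C/r]`, zero-initialized biases) and the
#' factorized spatial convolutions (1x1 reducing 2 pooled maps to 1 channel,
#' then 7x1 and 1x7 kernels).
#'
#' @param C channel count of the feature maps this module will see.
#' @param r reduction ratio of the MLP hidden layer; must divide `C`.
#'   Defaults to 16, the ratio at which the attention design performs best.
#' @param init `"kaiming"` (seeded by the caller via `set.seed`) or `"zero"`.
#' @return parameter list with class `"csam_params"`.
#' @export
csam_params <- function(C, r = 16L, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  C <- as.integer(C); r <- as.integer(r)
  if (r < 1L || C %% r != 0L)
    stop(sprintf("channel count C = %d must be divisible by reduction ratio r = %d", C, r))
  h <- C %/% r
  zero <- init == "zero"
  p <- list(
    W0 = matrix(if (zero) 0 else kaiming(h * C, C), h, C),
    b0 = numeric(h),
    W1 = matrix(if (zero) 0 else kaiming(C * h, h), C, h),
    b1 = numeric(C),
    conv_reduce = conv_layer(1L, 1L, 2L, 1L, init = init),
    conv7x1 = conv_layer(7L, 1L, 1L, 1L, pad = c(3L, 0L), init = init),
    conv1x7 = conv_layer(1L, 7L, 1L, 1L, pad = c(0L, 3L), init = init),
    .meta = list(C = C, r = r))
  class(p) <- "csam_params"
  p
}

check_csam <- function(F, p) {
  if (!inherits(p, "csam_params")) stop("p must be created by csam_params()")
  if (dim(F)[3L] != p$.meta$C)
    stop(sprintf("CSAM params built for C = %d channels, feature map has %d",
                 p$.meta$C, dim(F)[3L]))
}

#' Pooled channel and spatial descriptors of a feature map
#'
#' Aggregates a `[H, W, C]` feature map along each of its two attention axes:
#' per-channel mean/max over all spatial positions (channel descriptors) and
#' per-position mean/max over all channels (spatial descriptors).
#'
#' @param F feature map array `[H, W, C]`.
#' @return list with `channel_avg`, `channel_max` (length `C`), `spatial_avg`,
#'   `spatial_max` (`H x W` matrices), plus the argmax indices
#'   (`which_channel_max`, `which_spatial_max`) used by backpropagation.
#' @export
pool_descriptors <- function(F) {
  F <- feature_map(F)
  d <- dim(F); hw <- d[1L] * d[2L]; C <- d[3L]
  xm <- matrix(F, hw, C)
  wc <- max.col(t(xm), ties.method = "first")   # argmax position per channel
  ws <- max.col(xm, ties.method = "first")      # argmax channel per position
  list(channel_avg = colMeans(xm),
       channel_max = xm[cbind(wc, seq_len(C))],
       spatial_avg = matrix(rowMeans(xm), d[1L], d[2L]),
       spatial_max = matrix(xm[cbind(seq_len(hw), ws)], d[1L], d[2L]),
       which_channel_max = wc,
       which_spatial_max = ws)
}

# shared-MLP evaluation with cache for backward
mlp_fwd <- function(p, v) {
  a0 <- as.vector(p$W0 %*% v + p$b0)
  ar <- pmax(a0, 0)
  a1 <- as.vector(p$W1 %*% ar + p$b1)
  list(out = a1, a0 = a0, ar = ar, v = v)
}

#' Channel attention vector
#'
#' Evaluates the channel branch: both pooled channel descriptors pass through
#' the shared one-hidden-layer MLP, the two outputs are summed elementwise,
#' and a sigmoid maps the result into (0, 1).
#'
#' @param F feature map `[H, W, C]`.
#' @param p [csam_params()] for `C` channels.
#' @return numeric vector of length `C`, entries strictly in (0, 1).
#' @export
channel_attention <- function(F, p) {
  F <- feature_map(F); check_csam(F, p)
  desc <- pool_descriptors(F)
  sigmoid(mlp_fwd(p, desc$channel_avg)$out + mlp_fwd(p, desc$channel_max)$out)
}

#' Spatial attention map
#'
#' Evaluates the spatial branch: the channel-pooled mean and max maps are
#' stacked into a 2-channel image and passed through the factorized
#' convolution chain 1x1 (2 to 1 channels), 7x1, 1x7 (all same-padded),
#' followed by a sigmoid.
#'
#' @inheritParams channel_attention
#' @return `H x W` matrix with entries strictly in (0, 1).
#' @export
spatial_attention <- function(F, p) {
  F <- feature_map(F); check_csam(F, p)
  desc <- pool_descriptors(F)
  s2 <- array(c(desc$spatial_avg, desc$spatial_max), dim = c(dim(F)[1:2], 2L))
  h1 <- conv_forward(p$conv_reduce, s2)
  h2 <- conv_forward(p$conv7x1, h1)
  h3 <- conv_forward(p$conv1x7, h2)
  matrix(sigmoid(h3), dim(F)[1L], dim(F)[2L])
}

# full forward with cache (training path)
csam_forward_cache <- function(F, p) {
  d <- dim(F); hw <- d[1L] * d[2L]; C <- d[3L]
  desc <- pool_descriptors(F)
  mc_a <- mlp_fwd(p, desc$channel_avg)
  mc_m <- mlp_fwd(p, desc$channel_max)
  Mc <- sigmoid(mc_a$out + mc_m$out)
  s2 <- array(c(desc$spatial_avg, desc$spatial_max), dim = c(d[1:2], 2L))
  h1 <- conv_forward(p$conv_reduce, s2)
  h2 <- conv_forward(p$conv7x1, h1)
  h3 <- conv_forward(p$conv1x7, h2)
  Ms <- sigmoid(as.vector(h3))
  xm <- matrix(F, hw, C)
  outm <- 2 * xm + sweep(xm, 2L, Mc, `*`) + xm * Ms
  out <- array(outm, dim = d)
  list(out = out,
       cache = list(F = F, desc = desc, mc_a = mc_a, mc_m = mc_m, Mc = Mc,
                    s2 = s2, h1 = h1, h2 = h2, Ms = Ms, d = d))
}

#' CSAM forward pass
#'
#' Applies both attention branches with their residual connections and sums
#' them: `F' = (F + F (*) M_C) + (F + F (*) M_S)`. The channel vector
#' broadcasts over space, the spatial map over channels; the output has the
#' shape of the input.
#'
#' @inheritParams channel_attention
#' @return feature map `[H, W, C]`.
#' @export
csam_forward <- function(F, p) {
  F <- feature_map(F); check_csam(F, p)
  csam_forward_cache(F, p)$out
}

mlp_bwd <- function(p, cache, dout) {
  dW1 <- outer(dout, cache$ar)
  db1 <- dout
  dar <- as.vector(crossprod(p$W1, dout))
  da0 <- dar * (cache$a0 > 0)
  dW0 <- outer(da0, cache$v)
  db0 <- da0
  dv <- as.vector(crossprod(p$W0, da0))
  list(dv = dv, dW0 = dW0, db0 = db0, dW1 = dW1, db1 = db1)
}

csam_backward <- function(p, cache, dout) {
  d <- cache$d; hw <- d[1L] * d[2L]; C <- d[3L]
  dm <- matrix(dout, hw, C)
  fm <- matrix(cache$F, hw, C)
  Mc <- cache$Mc; Ms <- cache$Ms
  # direct residual + gating terms
  dF <- 2 * dm + sweep(dm, 2L, Mc, `*`) + dm * Ms
  # gradients wrt the attention maps themselves
  dMc <- colSums(dm * fm)
  dMs <- rowSums(dm * fm)
  # channel branch
  dz <- dMc * Mc * (1 - Mc)
  ba <- mlp_bwd(p, cache$mc_a, dz)
  bm <- mlp_bwd(p, cache$mc_m, dz)
  dW0 <- ba$dW0 + bm$dW0; db0 <- ba$db0 + bm$db0
  dW1 <- ba$dW1 + bm$dW1; db1 <- ba$db1 + bm$db1
  dF <- dF + matrix(rep(ba$dv / hw, each = hw), hw, C)        # avg descriptor
  wc <- cache$desc$which_channel_max                           # max descriptor
  dF[cbind(wc, seq_len(C))] <- dF[cbind(wc, seq_len(C))] + bm$dv
  # spatial branch
  dh3 <- array(dMs * Ms * (1 - Ms), dim = c(d[1:2], 1L))
  b3 <- conv_backward(p$conv1x7, cache$h2, dh3)
  b2 <- conv_backward(p$conv7x1, cache$h1, b3$dx)
  b1 <- conv_backward(p$conv_reduce, cache$s2, b2$dx)
  ds_avg <- as.vector(b1$dx[, , 1L])
  ds_max <- as.vector(b1$dx[, , 2L])
  dF <- dF + outer(ds_avg, rep(1 / C, C))
  ws <- cache$desc$which_spatial_max
  dF[cbind(seq_len(hw), ws)] <- dF[cbind(seq_len(hw), ws)] + ds_max
  dparams <- list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1,
                  conv_reduce = b1$dparams, conv7x1 = b2$dparams,
                  conv1x7 = b3$dparams)
  list(dx = array(dF, dim = d), dparams = dparams)
}
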