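# Multi-scale attention DenseNet backbone.
#
# Building block (replacing the classic BN-ReLU-1x1-BN-ReLU-3x3 unit):
#   BN-ReLU-1x1 conv to k channels; split channels contiguously into four
#   subsets X1..X4 of g = k/4 channels; y1 = X1 and, for i = 2..4,
#   y_i = K_i(X_i + y_{i-1}) with K_i = BN-ReLU-3x1 conv-BN-ReLU-1x3 conv
#   (same padding); the concatenation [y1; y2; y3; y4] passes through CSAM
#   and becomes the block's k new feature channels. Each K application grows
#   the receptive field, so the four subsets carry features at four scales.
#
# Dense connectivity: layer l consumes the concatenation of the block input
# and all previous layers' new features; a dense block with L layers adds
# L * k channels. Transition layers (BN, 1x1 conv halving channels, 2x2
# average pool) sit between dense blocks.

cat3 <- function(lst) {
  d <- dim(lst[[1L]])
  array(unlist(lst, use.names = FALSE),
        dim = c(d[1L], d[2L], sum(vapply(lst, function(a) dim(a)[3L], 1L))))
}

split3 <- function(x, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, , at + seq_len(sizes[i]), drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# ---- multi-scale convolution block ------------------------------------------

#' Create parameters for one multi-scale attention building block
#'
#' @param cin input channel count.
#' @param k growth rate (output channels of the block); must be divisible by 4.
#' @param r CSAM reduction ratio; must divide `k`.
#' @param use_bn include the per-channel normalization layers (disable only
#'   for analytic tests of the convolution structure).
#' @param init weight init scheme passed to the conv layers and CSAM.
#' @return parameter list of class `"msblock_params"`.
#' @export
msblock_params <- function(cin, k, r = 16L, use_bn = TRUE,
                           init = c("kaiming", "zero")) {
  init <- match.arg(init)
  k <- as.integer(k)
  if (k %% 4L != 0L) stop(sprintf("growth rate k = %d must be divisible by 4", k))
  if (k %% as.integer(r) != 0L)
    stop(sprintf("growth rate k = %d must be divisible by the CSAM ratio r = %d", k, r))
  g <- k %/% 4L
  kset <- function() list(
    bn_a = norm_layer(g, enabled = use_bn),
    conv_a = conv_layer(3L, 1L, g, g, pad = c(1L, 0L), init = init),
    bn_b = norm_layer(g, enabled = use_bn),
    conv_b = conv_layer(1L, 3L, g, g, pad = c(0L, 1L), init = init))
  p <- list(bn0 = norm_layer(cin, enabled = use_bn),
            conv0 = conv_layer(1L, 1L, cin, k, init = init),
            k2 = kset(), k3 = kset(), k4 = kset(),
            csam = csam_params(k, r = r, init = init),
            .meta = list(cin = as.integer(cin), k = k, g = g, use_bn = use_bn))
  class(p) <- "msblock_params"
  p
}

kchain_fwd <- function(kp, t) {
  na <- norm_forward(kp$bn_a, t)
  ra <- relu_forward(na$out)
  u <- conv_forward(kp$conv_a, ra$out)
  nb <- norm_forward(kp$bn_b, u)
  rb <- relu_forward(nb$out)
  y <- conv_forward(kp$conv_b, rb$out)
  list(out = y, cache = list(na = na$cache, ra = ra$cache, ra_out = ra$out,
                             nb = nb$cache, rb = rb$cache, rb_out = rb$out))
}

kchain_bwd <- function(kp, cache, dy) {
  cb <- conv_backward(kp$conv_b, cache$rb_out, dy)
  dnb <- relu_backward(cache$rb, cb$dx)
  nb <- norm_backward(kp$bn_b, cache$nb, dnb)
  ca <- conv_backward(kp$conv_a, cache$ra_out, nb$dx)
  dna <- relu_backward(cache$ra, ca$dx)
  na <- norm_backward(kp$bn_a, cache$na, dna)
  list(dt = na$dx,
       dparams = list(bn_a = na$dparams, conv_a = ca$dparams,
                      bn_b = nb$dparams, conv_b = cb$dparams))
}

msblock_forward_cache <- function(x, p) {
  m <- p$.meta
  if (dim(x)[3L] != m$cin)
    stop(sprintf("block expects %d input channels, got %d", m$cin, dim(x)[3L]))
  n0 <- norm_forward(p$bn0, x)
  r0 <- relu_forward(n0$out)
  h <- conv_forward(p$conv0, r0$out)
  X <- split3(h, rep(m$g, 4L))
  y <- vector("list", 4L)
  kc <- vector("list", 4L)
  t_in <- vector("list", 4L)
  y[[1L]] <- X[[1L]]
  for (i in 2:4) {
    t_in[[i]] <- X[[i]] + y[[i - 1L]]
    kf <- kchain_fwd(p[[paste0("k", i)]], t_in[[i]])
    y[[i]] <- kf$out
    kc[[i]] <- kf$cache
  }
  cat_y <- cat3(y)
  cs <- csam_forward_cache(cat_y, p$csam)
  list(out = cs$out,
       cache = list(n0 = n0$cache, r0 = r0$cache, r0_out = r0$out,
                    X = X, kc = kc, cs = cs$cache, g = m$g))
}

#' Multi-scale building block forward pass
#'
#' Applies BN-ReLU-1x1 projection to `k` channels, the hierarchical 4-way
#' residual multi-scale convolution, and CSAM. Returns the block's `k`
#' new-feature channels; dense connectivity (concatenation with the input)
#' is the caller's job.
#'
#' @param x input feature map `[H, W, cin]`.
#' @param p [msblock_params()].
#' @return feature map `[H, W, k]`.
#' @export
msblock_forward <- function(x, p) msblock_forward_cache(feature_map(x), p)$out

msblock_backward <- function(p, cache, dout) {
  g <- cache$g
  cb <- csam_backward(p$csam, cache$cs, dout)
  dy <- split3(cb$dx, rep(g, 4L))
  dX <- vector("list", 4L)
  kgrads <- vector("list", 4L)
  for (i in 4:2) {
    kb <- kchain_bwd(p[[paste0("k", i)]], cache$kc[[i]], dy[[i]])
    kgrads[[i]] <- kb$dparams
    dX[[i]] <- kb$dt
    dy[[i - 1L]] <- dy[[i - 1L]] + kb$dt  # y_{i-1} also feeds t_i
  }
  dX[[1L]] <- dy[[1L]]
  dh <- cat3(dX)
  c0 <- conv_backward(p$conv0, cache$r0_out, dh)
  dr0 <- relu_backward(cache$r0, c0$dx)
  n0 <- norm_backward(p$bn0, cache$n0, dr0)
  list(dx = n0$dx,
       dparams = list(bn0 = n0$dparams, conv0 = c0$dparams,
                      k2 = kgrads[[2L]], k3 = kgrads[[3L]], k4 = kgrads[[4L]],
                      csam = cb$dparams))
}

# ---- dense block ------------------------------------------------------------

#' Create parameters for a dense block
#'
#' @param cin input channel count.
#' @param L number of building blocks (layers).
#' @inheritParams msblock_params
#' @return list of class `"dense_block_params"` with one [msblock_params()]
#'   per layer (layer l sees `cin + (l-1) * k` input channels).
#' @export
dense_block_params <- function(cin, L, k, r = 16L, use_bn = TRUE,
                               init = "kaiming") {
  if (L < 1L) stop("dense block needs L >= 1 layers")
  layers <- lapply(seq_len(L), function(l)
    msblock_params(cin + (l - 1L) * k, k, r = r, use_bn = use_bn, init = init))
  p <- list(layers = layers,
            .meta = list(cin = as.integer(cin), L = as.integer(L), k = as.integer(k)))
  class(p) <- "dense_block_params"
  p
}

dense_block_forward_cache <- function(x, p, keep_cache = TRUE) {
  L <- p$.meta$L
  feats <- vector("list", L + 1L)
  feats[[1L]] <- x
  caches <- if (keep_cache) vector("list", L) else NULL
  reads <- integer(L)
  for (l in seq_len(L)) {
    inp <- if (l == 1L) x else cat3(feats[seq_len(l)])
    reads[l] <- l  # layer l reads the l preceding tensors x0..x_{l-1}
    mf <- msblock_forward_cache(inp, p$layers[[l]])
    feats[[l + 1L]] <- mf$out
    if (keep_cache) caches[[l]] <- mf$cache
  }
  list(out = cat3(feats), caches = caches, reads = reads,
       chunk_sizes = c(dim(x)[3L], rep(p$.meta$k, L)))
}

#' Dense block forward pass
#'
#' Runs `L` multi-scale attention blocks with dense connectivity: layer l
#' consumes the concatenation of the block input and all previous layers' new
#' features, and the block returns that full concatenation
#' (`cin + L * k` channels). With L layers the block realizes
#' `L * (L + 1) / 2` tensor-read connections.
#'
#' @param x input feature map.
#' @param p [dense_block_params()].
#' @return feature map `[H, W, cin + L * k]`.
#' @export
dense_block_forward <- function(x, p)
  dense_block_forward_cache(feature_map(x), p, keep_cache = FALSE)$out

#' Number of connections realized by a dense block
#'
#' @param L number of layers.
#' @return `L * (L + 1) / 2`, the count of tensor reads across all layers.
#' @export
dense_block_connections <- function(L) L * (L + 1) / 2

dense_block_backward <- function(p, fwd, dout) {
  L <- p$.meta$L
  sizes <- fwd$chunk_sizes
  dfeats <- split3(dout, sizes)
  lgrads <- vector("list", L)
  for (l in L:1) {
    mb <- msblock_backward(p$layers[[l]], fwd$caches[[l]], dfeats[[l + 1L]])
    lgrads[[l]] <- mb$dparams
    dinp <- split3(mb$dx, sizes[seq_len(l)])
    for (j in seq_len(l)) dfeats[[j]] <- dfeats[[j]] + dinp[[j]]
  }
  list(dx = dfeats[[1L]], dparams = list(layers = lgrads))
}

# ---- transition layer -------------------------------------------------------

#' Create transition layer parameters
#'
#' @param cin input channel count (must be even; the 1x1 convolution
#'   compresses to `cin / 2`).
#' @param init weight init scheme.
#' @param use_bn include normalization.
#' @return list of class `"transition_params"`.
#' @export
transition_params <- function(cin, use_bn = TRUE, init = "kaiming") {
  cin <- as.integer(cin)
  if (cin %% 2L != 0L) stop("transition input channels must be even")
  p <- list(bn = norm_layer(cin, enabled = use_bn),
            conv = conv_layer(1L, 1L, cin, cin %/% 2L, init = init),
            .meta = list(cin = cin))
  class(p) <- "transition_params"
  p
}

transition_forward_cache <- function(x, p) {
  d <- dim(x)
  if (d[3L] != p$.meta$cin)
    stop(sprintf("transition expects %d channels, got %d", p$.meta$cin, d[3L]))
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L)
    stop("transition requires even spatial extents")
  nf <- norm_forward(p$bn, x)
  h <- conv_forward(p$conv, nf$out)
  out <- avgpool_forward(h, 2L, 2L)
  list(out = out, cache = list(n = nf$cache, n_out = nf$out, hd = dim(h)))
}

#' Transition layer forward pass
#'
#' Normalization, 1x1 convolution halving the channel count, then 2x2 average
#' pooling with stride 2 halving both spatial extents.
#'
#' @param x feature map `[H, W, C]` with even `H`, `W`, `C`.
#' @param p [transition_params()].
#' @return feature map `[H/2, W/2, C/2]`.
#' @export
transition_forward <- function(x, p) transition_forward_cache(feature_map(x), p)$out

transition_backward <- function(p, cache, dout) {
  dh <- avgpool_backward(dout, 2L, 2L, cache$hd[1L], cache$hd[2L])
  cb <- conv_backward(p$conv, cache$n_out, dh)
  nb <- norm_backward(p$bn, cache$n, cb$dx)
  list(dx = nb$dx, dparams = list(bn = nb$dparams, conv = cb$dparams))
}

# ---- full backbone ----------------------------------------------------------

#' Describe a multi-scale attention DenseNet backbone
#'
#' The canonical network takes one 512x512 grayscale channel through a 7x7
#' stride-2 stem convolution and 3x3 stride-2 max pool, five dense blocks of
#' (6, 12, 24, 32, 16) building blocks interleaved with four transition
#' layers, and a final global average pool, giving the 186-layer architecture
#' (see [count_depth()]).
#'
#' @param input_size input image side length (square input), default 512.
#' @param stem_channels channels produced by the stem convolution, default 64.
#' @param block_sizes building blocks per dense block, default
#'   `c(6, 12, 24, 32, 16)`.
#' @param growth_rate new channels per building block (k), default 32;
#'   divisible by 4 (the multi-scale split) and by `r`.
#' @param r CSAM reduction ratio, default 16.
#' @param use_bn include normalization layers.
#' @return object of class `"backbone_spec"`.
#' @export
backbone_spec <- function(input_size = 512L, stem_channels = 64L,
                          block_sizes = c(6L, 12L, 24L, 32L, 16L),
                          growth_rate = 32L, r = 16L, use_bn = TRUE) {
  spec <- list(input_size = as.integer(input_size),
               stem_channels = as.integer(stem_channels),
               block_sizes = as.integer(block_sizes),
               growth_rate = as.integer(growth_rate),
               r = as.integer(r), use_bn = isTRUE(use_bn))
  if (spec$growth_rate %% 4L != 0L) stop("growth_rate must be divisible by 4")
  class(spec) <- "backbone_spec"
  spec
}

#' Channel trace of a backbone
#'
#' @param spec [backbone_spec()].
#' @return integer vector of channel counts after the stem and after each
#'   dense block / transition, ending with the feature-vector length.
#' @export
backbone_channels <- function(spec) {
  C <- spec$stem_channels
  out <- c(stem = C)
  nb <- length(spec$block_sizes)
  for (i in seq_len(nb)) {
    C <- C + spec$block_sizes[i] * spec$growth_rate
    out[paste0("block", i)] <- C
    if (i < nb) {
      C <- C %/% 2L
      out[paste0("transition", i)] <- C
    }
  }
  out
}

#' Network depth under the DenseNet counting convention
#'
#' Counts 1 for the stem convolution, 2 per building block (the 1x1
#' projection and the multi-scale stage, mirroring the classic 1x1/3x3
#' pair), 1 per transition layer, and 1 for the classifier layer. The
#' canonical spec gives 1 + 2 * 90 + 4 + 1 = 186.
#'
#' @param spec [backbone_spec()].
#' @return integer depth.
#' @export
count_depth <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  n_trans <- length(spec$block_sizes) - 1L
  1L + 2L * sum(spec$block_sizes) + n_trans + 1L
}

#' Initialize backbone weights
#'
#' @param spec [backbone_spec()].
#' @param seed integer seed for the Kaiming-style initialization.
#' @return parameter tree of class `"backbone_params"`.
#' @export
backbone_init <- function(spec, seed = 1L) {
  set.seed(seed)
  nb <- length(spec$block_sizes)
  ch <- spec$stem_channels
  blocks <- vector("list", nb)
  transitions <- vector("list", max(nb - 1L, 0L))
  for (i in seq_len(nb)) {
    blocks[[i]] <- dense_block_params(ch, spec$block_sizes[i], spec$growth_rate,
                                      r = spec$r, use_bn = spec$use_bn)
    ch <- ch + spec$block_sizes[i] * spec$growth_rate
    if (i < nb) {
      transitions[[i]] <- transition_params(ch, use_bn = spec$use_bn)
      ch <- ch %/% 2L
    }
  }
  p <- list(stem = conv_layer(7L, 7L, 1L, spec$stem_channels,
                              stride = c(2L, 2L), pad = c(3L, 3L)),
            blocks = blocks, transitions = transitions,
            final_bn = norm_layer(ch, enabled = spec$use_bn),
            .meta = list(out_channels = ch))
  class(p) <- "backbone_params"
  p
}

backbone_forward_cache <- function(image, params, spec, keep_cache = TRUE) {
  image <- feature_map(image)
  d <- dim(image)
  if (d[1L] != spec$input_size || d[2L] != spec$input_size || d[3L] != 1L)
    stop(sprintf("backbone expects a single-channel %dx%d input, got %dx%dx%d",
                 spec$input_size, spec$input_size, d[1L], d[2L], d[3L]))
  trace <- c()
  cache <- list()
  x <- conv_forward(params$stem, image)
  trace["conv"] <- dim(x)[1L]
  mp <- maxpool_forward(x, 3L, 2L, 1L)
  if (keep_cache) { cache$stem_in <- image; cache$mp <- mp$cache }
  x <- mp$out
  trace["pool"] <- dim(x)[1L]
  nb <- length(spec$block_sizes)
  bcaches <- vector("list", nb); tcaches <- vector("list", nb)
  for (i in seq_len(nb)) {
    bf <- dense_block_forward_cache(x, params$blocks[[i]], keep_cache = keep_cache)
    x <- bf$out
    if (keep_cache) bcaches[[i]] <- bf[c("caches", "chunk_sizes")]
    trace[paste0("dense", i)] <- dim(x)[1L]
    if (i < nb) {
      tf <- transition_forward_cache(x, params$transitions[[i]])
      trace[paste0("trans", i, "_conv")] <- dim(x)[1L]
      x <- tf$out
      if (keep_cache) tcaches[[i]] <- tf$cache
      trace[paste0("trans", i, "_pool")] <- dim(x)[1L]
    }
  }
  fn <- norm_forward(params$final_bn, x)
  fr <- relu_forward(fn$out)
  last_act <- fr$out                       # saliency taps this activation
  feat <- global_avgpool_forward(last_act)
  trace["gap"] <- 1L
  if (keep_cache) {
    cache$blocks <- bcaches; cache$transitions <- tcaches
    cache$final_n <- fn$cache; cache$final_r <- fr$cache
    cache$last_dims <- dim(last_act)
  }
  list(features = feat, trace = trace, last_act = last_act, cache = cache)
}

#' Backbone forward pass
#'
#' Runs an image through stem, dense blocks, transitions, final
#' normalization/ReLU, and global average pooling.
#'
#' @param image feature map `[input_size, input_size, 1]`.
#' @param params [backbone_init()] weights.
#' @param spec [backbone_spec()] matching `params`.
#' @return list with `features` (numeric vector), `trace` (named per-stage
#'   spatial sizes for audit), and `last_act` (the feature map entering the
#'   global pool, used for heat maps).
#' @export
backbone_forward <- function(image, params, spec) {
  r <- backbone_forward_cache(image, params, spec, keep_cache = FALSE)
  r[c("features", "trace", "last_act")]
}

backbone_backward <- function(dfeat, fwd, params, spec) {
  ld <- fwd$cache$last_dims
  dx <- global_avgpool_backward(dfeat, ld[1L], ld[2L])
  dx <- relu_backward(fwd$cache$final_r, dx)
  fb <- norm_backward(params$final_bn, fwd$cache$final_n, dx)
  dx <- fb$dx
  nb <- length(spec$block_sizes)
  dblocks <- vector("list", nb); dtrans <- vector("list", max(nb - 1L, 0L))
  for (i in nb:1) {
    if (i < nb) {
      tb <- transition_backward(params$transitions[[i]],
                                fwd$cache$transitions[[i]], dx)
      dtrans[[i]] <- tb$dparams
      dx <- tb$dx
    }
    bb <- dense_block_backward(params$blocks[[i]], fwd$cache$blocks[[i]], dx)
    dblocks[[i]] <- bb$dparams
    dx <- bb$dx
  }
  dx <- maxpool_backward(fwd$cache$mp, dx)
  sb <- conv_backward(params$stem, fwd$cache$stem_in, dx)
  list(dparams = list(stem = sb$dparams, blocks = dblocks,
                      transitions = dtrans, final_bn = fb$dparams))
}

#' Count trainable parameters in a parameter tree
#'
#' @param params any layer/model parameter tree.
#' @return integer number of scalar trainable parameters.
#' @export
count_params <- function(params) length(tree_flatten(params))
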