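#' @useDynLib mvnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
NULL

# ---- feature maps -----------------------------------------------------------
# A feature map is a numeric array with dim = c(H, W, C). Channel-first in the
# mathematical description, channel-last in memory (idiomatic for R arrays).

#' Construct and validate a feature map
#'
#' Feature maps are plain numeric arrays with `dim = c(H, W, C)`; this helper
#' validates the invariants every network operation assumes (rank 3, positive
#' extents, all entries finite).
#'
#' @param x numeric array `[H, W, C]`, or a matrix `[H, W]` promoted to a
#'   single-channel map.
#' @return the validated array, dim `c(H, W, C)`.
#' @export
feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be a [H, W, C] array")
  if (any(dim(x) < 1L)) stop("feature map extents must all be >= 1")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  storage.mode(x) <- "double"
  x
}

fm_dims <- function(x) {
  d <- dim(x)
  list(H = d[1L], W = d[2L], C = d[3L])
}

# ---- parameter trees --------------------------------------------------------
# Layers are named lists whose double-typed leaves are trainable parameters;
# structural metadata lives under the ".meta" key and is never updated.

tree_idx <- function(p) {
  nms <- names(p)
  if (is.null(nms)) seq_along(p) else which(nms != ".meta")
}

tree_map <- function(p, f) {
  if (is.list(p)) {
    for (i in tree_idx(p)) p[[i]] <- tree_map(p[[i]], f)
    p
  } else if (is.double(p)) f(p) else p
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    for (i in tree_idx(a)) a[[i]] <- tree_map2(a[[i]], b[[i]], f)
    a
  } else if (is.double(a)) f(a, b) else a
}

tree_zero <- function(p) tree_map(p, function(x) x * 0)

tree_add <- function(a, b) tree_map2(a, b, function(x, y) x + y)

tree_scale <- function(p, s) tree_map(p, function(x) x * s)

# Flatten all trainable leaves to one numeric vector (freeze audits, hashes).
tree_flatten <- function(p) {
  acc <- list()
  walk <- function(q) {
    if (is.list(q)) {
      for (i in tree_idx(q)) walk(q[[i]])
    } else if (is.double(q)) acc[[length(acc) + 1L]] <<- as.vector(q)
  }
  walk(p)
  unlist(acc, use.names = FALSE)
}

# One SGD step with classical momentum and L2 weight decay:
#   v <- momentum * v - lr * (g + wd * p);  p <- p + v
sgd_step <- function(params, grads, vel, lr, momentum, weight_decay) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      for (i in tree_idx(p)) {
        r <- walk(p[[i]], g[[i]], v[[i]])
        p[[i]] <- r$p; v[[i]] <- r$v
      }
      list(p = p, v = v)
    } else if (is.double(p)) {
      gg <- g + weight_decay * p
      v <- momentum * v - lr * gg
      list(p = p + v, v = v)
    } else list(p = p, v = v)
  }
  walk(params, grads, vel)
}

# ---- weight init ------------------------------------------------------------
# Kaiming-style normal init, sd = sqrt(2 / fan_in); biases start at zero.

kaiming <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

# ---- convolution ------------------------------------------------------------

conv_layer <- function(kh, kw, cin, cout, stride = c(1L, 1L), pad = c(0L, 0L),
                       init = c("kaiming", "zero")) {
  init <- match.arg(init)
  n <- kh * kw * cin * cout
  w <- if (init == "zero") numeric(n) else kaiming(n, kh * kw * cin)
  list(w = array(w, dim = c(kh, kw, cin, cout)),
       b = numeric(cout),
       .meta = list(kh = as.integer(kh), kw = as.integer(kw),
                    cin = as.integer(cin), cout = as.integer(cout),
                    sh = as.integer(stride[1L]), sw = as.integer(stride[2L]),
                    ph = as.integer(pad[1L]), pw = as.integer(pad[2L])))
}

conv_forward <- function(layer, x) {
  m <- layer$.meta
  if (dim(x)[3L] != m$cin)
    stop(sprintf("conv expects %d input channels, got %d", m$cin, dim(x)[3L]))
  .conv2d_fwd(x, as.vector(layer$w), layer$b, m$kh, m$kw, m$cout,
              m$sh, m$sw, m$ph, m$pw)
}

conv_backward <- function(layer, x, dout) {
  m <- layer$.meta
  r <- .conv2d_bwd(x, as.vector(layer$w), dout, m$kh, m$kw, m$sh, m$sw, m$ph, m$pw)
  list(dx = r$dx,
       dparams = list(w = array(r$dw, dim = dim(layer$w)), b = as.vector(r$db)))
}

# ---- normalization ----------------------------------------------------------
# Per-sample, per-channel normalization with learned affine (gamma, beta):
# batch normalization evaluated at batch size one, so the same statistics are
# used at train and test time and the layer carries no running state.

norm_layer <- function(C, enabled = TRUE, eps = 1e-5) {
  list(gamma = rep(1, C), beta = numeric(C),
       .meta = list(C = as.integer(C), eps = eps, enabled = isTRUE(enabled)))
}

norm_forward <- function(layer, x) {
  m <- layer$.meta
  if (!m$enabled) return(list(out = x, cache = NULL))
  d <- dim(x); hw <- d[1L] * d[2L]
  xm <- matrix(x, hw, d[3L])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + m$eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  out <- sweep(sweep(xhat, 2L, layer$gamma, `*`), 2L, layer$beta, `+`)
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, istd = istd, d = d))
}

norm_backward <- function(layer, cache, dout) {
  m <- layer$.meta
  if (!m$enabled)
    return(list(dx = dout, dparams = list(gamma = numeric(m$C), beta = numeric(m$C))))
  d <- cache$d; hw <- d[1L] * d[2L]
  dm <- matrix(dout, hw, d[3L])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2L, layer$gamma, `*`)
  # dX = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per channel
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2L, cache$istd, `*`)
  dim(dx) <- d
  list(dx = dx, dparams = list(gamma = dgamma, beta = dbeta))
}

# ---- activations ------------------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(mask, dout) dout * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- pooling ----------------------------------------------------------------

maxpool_forward <- function(x, k, stride, pad = 0L) {
  r <- .maxpool_fwd(x, as.integer(k), as.integer(stride), as.integer(pad))
  list(out = r$out, cache = list(idx = r$idx, H = dim(x)[1L], W = dim(x)[2L]))
}

maxpool_backward <- function(cache, dout)
  .maxpool_bwd(cache$idx, dout, cache$H, cache$W)

avgpool_forward <- function(x, k, stride) .avgpool_fwd(x, as.integer(k), as.integer(stride))

avgpool_backward <- function(dout, k, stride, H, W)
  .avgpool_bwd(dout, as.integer(k), as.integer(stride), as.integer(H), as.integer(W))

global_avgpool_forward <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1L] * d[2L], d[3L]))
}

global_avgpool_backward <- function(dvec, H, W) {
  C <- length(dvec)
  array(rep(dvec / (H * W), each = H * W), dim = c(H, W, C))
}

# ---- dense (fully connected) ------------------------------------------------

linear_layer <- function(din, dout, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") numeric(din * dout) else kaiming(din * dout, din)
  list(w = matrix(w, dout, din), b = numeric(dout),
       .meta = list(din = as.integer(din), dout = as.integer(dout)))
}

linear_forward <- function(layer, v) as.vector(layer$w %*% v + layer$b)

linear_backward <- function(layer, v, dout) {
  list(dx = as.vector(crossprod(layer$w, dout)),
       dparams = list(w = outer(dout, v), b = dout))
}

# ---- softmax / cross-entropy ------------------------------------------------

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# label: 1-based class index; returns loss and dlogits
softmax_xent <- function(logits, label) {
  p <- softmax(logits)
  loss <- -log(max(p[label], 1e-12))
  d <- p
  d[label] <- d[label] - 1
  list(loss = loss, probs = p, dlogits = d)
}
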