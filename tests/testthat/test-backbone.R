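test_that("multi-scale block with identity kernels yields the cumulative-subset pattern", {
  k <- 8; g <- 2
  p <- msblock_params(k, k, r = 4, use_bn = FALSE, init = "zero")
  p$conv0$w <- ident_kernel(1, 1, k, 1, 1)
  for (nm in c("k2", "k3", "k4")) {
    p[[nm]]$conv_a$w <- ident_kernel(3, 1, g, 2, 1)
    p[[nm]]$conv_b$w <- ident_kernel(1, 3, g, 1, 2)
  }
  set.seed(31)
  x <- array(runif(5 * 5 * k), c(5, 5, k))   # nonnegative so ReLU is inert
  out <- msblock_forward(x, p)
  X <- lapply(1:4, function(i) x[, , (i - 1) * g + 1:g, drop = FALSE])
  cum <- list(X[[1]], X[[1]] + X[[2]], X[[1]] + X[[2]] + X[[3]],
              X[[1]] + X[[2]] + X[[3]] + X[[4]])
  # loop-oracle re-derivation of y_i = K_i(X_i + y_{i-1}) with identity K
  y <- X[[1]]
  for (i in 2:4) {
    y <- X[[i]] + y
    expect_equal(out[, , (i - 1) * g + 1:g, drop = FALSE], 3 * y,
                 tolerance = 1e-12)
  }
  expect_equal(out, 3 * mvnn:::cat3(cum), tolerance = 1e-12)
})

test_that("multi-scale block propagates zero and keeps k output channels", {
  set.seed(32)
  p <- msblock_params(6, 8, r = 4)
  z <- msblock_forward(array(0, c(6, 6, 6)), p)
  expect_equal(z, array(0, c(6, 6, 8)))
  out <- msblock_forward(array(rnorm(6 * 6 * 6), c(6, 6, 6)), p)
  expect_equal(dim(out), c(6L, 6L, 8L))
  expect_error(msblock_params(6, 6, r = 2), "divisible by 4")
})

test_that("dense block channel arithmetic and connection count follow dense connectivity", {
  set.seed(33)
  db <- dense_block_params(64, 6, 32, r = 16)
  x <- array(rnorm(4 * 4 * 64), c(4, 4, 64))
  f <- mvnn:::dense_block_forward_cache(x, db)
  expect_equal(dim(f$out)[3], 64L + 6L * 32L)   # 256
  expect_equal(sum(f$reads), 21)                # L(L+1)/2 for L = 6
  expect_equal(dense_block_connections(6), 21)
  # degenerate L = 1 equals one block plus concatenation
  db1 <- dense_block_params(8, 1, 8, r = 4)
  x1 <- array(rnorm(5 * 5 * 8), c(5, 5, 8))
  got <- dense_block_forward(x1, db1)
  want <- mvnn:::cat3(list(x1, msblock_forward(x1, db1$layers[[1]])))
  expect_equal(got, want)
})

test_that("transition halves channels and spatial size and matches the pooling oracle", {
  set.seed(34)
  tp <- transition_params(16)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  out <- transition_forward(x, tp)
  expect_equal(dim(out), c(4L, 4L, 8L))
  # pooling stage equals a naive strided-window mean of the conv output
  nf <- mvnn:::norm_forward(tp$bn, x)
  h <- naive_conv(nf$out, tp$conv$w, tp$conv$b)
  for (c in sample(8, 3)) for (i in 1:4) for (j in 1:4)
    expect_equal(out[i, j, c],
                 mean(h[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]),
                 tolerance = 1e-10)
  expect_error(transition_params(15), "even")
  expect_error(transition_forward(array(0, c(7, 8, 16)), tp), "even")
})

test_that("depth accounting reproduces the canonical 186 and its closed form", {
  expect_equal(count_depth(backbone_spec()), 186L)
  expect_equal(count_depth(backbone_spec(block_sizes = 1L)), 4L)
  for (bs in list(c(2, 2), c(3, 5, 7), c(6, 12, 24, 32, 16))) {
    spec <- backbone_spec(block_sizes = as.integer(bs))
    expect_equal(count_depth(spec), 2L * sum(bs) + (length(bs) - 1L) + 2L)
  }
})

test_that("factorized 3x1 + 1x3 pairs use 6g^2 weights against 9g^2 for a full 3x3", {
  g <- 8
  p <- msblock_params(32, 32, r = 4)
  n_pair <- length(p$k2$conv_a$w) + length(p$k2$conv_b$w)
  expect_equal(n_pair, 6 * g^2)
  expect_equal(3 * 3 * g * g, 9 * g^2)
  expect_lt(n_pair, 9 * g^2)
})

test_that("later subsets have wider impulse response (receptive-field growth)", {
  k <- 8; g <- 2
  p <- msblock_params(k, k, r = 4, use_bn = FALSE, init = "zero")
  # spread input into all subsets; all-ones K kernels spread support
  w0 <- array(0, c(1, 1, k, k))
  for (d in 1:k) w0[1, 1, 1, d] <- 1
  p$conv0$w <- w0
  for (nm in c("k2", "k3", "k4")) {
    p[[nm]]$conv_a$w <- array(1, c(3, 1, g, g))
    p[[nm]]$conv_b$w <- array(1, c(1, 3, g, g))
  }
  x <- array(0, c(15, 15, k)); x[8, 8, 1] <- 1
  out <- msblock_forward(x, p)
  support_width <- function(ch) {
    nz <- which(out[, , ch] != 0, arr.ind = TRUE)
    max(nz[, 1]) - min(nz[, 1]) + 1
  }
  w_y2 <- support_width(g + 1)        # one K application: 3
  w_y4 <- support_width(3 * g + 1)    # three K applications: 7
  expect_equal(w_y2, 3)
  expect_equal(w_y4, 7)
  expect_gt(w_y4, w_y2)
})

test_that("small backbone tracks channels, halves sizes, and validates input", {
  spec <- small_spec(48)
  ch <- backbone_channels(spec)
  expect_equal(unname(ch), c(16, 16 + 16, 16, 16 + 16))
  params <- backbone_init(spec, seed = 41)
  img <- array(runif(48 * 48), c(48, 48, 1))
  r <- backbone_forward(img, params, spec)
  expect_equal(unname(r$trace),
               c(24, 12, 12, 12, 6, 6, 1))
  expect_length(r$features, 32)
  expect_error(backbone_forward(array(0, c(32, 32, 1)), params, spec), "512|48")
  # determinism of the forward pass
  r2 <- backbone_forward(img, params, spec)
  expect_identical(r$features, r2$features)
})
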