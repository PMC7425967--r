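test_that("pooled descriptors match direct loop computation", {
  set.seed(21)
  F <- array(rnorm(3 * 4 * 4), c(4, 4, 3))  # 3 channels on a 4x4 grid
  d <- pool_descriptors(F)
  for (c in 1:3) {
    expect_equal(d$channel_avg[c], mean(F[, , c]))
    expect_equal(d$channel_max[c], max(F[, , c]))
  }
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d$spatial_avg[i, j], mean(F[i, j, ]))
    expect_equal(d$spatial_max[i, j], max(F[i, j, ]))
  }
  expect_true(all(d$channel_max >= d$channel_avg))
  expect_true(all(d$spatial_max >= d$spatial_avg))
})

test_that("pooled descriptors handle constant and single-spike fields", {
  F <- array(0.3, c(5, 6, 2))
  d <- pool_descriptors(F)
  expect_equal(unname(d$channel_avg), c(0.3, 0.3))
  expect_equal(unname(d$channel_max), c(0.3, 0.3))
  expect_true(all(d$spatial_avg == 0.3) && all(d$spatial_max == 0.3))
  spike <- array(0, c(4, 5, 1)); spike[2, 3, 1] <- 1
  d2 <- pool_descriptors(spike)
  expect_equal(d2$channel_avg[1], 1 / 20)
  expect_equal(d2$channel_max[1], 1)
  expect_error(pool_descriptors(array(Inf, c(2, 2, 1))), "finite")
})

test_that("channel attention: zero parameters give 0.5, identity weights give sigmoid(2, 0)", {
  F <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  p0 <- csam_params(4, r = 2, init = "zero")
  expect_equal(channel_attention(F, p0), rep(0.5, 4))
  # C = 2, r = 1, identity MLP; channel means and maxima (1, 0)
  p <- csam_params(2, r = 1, init = "zero")
  p$W0 <- diag(2); p$W1 <- diag(2)
  Fc <- array(c(rep(1, 9), rep(0, 9)), c(3, 3, 2))
  expect_equal(channel_attention(Fc, p), 1 / (1 + exp(-c(2, 0))), tolerance = 1e-6)
  expect_equal(round(channel_attention(Fc, p), 4), c(0.8808, 0.5))
})

test_that("channel and spatial attention match straight-line formula oracles", {
  set.seed(22)
  for (rep in 1:3) {
    F <- array(rnorm(9 * 9 * 4), c(9, 9, 4))
    p <- csam_params(4, r = 2)
    expect_equal(channel_attention(F, p), oracle_channel_attention(F, p),
                 tolerance = 1e-6)
    expect_equal(spatial_attention(F, p), oracle_spatial_attention(F, p),
                 tolerance = 1e-6)
  }
})

test_that("spatial attention: zero parameters give a uniform 0.5 map, constant input a uniform interior", {
  F <- array(rnorm(6 * 7 * 3), c(6, 7, 3))
  p0 <- csam_params(3, r = 3, init = "zero")
  expect_equal(spatial_attention(F, p0), matrix(0.5, 6, 7))
  set.seed(23)
  p <- csam_params(3, r = 3)
  Fc <- array(0.4, c(12, 12, 3))
  m <- spatial_attention(Fc, p)
  interior <- m[5:8, 5:8]  # away from zero-padding border effects
  expect_lt(diff(range(interior)), 1e-12)
})

test_that("CSAM forward obeys the residual aggregation identities", {
  set.seed(24)
  F <- array(rnorm(5 * 6 * 4), c(5, 6, 4))
  p0 <- csam_params(4, r = 2, init = "zero")
  expect_equal(csam_forward(F, p0), 3 * F)                 # sigma(0) = 0.5 branch
  p <- csam_params(4, r = 2)
  expect_equal(csam_forward(array(0, c(5, 6, 4)), p), array(0, c(5, 6, 4)))
  out <- csam_forward(F, p)
  expect_equal(dim(out), dim(F))
  # F' = 2F + F (*) (M_C broadcast-sum M_S), with branch maps from the oracles
  Mc <- oracle_channel_attention(F, p)
  Ms <- oracle_spatial_attention(F, p)
  want <- F * 0
  for (c in 1:4) want[, , c] <- 2 * F[, , c] + F[, , c] * (Mc[c] + Ms)
  expect_equal(out, want, tolerance = 1e-6)
})

test_that("attention values are in (0,1) and monotone in the channel bias", {
  set.seed(25)
  F <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  p <- csam_params(4, r = 2)
  mc <- channel_attention(F, p)
  ms <- spatial_attention(F, p)
  expect_true(all(mc > 0 & mc < 1))
  expect_true(all(ms > 0 & ms < 1))
  for (i in 1:4) {
    p2 <- p
    p2$b1[i] <- p2$b1[i] + 0.7
    mc2 <- channel_attention(F, p2)
    expect_gte(mc2[i], mc[i])
  }
})

test_that("CSAM validates shapes and the reduction ratio", {
  expect_error(csam_params(6, r = 4), "divisible")
  p <- csam_params(4, r = 2)
  expect_error(csam_forward(array(0, c(3, 3, 6)), p), "channels")
})
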