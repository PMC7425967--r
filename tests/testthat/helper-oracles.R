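# Independent reference implementations used as oracles. These deliberately
# use plain loops / direct formulas, not the package's kernels.

naive_conv <- function(x, w, b, sh = 1, sw = 1, ph = 0, pw = 0) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  Ho <- (H + 2 * ph - kh) %/% sh + 1
  Wo <- (W + 2 * pw - kw) %/% sw + 1
  y <- array(0, c(Ho, Wo, cout))
  for (d in seq_len(cout)) for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
    acc <- b[d]
    for (c in seq_len(cin)) for (a in seq_len(kh)) for (bb in seq_len(kw)) {
      ii <- (oi - 1) * sh - ph + a
      jj <- (oj - 1) * sw - pw + bb
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * w[a, bb, c, d]
    }
    y[oi, oj, d] <- acc
  }
  y
}

# pairwise-ordering (Mann-Whitney) AUC with ties counted half
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# straight-line evaluation of the channel attention formula
oracle_channel_attention <- function(F, p) {
  C <- dim(F)[3]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) { avg[c] <- mean(F[, , c]); mx[c] <- max(F[, , c]) }
  mlp <- function(v) as.vector(p$W1 %*% pmax(p$W0 %*% v + p$b0, 0) + p$b1)
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

# straight-line evaluation of the spatial attention formula via naive convs
oracle_spatial_attention <- function(F, p) {
  H <- dim(F)[1]; W <- dim(F)[2]
  avg <- apply(F, c(1, 2), mean)
  mx <- apply(F, c(1, 2), max)
  s2 <- array(c(avg, mx), c(H, W, 2))
  h1 <- naive_conv(s2, p$conv_reduce$w, p$conv_reduce$b)
  h2 <- naive_conv(h1, p$conv7x1$w, p$conv7x1$b, ph = 3, pw = 0)
  h3 <- naive_conv(h2, p$conv1x7$w, p$conv1x7$b, ph = 0, pw = 3)
  matrix(1 / (1 + exp(-h3[, , 1])), H, W)
}

# identity-impulse 4-D kernel: output channel d copies input channel d
ident_kernel <- function(kh, kw, cin, ch, cw) {
  w <- array(0, c(kh, kw, cin, cin))
  for (c in seq_len(cin)) w[ch, cw, c, c] <- 1
  w
}

# small backbone used across training tests
small_spec <- function(input_size = 48L)
  backbone_spec(input_size = input_size, stem_channels = 16L,
                block_sizes = c(2L, 2L), growth_rate = 8L, r = 4L)

# easy-contrast screening phantoms: large, bright mass lesions
easy_dataset <- function(n, seed, image_size = 48L)
  generate_dataset(n, c(normal = 0.5, benign = 0.25, malignant = 0.25),
                   seed = seed, image_size = image_size,
                   lesion_contrast = 0.8, mass_radius_frac = c(0.18, 0.28),
                   lesion_types = "mass")

preprocess_cases <- function(cases, size) {
  pc <- preprocess_config(target_size = size)
  lapply(cases, function(cs) {
    cs$cc <- preprocess(as.matrix(cs$cc[, , 1]), pc)
    cs$mlo <- preprocess(as.matrix(cs$mlo[, , 1]), pc)
    cs
  })
}

screening_labels <- function(cases)
  ifelse(vapply(cases, `[[`, "", "label") == "normal", 1L, 2L)
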