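# Data enhancement.
#
# Single-view expansion (default 50x): each output image is produced by one
# or two geometric operations (flip up-down, flip left-right, random crop,
# random scale in [0.8, 1], translation by 10% in one of four directions)
# followed by one or two photometric operations (contrast/gamma adjustment,
# Gaussian noise, random rotation in [0, 180] degrees).
#
# Two-view expansion preserves the inter-view correlation: a CC up-down flip
# leaves the MLO view untouched; a left-right flip is applied to both views
# jointly. The closure of the two rules (identity, rule 1, rule 2, their
# composition) gives four pairs.

#' Augmentation configuration
#'
#' @param n_single number of augmented images per input in the single-view
#'   expansion, default 50.
#' @param scale_range random-scaling factor range, canonically `[0.8, 1]`.
#' @param translate_frac translation magnitude as a fraction of the side
#'   length, canonically 0.10.
#' @param rotation_range rotation angle range in degrees, canonically
#'   `[0, 180]`.
#' @param noise_sigma Gaussian noise standard deviation in `[0, 1]` intensity
#'   units, default 0.01.
#' @param gamma_range contrast (gamma) adjustment range, default
#'   `[0.8, 1.2]`.
#' @param crop_range random-crop side fraction range, default `[0.85, 1]`.
#' @param seed RNG seed making the expansion reproducible.
#' @return list of class `"augment_config"`.
#' @export
augment_config <- function(n_single = 50L, scale_range = c(0.8, 1.0),
                           translate_frac = 0.10, rotation_range = c(0, 180),
                           noise_sigma = 0.01, gamma_range = c(0.8, 1.2),
                           crop_range = c(0.85, 1.0), seed = 1L) {
  if (n_single < 1L) stop("n_single must be >= 1")
  if (scale_range[1L] < 0.8 - 1e-9 || scale_range[2L] > 1 + 1e-9)
    stop("scale_range must lie within [0.8, 1]")
  structure(list(n_single = as.integer(n_single), scale_range = scale_range,
                 translate_frac = translate_frac,
                 rotation_range = rotation_range, noise_sigma = noise_sigma,
                 gamma_range = gamma_range, crop_range = crop_range,
                 seed = as.integer(seed)),
            class = "augment_config")
}

as_mat <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1L]
  as.matrix(x)
}

#' Flip an image up-down (reverse rows)
#' @param x image matrix.
#' @return flipped matrix.
#' @export
flip_ud <- function(x) { x <- as_mat(x); x[nrow(x):1L, , drop = FALSE] }

#' Flip an image left-right (reverse columns)
#' @param x image matrix.
#' @return flipped matrix.
#' @export
flip_lr <- function(x) { x <- as_mat(x); x[, ncol(x):1L, drop = FALSE] }

resize_mat <- function(x, h, w)
  matrix(EBImage::imageData(EBImage::resize(x, w = h, h = w)), h, w)

aug_crop <- function(x, frac) {
  h <- nrow(x); w <- ncol(x)
  ch <- max(2L, round(frac * h)); cw <- max(2L, round(frac * w))
  oi <- sample.int(h - ch + 1L, 1L); oj <- sample.int(w - cw + 1L, 1L)
  resize_mat(x[oi:(oi + ch - 1L), oj:(oj + cw - 1L), drop = FALSE], h, w)
}

aug_scale <- function(x, s) {
  h <- nrow(x); w <- ncol(x)
  nh <- max(2L, round(s * h)); nw <- max(2L, round(s * w))
  y <- resize_mat(x, nh, nw)
  out <- matrix(0, h, w)
  oi <- (h - nh) %/% 2L; oj <- (w - nw) %/% 2L
  out[oi + seq_len(nh), oj + seq_len(nw)] <- y
  out
}

aug_translate <- function(x, frac, dir) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  di <- round(frac * h); dj <- round(frac * w)
  switch(dir,
    up    = { out[seq_len(h - di), ] <- x[di + seq_len(h - di), ] },
    down  = { out[di + seq_len(h - di), ] <- x[seq_len(h - di), ] },
    left  = { out[, seq_len(w - dj)] <- x[, dj + seq_len(w - dj)] },
    right = { out[, dj + seq_len(w - dj)] <- x[, seq_len(w - dj)] })
  out
}

aug_gamma <- function(x, g) pmin(pmax(x, 0), 1)^g

aug_noise <- function(x, sigma)
  pmin(pmax(x + matrix(rnorm(length(x), sd = sigma), nrow(x)), 0), 1)

aug_rotate <- function(x, angle) {
  y <- EBImage::rotate(x, angle, output.dim = c(nrow(x), ncol(x)), bg.col = 0)
  pmin(pmax(matrix(EBImage::imageData(y), nrow(x), ncol(x)), 0), 1)
}

#' Single-view augmentation
#'
#' Produces exactly `cfg$n_single` augmented copies of one preprocessed view.
#' Each copy applies 1-2 randomly chosen geometric operations followed by
#' 1-2 randomly chosen photometric operations; the whole expansion is
#' reproducible from `cfg$seed`.
#'
#' @param img preprocessed view (`[H, W]` matrix or `[H, W, 1]` array,
#'   values in `[0, 1]`).
#' @param cfg [augment_config()].
#' @return list of `n_single` matrices, same shape as the input, values in
#'   `[0, 1]`.
#' @export
augment_single_view <- function(img, cfg = augment_config()) {
  x0 <- as_mat(img)
  set.seed(cfg$seed)
  geo <- c("flip_ud", "flip_lr", "crop", "scale", "translate")
  photo <- c("gamma", "noise", "rotate")
  lapply(seq_len(cfg$n_single), function(i) {
    x <- x0
    for (op in sample(geo, sample(1:2, 1L))) {
      x <- switch(op,
        flip_ud = flip_ud(x),
        flip_lr = flip_lr(x),
        crop = aug_crop(x, runif(1L, cfg$crop_range[1L], cfg$crop_range[2L])),
        scale = aug_scale(x, runif(1L, cfg$scale_range[1L], cfg$scale_range[2L])),
        translate = aug_translate(x, cfg$translate_frac,
                                  sample(c("up", "down", "left", "right"), 1L)))
    }
    for (op in sample(photo, sample(1:2, 1L))) {
      x <- switch(op,
        gamma = aug_gamma(x, runif(1L, cfg$gamma_range[1L], cfg$gamma_range[2L])),
        noise = aug_noise(x, cfg$noise_sigma),
        rotate = aug_rotate(x, runif(1L, cfg$rotation_range[1L],
                                     cfg$rotation_range[2L])))
    }
    pmin(pmax(x, 0), 1)
  })
}

#' Correlation-preserving two-view augmentation
#'
#' Expands a CC/MLO pair by the two flip rules that respect the inter-view
#' relationship: (1) flipping the CC view up-down while the MLO view stays
#' unchanged; (2) flipping both views left-right jointly. The default output
#' is the closure of the rules: identity, rule 1, rule 2, and their
#' composition (4 pairs); `include_composition = FALSE` drops the fourth.
#'
#' @param cc,mlo the two view images.
#' @param include_composition emit the rule1-then-rule2 pair too.
#' @return list of `list(cc = , mlo = )` pairs, the first being the
#'   unchanged input.
#' @export
augment_two_view <- function(cc, mlo, include_composition = TRUE) {
  cc <- as_mat(cc); mlo <- as_mat(mlo)
  out <- list(
    list(cc = cc, mlo = mlo),
    list(cc = flip_ud(cc), mlo = mlo),
    list(cc = flip_lr(cc), mlo = flip_lr(mlo)))
  if (include_composition)
    out[[4L]] <- list(cc = flip_lr(flip_ud(cc)), mlo = flip_lr(mlo))
  out
}
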