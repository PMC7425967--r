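# Synthetic two-view breast phantoms.
#
# Each case renders a bright half-elliptical breast region (chest wall at the
# left image edge) over a dark background, with smoothed-noise parenchymal
# texture; the MLO view additionally carries a brighter pectoral-muscle wedge
# in its upper-left corner. Abnormal cases plant one lesion at a normalized
# depth coordinate shared between the two views (the only cross-view
# correlation modeled — no physical projection geometry): a Gaussian mass
# (smooth when benign, spiculated when malignant) or a cluster of 1-3 px
# bright calcification specks. Ground-truth lesion masks are returned for
# both views. Everything is deterministic given the seed.

#' Phantom case specification
#'
#' @param label `"normal"`, `"benign"` or `"malignant"`.
#' @param image_size side length in pixels, default 512.
#' @param lesion_type `"mass"` or `"calcification"` (ignored for normal
#'   cases; required otherwise).
#' @param n_calcifications specks per calcification cluster, default 6.
#' @param mass_radius_frac mass radius range as a fraction of the image
#'   side, default `c(0.05, 0.09)`.
#' @param spiculation number of radial spikes on malignant masses, default 8.
#' @param lesion_contrast added intensity of the lesion over the local
#'   background, default 0.35 (clearly visible; lower values make the
#'   classification task harder).
#' @param background_texture_scale amplitude of the smoothed parenchymal
#'   noise texture, default 0.15.
#' @param seed per-case RNG seed.
#' @return list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(label, image_size = 512L, lesion_type = NULL,
                         n_calcifications = 6L,
                         mass_radius_frac = c(0.05, 0.09), spiculation = 8L,
                         lesion_contrast = 0.35,
                         background_texture_scale = 0.15, seed = 1L) {
  label <- match.arg(label, CASE_LABELS)
  if (label == "normal") {
    lesion_type <- NULL
  } else {
    if (is.null(lesion_type)) stop("abnormal phantom requires a lesion_type")
    lesion_type <- match.arg(lesion_type, LESION_TYPES)
    if (lesion_type == "calcification" && n_calcifications < 1L)
      stop("n_calcifications must be >= 1")
  }
  structure(list(label = label, image_size = as.integer(image_size),
                 lesion_type = lesion_type,
                 n_calcifications = as.integer(n_calcifications),
                 mass_radius_frac = mass_radius_frac,
                 spiculation = as.integer(spiculation),
                 lesion_contrast = lesion_contrast,
                 background_texture_scale = background_texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

smooth_noise <- function(S, sigma) {
  z <- matrix(rnorm(S * S), S, S)
  z <- EBImage::imageData(EBImage::gblur(z, sigma = sigma))
  z / max(abs(z))
}

# breast interior indicator and normalized depth (0 at chest wall, 1 at the
# breast apex) for a half-ellipse anchored on the left image edge
breast_geometry <- function(S, extent = 0.85, half_height = 0.42) {
  jj <- matrix(rep(seq_len(S), each = S), S, S)    # column index
  ii <- matrix(rep(seq_len(S), S), S, S)           # row index
  u <- (jj - 1) / (extent * S)
  v <- (ii - S / 2) / (half_height * S)
  rho <- sqrt(u^2 + v^2)
  list(inside = rho <= 1, rho = rho, depth = u, lateral = v, ii = ii, jj = jj)
}

render_view <- function(S, geom, spec, lesion, pectoral = FALSE) {
  img <- matrix(0.03, S, S)
  base <- 0.45 + 0.25 * pmax(1 - geom$rho^2, 0)
  tex <- spec$background_texture_scale *
    smooth_noise(S, sigma = max(2, S / 40))
  img[geom$inside] <- pmin(pmax(base[geom$inside] + tex[geom$inside], 0.05), 0.9)
  if (pectoral) {
    wedge <- geom$jj < 0.30 * S - 0.35 * geom$ii & geom$ii < 0.85 * S
    img[wedge & geom$inside] <- pmin(img[wedge & geom$inside] + 0.18, 0.95)
  }
  mask <- matrix(FALSE, S, S)
  if (!is.null(lesion)) {
    ci <- lesion$ci; cj <- lesion$cj
    d2 <- (geom$ii - ci)^2 + (geom$jj - cj)^2
    if (lesion$type == "mass") {
      r <- lesion$radius
      img <- img + spec$lesion_contrast * exp(-d2 / (2 * (r / 1.8)^2))
      if (lesion$spiculated) {
        ang <- seq(0, 2 * pi, length.out = spec$spiculation + 1L)[-1L] +
          lesion$spike_phase
        for (a in ang) {
          tpar <- seq(0, 2.2 * r, by = 0.5)
          si <- round(ci + tpar * sin(a)); sj <- round(cj + tpar * cos(a))
          ok <- si >= 1 & si <= S & sj >= 1 & sj <= S
          decay <- spec$lesion_contrast * 0.55 * exp(-tpar / (1.5 * r))
          img[cbind(si[ok], sj[ok])] <-
            pmin(img[cbind(si[ok], sj[ok])] + decay[ok], 1)
        }
      }
      mask <- d2 <= r^2
    } else {
      for (q in seq_len(nrow(lesion$specks))) {
        si <- lesion$specks[q, 1L]; sj <- lesion$specks[q, 2L]
        sr <- lesion$specks[q, 3L]
        sel <- (geom$ii - si)^2 + (geom$jj - sj)^2 <= sr^2
        img[sel] <- 0.95
        mask <- mask | sel
      }
    }
  }
  list(img = pmin(pmax(img, 0), 1), mask = mask)
}

place_lesion <- function(S, geom_extent, spec, depth, view_seed_draws) {
  # depth shared across views; lateral position and nuisance angles per view
  lat <- view_seed_draws$lat
  ci <- round(S / 2 + lat * 0.42 * S * sqrt(max(1 - depth^2, 0.05)) * 0.6)
  cj <- round(1 + depth * geom_extent * S)
  les <- list(ci = ci, cj = cj, type = spec$lesion_type)
  if (spec$lesion_type == "mass") {
    les$radius <- view_seed_draws$radius
    les$spiculated <- spec$label == "malignant"
    les$spike_phase <- view_seed_draws$phase
  } else {
    n <- spec$n_calcifications
    # specks on jittered rings around the cluster center, so that pairwise
    # separation is guaranteed and the cluster scales with the image
    ring <- max(0.06 * S, 9)
    pts <- matrix(0, 0, 3)
    guard <- 0L
    while (nrow(pts) < n && guard < 10000L) {
      guard <- guard + 1L
      q <- nrow(pts) + 1L
      a <- 2 * pi * q / min(n, 6L) + runif(1L, -0.25, 0.25) +
        2 * pi * (q %/% 7L) / 12
      rad <- ring * (1 + 0.6 * (q - 1) %/% 6L) * runif(1L, 0.85, 1.1)
      si <- round(ci + rad * sin(a)); sj <- round(cj + rad * cos(a))
      sr <- sample(1:2, 1L)
      if (si < 3L || si > S - 2L || sj < 3L || sj > S - 2L) next
      if (nrow(pts) && any((pts[, 1L] - si)^2 + (pts[, 2L] - sj)^2 < (3 + 2 * sr)^2))
        next
      pts <- rbind(pts, c(si, sj, sr))
    }
    if (nrow(pts) < n)
      stop("could not place calcification cluster; increase image_size")
    les$specks <- pts
  }
  les
}

#' Generate one two-view phantom case
#'
#' @param spec [phantom_spec()].
#' @return [case_pair()] with both views, label, lesion type, and per-view
#'   ground-truth lesion masks.
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$image_size
  set.seed(spec$seed)
  extent <- 0.85
  geom <- breast_geometry(S, extent = extent)
  lesion_cc <- lesion_mlo <- NULL
  if (spec$label != "normal") {
    depth <- runif(1L, 0.25, 0.7)         # shared normalized depth coordinate
    radius <- runif(1L, spec$mass_radius_frac[1L], spec$mass_radius_frac[2L]) * S
    draws_cc <- list(lat = runif(1L, -0.5, 0.5), radius = radius,
                     phase = runif(1L, 0, 2 * pi))
    draws_mlo <- list(lat = runif(1L, -0.5, 0.5), radius = radius,
                      phase = runif(1L, 0, 2 * pi))
    lesion_cc <- place_lesion(S, extent, spec, depth, draws_cc)
    lesion_mlo <- place_lesion(S, extent, spec, depth, draws_mlo)
  }
  cc <- render_view(S, geom, spec, lesion_cc, pectoral = FALSE)
  mlo <- render_view(S, geom, spec, lesion_mlo, pectoral = TRUE)
  case_pair(cc$img, mlo$img, spec$label, lesion_type = spec$lesion_type,
            masks = list(cc = cc$mask, mlo = mlo$mask),
            id = sprintf("phantom_%08d", spec$seed))
}

#' Generate a phantom dataset
#'
#' Class counts follow `class_mix` by largest-remainder rounding; abnormal
#' cases alternate between mass and calcification lesions; per-case seeds
#' derive deterministically from the master seed.
#'
#' @param n_cases number of cases.
#' @param class_mix named proportions over
#'   `c("normal", "benign", "malignant")`, summing to 1.
#' @param seed master seed.
#' @param lesion_types lesion types to cycle through for abnormal cases,
#'   default both `"mass"` and `"calcification"`.
#' @param ... further arguments forwarded to [phantom_spec()]
#'   (e.g. `image_size`, `lesion_contrast`).
#' @return list of [case_pair()] objects.
#' @export
generate_dataset <- function(n_cases,
                             class_mix = c(normal = 1/3, benign = 1/3,
                                           malignant = 1/3),
                             seed = 1L, lesion_types = LESION_TYPES, ...) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8)
  class_mix <- class_mix[class_mix > 0]
  if (n_cases < length(class_mix))
    stop("n_cases is smaller than the number of requested classes")
  raw <- class_mix * n_cases
  counts <- floor(raw)
  rem <- n_cases - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  labels <- rep(names(counts), counts)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  lesions <- rep_len(lesion_types, n_cases)   # alternate over abnormal cases
  out <- vector("list", n_cases)
  li <- 0L
  for (i in seq_len(n_cases)) {
    lt <- NULL
    if (labels[i] != "normal") {
      li <- li + 1L
      lt <- lesions[li]
    }
    sp <- phantom_spec(label = labels[i], lesion_type = lt,
                       seed = case_seeds[i], ...)
    out[[i]] <- generate_case(sp)
    out[[i]]$id <- sprintf("case_%04d", i)
  }
  out
}
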