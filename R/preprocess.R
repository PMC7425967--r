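# Preprocessing chain for raw mammograms: contrast-limited adaptive histogram
# equalization (CLAHE), edge-preserving bilateral filtering, per-image min-max
# normalization to [0, 1], and bilinear resizing to the network input size.

#' Preprocessing configuration
#'
#' @param clahe_clip CLAHE clip limit, default 2.0.
#' @param clahe_tiles CLAHE tile grid `c(nx, ny)`, default 8x8.
#' @param bilateral_diameter bilateral filter window diameter in pixels
#'   (odd), default 9.
#' @param bilateral_sigma_color range sigma on the 0-255 intensity scale
#'   (the conventional parameterization), default 75.
#' @param bilateral_sigma_space spatial sigma in pixels, default 75.
#' @param target_size network input side length, default 512.
#' @return list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(clahe_clip = 2, clahe_tiles = c(8L, 8L),
                              bilateral_diameter = 9L,
                              bilateral_sigma_color = 75,
                              bilateral_sigma_space = 75,
                              target_size = 512L) {
  if (bilateral_diameter %% 2L != 1L) stop("bilateral_diameter must be odd")
  structure(list(clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 bilateral_diameter = as.integer(bilateral_diameter),
                 bilateral_sigma_color = bilateral_sigma_color,
                 bilateral_sigma_space = bilateral_sigma_space,
                 target_size = as.integer(target_size)),
            class = "preprocess_config")
}

to_unit_range <- function(img, bit_depth = NULL) {
  img <- as.matrix(img)
  storage.mode(img) <- "double"
  if (is.null(bit_depth)) {
    mx <- max(img)
    if (mx <= 1) return(img)
    bit_depth <- if (mx <= 255) 8L else 16L
  }
  img / (2^bit_depth - 1)
}

#' Preprocess a raw view image
#'
#' Applies, in order: intensity scaling to `[0, 1]` by bit depth, CLAHE
#' contrast enhancement, bilateral filtering, per-image min-max
#' normalization (a constant image is pinned to all-zero rather than divided
#' by zero), and bilinear resizing to `target_size`.
#'
#' @param img 2-D image: integer counts at 8/16-bit depth, or doubles already
#'   in `[0, 1]`.
#' @param cfg [preprocess_config()].
#' @param bit_depth override the bit-depth autodetection (8 or 16).
#' @return feature map `[target_size, target_size, 1]` with values in
#'   `[0, 1]`.
#' @export
preprocess <- function(img, cfg = preprocess_config(), bit_depth = NULL) {
  if (length(img) == 0L) stop("empty image")
  if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1L]
  x <- to_unit_range(img, bit_depth)
  if (diff(range(x)) > 0) {
    # CLAHE needs extents divisible by the tile grid: replicate-pad, enhance,
    # crop back
    nx <- cfg$clahe_tiles[1L]; ny <- cfg$clahe_tiles[2L]
    h <- nrow(x); w <- ncol(x)
    ph <- (nx - h %% nx) %% nx
    pw <- (ny - w %% ny) %% ny
    xp <- x[c(seq_len(h), rep(h, ph)), c(seq_len(w), rep(w, pw)), drop = FALSE]
    xp <- EBImage::imageData(EBImage::clahe(xp, nx = nx, ny = ny,
                                            limit = cfg$clahe_clip))
    x <- matrix(xp, nrow(xp), ncol(xp))[seq_len(h), seq_len(w), drop = FALSE]
  }
  x <- .bilateral_filter(x, cfg$bilateral_diameter,
                         cfg$bilateral_sigma_color / 255,
                         cfg$bilateral_sigma_space)
  rng <- range(x)
  x <- if (diff(rng) < 1e-12) x * 0 else (x - rng[1L]) / diff(rng)
  x <- EBImage::imageData(EBImage::resize(x, w = cfg$target_size,
                                          h = cfg$target_size))
  x <- pmin(pmax(x, 0), 1)
  feature_map(matrix(x, cfg$target_size, cfg$target_size))
}

#' Read a grayscale view image from disk
#'
#' Reads PNG or TIFF (8/16-bit) via EBImage and returns intensities in
#' `[0, 1]`; multi-channel files are averaged to grayscale.
#'
#' @param path image file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_view <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  pmin(pmax(as.matrix(img), 0), 1)
}

#' Write a grayscale image to disk
#'
#' @param img matrix in `[0, 1]`.
#' @param path output path; format chosen from the extension (PNG/TIFF).
#' @return `path`, invisibly.
#' @export
write_view <- function(img, path) {
  EBImage::writeImage(pmin(pmax(as.matrix(img), 0), 1), path)
  invisible(path)
}
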