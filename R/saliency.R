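# Gradient-weighted class-activation heat maps (Grad-CAM) over the feature
# map entering each branch's global average pool: channel weights are the
# mean gradient of the chosen class logit with respect to that activation;
# the weighted sum is ReLU-rectified, min-max normalized, and upsampled to
# the view size. Because pooling is a global average, the per-channel
# gradient is spatially constant and follows in closed form from the fusion
# and head weights.

#' Min-max normalize a heat map
#'
#' Maps to `[0, 1]`; a constant input (degenerate case) returns all zeros.
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param x numeric matrix.
#' @return matrix in `[0, 1]`.
#' @export
normalize_heat <- function(x) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(x * 0)
  (x - rng[1L]) / diff(rng)
}

jet_colors <- function(n = 256L) {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "#007FFF", "cyan",
                                 "#7FFF7F", "yellow", "#FF7F00", "red",
                                 "#7F0000"))
  ramp(seq(0, 1, length.out = n)) / 255
}

#' Class-activation heat map for one view
#'
#' Computes a Grad-CAM style saliency map for the chosen branch of a
#' two-view model: the gradient of the target-class logit with respect to
#' the branch's last feature map (the activation entering the global average
#' pool) weights the channels; the rectified weighted sum is normalized and
#' upsampled to the view resolution. The model's softmax score P for the
#' target class is reported alongside.
#'
#' @param model [mvnn_model][mvnn_init()] (trained or not; an untrained
#'   model yields a valid but uninformative map).
#' @param case [case_pair()].
#' @param view `"cc"` or `"mlo"`.
#' @param target_class class index into the 2-way softmax (2 = positive
#'   class, the default).
#' @param alpha overlay blending weight of the colormap, default 0.4.
#' @return object of class `"heatmap_overlay"`: `heat` (view-sized matrix in
#'   `[0, 1]`, all-zero if the raw map is constant), `overlay`
#'   (`[H, W, 3]` RGB array), `score` (softmax score P of `target_class`),
#'   `cam` (the coarse unnormalized map), `view`, `target_class`.
#' @export
heatmap_for_view <- function(model, case, view = c("cc", "mlo"),
                             target_class = 2L, alpha = 0.4) {
  view <- match.arg(view)
  stopifnot(inherits(model, "mvnn_model"), inherits(case, "case_pair"))
  fc <- backbone_forward_cache(case$cc, model$branch_cc, model$spec,
                               keep_cache = FALSE)
  fm <- backbone_forward_cache(case$mlo, model$branch_mlo, model$spec,
                               keep_cache = FALSE)
  feat <- c(fc$features, fm$features)
  hf <- fusion_head_fwd(model, feat)
  probs <- softmax(hf$logits)
  # d logit_t / d feat, through the ReLU fusion layer
  mask <- as.numeric(hf$cache$a1 > 0)
  dfeat <- as.vector(crossprod(model$fc1$w, mask * model$fc2$w[target_class, ]))
  cf <- length(fc$features)
  seg <- if (view == "cc") dfeat[seq_len(cf)] else dfeat[cf + seq_len(cf)]
  A <- if (view == "cc") fc$last_act else fm$last_act
  d <- dim(A)
  w_ch <- seg / (d[1L] * d[2L])            # mean spatial gradient per channel
  cam <- matrix(matrix(A, d[1L] * d[2L], d[3L]) %*% w_ch, d[1L], d[2L])
  cam <- pmax(cam, 0)
  src <- as_mat(if (view == "cc") case$cc else case$mlo)
  heat <- normalize_heat(
    matrix(EBImage::imageData(EBImage::resize(cam, w = nrow(src), h = ncol(src))),
           nrow(src), ncol(src)))
  heat <- pmin(pmax(heat, 0), 1)
  pal <- jet_colors()
  idx <- pmin(pmax(round(heat * 255) + 1L, 1L), 256L)
  overlay <- array(0, c(nrow(src), ncol(src), 3L))
  for (ch in 1:3)
    overlay[, , ch] <- (1 - alpha) * src + alpha * matrix(pal[idx, ch], nrow(src))
  structure(list(heat = heat, overlay = pmin(pmax(overlay, 0), 1),
                 score = probs[target_class], cam = cam, view = view,
                 target_class = as.integer(target_class)),
            class = "heatmap_overlay")
}
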