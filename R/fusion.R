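# Two-branch multi-view model (MVNN): independent CC and MLO backbones whose
# pooled feature vectors are concatenated, fused by a 1024-unit fully
# connected layer (ReLU), and classified by a 2-way softmax head. Two such
# models form the cascade: screening (normal vs abnormal) then diagnosis
# (benign vs malignant).

CASE_LABELS <- c("normal", "benign", "malignant")
LESION_TYPES <- c("mass", "calcification")

#' Construct a two-view case
#'
#' One breast: its CC and MLO projections, the case label, and (for phantom
#' data) the lesion type and ground-truth lesion masks.
#'
#' @param cc,mlo single-channel images (`[H, W]` matrices or `[H, W, 1]`
#'   arrays) of the two views.
#' @param label one of `"normal"`, `"benign"`, `"malignant"`.
#' @param lesion_type `"mass"` or `"calcification"`; required iff the label
#'   is not `"normal"`.
#' @param masks optional list with binary `cc` and `mlo` lesion masks
#'   matching the view shapes.
#' @param id optional case identifier.
#' @return object of class `"case_pair"`.
#' @export
case_pair <- function(cc, mlo, label, lesion_type = NULL, masks = NULL,
                      id = NULL) {
  if (is.null(cc) || is.null(mlo)) stop("both CC and MLO views are required")
  cc <- feature_map(cc); mlo <- feature_map(mlo)
  label <- match.arg(label, CASE_LABELS)
  if (label == "normal") {
    if (!is.null(lesion_type)) stop("normal cases carry no lesion_type")
  } else {
    if (is.null(lesion_type)) stop("abnormal cases require a lesion_type")
    lesion_type <- match.arg(lesion_type, LESION_TYPES)
  }
  if (!is.null(masks)) {
    stopifnot(all(dim(masks$cc)[1:2] == dim(cc)[1:2]),
              all(dim(masks$mlo)[1:2] == dim(mlo)[1:2]))
  }
  structure(list(cc = cc, mlo = mlo, label = label, lesion_type = lesion_type,
                 masks = masks, id = id), class = "case_pair")
}

#' Initialize a two-branch multi-view model
#'
#' @param spec [backbone_spec()] shared by both branches (architecturally
#'   identical branches; weights are independent, never tied).
#' @param hidden width of the fusion layer, default 1024 (the canonical
#'   model).
#' @param task `"screening"` (normal vs abnormal) or `"diagnosis"` (benign vs
#'   malignant); class 2 of the softmax is the positive class (abnormal /
#'   malignant).
#' @param seed initialization seed; the two branches draw independent weights.
#' @return object of class `"mvnn_model"`.
#' @export
mvnn_init <- function(spec, hidden = 1024L, task = c("screening", "diagnosis"),
                      seed = 1L) {
  task <- match.arg(task)
  branch_cc <- backbone_init(spec, seed = seed)
  branch_mlo <- backbone_init(spec, seed = seed + 1L)
  cf <- branch_cc$.meta$out_channels
  set.seed(seed + 2L)
  model <- list(spec = spec,
                branch_cc = branch_cc, branch_mlo = branch_mlo,
                fc1 = linear_layer(2L * cf, hidden),
                fc2 = linear_layer(hidden, 2L),
                task = task,
                hidden = as.integer(hidden))
  class(model) <- "mvnn_model"
  model
}

fusion_head_fwd <- function(model, feat) {
  z1 <- linear_forward(model$fc1, feat)
  r1 <- relu_forward(z1)
  logits <- linear_forward(model$fc2, r1$out)
  list(logits = logits, cache = list(feat = feat, r1 = r1$cache, a1 = r1$out))
}

fusion_head_bwd <- function(model, cache, dlogits) {
  b2 <- linear_backward(model$fc2, cache$a1, dlogits)
  da1 <- relu_backward(cache$r1, b2$dx)
  b1 <- linear_backward(model$fc1, cache$feat, da1)
  list(dfeat = b1$dx, dparams = list(fc1 = b1$dparams, fc2 = b2$dparams))
}

#' Multi-view forward pass
#'
#' Runs both views through their branches, concatenates the two pooled
#' feature vectors, applies the fusion layer (affine + ReLU) and softmax
#' head.
#'
#' @param case [case_pair()]; both views must match the model's input size.
#' @param model [mvnn_model][mvnn_init()].
#' @return list of class `"mvnn_prediction"`: `probs` (2-vector summing to 1,
#'   `(negative, positive)`), `score` (softmax score P of the positive
#'   class), and `label` (task-specific class name at the 0.5 threshold).
#' @export
mvnn_forward <- function(case, model) {
  stopifnot(inherits(case, "case_pair"), inherits(model, "mvnn_model"))
  fc <- backbone_forward_cache(case$cc, model$branch_cc, model$spec,
                               keep_cache = FALSE)
  fm <- backbone_forward_cache(case$mlo, model$branch_mlo, model$spec,
                               keep_cache = FALSE)
  hf <- fusion_head_fwd(model, c(fc$features, fm$features))
  probs <- softmax(hf$logits)
  classes <- if (model$task == "screening") c("normal", "abnormal")
             else c("benign", "malignant")
  structure(list(probs = probs, score = probs[2L],
                 label = classes[if (probs[2L] >= 0.5) 2L else 1L],
                 task = model$task),
            class = "mvnn_prediction")
}

#' Two-stage cascade classification
#'
#' Stage 1 labels the case normal vs abnormal at `threshold`; only cases
#' labeled abnormal proceed to stage 2, which labels them benign vs
#' malignant. Both stage scores are reported.
#'
#' @param case [case_pair()].
#' @param screening stage-1 [mvnn_model][mvnn_init()] (task `"screening"`).
#' @param diagnosis stage-2 model (task `"diagnosis"`).
#' @param threshold stage-1 decision threshold on P(abnormal), default 0.5.
#' @return list with `stage1_prob`, `stage1_label`, `stage2_prob` (NA when
#'   stage 2 is not invoked), `stage2_label`, and the final `label` in
#'   `c("normal", "benign", "malignant")`.
#' @export
classify_two_stage <- function(case, screening, diagnosis, threshold = 0.5) {
  p1 <- mvnn_forward(case, screening)
  if (p1$score < threshold)
    return(list(stage1_prob = p1$score, stage1_label = "normal",
                stage2_prob = NA_real_, stage2_label = NA_character_,
                label = "normal"))
  p2 <- mvnn_forward(case, diagnosis)
  list(stage1_prob = p1$score, stage1_label = "abnormal",
       stage2_prob = p2$score, stage2_label = p2$label,
       label = p2$label)
}

#' Write cascade predictions to CSV
#'
#' @param results list of [classify_two_stage()] results.
#' @param ids case identifiers.
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_predictions <- function(results, ids, path) {
  df <- data.frame(
    case_id = ids,
    stage1_prob = vapply(results, `[[`, 1, "stage1_prob"),
    stage1_label = vapply(results, `[[`, "", "stage1_label"),
    stage2_prob = vapply(results, `[[`, 1, "stage2_prob"),
    stage2_label = vapply(results, function(r) {
      if (is.na(r$stage2_prob)) NA_character_ else r$stage2_label
    }, ""),
    label = vapply(results, `[[`, "", "label"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
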