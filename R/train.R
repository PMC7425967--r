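# Training protocol: SGD with momentum 0.9, initial learning rate 0.001,
# weight decay 1e-4, mini-batch 16, 300 epochs (all overridable for
# desk-scale runs). Two phases: (1) each branch backbone is trained on its
# own view with a private softmax head; (2) the fusion layer and head are
# fine-tuned on view pairs while every convolutional / normalization weight
# in both branches stays frozen.

#' Training configuration
#'
#' Defaults follow the canonical protocol; all values can be overridden for
#' small-scale runs.
#'
#' @param lr initial learning rate (constant schedule by default).
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param seed RNG seed controlling shuffling (and any weight init done by
#'   the caller).
#' @return list of class `"train_config"`.
#' @export
train_config <- function(lr = 0.001, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 16L, epochs = 300L, seed = 1L) {
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

branch_forward_cache <- function(image, branch, keep_cache = TRUE) {
  bf <- backbone_forward_cache(image, branch$params, branch$spec,
                               keep_cache = keep_cache)
  logits <- linear_forward(branch$head, bf$features)
  list(logits = logits, features = bf$features, bf = bf)
}

#' Single-view branch prediction
#'
#' @param image preprocessed view.
#' @param branch trained branch from [train_branch()].
#' @return 2-class probability vector `(negative, positive)`.
#' @export
branch_predict <- function(image, branch) {
  softmax(branch_forward_cache(image, branch, keep_cache = FALSE)$logits)
}

#' Train one feature-extraction branch
#'
#' Trains a backbone plus a private 2-way softmax head on single-view images
#' with cross-entropy loss and momentum SGD. Gradients are averaged over each
#' mini-batch.
#'
#' @param images list of `[size, size, 1]` preprocessed view images.
#' @param labels integer vector in `{1, 2}` (2 = positive class) or a factor
#'   whose second level is the positive class.
#' @param spec [backbone_spec()] of the branch.
#' @param cfg [train_config()].
#' @param init_seed seed for weight initialization.
#' @return list of class `"mvnn_branch"`: `spec`, `params`, `head`,
#'   `loss_trace` (mean batch loss per step), `train_accuracy`.
#' @export
train_branch <- function(images, labels, spec, cfg = train_config(),
                         init_seed = cfg$seed) {
  n <- length(images)
  if (n == 0L) stop("empty training set")
  labels <- as_binary_labels(labels)
  params <- backbone_init(spec, seed = init_seed)
  set.seed(init_seed + 1L)
  head <- linear_layer(params$.meta$out_channels, 2L)
  full <- list(bb = params, head = head)
  vel <- tree_zero(full)
  loss_trace <- numeric(0)
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (bt in batches) {
      grads <- NULL
      loss <- 0
      for (i in bt) {
        bf <- backbone_forward_cache(images[[i]], full$bb, spec)
        logits <- linear_forward(full$head, bf$features)
        sx <- softmax_xent(logits, labels[i])
        loss <- loss + sx$loss
        hb <- linear_backward(full$head, bf$features, sx$dlogits)
        bb <- backbone_backward(hb$dx, bf, full$bb, spec)
        g <- list(bb = bb$dparams, head = hb$dparams)
        grads <- if (is.null(grads)) g else tree_add(grads, g)
      }
      loss <- loss / length(bt)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d; aborting (last finite loss %.4f)",
                     epoch, if (length(loss_trace)) loss_trace[length(loss_trace)] else NA))
      loss_trace <- c(loss_trace, loss)
      grads <- tree_scale(grads, 1 / length(bt))
      up <- sgd_step(full, grads, vel, cfg$lr, cfg$momentum, cfg$weight_decay)
      full <- up$p; vel <- up$v
    }
  }
  preds <- vapply(images, function(im) {
    which.max(linear_forward(full$head,
      backbone_forward_cache(im, full$bb, spec, keep_cache = FALSE)$features))
  }, 1L)
  structure(list(spec = spec, params = full$bb, head = full$head,
                 loss_trace = loss_trace,
                 train_accuracy = mean(preds == labels)),
            class = "mvnn_branch")
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  if (is.character(labels)) stop("labels must be integer in {1, 2} or a factor")
  labels <- as.integer(labels)
  if (!all(labels %in% c(1L, 2L))) stop("labels must be coded 1 (negative) / 2 (positive)")
  labels
}

#' Assemble a multi-view model from two trained branches
#'
#' @param branch_cc,branch_mlo [train_branch()] results for the two views.
#' @param hidden fusion-layer width, default 1024.
#' @param task `"screening"` or `"diagnosis"`.
#' @param seed seed for the fusion/head initialization.
#' @return [mvnn_model][mvnn_init()] whose branches carry the trained weights.
#' @export
mvnn_from_branches <- function(branch_cc, branch_mlo, hidden = 1024L,
                               task = c("screening", "diagnosis"), seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(branch_cc, "mvnn_branch"), inherits(branch_mlo, "mvnn_branch"))
  cf <- branch_cc$params$.meta$out_channels
  set.seed(seed)
  model <- list(spec = branch_cc$spec,
                branch_cc = branch_cc$params, branch_mlo = branch_mlo$params,
                fc1 = linear_layer(2L * cf, hidden),
                fc2 = linear_layer(hidden, 2L),
                task = task, hidden = as.integer(hidden))
  class(model) <- "mvnn_model"
  model
}

#' Fine-tune the fusion layers of a multi-view model
#'
#' Phase-2 training: both branch feature extractors are frozen (their
#' convolutional and normalization parameters are not touched by the
#' optimizer; branch features are computed once up front), and only the
#' fusion layer and softmax head are updated by momentum SGD.
#'
#' @param cases list of [case_pair()].
#' @param labels binary labels as in [train_branch()].
#' @param model [mvnn_model][mvnn_init()] with pre-trained branches.
#' @param cfg [train_config()].
#' @return list: the updated `model`, `loss_trace`, and `features` (the
#'   cached per-case fused input vectors).
#' @export
finetune_fusion <- function(cases, labels, model, cfg = train_config()) {
  stopifnot(inherits(model, "mvnn_model"))
  n <- length(cases)
  if (n == 0L) stop("empty training set")
  labels <- as_binary_labels(labels)
  feats <- lapply(cases, function(cs) {
    c(backbone_forward_cache(cs$cc, model$branch_cc, model$spec,
                             keep_cache = FALSE)$features,
      backbone_forward_cache(cs$mlo, model$branch_mlo, model$spec,
                             keep_cache = FALSE)$features)
  })
  fuse <- list(fc1 = model$fc1, fc2 = model$fc2)
  vel <- tree_zero(fuse)
  loss_trace <- numeric(0)
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (bt in batches) {
      grads <- NULL
      loss <- 0
      for (i in bt) {
        z1 <- linear_forward(fuse$fc1, feats[[i]])
        r1 <- relu_forward(z1)
        logits <- linear_forward(fuse$fc2, r1$out)
        sx <- softmax_xent(logits, labels[i])
        loss <- loss + sx$loss
        b2 <- linear_backward(fuse$fc2, r1$out, sx$dlogits)
        da1 <- relu_backward(r1$cache, b2$dx)
        b1 <- linear_backward(fuse$fc1, feats[[i]], da1)
        g <- list(fc1 = b1$dparams, fc2 = b2$dparams)
        grads <- if (is.null(grads)) g else tree_add(grads, g)
      }
      loss <- loss / length(bt)
      if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d; aborting", epoch))
      loss_trace <- c(loss_trace, loss)
      grads <- tree_scale(grads, 1 / length(bt))
      up <- sgd_step(fuse, grads, vel, cfg$lr, cfg$momentum, cfg$weight_decay)
      fuse <- up$p; vel <- up$v
    }
  }
  model$fc1 <- fuse$fc1
  model$fc2 <- fuse$fc2
  list(model = model, loss_trace = loss_trace, features = feats)
}

#' Stratified k-fold plan
#'
#' Assigns cases to `k` disjoint, exhaustive folds, stratified so that each
#' fold's class counts are within one case of proportional; reproducible
#' from `seed`.
#'
#' @param labels class label per case (factor or character).
#' @param k number of folds, default 10.
#' @param seed RNG seed.
#' @return object of class `"fold_plan"`: list with `fold` (integer
#'   assignment per case), `k`, `labels`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small))
    stop(sprintf("class '%s' has only %d cases, fewer than k = %d folds",
                 small[1L], tab[small[1L]], k))
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(fold = fold, k = k, labels = labels), class = "fold_plan")
}
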