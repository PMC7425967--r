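test_that("heat-map normalization is idempotent and zeroes constant maps", {
  set.seed(101)
  m <- matrix(runif(64), 8, 8)
  n1 <- normalize_heat(m)
  expect_identical(normalize_heat(n1), n1)
  expect_equal(min(n1), 0)
  expect_equal(max(n1), 1)
  expect_equal(normalize_heat(matrix(0.7, 5, 5)), matrix(0, 5, 5))
})

test_that("heat maps satisfy the shape/range contract even for untrained models", {
  spec <- small_spec(48)
  model <- mvnn_init(spec, hidden = 16, task = "screening", seed = 102)
  cs <- generate_case(phantom_spec("benign", image_size = 48,
                                   lesion_type = "mass", seed = 103))
  cs$cc <- feature_map(as.matrix(cs$cc[, , 1]))
  cs$mlo <- feature_map(as.matrix(cs$mlo[, , 1]))
  hv <- heatmap_for_view(model, cs, "cc")
  expect_equal(dim(hv$heat), c(48L, 48L))
  expect_true(all(hv$heat >= 0 & hv$heat <= 1))
  expect_equal(dim(hv$overlay), c(48L, 48L, 3L))
  expect_true(all(hv$overlay >= 0 & hv$overlay <= 1))
  expect_true(hv$score >= 0 && hv$score <= 1)
  hv2 <- heatmap_for_view(model, cs, "mlo", target_class = 1L)
  expect_equal(dim(hv2$heat), c(48L, 48L))
})

test_that("the activation behind a view's heat map is independent of the other branch", {
  spec <- small_spec(48)
  model <- mvnn_init(spec, hidden = 16, task = "screening", seed = 104)
  cs <- generate_case(phantom_spec("normal", image_size = 48, seed = 105))
  cs$cc <- feature_map(as.matrix(cs$cc[, , 1]))
  cs$mlo <- feature_map(as.matrix(cs$mlo[, , 1]))
  act1 <- backbone_forward(cs$cc, model$branch_cc, spec)$last_act
  model$branch_mlo <- mvnn:::tree_map(model$branch_mlo, function(x) x * 1.3)
  act2 <- backbone_forward(cs$cc, model$branch_cc, spec)$last_act
  expect_identical(act1, act2)
})

test_that("after overfitting, the interior heat-map peak localizes a planted mass", {
  # Matched-background harness: for each seeded run the positive class is a
  # single mass phantom (plus small translations) against normal phantoms,
  # so the planted mass is the only stable discriminative structure. The
  # peak is taken over the interior of the coarse activation map because the
  # outermost feature cells carry zero-padding artifacts.
  run_one <- function(run_seed) {
    mass <- generate_case(phantom_spec("malignant", image_size = 48,
                                       lesion_type = "mass", seed = run_seed,
                                       lesion_contrast = 0.9,
                                       mass_radius_frac = c(0.2, 0.28)))
    normals <- lapply(1:3, function(i)
      generate_case(phantom_spec("normal", image_size = 48,
                                 seed = run_seed + 1000 * i)))
    pc <- preprocess_config(target_size = 48)
    mimg <- preprocess(as.matrix(mass$cc[, , 1]), pc)
    nimgs <- lapply(normals, function(cs) preprocess(as.matrix(cs$cc[, , 1]), pc))
    shift <- function(m) lapply(c("up", "down", "left", "right"), function(d)
      mvnn:::aug_translate(m[, , 1], 0.08, d))
    pos <- c(list(mimg[, , 1]), shift(mimg))
    neg <- c(lapply(nimgs, function(m) m[, , 1]), shift(nimgs[[1]]))
    imgs <- c(lapply(pos, feature_map), lapply(neg, feature_map))
    y <- c(rep(2L, length(pos)), rep(1L, length(neg)))
    spec <- small_spec(48)
    br <- train_branch(imgs, y, spec,
                       train_config(batch_size = 8, epochs = 50,
                                    seed = run_seed, lr = 0.02))
    model <- mvnn_from_branches(br, br, hidden = 16, task = "screening",
                                seed = run_seed)
    cases <- lapply(seq_along(imgs), function(i)
      case_pair(imgs[[i]], imgs[[i]],
                if (y[i] == 2) "malignant" else "normal",
                lesion_type = if (y[i] == 2) "mass" else NULL))
    ft <- finetune_fusion(cases, y, model,
                          train_config(batch_size = 8, epochs = 40,
                                       seed = run_seed, lr = 0.01))
    cs <- case_pair(mimg, mimg, "malignant", lesion_type = "mass")
    hv <- heatmap_for_view(ft$model, cs, "cc", target_class = 2)
    cam <- hv$cam
    n <- nrow(cam)
    interior <- matrix(-Inf, n, n)
    interior[2:(n - 1), 2:(n - 1)] <- cam[2:(n - 1), 2:(n - 1)]
    heat <- matrix(EBImage::imageData(
      EBImage::resize(pmax(interior, 0), w = 48, h = 48)), 48, 48)
    pk <- which(heat == max(heat), arr.ind = TRUE)[1, ]
    dil <- EBImage::dilate(mass$masks$cc, EBImage::makeBrush(11, "disc"))
    dil[pk[1], pk[2]] > 0
  }
  hits <- sum(vapply(201:210, run_one, TRUE))
  expect_gte(hits, 8)
})
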