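make_tiny_case <- function(seed, label = "normal", lesion = NULL, size = 48L) {
  cs <- generate_case(phantom_spec(label, image_size = size,
                                   lesion_type = lesion, seed = seed))
  cs$cc <- feature_map(as.matrix(cs$cc[, , 1]))
  cs$mlo <- feature_map(as.matrix(cs$mlo[, , 1]))
  cs
}

test_that("case pairs validate views, labels and lesion typing", {
  img <- matrix(runif(16), 4, 4)
  expect_error(case_pair(NULL, img, "normal"), "both")
  expect_error(case_pair(img, img, "benign"), "lesion_type")
  expect_error(case_pair(img, img, "normal", lesion_type = "mass"), "no lesion_type")
  cs <- case_pair(img, img, "malignant", lesion_type = "calcification")
  expect_s3_class(cs, "case_pair")
})

test_that("multi-view forward produces a normalized softmax over two classes", {
  spec <- small_spec(48)
  model <- mvnn_init(spec, hidden = 16, task = "screening", seed = 51)
  cs <- make_tiny_case(7)
  pred <- mvnn_forward(cs, model)
  expect_equal(sum(pred$probs), 1, tolerance = 1e-9)
  expect_true(all(pred$probs >= 0 & pred$probs <= 1))
  # zero head weights force a uniform softmax
  m0 <- model
  m0$fc2$w[] <- 0; m0$fc2$b[] <- 0
  expect_equal(mvnn_forward(cs, m0)$probs, c(0.5, 0.5))
})

test_that("multi-view forward equals a straight-line evaluation of the fusion head", {
  spec <- small_spec(48)
  model <- mvnn_init(spec, hidden = 16, task = "diagnosis", seed = 52)
  cs <- make_tiny_case(8, "benign", "mass")
  f_cc <- backbone_forward(cs$cc, model$branch_cc, spec)$features
  f_mlo <- backbone_forward(cs$mlo, model$branch_mlo, spec)$features
  v <- c(f_cc, f_mlo)
  z1 <- as.vector(model$fc1$w %*% v + model$fc1$b)
  z2 <- as.vector(model$fc2$w %*% pmax(z1, 0) + model$fc2$b)
  want <- exp(z2 - max(z2)); want <- want / sum(want)
  expect_equal(mvnn_forward(cs, model)$probs, want, tolerance = 1e-10)
})

test_that("branches are independent: MLO weight perturbations leave CC features unchanged", {
  spec <- small_spec(48)
  model <- mvnn_init(spec, hidden = 16, seed = 53)
  cs <- make_tiny_case(9)
  f_before <- backbone_forward(cs$cc, model$branch_cc, spec)$features
  model$branch_mlo <- mvnn:::tree_map(model$branch_mlo, function(x) x + 0.1)
  f_after <- backbone_forward(cs$cc, model$branch_cc, spec)$features
  expect_identical(f_before, f_after)
  f_mlo1 <- backbone_forward(cs$mlo, model$branch_mlo, spec)$features
  model$branch_cc <- mvnn:::tree_map(model$branch_cc, function(x) x - 0.1)
  f_mlo2 <- backbone_forward(cs$mlo, model$branch_mlo, spec)$features
  expect_identical(f_mlo1, f_mlo2)
})

test_that("the two-stage cascade gates stage 2 on the stage-1 threshold", {
  spec <- small_spec(48)
  scr <- mvnn_init(spec, hidden = 8, task = "screening", seed = 54)
  dia <- mvnn_init(spec, hidden = 8, task = "diagnosis", seed = 55)
  # uniform stage-1 softmax scores exactly 0.5
  scr$fc2$w[] <- 0; scr$fc2$b[] <- 0
  cs <- make_tiny_case(10)
  r_lo <- classify_two_stage(cs, scr, dia, threshold = 0.6)
  expect_equal(r_lo$label, "normal")
  expect_true(is.na(r_lo$stage2_prob))
  r_hi <- classify_two_stage(cs, scr, dia, threshold = 0.5)
  expect_equal(r_hi$stage1_label, "abnormal")
  expect_false(is.na(r_hi$stage2_prob))
  expect_true(r_hi$label %in% c("benign", "malignant"))
})

test_that("cascade outputs partition a batch across the three labels", {
  spec <- small_spec(48)
  scr <- mvnn_init(spec, hidden = 8, task = "screening", seed = 56)
  dia <- mvnn_init(spec, hidden = 8, task = "diagnosis", seed = 57)
  cases <- lapply(1:6, function(i) make_tiny_case(100 + i))
  res <- lapply(cases, classify_two_stage, screening = scr, diagnosis = dia)
  labs <- vapply(res, `[[`, "", "label")
  expect_true(all(labs %in% c("normal", "benign", "malignant")))
  expect_equal(length(labs), 6L)
  df <- write_predictions(res, sprintf("c%02d", 1:6),
                          file.path(tempdir(), "preds.csv"))
  expect_equal(nrow(df), 6L)
  expect_true(all(is.na(df$stage2_prob) == (df$stage1_label == "normal")))
})
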