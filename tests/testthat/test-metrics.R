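test_that("metrics reproduce hand-derived confusion and pairwise-ordering values", {
  r <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1), threshold = 0.5)
  expect_equal(r$sensitivity, 0.5)   # TP = 1, FN = 1
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$auc, 3 / 4)         # 3 of 4 label-discordant pairs ordered
  # perfect separation
  rp <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(rp$auc, 1)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$accuracy, 1)
  # uninformative scores: ties counted half
  rt <- compute_metrics(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(rt$auc, 0.5)
  expect_error(compute_metrics(c(0, 1), c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("single-class labels yield NA AUC with a warning", {
  expect_warning(r <- compute_metrics(c(1, 1, 1), c(0.2, 0.5, 0.9)), "one class")
  expect_true(is.na(r$auc))
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic on random instances", {
  set.seed(81)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    # mix of continuous and heavily tied score sets
    scores <- if (i %% 3 == 0) round(runif(n), 1) else runif(n)
    r <- compute_metrics(labels, scores)
    expect_equal(r$auc, brute_auc(labels, scores), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  for (i in 1:5) {
    labels <- rbinom(60, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(60), 2)
    r <- compute_metrics(labels, scores)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(r$auc, ref, tolerance = 1e-10)
  }
})

test_that("ROC curves run from (0,0) to (1,1) and are monotone", {
  set.seed(83)
  for (i in 1:10) {
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    r <- compute_metrics(labels, runif(40))
    roc <- r$roc_points
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  }
})

test_that("per-lesion breakdown splits abnormal cases by type and recombines", {
  mk <- function(label, lt) {
    img <- matrix(0.5, 8, 8)
    case_pair(img, img, label, lesion_type = lt)
  }
  cases <- list(mk("normal", NULL), mk("benign", "mass"),
                mk("malignant", "mass"), mk("benign", "calcification"),
                mk("malignant", "calcification"),
                mk("malignant", "calcification"))
  all_ok <- rep(TRUE, 6)
  bd <- per_lesion_breakdown(cases, all_ok)
  expect_equal(unname(bd), c(1, 1))
  # planted errors in calcification cases only
  correct <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  bd2 <- per_lesion_breakdown(cases, correct)
  expect_equal(unname(bd2["mass"]), 1)
  expect_lt(bd2["calcification"], 1)
  # partition identity over abnormal cases
  abn <- vapply(cases, function(cs) cs$label != "normal", TRUE)
  expect_equal(sum(correct[abn]), bd2["mass"] * 2 + bd2["calcification"] * 3,
               ignore_attr = TRUE)
  # missing lesion type on an abnormal case warns and is excluded
  broken <- cases
  broken[[2]]$lesion_type <- NULL
  expect_warning(bd3 <- per_lesion_breakdown(broken, all_ok), "without lesion_type")
  expect_equal(unname(bd3), c(1, 1))
})

test_that("fold plans are disjoint, exhaustive, stratified and reproducible", {
  labels <- rep(c("a", "b"), each = 50)
  plan <- make_folds(labels, k = 10, seed = 3)
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_equal(length(plan$fold), 100)
  for (f in 1:10) {
    sel <- plan$fold == f
    expect_equal(sum(sel), 10)                       # exhaustive, balanced
    expect_equal(sum(labels[sel] == "a"), 5)         # exact stratification
  }
  expect_identical(plan$fold, make_folds(labels, k = 10, seed = 3)$fold)
  expect_false(identical(plan$fold, make_folds(labels, k = 10, seed = 4)$fold))
  expect_error(make_folds(c(rep("a", 30), rep("b", 5)), k = 10), "'b' has only 5")
  # uneven classes stay within one case of proportional
  labs2 <- c(rep("a", 23), rep("b", 31))
  plan2 <- make_folds(labs2, k = 5, seed = 1)
  for (f in 1:5) {
    na <- sum(labs2[plan2$fold == f] == "a")
    expect_true(abs(na - 23 / 5) < 1)
  }
})
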