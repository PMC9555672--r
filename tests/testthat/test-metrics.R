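test_that("confusion counts and derived metrics match their formulas", {
  # perfect prediction
  gt <- array(0, c(5, 5, 4)); gt[2:3, 2:3, 2] <- 1
  cc <- confusion_counts(gt, gt)
  expect_equal(cc, list(TP = 4L, TN = 96L, FP = 0L, FN = 0L))
  expect_equal(accuracy_score(cc), 1)
  expect_equal(recall_score(cc), 1)
  expect_equal(precision_score(cc), 1)
  expect_equal(f2_score(cc), 1)
  # complement prediction has no agreement
  cc2 <- confusion_counts(1 - gt, gt)
  expect_equal(cc2$TP, 0L)
  expect_equal(cc2$TN, 0L)
  # direct substitutions
  expect_equal(f2_score(list(TP = 8, FP = 2, FN = 2, TN = 0)), 0.8)
  expect_equal(recall_score(list(TP = 10, FN = 30, FP = 0, TN = 0)), 0.25)
  expect_equal(precision_score(list(TP = 10, FP = 30, FN = 0, TN = 0)), 0.25)
  expect_error(f2_score(list(TP = 0, FP = 0, FN = 0, TN = 5)),
               class = "cbctseg_undefined_metric_error")
})

test_that("Dice follows its set formula, is symmetric, errors when empty", {
  a <- array(0, c(4, 4, 2)); a[1:5] <- 1            # |A| = 5
  m <- array(0, c(4, 4, 2)); m[3:10] <- 1           # |M| = 8, overlap 3
  expect_equal(dice_coefficient(m, a), 2 * 3 / (5 + 8))
  expect_equal(dice_coefficient(a, m), dice_coefficient(m, a))
  expect_equal(dice_coefficient(a, a), 1)
  b <- array(0, c(4, 4, 2)); b[11:13] <- 1
  expect_equal(dice_coefficient(a, b), 0)
  expect_error(dice_coefficient(b * 0, b * 0),
               class = "cbctseg_undefined_metric_error")
})

test_that("metrics agree exactly with the naive counting oracle", {
  set.seed(11)
  for (i in 1:25) {
    pred <- as.numeric(runif(8^3) < 0.4)
    gt <- as.numeric(runif(8^3) < 0.15)
    if (sum(gt) == 0 || sum(pred) == 0) next
    cc <- confusion_counts(array(pred, c(8, 8, 8)), array(gt, c(8, 8, 8)))
    oc <- oracle_confusion(pred, gt)
    expect_identical(cc[c("TP", "TN", "FP", "FN")],
                     oc[c("TP", "TN", "FP", "FN")])
    expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 512L)
    expect_equal(dice_coefficient(array(pred, c(8, 8, 8)),
                                  array(gt, c(8, 8, 8))),
                 2 * oc$TP / (2 * oc$TP + oc$FP + oc$FN))
  }
})

test_that("the harmonic mean of recall and precision equals Dice", {
  set.seed(12)
  for (i in 1:10) {
    pred <- array(as.numeric(runif(6^3) < 0.5), c(6, 6, 6))
    gt <- array(as.numeric(runif(6^3) < 0.3), c(6, 6, 6))
    cc <- confusion_counts(pred, gt)
    if (cc$TP == 0) next
    r <- recall_score(cc); p <- precision_score(cc)
    expect_equal(2 * r * p / (r + p), dice_coefficient(pred, gt))
  }
})

test_that("PR curve and AUPRC match the exhaustive sweep oracle", {
  set.seed(13)
  for (i in 1:10) {
    probs <- array(runif(8^3), c(8, 8, 8))
    gt <- array(as.numeric(runif(8^3) < 0.2), c(8, 8, 8))
    if (sum(gt) == 0) next
    curve <- pr_curve(probs, gt)
    expect_true(all(diff(curve$recall) >= 0))
    expect_true(all(curve$recall >= 0 & curve$recall <= 1))
    expect_true(all(curve$precision >= 0 & curve$precision <= 1))
    expect_equal(auprc(curve), oracle_auprc(probs, gt), tolerance = 1e-6)
  }
})

test_that("PR curve endpoints behave as documented", {
  gt <- array(c(rep(1, 20), rep(0, 108)), c(8, 4, 4))
  # scores equal to the truth pass through recall 1 / precision 1
  curve <- pr_curve(gt + 0, gt)
  expect_true(any(curve$recall == 1 & curve$precision == 1))
  expect_equal(auprc(curve), 1)
  # constant scores: single interior point (R=1, P=prevalence)
  curve2 <- pr_curve(array(0.5, dim(gt)), gt)
  expect_equal(auprc(curve2), mean(gt), tolerance = 1e-12)
  expect_error(pr_curve(gt + 0, gt * 0),
               class = "cbctseg_undefined_metric_error")
})

test_that("the printed-integrand variant is exposed but inert for flat curves", {
  gt <- array(c(rep(1, 16), rep(0, 48)), c(4, 4, 4))
  curve <- pr_curve(array(0.5, dim(gt)), gt)
  expect_lt(abs(auprc(curve, integrand = "difference")), 0.40)
  expect_equal(auprc(curve, integrand = "trapezoid"), mean(gt),
               tolerance = 1e-12)
})

test_that("AUPRC baseline is the foreground prevalence", {
  gt <- array(0, c(10, 10, 10)); gt[1:11] <- 1
  expect_equal(auprc_baseline(gt), 0.011)
  expect_equal(auprc_baseline(array(1, c(2, 2, 2))), 1)
  expect_equal(auprc_baseline(array(c(0, 1), c(2, 2, 2))), 0.5)
})

test_that("random scores converge to the prevalence baseline", {
  set.seed(14)
  n <- 40L
  gt <- array(as.numeric(runif(n^3) < 0.1), c(n, n, n))
  probs <- array(runif(n^3), c(n, n, n))
  prev <- mean(gt)
  # binomial-ish 3 sigma band around the baseline
  tol <- 3 * sqrt(prev * (1 - prev) / sum(gt))
  expect_lt(abs(auprc(pr_curve(probs, gt)) - prev), tol + 0.01)
})

test_that("metrics are invariant under a shared spatial permutation", {
  set.seed(15)
  pred <- array(as.numeric(runif(6^3) < 0.4), c(6, 6, 6))
  gt <- array(as.numeric(runif(6^3) < 0.3), c(6, 6, 6))
  perm <- sample(6^3)
  pred2 <- array(as.numeric(pred)[perm], c(6, 6, 6))
  gt2 <- array(as.numeric(gt)[perm], c(6, 6, 6))
  expect_equal(dice_coefficient(pred, gt), dice_coefficient(pred2, gt2))
  expect_identical(confusion_counts(pred, gt), confusion_counts(pred2, gt2))
})

test_that("evaluate_segmentation composes its parts", {
  set.seed(16)
  gt <- sphere_label(12, radius = 4)
  probs <- array(runif(12^3), c(12, 12, 12))
  probs[gt$voxels > 0] <- probs[gt$voxels > 0] * 0.5 + 0.5
  pred <- label_map(array(as.numeric(probs > 0.6), c(12, 12, 12)))
  rep <- evaluate_segmentation(probs, pred, gt)
  cc <- confusion_counts(pred, gt)
  expect_equal(rep$dice, dice_coefficient(pred, gt))
  expect_equal(rep$f2, f2_score(cc))
  expect_equal(rep$accuracy, accuracy_score(cc))
  expect_equal(rep$recall, recall_score(cc))
  expect_equal(rep$precision, precision_score(cc))
  expect_equal(rep$auprc, auprc(pr_curve(probs, gt)))
  expect_equal(rep$auprc_baseline, mean(gt$voxels > 0))
  # a perfect prediction scores 1 everywhere
  perf <- evaluate_segmentation(gt$voxels + 0, gt, gt)
  for (f in c("auprc", "dice", "f2", "accuracy", "recall", "precision"))
    expect_equal(perf[[f]], 1)
})
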