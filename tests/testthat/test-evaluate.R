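test_that("confusion matrix equals a hand count on a fixed score list", {
  ## scores printed here; threshold 60; hand-tallied truth table
  scores <- c(72, 65, 58, 61, 90, 49, 52, 66, 55, 60)
  labels <- c(1,  1,  1,  1,  1,  0,  0,  0,  0,  0)
  cm <- confusionFromScores(scores, labels, 60)
  ## positives above 60: 72, 65, 61, 90 -> tp = 4, fn = 1 (58)
  ## negatives above 60: 66 -> fp = 1; tie at 60 scores negative -> tn = 4
  expect_equal(cm[c("tp", "fp", "tn", "fn")],
               list(tp = 4L, fp = 1L, tn = 4L, fn = 1L))
  expect_equal(cm$sensitivity, 4 / 5)
  expect_equal(cm$specificity, 4 / 5)
})

test_that("perfect separation gives unit rates and unit AUC", {
  scores <- c(80, 85, 90, 40, 45, 50)
  labels <- c(1, 1, 1, 0, 0, 0)
  cm <- confusionFromScores(scores, labels, 60)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  roc <- rocSweep(scores = scores, labels = labels, nThresholds = 51)
  expect_equal(roc$auc, 1)
  expect_equal(roc$aucConcordance, 1)
})

test_that("uninformative scores give AUC one half", {
  scores <- rep(c(50, 60, 70), 4)
  labels <- rep(c(1, 0), each = 6)
  roc <- rocSweep(scores = scores, labels = labels, nThresholds = 201)
  expect_equal(roc$aucConcordance, 0.5)
  expect_equal(roc$auc, 0.5, tolerance = 0.01)
})

test_that("sweep AUC matches pairwise concordance within discretization", {
  set.seed(13)
  for (i in 1:5) {
    scores <- c(rnorm(15, 62, 6), rnorm(15, 52, 6))
    labels <- rep(c(1, 0), each = 15)
    nThr <- 200
    roc <- rocSweep(scores = scores, labels = labels, nThresholds = nThr)
    oracle <- pairwiseAuc(scores, labels)
    expect_equal(roc$aucConcordance, oracle)
    expect_lt(abs(roc$auc - oracle), 1 / (2 * nThr) + 1 / length(scores))
  }
})

test_that("sweep AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- c(rnorm(20, 60, 5), rnorm(20, 52, 5))
  labels <- rep(c(1, 0), each = 20)
  roc <- rocSweep(scores = scores, labels = labels, nThresholds = 501)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc$aucConcordance, ref, tolerance = 1e-10)
})

test_that("metrics are invariant to cohort order and monotone in threshold", {
  set.seed(19)
  scores <- c(rnorm(12, 64, 5), rnorm(12, 50, 5))
  labels <- rep(c(1, 0), each = 12)
  perm <- sample(length(scores))
  cmA <- confusionFromScores(scores, labels, 57)
  cmB <- confusionFromScores(scores[perm], labels[perm], 57)
  expect_identical(cmA, cmB)
  expect_equal(concordanceAuc(scores, labels),
               concordanceAuc(scores[perm], labels[perm]))
  ## sensitivity non-increasing, specificity non-decreasing in threshold
  thr <- seq(40, 75, by = 2.5)
  sens <- sapply(thr, function(t) confusionFromScores(scores, labels, t)$sensitivity)
  spec <- sapply(thr, function(t) confusionFromScores(scores, labels, t)$specificity)
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("single-class cohorts report the undefined rate as NA", {
  cm <- confusionFromScores(c(60, 70), c(1, 1), 65)
  expect_equal(cm$sensitivity, 0.5)
  expect_true(is.na(cm$specificity))
  expect_error(rocSweep(scores = c(60, 70), labels = c(1, 1)),
               "both classes")
})

test_that("a small synthetic cohort scores cleanly end to end", {
  cam <- tinyCam(noiseSigma = 2)
  ## tiny frames need a proportionally scaled optical magnification so
  ## the blob fits: use 2 px/mm
  cam <- cameraModel(width = 160, height = 120, noiseSigma = 2, pxPerMm = 2)
  coh <- generateCohort(6, 6, cam, seed = 23)
  cal <- defaultCalibration(cam)
  res <- scoreCohort(coh, cal)
  expect_equal(with(res$confusion, tp + fp + tn + fn), 12)
  expect_gte(res$sensitivity, 5 / 6)
  expect_gte(res$specificity, 5 / 6)
  roc <- rocSweep(scores = res$scores$score, labels = res$scores$label)
  expect_gte(roc$aucConcordance, 0.9)
})
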