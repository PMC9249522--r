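test_that("overlap metrics match hand cases and keep the CM identity", {
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  same <- segmentation_metrics(m, m)
  expect_equal(same[c("AOM", "AVM", "AUM", "CM")],
               list(AOM = 1, AVM = 0, AUM = 0, CM = 1))

  other <- matrix(0, 8, 8); other[1:2, 1:2] <- 1
  disj <- segmentation_metrics(m, other)
  expect_equal(disj[c("AOM", "AVM", "AUM", "CM")],
               list(AOM = 0, AVM = 1, AUM = 1, CM = 0))

  empty <- matrix(0, 8, 8)
  conv <- segmentation_metrics(empty, m)      # documented convention
  expect_equal(conv$AOM, 0); expect_equal(conv$AVM, 1)
  expect_error(segmentation_metrics(m, empty), "empty")

  # CM identity holds exactly for random mask pairs; AOM is symmetric
  set.seed(15)
  for (i in 1:20) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.5), 8, 8)
    if (!any(b) || !any(a)) next
    r <- segmentation_metrics(a, b)
    expect_identical(r$CM, (r$AOM + (1 - r$AVM) + (1 - r$AUM)) / 3)
    expect_equal(r$AOM, segmentation_metrics(b, a)$AOM)
    expect_equal(r$AVM, segmentation_metrics(b, a)$AUM)  # roles swap
  }
})

test_that("the composite measure reproduces the published overlap table rows", {
  # proposed method: AOM 0.83, AVM 0.22, AUM 0.20 -> CM 0.80 at 2 d.p.
  expect_equal(round(composite_measure(0.83, 0.22, 0.20), 2), 0.80)
  expect_equal(round(composite_measure(0.78, 0.31, 0.29), 2), 0.73)
  expect_equal(round(composite_measure(0.80, 0.26, 0.27), 2), 0.76)
  expect_equal(round(composite_measure(0.71, 0.35, 0.33), 2), 0.68)
})

test_that("detection rate is the guarded ratio", {
  expect_equal(detection_rate(98, 100), 0.98)
  expect_equal(detection_rate(7, 7), 1)
  expect_equal(detection_rate(0, 5), 0)
  expect_error(detection_rate(1, 0), "> 0")
  expect_error(detection_rate(6, 5), "0, total")
})

test_that("classification metrics follow their confusion-count definitions", {
  r <- classification_metrics(TP = 9, FP = 2, FN = 1, TN = 8)
  expect_equal(r, list(SEN = 0.9, SPE = 0.8, ACC = 0.85, FPF = 0.15))

  sym <- classification_metrics(TP = 4, FP = 4, FN = 4, TN = 4)
  expect_equal(sym, list(SEN = 0.5, SPE = 0.5, ACC = 0.5, FPF = 0.5))

  # false-positive fraction is the accuracy complement on the percent scale
  pc <- classification_metrics(TP = 55, FP = 3, FN = 4, TN = 38,
                               percent = TRUE)
  expect_equal(pc$FPF, 100 - pc$ACC)

  und <- classification_metrics(TP = 0, FP = 0, FN = 0, TN = 5)
  expect_true(is.na(und$SEN)); expect_equal(und$SPE, 1)
  expect_error(classification_metrics(TP = -1, FP = 0, FN = 0, TN = 1))
})

test_that("ROC points and AUC match the concordance oracle and pROC", {
  perf <- roc_points(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0))
  expect_equal(perf$auc, 1)
  expect_true(all(c(0, 1) %in% perf$points$FPR))

  flat <- roc_points(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(flat$auc, 0.5)

  hand_s <- c(0.9, 0.4, 0.65, 0.65, 0.2, 0.7)
  hand_l <- c(1, 0, 1, 0, 0, 1)
  expect_equal(roc_points(hand_s, hand_l)$auc, auc_concordance(hand_s, hand_l))

  set.seed(16)
  s <- runif(40); l <- rbinom(40, 1, 0.5)
  if (any(l) && !all(l)) {
    expect_equal(roc_points(s, l)$auc, auc_concordance(s, l))
    # monotone transform invariance
    expect_equal(roc_points(exp(3 * s), l)$auc, roc_points(s, l)$auc)
    # independent implementation cross-check
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_points(s, l)$auc, ref, tolerance = 1e-12)
    }
  }
  expect_error(roc_points(s, rep(1, 40)), "both classes")
})
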