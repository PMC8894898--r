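# asymmetry index, normative limits, classification, discrimination

test_that("the asymmetry index matches its defining identities", {
  for (v in c(0.2, 1, 3000))
    expect_equal(asymmetryIndex(v, v), 0)
  expect_equal(asymmetryIndex(1000, 0), 1)
  expect_equal(asymmetryIndex(0, 1000), -1)
  expect_equal(asymmetryIndex(3000, 3500), -0.076923, tolerance = 1e-5)
  expect_error(asymmetryIndex(0, 0), "positive")
  expect_error(asymmetryIndex(-1, 2), "non-negative")
  # antisymmetry and scale invariance
  withr::with_seed(1, {
    a <- runif(50, 10, 100); b <- runif(50, 10, 100)
  })
  expect_equal(asymmetryIndex(a, b), -asymmetryIndex(b, a))
  expect_equal(asymmetryIndex(7.3 * a, 7.3 * b), asymmetryIndex(a, b))
  expect_true(all(abs(asymmetryIndex(a, b)) <= 1))
})

test_that("normative limits reproduce hand arithmetic and shift with the data", {
  z <- as.vector(scale(1:11))      # mean 0, sample SD exactly 1
  lim <- fitNormativeLimits(0.02 * z)
  expect_equal(lim@hc_mean_ai, 0)
  expect_equal(lim@hc_sd_ai, 0.02)
  expect_equal(lim@thresholds[["3SD"]], c(-0.06, 0.06))
  expect_equal(lim@thresholds[["2SD"]], c(-0.04, 0.04))
  lim2 <- fitNormativeLimits(0.02 * z + 0.01)
  expect_equal(lim2@thresholds[["3SD"]], c(-0.05, 0.07))
  expect_error(fitNormativeLimits(rep(0.01, 20)), "spread")
  expect_error(fitNormativeLimits(c(-0.02, 0, 0.02)), "at least 10")
})

make_limits <- function(mean_ai, sd_ai, metric = "volume") {
  new("AsymmetryLimits", metric = metric, hc_mean_ai = mean_ai,
      hc_sd_ai = sd_ai, n_hc = 100L,
      thresholds = list("2SD" = mean_ai + c(-2, 2) * sd_ai,
                        "3SD" = mean_ai + c(-3, 3) * sd_ai))
}

test_that("classification sides follow the metric's disease direction", {
  lim <- make_limits(-0.005, 0.0183)   # 3SD limits approx (-0.060, 0.050)
  expect_equal(as.character(classifyByAsymmetry(-0.10, lim)),
               "left-abnormal")
  expect_equal(as.character(classifyByAsymmetry(0.10, lim)),
               "right-abnormal")
  expect_equal(as.character(classifyByAsymmetry(0.01, lim)), "within-norm")
  sv <- make_limits(-0.005, 0.0183, metric = "surface_to_volume_ratio")
  expect_equal(as.character(classifyByAsymmetry(0.10, sv)), "left-abnormal")
  expect_equal(as.character(classifyByAsymmetry(-0.10, sv)),
               "right-abnormal")
  # 2SD level is stricter than 3SD
  x <- make_limits(0, 0.02)
  expect_equal(as.character(classifyByAsymmetry(0.05, x, level = "2SD")),
               "right-abnormal")
  expect_equal(as.character(classifyByAsymmetry(0.05, x, level = "3SD")),
               "within-norm")
  expect_error(classifyByAsymmetry(0.05, make_limits(0, 0.02, "weird")),
               "convention")
})

test_that("sensitivity, specificity and F1 match the confusion counts", {
  # TP = 30, FN = 7, FP = 10, TN = 76 on the unilateral-HS contrast
  groups <- c(rep("HS-left", 37), rep("EPI-other", 86),
              rep("HC", 5), rep("HS-bilateral", 2))  # extras must be ignored
  pred <- factor(
    c(rep("left-abnormal", 30), rep("within-norm", 7),
      rep("left-abnormal", 10), rep("within-norm", 76),
      rep("left-abnormal", 7)),
    levels = c("within-norm", "left-abnormal", "right-abnormal"))
  bm <- binaryMetrics(pred, groups)
  expect_equal(bm$sensitivity, 30 / 37, tolerance = 1e-9)
  expect_equal(bm$specificity, 76 / 86, tolerance = 1e-9)
  expect_equal(bm$f1, 2 * 30 / (2 * 30 + 10 + 7), tolerance = 1e-9)
  expect_equal(bm$sensitivity, 0.8108, tolerance = 1e-4)
  expect_equal(bm$specificity, 0.8837, tolerance = 1e-4)
  expect_equal(bm$f1, 0.7792, tolerance = 1e-4)

  perfect <- factor(ifelse(groups %in% c("HS-left", "HS-right"),
                           "left-abnormal", "within-norm"),
                    levels = levels(pred))
  bp <- binaryMetrics(perfect, groups)
  expect_equal(c(bp$sensitivity, bp$specificity, bp$f1), c(1, 1, 1))

  none <- factor(rep("within-norm", length(groups)), levels = levels(pred))
  bn <- binaryMetrics(none, groups)
  expect_equal(bn$sensitivity, 0)
  expect_equal(bn$f1, 0)
})

test_that("rank AUC equals brute-force pair counting, ties included", {
  expect_equal(rocAuc(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE,
                                             FALSE, FALSE)), 1)
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 8 / 9)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
  for (case in 1:100) {
    withr::with_seed(case, {
      n <- sample(4:50, 1)
      labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forced ties
    })
    expect_equal(rocAuc(scores, labels), auc_pair_counting(scores, labels))
    # invariance under a strictly monotone transform
    expect_equal(rocAuc(exp(3 * scores), labels), rocAuc(scores, labels))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    scores <- c(rnorm(40, 1), rnorm(60))
    labels <- rep(c(TRUE, FALSE), c(40, 60))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(scores, labels), ref, tolerance = 1e-12)
})

test_that("the ROC curve starts at (1,1), ends at (0,0) and majorizes AUC", {
  withr::with_seed(8, {
    scores <- c(rnorm(20, 1), rnorm(30))
    labels <- rep(c(TRUE, FALSE), c(20, 30))
  })
  rc <- rocCurve(scores, labels)
  expect_equal(rc$fpr[1], 1); expect_equal(rc$tpr[1], 1)
  expect_equal(rc$fpr[nrow(rc)], 0); expect_equal(rc$tpr[nrow(rc)], 0)
  # trapezoidal area under the curve equals the rank AUC
  o <- order(rc$fpr, rc$tpr)
  auc_trap <- sum(diff(rc$fpr[o]) * (head(rc$tpr[o], -1) +
                                       tail(rc$tpr[o], -1)) / 2)
  expect_equal(auc_trap, rocAuc(scores, labels), tolerance = 1e-9)
})

test_that("sensitivity at 3 SD grows with the planted volume deficit", {
  sens <- sapply(c(2, 4, 6), function(effect) {
    mean(sapply(1:30, function(s) {
      cfg <- cohortConfig(seed = s,
                          vol_ai_effects = c("HS-left" = -effect,
                                             "HS-right" = effect,
                                             "HS-bilateral" = 0,
                                             "EPI-other" = 0))
      co <- generateMeasurementCohort(cfg)
      ai <- asymmetryIndex(co$volume_lh, co$volume_rh)
      lim <- fitNormativeLimits(ai[co$group == "HC"], "volume")
      pred <- classifyByAsymmetry(ai, lim, level = "3SD")
      binaryMetrics(pred, co$group)$sensitivity
    }))
  })
  expect_true(all(diff(sens) > 0))
  expect_gt(sens[3], 0.95)
})
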