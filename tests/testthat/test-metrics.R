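# Metric formulas, AUROC, kappa, PCA, feature importance.

test_that("confusion-count metrics match hand arithmetic", {
  perfect <- classificationMetrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "precision",
                                "accuracy", "f1")]),
               c(sensitivity = 1, specificity = 1, precision = 1,
                 accuracy = 1, f1 = 1))
  m <- classificationMetrics(list(TP = 3, FN = 1, FP = 2, TN = 4))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$precision, 0.6)
  expect_equal(m$f1, 2 / (4 / 3 + 5 / 3))
  expect_equal(m$accuracy, 0.7)
})

test_that("zero denominators flag undefined metrics instead of NaN", {
  m <- classificationMetrics(list(TP = 0, TN = 10, FP = 0, FN = 5))
  expect_true(is.na(m$precision))
  expect_true("precision" %in% attr(m, "undefined"))
  expect_false(is.na(m$accuracy))
})

test_that("the harmonic-mean F1 equals its algebraic form", {
  set.seed(41)
  for (i in 1:25) {
    tp <- sample(1:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    m <- classificationMetrics(list(TP = tp, TN = 5, FP = fp, FN = fn))
    expect_equal(f1Score(m$sensitivity, m$precision),
                 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("accuracy is the prevalence-weighted mean of sens and spec", {
  set.seed(42)
  for (i in 1:20) {
    cc <- as.list(setNames(sample(1:40, 4, replace = TRUE),
                           c("TP", "TN", "FP", "FN")))
    m <- classificationMetrics(cc)
    n <- sum(unlist(cc))
    prev <- (cc$TP + cc$FN) / n
    expect_equal(m$accuracy,
                 prev * m$sensitivity + (1 - prev) * m$specificity)
  }
})

test_that("AUROC matches pair counting, pROC, and rank invariance", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(pairCountAuroc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  # perfectly separated
  expect_equal(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(43)
  sc <- runif(300); lb <- runif(300) < 0.4
  expect_equal(aurocScore(sc, lb), pairCountAuroc(sc, lb))
  expect_equal(aurocScore(sc, lb),
               as.numeric(pROC::auc(pROC::roc(as.numeric(lb), sc,
                                              quiet = TRUE,
                                              direction = "<"))))
  # invariant under strictly monotone transforms
  expect_equal(aurocScore(qlogis(sc), lb), aurocScore(sc, lb))
  # chance level for independent labels
  expect_lt(abs(aurocScore(sc, lb) - 0.5), 0.1)
  expect_error(aurocScore(sc, rep(TRUE, 300)), "one class absent")
})

test_that("ROC sweep covers sentinels and brackets the rank AUROC", {
  set.seed(44)
  sc <- runif(50); lb <- runif(50) < 0.5
  curve <- rocCurve(sc, lb)
  expect_equal(curve$sensitivity[1], 0)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$sensitivity[nrow(curve)], 1)
  expect_equal(curve$fpr[nrow(curve)], 1)
  # trapezoid over the sweep equals the rank form (no ties here)
  auc <- sum(diff(curve$fpr) *
               (head(curve$sensitivity, -1) + diff(curve$sensitivity) / 2))
  expect_equal(auc, aurocScore(sc, lb), tolerance = 1e-12)
})

test_that("Cohen's kappa matches independent marginal arithmetic", {
  expect_equal(cohensKappa(list(TP = 50, TN = 50, FP = 0, FN = 0)), 1)
  # hand-computed: po 0.85, pe (50*55 + 50*45)/100^2 = 0.5 -> kappa 0.7
  expect_equal(cohensKappa(list(TP = 45, FN = 5, FP = 10, TN = 40)), 0.7)
  # predictions carrying no information stay near zero
  expect_equal(cohensKappa(list(TP = 25, FN = 25, FP = 25, TN = 25)), 0)
  # degenerate marginals flag undefined
  k <- cohensKappa(list(TP = 10, TN = 0, FP = 0, FN = 0))
  expect_true(is.na(k))
})

test_that("PCA on standardized descriptors matches the eigen oracle", {
  tab <- quickTable(n = c(LBP = 30, PP = 120), seed = 45)
  pj <- pcaProject(tab, nComponents = 3)
  x <- as.matrix(descriptorRows(tab)[, descriptorNames()])
  ev <- eigen(cor(x), symmetric = TRUE)
  expect_equal(pj$explained, (ev$values / sum(ev$values))[1:3],
               tolerance = 1e-9)
  # loadings agree up to sign
  for (k in 1:3)
    expect_equal(abs(pj$loadings[, k]), abs(ev$vectors[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(diff(pj$explained) <= 1e-12))
})

test_that("rows on a line load entirely on PC1; constants drop", {
  base <- descriptorRows(quickTable(n = c(LBP = 2, PP = 4), seed = 46))
  t <- seq_len(6)
  base$pock_vol <- 10 * t; base$nb_AS <- 5 * t
  base$hydrophobicity_score <- -2 * t
  keep <- c("structure_id", "pocket_id", "pock_vol", "nb_AS",
            "hydrophobicity_score", "label", "matched_ligand")
  lineTab <- DescriptorTable(base[, keep])
  pj <- pcaProject(lineTab, nComponents = 2)
  expect_equal(pj$explained[1], 1)
  base$flex <- 1
  constTab <- DescriptorTable(base[, c(keep, "flex")])
  expect_warning(pj2 <- pcaProject(constTab, nComponents = 2), "flex")
  expect_equal(pj2$dropped, "flex")
})

test_that("permutation importance isolates the informative feature", {
  tab <- quickTable(n = c(LBP = 80, PP = 400), separation = 3, seed = 47)
  m <- trainClassifier(tab, seed = 48)
  pi <- permutationImportance(m, tab, nRepeats = 5, seed = 49)
  top <- pi$feature[which.max(pi$mean_delta_f1)]
  expect_equal(top, "hydrophobicity_score")
  # a feature the forest never uses loses nothing
  unused <- pi$mean_delta_f1[pi$feature == "charge_score"]
  expect_lt(abs(unused), 0.05)
  # deterministic
  pi2 <- permutationImportance(m, tab, nRepeats = 5, seed = 49)
  expect_identical(pi, pi2)
})

test_that("impurity importance is a normalized fraction vector", {
  tab <- quickTable(n = c(LBP = 80, PP = 400), seed = 50)
  m <- trainClassifier(tab, seed = 51)
  imp <- impurityImportance(m)
  expect_true(all(imp >= 0))
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  # top-1 agreement with permutation importance on this corpus
  pi <- permutationImportance(m, tab, nRepeats = 5, seed = 52)
  expect_equal(names(which.max(imp)),
               pi$feature[which.max(pi$mean_delta_f1)])
  mLog <- trainClassifier(tab, algorithm = "logistic", seed = 51)
  expect_error(impurityImportance(mLog), "tree-ensemble")
})

test_that("impurity ranking agrees with an independent forest", {
  tab <- quickTable(n = c(LBP = 80, PP = 400), seed = 53)
  m <- trainClassifier(tab, seed = 54)
  r <- descriptorRows(tab)
  set.seed(55)
  rf <- randomForest::randomForest(
    x = r[, descriptorNames()], y = factor(r$label == "LBP"))
  ref <- rf$importance[, "MeanDecreaseGini"]
  expect_equal(names(which.max(impurityImportance(m))),
               names(which.max(ref)))
})

test_that("box-plot summaries define outliers by 1.5 IQR", {
  v <- c(1:10, 100)
  bs <- boxplotSummary(v)
  expect_equal(bs$q1, as.numeric(quantile(v, 0.25)))
  expect_equal(bs$outliers, 100)
  expect_equal(bs$whisker_hi, 10)
  expect_equal(bs$min, 1)
  expect_equal(bs$max, 100)
})
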