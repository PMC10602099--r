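# Profiling workflow: scaling, regrouping, OPLS-DA, RF/ROC, ddCt.

two_group_table <- function(seed = 42L, nDiff = 5L, nFeat = 100L,
                            effect = 2) {
  generateFeatureTable(TableSpec(groups = c("a", "b"),
    groupSizes = c(40L, 40L), nFeatures = nFeat, nDifferential = nDiff,
    effectProfile = c(0, effect), orientationFraction = 0,
    seed = as.integer(seed)))
}

test_that("range scaling hits the worked example and its contract", {
  ft <- FeatureTable(matrix(c(1, 2, 3), 3, 1,
                            dimnames = list(NULL, "f")),
                     group = c("a", "a", "b"))
  expect_equal(unname(featureMatrix(rangeScale(ft))[, 1]), c(-0.5, 0, 0.5))
  set.seed(1)
  big <- FeatureTable(matrix(rnorm(200, 5, 3), 20, 10), group = rep(1:2, 10))
  sc <- featureMatrix(rangeScale(big))
  expect_true(all(abs(colMeans(sc)) < 1e-9))
  expect_true(all(abs(apply(sc, 2, function(x) diff(range(x))) - 1) < 1e-9))
  # constant feature dropped with warning
  cm <- cbind(matrix(rnorm(40), 20, 2), konst = 7)
  colnames(cm) <- c("f1", "f2", "konst")
  expect_warning(out <- rangeScale(FeatureTable(cm, group = rep(1:2, 10))),
                 "constant")
  expect_equal(nrow(out), 2)
})

test_that("power scaling hits the worked example, contract and error", {
  ft <- FeatureTable(matrix(c(1, 4, 9), 3, 1,
                            dimnames = list(NULL, "f")),
                     group = c("a", "a", "b"))
  expect_equal(unname(featureMatrix(powerScale(ft))[, 1]), c(-1, 0, 1))
  set.seed(2)
  big <- FeatureTable(matrix(rgamma(200, 2), 20, 10), group = rep(1:2, 10))
  expect_true(all(abs(colMeans(featureMatrix(powerScale(big)))) < 1e-9))
  bad <- FeatureTable(matrix(c(1, -2, 3), 3, 1,
                             dimnames = list(NULL, "negfeat")),
                      group = c("a", "a", "b"))
  expect_error(powerScale(bad), "negfeat")
})

test_that("orientation features are dropped by name pattern", {
  ft <- generateFeatureTable(TableSpec(nFeatures = 100L,
                                       orientationFraction = 0.03,
                                       seed = 6L))
  expect_message(out <- dropOrientationFeatures(ft), "3 of 100")
  expect_equal(nrow(out), 97)
  expect_false(any(grepl("orientation", rownames(out))))
  # no match -> unchanged
  expect_message(same <- dropOrientationFeatures(out, "orientation"))
  expect_equal(featureMatrix(same), featureMatrix(out))
  # all match -> warning, table kept
  expect_warning(suppressMessages(dropOrientationFeatures(out, ".")),
                 "all features")
})

test_that("regrouping relabels dose groups and rejects unmapped labels", {
  ft <- FeatureTable(matrix(rnorm(50), 10, 5),
                     group = rep(c("0.0001", "0.001", "0.01", "0.1", "1"),
                                 2))
  e2map <- c("0.0001" = "low", "0.001" = "low", "0.01" = "medium",
             "0.1" = "high", "1" = "high")
  out <- regroupSamples(ft, e2map)
  expect_equal(sort(unique(groupLabels(out))), c("high", "low", "medium"))
  expect_equal(featureMatrix(out), featureMatrix(ft))
  idmap <- c(low = "low", medium = "medium", high = "high")
  expect_equal(groupLabels(regroupSamples(out, idmap)), groupLabels(out))
  expect_error(regroupSamples(ft, c("0.0001" = "low")), "unmapped")
})

test_that("OPLS-DA with no orthogonal component reduces to NIPALS PLS1", {
  ft <- two_group_table(seed = 7L)
  m <- fitOplsDa(ft, nOrtho = 0L, seed = 1L)
  ref <- pls1_scores(featureMatrix(ft),
                     as.numeric(groupLabels(ft) == "b"))
  # sign of the component is arbitrary
  flip <- sign(sum(m@scores * ref))
  expect_lt(max(abs(m@scores - flip * ref)), 1e-8)
})

test_that("OPLS-DA invariants: VIP normalization and score orthogonality", {
  for (seed in c(1L, 2L)) {
    ft <- two_group_table(seed = seed)
    m <- fitOplsDa(ft, nOrtho = 2L, seed = 1L)
    expect_equal(mean(vipScores(m)^2), 1, tolerance = 1e-8)
    dots <- abs(crossprod(m@orthoScores, m@scores)) /
      (sqrt(colSums(m@orthoScores^2)) * sqrt(sum(m@scores^2)))
    expect_lt(max(dots), 1e-6)
  }
  # error cases
  one <- FeatureTable(matrix(rnorm(40), 10, 4), group = rep("a", 10))
  expect_error(fitOplsDa(one), "at least 2 groups")
  tiny <- FeatureTable(matrix(rnorm(8), 4, 2), group = c("a", "a", "b", "b"))
  expect_error(fitOplsDa(tiny, nOrtho = 5L, seed = 1L), "rank")
})

test_that("planted differential features top the VIP ranking and are
           selected at the conventional cutoff", {
  ft <- two_group_table(seed = 11L)
  m <- fitOplsDa(ft, seed = 1L)
  planted <- attr(ft, "differential")
  top5 <- names(sort(vipScores(m), decreasing = TRUE))[1:5]
  expect_setequal(top5, planted)
  sel <- selectDifferentialFeatures(m, 1.0)
  expect_true(all(planted %in% sel))
  # threshold semantics
  expect_equal(length(selectDifferentialFeatures(m, max(vipScores(m)))), 0)
  allFeat <- selectDifferentialFeatures(m, 0)
  expect_equal(length(allFeat), length(vipScores(m)))
  expect_equal(allFeat[1], names(sort(vipScores(m), decreasing = TRUE))[1])
})

test_that("feature intersection is order-stable", {
  expect_equal(intersectFeatures(c("f1", "f2"), c("f2", "f3")), "f2")
  expect_equal(intersectFeatures(c("a", "b"), c("c")), character(0))
  a <- c("f3", "f1", "f2")
  expect_equal(intersectFeatures(a, a), a)
  expect_equal(intersectFeatures(c("x", "y", "z"), c("z", "x")), c("x", "z"))
})

test_that("random-forest evaluation separates a separable table and is
           deterministic", {
  sp <- TableSpec(groups = c("c", "l", "m", "h"), groupSizes = rep(25L, 4),
                  nFeatures = 40L, nDifferential = 8L,
                  effectProfile = c(0, 4, 8, 12), orientationFraction = 0,
                  seed = 9L)
  ft <- generateFeatureTable(sp)
  roc <- trainRfAndEvaluate(ft, seed = 1L)
  expect_gte(roc@macroAuc, 0.999)
  expect_equal(roc@macroAuc, mean(roc@perClassAuc))
  roc2 <- trainRfAndEvaluate(ft, seed = 1L)
  expect_identical(roc@perClassAuc, roc2@perClassAuc)
  expect_identical(roc@microAuc, roc2@microAuc)
  # rank-based AUC equals explicit trapezoid integration
  set.seed(3)
  sc <- sample(seq(0, 1, by = 0.1), 60, replace = TRUE) # heavy ties
  lab <- runif(60) < 0.4
  expect_equal(microlumen:::.auc(sc, lab), trapezoid_auc(sc, lab))
  expect_error(trainRfAndEvaluate(ft, features = "nope"), "unknown feature")
})

test_that("normalizer comparison harness ranks methods by class
           separation", {
  ft <- generateFeatureTable(TableSpec(groupSizes = rep(15L, 4),
                                       nFeatures = 30L, seed = 14L,
                                       orientationFraction = 0))
  # shift positive so power scaling applies
  m <- featureMatrix(ft) + 10
  ft2 <- FeatureTable(m, groupLabels(ft))
  out <- compareNormalizers(ft2)
  expect_setequal(out$method, c("range", "power"))
  expect_true(all(is.finite(out$score)))
})

test_that("ddCt fold changes follow the Livak closed forms", {
  expect_equal(ddctFoldChange(20, 15, 25, 20), 1)    # ddCt 0
  expect_equal(ddctFoldChange(25, 20, 26, 20), 2)    # ddCt -1
  expect_equal(ddctFoldChange(24, 20, 22, 20), 0.25) # ddCt 2
  expect_equal(ddctFoldChange(24, 20, 22, 20, flipSign = TRUE), 4)
  expect_equal(ddctFoldChange(c(25, 24), 20, c(26, 22), 20), c(2, 0.25))
  expect_error(ddctFoldChange(NA, 20, 22, 20))
})
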