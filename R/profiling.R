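# Feature-table workflow: normalization (range/power scaling), orientation
# feature removal, dose regrouping, OPLS-DA differential-feature selection,
# random-forest classification with macro/micro multi-class AUC, and
# delta-delta-Ct fold-change arithmetic.

.rebuild_table <- function(table, m) {
  FeatureTable(m, group = groupLabels(table),
               sampleIds = colnames(SummarizedExperiment::assay(table)))
}

#' Range scaling
#'
#' Per feature: `(x - mean(x)) / (max(x) - min(x))`, so each scaled feature
#' has mean 0 and range exactly 1. Constant features have no range and are
#' dropped with a warning.
#'
#' @param table a [FeatureTable-class].
#' @return the scaled [FeatureTable-class].
#' @examples
#' ft <- FeatureTable(matrix(c(1, 2, 3), 3, 1,
#'                    dimnames = list(NULL, "f1")), group = c("a","a","b"))
#' featureMatrix(rangeScale(ft))[, 1]  # -0.5 0 0.5
#' @export
rangeScale <- function(table) {
  m <- featureMatrix(table)
  rng <- apply(m, 2, function(x) diff(range(x)))
  if (any(rng == 0)) {
    warning("dropping ", sum(rng == 0), " constant feature(s): ",
            paste(head(colnames(m)[rng == 0], 5), collapse = ", "))
    m <- m[, rng > 0, drop = FALSE]
    rng <- rng[rng > 0]
  }
  if (ncol(m) == 0) stop("no non-constant features left")
  m <- sweep(sweep(m, 2, colMeans(m)), 2, rng, "/")
  .rebuild_table(table, m)
}

#' Power scaling
#'
#' Per feature: square root, then mean-centering; scaled features have
#' mean 0. Requires non-negative values.
#'
#' @param table a [FeatureTable-class].
#' @return the scaled [FeatureTable-class].
#' @export
powerScale <- function(table) {
  m <- featureMatrix(table)
  neg <- colSums(m < 0) > 0
  if (any(neg))
    stop("power scaling needs non-negative values; negative entries in: ",
         paste(head(colnames(m)[neg], 5), collapse = ", "))
  m <- sqrt(m)
  m <- sweep(m, 2, colMeans(m))
  .rebuild_table(table, m)
}

#' Drop orientation-describing features
#'
#' Object-orientation features depend on how a microtissue happens to lie
#' in the well and are removed before profiling.
#'
#' @param table a [FeatureTable-class].
#' @param patterns character regex patterns (case-insensitive); features
#'   whose names match any pattern are removed.
#' @return the reduced [FeatureTable-class].
#' @export
dropOrientationFeatures <- function(table, patterns = "orientation") {
  stopifnot(length(patterns) > 0)
  nm <- rownames(table)
  hit <- Reduce(`|`, lapply(patterns, grepl, x = nm, ignore.case = TRUE))
  message("dropping ", sum(hit), " of ", length(nm),
          " features matching orientation patterns")
  if (all(hit)) {
    warning("all features match the orientation patterns; table unchanged")
    return(table)
  }
  if (!any(hit)) return(table)
  m <- featureMatrix(table)[, !hit, drop = FALSE]
  .rebuild_table(table, m)
}

#' Regroup sample labels
#'
#' Replaces dose labels by coarser groups (e.g. pooling the two highest
#' doses into one "high" group) without touching the feature matrix.
#'
#' @param table a [FeatureTable-class].
#' @param mapping named character vector or list, `old label -> new label`;
#'   must cover every observed label.
#' @return the relabelled [FeatureTable-class].
#' @examples
#' \dontrun{
#' regroupSamples(ft, c("0.1" = "high", "1" = "high", "0.01" = "medium"))
#' }
#' @export
regroupSamples <- function(table, mapping) {
  mapping <- unlist(mapping)
  old <- groupLabels(table)
  missing <- setdiff(unique(old), names(mapping))
  if (length(missing))
    stop("unmapped label(s): ", paste(missing, collapse = ", "))
  groupLabels(table) <- unname(mapping[old])
  table
}

# ---------------------------------------------------------------------------
# OPLS-DA
# ---------------------------------------------------------------------------

# Core OPLS fit on centered X (n x p) and centered one-hot Y (n x G):
# predictive weight w = first left singular vector of X'Y; nOrtho
# orthogonal components are extracted and deflated before the final
# predictive component. Returns NULL if rank is exhausted early.
.opls_core <- function(X, Yc, nOrtho) {
  w <- svd(crossprod(X, Yc), nu = 1, nv = 0)$u[, 1]
  Xd <- X
  p_feat <- ncol(X)
  Wo <- matrix(0, p_feat, 0); Po <- matrix(0, p_feat, 0)
  To <- matrix(0, nrow(X), 0)
  for (k in seq_len(nOrtho)) {
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) return(NULL) # rank exhausted
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  C <- crossprod(Yc, t) / sum(t^2) # G x 1
  list(w = w, t = t, p = p, C = C, Wo = Wo, Po = Po, To = To)
}

.opls_predict <- function(fit, Xnew) {
  for (k in seq_len(ncol(fit$Wo))) {
    to <- drop(Xnew %*% fit$Wo[, k])
    Xnew <- Xnew - tcrossprod(to, fit$Po[, k])
  }
  tnew <- drop(Xnew %*% fit$w)
  tcrossprod(tnew, fit$C) # n x G, centered scale
}

# cross-validated Q2 for a given number of orthogonal components
.opls_q2 <- function(X, Y, folds, nOrtho) {
  press <- 0; tss <- 0
  for (f in unique(folds)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, mu)
    ymu <- colMeans(Y[tr, , drop = FALSE])
    Ytr <- sweep(Y[tr, , drop = FALSE], 2, ymu)
    fit <- .opls_core(Xtr, Ytr, nOrtho)
    if (is.null(fit)) return(NA_real_)
    Yhat <- sweep(.opls_predict(fit, sweep(X[te, , drop = FALSE], 2, mu)),
                  2, ymu, "+")
    press <- press + sum((Y[te, , drop = FALSE] - Yhat)^2)
    tss <- tss + sum(sweep(Y[te, , drop = FALSE], 2, ymu)^2)
  }
  1 - press / tss
}

#' Fit an OPLS-DA model
#'
#' Orthogonal PLS discriminant analysis against a centered one-hot group
#' encoding, with one predictive component (NIPALS-style: the predictive
#' weight is the leading singular vector of `X'Y`, orthogonal components
#' are deflated first). With `nOrtho = "auto"`, orthogonal components are
#' added while the `cvFolds`-fold cross-validated Q2 improves by more than
#' `q2Tol`, capped at `maxOrtho`. With `nOrtho = 0` the predictive scores
#' reduce exactly to the first PLS component. Per-feature VIP is normalized
#' so `mean(VIP^2) = 1`.
#'
#' @param table a [FeatureTable-class]; features are centered internally
#'   (normalize first — see [rangeScale()] / [powerScale()]).
#' @param nOrtho `"auto"` or a fixed non-negative integer.
#' @param cvFolds folds for the Q2 cross-validation (default 2).
#' @param q2Tol minimum Q2 gain to accept another orthogonal component.
#' @param maxOrtho cap on orthogonal components under `"auto"`.
#' @param seed seed for the stratified fold assignment.
#' @return An [OplsModel-class].
#' @export
fitOplsDa <- function(table, nOrtho = "auto", cvFolds = 2L, q2Tol = 0.01,
                      maxOrtho = 10L, seed = 1L) {
  X <- featureMatrix(table)
  g <- factor(groupLabels(table))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- nrow(X)
  Y <- stats::model.matrix(~ g - 1)
  colnames(Y) <- levels(g)

  set.seed(as.integer(seed))
  folds <- integer(n)
  for (lv in levels(g)) { # stratified fold assignment
    idx <- sample(which(g == lv))
    folds[idx] <- rep_len(seq_len(cvFolds), length(idx))
  }

  pickQ2 <- function(h) .opls_q2(X, Y, folds, h)
  if (identical(nOrtho, "auto")) {
    h <- 0L
    q2 <- pickQ2(0L)
    while (h < maxOrtho) {
      q2next <- pickQ2(h + 1L)
      if (is.na(q2next) || q2next - q2 <= q2Tol) break
      h <- h + 1L
      q2 <- q2next
    }
  } else {
    h <- as.integer(nOrtho)
    stopifnot(h >= 0)
    q2 <- pickQ2(h)
  }

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Yc <- sweep(Y, 2, colMeans(Y))
  fit <- .opls_core(Xc, Yc, h)
  if (is.null(fit))
    stop("requested more orthogonal components than the data rank permits")
  vip <- sqrt(ncol(X)) * abs(fit$w) / sqrt(sum(fit$w^2))
  names(vip) <- colnames(X)
  new("OplsModel", scores = fit$t, loadings = fit$p, weights = fit$w,
      orthoScores = fit$To, orthoLoadings = fit$Po, orthoWeights = fit$Wo,
      vip = vip, q2 = q2, nOrtho = h, groups = levels(g),
      featureMeans = mu)
}

#' @describeIn fitOplsDa per-feature VIP scores of a fitted model.
#' @param x an `OplsModel`.
#' @export
setMethod("vipScores", "OplsModel", function(x) x@vip)

setMethod("show", "OplsModel", function(object) {
  cat("OplsModel: 1 predictive +", object@nOrtho,
      "orthogonal component(s),", length(object@vip), "features\n")
  cat("  groups:", paste(object@groups, collapse = ", "),
      " Q2:", signif(object@q2, 4), "\n")
})

#' Select differential features by VIP
#'
#' Features with VIP above the threshold (community convention: 1.0),
#' sorted by decreasing VIP.
#'
#' @param model an [OplsModel-class].
#' @param vipThreshold VIP cutoff.
#' @return character vector of feature names.
#' @export
selectDifferentialFeatures <- function(model, vipThreshold = 1.0) {
  v <- sort(model@vip, decreasing = TRUE)
  names(v)[v > vipThreshold]
}

#' Order-stable intersection of feature lists
#'
#' @param a,b character vectors.
#' @return elements of `a` also present in `b`, in `a`'s order.
#' @export
intersectFeatures <- function(a, b) a[a %in% b]

# ---------------------------------------------------------------------------
# Random forest + multi-class ROC
# ---------------------------------------------------------------------------

# Mann-Whitney AUC (equivalent to trapezoidal ROC integration with mid-rank
# tie handling)
.auc <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Train a random forest and evaluate multi-class ROC
#'
#' Stratified 80/20 split by seed, a `nTrees`-tree random forest on the
#' training part, one-vs-rest ROC on the held-out part from class
#' probability scores. Returns per-class AUC, their arithmetic mean
#' (macro-average) and the AUC of the pooled one-vs-rest decisions
#' (micro-average). ROC integration uses mid-rank tie handling.
#'
#' @param table a [FeatureTable-class]; every group needs >= 2 samples.
#' @param features feature names to use (default: all).
#' @param nTrees forest size (default 100).
#' @param split training fraction (default 0.8).
#' @param seed split + training seed.
#' @return A [RocResult-class].
#' @export
trainRfAndEvaluate <- function(table, features = NULL, nTrees = 100L,
                               split = 0.8, seed = 1L) {
  m <- featureMatrix(table)
  if (!is.null(features)) {
    bad <- setdiff(features, colnames(m))
    if (length(bad)) stop("unknown feature(s): ", paste(head(bad, 5),
                                                        collapse = ", "))
    m <- m[, features, drop = FALSE]
  }
  y <- factor(groupLabels(table))
  if (any(table(y) < 2)) stop("every group needs at least 2 samples")
  set.seed(as.integer(seed))
  for (attempt in 1:10) {
    trainIdx <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      nTrain <- min(length(idx) - 1L, max(1L, floor(split * length(idx))))
      sample(idx, nTrain)
    }))
    testIdx <- setdiff(seq_along(y), trainIdx)
    if (all(levels(y) %in% y[testIdx])) break
    warning("class absent from test split; re-drawing")
  }
  rf <- randomForest::randomForest(x = m[trainIdx, , drop = FALSE],
                                   y = y[trainIdx], ntree = nTrees)
  prob <- predict(rf, m[testIdx, , drop = FALSE], type = "prob")
  ytest <- y[testIdx]
  perClass <- vapply(levels(y), function(lv)
    .auc(prob[, lv], ytest == lv), numeric(1))
  micro <- .auc(as.vector(prob),
                as.vector(vapply(levels(y), function(lv) ytest == lv,
                                 logical(length(ytest)))))
  new("RocResult", perClassAuc = perClass, macroAuc = mean(perClass),
      microAuc = micro, seed = as.integer(seed))
}

setMethod("show", "RocResult", function(object) {
  cat("RocResult: macro AUC", round(object@macroAuc, 4),
      "| micro AUC", round(object@microAuc, 4), "\n  per class:",
      paste(sprintf("%s %.4f", names(object@perClassAuc),
                    object@perClassAuc), collapse = ", "), "\n")
})

#' Compare normalization methods by class separation
#'
#' Small harness ranking registered normalizers by the mean per-feature
#' one-way ANOVA F statistic between groups after normalization (a simple
#' downstream class-separation score).
#'
#' @param table a [FeatureTable-class].
#' @param normalizers named list of `function(table) -> table`.
#' @return data.frame `method, score`, best first.
#' @export
compareNormalizers <- function(table,
                               normalizers = list(range = rangeScale,
                                                  power = powerScale)) {
  g <- factor(groupLabels(table))
  scores <- vapply(normalizers, function(fn) {
    m <- featureMatrix(suppressWarnings(fn(table)))
    f <- apply(m, 2, function(x) {
      fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
      as.numeric(fit$statistic)
    })
    mean(f[is.finite(f)])
  }, numeric(1))
  out <- data.frame(method = names(normalizers), score = scores,
                    row.names = NULL)
  out[order(-out$score), ]
}

#' Delta-delta-Ct fold change
#'
#' Livak convention: `dCt = Ct_target - Ct_reference` per condition,
#' `ddCt = dCt_treated - dCt_control`, fold change `2^(-ddCt)`.
#' `flipSign = TRUE` negates `ddCt` for the opposite subtraction order.
#'
#' @param ctTargetTreat,ctRefTreat,ctTargetCtrl,ctRefCtrl cycle-threshold
#'   values (vectors recycle).
#' @param flipSign negate the double delta before exponentiation.
#' @return fold change(s), `2^(-ddCt)`.
#' @examples
#' ddctFoldChange(25, 20, 26, 20)  # dCt 5 vs 6 -> ddCt -1 -> fold 2
#' @export
ddctFoldChange <- function(ctTargetTreat, ctRefTreat, ctTargetCtrl,
                           ctRefCtrl, flipSign = FALSE) {
  stopifnot(all(is.finite(c(ctTargetTreat, ctRefTreat, ctTargetCtrl,
                            ctRefCtrl))))
  ddct <- (ctTargetTreat - ctRefTreat) - (ctTargetCtrl - ctRefCtrl)
  if (flipSign) ddct <- -ddct
  2^(-ddct)
}
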