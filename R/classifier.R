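#' Feature scaling with train-only statistics
#'
#' Scaling statistics are estimated on the training matrix only and applied
#' to both matrices, so no information leaks from test to train.  `zscore`
#' centres by the column mean and divides by the population SD (divisor
#' `n`); `minmax` maps the training range to \[0, 1\] (test values may fall
#' outside it); `none` is the identity.  A zero-variance (or zero-range)
#' training column is scaled to 0 with a warning.
#'
#' @param train numeric matrix, samples x features.
#' @param test optional matrix with the same columns.
#' @param mode `"zscore"`, `"minmax"` or `"none"`.
#' @return list with `train`, `test` (NULL if not supplied), `center`,
#'   `scale`, `mode`.
#' @export
scaleFeatures <- function(train, test = NULL,
                          mode = c("zscore", "minmax", "none")) {
  mode <- match.arg(mode)
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("training matrix is empty")
  if (mode == "none")
    return(list(train = train, test = test, center = rep(0, ncol(train)),
                scale = rep(1, ncol(train)), mode = mode))
  if (mode == "zscore") {
    center <- colMeans(train)
    scale <- sqrt(colMeans(sweep(train, 2L, center)^2))
  } else {
    center <- apply(train, 2L, min)
    scale <- apply(train, 2L, max) - center
  }
  zero <- scale == 0
  if (any(zero)) {
    warning("zero-variance feature(s) scaled to 0: ",
            paste(colnames(train)[zero], collapse = ", "))
    scale[zero] <- 1
  }
  apply_ <- function(m) sweep(sweep(as.matrix(m), 2L, center), 2L, scale, "/")
  list(train = apply_(train),
       test = if (is.null(test)) NULL else apply_(test),
       center = center, scale = scale, mode = mode)
}

# accepts +1/-1, "responder"/"non_responder", or a factor; responder == +1
responseFactor <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(1, -1))) stop("numeric labels must be +1/-1")
    labels <- ifelse(labels == 1, "responder", "non_responder")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("responder", "non_responder")))
    stop("labels must be responder/non_responder or +1/-1")
  factor(labels, levels = c("responder", "non_responder"))
}

#' Train an RBF-kernel support vector machine
#'
#' Soft-margin SVM with Gaussian kernel
#' `K(xi, xj) = exp(-gamma * ||xi - xj||^2)`, solved by LIBSVM (via e1071)
#' to its stated tolerance; deterministic for fixed inputs and parameters.
#' Responder is the positive class (+1).  Features are scaled with
#' train-only statistics (see [scaleFeatures()]) before fitting, and the
#' statistics are stored in the model for prediction.
#'
#' @param x numeric matrix, samples x features.
#' @param labels responder/non-responder labels (or +1/-1).
#' @param cost soft-margin cost C (> 0).
#' @param gamma RBF width (> 0); `NULL` selects
#'   `1 / (n_features * var(scaled training values))`.
#' @param scaleMode feature scaling mode (default `"zscore"`).
#' @return object of class `svmRBF`: the LIBSVM fit plus scaling statistics
#'   and the kernel parameters.
#' @export
trainSVMRBF <- function(x, labels, cost = 1, gamma = NULL,
                        scaleMode = c("zscore", "minmax", "none")) {
  scaleMode <- match.arg(scaleMode)
  x <- as.matrix(x)
  y <- responseFactor(labels)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (cost <= 0) stop("cost must be > 0")
  sc <- scaleFeatures(x, mode = scaleMode)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(sc$train)) * (length(sc$train) - 1) /
      length(sc$train)
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  if (gamma <= 0) stop("gamma must be > 0")
  fit <- e1071::svm(sc$train, y, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE, type = "C-classification")
  structure(list(fit = fit, center = sc$center, scale = sc$scale,
                 scaleMode = scaleMode, gamma = gamma, cost = cost,
                 nFeatures = ncol(x)),
            class = "svmRBF")
}

#' @export
print.svmRBF <- function(x, ...) {
  cat(sprintf("RBF-SVM: C = %.4g, gamma = %.4g, %d support vectors, %d feature(s)\n",
              x$cost, x$gamma, x$fit$tot.nSV, x$nFeatures))
  invisible(x)
}

#' Predict responder status
#'
#' The predicted class is the sign of the decision value (the signed
#' distance of the case from the separating hyperplane); a decision value
#' of exactly 0 is mapped to +1.  Decision values are oriented so that
#' positive means responder and are returned for ROC analysis.
#'
#' @param object an `svmRBF` model from [trainSVMRBF()].
#' @param newdata numeric matrix, samples x features (same features as
#'   training).
#' @param ... ignored.
#' @return list with `label` (+1/-1 per sample) and `decision` (numeric).
#' @export
predict.svmRBF <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$nFeatures)
    stop("feature dimension mismatch: model has ", object$nFeatures,
         ", data has ", ncol(newdata))
  z <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  pr <- stats::predict(object$fit, z, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  d <- as.numeric(dv[, 1L])
  # e1071 orients decision values toward the first named class
  if (!startsWith(colnames(dv)[1L], "responder")) d <- -d
  lab <- ifelse(d >= 0, 1L, -1L)
  list(label = lab, decision = d)
}

#' Confusion counts with responder as the positive class
#'
#' @param predicted,truth label vectors (+1/-1 or responder strings).
#' @return named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(predicted, truth) {
  p <- responseFactor(predicted) == "responder"
  t <- responseFactor(truth) == "responder"
  c(TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / N`.  A zero denominator yields `NaN` with a
#' warning, never a silent 0.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector (`sensitivity`, `specificity`,
#'   `accuracy`).
#' @export
classifierMetrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (any(is.na(counts))) stop("counts must contain TP, TN, FP, FN")
  if (any(counts < 0)) stop("negative confusion counts")
  n <- sum(counts)
  if (n == 0) stop("no evaluated samples")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  c(sensitivity = ratio(counts[["TP"]], counts[["TP"]] + counts[["FN"]],
                        "sensitivity"),
    specificity = ratio(counts[["TN"]], counts[["TN"]] + counts[["FP"]],
                        "specificity"),
    accuracy = (counts[["TP"]] + counts[["TN"]]) / n)
}

stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the RBF-SVM
#'
#' Per repeat, samples are assigned to stratified folds from a seeded RNG;
#' per fold, features are scaled on the training part only, the SVM is
#' fitted and the held-out samples are predicted.  Metrics are pooled over
#' the folds of each repeat (confusion counts summed; AUC from the pooled
#' decision values) and averaged across repeats.  An assignment leaving a
#' training set with one class is redrawn (bounded retries).
#'
#' @param x numeric matrix, samples x features.
#' @param labels responder/non-responder labels (or +1/-1).
#' @param k folds (>= 2, <= n).
#' @param repeats number of CV repetitions.
#' @param cost,gamma,scaleMode passed to [trainSVMRBF()].
#' @param seed RNG seed for the fold assignments.
#' @return a [CVReport-class].
#' @export
kfoldCV <- function(x, labels, k = 5, repeats = 5, cost = 1, gamma = NULL,
                    scaleMode = "zscore", seed = 1) {
  x <- as.matrix(x)
  y <- responseFactor(labels)
  n <- nrow(x)
  if (n < k) stop("need at least k samples")
  if (min(table(y)) < 2L) stop("both classes need >= 2 members")
  foldRows <- list(); repRows <- list()
  assignments <- matrix(NA_integer_, n, repeats,
                        dimnames = list(rownames(x), NULL))
  withSeed(seed, {
    for (r in seq_len(repeats)) {
      fold <- NULL
      for (try in seq_len(25L)) {
        cand <- stratifiedFolds(y, k)
        ok <- all(vapply(seq_len(k), function(f)
          length(unique(y[cand != f])) == 2L, TRUE))
        if (ok) { fold <- cand; break }
      }
      if (is.null(fold))
        stop("could not stratify folds with both classes in every training set")
      assignments[, r] <- fold
      dvAll <- numeric(n)
      for (f in seq_len(k)) {
        testIdx <- which(fold == f)
        if (length(testIdx) == 0L) next
        trainIdx <- setdiff(seq_len(n), testIdx)
        model <- trainSVMRBF(x[trainIdx, , drop = FALSE], y[trainIdx],
                             cost = cost, gamma = gamma,
                             scaleMode = scaleMode)
        pr <- predict(model, x[testIdx, , drop = FALSE])
        dvAll[testIdx] <- pr$decision
        cc <- confusionCounts(pr$label, y[testIdx])
        met <- suppressWarnings(classifierMetrics(cc))
        foldAuc <- if (length(unique(y[testIdx])) == 2L)
          rocAUC(pr$decision, y[testIdx])$auc else NA_real_
        foldRows[[length(foldRows) + 1L]] <- data.frame(
          rep = r, fold = f, TP = cc[["TP"]], TN = cc[["TN"]],
          FP = cc[["FP"]], FN = cc[["FN"]],
          accuracy = met[["accuracy"]],
          sensitivity = met[["sensitivity"]],
          specificity = met[["specificity"]], auc = foldAuc)
      }
      rows <- do.call(rbind, foldRows)
      rows <- rows[rows$rep == r, ]
      cc <- c(TP = sum(rows$TP), TN = sum(rows$TN),
              FP = sum(rows$FP), FN = sum(rows$FN))
      met <- classifierMetrics(cc)
      repRows[[r]] <- data.frame(
        rep = r, TP = cc[["TP"]], TN = cc[["TN"]], FP = cc[["FP"]],
        FN = cc[["FN"]], accuracy = met[["accuracy"]],
        sensitivity = met[["sensitivity"]],
        specificity = met[["specificity"]],
        auc = rocAUC(dvAll, y)$auc)
    }
  })
  folds <- do.call(rbind, foldRows)
  reps <- do.call(rbind, repRows)
  summ <- c(mean_accuracy = mean(reps$accuracy),
            sd_accuracy = stats::sd(reps$accuracy),
            mean_sensitivity = mean(reps$sensitivity),
            sd_sensitivity = stats::sd(reps$sensitivity),
            mean_specificity = mean(reps$specificity),
            sd_specificity = stats::sd(reps$specificity),
            mean_auc = mean(reps$auc),
            sd_auc = stats::sd(reps$auc))
  new("CVReport", folds = folds, repeats = reps, summary = summ,
      assignments = assignments, seed = seed)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random responder's score
#' exceeds a random non-responder's, ties counting one half (computed from
#' mid-ranks).  ROC points are obtained by thresholding the scores at every
#' observed value, descending.
#'
#' @param scores numeric scores, larger meaning more responder-like.
#' @param labels responder/non-responder labels (or +1/-1).
#' @return list with `auc` and `points` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
rocAUC <- function(scores, labels) {
  y <- responseFactor(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pos <- y == "responder"
  r <- rank(scores, ties.method = "average")
  nPos <- sum(pos); nNeg <- sum(!pos)
  auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), 0),
    tpr = vapply(th, function(t) mean(scores[pos] >= t), 0))
  list(auc = auc, points = points)
}

#' Compare two correlated AUCs (DeLong test)
#'
#' Two-sided DeLong test for paired ROC curves computed from two score
#' vectors on the same samples.  Degenerate cases are never silent: two
#' perfect curves (both AUC 1, zero covariance) yield p = 1 with a warning
#' that the comparison is uninformative, and a variance failure yields
#' `NA` with a warning.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels responder/non-responder labels (or +1/-1).
#' @return list with `aucA`, `aucB`, `statistic` (z), `p_value`.
#' @export
compareAUC <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB))
    stop("score vectors must be paired")
  y <- responseFactor(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  mk <- function(s) pROC::roc(response = y, predictor = s,
                              levels = c("non_responder", "responder"),
                              direction = "<", quiet = TRUE)
  rA <- mk(scoresA); rB <- mk(scoresB)
  res <- tryCatch(pROC::roc.test(rA, rB, method = "delong", paired = TRUE),
                  error = function(e) NULL)
  p <- if (is.null(res)) NA_real_ else as.numeric(res$p.value)
  z <- if (is.null(res)) NA_real_ else as.numeric(res$statistic)
  if (!is.null(res) && (is.na(p) || is.nan(p))) p <- NA_real_
  if (is.na(p))
    warning("DeLong comparison not computable (degenerate variance)")
  list(aucA = as.numeric(pROC::auc(rA)), aucB = as.numeric(pROC::auc(rB)),
       statistic = z, p_value = p)
}

#' Orient a univariate marker for ROC analysis
#'
#' Uses a raw covariate or single-marker value directly as a classification
#' score, flipping its sign when needed so the reported AUC is >= 0.5; the
#' chosen orientation is returned.
#'
#' @param values numeric marker values.
#' @param labels responder/non-responder labels (or +1/-1).
#' @return list with `auc`, `orientation` (+1 or -1) and `scores` (the
#'   oriented values).
#' @export
univariateROC <- function(values, labels) {
  a <- rocAUC(values, labels)$auc
  orientation <- if (a >= 0.5) 1 else -1
  scores <- orientation * values
  list(auc = rocAUC(scores, labels)$auc, orientation = orientation,
       scores = scores)
}

#' Comparative-CT qPCR fold change
#'
#' `fold = 2^-ddCt` with
#' `ddCt = (Ct_target_case - Ct_ref_case) - (Ct_target_ctrl - Ct_ref_ctrl)`,
#' i.e. target expression normalised to the reference gene (U6) and
#' expressed relative to the control condition.
#'
#' @param ctTargetCase,ctRefCase,ctTargetCtrl,ctRefCtrl positive Ct values
#'   (vectors recycle).
#' @return fold change(s).
#' @examples
#' ddctFoldChange(20, 18, 22, 18)  # 4
#' @export
ddctFoldChange <- function(ctTargetCase, ctRefCase, ctTargetCtrl,
                           ctRefCtrl) {
  cts <- c(ctTargetCase, ctRefCase, ctTargetCtrl, ctRefCtrl)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be positive reals")
  ddct <- (ctTargetCase - ctRefCase) - (ctTargetCtrl - ctRefCtrl)
  2^(-ddct)
}
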