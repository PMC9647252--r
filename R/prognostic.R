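#' ROC AUC via the Mann-Whitney identity
#'
#' Exact on small n, with the standard 1/2 tie credit.
#'
#' @param pred Numeric predictions.
#' @param y Binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(pred, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(pred)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared error between predicted probabilities and binary labels.
#'
#' @param pred Predicted probabilities.
#' @param y Binary 0/1 labels.
#' @return Brier score in `[0, 1]`.
#' @export
brier_score <- function(pred, y) mean((pred - as.numeric(y))^2)

#' ROC curve points
#'
#' @param pred Numeric predictions.
#' @param y Binary 0/1 labels.
#' @return Data.frame with `threshold`, `fpr`, `tpr`, sorted for
#'   trapezoidal integration.
#' @export
roc_points <- function(pred, y) {
  y <- as.integer(y)
  th <- c(Inf, sort(unique(pred), decreasing = TRUE))
  out <- t(vapply(th, function(t_) {
    yy <- pred >= t_
    c(fpr = sum(yy & y == 0L) / max(sum(y == 0L), 1L),
      tpr = sum(yy & y == 1L) / max(sum(y == 1L), 1L))
  }, numeric(2)))
  data.frame(threshold = th, fpr = out[, "fpr"], tpr = out[, "tpr"])
}

# stratified k-fold assignment
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated evaluation of logistic prognostic models
#'
#' Stratified k-fold logistic regression per feature set; out-of-fold
#' probabilities are pooled and scored: ROC curve and AUC (Mann-Whitney),
#' Brier score, and a decile calibration table (predicted vs observed per
#' bin). Folds that would miss one outcome class are re-drawn with a new
#' seed (logged in the report).
#'
#' @param data Data.frame.
#' @param feature_sets Named list of character feature vectors.
#' @param outcome Binary 0/1 outcome column.
#' @param k Folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return Named list (per feature set) of `model_report`s: `auc`,
#'   `brier`, `roc` (points), `calibration` (decile bins), `oof`
#'   (out-of-fold probabilities), `refolds`.
#' @export
cv_evaluate <- function(data, feature_sets, outcome, k = 10L, seed = 1L) {
  y <- as.integer(data[[outcome]])
  stopifnot(all(y %in% 0:1))
  if (is.null(names(feature_sets)))
    names(feature_sets) <- vapply(feature_sets, paste, "", collapse = "+")
  n <- nrow(data)
  k <- min(k, min(table(y)))

  out <- list()
  for (fs in names(feature_sets)) {
    feats <- feature_sets[[fs]]
    miss <- setdiff(feats, names(data))
    if (length(miss))
      stop("features absent: ", paste(miss, collapse = ", "), call. = FALSE)
    X <- stats::model.matrix(~ ., data = data[, feats, drop = FALSE])
    refolds <- 0L
    s <- seed
    repeat {
      fold <- .stratified_folds(y, k, s)
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[fold != f])) == 2L, logical(1)))
      if (ok) break
      refolds <- refolds + 1L
      s <- s + 1000L
      if (refolds > 50L) stop("cannot stratify folds", call. = FALSE)
    }
    oof <- numeric(n)
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- suppressWarnings(stats::glm.fit(X[tr, , drop = FALSE], y[tr],
                                             family = stats::binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      eta <- drop(X[!tr, , drop = FALSE] %*% cf)
      oof[!tr] <- stats::plogis(eta)
    }
    bins <- cut(oof, breaks = stats::quantile(oof, 0:10 / 10, type = 7),
                include.lowest = TRUE)
    calib <- data.frame(bin = levels(bins),
                        n = as.integer(table(bins)),
                        predicted = as.numeric(tapply(oof, bins, mean)),
                        observed = as.numeric(tapply(y, bins, mean)))
    out[[fs]] <- structure(
      list(features = feats, auc = auc_mw(oof, y),
           brier = brier_score(oof, y), roc = roc_points(oof, y),
           calibration = calib, oof = oof, refolds = refolds, k = k),
      class = "model_report")
  }
  out
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> {%s}: AUC = %.3f, Brier = %.3f (k = %d)\n",
              paste(x$features, collapse = ", "), x$auc, x$brier, x$k))
  invisible(x)
}

# --- RBF-kernel maximum-margin classifier (C-SVM dual via quadprog) ----

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an RBF-kernel support vector machine
#'
#' Soft-margin C-SVM solved exactly in the dual with quadratic
#' programming; suitable for the small fold sizes used in nested
#' cross-validation.
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param C Soft-margin cost (default 1).
#' @param gamma RBF width; default is the median heuristic
#'   `1 / median(pairwise squared distance)`.
#' @return An `svm_rbf` model.
#' @export
svm_rbf <- function(X, y, C = 1, gamma = NULL) {
  X <- as.matrix(X)
  ys <- ifelse(as.integer(y) == 1L, 1, -1)
  n <- nrow(X)
  if (is.null(gamma)) {
    d2 <- as.numeric(stats::dist(X))^2
    med <- stats::median(d2[d2 > 0])
    gamma <- if (is.finite(med) && med > 0) 1 / med else 1
  }
  K <- .rbf_kernel(X, X, gamma)
  D <- (ys %o% ys) * K
  diag(D) <- diag(D) + 1e-8 * max(diag(D))
  A <- cbind(ys, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-6 * C
  # bias from margin vectors (0 < alpha < C)
  marg <- which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6))
  f0 <- drop(K %*% (alpha * ys))
  b <- if (length(marg)) mean(ys[marg] - f0[marg]) else
    -(max(f0[ys == -1]) + min(f0[ys == 1])) / 2
  structure(list(X = X[sv, , drop = FALSE], coef = (alpha * ys)[sv],
                 b = b, gamma = gamma, C = C),
            class = "svm_rbf")
}

#' @param object An `svm_rbf` model.
#' @param newdata Feature matrix to classify.
#' @param ... Unused.
#' @return Integer 0/1 predicted labels.
#' @rdname svm_rbf
#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  K <- .rbf_kernel(as.matrix(newdata), object$X, object$gamma)
  as.integer(drop(K %*% object$coef) + object$b > 0)
}

#' Two-step feature ranking: LASSO selection then SVM-RBF classification
#'
#' Repeated nested cross-validation: per repeat and outer fold, an
#' L1-penalised logistic model is tuned on the inner folds by
#' classification accuracy (0.5 probability cutoff); the features it
#' selects feed an RBF-kernel maximum-margin classifier whose accuracy is
#' measured on the outer fold. Selections from models with outer accuracy
#' above `acc_thresh` are tallied into a frequency ranking.
#'
#' @param data Data.frame.
#' @param features Candidate feature columns.
#' @param outcome Binary 0/1 outcome column.
#' @param repeats Number of repeats (default 100).
#' @param outer_k,inner_k Outer/inner fold counts (default 5/5).
#' @param acc_thresh Accuracy acceptance threshold (default 0.8).
#' @param top_k Length of the reported top list (default 10).
#' @param seed Integer seed.
#' @return A `feature_ranking`: `frequency` (named, descending), `top`
#'   (head of the ranking), `n_accepted`, `n_models`.
#' @export
two_step_select <- function(data, features, outcome, repeats = 100L,
                            outer_k = 5L, inner_k = 5L, acc_thresh = 0.8,
                            top_k = 10L, seed = 1L) {
  stopifnot(length(features) >= top_k)
  y <- as.integer(data[[outcome]])
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)

  counts <- setNames(numeric(length(features)), features)
  n_accepted <- 0L
  n_models <- 0L
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(y, outer_k, seed + r * 131L)
    for (f in seq_len(outer_k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
      n_models <- n_models + 1L
      ifold <- .stratified_folds(y[tr], inner_k, seed + r * 131L + f)
      fit <- tryCatch(
        suppressWarnings(
          glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr],
                            family = "binomial", type.measure = "class",
                            nfolds = inner_k, foldid = ifold,
                            standardize = TRUE)),
        error = function(e) NULL)
      if (is.null(fit)) next
      cf <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1L, 1L]
      sel <- names(cf)[cf != 0]
      if (!length(sel)) next
      svm <- tryCatch(svm_rbf(X[tr, sel, drop = FALSE], y[tr]),
                      error = function(e) NULL)
      if (is.null(svm)) next
      acc <- mean(predict(svm, X[!tr, sel, drop = FALSE]) == y[!tr])
      if (acc > acc_thresh) {
        counts[sel] <- counts[sel] + 1
        n_accepted <- n_accepted + 1L
      }
    }
  }
  if (n_accepted == 0L) {
    warning("no model passed the accuracy threshold; empty ranking")
    freq <- counts
  } else {
    freq <- counts / n_accepted
  }
  freq <- sort(freq, decreasing = TRUE)
  structure(list(frequency = freq, top = utils::head(freq, top_k),
                 n_accepted = n_accepted, n_models = n_models,
                 acc_thresh = acc_thresh),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d / %d models accepted (accuracy > %.2f)\n",
              x$n_accepted, x$n_models, x$acc_thresh))
  print(round(x$top, 3))
  invisible(x)
}
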