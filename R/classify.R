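#' Fisher linear discriminant projection
#'
#' Finds the k-dimensional linear projection maximizing the Fisher
#' criterion — the ratio of between-class to within-class scatter — by
#' solving the generalized eigenproblem \code{Sb w = lambda Sw w}.
#' Columns of the projection matrix are the leading eigenvectors of
#' \code{solve(Sw + ridge * I) \%*\% Sb}, normalized to unit length with the
#' sign fixed so the largest-magnitude loading is positive (the
#' deterministic tie-break). A small ridge on the within-class scatter
#' handles near-singular scatter matrices; with \code{ridge = 0} a singular
#' scatter raises an error advising regularization.
#'
#' @param features data.frame or matrix of numeric features (rows =
#'   particles).
#' @param labels class labels, one per row; >= 2 classes, each with more
#'   records than features.
#' @param k number of projected dimensions, at most (number of classes - 1).
#' @param ridge ridge added to the diagonal of the within-class scatter
#'   (relative to its mean diagonal); default 0.
#' @return object of class \code{lda_projection}: list with \code{W}
#'   (features x k projection matrix), \code{centroid}, \code{class_means}
#'   (projected), \code{eigenvalues}.
#' @export
lda_project <- function(features, labels, k = 2L, ridge = 0) {
  X <- as.matrix(features[, vapply(as.data.frame(features), is.numeric,
                                   logical(1)), drop = FALSE])
  labels <- factor(labels)
  g <- nlevels(labels)
  if (g < 2L) stop("need at least 2 classes")
  if (k > g - 1L) stop("k must be <= number of classes - 1 (", g - 1L, ")")
  cnt <- table(labels)
  if (any(cnt < ncol(X) + 1L))
    stop("each class needs at least ", ncol(X) + 1L, " records")
  mu <- colMeans(X)
  Sw <- matrix(0, ncol(X), ncol(X))
  Sb <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(labels)) {
    Xi <- X[labels == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  if (ridge > 0) Sw <- Sw + diag(ridge * mean(diag(Sw)), ncol(X))
  if (rcond(Sw) < .Machine$double.eps * 100)
    stop("within-class scatter is (near) singular; pass ridge > 0 ",
         "to regularize")
  ev <- eigen(solve(Sw, Sb))
  ord <- order(Re(ev$values), decreasing = TRUE)[seq_len(k)]
  W <- Re(ev$vectors[, ord, drop = FALSE])
  for (j in seq_len(ncol(W))) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- colnames(X)
  colnames(W) <- paste0("x", seq_len(k))
  proj <- sweep(X, 2, mu) %*% W
  cm <- apply(proj, 2, function(p) tapply(p, labels, mean))
  structure(list(W = W, centroid = mu,
                 class_means = cm,
                 eigenvalues = Re(ev$values[ord]),
                 projected = data.frame(proj, label = labels)),
            class = "lda_projection")
}

#' Project new feature records with a stored LDA model
#'
#' @param object an \code{lda_projection}.
#' @param newdata feature table with the training columns.
#' @param ... unused.
#' @return matrix of projected coordinates x1..xk.
#' @export
predict.lda_projection <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, rownames(object$W), drop = FALSE])
  sweep(X, 2, object$centroid) %*% object$W
}

#' Row-normalized confusion matrix
#'
#' @param true,predicted label vectors of equal length over the same label
#'   set.
#' @return list with \code{counts} (rows = true class), \code{percent}
#'   (row-normalized, each row summing to 100), and \code{accuracy}
#'   (overall fraction correct).
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  lev <- union(levels(factor(true)), levels(factor(predicted)))
  true <- factor(true, levels = lev)
  predicted <- factor(predicted, levels = lev)
  counts <- table(true = true, predicted = predicted)
  percent <- 100 * prop.table(counts + 0, margin = 1)
  percent[is.nan(percent)] <- 0
  list(counts = counts, percent = percent,
       accuracy = sum(diag(counts)) / sum(counts))
}

#' Train and evaluate an SVM classifier on particle features
#'
#' Stratified train/test split, z-score standardization fitted on the
#' training split only, then a radial-kernel support vector machine with a
#' small grid search over cost and kernel width scored by 5-fold
#' cross-validation on the training split. Reports held-out per-class
#' accuracy and the row-normalized confusion matrix. Deterministic under
#' the seed.
#'
#' @param features feature data.frame (numeric columns used).
#' @param labels class labels.
#' @param feature_set \code{"pol5"} (I, q, u, v, dop) or \code{"pol5+F"}
#'   (adds the fluorescence ratio F); \code{"all"} uses every numeric
#'   column.
#' @param split training fraction (default 0.7, stratified).
#' @param seed integer seed for the split and CV folds.
#' @param cost_grid,gamma_grid hyperparameter grids.
#' @return object of class \code{classifier_report}: per-class accuracy,
#'   confusion matrix (counts and row percent), overall accuracy, chosen
#'   hyperparameters, split description.
#' @export
svm_train_eval <- function(features, labels,
                           feature_set = c("pol5+F", "pol5", "all"),
                           split = 0.7, seed = 1,
                           cost_grid = c(0.1, 1, 10, 100),
                           gamma_grid = c(0.01, 0.1, 1)) {
  feature_set <- match.arg(feature_set)
  cols <- switch(feature_set,
                 "pol5" = c("I", "q", "u", "v", "dop"),
                 "pol5+F" = c("I", "q", "u", "v", "dop", "F"),
                 "all" = names(Filter(is.numeric, as.data.frame(features))))
  X <- as.matrix(as.data.frame(features)[, cols, drop = FALSE])
  y <- factor(labels)
  set.seed(seed)
  tr <- unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    sample(idx, round(split * length(idx)))
  }))
  if (length(unique(y[tr])) < nlevels(y) ||
      length(unique(y[-tr])) < nlevels(y))
    stop("every class must appear in both the training and test split")
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  folds <- sample(rep_len(1:5, length(tr)))
  cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
    accs <- vapply(1:5, function(f) {
      it <- tr[folds != f]; iv <- tr[folds == f]
      fit <- e1071::svm(Z[it, , drop = FALSE], y[it], kernel = "radial",
                        cost = grid$cost[i], gamma = grid$gamma[i],
                        scale = FALSE)
      mean(predict(fit, Z[iv, , drop = FALSE]) == y[iv])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- grid[which.max(cv_acc), ]
  fit <- e1071::svm(Z[tr, , drop = FALSE], y[tr], kernel = "radial",
                    cost = best$cost, gamma = best$gamma, scale = FALSE)
  pred <- predict(fit, Z[-tr, , drop = FALSE])
  cm <- confusion_matrix(y[-tr], pred)
  structure(list(feature_set = feature_set, features = cols,
                 per_class_accuracy = diag(cm$percent) / 100,
                 confusion = cm,
                 accuracy = cm$accuracy,
                 hyperparameters = c(cost = best$cost, gamma = best$gamma,
                                     cv_accuracy = max(cv_acc)),
                 split = sprintf("stratified %.0f/%.0f%%, seed %d",
                                 100 * split, 100 * (1 - split), seed),
                 n_train = length(tr), n_test = length(y) - length(tr),
                 model = fit, scaling = list(mu = mu, sd = sdv)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("SVM classifier report [", x$feature_set, "]  (", x$split, ")\n",
      sep = "")
  cat("  train/test: ", x$n_train, "/", x$n_test, "; kernel RBF, cost ",
      x$hyperparameters[["cost"]], ", gamma ",
      x$hyperparameters[["gamma"]], "\n", sep = "")
  cat("  held-out accuracy:", sprintf("%.1f%%", 100 * x$accuracy), "\n")
  cat("  per-class accuracy (%):\n")
  print(round(100 * x$per_class_accuracy, 1))
  cat("  confusion (row %):\n")
  print(round(x$confusion$percent, 1))
  invisible(x)
}
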