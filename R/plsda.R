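#' Fit a PLS-DA model by NIPALS
#'
#' Multi-class partial least squares discriminant analysis: the class
#' vector is one-hot encoded and column-centered, predictors are
#' zero-variance-filtered and autoscaled (centered, unit SD), and PLS2
#' components are extracted by NIPALS (unit-norm X-weights, score
#' regression loadings, X and Y deflation). Prediction assigns the class
#' with the largest fitted indicator value.
#'
#' @param X Numeric sample x feature matrix without missing values
#'   (complete cases only, the convention for protein classification).
#' @param labels Class vector, length `nrow(X)`, >= 2 classes.
#' @param A Number of components; at most `min(n - 1, rank)`.
#' @return A `plsda_model`: weights `W`, X-loadings `P`, Y-loadings `Q`,
#'   scores `T` (all with `A` columns), preprocessing record, class
#'   levels and per-component regression coefficients.
#' @export
fit_plsda <- function(X, labels, A) {
  if (anyNA(X)) stop("PLS-DA requires complete data (no missing values)", call. = FALSE)
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(table(labels) == 1L)) {
    warning("class with a single sample; stratified CV will degrade around it")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  kept <- colnames(X)[sds > 1e-12]
  if (length(kept) < 1L) stop("no predictor with non-zero variance", call. = FALSE)
  Xk <- X[, kept, drop = FALSE]
  x_center <- colMeans(Xk)
  x_scale <- apply(Xk, 2, stats::sd)
  Xa <- sweep(sweep(Xk, 2, x_center), 2, x_scale, `/`)
  rank <- qr(Xa)$rank
  A_max <- min(nrow(X) - 1L, rank)
  if (A > A_max) stop("A exceeds min(n - 1, rank) = ", A_max, call. = FALSE)
  classes <- levels(labels)
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- classes
  y_center <- colMeans(Y)
  Ya <- sweep(Y, 2, y_center)
  P_dim <- length(kept)
  W <- Pl <- matrix(0, P_dim, A, dimnames = list(kept, NULL))
  Q <- matrix(0, length(classes), A, dimnames = list(classes, NULL))
  Tm <- matrix(0, nrow(X), A)
  for (a in seq_len(A)) {
    u <- Ya[, which.max(apply(Ya, 2, stats::var))]
    t_old <- rep(Inf, nrow(X))
    for (it in seq_len(500L)) {
      w <- drop(crossprod(Xa, u))
      w <- w / sqrt(sum(w^2))
      tt <- drop(Xa %*% w)
      q <- drop(crossprod(Ya, tt)) / sum(tt^2)
      u <- drop(Ya %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < 1e-10) break
      t_old <- tt
    }
    p <- drop(crossprod(Xa, tt)) / sum(tt^2)
    Xa <- Xa - tcrossprod(tt, p)
    Ya <- Ya - tcrossprod(tt, q)
    W[, a] <- w; Pl[, a] <- p; Q[, a] <- q; Tm[, a] <- tt
  }
  structure(list(A = A, W = W, P = Pl, Q = Q, T = Tm,
                 classes = classes, kept = kept,
                 x_center = x_center, x_scale = x_scale, y_center = y_center,
                 labels = labels),
            class = "plsda_model")
}

# Regression coefficients using the first `a` components:
# B_a = W_a (P_a' W_a)^{-1} Q_a'.
plsda_coefficients <- function(model, a = model$A) {
  Wa <- model$W[, seq_len(a), drop = FALSE]
  Pa <- model$P[, seq_len(a), drop = FALSE]
  Qa <- model$Q[, seq_len(a), drop = FALSE]
  Wa %*% solve(crossprod(Pa, Wa)) %*% t(Qa)
}

#' Predict classes (and fitted indicator values) from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Sample x feature matrix containing the model's kept
#'   predictors.
#' @param a Number of components to use (default all fitted).
#' @param ... Unused.
#' @return List with `class` (factor) and `fitted` (matrix of indicator
#'   predictions).
#' @export
predict.plsda_model <- function(object, newdata, a = object$A, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) colnames(newdata) <- paste0("V", seq_len(ncol(newdata)))
  miss <- setdiff(object$kept, colnames(newdata))
  if (length(miss)) stop("newdata lacks predictors: ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  Xs <- sweep(sweep(newdata[, object$kept, drop = FALSE], 2, object$x_center),
              2, object$x_scale, `/`)
  B <- plsda_coefficients(object, a)
  fitted <- Xs %*% B
  fitted <- sweep(fitted, 2, object$y_center, `+`)
  cls <- factor(object$classes[max.col(fitted, ties.method = "first")],
                levels = object$classes)
  list(class = cls, fitted = fitted)
}

#' Stratified repeated k-fold cross-validation with oneSE selection
#'
#' Folds are stratified by class within each repeat; preprocessing
#' (zero-variance removal, autoscaling) is refit inside every training
#' fold, so no information leaks from held-out samples. Accuracy is
#' recorded per (component count, fold, repeat); the oneSE rule selects
#' the smallest component count whose mean accuracy is within one
#' standard error (computed across the best count's fold x repeat
#' accuracies) of the best mean.
#'
#' @param X Complete sample x feature matrix.
#' @param labels Class vector.
#' @param k Number of folds (default 3).
#' @param repeats Number of repeats (15 for the subregion convention,
#'   100 for strata).
#' @param A_grid Candidate component counts (default `1:A_max`).
#' @param A_max Largest candidate when `A_grid` is NULL.
#' @param seed Integer seed; results are deterministic given it.
#' @return A `plsda_cv`: list with `table` (per-A mean accuracy and SE),
#'   `chosen_A`, `best_A`, `accuracies` (A x (fold*repeat) matrix),
#'   `fold_assignments` and `seed`.
#' @export
cross_validate_plsda <- function(X, labels, k = 3L, repeats = 15L,
                                 A_grid = NULL, A_max = 5L, seed = 1L) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (is.null(A_grid)) A_grid <- seq_len(A_max)
  if (!length(A_grid)) stop("empty component grid", call. = FALSE)
  A_grid <- sort(unique(as.integer(A_grid)))
  set.seed(seed)
  acc <- matrix(NA_real_, length(A_grid), k * repeats,
                dimnames = list(paste0("A", A_grid), NULL))
  assignments <- matrix(NA_integer_, nrow(X), repeats)
  col <- 0L
  for (r in seq_len(repeats)) {
    fold <- integer(nrow(X))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    assignments[, r] <- fold
    for (f in seq_len(k)) {
      col <- col + 1L
      train <- fold != f
      test <- !train
      if (!any(test) || nlevels(droplevels(labels[train])) < 2L) next
      Xtr <- X[train, , drop = FALSE]
      A_eff <- min(max(A_grid), sum(train) - 1L)
      fit <- tryCatch(fit_plsda(Xtr, labels[train], A = A_eff),
                      error = function(e) NULL)
      if (is.null(fit)) next
      for (ai in seq_along(A_grid)) {
        a_use <- min(A_grid[ai], fit$A)
        pred <- predict(fit, X[test, , drop = FALSE], a = a_use)$class
        acc[ai, col] <- mean(as.character(pred) == as.character(labels[test]))
      }
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best_i <- which.max(mean_acc)
  best_acc <- acc[best_i, !is.na(acc[best_i, ])]
  se_best <- stats::sd(best_acc) / sqrt(length(best_acc))
  chosen_i <- min(which(mean_acc >= mean_acc[best_i] - se_best))
  tab <- data.frame(A = A_grid, mean_accuracy = unname(mean_acc),
                    se = apply(acc, 1, function(a) {
                      a <- a[!is.na(a)]
                      stats::sd(a) / sqrt(length(a))
                    }))
  structure(list(table = tab, chosen_A = A_grid[chosen_i], best_A = A_grid[best_i],
                 se_best = se_best, accuracies = acc,
                 fold_assignments = assignments, seed = seed),
            class = "plsda_cv")
}

#' Variable Importance in Projection (VIP) scores
#'
#' `VIP_j = sqrt(P * sum_a SSY_a w_aj^2 / sum_a SSY_a)` with
#' `SSY_a = (t_a . t_a)(q_a . q_a)`, the Y-variance captured by
#' component `a`, and `P` the number of retained predictors. The mean of
#' squared VIPs is 1 by construction. The scaled score is
#' `100 * VIP / max(VIP)`.
#'
#' @param model A fitted `plsda_model`.
#' @param scale_0_100 Also return the 0-100 scaled score.
#' @return Data frame `predictor`, `vip` and (optionally) `vip_scaled`,
#'   sorted by decreasing VIP.
#' @export
vip_scores <- function(model, scale_0_100 = TRUE) {
  stopifnot(inherits(model, "plsda_model"))
  ssy <- colSums(model$T^2) * colSums(model$Q^2)
  if (all(ssy <= 0)) stop("degenerate model: no explained Y variance", call. = FALSE)
  P <- nrow(model$W)
  vip <- sqrt(P * drop(model$W^2 %*% ssy) / sum(ssy))
  out <- data.frame(predictor = rownames(model$W), vip = unname(vip),
                    stringsAsFactors = FALSE)
  if (scale_0_100) out$vip_scaled <- 100 * out$vip / max(out$vip)
  out <- out[order(-out$vip, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
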