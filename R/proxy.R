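#' Min-max feature scaling fitted on a training set
#'
#' Maps each feature linearly so that the training samples span `[0, 1]`.
#' The transform is a pure linear map: test values outside the training
#' range are *not* clamped. Constant features map to 0.
#'
#' @param X Training feature matrix.
#' @return An object of class `"scaling_model"` with `min` and `range`.
#' @export
fit_scaling <- function(X) {
  X <- as.matrix(X)
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  rg <- mx - mn
  rg[rg == 0] <- 1            # constant column guard: maps to 0
  structure(list(min = mn, range = rg), class = "scaling_model")
}

#' @rdname fit_scaling
#' @param scaling A fitted `scaling_model`.
#' @export
apply_scaling <- function(X, scaling) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaling$min), 2, scaling$range, "/")
}

#' Fit the proxy drowsiness model (four linear max-margin classifiers)
#'
#' The proxy system represents the standard feature-based approach: one
#' L2-regularized linear hinge-loss classifier per timescale, trained on the
#' 24-dimensional multi-window ocular feature vectors. For each timescale,
#' samples with an indeterminate label (probability 0.5) are discarded, the
#' regularization strength `C` is selected by an inner leave-one-subject-out
#' cross-validation maximizing balanced accuracy, and the final classifier
#' is refit on all training subjects with classes weighted by the reciprocal
#' of their occurrence counts.
#'
#' @param X Feature matrix `n x 24` of the training samples.
#' @param p Matrix `n x 4` of ground-truth probabilities.
#' @param subjects Character vector of length `n`: the subject of each
#'   sample (drives the inner folds).
#' @param C_grid Candidate regularization strengths (default 13 points,
#'   log-spaced over `10^-3 .. 10^3`).
#' @return An object of class `"proxy_model"`: the per-timescale
#'   classifiers, chosen `C`s, and the common [`scaling_model`][fit_scaling].
#' @export
fit_proxy <- function(X, p, subjects, C_grid = 10^seq(-3, 3, length.out = 13)) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(p), nrow(X) == length(subjects))
  if (length(unique(subjects)) < 2)
    stop("inner cross-validation needs at least 2 training subjects")
  scaling <- fit_scaling(X)
  Xs <- apply_scaling(X, scaling)
  classifiers <- vector("list", 4)
  chosen_C <- numeric(4)
  for (i in 1:4) {
    keep <- filter_definite(p[, i])
    if (length(unique(p[keep, i])) < 2)
      stop("training set has a single class at timescale ", i)
    Xi <- Xs[keep, , drop = FALSE]
    yi <- factor(p[keep, i], levels = c(0, 1))
    si <- subjects[keep]
    chosen_C[i] <- select_C(Xi, yi, si, C_grid)
    classifiers[[i]] <- fit_linear_svm(Xi, yi, chosen_C[i])
  }
  structure(list(classifiers = classifiers, C = chosen_C, scaling = scaling),
            class = "proxy_model")
}

# class weights: reciprocal of the class occurrence counts
class_weights_recip <- function(y) {
  cw <- 1 / table(y)
  stats::setNames(as.numeric(cw), names(cw))
}

fit_linear_svm <- function(X, y, C) {
  e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE,
             class.weights = class_weights_recip(y))
}

# inner leave-one-subject-out selection of C by pooled balanced accuracy
select_C <- function(X, y, subjects, C_grid) {
  us <- unique(subjects)
  best_C <- C_grid[1]; best_ba <- -Inf
  for (C in C_grid) {
    pred <- rep(NA_character_, length(y))
    for (s in us) {
      ho <- subjects == s
      if (length(unique(y[!ho])) < 2) next
      fit <- tryCatch(fit_linear_svm(X[!ho, , drop = FALSE], y[!ho], C),
                      error = function(e) NULL)
      if (is.null(fit)) next
      pred[ho] <- as.character(predict(fit, X[ho, , drop = FALSE]))
    }
    ok <- !is.na(pred)
    if (!any(ok)) next
    tpr <- mean(pred[ok & y == "1"] == "1")
    tnr <- mean(pred[ok & y == "0"] == "0")
    ba <- (tpr + tnr) / 2
    if (is.finite(ba) && ba > best_ba) { best_ba <- ba; best_C <- C }
  }
  best_C
}

#' Predict binary drowsiness decisions with the proxy model
#'
#' @param model A [`proxy_model`][fit_proxy].
#' @param X Feature matrix `n x 24` (raw scale; the stored training scaling
#'   is applied).
#' @return Matrix `n x 4` of binary decisions (0 = alert, 1 = drowsy).
#' @export
predict_proxy <- function(model, X) {
  Xs <- apply_scaling(as.matrix(X), model$scaling)
  out <- vapply(1:4, function(i)
    as.numeric(as.character(predict(model$classifiers[[i]], Xs))),
    numeric(nrow(Xs)))
  colnames(out) <- paste0("d", 1:4)
  out
}
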