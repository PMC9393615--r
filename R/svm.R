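#' Train the linear maximum-margin classifier
#'
#' Soft-margin linear SVM (libsvm via e1071) with box constraint `C`
#' (default 1, no hyperparameter search) on the binary RT/ST problem.
#' Standardization is a model property: when `standardize = TRUE` the
#' per-feature mean/scale are learned from the training rows only and
#' re-applied at prediction. The decision rule is `sign(w.x + b)` with the
#' positive class (RT) on the non-negative side, so a point exactly on the
#' boundary is assigned positive.
#'
#' @param data Data frame holding the label column and feature columns.
#' @param label Name of the label column (default `"group"`); must contain
#'   exactly the two classes.
#' @param feature_names Feature columns; defaults to registry indices
#'   present in `data`.
#' @param standardize Standardize features inside the model?
#' @param C Box constraint.
#' @param positive Positive class label (default `"RT"`).
#' @return An object of class `linear_svm`.
#' @export
train_svm <- function(data, label = "group",
                      feature_names = intersect(spectral_index_registry()$name,
                                                names(data)),
                      standardize = TRUE, C = 1, positive = "RT") {
  y <- as.character(data[[label]])
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("training data must contain exactly two classes")
  }
  if (!positive %in% classes) stop("positive class absent from training data")
  negative <- setdiff(classes, positive)
  X <- as.matrix(as.data.frame(data)[, feature_names, drop = FALSE])
  if (!all(is.finite(X))) stop("features must be finite; drop flagged rows")
  yf <- factor(y, levels = c(positive, negative))
  fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = C,
                    scale = standardize, type = "C-classification")
  structure(list(fit = fit, feature_names = feature_names,
                 positive = positive, negative = negative,
                 standardize = standardize, C = C),
            class = "linear_svm")
}

# labels from decision values for a given orientation: the decision-value
# column is named "<first>/<second>" with positive values meaning <first>
labels_from_decision <- function(dv, first, second) {
  ifelse(dv >= 0, first, second)
}

#' Predict with a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Data frame or matrix with the model's feature columns.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  if (ncol(X) != length(object$feature_names) &&
      !is.null(colnames(X)) && all(object$feature_names %in% colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  pred <- predict(object$fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  pair <- strsplit(colnames(dv)[1], "/")[[1]]
  unname(labels_from_decision(as.numeric(dv[, 1]), pair[1], pair[2]))
}

#' Tidy a linear SVM: per-feature weights of the separating hyperplane
#'
#' Weights are in the model's internal (possibly standardized) feature
#' space.
#'
#' @param x A `linear_svm`.
#' @param ... Unused.
#' @return Tibble with `feature` and `weight`, plus an `intercept` row.
#' @export
tidy.linear_svm <- function(x, ...) {
  w <- drop(t(x$fit$coefs) %*% x$fit$SV)
  tibble::tibble(feature = c(x$feature_names, "(intercept)"),
                 weight = c(w, -x$fit$rho))
}

#' Glance at a linear SVM
#'
#' @param x A `linear_svm`.
#' @param ... Unused.
#' @return One-row tibble: `n_support`, `C`, `standardize`, `positive`.
#' @export
glance.linear_svm <- function(x, ...) {
  tibble::tibble(n_support = nrow(x$fit$SV), C = x$C,
                 standardize = x$standardize, positive = x$positive)
}
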