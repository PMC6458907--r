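#' Fit a linear soft-margin support-vector classifier
#'
#' Solves the standard C-SVC dual (hinge loss, regularization constant
#' `cost`, unregularized bias) by sequential minimal optimization and returns
#' the primal weight vector. This is the classifier behind all decoding
#' functions in the package; for a linear kernel the weight vector
#' `w = sum_i alpha_i y_i x_i` is exactly the per-voxel sensitivity pattern.
#'
#' @param x numeric matrix, samples in rows, features (voxels) in columns.
#' @param y class labels: a factor, character or numeric vector with exactly
#'   two distinct values. The `positive` class is coded +1.
#' @param cost soft-margin regularization constant C (default 1).
#' @param positive which label is coded +1; defaults to the first level
#'   (factor input) or the first distinct value encountered.
#' @param eps KKT violation tolerance for the dual solver.
#' @param max_iter maximum SMO pair updates before aborting.
#' @param gram optional precomputed Gram matrix `tcrossprod(x)`; supplying it
#'   avoids recomputation across many refits on the same samples.
#' @return an object of class `"linear_svm"`: list with elements `w` (weight
#'   vector), `b` (intercept), `alpha`, `levels` (c(positive, negative)),
#'   `cost`, `converged`.
#' @examples
#' x <- rbind(matrix(rnorm(20, 2), 10), matrix(rnorm(20, -2), 10))
#' y <- rep(c("a", "b"), each = 10)
#' fit <- linear_svm(x, y)
#' mean(predict(fit, x) == y)
#' @export
linear_svm <- function(x, y, cost = 1, positive = NULL,
                       eps = 1e-8, max_iter = 100000L, gram = NULL) {
  x <- as.matrix(x)
  labs <- if (is.factor(y)) as.character(y) else as.character(y)
  u <- if (is.factor(y)) intersect(levels(y), unique(labs)) else unique(labs)
  if (length(u) != 2L)
    stop("training data must contain exactly two classes, got: ",
         paste(u, collapse = ", "))
  if (is.null(positive)) positive <- u[1L]
  if (!positive %in% u) stop("'positive' is not a training label")
  negative <- setdiff(u, positive)
  yy <- ifelse(labs == positive, 1, -1)
  if (!is.finite(cost) || cost <= 0) stop("'cost' must be positive")
  if (is.null(gram)) gram <- tcrossprod(x)
  sol <- svm_smo_cpp(gram, yy, cost, eps, as.integer(max_iter))
  if (!sol$converged)
    warning("SMO did not reach tolerance within max_iter; results approximate")
  w <- as.numeric(crossprod(x, sol$alpha * yy))
  structure(list(w = w, b = sol$b, alpha = sol$alpha,
                 levels = c(positive, negative), cost = cost,
                 converged = sol$converged),
            class = "linear_svm")
}

#' @param object,newdata,... standard predict-method arguments; `newdata` is a
#'   matrix with the same feature ordering as the training data.
#' @param decision return the real-valued decision values instead of labels.
#' @rdname linear_svm
#' @export
predict.linear_svm <- function(object, newdata, decision = FALSE, ...) {
  f <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  if (decision) return(f)
  ifelse(f >= 0, object$levels[1L], object$levels[2L])
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear soft-margin SVM: ", length(x$w), " features, C = ", x$cost,
      ", positive class = ", x$levels[1L], "\n", sep = "")
  invisible(x)
}
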