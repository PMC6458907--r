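resolve_class_col <- function(set, class_col) {
  if (!is.null(class_col)) return(class_col)
  if ("class" %in% names(set$meta)) "class" else "modality"
}

resolve_positive <- function(labels, positive) {
  u <- unique(labels)
  if (length(u) != 2) stop("classification needs exactly two classes, got: ",
                           paste(u, collapse = ", "))
  if (is.null(positive)) positive <- if ("pain" %in% u) "pain" else u[1]
  if (!positive %in% u) stop("'positive' class not present")
  positive
}

perm_labels <- function(y, scheme) {
  if (scheme == "exchange") sample(y) else sample(c(-1, 1), length(y),
                                                  replace = TRUE)
}

# p-value conventions for permutation nulls: proportion of null >= observed,
# reported as the resolution bound 1/n_perm (flagged) when the count is zero;
# or the (k+1)/(n+1) estimator
perm_pvalue <- function(null, observed, estimator = c("floor", "plus_one")) {
  estimator <- match.arg(estimator)
  n_perm <- length(null)
  k <- sum(null >= observed - 1e-12)
  if (estimator == "plus_one") return(list(p = (k + 1) / (n_perm + 1),
                                           floored = FALSE))
  if (k == 0) list(p = 1 / n_perm, floored = TRUE)
  else list(p = k / n_perm, floored = FALSE)
}

#' Leave-one-subject-out linear SVM classification
#'
#' The package's core decoding routine: for each of the N subjects, a linear
#' soft-margin SVM is trained on the samples of the other N - 1 subjects and
#' tested on the held-out subject; fold accuracy is the fraction of correct
#' guesses on the held-out samples and the overall accuracy is the mean over
#' folds. Because each fold generalizes to an unseen person, a successful
#' classification demonstrates a between-subject, spatially consistent
#' activity pattern.
#'
#' When `n_perm > 0`, a permutation null is built: per permutation the
#' training labels within each fold are randomly exchanged (class counts
#' preserved; the held-out test labels are untouched), the classifier is
#' retrained and the fold accuracies re-averaged, yielding one null accuracy
#' per permutation. The p-value is the proportion of null accuracies greater
#' than or equal to the observed one; when none reaches it the value is
#' reported as the resolution bound 1/n_perm with `p_floored = TRUE`
#' (printed as "< 1/n_perm").
#'
#' @param set a [sample_set()] with metadata columns `subject` and a binary
#'   class column; every subject should contribute the same number of
#'   samples per class.
#' @param cost SVM regularization constant C.
#' @param n_perm permutations for the null distribution (0 = skip).
#' @param seed RNG seed for the permutations.
#' @param class_col metadata column holding the class labels (default
#'   `"class"` if present, else `"modality"`).
#' @param positive label coded +1; positive weights then mean higher signal
#'   for that class (default `"pain"` when present).
#' @param perm_scheme `"exchange"` (permute the existing labels, preserving
#'   class counts) or `"bernoulli"` (unrestricted random relabeling).
#' @param p_estimator `"floor"` reports k/n_perm floored at 1/n_perm;
#'   `"plus_one"` reports (k+1)/(n_perm+1).
#' @return object of class `"pp_classification"`: list with `accuracy`,
#'   `fold_accuracy`, `weights` (folds x voxels), `bias`, `sensitivity`
#'   (mean fold weight vector), `null`, `p`, `p_floored`, `n_perm`,
#'   `positive`, `levels`, `mask`, `type = "loso"`.
#' @export
loso_classify <- function(set, cost = 1, n_perm = 0L, seed = NULL,
                          class_col = NULL, positive = NULL,
                          perm_scheme = c("exchange", "bernoulli"),
                          p_estimator = c("floor", "plus_one")) {
  perm_scheme <- match.arg(perm_scheme)
  p_estimator <- match.arg(p_estimator)
  class_col <- resolve_class_col(set, class_col)
  if (!"subject" %in% names(set$meta)) stop("metadata lacks a 'subject' column")
  labels <- as.character(set$meta[[class_col]])
  positive <- resolve_positive(labels, positive)
  negative <- setdiff(unique(labels), positive)
  y <- ifelse(labels == positive, 1, -1)
  subjects <- unique(set$meta$subject)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  if (length(subjects) < 3)
    warning("only ", length(subjects),
            " subjects: leave-one-subject-out estimates will be unstable")
  per_subj <- table(set$meta$subject, labels)
  if (length(unique(as.vector(per_subj))) != 1)
    warning("subjects contribute unequal samples per class; ",
            "fold accuracies are per-sample within each held-out subject")
  x <- set$x
  gram <- tcrossprod(x)
  folds <- lapply(subjects, function(s) which(set$meta$subject == s))
  fold_fit <- function(tr, yt) {
    if (length(unique(yt)) < 2)
      stop("training data contains a single class in a fold")
    svm_smo_cpp(gram[tr, tr, drop = FALSE], yt, cost, 1e-8, 100000L)
  }
  fold_acc <- numeric(length(folds))
  W <- matrix(0, length(folds), ncol(x))
  bias <- numeric(length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]; tr <- setdiff(seq_len(nrow(x)), te)
    sol <- fold_fit(tr, y[tr])
    av <- sol$alpha * y[tr]
    dec <- gram[te, tr, drop = FALSE] %*% av + sol$b
    fold_acc[f] <- mean((dec >= 0) == (y[te] > 0))
    W[f, ] <- as.numeric(crossprod(x[tr, , drop = FALSE], av))
    bias[f] <- sol$b
  }
  accuracy <- mean(fold_acc)
  null <- p <- NULL; p_floored <- FALSE
  if (n_perm > 0) {
    null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(pp) {
        accs <- vapply(seq_along(folds), function(f) {
          te <- folds[[f]]; tr <- setdiff(seq_len(nrow(x)), te)
          yp <- perm_labels(y[tr], perm_scheme)
          if (length(unique(yp)) < 2) return(0.5)
          sol <- fold_fit(tr, yp)
          dec <- gram[te, tr, drop = FALSE] %*% (sol$alpha * yp) + sol$b
          mean((dec >= 0) == (y[te] > 0))
        }, numeric(1))
        mean(accs)
      }, numeric(1))
    })
    pv <- perm_pvalue(null, accuracy, p_estimator)
    p <- pv$p; p_floored <- pv$floored
  }
  structure(list(type = "loso", accuracy = accuracy,
                 fold_accuracy = stats::setNames(fold_acc, subjects),
                 weights = W, bias = bias, sensitivity = colMeans(W),
                 null = null, p = p, p_floored = p_floored,
                 n_perm = as.integer(n_perm), cost = cost,
                 positive = positive, levels = c(positive, negative),
                 mask = set$mask, n_samples = nrow(x)),
            class = "pp_classification")
}

#' Train on one dataset, test on another
#'
#' Cross-dataset generalization: a single linear SVM is trained on every
#' sample of `train` and evaluated on every sample of `test`, which must
#' come from a mask with identical voxel ordering. Because the two datasets
#' differ in scanner, design and signal scale, both sets are required to be
#' ROI-normalized ([roi_normalize()]); un-normalized inputs are rejected.
#' The permutation null retrains on label-permuted training data, keeping
#' the test labels fixed.
#'
#' @param train,test ROI-normalized [sample_set()]s with the same voxel
#'   count and a common binary class column.
#' @inheritParams loso_classify
#' @return `"pp_classification"` object with `type = "cross_dataset"`.
#' @export
cross_dataset_classify <- function(train, test, cost = 1, n_perm = 0L,
                                   seed = NULL, class_col = NULL,
                                   positive = NULL,
                                   perm_scheme = c("exchange", "bernoulli"),
                                   p_estimator = c("floor", "plus_one")) {
  perm_scheme <- match.arg(perm_scheme)
  p_estimator <- match.arg(p_estimator)
  if (!train$normalized || !test$normalized)
    stop("cross-dataset classification requires ROI-normalized samples ",
         "(run roi_normalize() on both sets)")
  if (ncol(train$x) != ncol(test$x))
    stop("train and test have different voxel counts")
  class_col <- resolve_class_col(train, class_col)
  lab_tr <- as.character(train$meta[[class_col]])
  lab_te <- as.character(test$meta[[resolve_class_col(test, class_col)]])
  positive <- resolve_positive(lab_tr, positive)
  negative <- setdiff(unique(lab_tr), positive)
  ytr <- ifelse(lab_tr == positive, 1, -1)
  yte <- ifelse(lab_te == positive, 1, -1)
  K <- tcrossprod(train$x)
  Kx <- test$x %*% t(train$x)
  fit1 <- function(yy) svm_smo_cpp(K, yy, cost, 1e-8, 200000L)
  sol <- fit1(ytr)
  av <- sol$alpha * ytr
  accuracy <- mean(((Kx %*% av + sol$b) >= 0) == (yte > 0))
  w <- as.numeric(crossprod(train$x, av))
  null <- p <- NULL; p_floored <- FALSE
  if (n_perm > 0) {
    null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(pp) {
        yp <- perm_labels(ytr, perm_scheme)
        if (length(unique(yp)) < 2) return(0.5)
        s2 <- fit1(yp)
        mean(((Kx %*% (s2$alpha * yp) + s2$b) >= 0) == (yte > 0))
      }, numeric(1))
    })
    pv <- perm_pvalue(null, accuracy, p_estimator)
    p <- pv$p; p_floored <- pv$floored
  }
  structure(list(type = "cross_dataset", accuracy = accuracy,
                 fold_accuracy = stats::setNames(accuracy, "all"),
                 weights = matrix(w, 1), bias = sol$b, sensitivity = w,
                 null = null, p = p, p_floored = p_floored,
                 n_perm = as.integer(n_perm), cost = cost,
                 positive = positive, levels = c(positive, negative),
                 mask = train$mask, n_samples = nrow(train$x)),
            class = "pp_classification")
}

format_p <- function(x) {
  if (is.null(x$p)) return("not computed")
  if (x$p_floored) sprintf("< %.4g (0 of %d permutations)", 1 / x$n_perm,
                           x$n_perm)
  else sprintf("= %.4g", x$p)
}

#' @export
print.pp_classification <- function(x, ...) {
  cat(if (x$type == "loso") "Leave-one-subject-out" else "Cross-dataset",
      " linear SVM classification (", x$levels[1], " [+] vs ", x$levels[2],
      " [-])\n", sep = "")
  cat(sprintf("  accuracy (correct rate) = %.3f over %d samples\n",
              x$accuracy, x$n_samples))
  if (!is.null(x$p))
    cat("  permutation p ", format_p(x), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pp_classification <- function(object, ...) {
  print(object)
  cat("  fold accuracies:\n")
  print(round(object$fold_accuracy, 3))
  if (!is.null(object$null))
    cat(sprintf("  null accuracy: mean %.3f, 95%% of null <= %.3f\n",
                mean(object$null), quantile(object$null, 0.95)))
  invisible(object)
}

#' @export
coef.pp_classification <- function(object, ...) object$sensitivity

#' Plot the permutation null against the observed accuracy
#'
#' @param x a `pp_classification` with a computed null.
#' @param ... passed to [graphics::hist()].
#' @export
plot.pp_classification <- function(x, ...) {
  if (is.null(x$null)) stop("no permutation null computed (n_perm = 0)")
  graphics::hist(x$null, breaks = 30, col = "grey80", border = "white",
                 main = sprintf("Null distribution (n = %d), p %s",
                                x$n_perm, format_p(x)),
                 xlab = "classification accuracy",
                 xlim = range(c(x$null, x$accuracy, 0.5)), ...)
  graphics::abline(v = x$accuracy, lwd = 2)
  graphics::abline(v = 0.5, lty = 2)
  invisible(x)
}

#' Sensitivity map of a linear classification
#'
#' The per-voxel linear SVM weight, averaged over the cross-validation folds
#' and mapped back to the ROI voxels. A positive weight marks a voxel whose
#' signal is higher for the positive class (pain, by convention), negative
#' the converse.
#'
#' @param result a `pp_classification`.
#' @param mask `vol_mask` fixing the voxel ordering (default: the mask
#'   stored with the result).
#' @return object of class `"sensitivity_map"`: list with `values` (one
#'   weight per ROI voxel), `mask`, `positive`.
#' @export
sensitivity_map <- function(result, mask = NULL) {
  if (is.null(mask)) mask <- result$mask
  if (!is.null(mask) && mask_count(mask) != length(result$sensitivity))
    stop("mask voxel count does not match the weight vector length")
  structure(list(values = result$sensitivity, mask = mask,
                 positive = result$positive),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat("Sensitivity map over ", length(x$values), " voxels (positive = ",
      x$positive %||% "first class", "); ", sum(x$values > 0),
      " positive-weight voxels\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a sensitivity map into a 3D volume
#'
#' @param map a `sensitivity_map` with a mask.
#' @return 3D array on the mask grid, zero outside the ROI.
#' @export
as_volume <- function(map) {
  if (is.null(map$mask)) stop("sensitivity map carries no mask")
  out <- array(0, dim(map$mask$data))
  out[which(map$mask$data)] <- map$values
  out
}

#' Voxels with a consistent weight sign across classifications
#'
#' Keeps the voxels whose weight has the same (strict) sign in every input
#' map — e.g. voxels preferring pain in all two-way classifications — with
#' the across-map average weight; all other voxels are zeroed.
#'
#' @param maps list of >= 2 `sensitivity_map`s (or plain numeric vectors of
#'   equal length) on the same mask.
#' @return `sensitivity_map` whose support is the consistent-sign set.
#' @export
consistent_sign_map <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 maps")
  vals <- lapply(maps, function(m) if (inherits(m, "sensitivity_map")) m$values
                 else as.numeric(m))
  p <- unique(lengths(vals))
  if (length(p) != 1) stop("maps have different lengths")
  M <- do.call(rbind, vals)
  consistent <- apply(M > 0, 2, all) | apply(M < 0, 2, all)
  avg <- colMeans(M)
  avg[!consistent] <- 0
  mask <- if (inherits(maps[[1]], "sensitivity_map")) maps[[1]]$mask else NULL
  structure(list(values = avg, mask = mask,
                 positive = if (inherits(maps[[1]], "sensitivity_map"))
                   maps[[1]]$positive else NULL),
            class = "sensitivity_map")
}

#' Median-split class construction from pooled ratings
#'
#' Pools all samples, sorts them by rating regardless of modality, and
#' assigns samples strictly above the pooled median to the "high" class and
#' the rest (ties included) to "low". Per-modality class counts are recorded
#' so imbalance can be repaired by [balance_classes_by_modality()].
#'
#' @param set a `sample_set` whose metadata has a numeric rating column.
#' @param rating_col name of the rating column (default `"rating"`).
#' @return the set with a `class` metadata column (`"high"`/`"low"`) and an
#'   attribute `"modality_counts"` (table modality x class).
#' @export
median_split_classes <- function(set, rating_col = "rating") {
  r <- set$meta[[rating_col]]
  if (is.null(r)) stop("metadata lacks rating column '", rating_col, "'")
  if (length(unique(r)) < 2)
    stop("all ratings identical: median split is degenerate")
  med <- median(r)
  set$meta$class <- ifelse(r > med, "high", "low")
  if ("modality" %in% names(set$meta))
    attr(set, "modality_counts") <- table(set$meta$modality, set$meta$class)
  set
}

#' Collapse trial-level high/low samples to subject x modality averages
#'
#' After a trial-level median split, subjects whose trials all fell into a
#' single class carry no within-subject contrast and are discarded (with a
#' message); remaining trials are averaged per subject x modality x class,
#' yielding equally many samples per class (subjects x modalities each).
#'
#' @param set a trial-level `sample_set` with metadata `subject`, `modality`,
#'   `class`.
#' @return averaged `sample_set`.
#' @export
collapse_high_low <- function(set) {
  need <- c("subject", "modality", "class")
  if (!all(need %in% names(set$meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  by_subj <- tapply(set$meta$class, set$meta$subject,
                    function(cl) length(unique(cl)))
  bad <- names(by_subj)[by_subj < 2]
  if (length(bad) > 0) {
    message("discarding ", length(bad),
            " subject(s) contributing to only one class: ",
            paste(bad, collapse = ", "))
    set <- subset_samples(set, !set$meta$subject %in% bad)
  }
  average_samples(set, by = c("subject", "modality", "class"))
}

#' Balance high/low class counts within each modality
#'
#' For every modality, retains min(high, low) samples per class by removing
#' from the larger class the samples closest to the median boundary: the
#' lowest-rated samples of the "high" class, the highest-rated samples of
#' the "low" class. A modality present in only one class is dropped entirely
#' with a warning. Removal is deterministic (rating, then original order,
#' break ties).
#'
#' @param set a `sample_set` with metadata `modality`, `class` and a rating
#'   column.
#' @param rating_col rating column name.
#' @return balanced `sample_set` with attribute `"removed"` (count removed
#'   per modality x class).
#' @export
balance_classes_by_modality <- function(set, rating_col = "rating") {
  m <- set$meta
  if (!all(c("modality", "class") %in% names(m)))
    stop("metadata must have 'modality' and 'class' columns")
  r <- m[[rating_col]]
  if (is.null(r)) stop("metadata lacks rating column '", rating_col, "'")
  keep <- rep(TRUE, nrow(m))
  removed <- list()
  for (mod in unique(m$modality)) {
    hi <- which(m$modality == mod & m$class == "high")
    lo <- which(m$modality == mod & m$class == "low")
    if (length(hi) == 0 || length(lo) == 0) {
      warning("modality '", mod, "' present in only one class; dropped")
      keep[c(hi, lo)] <- FALSE
      next
    }
    k <- min(length(hi), length(lo))
    if (length(hi) > k) {
      drop <- hi[order(r[hi], hi)][seq_len(length(hi) - k)]
      keep[drop] <- FALSE
      removed[[paste0(mod, ".high")]] <- length(drop)
    }
    if (length(lo) > k) {
      drop <- lo[order(-r[lo], lo)][seq_len(length(lo) - k)]
      keep[drop] <- FALSE
      removed[[paste0(mod, ".low")]] <- length(drop)
    }
  }
  out <- subset_samples(set, keep)
  attr(out, "removed") <- unlist(removed)
  out
}
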