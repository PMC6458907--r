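#' Mean signal of one sample over an ROI
#'
#' @param set a `sample_set` (rows are samples over the set's mask voxels).
#' @param roi `vol_mask`; must intersect the set's mask.
#' @return numeric vector, one ROI-mean per sample.
#' @export
roi_mean_signal <- function(set, roi) {
  if (is.null(set$mask)) stop("sample set carries no mask")
  check_grid(set$mask, roi)
  vox <- which(set$mask$data)
  keep <- which(roi$data[vox])
  if (length(keep) == 0) stop("ROI does not intersect the sample mask")
  rowMeans(set$x[, keep, drop = FALSE])
}

#' ROI-family paired comparison with max-statistic permutation correction
#'
#' For each ROI of a family (10 in the canonical analysis), compares two
#' conditions' per-subject ROI means with a paired t-test, then controls the
#' family-wise error non-parametrically: under the null the sign of each
#' subject's difference vector is exchangeable, so the null distribution of
#' the maximum |t| over the family is built from random (exhaustive when
#' feasible) sign flips applied jointly across ROIs. The corrected p of an
#' ROI is the proportion of flips whose max |t| reaches that ROI's observed
#' |t|; the uncorrected permutation p uses the ROI's own flip distribution,
#' so corrected >= uncorrected always holds. ROIs with zero-variance
#' differences are flagged and excluded from the max statistic.
#'
#' @param cond_a,cond_b numeric matrices, subjects x ROIs, of per-subject
#'   ROI mean signals under each condition.
#' @param n_perm number of sign-flip permutations (default 5000). When
#'   `2^n_subjects <= n_perm` all flips are enumerated instead.
#' @param seed RNG seed for the flips.
#' @return object of class `"roi_family_test"`: data frame `table` with per
#'   ROI `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `df`, `p_param`,
#'   `p_uncorrected`, `p_corrected`, `degenerate`; plus fields `n_perm`,
#'   `exhaustive`, `scheme`.
#' @export
roi_family_test <- function(cond_a, cond_b, n_perm = 5000L, seed = NULL) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  stopifnot(all(dim(cond_a) == dim(cond_b)))
  ns <- nrow(cond_a); nr <- ncol(cond_a)
  if (ns < 2) stop("need >= 2 subjects")
  D <- cond_a - cond_b
  tvec <- function(M) {
    mu <- colMeans(M)
    s <- apply(M, 2, sd)
    ifelse(s > 0, mu / (s / sqrt(ns)), NA_real_)
  }
  t_obs <- tvec(D)
  degenerate <- !is.finite(t_obs)
  exhaustive <- 2^ns <= n_perm
  flips <- with_seed(seed, {
    if (exhaustive) {
      f <- as.matrix(expand.grid(rep(list(c(1, -1)), ns)))
      storage.mode(f) <- "double"
      f
    } else matrix(sample(c(1, -1), ns * n_perm, replace = TRUE), n_perm, ns)
  })
  np <- nrow(flips)
  t_null <- matrix(NA_real_, np, nr)
  for (p in seq_len(np)) t_null[p, ] <- tvec(D * flips[p, ])
  amax <- apply(abs(t_null[, !degenerate, drop = FALSE]), 1,
                function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  p_unc <- p_cor <- rep(NA_real_, nr)
  for (j in which(!degenerate)) {
    p_unc[j] <- mean(abs(t_null[, j]) >= abs(t_obs[j]) - 1e-12, na.rm = TRUE)
    p_cor[j] <- mean(amax >= abs(t_obs[j]) - 1e-12, na.rm = TRUE)
  }
  roi_names <- colnames(cond_a)
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(nr))
  tab <- data.frame(
    roi = roi_names,
    mean_a = colMeans(cond_a), sd_a = apply(cond_a, 2, sd),
    mean_b = colMeans(cond_b), sd_b = apply(cond_b, 2, sd),
    t = t_obs, df = ns - 1,
    p_param = 2 * pt(-abs(t_obs), df = ns - 1),
    p_uncorrected = p_unc, p_corrected = p_cor,
    degenerate = degenerate, row.names = NULL)
  structure(list(table = tab, n_perm = np, exhaustive = exhaustive,
                 scheme = "max-|t| over family, subject sign flips"),
            class = "roi_family_test")
}

#' @export
print.roi_family_test <- function(x, ...) {
  cat("ROI-family paired comparison (", x$scheme, "; ",
      x$n_perm, if (x$exhaustive) " exhaustive" else " random",
      " permutations)\n", sep = "")
  print(x$table[, c("roi", "t", "p_param", "p_corrected")], digits = 3)
  invisible(x)
}
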