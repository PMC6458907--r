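#' First-level GLM beta maps
#'
#' Fits, per voxel, an ordinary-least-squares GLM whose design holds one
#' HRF-convolved stick regressor per condition, the temporal derivative of
#' each, the 6 motion columns, an intercept and a linear drift term. Slow
#' signal drift is absorbed by the intercept + drift columns (standing in
#' for a high-pass filter). Returns one beta map per condition, i.e. the
#' evoked amplitude in signal units.
#'
#' @param series a [vol_series()].
#' @param events event data frame with `onset` and a condition column.
#' @param motion 6-column motion table (or NULL to omit).
#' @param mask optional `vol_mask`; betas are returned for mask voxels only
#'   (default: whole grid).
#' @param condition metadata column defining the conditions (default
#'   `"modality"`).
#' @param hrf function(t_seconds) giving the impulse response (default
#'   [hrf_double_gamma()]).
#' @return `sample_set` with one row per condition (metadata column
#'   `condition`), plus attribute `"design"` holding the design matrix.
#' @export
glm_betas <- function(series, events, motion = NULL, mask = NULL,
                      condition = "modality", hrf = hrf_double_gamma) {
  n <- n_volumes(series)
  tr <- series$tr
  conds <- unique(events[[condition]])
  kern <- hrf(seq(0, 32, by = tr))
  regs <- lapply(conds, function(cc) {
    sticks <- numeric(n)
    v <- floor(events$onset[events[[condition]] == cc] / tr) + 1L
    v <- v[v >= 1 & v <= n]
    sticks[v] <- sticks[v] + 1
    convolve_sticks(sticks, kern)
  })
  derivs <- lapply(regs, function(r) c(0, diff(r)) / tr)
  D <- cbind(do.call(cbind, regs), do.call(cbind, derivs))
  colnames(D) <- c(paste0("cond_", conds), paste0("deriv_", conds))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n) stop("motion rows must equal n_volumes")
    colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
    D <- cbind(D, motion)
  }
  D <- cbind(D, intercept = 1, drift = seq_len(n) - (n + 1) / 2)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  vox <- if (is.null(mask)) seq_len(prod(dim(series$data)[1:3]))
         else which(mask$data)
  X <- as_vxt(series)[vox, , drop = FALSE]
  B <- qr.coef(qrD, t(X))          # coefficients x voxels
  betas <- matrix(B[seq_along(conds), , drop = FALSE],
                  nrow = length(conds), ncol = length(vox))
  out <- sample_set(betas, data.frame(condition = conds), mask = mask)
  attr(out, "design") <- D
  out
}

#' Trial-averaged BOLD time courses in an ROI
#'
#' For every condition, extracts the ROI-mean signal at each volume from
#' `window[1]` to `window[2]` TRs relative to each stimulus onset volume,
#' then averages (and takes the sd) across trials. A window of c(-1, 5) at
#' TR 3 s spans 18 s in 7 points; c(-1, 15) at TR 0.8 s spans 12.8 s in 17
#' points. Events whose window leaves the run are excluded; if none remain
#' an error is raised.
#'
#' @param series a [vol_series()].
#' @param events event data frame (`onset` + condition column).
#' @param roi `vol_mask` on the series grid.
#' @param window integer range in TRs relative to onset, default `c(-1, 5)`.
#' @param condition metadata column defining the conditions.
#' @return data frame with columns `condition`, `rel_vol`, `time_s`, `mean`,
#'   `sd`, `n_trials`.
#' @export
extract_timecourses <- function(series, events, roi, window = c(-1L, 5L),
                                condition = "modality") {
  n <- n_volumes(series)
  tr <- series$tr
  rel <- seq.int(window[1], window[2])
  vox <- which(roi$data)
  roi_mean <- colMeans(as_vxt(series)[vox, , drop = FALSE])
  out <- list()
  for (cc in unique(events[[condition]])) {
    on <- events$onset[events[[condition]] == cc]
    v0 <- floor(on / tr) + 1L
    ok <- v0 + window[1] >= 1L & v0 + window[2] <= n
    if (!any(ok)) next
    courses <- vapply(v0[ok], function(v) roi_mean[v + rel], numeric(length(rel)))
    out[[length(out) + 1L]] <- data.frame(
      condition = cc, rel_vol = rel, time_s = rel * tr,
      mean = rowMeans(courses),
      sd = apply(courses, 1, sd),
      n_trials = sum(ok))
  }
  if (length(out) == 0) stop("no event has its full window inside the run")
  do.call(rbind, out)
}
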