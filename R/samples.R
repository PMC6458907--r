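#' Pattern-sample sets
#'
#' A `sample_set` holds one pattern vector per row — the values of the ROI
#' voxels for one trial, or one subject x condition average — together with a
#' metadata table (subject, modality, class, rating, ...) and the mask that
#' fixes the voxel ordering. It is the unit of all multivariate analyses.
#'
#' @param x numeric matrix, samples in rows, ROI voxels in columns.
#' @param meta data frame with one row per sample.
#' @param mask the `vol_mask` the columns were extracted through (optional
#'   but required to map weights back to the volume).
#' @param normalized logical flag: TRUE once [roi_normalize()] has been
#'   applied.
#' @return object of class `"sample_set"`.
#' @export
sample_set <- function(x, meta, mask = NULL, normalized = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(meta)) stop("meta must have one row per sample")
  if (!is.null(mask) && ncol(x) != mask_count(mask))
    stop("sample length (", ncol(x), ") != mask voxel count (",
         mask_count(mask), ")")
  structure(list(x = x, meta = as.data.frame(meta), mask = mask,
                 normalized = normalized), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("Sample set: ", nrow(x$x), " samples x ", ncol(x$x), " voxels",
      if (x$normalized) " (ROI-normalized)", "\n", sep = "")
  if ("class" %in% names(x$meta))
    print(table(x$meta$class))
  invisible(x)
}

#' @export
dim.sample_set <- function(x) dim(x$x)

#' Row-bind sample sets with identical voxel ordering
#'
#' @param ... `sample_set` objects sharing column count and normalization
#'   state.
#' @return combined `sample_set`.
#' @export
bind_samples <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "sample_set")) sets <- sets[[1]]
  p <- unique(vapply(sets, function(s) ncol(s$x), integer(1)))
  if (length(p) != 1L) stop("sample sets have different voxel counts")
  metas <- lapply(sets, `[[`, "meta")
  cols <- Reduce(intersect, lapply(metas, names))
  sample_set(do.call(rbind, lapply(sets, `[[`, "x")),
             do.call(rbind, lapply(metas, function(m) m[, cols, drop = FALSE])),
             mask = sets[[1]]$mask,
             normalized = all(vapply(sets, `[[`, logical(1), "normalized")))
}

#' Subset a sample set by a metadata predicate
#'
#' @param set a `sample_set`.
#' @param keep logical or integer index over samples.
#' @return subset `sample_set`.
#' @export
subset_samples <- function(set, keep) {
  sample_set(set$x[keep, , drop = FALSE], set$meta[keep, , drop = FALSE],
             mask = set$mask, normalized = set$normalized)
}

#' Extract peak-volume pattern samples for each event
#'
#' For each stimulus, takes the ROI voxel values of the volume
#' `floor(onset / tr) + peak_offset` (volume i covers
#' `[i * tr, (i+1) * tr)`, so "the k-th volume after onset" is the k-th
#' volume after the one containing the onset). With TR 3 s the default
#' offset 2 samples 4–6 s after onset; with TR 0.8 s an offset of 8 samples
#' about 6 s after onset — both at the expected BOLD peak. Events whose peak
#' volume falls outside the run are skipped with a warning.
#'
#' @param series a [vol_series()].
#' @param events event data frame (`onset`, `modality`, optional `level`,
#'   `rating`, `run`).
#' @param mask ROI `vol_mask` on the series grid.
#' @param peak_offset volumes after the onset volume (default 2).
#' @return `sample_set` with one row per extractable event; metadata carries
#'   the event columns.
#' @export
extract_peak_samples <- function(series, events, mask, peak_offset = 2L) {
  check_grid(list(data = array(TRUE, dim(series$data)[1:3]),
                  affine = series$affine), mask)
  n <- n_volumes(series)
  vol_idx <- floor(events$onset / series$tr) + peak_offset + 1L
  ok <- vol_idx >= 1L & vol_idx <= n
  if (any(!ok))
    warning(sum(!ok), " event(s) with peak volume outside the run skipped")
  vox <- which(mask$data)
  X <- as_vxt(series)
  sample_set(t(X[vox, vol_idx[ok], drop = FALSE]),
             events[ok, , drop = FALSE], mask = mask)
}

#' Average pattern samples within metadata groups
#'
#' Element-wise mean of all samples sharing the values of the grouping
#' columns — e.g. `c("subject", "modality")` averages every subject's trials
#' per modality into one pattern. Grouping labels are propagated; numeric
#' rating columns are averaged alongside.
#'
#' @param set a `sample_set`.
#' @param by character vector of metadata columns to group by.
#' @return `sample_set` with one row per group.
#' @export
average_samples <- function(set, by) {
  if (!all(by %in% names(set$meta)))
    stop("grouping column(s) missing from metadata: ",
         paste(setdiff(by, names(set$meta)), collapse = ", "))
  key <- interaction(set$meta[, by, drop = FALSE], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(set$x)), key)
  gm <- vapply(groups, function(i) colMeans(set$x[i, , drop = FALSE]),
               numeric(ncol(set$x)))
  xm <- if (is.matrix(gm)) t(gm) else matrix(gm, ncol = 1L)
  meta <- set$meta[vapply(groups, `[`, integer(1), 1L), by, drop = FALSE]
  num_cols <- setdiff(names(set$meta)[vapply(set$meta, is.numeric, logical(1))],
                      c(by, "onset"))
  for (cn in num_cols)
    meta[[cn]] <- vapply(groups, function(i) mean(set$meta[[cn]][i]), numeric(1))
  rownames(xm) <- rownames(meta) <- NULL
  sample_set(xm, meta, mask = set$mask, normalized = set$normalized)
}

#' ROI-wise signal normalization of each sample
#'
#' Centers and scales every pattern across the ROI voxels: the voxel-wise
#' mean over the ROI is subtracted and the result divided by the standard
#' deviation over the ROI, so each sample has mean 0 and sd 1. This removes
#' differences in mean ROI amplitude (and overall scaling) between samples —
#' required before any cross-dataset classification. Idempotent; constant
#' samples are degenerate and raise an error.
#'
#' @param set a `sample_set` with >= 2 voxels.
#' @return normalized `sample_set` (flag set).
#' @export
roi_normalize <- function(set) {
  if (ncol(set$x) < 2) stop("ROI normalization needs >= 2 voxels")
  mu <- rowMeans(set$x)
  s <- apply(set$x, 1, sd)
  if (any(s == 0)) stop("constant sample(s) cannot be ROI-normalized")
  sample_set((set$x - mu) / s, set$meta, mask = set$mask, normalized = TRUE)
}

#' Restrict a sample set to a sub-region of its mask
#'
#' @param set a `sample_set` with a mask.
#' @param roi `vol_mask`; must be a subset of the set's mask.
#' @return `sample_set` over the ROI voxels only.
#' @export
restrict_samples <- function(set, roi) {
  if (is.null(set$mask)) stop("sample set carries no mask")
  check_grid(set$mask, roi)
  vox <- which(set$mask$data)
  keep <- which(roi$data[vox])
  if (length(keep) == 0) stop("ROI does not intersect the sample mask")
  sample_set(set$x[, keep, drop = FALSE], set$meta, mask = roi,
             normalized = set$normalized)
}

#' Build per-subject modality-average samples from a synthetic dataset
#'
#' Runs the fixed first-level pipeline of the event-related analysis on every
#' subject and run: motion regression, linear detrending + z-scoring,
#' peak-volume extraction through the ROI mask, trial averaging per modality
#' and run, then averaging across runs — one pattern per subject x modality.
#'
#' @param dataset a [generate_dataset()] result.
#' @param mask ROI mask (default: the dataset's ground-truth ROI).
#' @param peak_offset volumes after onset (default 2 for TR 3 s designs,
#'   8 for TR 0.8 s designs).
#' @param motion_regression,detrend stages toggles (both TRUE by default;
#'   the motion-regression-then-detrend order is the package default).
#' @param normalize apply [roi_normalize()] at the end.
#' @param events_filter optional function(events) -> logical vector selecting
#'   trials (e.g. intensity-matched subsets) before averaging.
#' @return `sample_set` with metadata columns `subject`, `modality`, `rating`.
#' @export
build_modality_samples <- function(dataset, mask = NULL, peak_offset = NULL,
                                   motion_regression = TRUE, detrend = TRUE,
                                   normalize = FALSE, events_filter = NULL) {
  if (is.null(mask)) mask <- dataset$truth$roi
  if (is.null(peak_offset))
    peak_offset <- if (dataset$config$tr >= 2) 2L else 8L
  per_subject <- lapply(dataset$subjects, function(s) {
    run_sets <- lapply(s$runs, function(run) {
      ser <- run$series
      if (motion_regression) ser <- regress_out_motion(ser, run$motion)
      if (detrend) ser <- detrend_zscore(ser)
      ev <- run$events
      if (!is.null(events_filter)) ev <- ev[events_filter(ev), , drop = FALSE]
      set <- extract_peak_samples(ser, ev, mask, peak_offset = peak_offset)
      average_samples(set, by = c("modality", "run"))
    })
    runs_set <- bind_samples(run_sets)
    avg <- average_samples(runs_set, by = "modality")
    avg$meta$subject <- s$id
    avg
  })
  out <- bind_samples(per_subject)
  if (normalize) out <- roi_normalize(out)
  out
}

#' Build trial-level samples from a synthetic dataset
#'
#' Same first-level pipeline as [build_modality_samples()] but stopping
#' before trial averaging: one pattern per extractable stimulus, with the
#' trial's modality, level and rating. This is the input to median-split
#' class construction for the blocked, two-level design.
#'
#' @inheritParams build_modality_samples
#' @return `sample_set` with one row per trial.
#' @export
build_trial_samples <- function(dataset, mask = NULL, peak_offset = NULL,
                                motion_regression = TRUE, detrend = TRUE) {
  if (is.null(mask)) mask <- dataset$truth$roi
  if (is.null(peak_offset))
    peak_offset <- if (dataset$config$tr >= 2) 2L else 8L
  per_subject <- lapply(dataset$subjects, function(s) {
    run_sets <- lapply(s$runs, function(run) {
      ser <- run$series
      if (motion_regression) ser <- regress_out_motion(ser, run$motion)
      if (detrend) ser <- detrend_zscore(ser)
      extract_peak_samples(ser, run$events, mask, peak_offset = peak_offset)
    })
    set <- bind_samples(run_sets)
    set$meta$subject <- s$id
    set
  })
  bind_samples(per_subject)
}
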