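#' 4D volume series
#'
#' A subject/run's voxel-wise signal: a 4D array (x, y, z, time) with a
#' repetition time and a voxel-to-world affine. All temporal preprocessing
#' operates voxel-wise on this container.
#'
#' @param data 4D numeric array.
#' @param tr repetition time in seconds (> 0).
#' @param affine 4x4 voxel-to-world transform; defaults to an isotropic grid
#'   centred at the world origin.
#' @param voxel_size used for the default affine.
#' @return object of class `"vol_series"`.
#' @export
vol_series <- function(data, tr, affine = NULL, voxel_size = 3) {
  if (length(dim(data)) != 4L) stop("series data must be a 4D array")
  if (!is.finite(tr) || tr <= 0) stop("tr must be positive")
  if (is.null(affine)) affine <- center_affine(dim(data)[1:3], voxel_size)
  structure(list(data = data, tr = tr, affine = as.matrix(affine)),
            class = "vol_series")
}

#' @export
print.vol_series <- function(x, ...) {
  d <- dim(x$data)
  cat("Volume series: grid ", paste(d[1:3], collapse = " x "), ", ",
      d[4], " volumes, TR ", x$tr, " s\n", sep = "")
  invisible(x)
}

n_volumes <- function(series) dim(series$data)[4]

# voxels x time view of a series
as_vxt <- function(series) {
  d <- dim(series$data)
  matrix(series$data, prod(d[1:3]), d[4])
}

vxt_to_series <- function(x, template) {
  vol_series(array(x, dim(template$data)), tr = template$tr,
             affine = template$affine)
}

#' Linear detrending and temporal z-scoring
#'
#' Removes each voxel's least-squares linear trend (intercept + slope) over
#' time, then standardizes the residual to mean 0 and standard deviation 1.
#' Voxels with zero residual variance (including constant voxels and pure
#' ramps) are set to all-zero so downstream linear algebra never sees
#' non-finite values.
#'
#' @param series a [vol_series()] with at least 3 volumes.
#' @return detrended, z-scored `vol_series`.
#' @export
detrend_zscore <- function(series) {
  n <- n_volumes(series)
  if (n < 3) stop("detrend_zscore needs at least 3 volumes")
  X <- as_vxt(series)
  tc <- seq_len(n) - (n + 1) / 2
  slope <- (X %*% tc) / sum(tc^2)
  R <- X - rowMeans(X) - tcrossprod(slope, tc)
  s <- sqrt(rowSums(R^2) / (n - 1))
  # voxels whose variance is numerically zero relative to their scale (pure
  # trends, constants) are zeroed rather than amplified
  tol <- 1e-10 * (rowMeans(abs(X)) + 1)
  R <- R / ifelse(s > tol, s, Inf)
  vxt_to_series(R, series)
}

#' Regress head-motion parameters out of every voxel's time series
#'
#' Computes per-voxel least-squares residuals on the design
#' (intercept + 6 motion columns). Collinear motion columns are dropped with
#' a warning so the fit is always well posed.
#'
#' @param series a [vol_series()].
#' @param motion numeric matrix, `n_volumes` rows x 6 columns (3 translations
#'   in mm, 3 rotations in radians).
#' @return residual `vol_series` (mean removed by the intercept).
#' @export
regress_out_motion <- function(series, motion) {
  motion <- as.matrix(motion)
  n <- n_volumes(series)
  if (nrow(motion) != n)
    stop("motion table has ", nrow(motion), " rows but series has ", n,
         " volumes")
  D <- cbind(1, motion)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop <- qrD$pivot[(qrD$rank + 1):ncol(D)]
    warning("dropping collinear motion column(s): ",
            paste(drop - 1L, collapse = ", "))
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
    qrD <- qr(D)
  }
  X <- as_vxt(series)
  # residual maker applied from the right: R = X (I - Q Q')
  Q <- qr.Q(qrD)
  R <- X - (X %*% Q) %*% t(Q)
  vxt_to_series(R, series)
}

#' Framewise displacement summarized over stimulation windows
#'
#' Framewise displacement of volume t is
#' `sum(|delta translations|) + 50 mm * sum(|delta rotations|)` (rotations
#' converted to arc length on a 50 mm sphere). The summary is the mean FD
#' over the volumes within the stimulation window of every event of the
#' requested modality, i.e. the average head displacement during
#' stimulation.
#'
#' @param motion 6-column motion table (translations mm, rotations rad).
#' @param events event data frame with `onset` and `modality`.
#' @param modality which events define the windows.
#' @param tr repetition time in s.
#' @param window_vols window length in volumes starting at the event's onset
#'   volume (default 2: the onset volume and the next).
#' @param radius rotation-to-translation conversion radius, mm.
#' @return mean framewise displacement in mm.
#' @export
summarize_motion <- function(motion, events, modality, tr, window_vols = 2L,
                             radius = 50) {
  motion <- as.matrix(motion)
  ev <- events[events$modality == modality, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events of modality '", modality, "'")
  fd <- c(0, rowSums(abs(diff(motion[, 1:3, drop = FALSE]))) +
            radius * rowSums(abs(diff(motion[, 4:6, drop = FALSE]))))
  n <- nrow(motion)
  vols <- unique(unlist(lapply(floor(ev$onset / tr) + 1L, function(v)
    seq.int(v, min(n, v + window_vols - 1L)))))
  vols <- vols[vols >= 1 & vols <= n]
  mean(fd[vols])
}

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along margin `along` of a 3D array with reflective boundaries
conv_axis <- function(vol, k, along) {
  if (length(k) == 1) return(vol)
  half <- (length(k) - 1) / 2
  d <- dim(vol)
  n <- d[along]
  perm <- c(along, setdiff(1:3, along))
  m <- matrix(aperm(vol, perm), n, prod(d[-along]))
  # half-sample symmetric padding: preserves the volume mean exactly for a
  # normalized symmetric kernel
  refl <- c(pmin(n, half:1), 1:n, pmax(1, n + 1 - (1:half)))
  mp <- m[refl, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * mp[i:(i + n - 1), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable 3D Gaussian smoothing of every volume, with the kernel width
#' given as full-width at half-maximum in millimetres
#' (`sigma = fwhm / 2.3548` converted to voxels via the affine). Reflective
#' boundary handling preserves the volume mean; `fwhm = 0` is the identity.
#'
#' @param series a [vol_series()].
#' @param fwhm kernel FWHM in mm (>= 0).
#' @return smoothed `vol_series`.
#' @export
gaussian_smooth <- function(series, fwhm) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(series)
  vox <- abs(diag(series$affine[1:3, 1:3]))
  sigmas <- fwhm / (2 * sqrt(2 * log(2))) / vox
  out <- series$data
  for (t in seq_len(n_volumes(series))) {
    v <- out[, , , t]
    for (ax in 1:3) v <- conv_axis(v, gauss_kernel_1d(sigmas[ax]), ax)
    out[, , , t] <- v
  }
  vol_series(out, series$tr, series$affine)
}

#' Read and write 4D series as NIfTI
#'
#' @param path NIfTI file path.
#' @param series a [vol_series()].
#' @param tr repetition time to attach when the header lacks one.
#' @return `read_series` returns a `vol_series`; `write_series` returns
#'   `path` invisibly.
#' @export
read_series <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D NIfTI image")
  if (is.null(tr)) {
    pd <- attr(img, "pixdim")
    tr <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else
      stop("TR not present in header; pass 'tr'")
  }
  vol_series(arr, tr = tr,
             affine = structure(RNifti::xform(img), class = NULL)[1:4, 1:4])
}

#' @rdname read_series
#' @export
write_series <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
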