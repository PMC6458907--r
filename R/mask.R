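#' Binary volumetric masks
#'
#' A `vol_mask` is a 3D logical field on a voxel grid together with a 4x4
#' voxel-to-world affine (mm). Masks define regions of interest and fix the
#' voxel ordering of every pattern vector extracted through them. All mask
#' algebra requires operands on the identical grid (same shape and affine).
#'
#' The affine follows the NIfTI convention: world = A %*% c(i, j, k, 1) with
#' zero-based voxel indices.
#'
#' @param data logical (or coercible) 3D array.
#' @param affine 4x4 voxel-to-world transform in mm. Default: isotropic
#'   `voxel_size` with the grid centre at the world origin.
#' @param voxel_size isotropic voxel edge in mm used when `affine` is missing.
#' @return object of class `"vol_mask"` with elements `data`, `affine`.
#' @examples
#' m <- vol_mask(array(TRUE, c(4, 4, 4)), voxel_size = 3)
#' mask_count(m)
#' @export
vol_mask <- function(data, affine = NULL, voxel_size = 3) {
  data <- array(as.logical(data), dim = dim(data))
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  if (is.null(affine)) affine <- center_affine(dim(data), voxel_size)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  structure(list(data = data, affine = affine), class = "vol_mask")
}

# isotropic affine placing the grid centre at world (0,0,0)
center_affine <- function(grid_shape, voxel_size) {
  a <- diag(c(rep(voxel_size, 3), 1))
  a[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  a
}

#' @rdname vol_mask
#' @param mask a `vol_mask`.
#' @export
mask_count <- function(mask) sum(mask$data)

#' @export
print.vol_mask <- function(x, ...) {
  cat("Binary mask: grid ", paste(dim(x$data), collapse = " x "),
      ", ", mask_count(x), " voxels in mask\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-8))
}

check_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("masks are defined on different grids (shape or affine mismatch)")
}

#' Mask algebra: union, overlap, left/right split
#'
#' `mask_union` and `mask_overlap` are voxel-wise OR and AND of two masks on
#' the same grid — the operations used to assemble a composite ROI (e.g.
#' merging a meta-analytic mask with a somatotopic sub-region, or intersecting
#' two component masks). `split_mask_lr` partitions a mask into left and right
#' halves by the world x coordinate of each voxel centre: x <= 0 goes left,
#' x > 0 goes right.
#'
#' @param a,b `vol_mask` objects on the same grid.
#' @return a `vol_mask`; for `split_mask_lr` a list with elements `left` and
#'   `right` that partition the input exactly.
#' @examples
#' m <- vol_mask(array(TRUE, c(4, 4, 4)))
#' lr <- split_mask_lr(m)
#' mask_count(lr$left) + mask_count(lr$right) == mask_count(m)
#' @export
mask_union <- function(a, b) {
  check_grid(a, b)
  vol_mask(a$data | b$data, a$affine)
}

#' @rdname mask_union
#' @export
mask_overlap <- function(a, b) {
  check_grid(a, b)
  vol_mask(a$data & b$data, a$affine)
}

#' @rdname mask_union
#' @param mask a `vol_mask`.
#' @export
split_mask_lr <- function(mask) {
  d <- dim(mask$data)
  idx <- which(mask$data, arr.ind = TRUE)
  left <- array(FALSE, d); right <- array(FALSE, d)
  if (nrow(idx) > 0) {
    world_x <- mask$affine[1, 1] * (idx[, 1] - 1) +
      mask$affine[1, 2] * (idx[, 2] - 1) +
      mask$affine[1, 3] * (idx[, 3] - 1) + mask$affine[1, 4]
    left[idx[world_x <= 0, , drop = FALSE]] <- TRUE
    right[idx[world_x > 0, , drop = FALSE]] <- TRUE
  }
  list(left = vol_mask(left, mask$affine), right = vol_mask(right, mask$affine))
}

neighbour_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  switch(as.character(connectivity),
         "6"  = offs[nz == 1, , drop = FALSE],
         "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
         "26" = offs[nz >= 1, , drop = FALSE],
         stop("connectivity must be 6, 18 or 26"))
}

shift_array <- function(x, off) {
  # shift with FALSE fill: out[i] = x[i + off] (off-grid counts as background)
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (off[k] >= 0) {
      dst[[k]] <- seq_len(d[k] - off[k]); src[[k]] <- dst[[k]] + off[k]
    } else {
      dst[[k]] <- seq(1 - off[k], d[k]);  src[[k]] <- dst[[k]] + off[k]
    }
    if (length(dst[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Morphological erosion of a mask
#'
#' Peels `layers` one-voxel shells off the mask: a voxel survives one layer
#' iff all its neighbours under the chosen `connectivity` are inside the mask.
#' Voxels beyond the grid boundary count as background, so the mask also
#' erodes inwards from the edge of the field of view. `layers = 0` is the
#' identity; heavy erosion may return an empty mask.
#'
#' The default 6-connectivity (face neighbours) has a crisp analytic
#' characterization (a solid cube of edge n erodes to edge n-2 per layer);
#' 26-connectivity matches a 3x3x3 box kernel as used by common neuroimaging
#' tools, and both are available.
#'
#' @param mask a `vol_mask`.
#' @param layers number of erosion iterations (>= 0).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full box).
#' @return eroded `vol_mask` on the same grid.
#' @export
erode_mask <- function(mask, layers, connectivity = 6) {
  if (layers < 0) stop("'layers' must be >= 0")
  offs <- neighbour_offsets(connectivity)
  out <- mask$data
  for (l in seq_len(layers)) {
    if (!any(out)) break
    acc <- out
    for (r in seq_len(nrow(offs))) acc <- acc & shift_array(out, offs[r, ])
    out <- acc
  }
  vol_mask(out, mask$affine)
}

#' Seeded uniform subsampling of mask voxels
#'
#' Keeps exactly `n_target` voxels drawn uniformly without replacement, used
#' to equate voxel counts between a control mask and an ROI (classification
#' accuracy depends on the number of features). Reproducible under `seed`.
#'
#' @param mask a `vol_mask`.
#' @param n_target voxels to keep; must not exceed `mask_count(mask)`.
#' @param seed integer seed for the draw (NULL = current RNG stream).
#' @return `vol_mask` with `n_target` voxels, a subset of the input.
#' @export
subsample_mask <- function(mask, n_target, seed = NULL) {
  n <- mask_count(mask)
  if (n_target > n) stop("n_target (", n_target, ") exceeds mask size (", n, ")")
  if (n_target == n) return(mask)
  keep <- with_seed(seed, sample(which(mask$data), n_target))
  out <- array(FALSE, dim(mask$data))
  out[keep] <- TRUE
  vol_mask(out, mask$affine)
}

#' Nearest-neighbour resampling of a mask to a new voxel size
#'
#' Builds a new isotropic grid covering the same world-space footprint (to
#' within one voxel) and assigns each new voxel the value of the nearest old
#' voxel centre. Only axis-aligned affines are supported, which covers every
#' grid this package constructs.
#'
#' @param mask a `vol_mask` with axis-aligned affine.
#' @param target_voxel_size new isotropic voxel edge in mm (> 0).
#' @return resampled `vol_mask`.
#' @export
resample_mask <- function(mask, target_voxel_size) {
  if (target_voxel_size <= 0) stop("target voxel size must be positive")
  a <- mask$affine
  if (any(abs(a[1:3, 1:3] - diag(diag(a[1:3, 1:3]))) > 1e-8))
    stop("resample_mask supports axis-aligned affines only")
  d <- dim(mask$data)
  vox <- diag(a[1:3, 1:3])
  if (all(abs(abs(vox) - target_voxel_size) < 1e-12)) return(mask)
  # world extent of voxel centres along each axis
  lo <- a[1:3, 4]
  hi <- lo + vox * (d - 1)
  new_d <- pmax(1L, as.integer(ceiling(abs(hi - lo) / target_voxel_size)) + 1L)
  new_vox <- sign(vox) * target_voxel_size
  new_a <- diag(c(new_vox, 1))
  # centre the new grid on the old grid's world centre
  new_a[1:3, 4] <- (lo + hi) / 2 - new_vox * (new_d - 1) / 2
  out <- array(FALSE, new_d)
  idx <- as.matrix(expand.grid(i = seq_len(new_d[1]), j = seq_len(new_d[2]),
                               k = seq_len(new_d[3])))
  world <- sweep(sweep(idx - 1, 2, new_vox, "*"), 2, new_a[1:3, 4], "+")
  old_idx <- round(sweep(sweep(world, 2, lo, "-"), 2, vox, "/")) + 1
  ok <- old_idx[, 1] >= 1 & old_idx[, 1] <= d[1] &
    old_idx[, 2] >= 1 & old_idx[, 2] <= d[2] &
    old_idx[, 3] >= 1 & old_idx[, 3] <= d[3]
  out[idx[ok, , drop = FALSE]] <- mask$data[old_idx[ok, , drop = FALSE]]
  vol_mask(out, new_a)
}

#' Read and write masks as NIfTI
#'
#' Thin wrappers over RNifti keeping the mask's grid and affine.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param mask a `vol_mask`.
#' @param threshold values strictly above this count as in-mask when reading.
#' @return `read_mask` returns a `vol_mask`; `write_mask` returns `path`
#'   invisibly.
#' @export
read_mask <- function(path, threshold = 0) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L) arr <- arr[, , , 1]
  vol_mask(arr > threshold, structure(RNifti::xform(img), class = NULL)[1:4, 1:4])
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
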