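# random mask on a cubic grid
random_mask <- function(n = 16, p = 0.3, seed = NULL, voxel_size = 3) {
  if (!is.null(seed)) set.seed(seed)
  vol_mask(array(runif(n^3) < p, c(n, n, n)), voxel_size = voxel_size)
}

# solid cube mask of edge `edge` centred in a grid of size n
cube_mask <- function(edge, n = edge + 4, voxel_size = 2) {
  a <- array(FALSE, c(n, n, n))
  lo <- floor((n - edge) / 2) + 1
  a[lo:(lo + edge - 1), lo:(lo + edge - 1), lo:(lo + edge - 1)] <- TRUE
  vol_mask(a, voxel_size = voxel_size)
}

# brute-force erosion oracle: per-voxel neighbourhood scan
erode_oracle <- function(mask, layers, connectivity = 6) {
  offs <- painpattern:::neighbour_offsets(connectivity)
  cur <- mask$data
  d <- dim(cur)
  for (l in seq_len(layers)) {
    nxt <- array(FALSE, d)
    idx <- which(cur, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      ok <- TRUE
      for (o in seq_len(nrow(offs))) {
        nb <- v + offs[o, ]
        if (any(nb < 1) || any(nb > d) || !cur[nb[1], nb[2], nb[3]]) {
          ok <- FALSE; break
        }
      }
      nxt[v[1], v[2], v[3]] <- ok
    }
    cur <- nxt
  }
  vol_mask(cur, mask$affine)
}

# small event-related config used across tests
tiny_config <- function(seed = 1, ...) {
  args <- list(design = "event_related_4mod", n_subjects = 3L, n_runs = 1L,
               stimuli_per_run_per_modality = 2L, grid_shape = c(8L, 8L, 8L),
               noise_sd = 0.5, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}

# scaled null-calibration config: 12 subjects, 500-voxel ROI, no signal
null_config <- function(seed) {
  synth_config("event_related_4mod", n_subjects = 12L, n_runs = 2L,
               stimuli_per_run_per_modality = 4L, grid_shape = c(10L, 10L, 10L),
               roi_target_voxels = 500L, modality_pattern_amplitude = 0,
               shared_intensity_amplitude = 0, subject_pattern_jitter_sd = 0,
               noise_sd = 1, seed = seed)
}

# one signal-free replicate -> LOSO pain vs touch fit
null_replicate <- function(seed, n_perm = 0L) {
  ds <- generate_dataset(null_config(seed))
  s <- build_modality_samples(ds)
  pt <- subset_samples(s, s$meta$modality %in% c("pain", "touch"))
  loso_classify(pt, class_col = "modality", n_perm = n_perm, seed = seed + 1L)
}

# sample set built directly from a matrix and labels (bypasses imaging)
toy_set <- function(x, subject, class, normalized = FALSE, rating = NULL) {
  meta <- data.frame(subject = subject, class = class)
  if (!is.null(rating)) meta$rating <- rating
  sample_set(x, meta, normalized = normalized)
}

# reference SVM through kernlab's QP solver (independent of SMO); returns
# NULL when the interior-point solve is numerically singular on a degenerate
# random instance
ipop_svm <- function(x, y01, C = 1) {
  y <- ifelse(y01 == 1, 1, -1)
  K <- tcrossprod(x)
  n <- nrow(x)
  H <- (y %*% t(y)) * K + 1e-8 * diag(n)
  sol <- tryCatch(
    kernlab::ipop(c = rep(-1, n), H = H, A = matrix(as.numeric(y), 1),
                  b = 0, l = rep(0, n), u = rep(C, n), r = 0,
                  sigf = 10, maxiter = 200),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  alpha <- kernlab::primal(sol)
  w <- as.numeric(crossprod(x, alpha * y))
  free <- alpha > 1e-6 & alpha < C - 1e-6
  b <- if (any(free)) mean(y[free] - (x[free, , drop = FALSE] %*% w))
       else 0
  list(w = w, b = b, alpha = alpha)
}
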