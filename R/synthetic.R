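#' Configuration for a synthetic evoked-fMRI dataset
#'
#' Describes one of the two emulated experimental designs and the parameters
#' of the signal, noise, rating and motion models. Defaults reproduce the
#' study conditions of the corresponding design:
#'
#' * `event_related_4mod` — 14 subjects, 4 runs, 32 stimuli per run (8 per
#'   modality across pain/touch/audition/vision), inter-stimulus interval
#'   uniform in 10–19 s with fewer than 3 consecutive same-modality stimuli,
#'   TR 3 s, per-stimulus saliency ratings on a 0–10 scale.
#' * `blocked_2mod` — 51 subjects, 2 sessions, per session 3 pain blocks and
#'   3 touch blocks of 4 trials each (25 s trial slots, stimulus onset
#'   uniform 2–12 s into the slot), two intensity levels rated around 3
#'   (low) and 6 (high), TR 0.8 s.
#'
#' Evoked responses are event impulses scaled by
#' (modality amplitude + shared amplitude x rating + subject jitter),
#' convolved with the canonical double-gamma HRF and multiplied by a
#' modality-specific spatial pattern inside the ROI; noise is AR(1) plus
#' white, spatially independent.
#'
#' @param design `"event_related_4mod"` or `"blocked_2mod"`.
#' @param n_subjects number of subjects (>= 2 to generate).
#' @param grid_shape voxels per axis (length 3, each >= 8 to generate).
#' @param voxel_size isotropic voxel edge, mm.
#' @param tr repetition time, s.
#' @param n_runs runs (event-related) or sessions (blocked) per subject.
#' @param stimuli_per_run_per_modality events per modality per run; for the
#'   blocked design must equal blocks x trials-per-block (3 x 4 = 12 by
#'   default).
#' @param isi_range inter-stimulus interval range in s (event-related).
#' @param modality_pattern_amplitude peak evoked amplitude per modality, in
#'   signal units; scalar or named vector over modalities. Must be >= 0.
#' @param shared_intensity_amplitude amplitude of the shared intensity-graded
#'   pattern, signal units per unit rating. Must be >= 0.
#' @param noise_sd marginal standard deviation of the total voxel noise
#'   (split evenly between the AR(1) and white components). Must be >= 0.
#' @param ar1_coef lag-1 autocorrelation of the AR(1) noise component,
#'   in `[0, 1)`.
#' @param subject_pattern_jitter_sd sd of the per-subject additive jitter on
#'   non-zero pattern amplitudes (amplitudes are floored at 0 after jitter).
#' @param rating_model list: `means` (per modality for the event-related
#'   design, per level `low`/`high` for the blocked design), `sd`, and
#'   optional `saliency_cor` / `valence_cor` targets in (-1, 1) for extra
#'   rating columns correlated with the intensity rating.
#' @param motion_model list: `drift_sd` (random-walk step sd, mm per volume;
#'   rotations use `drift_sd / 50` radians), `stim_amp` (stimulus-locked
#'   translation component, mm), `artifact_amp` (amplitude of the
#'   motion-correlated signal artifact injected into the data, signal units).
#' @param roi_target_voxels if non-NULL, the spherical ROI is subsampled to
#'   exactly this many voxels (seeded).
#' @param pattern_sigma width (voxels) of the Gaussian pattern blobs; blobs
#'   are truncated at 3 sigma, so centres more than 6 sigma apart give
#'   exactly orthogonal patterns.
#' @param pattern_centers optional named list of voxel-index triples fixing
#'   the blob centre of each modality pattern (and `"intensity"`); lets two
#'   configurations share or explicitly separate their ground-truth patterns.
#' @param baseline constant signal offset added to every voxel.
#' @param seed integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return object of class `"synth_config"` (a validated list).
#' @export
synth_config <- function(design = c("event_related_4mod", "blocked_2mod"),
                         n_subjects = NULL,
                         grid_shape = c(12L, 12L, 12L),
                         voxel_size = 3,
                         tr = NULL,
                         n_runs = NULL,
                         stimuli_per_run_per_modality = NULL,
                         isi_range = c(10, 19),
                         modality_pattern_amplitude = 1,
                         shared_intensity_amplitude = 0.1,
                         noise_sd = 1,
                         ar1_coef = 0.3,
                         subject_pattern_jitter_sd = 0.1,
                         rating_model = NULL,
                         motion_model = NULL,
                         roi_target_voxels = NULL,
                         pattern_sigma = 1.5,
                         pattern_centers = NULL,
                         baseline = 100,
                         seed = 1L) {
  design <- match.arg(design)
  er <- design == "event_related_4mod"
  if (is.null(n_subjects)) n_subjects <- if (er) 14L else 51L
  if (is.null(tr)) tr <- if (er) 3 else 0.8
  if (is.null(n_runs)) n_runs <- if (er) 4L else 2L
  if (is.null(stimuli_per_run_per_modality))
    stimuli_per_run_per_modality <- if (er) 8L else 12L
  modalities <- if (er) c("pain", "touch", "audition", "vision")
                else c("pain", "touch")
  if (is.null(rating_model))
    rating_model <- if (er)
      list(means = c(pain = 5.5, touch = 5.5, audition = 5.4, vision = 4.9),
           sd = 2.2)
    else list(means = c(low = 3, high = 6), sd = 1)
  if (is.null(rating_model$sd)) rating_model$sd <- if (er) 2.2 else 1
  for (nm in c("saliency_cor", "valence_cor")) {
    r <- rating_model[[nm]]
    if (!is.null(r) && (abs(r) >= 1)) stop(nm, " must lie in (-1, 1)")
  }
  if (is.null(motion_model)) motion_model <- list()
  motion_model <- utils::modifyList(
    list(drift_sd = 0.02, stim_amp = 0, artifact_amp = 0), motion_model)
  amp <- modality_pattern_amplitude
  if (length(amp) == 1L && is.null(names(amp)))
    amp <- stats::setNames(rep(amp, length(modalities)), modalities)
  if (!all(modalities %in% names(amp)))
    stop("modality_pattern_amplitude must name all modalities: ",
         paste(modalities, collapse = ", "))
  amp <- amp[modalities]
  if (any(!is.finite(amp)) || any(amp < 0))
    stop("pattern amplitudes must be finite and >= 0")
  if (!is.finite(shared_intensity_amplitude) || shared_intensity_amplitude < 0)
    stop("shared_intensity_amplitude must be finite and >= 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (ar1_coef < 0 || ar1_coef >= 1) stop("ar1_coef must be in [0, 1)")
  if (subject_pattern_jitter_sd < 0) stop("subject_pattern_jitter_sd must be >= 0")
  if (!er && stimuli_per_run_per_modality %% 4L != 0L)
    stop("blocked design needs stimuli_per_run_per_modality divisible by 4")
  structure(list(
    design = design, modalities = modalities, n_subjects = as.integer(n_subjects),
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size, tr = tr,
    n_runs = as.integer(n_runs),
    stimuli_per_run_per_modality = as.integer(stimuli_per_run_per_modality),
    isi_range = isi_range, modality_pattern_amplitude = amp,
    shared_intensity_amplitude = shared_intensity_amplitude,
    noise_sd = noise_sd, ar1_coef = ar1_coef,
    subject_pattern_jitter_sd = subject_pattern_jitter_sd,
    rating_model = rating_model, motion_model = motion_model,
    roi_target_voxels = roi_target_voxels, pattern_sigma = pattern_sigma,
    pattern_centers = pattern_centers,
    baseline = baseline, seed = as.integer(seed)), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic design '", x$design, "': ", x$n_subjects, " subjects, ",
      x$n_runs, " runs, ", x$stimuli_per_run_per_modality,
      " stimuli/modality/run, TR ", x$tr, " s, grid ",
      paste(x$grid_shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Simulate per-run stimulus event tables
#'
#' Event-related runs deliver `stimuli_per_run_per_modality` events of each
#' modality in pseudo-random order with fewer than 3 consecutive events of
#' the same modality and inter-stimulus intervals uniform in `isi_range`.
#' Blocked sessions deliver 3 blocks per modality of 4 trials each in
#' shuffled block order, one stimulus per 25 s trial slot at a random onset
#' 2–12 s into the slot, with intensity levels low/high balanced within
#' modality and session.
#'
#' @param config a [synth_config()].
#' @return list of data frames (one per run) with columns `onset`,
#'   `modality`, `level`, `run`.
#' @export
simulate_events <- function(config) {
  lapply(seq_len(config$n_runs), function(r) {
    if (config$design == "event_related_4mod") {
      k <- config$stimuli_per_run_per_modality
      seq_mod <- rep(config$modalities, k)
      repeat {
        seq_mod <- sample(seq_mod)
        rl <- rle(seq_mod)$lengths
        if (max(rl) < 3) break
      }
      isi <- runif(length(seq_mod), config$isi_range[1], config$isi_range[2])
      onsets <- cumsum(isi)
      data.frame(onset = onsets, modality = seq_mod,
                 level = NA_character_, run = r)
    } else {
      trials_per_block <- 4L
      blocks_per_mod <- config$stimuli_per_run_per_modality / trials_per_block
      block_mods <- sample(rep(config$modalities, blocks_per_mod))
      trial_dur <- 25
      ev <- list()
      for (b in seq_along(block_mods)) {
        block_start <- (b - 1L) * trials_per_block * trial_dur
        on <- block_start + (seq_len(trials_per_block) - 1L) * trial_dur +
          runif(trials_per_block, 2, 12)
        ev[[b]] <- data.frame(onset = on, modality = block_mods[b],
                              level = NA_character_, run = r)
      }
      ev <- do.call(rbind, ev)
      # balanced low/high levels within modality
      for (m in config$modalities) {
        i <- which(ev$modality == m)
        lv <- sample(rep(c("low", "high"), length.out = length(i)))
        ev$level[i] <- lv
      }
      ev[order(ev$onset), , drop = FALSE]
    }
  })
}

#' Draw perceived-intensity/saliency ratings for an event table
#'
#' Event-related events are rated from the per-modality saliency
#' distribution; blocked events from the per-level intensity distribution
#' (means 3 and 6 by default). All ratings are clipped to the 0–10 scale.
#' When the rating model specifies `saliency_cor` or `valence_cor`, extra
#' columns are generated with the requested correlation to the intensity
#' rating (on the latent Gaussian scale, before clipping).
#'
#' @param config a [synth_config()].
#' @param events a single event data frame as produced by
#'   [simulate_events()]; an empty table is returned unchanged.
#' @return `events` with a numeric `rating` column (and optional
#'   `saliency` / `valence` columns) appended.
#' @export
simulate_ratings <- function(config, events) {
  if (nrow(events) == 0) {
    events$rating <- numeric(0)
    return(events)
  }
  rm_ <- config$rating_model
  mu <- if (config$design == "event_related_4mod")
    unname(rm_$means[events$modality]) else unname(rm_$means[events$level])
  z <- rnorm(nrow(events))
  events$rating <- pmin(10, pmax(0, mu + rm_$sd * z))
  for (col in c("saliency", "valence")) {
    rho <- switch(col, saliency = rm_$saliency_cor, valence = rm_$valence_cor)
    if (!is.null(rho)) {
      w <- rnorm(nrow(events))
      # correlate with the pooled (across-level) intensity rating so the
      # sample correlation over a trial table matches the target
      sr <- sd(events$rating)
      zi <- if (nrow(events) > 1 && sr > 0)
        (events$rating - mean(events$rating)) / sr else rep(0, nrow(events))
      zc <- rho * zi + sqrt(1 - rho^2) * w
      events[[col]] <- pmin(10, pmax(0, mean(mu) + rm_$sd * zc))
    }
  }
  events
}

# truncated Gaussian blob (3 sigma support) around a voxel centre, restricted
# to the ROI, peak 1
pattern_blob <- function(center, roi, sigma = 1.5) {
  d <- dim(roi$data)
  idx <- which(roi$data, arr.ind = TRUE)
  dist2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  v <- exp(-dist2 / (2 * sigma^2))
  v[dist2 > (3 * sigma)^2] <- 0
  out <- array(0, d)
  out[idx] <- v
  out
}

make_ground_truth <- function(config) {
  d <- config$grid_shape
  affine <- center_affine(d, config$voxel_size)
  centre <- (d + 1) / 2
  radius <- min(d) / 2   # inscribed sphere
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  inside <- ((g$i - centre[1])^2 + (g$j - centre[2])^2 +
               (g$k - centre[3])^2) <= radius^2
  roi <- vol_mask(array(inside, d), affine)
  if (!is.null(config$roi_target_voxels))
    roi <- subsample_mask(roi, config$roi_target_voxels)

  # 10 sub-regions: left/right split crossed with 5 slabs along z
  lr <- split_mask_lr(roi)
  region_names <- c("S1", "S2", "insula", "cingulate", "thalamus")
  idx_all <- which(roi$data, arr.ind = TRUE)
  zb <- quantile(idx_all[, 3], probs = seq(0, 1, length.out = 6))
  subregions <- list()
  for (side in c("left", "right")) {
    side_mask <- lr[[side]]
    si <- which(side_mask$data, arr.ind = TRUE)
    for (s in seq_len(5)) {
      inslab <- si[, 3] >= zb[s] & (if (s == 5) si[, 3] <= zb[6]
                                    else si[, 3] < zb[s + 1])
      a <- array(FALSE, d)
      a[si[inslab, , drop = FALSE]] <- TRUE
      subregions[[paste(region_names[s], side, sep = "_")]] <-
        vol_mask(a, affine)
    }
  }

  # pattern centres: supplied, or drawn from the ROI interior
  mods <- config$modalities
  centers <- config$pattern_centers
  if (is.null(centers)) {
    pool <- which(erode_mask(roi, 1)$data, arr.ind = TRUE)
    if (nrow(pool) < length(mods) + 1) pool <- idx_all
    pick <- sample(nrow(pool), length(mods) + 1)
    centers <- c(stats::setNames(lapply(pick[seq_along(mods)],
                                        function(p) pool[p, ]), mods),
                 list(intensity = pool[pick[length(mods) + 1], ]))
  }
  sg <- config$pattern_sigma %||% 1.5
  patterns <- lapply(mods, function(m) pattern_blob(centers[[m]], roi, sg))
  names(patterns) <- mods
  intensity_pattern <- pattern_blob(centers[["intensity"]], roi, sg)
  list(patterns = patterns, intensity_pattern = intensity_pattern,
       roi = roi, subregions = subregions, centers = centers)
}

# AR(1)+white noise matrix, voxels x volumes, marginal sd = noise_sd
noise_matrix <- function(n_vox, n_vol, noise_sd, phi) {
  if (noise_sd == 0) return(matrix(0, n_vox, n_vol))
  s <- noise_sd / sqrt(2)
  innov_sd <- s * sqrt(1 - phi^2)
  ar <- matrix(rnorm(n_vox * n_vol, sd = innov_sd), n_vox, n_vol)
  ar[, 1] <- rnorm(n_vox, sd = s)
  for (t in 2:n_vol) ar[, t] <- phi * ar[, t - 1] + ar[, t]
  ar + matrix(rnorm(n_vox * n_vol, sd = s), n_vox, n_vol)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Simulates every subject's runs — 4D volume series, event tables with
#' ratings, and 6-column motion tables — plus the ground-truth spatial
#' patterns, ROI mask and 10 sub-region masks used to score downstream
#' recovery. The evoked signal of each event is an impulse of amplitude
#' (modality amplitude + subject jitter) on the modality pattern plus
#' (shared amplitude x rating) on the intensity pattern, convolved with the
#' canonical HRF at the volume grid; noise is AR(1)+white, and motion tables
#' follow a random walk with an optional stimulus-locked component.
#'
#' @param config a [synth_config()].
#' @param truth optionally reuse the ground truth of another dataset (for
#'   cross-dataset experiments with shared patterns).
#' @return object of class `"synth_dataset"`: list with `subjects` (each with
#'   `id` and `runs`, a run holding `series`, `events`, `motion`), `truth`
#'   (`patterns`, `intensity_pattern`, `roi`, `subregions`), `config`.
#' @examples
#' cfg <- synth_config("event_related_4mod", n_subjects = 2, n_runs = 1,
#'                     stimuli_per_run_per_modality = 2,
#'                     grid_shape = c(8, 8, 8), seed = 7)
#' ds <- generate_dataset(cfg)
#' nrow(ds$subjects[[1]]$runs[[1]]$events)  # 8 events, 2 per modality
#' @export
generate_dataset <- function(config, truth = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (any(config$grid_shape < 8)) stop("grid_shape must be >= 8 voxels per axis")
  if (config$n_subjects < 2) stop("n_subjects must be >= 2")
  with_seed(config$seed, {
    if (is.null(truth)) truth <- make_ground_truth(config)
    d <- config$grid_shape
    n_vox <- prod(d)
    kern <- hrf_kernel(config$tr)
    pat_mat <- vapply(config$modalities,
                      function(m) as.numeric(truth$patterns[[m]]),
                      numeric(n_vox))
    q_vec <- as.numeric(truth$intensity_pattern)
    art_map <- rnorm(n_vox)
    art_map <- art_map / sqrt(sum(art_map^2))
    subjects <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      jit <- rnorm(length(config$modalities),
                   sd = config$subject_pattern_jitter_sd)
      amps <- config$modality_pattern_amplitude
      amps_eff <- ifelse(amps > 0, pmax(0, amps + jit), 0)
      runs <- vector("list", config$n_runs)
      for (r in seq_len(config$n_runs)) {
        ev <- simulate_events_one(config, r)
        ev <- simulate_ratings(config, ev)
        dur <- max(ev$onset) + 20
        n_vol <- as.integer(ceiling(dur / config$tr))
        vol_of <- pmin(n_vol, floor(ev$onset / config$tr) + 1L)
        U <- matrix(0, length(config$modalities) + 1L, n_vol)
        for (mi in seq_along(config$modalities)) {
          sticks <- numeric(n_vol)
          e_i <- which(ev$modality == config$modalities[mi])
          for (e in e_i) sticks[vol_of[e]] <- sticks[vol_of[e]] + amps_eff[mi]
          U[mi, ] <- convolve_sticks(sticks, kern)
        }
        sticks_q <- numeric(n_vol)
        for (e in seq_len(nrow(ev)))
          sticks_q[vol_of[e]] <- sticks_q[vol_of[e]] +
            config$shared_intensity_amplitude * ev$rating[e]
        U[nrow(U), ] <- convolve_sticks(sticks_q, kern)
        X <- cbind(pat_mat, q_vec) %*% U
        X <- X + noise_matrix(n_vox, n_vol, config$noise_sd, config$ar1_coef)
        # motion table: random walk, stimulus-locked translation option
        mm <- config$motion_model
        motion <- cbind(
          apply(matrix(rnorm(n_vol * 3, sd = mm$drift_sd), n_vol, 3), 2, cumsum),
          apply(matrix(rnorm(n_vol * 3, sd = mm$drift_sd / 50), n_vol, 3), 2,
                cumsum))
        colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
        if (mm$stim_amp > 0) {
          all_stick <- numeric(n_vol)
          all_stick[vol_of] <- 1
          motion[, 1] <- motion[, 1] +
            mm$stim_amp * convolve_sticks(all_stick, kern)
        }
        if (mm$artifact_amp > 0)
          X <- X + mm$artifact_amp * art_map %*% t(motion[, 1])
        X <- X + config$baseline
        series <- vol_series(array(X, c(d, n_vol)), tr = config$tr,
                             affine = truth$roi$affine)
        runs[[r]] <- list(series = series, events = ev, motion = motion)
      }
      subjects[[s]] <- list(id = sprintf("sub%02d", s), runs = runs)
    }
    structure(list(subjects = subjects, truth = truth, config = config),
              class = "synth_dataset")
  })
}

# one run's events (simulate_events() wraps this for all runs; kept separate
# so generate_dataset interleaves event and rating draws per run)
simulate_events_one <- function(config, r) {
  ev <- local({
    cfg1 <- config
    cfg1$n_runs <- 1L
    simulate_events(cfg1)[[1]]
  })
  ev$run <- r
  ev
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic dataset ('", x$config$design, "'): ",
      length(x$subjects), " subjects, ", x$config$n_runs,
      " runs each, ROI ", mask_count(x$truth$roi), " voxels\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes per-run NIfTI 4D series, tab-separated event and motion tables,
#' NIfTI ROI/sub-region masks and a JSON ground-truth manifest.
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mask(dataset$truth$roi, file.path(dir, "roi_mask.nii.gz"))
  for (nm in names(dataset$truth$subregions))
    write_mask(dataset$truth$subregions[[nm]],
               file.path(dir, paste0("roi_", nm, ".nii.gz")))
  for (s in dataset$subjects) {
    for (r in seq_along(s$runs)) {
      run <- s$runs[[r]]
      base <- file.path(dir, sprintf("%s_run%02d", s$id, r))
      write_series(run$series, paste0(base, "_bold.nii.gz"))
      ev <- run$events
      names(ev)[names(ev) == "onset"] <- "onset_s"
      utils::write.table(ev, paste0(base, "_events.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(run$motion, paste0(base, "_motion.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(design = dataset$config$design,
                     n_subjects = dataset$config$n_subjects,
                     tr = dataset$config$tr,
                     roi_voxels = mask_count(dataset$truth$roi),
                     pattern_centers = lapply(dataset$truth$centers, as.integer))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
               file.path(dir, "ground_truth.json"))
  }
  invisible(dir)
}
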