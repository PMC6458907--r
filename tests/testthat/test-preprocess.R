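make_series <- function(X, tr = 3, n = NULL) {
  # X: voxels x time for a cubic grid
  d <- round(nrow(X)^(1 / 3))
  stopifnot(d^3 == nrow(X))
  vol_series(array(X, c(d, d, d, ncol(X))), tr = tr)
}

test_that("detrend_zscore removes linear trends and standardizes", {
  set.seed(1)
  nt <- 40
  # pure ramps (different slopes/offsets) -> all zero after the variance guard
  X <- outer(seq_len(8^3), seq_len(nt), function(v, t) 0.5 * v + 0.1 * v * t)
  out <- detrend_zscore(make_series(X))
  expect_true(all(out$data == 0))
  # sinusoid + ramp matches a closed-form regression oracle
  t <- seq_len(nt)
  X <- matrix(0, 8^3, nt)
  for (v in 1:20) X[v, ] <- sin(t / 3 + v) + 0.2 * v * t + v
  out <- painpattern:::as_vxt(detrend_zscore(make_series(X)))
  for (v in 1:20) {
    fit <- lm.fit(cbind(1, t), X[v, ])
    want <- fit$residuals / sd(fit$residuals)
    expect_equal(out[v, ], want, tolerance = 1e-10)
  }
  # non-degenerate voxels: mean 0, sd 1
  X <- matrix(rnorm(8^3 * nt), 8^3, nt)
  out <- painpattern:::as_vxt(detrend_zscore(make_series(X)))
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-12)
})

test_that("motion regression leaves residuals orthogonal to the design", {
  set.seed(2)
  nt <- 30
  motion <- matrix(rnorm(nt * 6), nt, 6)
  X <- matrix(rnorm(8^3 * nt), 8^3, nt)
  out <- painpattern:::as_vxt(regress_out_motion(make_series(X), motion))
  # normal-equations oracle: residuals orthogonal to every column
  for (j in 1:6) expect_lt(max(abs(out %*% motion[, j])), 1e-7)
  expect_lt(max(abs(rowSums(out))), 1e-7)  # intercept too
  # series equal to a motion column -> zero residual
  X2 <- matrix(rep(motion[, 3], each = 8^3), 8^3, nt)
  out2 <- painpattern:::as_vxt(regress_out_motion(make_series(X2), motion))
  expect_lt(max(abs(out2)), 1e-10)
  # zero motion: unchanged except mean removal (collinear columns dropped)
  X3 <- matrix(rnorm(8^3 * nt), 8^3, nt)
  expect_warning(out3 <- regress_out_motion(make_series(X3),
                                            matrix(0, nt, 6)), "collinear")
  expect_equal(painpattern:::as_vxt(out3), X3 - rowMeans(X3), tolerance = 1e-10)
})

test_that("framewise displacement summary matches hand computation", {
  nt <- 20
  motion <- matrix(0, nt, 6)
  ev <- data.frame(onset = 9, modality = "pain")
  expect_equal(summarize_motion(motion, ev, "pain", tr = 3), 0)
  # a 1 mm step at volume 5 inside a window starting at volume 4
  motion[5:nt, 1] <- 1
  ev <- data.frame(onset = 9.5, modality = "pain")  # onset volume 4
  got <- summarize_motion(motion, ev, "pain", tr = 3, window_vols = 2)
  expect_equal(got, 1 / 2)   # FD = 1 at volume 5, 0 at volume 4
  # rotations scale by the 50 mm radius
  motion2 <- matrix(0, nt, 6)
  motion2[5:nt, 4] <- 0.01
  got2 <- summarize_motion(motion2, ev, "pain", tr = 3, window_vols = 2)
  expect_equal(got2, 0.01 * 50 / 2)
  expect_error(summarize_motion(motion, ev, "vision", tr = 3), "no events")
})

test_that("gaussian smoothing is identity at fwhm 0, mean-preserving, and matches direct convolution", {
  set.seed(3)
  s <- make_series(matrix(rnorm(8^3 * 2), 8^3, 2), tr = 1)
  expect_identical(gaussian_smooth(s, 0), s)
  sm <- gaussian_smooth(s, 6)
  expect_equal(mean(sm$data[, , , 1]), mean(s$data[, , , 1]), tolerance = 1e-9)
  # delta input reproduces the separable discretized Gaussian
  X <- matrix(0, 12^3, 1)
  ds <- vol_series(array(X, c(12, 12, 12, 1)), tr = 1, voxel_size = 2)
  ds$data[6, 6, 6, 1] <- 1
  fwhm <- 4
  sm <- gaussian_smooth(ds, fwhm)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / 2
  k <- painpattern:::gauss_kernel_1d(sigma_vox)
  half <- (length(k) - 1) / 2
  want <- outer(outer(k, k), k)
  got <- sm$data[(6 - half):(6 + half), (6 - half):(6 + half),
                 (6 - half):(6 + half), 1]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("peak-volume extraction uses floor(onset/tr) + offset", {
  nt <- 15
  d <- 8
  # encode the volume index in the signal so extraction is directly readable
  X <- matrix(rep(seq_len(nt), each = d^3), d^3, nt)
  s3 <- make_series(X, tr = 3)
  mask <- vol_mask(array(TRUE, c(d, d, d)))
  ev <- data.frame(onset = 10, modality = "pain")
  got <- extract_peak_samples(s3, ev, mask, peak_offset = 2)
  expect_equal(unique(as.vector(got$x)), 3 + 2 + 1)  # volume index 5, 1-based 6
  s08 <- make_series(X, tr = 0.8)
  ev <- data.frame(onset = 2.0, modality = "pain")
  got <- extract_peak_samples(s08, ev, mask, peak_offset = 8)
  expect_equal(unique(as.vector(got$x)), 2 + 8 + 1)  # volume index 10, 1-based 11
  # out-of-range events are skipped with a warning
  ev2 <- data.frame(onset = c(10, 44), modality = c("pain", "touch"))
  expect_warning(got2 <- extract_peak_samples(s3, ev2, mask, 2), "skipped")
  expect_equal(nrow(got2$x), 1)
})

test_that("noise-free peak samples recover the injected pattern", {
  cfg <- tiny_config(seed = 21, noise_sd = 0, subject_pattern_jitter_sd = 0,
                     shared_intensity_amplitude = 0,
                     modality_pattern_amplitude = c(pain = 2, touch = 1,
                                                    audition = 1, vision = 1),
                     motion_model = list(drift_sd = 0))
  ds <- generate_dataset(cfg)
  run <- ds$subjects[[1]]$runs[[1]]
  samp <- extract_peak_samples(run$series, run$events, ds$truth$roi, 2)
  pain_pat <- ds$truth$patterns$pain[ds$truth$roi$data]
  for (i in which(samp$meta$modality == "pain")) {
    v <- samp$x[i, ] - 100  # baseline
    expect_gt(cor(v[pain_pat > 0], pain_pat[pain_pat > 0]), 0.95)
  }
})

test_that("sample averaging satisfies the grand-mean identity", {
  set.seed(4)
  x <- matrix(rnorm(32 * 10), 32, 10)
  meta <- data.frame(modality = rep(c("pain", "touch"), each = 16),
                     run = rep(1:4, times = 8), subject = "s1")
  set <- sample_set(x, meta)
  by_run <- average_samples(set, by = c("modality", "run"))
  by_mod <- average_samples(by_run, by = "modality")
  grand <- average_samples(set, by = "modality")
  expect_equal(by_mod$x, grand$x, tolerance = 1e-12)
  # identity and cancellation
  one <- subset_samples(set, 1)
  expect_equal(average_samples(one, "modality")$x[1, ], x[1, ])
  pm <- sample_set(rbind(x[1, ], -x[1, ]),
                   data.frame(modality = c("a", "a")))
  expect_equal(as.vector(average_samples(pm, "modality")$x), rep(0, 10))
})

test_that("ROI normalization yields mean 0 sd 1, is idempotent and affine-invariant", {
  set.seed(5)
  x <- matrix(rnorm(6 * 50), 6, 50)
  set <- sample_set(x, data.frame(id = 1:6))
  nz <- roi_normalize(set)
  expect_lt(max(abs(rowMeans(nz$x))), 1e-9)
  expect_lt(max(abs(apply(nz$x, 1, sd) - 1)), 1e-9)
  expect_true(nz$normalized)
  expect_equal(roi_normalize(nz)$x, nz$x, tolerance = 1e-9)
  aff <- sample_set(3.2 * x + 7, data.frame(id = 1:6))
  expect_equal(roi_normalize(aff)$x, nz$x, tolerance = 1e-9)
  const <- sample_set(matrix(1, 2, 50), data.frame(id = 1:2))
  expect_error(roi_normalize(const), "constant")
})

test_that("time-course windows span the stated number of points", {
  nt <- 60
  X <- matrix(rep(seq_len(nt), each = 8^3), 8^3, nt)
  roi <- vol_mask(array(TRUE, c(8, 8, 8)))
  s3 <- make_series(X, tr = 3)
  ev <- data.frame(onset = c(30, 60), modality = "pain")
  tc <- extract_timecourses(s3, ev, roi, window = c(-1, 5))
  expect_equal(nrow(tc), 7)
  expect_equal(tc$rel_vol, -1:5)
  s08 <- make_series(X, tr = 0.8)
  ev2 <- data.frame(onset = c(8, 16), modality = "touch")
  tc2 <- extract_timecourses(s08, ev2, roi, window = c(-1, 15))
  expect_equal(nrow(tc2), 17)
  # constant series -> flat course, sd 0
  Xc <- matrix(5, 8^3, nt)
  tcc <- extract_timecourses(make_series(Xc, tr = 3), ev, roi, c(-1, 5))
  expect_true(all(tcc$mean == 5))
  expect_true(all(tcc$sd == 0))
  # no includable events
  ev3 <- data.frame(onset = 179, modality = "pain")
  expect_error(extract_timecourses(make_series(Xc, tr = 3), ev3, roi,
                                   c(-1, 5)), "window")
})
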