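separable_set <- function(n_subj = 10, p = 20, gap = 4, sd = 0.3, seed = 50) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_subj * p, sd = sd), 2 * n_subj, p)
  x[seq_len(n_subj), 1] <- x[seq_len(n_subj), 1] + gap
  toy_set(x, subject = rep(paste0("s", seq_len(n_subj)), 2),
          class = rep(c("pain", "touch"), each = n_subj))
}

test_that("perfectly separated subjects classify at accuracy 1 and match the QP reference per fold", {
  skip_if_not_installed("kernlab")
  set <- separable_set()
  fit <- loso_classify(set)
  expect_equal(fit$accuracy, 1)
  expect_equal(fit$accuracy, mean(fit$fold_accuracy))
  # fold-level equivalence against the independent QP margin classifier
  set.seed(51)
  x <- matrix(rnorm(8 * 3), 8, 3)
  small <- toy_set(x, subject = rep(paste0("s", 1:4), each = 2),
                   class = rep(c("pain", "touch"), 4))
  fit2 <- loso_classify(small)
  y <- ifelse(small$meta$class == "pain", 1, -1)
  for (f in seq_along(unique(small$meta$subject))) {
    te <- which(small$meta$subject == paste0("s", f))
    tr <- setdiff(1:8, te)
    ref <- ipop_svm(x[tr, , drop = FALSE], as.integer(y[tr] == 1))
    if (is.null(ref)) next
    ref_pred <- (x[te, , drop = FALSE] %*% ref$w + ref$b) >= 0
    expect_equal(unname(fit2$fold_accuracy[f]),
                 mean(ref_pred == (y[te] > 0)))
  }
})

test_that("accuracy is invariant to consistent voxel permutation and weights flip with labels", {
  set.seed(52)
  x <- matrix(rnorm(16 * 30), 16, 30)
  x[1:8, 1:5] <- x[1:8, 1:5] + 1
  set <- toy_set(x, subject = rep(paste0("s", 1:8), 2),
                 class = rep(c("pain", "touch"), each = 8))
  fit <- loso_classify(set)
  perm <- sample(30)
  setp <- toy_set(x[, perm], set$meta$subject, set$meta$class)
  fitp <- loso_classify(setp)
  expect_equal(fitp$accuracy, fit$accuracy)
  expect_equal(fitp$sensitivity, fit$sensitivity[perm], tolerance = 1e-8)
  # flipping the positive class flips every weight sign
  fit_neg <- loso_classify(set, positive = "touch")
  expect_equal(fit_neg$sensitivity, -fit$sensitivity, tolerance = 1e-8)
})

test_that("permutation p-value conventions match the reporting rules", {
  pp <- painpattern:::perm_pvalue
  expect_equal(pp(c(0.4, 0.5, 0.6), 0.55)$p, 1 / 3)
  expect_equal(pp(c(0.4, 0.5, 0.6), 0.4)$p, 1)        # observed = min null
  expect_false(pp(c(0.4, 0.5, 0.6), 0.4)$floored)
  z <- pp(rep(0.4, 5000), 0.9)
  expect_equal(z$p, 0.0002)
  expect_true(z$floored)
  expect_equal(pp(c(0.4, 0.5), 0.9, "plus_one")$p, 1 / 3)
})

test_that("a strong signal yields a floored p and the null is seed-deterministic", {
  set <- separable_set()
  fit <- loso_classify(set, n_perm = 200, seed = 9)
  expect_equal(fit$p, 1 / 200)
  expect_true(fit$p_floored)
  expect_length(fit$null, 200)
  fit2 <- loso_classify(set, n_perm = 200, seed = 9)
  expect_identical(fit$null, fit2$null)
  expect_identical(fit$p, fit2$p)
  fit3 <- loso_classify(set, n_perm = 200, seed = 10)
  expect_false(identical(fit$null, fit3$null))
})

test_that("permutation p-values are calibrated on signal-free samples", {
  # pure-noise toy samples (no imaging pipeline): p <= 0.05 in at most
  # 5% + 99% binomial margin of replicates, and accuracy centers on 0.5
  set.seed(53)
  n_rep <- 200
  res <- replicate(n_rep, {
    x <- matrix(rnorm(24 * 30), 24, 30)
    set <- toy_set(x, subject = rep(paste0("s", 1:12), 2),
                   class = rep(c("pain", "touch"), each = 12))
    fit <- loso_classify(set, n_perm = 100, seed = sample.int(1e6, 1))
    c(fit$accuracy, fit$p)
  })
  expect_lt(abs(mean(res[1, ]) - 0.5), 3 * sd(res[1, ]) / sqrt(n_rep))
  margin <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(res[2, ] <= 0.05), 0.05 + margin)
})

test_that("errors: single-class training data and too few subjects", {
  x <- matrix(rnorm(8), 4, 2)
  one_class <- toy_set(x, subject = paste0("s", 1:4), class = rep("pain", 4))
  expect_error(loso_classify(one_class), "two classes")
  two_subj <- toy_set(x, subject = rep(c("s1", "s2"), each = 2),
                      class = rep(c("pain", "touch"), 2))
  expect_warning(fit <- loso_classify(two_subj), "unstable")
  expect_length(fit$fold_accuracy, 2)
})

test_that("sensitivity maps average fold weights and map back to the volume", {
  set <- separable_set(n_subj = 6, p = 4)
  mask <- vol_mask(array(c(rep(TRUE, 4), rep(FALSE, 8^3 - 4)), c(8, 8, 8)))
  set$mask <- mask
  fit <- loso_classify(set)
  expect_equal(fit$sensitivity, colMeans(fit$weights))
  sm <- sensitivity_map(fit)
  expect_length(sm$values, 4)
  vol <- as_volume(sm)
  expect_equal(dim(vol), c(8, 8, 8))
  expect_equal(vol[which(mask$data)], sm$values)
  expect_equal(sum(vol != 0), sum(sm$values != 0))
  expect_error(sensitivity_map(fit, random_mask(8, 0.5, seed = 1)), "count")
})

test_that("consistent-sign maps keep same-sign voxels with averaged weights", {
  m1 <- c(1, -1, 2, 0.5)
  m2 <- c(3, 1, -1, 0.7)
  out <- consistent_sign_map(list(m1, m2))
  expect_equal(out$values, c(2, 0, 0, 0.6))
  # element-wise oracle on random maps
  set.seed(54)
  maps <- replicate(3, rnorm(50), simplify = FALSE)
  got <- consistent_sign_map(maps)$values
  M <- do.call(rbind, maps)
  same <- apply(M > 0, 2, all) | apply(M < 0, 2, all)
  expect_equal(got != 0, same)
  expect_equal(got[same], colMeans(M)[same])
})

test_that("median split assigns above-median to high, ties to low", {
  x <- matrix(0, 56, 1)
  set <- sample_set(x, data.frame(modality = rep("pain", 56), rating = 1:56))
  sp <- median_split_classes(set)
  expect_equal(sum(sp$meta$class == "high"), 28)
  expect_equal(sum(sp$meta$class == "low"), 28)
  # tie at the median goes low
  set2 <- sample_set(matrix(0, 5, 1),
                     data.frame(modality = "a", rating = c(1, 2, 3, 3, 9)))
  sp2 <- median_split_classes(set2)
  expect_equal(sp2$meta$class, c("low", "low", "low", "low", "high"))
  const <- sample_set(matrix(0, 4, 1), data.frame(rating = rep(2, 4)))
  expect_error(median_split_classes(const), "degenerate")
})

test_that("modality balancing removes boundary samples from the larger class", {
  # high {m: 3}, low {m: 1}: keep 1 per class, dropping the 2 lowest-rated
  # high samples
  set <- sample_set(matrix(0, 4, 1),
                    data.frame(modality = "m",
                               class = c("high", "high", "high", "low"),
                               rating = c(7, 5, 6, 2)))
  bal <- balance_classes_by_modality(set)
  expect_equal(nrow(bal$x), 2)
  expect_equal(bal$meta$rating[bal$meta$class == "high"], 7)
  # modality in a single class is dropped with a warning
  set2 <- sample_set(matrix(0, 3, 1),
                     data.frame(modality = c("m", "m", "q"),
                                class = c("high", "low", "high"),
                                rating = c(6, 2, 9)))
  expect_warning(bal2 <- balance_classes_by_modality(set2), "dropped")
  expect_equal(nrow(bal2$x), 2)
  # already balanced sets pass through unchanged
  expect_silent(bal3 <- balance_classes_by_modality(subset_samples(set, c(1, 4))))
  expect_equal(nrow(bal3$x), 2)
})

test_that("cross-dataset classification enforces normalization and transfers shared patterns", {
  set.seed(55)
  # shared discriminative direction between train and test
  w_true <- rnorm(40)
  mk <- function(n_subj, seed) {
    set.seed(seed)
    x <- matrix(rnorm(2 * n_subj * 40), 2 * n_subj, 40)
    cls <- rep(c("pain", "touch"), each = n_subj)
    x[cls == "pain", ] <- x[cls == "pain", ] + 1.5 * rep(w_true, each = n_subj)
    toy_set(x, subject = rep(paste0("s", seq_len(n_subj)), 2), class = cls)
  }
  train <- roi_normalize(mk(10, 1)); test <- roi_normalize(mk(8, 2))
  fit <- cross_dataset_classify(train, test, n_perm = 100, seed = 1)
  expect_gt(fit$accuracy, 0.9)
  expect_equal(fit$p, 1 / 100)
  # un-normalized inputs are rejected
  expect_error(cross_dataset_classify(mk(10, 1), test), "normalize")
  expect_error(cross_dataset_classify(train, mk(8, 2)), "normalize")
})

test_that("trial-level high/low collapse discards single-class subjects", {
  # 6 subjects x 2 modalities x 4 trials; subject s6 rated everything at the
  # top of the scale and so contributes to a single class
  meta <- expand.grid(trial = 1:4, modality = c("pain", "touch"),
                      subject = paste0("s", 1:6), stringsAsFactors = FALSE)
  meta$rating <- rep(c(1, 2, 8, 9), length.out = nrow(meta))
  meta$rating[meta$subject == "s6"] <- 9.5
  set <- sample_set(matrix(rnorm(nrow(meta) * 3), nrow(meta), 3), meta)
  sp <- median_split_classes(set)
  expect_message(cl <- collapse_high_low(sp), "s6")
  expect_equal(nrow(cl$x), 5 * 2 * 2)  # 5 subjects x 2 modalities x 2 classes
  expect_true(all(table(cl$meta$class) == 10))
})
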