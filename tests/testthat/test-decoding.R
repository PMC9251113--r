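test_that("block binning reduces maps with edge handling and NA awareness", {
  # the standard camera frame reduces 10-fold to 131 x 108
  big <- matrix(0, 1308, 1080)
  expect_equal(dim(bin_map(big, 10)), c(131, 108))
  expect_equal(dim(bin_map(matrix(0, 100, 100), 10)), c(10, 10))

  # hand-computed 2x2 block means on a 4x4 map
  m <- matrix(1:16, 4, 4)
  b <- bin_map(m, 2)
  expect_equal(b, rbind(c(mean(c(1, 2, 5, 6)), mean(c(9, 10, 13, 14))),
                        c(mean(c(3, 4, 7, 8)), mean(c(11, 12, 15, 16)))))

  # partial edge blocks average over available pixels
  m2 <- matrix(1, 5, 5)
  m2[5, ] <- 11
  b2 <- bin_map(m2, 2)
  expect_equal(dim(b2), c(3, 3))
  expect_equal(b2[3, 1], mean(c(11, 11)))

  # NA pixels excluded from block means; all-NA block invalid
  m3 <- matrix(1, 4, 4)
  m3[1, 1] <- NA
  m3[3:4, 3:4] <- NA
  b3 <- bin_map(m3, 2)
  expect_equal(b3[1, 1], 1)
  expect_true(is.na(b3[2, 2]))

  # response_map input: pitch scales by the factor
  rm <- response_map(matrix(0, 40, 40), pixel_pitch = 8)
  expect_equal(bin_map(rm, 10)$pixel_pitch, 80)
})

# small labeled feature construction: class-dependent mean at a few bins
toy_maps <- function(n_per_class, classes = dkl_hue_angles(), amp = 1,
                     dim = 20, seed = 1) {
  set.seed(seed)
  labels <- rep(classes, each = n_per_class)
  maps <- lapply(seq_along(labels), function(i) {
    m <- matrix(rnorm(dim^2), dim)
    k <- match(labels[i], classes)
    m[((k - 1) %% dim) + 1, ((k * 3) %% dim) + 1] <- amp * 5
    m
  })
  list(maps = maps, labels = labels)
}

test_that("feature matrices are z-normalized under both schemes", {
  tm <- toy_maps(6, amp = 1)
  fm <- make_features(tm$maps, tm$labels, factor = 2)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(unname(colMeans(fm$X)), rep(0, ncol(fm$X)))
  expect_equal(unname(apply(fm$X, 2, sd)), rep(1, ncol(fm$X)))
  fm2 <- make_features(tm$maps, tm$labels, factor = 2,
                       normalization = "per_stimulus")
  for (l in levels(fm2$y)) {
    expect_equal(max(abs(colMeans(fm2$X[fm2$y == l, ]))), 0,
                 tolerance = 1e-12)
  }
  # pooled scheme preserves class-mean differences at planted bins
  cm <- vapply(levels(fm$y), function(l) colMeans(fm$X[fm$y == l, ]),
               numeric(ncol(fm$X)))
  expect_gt(max(apply(cm, 1, function(r) diff(range(r)))), 1)
})

test_that("constant features are dropped and ROI selects bins", {
  maps <- replicate(8, matrix(rnorm(64), 8), simplify = FALSE)
  for (i in seq_along(maps)) maps[[i]][1:2, 1:2] <- 7  # constant block
  expect_message(fm <- make_features(maps, rep(c("a", "b"), 4), factor = 2),
                 "dropped")
  expect_equal(ncol(fm$X), 15)
  # ROI on the original grid keeps only overlapping bins
  roi <- matrix(FALSE, 8, 8); roi[5:8, 5:8] <- TRUE
  fm2 <- make_features(lapply(maps, function(m) m + matrix(rnorm(64), 8)),
                       rep(c("a", "b"), 4), roi = roi, factor = 2)
  expect_equal(ncol(fm2$X), 4)
  expect_true(all(fm2$coords$bin_row >= 3 & fm2$coords$bin_col >= 3))
})

test_that("trial balancing downsamples to the smallest class", {
  tm <- toy_maps(6)
  fm <- make_features(tm$maps, tm$labels, factor = 4)
  # drop one trial of the last class -> everyone comes down to 5
  keep <- seq_len(nrow(fm$X) - 1)
  fm$X <- fm$X[keep, ]; fm$y <- droplevels(fm$y[keep])
  bal <- balance_trials(fm, seed = 4)
  expect_equal(as.numeric(table(bal$y)), rep(5, 8))
  bal2 <- balance_trials(fm, seed = 4)
  expect_identical(bal$X, bal2$X)
  # already balanced -> untouched
  fm0 <- make_features(tm$maps, tm$labels, factor = 4)
  expect_equal(nrow(balance_trials(fm0, 1)$X), nrow(fm0$X))
})

test_that("feature subsampling is seeded and order does not affect accuracy", {
  tm <- toy_maps(6, amp = 2)
  fm <- make_features(tm$maps, tm$labels, factor = 2)
  sub <- subsample_features(fm, 20, seed = 2)
  expect_equal(ncol(sub$X), 20)
  expect_identical(subsample_features(fm, 20, seed = 2)$coords, sub$coords)
  expect_error(subsample_features(fm, 1e5, 1), "exceeds")
  acc1 <- cv_accuracy(fm, k = 3, seed = 5)$overall_accuracy
  perm <- sample(ncol(fm$X))
  fmp <- fm; fmp$X <- fm$X[, perm]; fmp$coords <- fm$coords[perm, ]
  acc2 <- cv_accuracy(fmp, k = 3, seed = 5)$overall_accuracy
  expect_equal(acc1, acc2)
})

test_that("cross-validated accuracy is perfect on separable classes", {
  # widely separated one-hot class means: linearly separable by construction
  set.seed(21)
  y <- factor(rep(dkl_hue_angles(), each = 12))
  X <- 10 * diag(8)[as.integer(y), ] + matrix(rnorm(96 * 8, 0, 0.1), 96)
  fm <- structure(list(X = cbind(X, matrix(rnorm(96 * 8), 96)), y = y,
                       coords = data.frame(bin_row = 1:16, bin_col = 1),
                       factor = 1, normalization = "pooled"),
                  class = "feature_matrix")
  res <- cv_accuracy(fm, k = 10, seed = 1)
  expect_equal(res$overall_accuracy, 1.0)
  expect_equal(unname(res$per_class_accuracy), rep(1, 8))
  expect_equal(res$chance, 1 / 8)
  # per-class accuracies average to the overall accuracy (balanced classes)
  expect_equal(mean(res$per_class_accuracy), res$overall_accuracy)
  expect_error(cv_accuracy(fm, k = 13), "smaller k")

  # the same holds end to end through map binning at high SNR
  tm <- toy_maps(10, amp = 8, dim = 12)
  fm2 <- make_features(tm$maps, tm$labels, factor = 2)
  expect_gt(cv_accuracy(fm2, k = 5, seed = 1)$overall_accuracy, 0.9)
})

test_that("label-shuffled decoding sits at chance", {
  tm <- toy_maps(5, amp = 3, dim = 12)
  fm <- make_features(tm$maps, tm$labels, factor = 2)
  accs <- vapply(1:12, function(s) {
    set.seed(100 + s)
    fs <- fm
    fs$y <- factor(sample(as.character(fm$y)), levels = levels(fm$y))
    cv_accuracy(fs, k = 5, seed = s)$overall_accuracy
  }, numeric(1))
  # consistent with 12.5% chance: one-sample t test at alpha 0.01
  tt <- t.test(accs, mu = 1 / 8)
  expect_gt(tt$p.value, 0.01)
})

test_that("bootstrap inference floors p and calibrates under the null", {
  # perfectly predictive single feature: every resample classifies the
  # test set perfectly, p hits the 1/B floor
  y <- factor(rep(c("a", "b"), each = 10))
  X <- matrix(ifelse(y == "a", -1, 1) + rnorm(20, 0, 1e-3), ncol = 1)
  bt <- bootstrap_accuracy(X, y, X, y, B = 100, seed = 1)
  expect_equal(bt$samples, rep(1, 100))
  expect_equal(bt$p_vs_chance, 1 / 100)
  expect_equal(bt$ci_95, c(1, 1))
  expect_equal(bt$chance, 0.5)

  # null features: p rarely small
  set.seed(9)
  p_small <- 0
  for (r in 1:10) {
    Xn <- matrix(rnorm(40 * 5), 40)
    yn <- factor(rep(c("a", "b"), 20))
    btn <- bootstrap_accuracy(Xn[1:32, ], yn[1:32], Xn[33:40, ], yn[33:40],
                              B = 120, seed = r)
    if (btn$p_vs_chance < 0.05) p_small <- p_small + 1
  }
  expect_lte(p_small, 2)
})

test_that("area comparison implements the 97.5% non-overlap rule", {
  set.seed(10)
  a <- rnorm(1000, 0.5, 0.02)
  expect_false(compare_areas(a, a)$significant)
  b <- a + 1  # disjoint supports
  cmp <- compare_areas(a, b)
  expect_true(cmp$significant)
  expect_equal(cmp$higher, "b")
  # boundary case agrees with the direct percentile computation
  for (shift in c(0.03, 0.06, 0.09, 0.12)) {
    d <- rnorm(1000, 0.5 + shift, 0.02)
    cmp2 <- compare_areas(a, d)
    expect_equal(cmp2$significant,
                 unname(quantile(d, 0.025) > quantile(a, 0.975)))
  }
})
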