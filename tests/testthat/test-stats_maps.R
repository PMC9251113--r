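test_that("pixel-wise t statistics match t.test at every pixel", {
  set.seed(1)
  A <- replicate(6, matrix(rnorm(9), 3), simplify = FALSE)
  B <- replicate(8, matrix(rnorm(9, 0.5), 3), simplify = FALSE)
  for (ve in c(TRUE, FALSE)) {
    sm <- pixelwise_ttest(A, B, var_equal = ve, pixel_pitch = 8)
    for (i in 1:3) for (j in 1:3) {
      o <- t.test(vapply(A, `[`, 0, i, j), vapply(B, `[`, 0, i, j),
                  var.equal = ve)
      expect_equal(sm$stat[i, j], unname(o$statistic))
      expect_equal(sm$p[i, j], o$p.value)
    }
  }
  expect_error(pixelwise_ttest(A[1], B), ">= 2 trials")
})

test_that("degenerate pixels are flagged invalid, not significant", {
  A <- replicate(3, matrix(1, 2, 2), simplify = FALSE)
  B <- replicate(3, matrix(2, 2, 2), simplify = FALSE)
  sm <- pixelwise_ttest(A, B)  # zero variance everywhere
  expect_true(all(is.na(sm$p)))
  # NA trials poison only their pixel
  A2 <- replicate(4, matrix(rnorm(4), 2), simplify = FALSE)
  B2 <- replicate(4, matrix(rnorm(4), 2), simplify = FALSE)
  A2[[2]][1, 1] <- NA
  sm2 <- pixelwise_ttest(A2, B2)
  expect_true(is.na(sm2$p[1, 1]))
  expect_false(anyNA(sm2$p[-1, ]))
})

test_that("one-way ANOVA matches aov and detects a shifted level", {
  set.seed(2)
  f <- rep(c("a", "b", "c"), each = 5)
  trials <- lapply(seq_along(f), function(i)
    matrix(rnorm(4, ifelse(f[i] == "c", 0.8, 0)), 2))
  sm <- pixelwise_anova(trials, f, pixel_pitch = 8)
  for (i in 1:2) for (j in 1:2) {
    y <- vapply(trials, `[`, 0, i, j)
    o <- summary(aov(y ~ factor(f)))[[1]]
    expect_equal(sm$stat[i, j], o$`F value`[1], tolerance = 1e-10)
    expect_equal(sm$p[i, j], o$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_equal(sm$df, c(2, 12))
})

test_that("two-way ANOVA separates hue and orientation main effects", {
  set.seed(3)
  grid <- expand.grid(hue = c(0, 90, 180, 270), ori = c(0, 90),
                      rep = 1:6)
  # pure orientation effect at pixel (1,1); pure hue effect at (2,2)
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    m <- matrix(rnorm(4), 2)
    m[1, 1] <- m[1, 1] + ifelse(grid$ori[i] == 90, 3, 0)
    m[2, 2] <- m[2, 2] + ifelse(grid$hue[i] == 90, 3, 0)
    m
  })
  out <- pixelwise_anova(trials, grid$hue, grid$ori, pixel_pitch = 8)
  # cross-check against aov main-effect rows (balanced design)
  y <- vapply(trials, `[`, 0, 1, 1)
  o <- summary(aov(y ~ factor(grid$hue) * factor(grid$ori)))[[1]]
  expect_equal(out$f1$stat[1, 1], o$`F value`[1], tolerance = 1e-10)
  expect_equal(out$f2$stat[1, 1], o$`F value`[2], tolerance = 1e-10)
  expect_equal(out$f2$p[1, 1], o$`Pr(>F)`[2], tolerance = 1e-10)
  # orientation pixel: strong orientation effect, unremarkable hue effect
  expect_lt(out$f2$p[1, 1], 1e-6)
  expect_gt(out$f1$p[1, 1], 0.01)
  # hue pixel: the reverse
  expect_lt(out$f1$p[2, 2], 1e-6)
  expect_gt(out$f2$p[2, 2], 0.01)
  expect_error(pixelwise_anova(trials[-1], grid$hue[-1], grid$ori[-1]),
               "balanced")
})

test_that("null p-values are uniform (KS) and planted effects are detected", {
  set.seed(4)
  A <- replicate(12, matrix(rnorm(1e4), 100), simplify = FALSE)
  B <- replicate(12, matrix(rnorm(1e4), 100), simplify = FALSE)
  p <- pixelwise_ttest(A, B)$p
  expect_gt(ks.test(as.vector(p), "punif")$p.value, 0.01)
  # 5 SD planted effect -> overwhelming significance
  A5 <- lapply(A, function(m) { m[1:10, 1:10] <- m[1:10, 1:10] + 5; m })
  p5 <- pixelwise_ttest(A5, B)$p
  expect_lt(max(p5[1:10, 1:10]), 1e-6)
})

test_that("vessel variance rule excludes ~alpha under homogeneity", {
  set.seed(5)
  blanks <- replicate(40, matrix(rnorm(256^2), 256), simplify = FALSE)
  vm <- vessel_mask(blanks, alpha = 0.05)
  frac <- mean(!vm$valid)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 256^2)
  expect_lt(abs(frac - 0.05), ci + 0.002)  # binomial 99% CI + median jitter
  expect_true(all(vm$reason[!vm$valid] == "vessel"))
})

test_that("vessel variance rule catches 3x-SD pixels and spares constants", {
  set.seed(6)
  vessel <- matrix(FALSE, 64, 64); vessel[20:22, ] <- TRUE
  blanks <- replicate(40, {
    m <- matrix(rnorm(64^2), 64)
    m[vessel] <- m[vessel] * 3
    m
  }, simplify = FALSE)
  vm <- vessel_mask(blanks)
  expect_equal(mean(!vm$valid[vessel]), 1)        # all vessels excluded
  expect_lt(mean(!vm$valid[!vessel]), 0.10)       # background near alpha
  # all-zero-variance field: nothing excluded
  vm0 <- vessel_mask(replicate(12, matrix(1, 4, 4), simplify = FALSE))
  expect_true(all(vm0$valid))
  expect_error(vessel_mask(list(matrix(1, 2, 2))), ">= 2")
})

test_that("inflating an above-median pixel variance never un-excludes others", {
  set.seed(7)
  blanks <- replicate(20, matrix(rnorm(30^2), 30), simplify = FALSE)
  vm1 <- vessel_mask(blanks)
  # pick an already-excluded (above-threshold, hence above-median) pixel
  target <- which(!vm1$valid)[1]
  blanks2 <- lapply(seq_along(blanks), function(i) {
    m <- blanks[[i]]
    m[target] <- m[target] * 10
    m
  })
  vm2 <- vessel_mask(blanks2)
  expect_true(all(vm2$valid[-target] == vm1$valid[-target]))
  expect_false(vm2$valid[target])
})

test_that("masks compose by logical AND with first-reason wins", {
  a <- pixel_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2), "vessel")
  b <- pixel_mask(matrix(c(TRUE, TRUE, FALSE, TRUE), 2), "user")
  m <- combine_masks(a, b)
  expect_equal(m$valid, matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
  expect_equal(m$reason[2, 1], "vessel")
  expect_equal(m$reason[1, 2], "user")
})

test_that("cluster-extent rule enforces size, peak and reproduction", {
  p <- matrix(0.5, 64, 64)
  blob <- as.matrix(expand.grid(10:27, 10:27))   # 324 px
  p[blob] <- 0.01
  p[15, 15] <- 1e-4
  pr <- matrix(0.5, 64, 64)
  pr[as.matrix(expand.grid(20:37, 20:37))] <- 0.01
  pr[25, 25] <- 1e-4
  rs <- cluster_extent_threshold(manual_stat_map(p), manual_stat_map(pr))
  expect_equal(nrow(rs$table), 1)
  expect_equal(rs$table$n_pixels, 324)
  expect_equal(rs$table$min_p, 1e-4)
  expect_equal(c(rs$table$peak_row, rs$table$peak_col), c(15, 15))
  expect_true(rs$table$reproduced)

  # too small (150 px) -> rejected even with a strong peak
  p2 <- matrix(0.5, 64, 64)
  p2[as.matrix(expand.grid(10:24, 10:19))] <- 0.01  # 150 px
  p2[12, 12] <- 1e-5
  expect_equal(nrow(cluster_extent_threshold(manual_stat_map(p2),
                                             manual_stat_map(p2))$table), 0)

  # no peak below peak_alpha -> rejected
  p3 <- matrix(0.5, 64, 64)
  p3[blob] <- 0.01
  expect_equal(nrow(cluster_extent_threshold(manual_stat_map(p3),
                                             manual_stat_map(p3))$table), 0)

  # no overlap with a qualifying region in the other session -> rejected
  pr2 <- matrix(0.5, 64, 64)
  pr2[as.matrix(expand.grid(40:57, 40:57))] <- 0.01
  pr2[45, 45] <- 1e-4
  expect_equal(nrow(cluster_extent_threshold(manual_stat_map(p),
                                             manual_stat_map(pr2))$table), 0)

  # masked pixels cannot join a region
  mask <- pixel_mask(matrix(TRUE, 64, 64))
  mask$valid[10:27, 18] <- FALSE   # cut the blob in two
  rs2 <- cluster_extent_threshold(manual_stat_map(p), manual_stat_map(pr),
                                  mask = mask)
  expect_true(all(rs2$table$n_pixels < 324))

  expect_error(cluster_extent_threshold(manual_stat_map(p),
                                        manual_stat_map(p[1:32, ])),
               "mismatch")
})

test_that("regions use 8-connectivity and extent scales with pixel pitch", {
  # diagonal chain: connected under 8- but not 4-connectivity
  p <- matrix(0.5, 40, 40)
  for (k in 0:19) p[10 + k, 10 + k] <- 0.01
  for (k in 0:18) p[11 + k, 10 + k] <- 0.01   # 39 px, diagonal band
  p[15, 15] <- 1e-4
  sm <- manual_stat_map(p, pixel_pitch = 8)
  rs <- cluster_extent_threshold(sm, sm, min_pixels = 30)
  expect_equal(nrow(rs$table), 1)
  expect_equal(rs$table$n_pixels, 39)
  # at 16 um pitch the same 39-px band meets a 140-original-px rule
  # (140 * (8/16)^2 = 35 px)
  sm16 <- manual_stat_map(p, pixel_pitch = 16)
  expect_equal(nrow(cluster_extent_threshold(sm16, sm16,
                                             min_pixels = 140)$table), 1)
  expect_equal(nrow(cluster_extent_threshold(sm, sm,
                                             min_pixels = 140)$table), 0)
})

test_that("relaxing alpha or min_pixels never removes a surviving region", {
  # deterministic case: a qualifying blob survives any relaxation
  pd <- matrix(0.5, 64, 64)
  pd[as.matrix(expand.grid(10:27, 10:27))] <- 0.03
  pd[15, 15] <- 1e-4
  base <- cluster_extent_threshold(manual_stat_map(pd), manual_stat_map(pd),
                                   min_pixels = 200)
  expect_equal(nrow(base$table), 1)
  for (rel in list(c(0.10, 200), c(0.05, 100))) {
    r <- cluster_extent_threshold(manual_stat_map(pd), manual_stat_map(pd),
                                  alpha = rel[1], min_pixels = rel[2])
    expect_true(all(r$labels[base$labels > 0] > 0))
  }
  set.seed(8)
  for (rep in 1:5) {
    z <- matrix(rnorm(48^2), 48)
    z <- smooth_map(z, 24, pixel_pitch = 8)  # correlate mildly
    p1 <- 2 * pnorm(-abs(z / sd(z)))
    z2 <- matrix(rnorm(48^2), 48)
    z2 <- smooth_map(z2, 24, pixel_pitch = 8)
    p2 <- 2 * pnorm(-abs(z2 / sd(z2)))
    strict <- cluster_extent_threshold(manual_stat_map(p1),
                                       manual_stat_map(p2),
                                       alpha = 0.05, peak_alpha = 0.05,
                                       min_pixels = 40)
    for (relaxed in list(
      cluster_extent_threshold(manual_stat_map(p1), manual_stat_map(p2),
                               alpha = 0.10, peak_alpha = 0.05,
                               min_pixels = 40),
      cluster_extent_threshold(manual_stat_map(p1), manual_stat_map(p2),
                               alpha = 0.05, peak_alpha = 0.05,
                               min_pixels = 20))) {
      if (nrow(strict$table) > 0) {
        # every strict surviving pixel set is covered by relaxed regions
        expect_true(all(relaxed$labels[strict$labels > 0] > 0))
      }
    }
  }
})
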