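test_that("equivalent diameter inverts the circle area", {
  expect_equal(equivalent_diameter(pi * 42^2), 84)
  expect_equal(equivalent_diameter(7853.98), 100, tolerance = 1e-5)
  expect_equal(equivalent_diameter(0), 0)
  expect_error(equivalent_diameter(-1), ">= 0")
  # pixel-count areas of rasterized disks agree with the analytic circle
  # within 5% for radii >= 5 px
  for (r in c(5, 7.5, 10, 12)) {
    n_px <- disk_pixel_count(r)
    expect_lt(abs(equivalent_diameter(n_px) - 2 * r) / (2 * r), 0.05)
  }
})

test_that("domains are extracted per region with vessel exclusion", {
  labels <- matrix(0L, 40, 40)
  labels[5:14, 5:14] <- 1L     # 100 px
  labels[25:30, 25:30] <- 2L   # 36 px
  tab <- data.frame(region_id = 1:2, n_pixels = c(100L, 36L),
                    min_p = c(1e-4, 1e-5), peak_row = c(7L, 27L),
                    peak_col = c(7L, 27L))
  rs <- structure(list(labels = labels, table = tab), class = "region_set")
  ds <- extract_domains(list("0" = rs), pixel_pitch = 8)
  expect_equal(nrow(ds$domains), 2)
  expect_equal(ds$domains$area_um2, c(100, 36) * 64)
  expect_equal(ds$domains$equiv_diam_um,
               equivalent_diameter(c(100, 36) * 64))
  expect_equal(ds$domains$hue_deg, c(0, 0))
  # region touching an invalid (vessel) pixel is dropped
  vm <- pixel_mask(matrix(TRUE, 40, 40))
  vm$valid[27, 27] <- FALSE
  ds2 <- extract_domains(list("0" = rs), vessel = vm, pixel_pitch = 8)
  expect_equal(nrow(ds2$domains), 1)
  expect_equal(ds2$domains$n_pixels, 100)
  # empty region set -> empty result
  empty <- structure(list(labels = matrix(0L, 40, 40),
                          table = tab[0, ]), class = "region_set")
  expect_equal(nrow(extract_domains(list("0" = empty),
                                    pixel_pitch = 8)$domains), 0)
})

# helper: horizontal chain of overlapping 5x5 squares, one per hue
chain_pixels <- function(hues, row0 = 10, col0 = 5, step = 3, dim = c(40, 60)) {
  lapply(seq_along(hues), function(k) {
    g <- expand.grid(r = row0:(row0 + 4),
                     c = (col0 + (k - 1) * step):(col0 + (k - 1) * step + 4))
    (g$c - 1) * dim[1] + g$r
  })
}

test_that("clusters assemble from overlap chains with the 4-hue rule", {
  hues8 <- dkl_hue_angles()
  ds <- manual_domain_set(chain_pixels(hues8), hues8, dim = c(40, 60))
  cs <- build_clusters(ds)
  expect_equal(nrow(cs$clusters), 1)
  expect_true(cs$clusters$complete)
  expect_equal(cs$clusters$n_hues, 8)
  expect_equal(cs$clusters$n_domains, 8)

  # two disjoint 4-hue chains -> two incomplete clusters
  px <- c(chain_pixels(1:4, row0 = 5), chain_pixels(1:4, row0 = 30))
  ds2 <- manual_domain_set(px, rep(c(0, 45, 90, 135), 2), dim = c(40, 60))
  cs2 <- build_clusters(ds2)
  expect_equal(nrow(cs2$clusters), 2)
  expect_equal(cs2$clusters$complete, c(FALSE, FALSE))

  # a 3-hue chain is not a cluster
  ds3 <- manual_domain_set(chain_pixels(1:3), c(0, 45, 90), dim = c(40, 60))
  cs3 <- build_clusters(ds3)
  expect_equal(nrow(cs3$clusters), 0)
  expect_true(all(is.na(cs3$membership$cluster_id)))
})

test_that("cluster assembly is invariant to domain order", {
  hues8 <- dkl_hue_angles()
  px <- c(chain_pixels(hues8, row0 = 5),
          chain_pixels(1:5, row0 = 30))
  hues <- c(hues8, c(0, 45, 90, 135, 180))
  perm <- c(9, 3, 12, 1, 7, 11, 5, 13, 2, 10, 6, 4, 8)
  ds_a <- manual_domain_set(px, hues, dim = c(40, 60))
  ds_b <- manual_domain_set(px[perm], hues[perm], dim = c(40, 60))
  ca <- build_clusters(ds_a)
  cb <- build_clusters(ds_b)
  sig <- function(cs) {
    m <- merge(cs$membership, cs$domain_set$domains, by = "domain_id")
    m <- m[!is.na(m$cluster_id), ]
    sort(vapply(split(m, m$cluster_id), function(g)
      paste(sort(paste(g$hue_deg, g$n_pixels)), collapse = "|"),
      character(1)))
  }
  expect_equal(unname(sig(ca)), unname(sig(cb)))
  expect_equal(sort(ca$clusters$n_hues), sort(cb$clusters$n_hues))
})

test_that("cluster area is the union footprint, normalized areas in (0,1]", {
  # two fully overlapping domains: each normalized area 1
  g <- expand.grid(r = 1:10, c = 1:10)
  px <- (g$c - 1) * 40 + g$r
  ds <- manual_domain_set(list(px, px, px, px), c(0, 45, 90, 135))
  cs <- build_clusters(ds)
  expect_equal(cs$clusters$n_pixels, 100)
  na <- normalized_domain_area(cs)
  expect_equal(na$normalized_area, rep(1, 4))

  # half-union domain: 0.5
  g2 <- expand.grid(r = 1:10, c = 6:15)
  px2 <- (g2$c - 1) * 40 + g2$r
  ds2 <- manual_domain_set(list(px, px2, px, px2), c(0, 45, 90, 135))
  cs2 <- build_clusters(ds2)
  expect_equal(cs2$clusters$n_pixels, 150)
  na2 <- normalized_domain_area(cs2)
  expect_equal(na2$normalized_area, rep(100 / 150, 4))
  # member areas sum to >= the union
  expect_gte(sum(na2$area_um2), cs2$clusters$area_um2)
})

test_that("completeness percentages reproduce the printed summaries", {
  mk <- function(n, inc) data.frame(complete = rep(c(FALSE, TRUE),
                                                   c(inc, n - inc)))
  expect_equal(completeness_summary(mk(136, 30))$pct_incomplete, 22.1)
  expect_equal(completeness_summary(mk(72, 7))$pct_incomplete, 9.7)
  expect_equal(completeness_summary(mk(240, 30))$pct_incomplete, 12.5)
  expect_equal(completeness_summary(mk(10, 0))$pct_incomplete, 0)
  tab <- rbind(cbind(mk(136, 30), area = "V1"),
               cbind(mk(72, 7), area = "V2"),
               cbind(mk(240, 30), area = "V4"))
  out <- completeness_summary(tab, by = "area")
  expect_equal(out$pct_incomplete, c(22.1, 9.7, 12.5))
  expect_equal(out$n_total, c(136, 72, 240))
})

test_that("arrangement paths order peaks by hue angle", {
  hues8 <- dkl_hue_angles()
  # linear arrangement: peaks march rightward with hue angle
  peaks <- cbind(rep(12L, 8), seq(7L, by = 3L, length.out = 8))
  ds <- manual_domain_set(chain_pixels(hues8), hues8, dim = c(40, 60),
                          peaks = peaks)
  cs <- build_clusters(ds)
  path <- arrangement_path(cs, 1)
  expect_equal(path$hue_deg, hues8)
  expect_true(all(diff(path$peak_col) > 0))  # monotone along one axis

  # single-domain cluster request errors; single domain in a 4-chain works
  expect_error(arrangement_path(cs, 99), "no such cluster")

  # circular arrangement: endpoints of the hue order are spatial neighbors
  ang <- hues8 * pi / 180
  cpeaks <- cbind(as.integer(round(20 + 8 * sin(ang))),
                  as.integer(round(20 + 8 * cos(ang))))
  pxc <- lapply(seq_len(8), function(k) {
    g <- expand.grid(r = (cpeaks[k, 1] - 3):(cpeaks[k, 1] + 3),
                     c = (cpeaks[k, 2] - 3):(cpeaks[k, 2] + 3))
    (g$c - 1) * 40 + g$r
  })
  dsc <- manual_domain_set(pxc, hues8, peaks = cpeaks)
  csc <- build_clusters(dsc)
  pathc <- arrangement_path(csc, 1)
  ends <- sqrt(sum((as.numeric(pathc[1, c("peak_row", "peak_col")]) -
                      as.numeric(pathc[8, c("peak_row", "peak_col")]))^2))
  diam <- equivalent_diameter(49 * 64) / 8  # one domain diameter, px
  expect_lt(ends, diam)
})
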