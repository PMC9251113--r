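# Pixel-wise hypothesis testing across trials and the two map-level
# screening procedures: chi-square vessel exclusion and cluster-extent
# significance thresholding with cross-session reproduction.

#' @noRd
new_stat_map <- function(p, stat, test, df, n_trials, pixel_pitch = NA_real_) {
  structure(list(p = p, stat = stat, test = test, df = df,
                 n_trials = n_trials, pixel_pitch = pixel_pitch),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map %s, %d x %d px, df = %s, %d invalid px>\n",
              x$test, nrow(x$p), ncol(x$p),
              paste(x$df, collapse = ","), sum(is.na(x$p))))
  invisible(x)
}

# list of maps -> (H*W) x n matrix plus dims
#' @noRd
trials_matrix <- function(maps) {
  a <- stack_maps(maps)
  d <- dim(a)
  list(Y = matrix(a, nrow = d[1] * d[2]), dim = d[1:2])
}

#' Pixel-wise two-sample t test
#'
#' Two-tailed two-sample t test at every pixel between two sets of trial
#' response maps (equal-variance pooled t by default, Welch optional).
#' Pixels where both groups have zero within-group variance, or any trial is
#' invalid, get NA p-values.
#'
#' @param trials_A,trials_B lists of response maps (or matrices), one per
#'   trial; at least 2 trials per group.
#' @param var_equal pool the variances (default TRUE).
#' @param pixel_pitch micrometers per pixel (taken from the first
#'   `response_map` if not given; used downstream for extent scaling).
#' @return a `stat_map` with fields `p`, `stat` (t), `test`, `df`,
#'   `n_trials`.
#' @export
pixelwise_ttest <- function(trials_A, trials_B, var_equal = TRUE,
                            pixel_pitch = NULL) {
  n1 <- length(trials_A); n2 <- length(trials_B)
  if (n1 < 2 || n2 < 2) stop("need >= 2 trials per group", call. = FALSE)
  pitch <- tryCatch(map_pitch(trials_A[[1]], pixel_pitch),
                    error = function(e) NA_real_)
  A <- trials_matrix(trials_A); B <- trials_matrix(trials_B)
  if (!identical(A$dim, B$dim)) stop("grid mismatch between groups",
                                     call. = FALSE)
  m1 <- rowMeans(A$Y); m2 <- rowMeans(B$Y)
  v1 <- rowSums((A$Y - m1)^2) / (n1 - 1)
  v2 <- rowSums((B$Y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  t[se == 0] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- NA_real_
  H <- A$dim[1]; W <- A$dim[2]
  new_stat_map(matrix(p, H, W), matrix(t, H, W), "ttest2",
               df = n1 + n2 - 2, n_trials = c(n1, n2), pixel_pitch = pitch)
}

#' Pixel-wise ANOVA (one-way, or two-way main effects)
#'
#' One-way: F test across the levels of a single factor (e.g. the eight
#' hues) at every pixel. Two-way (balanced designs only): main-effect F maps
#' for each factor from the full factorial model with interaction; returns a
#' named list of two `stat_map`s.
#'
#' @param trials list of response maps (or matrices), one per trial.
#' @param f1 factor (or vector) of level labels for the first factor, one
#'   per trial.
#' @param f2 optional second factor for a two-way ANOVA.
#' @param pixel_pitch see [pixelwise_ttest()].
#' @return a `stat_map` (one-way) or a list with elements `f1` and `f2`
#'   holding the main-effect `stat_map`s (two-way).
#' @export
pixelwise_anova <- function(trials, f1, f2 = NULL, pixel_pitch = NULL) {
  f1 <- factor(f1)
  if (length(f1) != length(trials))
    stop("f1 must have one label per trial", call. = FALSE)
  pitch <- tryCatch(map_pitch(trials[[1]], pixel_pitch),
                    error = function(e) NA_real_)
  M <- trials_matrix(trials)
  Y <- M$Y; H <- M$dim[1]; W <- M$dim[2]; n <- ncol(Y)
  gm <- rowMeans(Y)
  sst <- rowSums((Y - gm)^2)
  group_means <- function(f) {
    G <- vapply(levels(f), function(l) rowMeans(Y[, f == l, drop = FALSE]),
                numeric(nrow(Y)))
    G  # npix x nlevels
  }
  if (is.null(f2)) {
    if (nlevels(f1) < 2) stop("need >= 2 levels", call. = FALSE)
    if (any(table(f1) < 2)) stop("need >= 2 trials per level", call. = FALSE)
    G <- group_means(f1)
    cnt <- as.numeric(table(f1))
    ssb <- (G - gm)^2 %*% cnt
    ssw <- sst - as.numeric(ssb)
    df1 <- nlevels(f1) - 1; df2 <- n - nlevels(f1)
    Fv <- (as.numeric(ssb) / df1) / (ssw / df2)
    Fv[ssw == 0] <- NA_real_
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p[!is.finite(Fv)] <- NA_real_
    return(new_stat_map(matrix(p, H, W), matrix(Fv, H, W), "anova1",
                        df = c(df1, df2), n_trials = n, pixel_pitch = pitch))
  }
  f2 <- factor(f2)
  if (length(f2) != length(trials))
    stop("f2 must have one label per trial", call. = FALSE)
  tab <- table(f1, f2)
  if (length(unique(as.vector(tab))) != 1 || any(tab < 2))
    stop("two-way ANOVA requires a balanced design with >= 2 trials per cell",
         call. = FALSE)
  a <- nlevels(f1); b <- nlevels(f2); r <- tab[1, 1]
  GA <- group_means(f1); GB <- group_means(f2)
  ssa <- as.numeric((GA - gm)^2 %*% rep(b * r, a))
  ssb <- as.numeric((GB - gm)^2 %*% rep(a * r, b))
  # cell means for interaction + error SS
  cell <- interaction(f1, f2, drop = FALSE)
  GC <- vapply(levels(cell), function(l) {
    sel <- cell == l
    if (any(sel)) rowMeans(Y[, sel, drop = FALSE]) else rep(0, nrow(Y))
  }, numeric(nrow(Y)))
  ss_cells <- as.numeric((GC - gm)^2 %*% rep(r, a * b))
  ssab <- ss_cells - ssa - ssb
  sse <- sst - ss_cells
  dfa <- a - 1; dfb <- b - 1; dfe <- n - a * b
  Fa <- (ssa / dfa) / (sse / dfe)
  Fb <- (ssb / dfb) / (sse / dfe)
  Fa[sse == 0] <- NA_real_; Fb[sse == 0] <- NA_real_
  pa <- stats::pf(Fa, dfa, dfe, lower.tail = FALSE)
  pb <- stats::pf(Fb, dfb, dfe, lower.tail = FALSE)
  pa[!is.finite(Fa)] <- NA_real_; pb[!is.finite(Fb)] <- NA_real_
  out <- list(
    new_stat_map(matrix(pa, H, W), matrix(Fa, H, W), "anova2_main",
                 df = c(dfa, dfe), n_trials = n, pixel_pitch = pitch),
    new_stat_map(matrix(pb, H, W), matrix(Fb, H, W), "anova2_main",
                 df = c(dfb, dfe), n_trials = n, pixel_pitch = pitch))
  names(out) <- c("f1", "f2")
  out
}

#' Pixel validity mask
#'
#' @param valid logical H x W matrix.
#' @param reason character matrix (or single string recycled over invalid
#'   pixels) coding why pixels are invalid (`"vessel"`, `"border"`,
#'   `"user"`); `NA` for valid pixels.
#' @return list of class `pixel_mask` with `valid` and `reason`. Masks
#'   compose with `&` via [combine_masks()].
#' @export
pixel_mask <- function(valid, reason = "user") {
  stopifnot(is.matrix(valid), is.logical(valid))
  if (!is.matrix(reason)) {
    r <- matrix(NA_character_, nrow(valid), ncol(valid))
    r[!valid] <- reason
    reason <- r
  }
  structure(list(valid = valid, reason = reason), class = "pixel_mask")
}

#' @rdname pixel_mask
#' @param ... `pixel_mask` objects to intersect (logical AND of validity).
#' @export
combine_masks <- function(...) {
  ms <- list(...)
  valid <- Reduce(`&`, lapply(ms, function(m) m$valid))
  reason <- ms[[1]]$reason
  for (m in ms[-1]) {
    take <- is.na(reason) & !is.na(m$reason)
    reason[take] <- m$reason[take]
  }
  pixel_mask(valid, reason)
}

#' Vessel exclusion by blank-trial variance (chi-square rule)
#'
#' Pixels on and near large vessels show inflated trial-to-trial fluctuation
#' even without stimulation. This computes the per-pixel SD of blank-trial
#' dR/R maps and excludes pixels whose variance exceeds the upper limit of
#' the one-sided `1 - alpha` confidence interval of the chi-square
#' distribution around a reference variance. The reference is the
#' across-pixel median of per-pixel variances (robust to vessel
#' contamination), rescaled by the median of the chi-square distribution so
#' that under homogeneous noise the expected exclusion fraction is exactly
#' `alpha`; `center = "mean"` uses the across-pixel mean instead.
#'
#' @param blank_trials list of >= 10 blank-condition response maps.
#' @param alpha one-sided tail probability (default 0.05).
#' @param center `"median"` (robust, default) or `"mean"`.
#' @return a [pixel_mask()] with reason `"vessel"` for excluded pixels and
#'   attributes `threshold_var` and `ref_var`.
#' @export
vessel_mask <- function(blank_trials, alpha = 0.05,
                        center = c("median", "mean")) {
  center <- match.arg(center)
  n <- length(blank_trials)
  if (n < 2) stop("need >= 2 blank trials", call. = FALSE)
  if (n < 10) warning("fewer than 10 blank trials; the variance rule is weak")
  M <- trials_matrix(blank_trials)
  nu <- n - 1
  s2 <- rowSums((M$Y - rowMeans(M$Y))^2) / nu
  ref <- if (center == "median") {
    # median(s2) estimates sigma^2 * qchisq(0.5, nu)/nu; rescale so the
    # chi-square upper limit is centered on sigma^2
    median(s2, na.rm = TRUE) / (stats::qchisq(0.5, nu) / nu)
  } else mean(s2, na.rm = TRUE)
  thr <- ref * stats::qchisq(1 - alpha, nu) / nu
  bad <- s2 > thr
  bad[is.na(bad)] <- FALSE
  valid <- matrix(!bad, M$dim[1], M$dim[2])
  out <- pixel_mask(valid, "vessel")
  # trials containing invalid pixels: mark those pixels as user-invalid
  anyna <- matrix(rowSums(is.na(M$Y)) > 0, M$dim[1], M$dim[2])
  if (any(anyna)) out <- combine_masks(out, pixel_mask(!anyna, "user"))
  attr(out, "threshold_var") <- thr
  attr(out, "ref_var") <- ref
  out
}

# 8-connected component labeling of a logical matrix via an igraph
# components call on the pixel adjacency graph
#' @noRd
label8 <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  idx <- which(bin)
  if (length(idx) == 0L) return(lab)
  lut <- integer(H * W); lut[idx] <- seq_along(idx)
  pos <- arrayInd(idx, c(H, W))
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nr <- pos[, 1] + off[1]; nc <- pos[, 2] + off[2]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    nidx <- (nc[ok] - 1L) * H + nr[ok]
    sel <- lut[nidx] > 0L
    if (any(sel))
      edges[[length(edges) + 1L]] <-
        cbind(lut[idx[ok]][sel], lut[nidx][sel])
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
    memb <- igraph::components(g)$membership
  } else memb <- seq_along(idx)
  lab[idx] <- as.integer(memb)
  lab
}

# qualifying regions of one stat map: connected p < alpha components with
# size >= min_px and min p < peak_alpha
#' @noRd
qualifying_regions <- function(stat, valid, alpha, peak_alpha, min_px) {
  supra <- !is.na(stat$p) & stat$p < alpha & valid
  lab <- label8(supra)
  if (max(lab) == 0L)
    return(list(labels = lab, table = data.frame(
      region_id = integer(0), n_pixels = integer(0), min_p = numeric(0),
      peak_row = integer(0), peak_col = integer(0))))
  sizes <- tabulate(lab[lab > 0L])
  rows <- list(); keep_ids <- integer(0); newlab <- matrix(0L, nrow(lab), ncol(lab))
  rid <- 0L
  for (i in which(sizes >= min_px)) {
    px <- which(lab == i)
    pv <- stat$p[px]
    if (min(pv) < peak_alpha) {
      rid <- rid + 1L
      # peak: min p; ties by larger |stat|, then row-major order
      cand <- px[pv == min(pv)]
      if (length(cand) > 1L) {
        sv <- abs(stat$stat[cand])
        cand <- cand[sv == max(sv)]
      }
      peak <- cand[1L]
      pk <- arrayInd(peak, dim(lab))
      newlab[px] <- rid
      rows[[rid]] <- data.frame(region_id = rid, n_pixels = length(px),
                                min_p = min(pv), peak_row = pk[1],
                                peak_col = pk[2])
    }
  }
  list(labels = newlab,
       table = if (rid > 0) do.call(rbind, rows) else data.frame(
         region_id = integer(0), n_pixels = integer(0), min_p = numeric(0),
         peak_row = integer(0), peak_col = integer(0)))
}

#' Cluster-extent thresholding with cross-session reproduction
#'
#' Multiple-comparison control for statistical maps: keeps only connected
#' regions (8-connectivity) of pixels with `p < alpha` that (i) contain at
#' least `min_pixels` contiguous pixels, (ii) contain a pixel with
#' `p < peak_alpha`, and (iii) overlap (>= 1 pixel) a region passing the same
#' size/peak rule in an independent session's map.
#'
#' `min_pixels` is defined at the reference pitch of 8 um/pixel (200 pixels
#' ~ 12,900 um^2) and is rescaled by `(8 / pixel_pitch)^2` when the grid
#' pitch differs, so the minimum physical extent is pitch-invariant.
#'
#' @param stat,stat_repro `stat_map`s of the primary and the reproduction
#'   session (same grid).
#' @param mask optional [pixel_mask()]; invalid pixels cannot be significant.
#' @param alpha pixel significance level (default 0.05).
#' @param peak_alpha required peak significance within a region
#'   (default 0.001).
#' @param min_pixels minimum contiguous extent at 8 um/pixel (default 200).
#' @return list of class `region_set`: `labels` (integer H x W matrix, 0 =
#'   background), `table` (`region_id`, `n_pixels`, `min_p`, `peak_row`,
#'   `peak_col`, `reproduced`), `min_px_used`, `params`.
#' @export
cluster_extent_threshold <- function(stat, stat_repro, mask = NULL,
                                     alpha = 0.05, peak_alpha = 0.001,
                                     min_pixels = 200) {
  if (!identical(dim(stat$p), dim(stat_repro$p)))
    stop("grid mismatch between sessions", call. = FALSE)
  valid <- if (is.null(mask)) matrix(TRUE, nrow(stat$p), ncol(stat$p))
           else mask$valid
  if (!identical(dim(valid), dim(stat$p)))
    stop("grid mismatch between mask and stat map", call. = FALSE)
  pitch <- stat$pixel_pitch
  min_px <- if (is.finite(pitch) && !is.na(pitch))
    max(1L, as.integer(round(min_pixels * (8 / pitch)^2))) else
      as.integer(min_pixels)
  prim <- qualifying_regions(stat, valid, alpha, peak_alpha, min_px)
  repr <- qualifying_regions(stat_repro, valid, alpha, peak_alpha, min_px)
  keep <- integer(0)
  if (nrow(prim$table) > 0 && nrow(repr$table) > 0) {
    for (i in prim$table$region_id) {
      if (any(repr$labels[prim$labels == i] > 0L)) keep <- c(keep, i)
    }
  }
  labels <- matrix(0L, nrow(stat$p), ncol(stat$p))
  tab <- prim$table[prim$table$region_id %in% keep, , drop = FALSE]
  if (nrow(tab) > 0) {
    for (j in seq_len(nrow(tab))) {
      labels[prim$labels == tab$region_id[j]] <- j
    }
    tab$region_id <- seq_len(nrow(tab))
    tab$reproduced <- TRUE
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(region_id = integer(0), n_pixels = integer(0),
                      min_p = numeric(0), peak_row = integer(0),
                      peak_col = integer(0), reproduced = logical(0))
  }
  structure(list(labels = labels, table = tab, min_px_used = min_px,
                 params = list(alpha = alpha, peak_alpha = peak_alpha,
                               min_pixels = min_pixels)),
            class = "region_set")
}
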