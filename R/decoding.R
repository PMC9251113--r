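# Multivariate decoding of hue identity from trial response maps: spatial
# binning, feature normalization, trial balancing, cross-validated linear
# classification, bootstrap inference and between-area comparison.

#' Reduce a map by block averaging
#'
#' Non-overlapping `factor x factor` block means (e.g. 10 x 10 camera pixels
#' of 8 um become one 80 um bin). Partial blocks at the bottom/right edges
#' are retained (output dimensions are the ceiling of input/factor) and
#' averaged over the available pixels. Invalid (NA) pixels are excluded from
#' block means; a block is invalid only if all its pixels are.
#'
#' @param map a [response_map()] or numeric matrix.
#' @param factor integer binning factor (default 10).
#' @return same type as `map`, with `ceiling(dim/factor)` dimensions.
#' @export
bin_map <- function(map, factor = 10) {
  v <- map_values(map)
  stopifnot(factor >= 1)
  gr <- ceiling(seq_len(nrow(v)) / factor)
  gc <- ceiling(seq_len(ncol(v)) / factor)
  fin <- is.finite(v)
  vz <- v; vz[!fin] <- 0
  sums <- t(rowsum(t(rowsum(vz, gr)), gc))
  cnts <- t(rowsum(t(rowsum(fin + 0, gr)), gc))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  if (inherits(map, "response_map")) {
    prov <- map$provenance
    prov$filters <- c(prov$filters, sprintf("bin(%dx%d)", factor, factor))
    response_map(out, map$pixel_pitch * factor, prov)
  } else out
}

#' Build the trials x features matrix for decoding
#'
#' Bins every trial map, keeps the bins inside the region of interest,
#' flattens them to feature vectors and z-normalizes each feature. The
#' default `"pooled"` scheme standardizes each feature with the mean and SD
#' over all trials of all conditions; `"per_stimulus"` standardizes within
#' each stimulus condition separately (which also removes class mean
#' differences -- see the package vignette). Features with zero SD, or with
#' any invalid bin, are dropped with a message.
#'
#' @param trial_maps list of response maps (or matrices), one per trial.
#' @param labels vector/factor of condition labels, one per trial.
#' @param roi optional logical matrix selecting pixels, on either the
#'   original or the binned grid; a bin on the original grid is kept when it
#'   contains at least one ROI pixel. Default: all bins.
#' @param factor binning factor (default 10).
#' @param normalization `"pooled"` (default) or `"per_stimulus"`.
#' @return list of class `feature_matrix`: `X` (trials x features), `y`
#'   (factor), `coords` (data.frame `bin_row`, `bin_col`), `factor`,
#'   `normalization`.
#' @export
make_features <- function(trial_maps, labels, roi = NULL, factor = 10,
                          normalization = c("pooled", "per_stimulus")) {
  normalization <- match.arg(normalization)
  y <- factor(labels)
  if (length(y) != length(trial_maps))
    stop("labels must have one entry per trial", call. = FALSE)
  if (any(table(y) < 2)) stop("need >= 2 trials per condition", call. = FALSE)
  binned <- lapply(trial_maps, bin_map, factor = factor)
  b1 <- map_values(binned[[1]])
  keep <- matrix(TRUE, nrow(b1), ncol(b1))
  if (!is.null(roi)) {
    if (inherits(roi, "pixel_mask")) roi <- roi$valid
    if (identical(dim(roi), dim(b1))) keep <- roi
    else keep <- map_values(bin_map(roi + 0, factor)) > 0
  }
  sel <- which(keep)
  X <- t(vapply(binned, function(b) map_values(b)[sel],
                numeric(length(sel))))
  coords <- as.data.frame(arrayInd(sel, dim(b1)))
  names(coords) <- c("bin_row", "bin_col")
  ok <- colSums(!is.finite(X)) == 0
  if (normalization == "pooled") {
    mu <- colMeans(X); sdv <- apply(X, 2, sd)
    ok <- ok & sdv > 0
    X <- sweep(sweep(X, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/")
  } else {
    for (l in levels(y)) {
      i <- y == l
      mu <- colMeans(X[i, , drop = FALSE])
      sdv <- apply(X[i, , drop = FALSE], 2, sd)
      ok <- ok & sdv > 0
      X[i, ] <- sweep(sweep(X[i, , drop = FALSE], 2, mu), 2,
                      ifelse(sdv > 0, sdv, 1), "/")
    }
  }
  if (!all(ok)) {
    message(sum(!ok), " feature(s) dropped (zero SD or invalid bins)")
    X <- X[, ok, drop = FALSE]
    coords <- coords[ok, , drop = FALSE]
  }
  if (ncol(X) == 0) stop("no usable features remain", call. = FALSE)
  structure(list(X = X, y = y, coords = coords, factor = factor,
                 normalization = normalization),
            class = "feature_matrix")
}

#' Balance trial counts across conditions
#'
#' Randomly downsamples every condition to the minimum per-condition trial
#' count (seeded, reproducible). Conditions already at the minimum are kept
#' intact.
#'
#' @param fm a `feature_matrix` from [make_features()].
#' @param seed integer seed.
#' @return a balanced `feature_matrix`.
#' @export
balance_trials <- function(fm, seed = 1) {
  cnt <- table(fm$y)
  nmin <- min(cnt)
  idx <- with_seed(derive_seed(seed, "balance"), {
    unlist(lapply(levels(fm$y), function(l) {
      i <- which(fm$y == l)
      if (length(i) > nmin) sort(sample(i, nmin)) else i
    }))
  })
  idx <- sort(idx)
  out <- fm
  out$X <- fm$X[idx, , drop = FALSE]
  out$y <- droplevels(fm$y[idx])
  out
}

#' Subsample features to a fixed count
#'
#' Used to keep the number of input features identical when comparing
#' decoding between cortical areas.
#'
#' @param fm a `feature_matrix`.
#' @param n_features target feature count (<= ncol).
#' @param seed integer seed.
#' @return a `feature_matrix` with `n_features` columns.
#' @export
subsample_features <- function(fm, n_features, seed = 1) {
  if (n_features > ncol(fm$X))
    stop("n_features exceeds the available feature count", call. = FALSE)
  j <- with_seed(derive_seed(seed, "features"),
                 sort(sample(ncol(fm$X), n_features)))
  out <- fm
  out$X <- fm$X[, j, drop = FALSE]
  out$coords <- fm$coords[j, , drop = FALSE]
  out
}

# linear max-margin classifier backend (LIBSVM via e1071, linear kernel).
# features are already standardized upstream, hence scale = FALSE.
#' @noRd
fit_linear_svm <- function(X, y, cost = 1) {
  e1071::svm(x = X, y = droplevels(factor(y)), kernel = "linear",
             cost = cost, scale = FALSE)
}

#' Cross-validated decoding accuracy
#'
#' Stratified k-fold cross-validation of a linear max-margin classifier
#' (linear SVM, cost = 1): the trials of every class are split into k folds,
#' the classifier is trained on k-1 folds and tested on the held-out fold,
#' and accuracy is averaged over all held-out trials. Chance level for c
#' balanced classes is 1/c.
#'
#' @param fm a (balanced) `feature_matrix`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param cost SVM regularization constant (default 1).
#' @return list of class `decoding_result`: `overall_accuracy`,
#'   `per_class_accuracy` (per-label recall), `confusion` (table),
#'   `k`, `n_trials`, `chance`, `classifier`, `seed`.
#' @export
cv_accuracy <- function(fm, k = 10, seed = 1, cost = 1) {
  y <- fm$y; X <- fm$X
  cnt <- table(y)
  if (any(cnt < k))
    stop("class with fewer trials than folds (", min(cnt),
         " < ", k, "); use a smaller k", call. = FALSE)
  fold <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (l in levels(y)) {
      i <- sample(which(y == l))
      fold[i] <- rep(seq_len(k), length.out = length(i))
    }
  })
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- fit_linear_svm(X[!te, , drop = FALSE], y[!te], cost)
    pred[te] <- stats::predict(fit, X[te, , drop = FALSE])
  }
  correct <- pred == y
  per_class <- vapply(levels(y), function(l) mean(correct[y == l]),
                      numeric(1))
  structure(list(overall_accuracy = mean(correct),
                 per_class_accuracy = per_class,
                 confusion = table(truth = y, predicted = pred),
                 k = k, n_trials = length(y), chance = 1 / nlevels(y),
                 classifier = sprintf("linear svm (cost=%g)", cost),
                 seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result: accuracy %.1f%% (chance %.1f%%), %d trials, %d-fold CV>\n",
              100 * x$overall_accuracy, 100 * x$chance, x$n_trials, x$k))
  invisible(x)
}

#' Bootstrap distribution of decoding accuracy
#'
#' Resamples the training set with replacement (same size), refits the
#' classifier, and evaluates it on the intact test set, B times. Returns the
#' bootstrap mean, the 95% percentile confidence interval, and the p-value
#' for the null hypothesis that accuracy does not exceed chance: the
#' fraction of bootstrap accuracies at or below chance, floored at `1/B`.
#'
#' @param train_X,train_y training features and labels.
#' @param test_X,test_y intact test features and labels.
#' @param B bootstrap samples (default 1000).
#' @param seed integer seed.
#' @param cost SVM regularization constant.
#' @param chance chance level; default `1/nlevels(train_y)`.
#' @return list of class `bootstrap_dist`: `samples` (length B), `mean`,
#'   `ci_95` (2.5/97.5 percentiles), `p_vs_chance`, `chance`, `B`.
#' @export
bootstrap_accuracy <- function(train_X, train_y, test_X, test_y, B = 1000,
                               seed = 1, cost = 1, chance = NULL) {
  train_y <- factor(train_y)
  test_y <- factor(test_y, levels = levels(train_y))
  if (is.null(chance)) chance <- 1 / nlevels(train_y)
  n <- nrow(train_X)
  acc <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(B), function(b) {
      i <- sample(n, n, replace = TRUE)
      if (length(unique(train_y[i])) < 2) return(1 / nlevels(train_y))
      fit <- fit_linear_svm(train_X[i, , drop = FALSE], train_y[i], cost)
      pred <- stats::predict(fit, test_X)
      mean(as.character(pred) == as.character(test_y))
    }, numeric(1))
  })
  structure(list(samples = acc, mean = mean(acc),
                 ci_95 = stats::quantile(acc, c(0.025, 0.975), names = FALSE),
                 p_vs_chance = max(1 / B, mean(acc <= chance)),
                 chance = chance, B = B),
            class = "bootstrap_dist")
}

#' Stratified train/test split
#'
#' Holds out `test_fraction` of each class's trials (seeded); the companion
#' of [bootstrap_accuracy()].
#'
#' @param fm a `feature_matrix`.
#' @param test_fraction held-out fraction per class (default 0.1).
#' @param seed integer seed.
#' @return list with `train_X`, `train_y`, `test_X`, `test_y`.
#' @export
train_test_split <- function(fm, test_fraction = 0.1, seed = 1) {
  te <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(levels(fm$y), function(l) {
      i <- which(fm$y == l)
      sample(i, max(1, round(length(i) * test_fraction)))
    }))
  })
  list(train_X = fm$X[-te, , drop = FALSE], train_y = fm$y[-te],
       test_X = fm$X[te, , drop = FALSE], test_y = fm$y[te])
}

#' Compare two bootstrap accuracy distributions
#'
#' Two areas are deemed statistically different when 97.5% of their
#' bootstrap distributions do not overlap: the 2.5th percentile of the
#' higher-mean distribution must exceed the 97.5th percentile of the
#' lower-mean one.
#'
#' @param dist_a,dist_b `bootstrap_dist` objects (or bare sample vectors).
#' @return list with `significant` (logical), `higher` (`"a"` or `"b"`),
#'   `lo_hi` (2.5th percentile of the higher distribution), `hi_lo`
#'   (97.5th percentile of the lower distribution).
#' @export
compare_areas <- function(dist_a, dist_b) {
  sa <- if (inherits(dist_a, "bootstrap_dist")) dist_a$samples else dist_a
  sb <- if (inherits(dist_b, "bootstrap_dist")) dist_b$samples else dist_b
  a_higher <- mean(sa) >= mean(sb)
  hi <- if (a_higher) sa else sb
  lo <- if (a_higher) sb else sa
  lo_hi <- stats::quantile(hi, 0.025, names = FALSE)
  hi_lo <- stats::quantile(lo, 0.975, names = FALSE)
  list(significant = lo_hi > hi_lo, higher = if (a_higher) "a" else "b",
       lo_hi = lo_hi, hi_lo = hi_lo)
}
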