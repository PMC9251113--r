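# Independent oracles and small builders shared across tests.

# brute-force running median with reflected padding (edge not duplicated);
# deliberately naive -- the reference for the package's filter
brute_median_filter <- function(x, k) {
  r <- (k - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  ridx <- c(rev(seq_len(r) + 1L), seq_len(H), H - seq_len(r))
  cidx <- c(rev(seq_len(r) + 1L), seq_len(W), W - seq_len(r))
  xp <- x[ridx, cidx]
  out <- x
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- median(xp[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# analytic tolerance of the package filter: 16-bit internal quantization
median_quant_tol <- function(x) 2 * (max(x) - min(x)) / 65535

# rasterized disk pixel count at radius r (pixels)
disk_pixel_count <- function(r) {
  n <- ceiling(r) + 1
  g <- expand.grid(x = -n:n, y = -n:n)
  sum(g$x^2 + g$y^2 <= r^2)
}

# tiny trial stack with explicit frames (18 frames, 4 Hz, onset 1 s)
tiny_stack <- function(frames, pixel_pitch = 8) {
  structure(list(frames = frames, frame_rate = 4, t_onset = 1,
                 duration = dim(frames)[3] / 4,
                 condition_id = "test", session_id = "s1",
                 pixel_pitch = pixel_pitch, seed = 0L),
            class = "trial_stack")
}

# small ground-truth layout (one cluster) for fast simulations
small_layout <- function(seed = 1, hues = dkl_hue_angles(), field = 96,
                         n_vessels = 1, ...) {
  make_layout(field_size = c(field, field), pixel_pitch = 8,
              n_clusters = 1, hue_subsets = list(hues),
              domain_diameter_um = 150, ring_radius_um = 120,
              n_vessels = n_vessels, seed = seed, ...)
}

# hand-built hue domain set from a list of pixel-index vectors
manual_domain_set <- function(pixels_by_domain, hues, dim = c(40, 40),
                              pixel_pitch = 8, peaks = NULL) {
  n <- length(pixels_by_domain)
  domains <- data.frame(
    domain_id = seq_len(n), hue_deg = hues,
    n_pixels = vapply(pixels_by_domain, length, integer(1)),
    area_um2 = vapply(pixels_by_domain, length, integer(1)) * pixel_pitch^2,
    equiv_diam_um = equivalent_diameter(
      vapply(pixels_by_domain, length, integer(1)) * pixel_pitch^2),
    min_p = rep(1e-5, n),
    peak_row = if (is.null(peaks)) rep(1L, n) else peaks[, 1],
    peak_col = if (is.null(peaks)) rep(1L, n) else peaks[, 2])
  structure(list(domains = domains, pixels = pixels_by_domain, dim = dim,
                 pixel_pitch = pixel_pitch),
            class = "hue_domain_set")
}

# stat_map holding given p values (stat = qnorm surrogate)
manual_stat_map <- function(p, pixel_pitch = 8) {
  structure(list(p = p, stat = -stats::qnorm(p / 2), test = "manual",
                 df = 38, n_trials = 40, pixel_pitch = pixel_pitch),
            class = "stat_map")
}

# Dice coefficient between two pixel index sets
dice <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))
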