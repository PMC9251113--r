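# Response maps: dR/R computation, median-filter high-pass / smoothing,
# single-condition, subtraction and vector-sum hue-preference maps.
#
# Maps are numeric H x W matrices (image coordinates, row 1 = top); invalid
# pixels are NA and propagate through every operation.

#' Construct a response map object
#'
#' A light container for an H x W dR/R matrix plus its pixel pitch and
#' provenance. Most functions in the package accept either a `response_map`
#' or a bare matrix (then `pixel_pitch` must be passed explicitly where it
#' matters).
#'
#' @param values numeric matrix of dR/R values (NA = invalid pixel).
#' @param pixel_pitch micrometers per pixel.
#' @param provenance free-form list (condition ids, trial count, filters).
#' @return list of class `response_map`.
#' @export
response_map <- function(values, pixel_pitch, provenance = list()) {
  assert_matrix(values, "values")
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 provenance = provenance),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("<response_map %d x %d px, %.3g um/px, %d invalid px>\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch,
              sum(is.na(x$values))))
  invisible(x)
}

#' Fractional reflectance change of one trial
#'
#' Computes the per-pixel dR/R map of a trial stack: `R0` is the mean of the
#' frames in the pre-stimulus window, `R1` the mean over the response window,
#' and the map is `(R1 - R0)/R0`. Windows are in seconds relative to stimulus
#' onset and select frames whose bin centers fall inside the half-open
#' interval; the defaults (pre `[-1, 0)`, response `[1, 3.5)`) select frames
#' 1-4 and 9-18 of the standard 18-frame, 4 frames/s acquisition.
#' Pixels with a non-positive baseline are flagged invalid (NA), not errors.
#'
#' @param stack a `trial_stack` (see [simulate_trial()] / [read_stack()]).
#' @param pre_window,resp_window numeric length-2 windows in seconds relative
#'   to stimulus onset.
#' @return a [response_map()].
#' @export
compute_dRR <- function(stack, pre_window = c(-1, 0), resp_window = c(1, 3.5)) {
  stopifnot(inherits(stack, "trial_stack"))
  Tn <- dim(stack$frames)[3]
  t_mid <- (seq_len(Tn) - 0.5) / stack$frame_rate
  rel <- t_mid - stack$t_onset
  in_pre <- rel >= pre_window[1] & rel < pre_window[2]
  in_resp <- rel >= resp_window[1] & rel < resp_window[2]
  if (!any(in_pre) || !any(in_resp))
    stop("stack does not cover the requested windows", call. = FALSE)
  H <- dim(stack$frames)[1]; W <- dim(stack$frames)[2]
  R0 <- matrix(rowMeans(matrix(stack$frames[, , in_pre, drop = FALSE],
                               H * W)), H, W)
  R1 <- matrix(rowMeans(matrix(stack$frames[, , in_resp, drop = FALSE],
                               H * W)), H, W)
  v <- (R1 - R0) / R0
  v[R0 <= 0] <- NA_real_
  response_map(v, stack$pixel_pitch,
               provenance = list(condition_id = stack$condition_id,
                                 session_id = stack$session_id,
                                 n_trials = 1L, filters = character(0)))
}

# 2-D running median with reflected border padding. EBImage's constant-time
# median filter operates on [0,1] with 16-bit internal quantization, so the
# input is affinely rescaled around the call; NA pixels are excluded from the
# filtering support and restored afterwards.
#' @noRd
median_filter2d <- function(x, k) {
  stopifnot(k %% 2L == 1L, k >= 3L)
  H <- nrow(x); W <- ncol(x)
  if (k > min(H, W)) stop("median filter kernel larger than image",
                          call. = FALSE)
  r <- (k - 1L) %/% 2L
  na <- is.na(x)
  if (all(na)) return(x)
  xf <- x
  if (any(na)) xf[na] <- median(x, na.rm = TRUE)
  # reflected padding (edge pixel not duplicated)
  ridx <- c(rev(seq_len(r) + 1L), seq_len(H), H - seq_len(r))
  cidx <- c(rev(seq_len(r) + 1L), seq_len(W), W - seq_len(r))
  xp <- xf[ridx, cidx]
  lo <- min(xp); hi <- max(xp)
  if (hi - lo < .Machine$double.eps) return(ifelse(na, NA_real_, x * 0 + lo))
  y01 <- EBImage::medianFilter((xp - lo) / (hi - lo), r)
  y <- as.matrix(y01)[r + seq_len(H), r + seq_len(W)] * (hi - lo) + lo
  y[na] <- NA_real_
  y
}

# shared plumbing for filter ops on response_map or matrix
#' @noRd
apply_filter <- function(map, pixel_pitch, size_um, mode, label) {
  v <- map_values(map)
  pitch <- map_pitch(map, pixel_pitch)
  k <- kernel_px(size_um, pitch)
  med <- median_filter2d(v, k)
  out <- if (mode == "highpass") v - med else med
  if (inherits(map, "response_map")) {
    prov <- map$provenance
    prov$filters <- c(prov$filters, sprintf("%s(k=%dpx)", label, k))
    response_map(out, pitch, prov)
  } else out
}

#' Median-filter high-pass
#'
#' Removes the large-scale global signal by subtracting a running median
#' (default kernel 1.0 mm x 1.0 mm) from the map. The kernel size in pixels
#' is `round(kernel_mm * 1000 / pixel_pitch)` forced odd; borders use
#' reflected padding.
#'
#' @param map a [response_map()] or numeric matrix.
#' @param kernel_mm kernel side length in millimeters (default 1.0).
#' @param pixel_pitch micrometers per pixel (required for bare matrices).
#' @return same type as `map`.
#' @export
highpass <- function(map, kernel_mm = 1.0, pixel_pitch = NULL) {
  apply_filter(map, pixel_pitch, kernel_mm * 1000, "highpass", "highpass")
}

#' Median-filter smoothing
#'
#' Running-median smoothing to suppress high-spatial-frequency noise before
#' pixel-wise statistics (default kernel 160 um x 160 um).
#'
#' @inheritParams highpass
#' @param kernel_um kernel side length in micrometers (default 160).
#' @return same type as `map`.
#' @export
smooth_map <- function(map, kernel_um = 160, pixel_pitch = NULL) {
  apply_filter(map, pixel_pitch, kernel_um, "median", "smooth")
}

# mean across a list of maps, NA if any contributing pixel is NA
#' @noRd
mean_map <- function(maps) {
  a <- stack_maps(maps)
  d <- dim(a)
  matrix(rowMeans(matrix(a, d[1] * d[2])), d[1], d[2])
}

#' Single-condition map
#'
#' Pixel-wise mean over the condition's trials minus the mean over blank
#' trials.
#'
#' @param trials_cond,trials_blank lists of response maps (or matrices).
#' @param pixel_pitch micrometers per pixel (taken from the first
#'   `response_map` if not given).
#' @return a [response_map()].
#' @export
single_condition_map <- function(trials_cond, trials_blank,
                                 pixel_pitch = NULL) {
  v <- mean_map(trials_cond) - mean_map(trials_blank)
  pitch <- tryCatch(map_pitch(trials_cond[[1]], pixel_pitch),
                    error = function(e) NA_real_)
  response_map(v, pitch,
               provenance = list(n_trials = c(cond = length(trials_cond),
                                              blank = length(trials_blank)),
                                 kind = "single_condition"))
}

#' Subtraction map between two conditions
#'
#' Pixel-wise `mean(A) - mean(B)`. By the display convention of ISOI, more
#' negative (darker) pixels indicate a stronger response to condition A.
#'
#' @param trials_A,trials_B lists of response maps (or matrices).
#' @inheritParams single_condition_map
#' @return a [response_map()].
#' @export
subtraction_map <- function(trials_A, trials_B, pixel_pitch = NULL) {
  v <- mean_map(trials_A) - mean_map(trials_B)
  pitch <- tryCatch(map_pitch(trials_A[[1]], pixel_pitch),
                    error = function(e) NA_real_)
  response_map(v, pitch,
               provenance = list(n_trials = c(A = length(trials_A),
                                              B = length(trials_B)),
                                 kind = "subtraction"))
}

#' Vector-sum hue-preference map
#'
#' Places each hue's single-condition response at its hue angle in polar
#' coordinates and sums the vectors pixel by pixel. Because ISOI responses
#' are darkenings, response strength defaults to the rectified darkening
#' `max(0, -value)`; set `rectify = FALSE` to use signed `-value`. The
#' resultant angle (degrees in `[0, 360)`) is the preferred hue and the
#' resultant length the selectivity magnitude. Pixels with zero magnitude
#' (or any invalid input) get an NA angle.
#'
#' @param maps_by_hue named list of exactly 8 single-condition maps, names =
#'   canonical hue angles (`"0"`, `"45"`, ..., `"315"`).
#' @param rectify clip responses at zero before summation (default TRUE).
#' @return list of class `hue_vector_map` with matrices `angle` (degrees,
#'   NA where undefined) and `magnitude`, plus `pixel_pitch`.
#' @export
hue_vector_map <- function(maps_by_hue, rectify = TRUE) {
  want <- as.character(dkl_hue_angles())
  if (!setequal(names(maps_by_hue), want))
    stop("maps_by_hue must be named by the 8 canonical hue angles; missing: ",
         paste(setdiff(want, names(maps_by_hue)), collapse = ", "),
         call. = FALSE)
  pitch <- tryCatch(map_pitch(maps_by_hue[[1]], NULL),
                    error = function(e) NA_real_)
  vx <- NULL; vy <- NULL; ssum <- NULL
  for (h in want) {
    v <- map_values(maps_by_hue[[h]])
    r <- -v
    if (rectify) r <- pmax(r, 0)
    a <- as.numeric(h) * pi / 180
    if (is.null(vx)) { vx <- r * cos(a); vy <- r * sin(a); ssum <- abs(r) }
    else { vx <- vx + r * cos(a); vy <- vy + r * sin(a)
           ssum <- ssum + abs(r) }
  }
  mag <- sqrt(vx^2 + vy^2)
  ang <- (atan2(vy, vx) * 180 / pi) %% 360
  # symmetric cancellation: resultants at numerical-noise scale relative to
  # the summed response have no meaningful direction
  ang[!is.finite(mag) | mag <= 1e-9 * ssum] <- NA_real_
  structure(list(angle = ang, magnitude = mag, pixel_pitch = pitch),
            class = "hue_vector_map")
}
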