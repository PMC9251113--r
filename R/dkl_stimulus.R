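#' Canonical hue angles of the eight-hue experiment
#'
#' The isoluminant DKL plane is sampled at the four cardinal directions
#' (0 = +L-M, 90 = +S, 180 = +M-L, 270 = -S) and the four intermediate
#' directions, i.e. every 45 degrees.
#'
#' @return Numeric vector `c(0, 45, ..., 315)`.
#' @export
dkl_hue_angles <- function() seq(0, 315, by = 45)

#' Cone contrasts of an isoluminant DKL hue
#'
#' Maps a hue angle in the isoluminant plane of DKL cone-opponent color space
#' to Weber cone contrasts relative to the background gray. Along the L-M
#' axis the L and M cone excitations covary with their sum (luminance) held
#' constant; along the S axis only S-cone excitation changes. Radial
#' saturation is equal for every hue: the locus is scaled so that the maximum
#' cone contrasts are `l_max` for the L cone (at 0 degrees) and `s_max` for
#' the S cone (at 90 degrees).
#'
#' @param theta hue angle(s) in degrees, in `[0, 360)`. 0 = +L-M, 90 = +S,
#'   180 = +M-L, 270 = -S.
#' @param l_max maximum L-cone Weber contrast (default 0.07).
#' @param s_max maximum S-cone Weber contrast (default 0.70).
#' @param lum_weights named numeric vector `c(L=, M=)` of relative luminance
#'   weights of the L and M cones used for the isoluminant L+M cancellation
#'   (default 2:1, a Smith-Pokorny-style ratio; configurable because the
#'   exact weights depend on the chosen fundamentals).
#' @return A data.frame with columns `theta`, `cL`, `cM`, `cS`.
#' @examples
#' dkl_cone_contrast(c(0, 90, 180))
#' @export
dkl_cone_contrast <- function(theta, l_max = 0.07, s_max = 0.70,
                              lum_weights = c(L = 2, M = 1)) {
  if (!is.numeric(l_max) || !is.numeric(s_max) || l_max <= 0 || s_max <= 0)
    stop("l_max and s_max must be positive", call. = FALSE)
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta >= 360))
    stop("theta must be in [0, 360)", call. = FALSE)
  if (!all(c("L", "M") %in% names(lum_weights)) || any(lum_weights[c("L", "M")] <= 0))
    stop("lum_weights must have positive elements named L and M", call. = FALSE)
  rad <- theta * pi / 180
  cL <- l_max * cos(rad)
  cS <- s_max * sin(rad)
  # luminance cancellation: wL*cL + wM*cM = 0
  cM <- -cL * lum_weights[["L"]] / lum_weights[["M"]]
  data.frame(theta = theta, cL = cL, cM = cM, cS = cS)
}

#' Build the stimulus condition set
#'
#' Enumerates the conditions of a hue-mapping run: one grating condition per
#' hue (times the number of orientations), one achromatic grating per
#' orientation, and a single blank (no stimulus) condition. The default
#' reproduces the canonical 10-condition set (8 hues + achromatic + blank).
#'
#' @param hues numeric vector of hue angles in degrees (default the eight
#'   canonical hues).
#' @param orientations grating orientations in degrees (subset of `c(0, 90)`;
#'   default a single orientation, 0).
#' @param luminance_contrast luminance contrast of the gratings (default 0.10).
#' @param l_max,s_max maximum cone contrasts, see [dkl_cone_contrast()].
#' @return A data.frame (one row per condition) with columns `condition_id`,
#'   `kind` (`"hue_grating"`, `"achromatic_grating"` or `"blank"`),
#'   `hue_deg` (NA unless a hue grating), `orientation_deg` (NA for blank)
#'   and `contrast`. Deterministic canonical order: hue gratings by
#'   orientation then hue angle, then achromatic gratings, then blank.
#' @export
make_condition_set <- function(hues = dkl_hue_angles(), orientations = 0,
                               luminance_contrast = 0.10,
                               l_max = 0.07, s_max = 0.70) {
  if (length(hues) < 1L) stop("need at least one hue", call. = FALSE)
  if (!all(orientations %in% c(0, 90)))
    stop("orientations must be within {0, 90}", call. = FALSE)
  hues <- sort(unique(hues))
  orientations <- sort(unique(orientations))
  rows <- list()
  for (o in orientations) {
    for (h in hues) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "hue_grating", hue_deg = h, orientation_deg = o,
        contrast = luminance_contrast)
    }
  }
  for (o in orientations) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "achromatic_grating", hue_deg = NA_real_, orientation_deg = o,
      contrast = luminance_contrast)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    kind = "blank", hue_deg = NA_real_, orientation_deg = NA_real_,
    contrast = 0)
  out <- do.call(rbind, rows)
  out$condition_id <- ifelse(
    out$kind == "hue_grating",
    sprintf("hue%03d_o%02d", out$hue_deg, out$orientation_deg),
    ifelse(out$kind == "achromatic_grating",
           sprintf("achrom_o%02d", out$orientation_deg), "blank"))
  out[, c("condition_id", "kind", "hue_deg", "orientation_deg", "contrast")]
}

#' Write / read a condition table as TSV
#'
#' @param conditions a condition data.frame from [make_condition_set()].
#' @param path file path of the TSV.
#' @return `write_condition_table()` returns `path` invisibly;
#'   `read_condition_table()` returns the condition data.frame.
#' @export
write_condition_table <- function(conditions, path) {
  utils::write.table(conditions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
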