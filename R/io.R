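# File formats: multi-frame TIFF trial stacks, TIFF maps with JSON sidecars,
# TSV tables, YAML configuration.

#' @noRd
sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a trial stack as multi-frame TIFF
#'
#' Stacks hold integer camera counts in `[0, 65535]` and are stored as
#' 16-bit TIFF (exactly lossless) with a JSON sidecar carrying the timing
#' metadata (`frame_rate`, `t_onset`, `duration`), `condition_id`,
#' `session_id`, `pixel_pitch` and `seed`.
#'
#' @param stack a `trial_stack`.
#' @param path TIFF file path; the sidecar is written at `<path>.json`.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   the `trial_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "trial_stack"))
  f <- stack$frames
  if (any(f < 0 | f > 65535) || any(f != round(f)))
    stop("stack frames must be integer counts in [0, 65535]", call. = FALSE)
  frames <- lapply(seq_len(dim(f)[3]), function(k) f[, , k] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  meta <- list(n_frames = dim(f)[3], frame_rate = stack$frame_rate,
               t_onset = stack$t_onset, duration = stack$duration,
               condition_id = stack$condition_id,
               session_id = stack$session_id,
               pixel_pitch = stack$pixel_pitch, seed = stack$seed,
               scale = 65535)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such stack: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar for stack: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (field in c("n_frames", "frame_rate", "t_onset", "pixel_pitch"))
    if (is.null(meta[[field]]))
      stop("sidecar is missing required field '", field, "'", call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (length(frames) != meta$n_frames)
    stop(sprintf("frame-count mismatch: TIFF has %d frames, sidecar says %d",
                 length(frames), meta$n_frames), call. = FALSE)
  a <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (k in seq_along(frames)) a[, , k] <- round(frames[[k]] * 65535)
  structure(list(frames = a, frame_rate = meta$frame_rate,
                 t_onset = meta$t_onset,
                 duration = meta$duration %||% (meta$n_frames / meta$frame_rate),
                 condition_id = meta$condition_id %||% NA_character_,
                 session_id = meta$session_id %||% NA_character_,
                 pixel_pitch = meta$pixel_pitch,
                 seed = meta$seed %||% NA_integer_),
            class = "trial_stack")
}

#' Write / read a response map as TIFF + JSON sidecar
#'
#' Maps are stored as a two-frame TIFF: frame 1 holds the values affinely
#' rescaled to `[0, 1]` at 32-bit depth, frame 2 a validity mask. The affine
#' `scale_lo`/`scale_hi`, `pixel_pitch` and provenance live in the JSON
#' sidecar. Round-trip error is bounded by `(max - min) * 2^-33`, finer than
#' single precision over the data range (the TIFF library stores 32-bit
#' samples as scaled integers, so arbitrary floats are not bit-preserved).
#'
#' @param map a [response_map()].
#' @param path TIFF file path; sidecar at `<path>.json`.
#' @return `write_map()` returns `path` invisibly; `read_map()` the
#'   [response_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "response_map"))
  v <- map$values
  fin <- is.finite(v)
  lo <- if (any(fin)) min(v[fin]) else 0
  hi <- if (any(fin)) max(v[fin]) else 0
  q <- matrix(0, nrow(v), ncol(v))
  if (hi > lo) q[fin] <- (v[fin] - lo) / (hi - lo)
  tiff::writeTIFF(list(q, fin + 0), path, bits.per.sample = 32L,
                  compression = "none")
  meta <- list(scale_lo = lo, scale_hi = hi, pixel_pitch = map$pixel_pitch,
               provenance = map$provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("no such map: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar for map: ", sc,
                             call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$pixel_pitch))
    stop("sidecar is missing required field 'pixel_pitch'", call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (length(frames) != 2)
    stop("map TIFF must have 2 frames (values, validity)", call. = FALSE)
  v <- frames[[1]] * (meta$scale_hi - meta$scale_lo) + meta$scale_lo
  v[frames[[2]] < 0.5] <- NA_real_
  prov <- meta$provenance
  response_map(v, meta$pixel_pitch,
               provenance = if (is.null(prov)) list() else as.list(prov))
}

#' Default experiment configuration
#'
#' All tunable constants of the pipeline in one nested list: geometry,
#' timing, filter sizes, statistical thresholds, cluster rule, decoding
#' settings and simulator parameters. `desk = TRUE` shrinks the simulated
#' field and trial counts for quick smoke runs.
#'
#' @param desk use the small smoke-test geometry (default FALSE).
#' @return nested configuration list.
#' @export
default_config <- function(desk = FALSE) {
  cfg <- list(
    pixel_pitch = 8,
    timing = list(frame_rate = 4, duration = 4.5, t_onset = 1.0,
                  pre_window = c(-1, 0), resp_window = c(1, 3.5)),
    filters = list(highpass_mm = 1.0, smooth_um = 160),
    stats = list(alpha = 0.05, peak_alpha = 0.001, min_pixels = 200,
                 vessel_alpha = 0.05),
    clusters = list(min_hues = 4),
    decoding = list(bin_factor = 10, k = 10, B = 1000, cost = 1,
                    normalization = "pooled", test_fraction = 0.1),
    synth = list(field_size = c(256, 256), n_trials_per_condition = 40,
                 n_sessions = 2, domain_diameter_um = 250,
                 ring_radius_um = 160, n_clusters = 4,
                 tuning_halfwidth = 45,
                 baseline_level = 40000, shot_noise_sd = 2.7e-4,
                 vessel_noise_multiplier = 3, global_amplitude = 5e-4,
                 vasomotion_sd = 1.2e-4, vasomotion_scale_um = 150,
                 hemodynamic_peak_dRR = -1e-3, hemodynamic_rise_time = 1.0),
    seed = 1)
  if (desk) {
    cfg$pixel_pitch <- 16
    cfg$synth$field_size <- c(128, 128)
    cfg$synth$n_trials_per_condition <- 6
    cfg$synth$ring_radius_um <- 240
    cfg$synth$domain_diameter_um <- 320
    cfg$decoding$k <- 3
    cfg$decoding$B <- 50
    cfg$decoding$bin_factor <- 5
  }
  cfg
}

#' Read / write a configuration as YAML
#'
#' @param config configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   configuration list merged over the defaults (so partial files work).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_rec(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_rec(default_config(), user)
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialization; recorded in every pipeline
#' output so results are traceable to (config, seed).
#'
#' @param config configuration list.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}
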