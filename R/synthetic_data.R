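# Synthetic ISOI experiment generator with planted ground truth.
#
# The generator emulates the features of hue-mapping intrinsic-signal data
# that the downstream pipeline must cope with: stimulus-evoked local
# darkening (negative dR/R, ~1e-3) confined to hue-tuned domains grouped in
# clusters, a large-scale global signal (>= millimeters), per-frame shot
# noise, and vessel pixels with inflated trial-to-trial variance.

#' Circular raised-cosine hue tuning
#'
#' Tuning weight of a domain preferring `pref` for a stimulus hue `hue`,
#' as a raised cosine of the circular hue difference with compact support:
#' `cos(pi/2 * d/halfwidth)^2` for circular distance `d < halfwidth`, else 0.
#' At the default `halfwidth = 45` each domain responds to exactly one of the
#' eight canonical hues, which keeps planted ground truth crisp; wider values
#' give graded responses to neighboring hues.
#'
#' @param hue stimulus hue angle(s), degrees.
#' @param pref preferred hue angle, degrees.
#' @param halfwidth half-width at zero of the raised cosine, degrees.
#' @return numeric tuning weight(s) in `[0, 1]`.
#' @export
hue_tuning <- function(hue, pref, halfwidth = 45) {
  d <- abs(((hue - pref + 180) %% 360) - 180)
  ifelse(d < halfwidth, cos(pi / 2 * d / halfwidth)^2, 0)
}

#' Acquisition / signal parameters for the simulator
#'
#' Bundles the noise and signal constants of the simulated recording: camera
#' baseline and shot noise, vessel noise inflation, global-signal and
#' vasomotion fluctuations, and the hemodynamic response amplitude and rise
#' time. Defaults put the per-trial dR/R map noise SD at ~2e-4, one fifth of
#' the default response peak.
#'
#' @param baseline_level mean reflectance in camera counts (default 40000,
#'   a 16-bit-range sensor working near 60\% full well).
#' @param shot_noise_sd per-frame, per-pixel independent noise SD as a
#'   fraction of baseline (default 2.7e-4, contributing about 1.6e-4 SD to
#'   a single-trial dR/R map).
#' @param vessel_noise_multiplier factor (> 1) by which the frame noise SD is
#'   inflated on vessel pixels (default 3).
#' @param global_amplitude SD of the per-trial global-signal amplitude, as a
#'   fraction of baseline (default 5e-4).
#' @param vasomotion_sd SD of the spatially correlated trial-to-trial
#'   hemodynamic fluctuation, expressed directly as its contribution to a
#'   single-trial dR/R map (default 1.2e-4). Together with the shot-noise
#'   contribution this puts the total map noise SD at about 2e-4, one fifth
#'   of the default response peak.
#' @param vasomotion_scale_um correlation length of the vasomotion field
#'   (default 150 um, the scale of the fine parenchymal vasculature; see the
#'   vignette for why the correlation length matters for cluster-level
#'   false positives).
#' @param hemodynamic_peak_dRR plateau fractional darkening of a fully driven
#'   domain pixel; must be negative (default -1e-3).
#' @param hemodynamic_rise_time seconds from stimulus onset to plateau
#'   (default 1.0).
#' @return list of class `acquisition_params`.
#' @export
acquisition_params <- function(baseline_level = 40000,
                               shot_noise_sd = 2.7e-4,
                               vessel_noise_multiplier = 3,
                               global_amplitude = 5e-4,
                               vasomotion_sd = 1.2e-4,
                               vasomotion_scale_um = 150,
                               hemodynamic_peak_dRR = -1e-3,
                               hemodynamic_rise_time = 1.0) {
  if (vessel_noise_multiplier <= 1)
    stop("vessel_noise_multiplier must be > 1", call. = FALSE)
  if (hemodynamic_peak_dRR >= 0)
    stop("hemodynamic_peak_dRR must be negative (activation darkens the tissue)",
         call. = FALSE)
  if (baseline_level <= 0 || shot_noise_sd < 0 || global_amplitude < 0 ||
      vasomotion_sd < 0 || vasomotion_scale_um <= 0 ||
      hemodynamic_rise_time <= 0)
    stop("invalid acquisition parameter", call. = FALSE)
  structure(list(baseline_level = baseline_level,
                 shot_noise_sd = shot_noise_sd,
                 vessel_noise_multiplier = vessel_noise_multiplier,
                 global_amplitude = global_amplitude,
                 vasomotion_sd = vasomotion_sd,
                 vasomotion_scale_um = vasomotion_scale_um,
                 hemodynamic_peak_dRR = hemodynamic_peak_dRR,
                 hemodynamic_rise_time = hemodynamic_rise_time),
            class = "acquisition_params")
}

# disk mask helper: logical H x W matrix, TRUE within radius of (row, col)
#' @noRd
disk_mask <- function(dim, center, radius) {
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Plant a ground-truth layout of hue domains, clusters and vessels
#'
#' Places `n_clusters` hue clusters on the field. Each cluster is a ring of
#' circular domains, one per hue in its `hue_subset`, positioned around the
#' cluster center at the hue's own polar angle (plus a per-cluster random
#' rotation), so that domains of adjacent hues overlap partially and the
#' cluster is detectable as a chain of overlapping domains arranged
#' circularly in hue order. Domain diameters are jittered log-normally around
#' `domain_diameter_um`. A smooth millimeter-scale global-signal field and a
#' set of vessel lines are also generated.
#'
#' Defaults plant domains of 250 um equivalent diameter, within the range
#' reported for higher visual areas. The detection pipeline imposes two
#' size floors that the defaults deliberately clear: the cluster-extent rule
#' (200 contiguous pixels at 8 um/pixel = equivalent diameter ~128 um) and
#' the 160 um median smoothing, which erodes compact dark disks and
#' fragments domains whose area is comparable to half its window (~200 um
#' diameter). Layouts emulating the smallest (V1-like, ~84 um) domains fall
#' below both floors and cannot be recovered by the described method.
#'
#' @param field_size `c(H, W)` in pixels (default `c(256, 256)`).
#' @param pixel_pitch micrometers per pixel (default 8).
#' @param n_clusters number of planted clusters (default 4, arranged on a
#'   2 x 2 grid with jitter). Ignored if `cluster_centers` is given.
#' @param cluster_centers optional matrix/list of `(row, col)` centers.
#' @param hue_subsets list (length `n_clusters`) of hue vectors planted in
#'   each cluster. Default: all but the last cluster complete (8 hues), the
#'   last missing hues 45 and 90 (emulating under-represented +S hues).
#' @param domain_diameter_um mean planted domain equivalent diameter
#'   (default 250).
#' @param diameter_jitter lognormal SD of the diameter jitter as a fraction
#'   (default 0.10, truncated at +/- 2 SD).
#' @param diameter_scale optional named vector of per-hue diameter
#'   multipliers (names = hue angles), e.g. to plant smaller 90-degree
#'   domains.
#' @param ring_radius_um radius of the domain-center ring (default 160).
#' @param tuning_halfwidth hue tuning half-width in degrees, see
#'   [hue_tuning()] (default 45).
#' @param amplitude relative response amplitude per domain (default 1;
#'   multiplies `hemodynamic_peak_dRR`).
#' @param n_vessels,vessel_width_px vessel lines drawn across the field
#'   (default 3 lines, 3 px wide).
#' @param global_wavelength_mm spatial wavelength of the global-signal field
#'   (default 10 mm -- global signals span the whole imaged region, several
#'   millimeters or more, so the 1 mm high-pass can remove them).
#' @param hues hue angles of the experiment (default the canonical eight).
#' @param seed integer seed; the layout is deterministic given the seed.
#' @return list of class `gt_layout` with fields `field_size`, `pixel_pitch`,
#'   `hues`, `domain_table` (one row per planted domain: `domain_id`,
#'   `cluster_id`, `hue_deg`, `center_row`, `center_col`, `radius_px`,
#'   `diameter_um`, `amplitude`), `domain_pixels` (list of pixel index
#'   vectors), `hue_masks` (named list of logical matrices, union per hue),
#'   `cluster_table` (`cluster_id`, `n_hues`, `complete`, `sub_threshold`),
#'   `vessel_mask`, `global_field`, `tuning_halfwidth`, `params`, `seed`.
#' @export
make_layout <- function(field_size = c(256, 256), pixel_pitch = 8,
                        n_clusters = 4, cluster_centers = NULL,
                        hue_subsets = NULL,
                        domain_diameter_um = 250, diameter_jitter = 0.10,
                        diameter_scale = NULL,
                        ring_radius_um = 160, tuning_halfwidth = 45,
                        amplitude = 1,
                        n_vessels = 3, vessel_width_px = 3,
                        global_wavelength_mm = 10,
                        hues = dkl_hue_angles(), seed = 1) {
  H <- field_size[1]; W <- field_size[2]
  if (is.null(cluster_centers)) {
    # jittered grid of cluster centers
    g <- ceiling(sqrt(n_clusters))
    centers <- expand.grid(
      row = seq(H / (2 * g), H - H / (2 * g), length.out = g),
      col = seq(W / (2 * g), W - W / (2 * g), length.out = g))
    centers <- centers[seq_len(n_clusters), , drop = FALSE]
  } else {
    centers <- as.data.frame(do.call(rbind, lapply(cluster_centers, as.numeric)))
    names(centers) <- c("row", "col")
    n_clusters <- nrow(centers)
  }
  if (is.null(hue_subsets)) {
    hue_subsets <- rep(list(hues), n_clusters)
    if (n_clusters > 1) hue_subsets[[n_clusters]] <- setdiff(hues, c(45, 90))
  }
  if (length(hue_subsets) != n_clusters)
    stop("hue_subsets must have one element per cluster", call. = FALSE)
  ring_px <- ring_radius_um / pixel_pitch
  max_r_px <- (domain_diameter_um * (1 + 2 * diameter_jitter) / 2) / pixel_pitch
  if (ring_px + max_r_px > min(H, W) / 2)
    stop("cluster radius exceeds field extent", call. = FALSE)

  with_seed(derive_seed(seed, "layout"), {
    rows <- list(); domain_pixels <- list(); did <- 0L
    for (ci in seq_len(n_clusters)) {
      rot <- runif(1, 0, 360)
      for (h in sort(hue_subsets[[ci]])) {
        did <- did + 1L
        a <- (h + rot) * pi / 180
        ctr <- c(centers$row[ci] + ring_px * sin(a),
                 centers$col[ci] + ring_px * cos(a))
        jit <- exp(pmin(pmax(rnorm(1, 0, diameter_jitter), -2 * diameter_jitter),
                        2 * diameter_jitter))
        sc <- if (!is.null(diameter_scale) && as.character(h) %in% names(diameter_scale))
          diameter_scale[[as.character(h)]] else 1
        diam_um <- domain_diameter_um * jit * sc
        r_px <- diam_um / 2 / pixel_pitch
        if (ctr[1] - r_px < 1 || ctr[1] + r_px > H ||
            ctr[2] - r_px < 1 || ctr[2] + r_px > W)
          stop("cluster radius exceeds field extent", call. = FALSE)
        m <- disk_mask(c(H, W), ctr, r_px)
        rows[[did]] <- data.frame(domain_id = did, cluster_id = ci, hue_deg = h,
                                  center_row = ctr[1], center_col = ctr[2],
                                  radius_px = r_px, diameter_um = diam_um,
                                  amplitude = amplitude)
        domain_pixels[[did]] <- which(m)
      }
    }
    domain_table <- do.call(rbind, rows)
    hue_masks <- setNames(lapply(hues, function(h) {
      m <- matrix(FALSE, H, W)
      for (i in which(domain_table$hue_deg == h)) m[domain_pixels[[i]]] <- TRUE
      m
    }), as.character(hues))
    cluster_table <- data.frame(
      cluster_id = seq_len(n_clusters),
      center_row = centers$row, center_col = centers$col,
      n_hues = vapply(hue_subsets, function(s) length(unique(s)), integer(1)))
    cluster_table$complete <- cluster_table$n_hues == length(hues)
    cluster_table$sub_threshold <- cluster_table$n_hues < 4

    # vessels: random straight lines of the configured width, rejected when
    # they run through a planted cluster (ground-truth clusters live in
    # analyzable, vessel-free tissue; the screening rule would otherwise
    # split or drop their domains, making the planted truth ambiguous)
    vessel_mask <- matrix(FALSE, H, W)
    if (n_vessels > 0) {
      rr <- matrix(seq_len(H), H, W)
      cc <- matrix(seq_len(W), H, W, byrow = TRUE)
      clearance <- ring_px + max_r_px + 12
      for (v in seq_len(n_vessels)) {
        best <- NULL; best_d <- -Inf
        for (try in seq_len(200)) {
          th <- runif(1, 0, pi)
          p0 <- c(runif(1, 1, H), runif(1, 1, W))
          dmin <- min(abs((centers$row - p0[1]) * cos(th) +
                            (centers$col - p0[2]) * sin(th)))
          if (dmin > best_d) { best_d <- dmin; best <- list(th = th, p0 = p0) }
          if (dmin > clearance) break
        }
        dist <- abs((rr - best$p0[1]) * cos(best$th) +
                      (cc - best$p0[2]) * sin(best$th))
        vessel_mask <- vessel_mask | (dist <= vessel_width_px / 2)
      }
    }

    # global-signal field: one low-spatial-frequency component; at the
    # default 10 mm wavelength its curvature over the 1 mm high-pass window
    # is negligible, so the running-median subtraction removes it almost
    # exactly (as the study's preprocessing assumes)
    lambda_px <- global_wavelength_mm * 1000 / pixel_pitch
    gth <- runif(1, 0, pi); gph <- runif(1, 0, 2 * pi)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    global_field <- cos(2 * pi * (rr * cos(gth) + cc * sin(gth)) / lambda_px + gph)

    structure(list(field_size = c(H, W), pixel_pitch = pixel_pitch,
                   hues = hues, domain_table = domain_table,
                   domain_pixels = domain_pixels, hue_masks = hue_masks,
                   cluster_table = cluster_table, vessel_mask = vessel_mask,
                   global_field = global_field,
                   tuning_halfwidth = tuning_halfwidth,
                   params = list(domain_diameter_um = domain_diameter_um,
                                 diameter_jitter = diameter_jitter,
                                 ring_radius_um = ring_radius_um,
                                 n_vessels = n_vessels,
                                 vessel_width_px = vessel_width_px),
                   seed = seed),
              class = "gt_layout")
  })
}

# spatially correlated unit-variance noise field: white noise on a coarse
# grid (spacing = correlation length), bilinearly upsampled with a random
# per-call grid offset so the variance pattern is stationary across trials
#' @noRd
correlated_field <- function(H, W, scale_px) {
  g <- max(scale_px, 2)
  off_r <- runif(1, 0, g); off_c <- runif(1, 0, g)
  u <- (seq_len(H) - 1 + off_r) / g
  v <- (seq_len(W) - 1 + off_c) / g
  i0 <- floor(u); j0 <- floor(v)
  wr <- u - i0; wc <- v - j0
  K <- matrix(rnorm((max(i0) + 2) * (max(j0) + 2)), max(i0) + 2)
  i0 <- i0 + 1L; j0 <- j0 + 1L
  f <- K[i0, j0] * outer(1 - wr, 1 - wc) +
    K[i0 + 1L, j0] * outer(wr, 1 - wc) +
    K[i0, j0 + 1L] * outer(1 - wr, wc) +
    K[i0 + 1L, j0 + 1L] * outer(wr, wc)
  # bilinear mixing of unit normals has mean variance 4/9 under a uniform
  # grid offset; rescale to unit variance
  f * 1.5
}

# expected dR/R amplitude map (fraction of baseline) for a condition
#' @noRd
condition_amplitude <- function(layout, condition, acq) {
  H <- layout$field_size[1]; W <- layout$field_size[2]
  A <- matrix(0, H, W)
  if (identical(condition$kind, "hue_grating")) {
    dt <- layout$domain_table
    for (i in seq_len(nrow(dt))) {
      w <- hue_tuning(condition$hue_deg, dt$hue_deg[i], layout$tuning_halfwidth)
      if (w > 0) {
        px <- layout$domain_pixels[[i]]
        # overlapping footprints saturate (take the max) rather than add
        A[px] <- pmax(A[px], dt$amplitude[i] * w)
      }
    }
  }
  A * acq$hemodynamic_peak_dRR
}

#' Simulate one stimulus presentation
#'
#' Generates an 18-frame (4 frames/s x 4.5 s) reflectance stack for one
#' condition: 1 s pre-stimulus baseline, then stimulus-evoked darkening in
#' hue-tuned domains ramping to plateau over the hemodynamic rise time, a
#' low-spatial-frequency global signal common to all conditions (including
#' blanks), per-frame shot noise, and inflated noise on vessel pixels.
#' Frames are digitized to integer camera counts. Frame k (1-based) covers
#' `[(k-1)/4, k/4)` seconds from trial start; stimulus onset is at 1.0 s.
#'
#' @param layout a `gt_layout` from [make_layout()].
#' @param condition one row of a condition table (list or 1-row data.frame
#'   with `condition_id`, `kind`, `hue_deg`).
#' @param acq an [acquisition_params()] object.
#' @param seed integer seed for this trial.
#' @param frame_rate frames per second (default 4).
#' @param duration trial length in seconds (default 4.5).
#' @param t_onset stimulus onset in seconds from trial start (default 1.0).
#' @return list of class `trial_stack`: `frames` (H x W x T integer counts),
#'   `frame_rate`, `t_onset`, `duration`, `condition_id`, `session_id`
#'   (NA here), `pixel_pitch`, `seed`.
#' @export
simulate_trial <- function(layout, condition, acq = acquisition_params(),
                           seed = 1, frame_rate = 4, duration = 4.5,
                           t_onset = 1.0) {
  if (is.data.frame(condition)) condition <- as.list(condition[1, ])
  if (is.null(condition$kind) ||
      !condition$kind %in% c("hue_grating", "achromatic_grating",
                             "red_green_grating", "black_white_grating",
                             "blank"))
    stop("unknown condition kind: ", condition$kind %||% "<missing>",
         call. = FALSE)
  H <- layout$field_size[1]; W <- layout$field_size[2]
  Tn <- round(frame_rate * duration)
  t_mid <- (seq_len(Tn) - 0.5) / frame_rate
  ramp <- pmin(pmax((t_mid - t_onset) / acq$hemodynamic_rise_time, 0), 1)
  A <- condition_amplitude(layout, condition, acq)
  B <- acq$baseline_level
  sd_map <- matrix(acq$shot_noise_sd * B, H, W)
  sd_map[layout$vessel_mask] <- sd_map[layout$vessel_mask] *
    acq$vessel_noise_multiplier
  # scale the slowly drifting components so that their net contribution to
  # the standard dR/R windows (pre [-1,0), response [1,3.5) s re onset)
  # equals the configured map-level SD
  rel <- t_mid - t_onset
  S <- (mean(t_mid[rel >= 1 & rel < 3.5]) -
          mean(t_mid[rel >= -1 & rel < 0])) / duration
  with_seed(seed, {
    g_amp <- rnorm(1, 0, acq$global_amplitude)
    vaso <- if (acq$vasomotion_sd > 0)
      correlated_field(H, W, acq$vasomotion_scale_um / layout$pixel_pitch) *
        (acq$vasomotion_sd / S) else 0
    frames <- array(0, dim = c(H, W, Tn))
    for (k in seq_len(Tn)) {
      mean_k <- B * (1 + (g_amp * layout$global_field + vaso) *
                       (t_mid[k] / duration) + A * ramp[k])
      frames[, , k] <- mean_k + rnorm(H * W) * sd_map
    }
    frames <- round(frames)
    frames[frames < 1] <- 1
    structure(list(frames = frames, frame_rate = frame_rate,
                   t_onset = t_onset, duration = duration,
                   condition_id = condition$condition_id %||% condition$kind,
                   session_id = NA_character_,
                   pixel_pitch = layout$pixel_pitch, seed = seed),
              class = "trial_stack")
  })
}

#' Expected mean dR/R of a pixel over the response window
#'
#' Closed-form counterpart of [simulate_trial()] + [compute_dRR()] for test
#' oracles: plateau amplitude times hue tuning times the mean of the
#' hemodynamic ramp over the response-window frames.
#'
#' @inheritParams simulate_trial
#' @param pixel `c(row, col)` of the probed pixel.
#' @param pre_window,resp_window windows in seconds relative to onset, as in
#'   [compute_dRR()].
#' @return expected dR/R (scalar).
#' @export
expected_dRR <- function(layout, condition, acq = acquisition_params(),
                         pixel, frame_rate = 4, duration = 4.5,
                         t_onset = 1.0, pre_window = c(-1, 0),
                         resp_window = c(1, 3.5)) {
  if (is.data.frame(condition)) condition <- as.list(condition[1, ])
  A <- condition_amplitude(layout, condition, acq)
  Tn <- round(frame_rate * duration)
  t_mid <- (seq_len(Tn) - 0.5) / frame_rate
  rel <- t_mid - t_onset
  ramp <- pmin(pmax(rel / acq$hemodynamic_rise_time, 0), 1)
  in_resp <- rel >= resp_window[1] & rel < resp_window[2]
  in_pre <- rel >= pre_window[1] & rel < pre_window[2]
  A[pixel[1], pixel[2]] * (mean(ramp[in_resp]) - mean(ramp[in_pre]))
}

#' Simulate a full experiment
#'
#' Runs [simulate_trial()] for every condition repeat in every session, in a
#' pseudo-random per-session order. Each session presents every condition
#' `n_trials_per_condition` times. To keep memory bounded, frames can be
#' reduced to dR/R response maps on the fly (`keep = "dRR"`, the default) or
#' written to multi-frame TIFF stacks (`outdir`).
#'
#' @param layout a `gt_layout`.
#' @param conditions condition table from [make_condition_set()].
#' @param n_trials_per_condition repeats of each condition per session
#'   (default 40).
#' @param n_sessions number of sessions (default 2).
#' @param acq an [acquisition_params()] object.
#' @param seed master seed; all per-trial seeds derive from it.
#' @param keep `"dRR"` to retain per-trial response maps, `"stacks"` to
#'   retain the raw stacks (memory heavy), `"none"` to retain neither.
#' @param outdir optional directory: stacks are written as multi-frame TIFF
#'   plus a TSV manifest and a JSON ground-truth summary.
#' @param ... passed to [compute_dRR()] when `keep = "dRR"`.
#' @return list of class `sim_experiment`: `manifest` (data.frame with
#'   `stack_id`, `condition_id`, `session_id`, `seed`, `path`), `maps`
#'   (list of dR/R matrices, if kept), `stacks` (if kept), `layout`,
#'   `conditions`, `acq`.
#' @export
simulate_experiment <- function(layout, conditions,
                                n_trials_per_condition = 40, n_sessions = 2,
                                acq = acquisition_params(), seed = 1,
                                keep = c("dRR", "stacks", "none"),
                                outdir = NULL, ...) {
  keep <- match.arg(keep)
  if (n_trials_per_condition < 1) stop("need >= 1 trial per condition",
                                       call. = FALSE)
  rows <- list(); maps <- list(); stacks <- list(); sid <- 0L
  for (s in seq_len(n_sessions)) {
    reps <- rep(seq_len(nrow(conditions)), n_trials_per_condition)
    order_seed <- derive_seed(seed, paste0("order", s))
    reps <- with_seed(order_seed, sample(reps))
    for (ri in seq_along(reps)) {
      sid <- sid + 1L
      cond <- conditions[reps[ri], ]
      tseed <- derive_seed(seed, paste0("s", s, "t", ri, cond$condition_id))
      st <- simulate_trial(layout, cond, acq, seed = tseed)
      st$session_id <- sprintf("session%02d", s)
      path <- NA_character_
      if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        path <- sprintf("stack_%05d.tif", sid)  # relative to outdir
        write_stack(st, file.path(outdir, path))
      }
      rows[[sid]] <- data.frame(stack_id = sid,
                                condition_id = cond$condition_id,
                                session_id = st$session_id,
                                seed = tseed, path = path)
      if (keep == "dRR") maps[[sid]] <- compute_dRR(st, ...)$values
      if (keep == "stacks") stacks[[sid]] <- st
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gt <- list(seed = seed,
               cluster_table = layout$cluster_table,
               domain_table = layout$domain_table)
    jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(manifest = manifest,
                 maps = if (keep == "dRR") maps,
                 stacks = if (keep == "stacks") stacks,
                 layout = layout, conditions = conditions, acq = acq,
                 seed = seed),
            class = "sim_experiment")
}
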