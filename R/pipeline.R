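# End-to-end pipeline stages over a working directory, and the thin
# orchestration used by the command-line script: simulate | maps | stats |
# domains | decode | report. Each stage reads the stage outputs before it,
# writes its own outputs plus a log line, and embeds the config hash + seed.

#' @noRd
log_stage <- function(workdir, stage, msg, t0 = NULL) {
  line <- sprintf("[%s] %s: %s%s", format(Sys.time(), "%H:%M:%S"), stage, msg,
                  if (!is.null(t0))
                    sprintf(" (%.1fs)", (proc.time() - t0)[["elapsed"]])
                  else "")
  cat(line, "\n", file = file.path(workdir, "pipeline.log"), append = TRUE)
  message(line)
}

#' @noRd
write_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# config_hash=%s seed=%s\n", config_hash(config),
              config$seed), file = con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @noRd
require_stage <- function(workdir, file, stage_needed) {
  p <- file.path(workdir, file)
  if (!file.exists(p))
    stop("missing '", file, "': run stage '", stage_needed, "' first",
         call. = FALSE)
  p
}

#' @noRd
layout_from_config <- function(config) {
  s <- config$synth
  make_layout(field_size = s$field_size, pixel_pitch = config$pixel_pitch,
              n_clusters = s$n_clusters,
              domain_diameter_um = s$domain_diameter_um,
              ring_radius_um = s$ring_radius_um,
              tuning_halfwidth = s$tuning_halfwidth,
              seed = config$seed)
}

#' @noRd
acq_from_config <- function(config) {
  s <- config$synth
  acquisition_params(baseline_level = s$baseline_level,
                     shot_noise_sd = s$shot_noise_sd,
                     vessel_noise_multiplier = s$vessel_noise_multiplier,
                     global_amplitude = s$global_amplitude,
                     vasomotion_sd = s$vasomotion_sd,
                     vasomotion_scale_um = s$vasomotion_scale_um,
                     hemodynamic_peak_dRR = s$hemodynamic_peak_dRR,
                     hemodynamic_rise_time = s$hemodynamic_rise_time)
}

#' Pipeline stages
#'
#' File-based stages of the hue-domain pipeline. `stage_simulate()` writes a
#' synthetic experiment (trial stacks + manifest + ground truth);
#' `stage_maps()` converts stacks to high-pass-filtered dR/R maps and builds
#' single-condition and vector-sum maps; `stage_stats()` computes vessel
#' masks and per-hue significant regions (cluster-extent rule across the two
#' sessions); `stage_domains()` extracts hue domains and clusters with
#' morphometrics; `stage_decode()` runs the decoding analysis;
#' `stage_report()` aggregates everything into `report.md`. A stage stops
#' with an informative error when the outputs of an earlier stage are
#' missing.
#'
#' @param config configuration list (see [default_config()]).
#' @param workdir working directory for stage inputs/outputs.
#' @return the workdir, invisibly (each stage); [run_pipeline()] returns a
#'   list of per-stage summaries.
#' @export
stage_simulate <- function(config, workdir) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()
  conditions <- make_condition_set()
  layout <- layout_from_config(config)
  simulate_experiment(layout, conditions,
                      n_trials_per_condition = config$synth$n_trials_per_condition,
                      n_sessions = config$synth$n_sessions,
                      acq = acq_from_config(config), seed = config$seed,
                      keep = "none", outdir = file.path(workdir, "stacks"))
  write_tsv(conditions, file.path(workdir, "conditions.tsv"), config)
  write_config(config, file.path(workdir, "config.yaml"))
  # ground-truth masks for later validation
  gtdir <- file.path(workdir, "ground_truth")
  dir.create(gtdir, showWarnings = FALSE)
  for (h in names(layout$hue_masks))
    write_map(response_map(layout$hue_masks[[h]] + 0, config$pixel_pitch,
                           list(kind = "gt_mask", hue = h)),
              file.path(gtdir, sprintf("mask_hue%s.tif", h)))
  write_map(response_map(layout$vessel_mask + 0, config$pixel_pitch,
                         list(kind = "gt_vessels")),
            file.path(gtdir, "vessels.tif"))
  log_stage(workdir, "simulate",
            sprintf("%d stacks (%d conditions x %d trials x %d sessions)",
                    nrow(conditions) * config$synth$n_trials_per_condition *
                      config$synth$n_sessions, nrow(conditions),
                    config$synth$n_trials_per_condition,
                    config$synth$n_sessions), t0)
  invisible(workdir)
}

#' @rdname stage_simulate
#' @export
stage_maps <- function(config, workdir) {
  t0 <- proc.time()
  manifest <- read_tsv(require_stage(workdir, "stacks/manifest.tsv",
                                     "simulate"))
  conditions <- read_tsv(file.path(workdir, "conditions.tsv"))
  mapdir <- file.path(workdir, "maps")
  dir.create(mapdir, showWarnings = FALSE)
  # per-trial raw dR/R maps on disk; per-condition means of high-pass
  # filtered maps accumulated for the display maps
  hp_sum <- list(); hp_n <- list()
  manifest$map_path <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    st <- read_stack(file.path(workdir, "stacks",
                               basename(manifest$path[i])))
    m <- compute_dRR(st, pre_window = config$timing$pre_window,
                     resp_window = config$timing$resp_window)
    mp <- sprintf("trial_%05d.tif", manifest$stack_id[i])
    write_map(m, file.path(mapdir, mp))
    manifest$map_path[i] <- mp
    hp <- highpass(m, kernel_mm = config$filters$highpass_mm)$values
    cid <- manifest$condition_id[i]
    if (is.null(hp_sum[[cid]])) { hp_sum[[cid]] <- hp; hp_n[[cid]] <- 1L }
    else { hp_sum[[cid]] <- hp_sum[[cid]] + hp; hp_n[[cid]] <- hp_n[[cid]] + 1L }
  }
  write_tsv(manifest, file.path(workdir, "maps_manifest.tsv"), config)
  # single-condition maps for the hues + vector-sum preference map
  blank_mean <- hp_sum[["blank"]] / hp_n[["blank"]]
  hues <- sort(conditions$hue_deg[conditions$kind == "hue_grating"])
  sc_maps <- list()
  for (h in hues) {
    cid <- conditions$condition_id[conditions$kind == "hue_grating" &
                                     conditions$hue_deg == h][1]
    sc <- response_map(hp_sum[[cid]] / hp_n[[cid]] - blank_mean,
                       config$pixel_pitch,
                       list(kind = "single_condition", hue = h,
                            n_trials = hp_n[[cid]]))
    write_map(sc, file.path(mapdir, sprintf("single_hue%03d.tif", h)))
    sc_maps[[as.character(h)]] <- sc
  }
  if (length(sc_maps) == 8) {
    vm <- hue_vector_map(sc_maps)
    write_map(response_map(vm$angle, config$pixel_pitch, list(kind = "angle")),
              file.path(mapdir, "hue_angle.tif"))
    write_map(response_map(vm$magnitude, config$pixel_pitch,
                           list(kind = "magnitude")),
              file.path(mapdir, "hue_magnitude.tif"))
    render_angle_map(vm, file.path(mapdir, "hue_angle.png"))
  }
  log_stage(workdir, "maps", sprintf("%d trial maps, %d single-condition maps",
                                     nrow(manifest), length(sc_maps)), t0)
  invisible(workdir)
}

#' @rdname stage_simulate
#' @export
stage_stats <- function(config, workdir) {
  t0 <- proc.time()
  manifest <- read_tsv(require_stage(workdir, "maps_manifest.tsv", "maps"))
  conditions <- read_tsv(file.path(workdir, "conditions.tsv"))
  mapdir <- file.path(workdir, "maps")
  statdir <- file.path(workdir, "stats")
  dir.create(statdir, showWarnings = FALSE)
  load_maps <- function(ids, filter = c("smooth", "highpass", "none")) {
    filter <- match.arg(filter)
    lapply(ids, function(id) {
      v <- read_map(file.path(mapdir, sprintf("trial_%05d.tif", id)))$values
      switch(filter,
             smooth = smooth_map(v, kernel_um = config$filters$smooth_um,
                                 pixel_pitch = config$pixel_pitch),
             highpass = highpass(v, kernel_mm = config$filters$highpass_mm,
                                 pixel_pitch = config$pixel_pitch),
             none = v)
    })
  }
  # vessel mask from blank trials (all sessions); high-passed (to strip the
  # global signal) but unsmoothed, so per-pixel variances stay local
  blank_ids <- manifest$stack_id[manifest$condition_id == "blank"]
  vmask <- vessel_mask(load_maps(blank_ids, filter = "highpass"),
                       alpha = config$stats$vessel_alpha)
  write_map(response_map(vmask$valid + 0, config$pixel_pitch,
                         list(kind = "vessel_valid")),
            file.path(statdir, "vessel_valid.tif"))
  sessions <- sort(unique(manifest$session_id))
  if (length(sessions) < 2)
    stop("cluster-extent thresholding needs two sessions", call. = FALSE)
  achrom_cid <- conditions$condition_id[conditions$kind ==
                                          "achromatic_grating"][1]
  hues <- sort(conditions$hue_deg[conditions$kind == "hue_grating"])
  rows <- list()
  for (h in hues) {
    cid <- conditions$condition_id[conditions$kind == "hue_grating" &
                                     conditions$hue_deg == h][1]
    stats_by_session <- lapply(sessions[1:2], function(s) {
      sel <- manifest$session_id == s
      A <- load_maps(manifest$stack_id[sel & manifest$condition_id == cid])
      B <- load_maps(manifest$stack_id[sel & manifest$condition_id ==
                                         achrom_cid])
      pixelwise_ttest(A, B, pixel_pitch = config$pixel_pitch)
    })
    rs <- cluster_extent_threshold(stats_by_session[[1]],
                                   stats_by_session[[2]], mask = vmask,
                                   alpha = config$stats$alpha,
                                   peak_alpha = config$stats$peak_alpha,
                                   min_pixels = config$stats$min_pixels)
    write_map(response_map(rs$labels + 0, config$pixel_pitch,
                           list(kind = "region_labels", hue = h)),
              file.path(statdir, sprintf("regions_hue%03d.tif", h)))
    if (nrow(rs$table) > 0)
      rows[[as.character(h)]] <- cbind(hue_deg = h, rs$table)
  }
  regions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hue_deg = numeric(0), region_id = integer(0),
               n_pixels = integer(0), min_p = numeric(0),
               peak_row = integer(0), peak_col = integer(0),
               reproduced = logical(0))
  write_tsv(regions, file.path(statdir, "regions.tsv"), config)
  log_stage(workdir, "stats",
            sprintf("%d significant regions over %d hues; %.1f%% pixels vessel-masked",
                    nrow(regions), length(hues),
                    100 * mean(!vmask$valid)), t0)
  invisible(workdir)
}

#' @rdname stage_simulate
#' @export
stage_domains <- function(config, workdir) {
  t0 <- proc.time()
  statdir <- dirname(require_stage(workdir, "stats/regions.tsv", "stats"))
  regions <- read_tsv(file.path(statdir, "regions.tsv"))
  vmask <- pixel_mask(read_map(file.path(statdir, "vessel_valid.tif"))$values
                      > 0.5, "vessel")
  hues <- dkl_hue_angles()
  regions_by_hue <- list()
  for (h in hues) {
    p <- file.path(statdir, sprintf("regions_hue%03d.tif", h))
    if (!file.exists(p)) next
    labels <- round(read_map(p)$values)
    tab <- regions[regions$hue_deg == h, setdiff(names(regions), "hue_deg"),
                   drop = FALSE]
    regions_by_hue[[as.character(h)]] <-
      structure(list(labels = labels, table = tab), class = "region_set")
  }
  ds <- extract_domains(regions_by_hue, vessel = vmask,
                        pixel_pitch = config$pixel_pitch)
  cs <- build_clusters(ds, min_hues = config$clusters$min_hues)
  domdir <- file.path(workdir, "domains")
  dir.create(domdir, showWarnings = FALSE)
  norm <- normalized_domain_area(cs)
  dom_out <- merge(ds$domains, norm[, c("domain_id", "cluster_id",
                                        "normalized_area")], by = "domain_id")
  write_tsv(dom_out, file.path(domdir, "domains.tsv"), config)
  write_tsv(cs$clusters, file.path(domdir, "clusters.tsv"), config)
  if (nrow(cs$clusters) > 0)
    write_tsv(completeness_summary(cs), file.path(domdir, "completeness.tsv"),
              config)
  log_stage(workdir, "domains",
            sprintf("%d domains, %d clusters (%d complete)",
                    nrow(ds$domains), nrow(cs$clusters),
                    sum(cs$clusters$complete)), t0)
  invisible(workdir)
}

#' @rdname stage_simulate
#' @export
stage_decode <- function(config, workdir) {
  t0 <- proc.time()
  manifest <- read_tsv(require_stage(workdir, "maps_manifest.tsv", "maps"))
  conditions <- read_tsv(file.path(workdir, "conditions.tsv"))
  mapdir <- file.path(workdir, "maps")
  hue_conds <- conditions[conditions$kind == "hue_grating", ]
  sel <- manifest$condition_id %in% hue_conds$condition_id
  maps <- lapply(manifest$stack_id[sel], function(id)
    highpass(read_map(file.path(mapdir, sprintf("trial_%05d.tif", id)))$values,
             kernel_mm = config$filters$highpass_mm,
             pixel_pitch = config$pixel_pitch))
  labels <- hue_conds$hue_deg[match(manifest$condition_id[sel],
                                    hue_conds$condition_id)]
  roi <- NULL
  vp <- file.path(workdir, "stats", "vessel_valid.tif")
  if (file.exists(vp)) roi <- read_map(vp)$values > 0.5
  fm <- make_features(maps, labels, roi = roi,
                      factor = config$decoding$bin_factor,
                      normalization = config$decoding$normalization)
  fm <- balance_trials(fm, seed = config$seed)
  cv <- cv_accuracy(fm, k = config$decoding$k, seed = config$seed,
                    cost = config$decoding$cost)
  sp <- train_test_split(fm, config$decoding$test_fraction,
                         seed = config$seed)
  bt <- bootstrap_accuracy(sp$train_X, sp$train_y, sp$test_X, sp$test_y,
                           B = config$decoding$B, seed = config$seed,
                           cost = config$decoding$cost)
  decdir <- file.path(workdir, "decoding")
  dir.create(decdir, showWarnings = FALSE)
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         n_trials = cv$n_trials, n_features = ncol(fm$X),
         k = cv$k, chance = cv$chance,
         overall_accuracy = cv$overall_accuracy,
         per_class_accuracy = as.list(cv$per_class_accuracy),
         bootstrap = list(B = bt$B, mean = bt$mean, ci_95 = bt$ci_95,
                          p_vs_chance = bt$p_vs_chance)),
    file.path(decdir, "decoding.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(as.data.frame(cv$confusion),
            file.path(decdir, "confusion.tsv"), config)
  write_tsv(data.frame(hue_deg = names(cv$per_class_accuracy),
                       accuracy = as.numeric(cv$per_class_accuracy)),
            file.path(decdir, "per_class.tsv"), config)
  log_stage(workdir, "decode",
            sprintf("accuracy %.1f%% (chance %.1f%%), bootstrap p = %.3g",
                    100 * cv$overall_accuracy, 100 * cv$chance,
                    bt$p_vs_chance), t0)
  invisible(workdir)
}

#' @rdname stage_simulate
#' @export
stage_report <- function(config, workdir) {
  t0 <- proc.time()
  dompath <- require_stage(workdir, "domains/domains.tsv", "domains")
  decpath <- require_stage(workdir, "decoding/decoding.json", "decode")
  domains <- read_tsv(dompath)
  clusters <- read_tsv(file.path(workdir, "domains", "clusters.tsv"))
  dec <- jsonlite::read_json(decpath, simplifyVector = TRUE)
  lines <- c(
    "# Hue-domain pipeline report", "",
    sprintf("- config hash: `%s`, seed %s", config_hash(config),
            config$seed), "",
    "## Domains", "",
    sprintf("- %d hue domains; mean equivalent diameter %.0f um (SD %.0f)",
            nrow(domains),
            if (nrow(domains)) mean(domains$equiv_diam_um) else NA,
            if (nrow(domains)) sd(domains$equiv_diam_um) else NA), "",
    "| hue | n domains | mean area (um^2) | mean normalized area |",
    "|---|---|---|---|")
  if (nrow(domains) > 0) {
    for (h in sort(unique(domains$hue_deg))) {
      d <- domains[domains$hue_deg == h, ]
      lines <- c(lines, sprintf("| %d | %d | %.0f | %.2f |", h, nrow(d),
                                mean(d$area_um2),
                                mean(d$normalized_area, na.rm = TRUE)))
    }
  }
  lines <- c(lines, "", "## Clusters", "",
             sprintf("- %d hue clusters, %d complete",
                     nrow(clusters), sum(clusters$complete)))
  if (file.exists(file.path(workdir, "domains", "completeness.tsv"))) {
    cmp <- read_tsv(file.path(workdir, "domains", "completeness.tsv"))
    lines <- c(lines, sprintf("- %.1f%% incomplete (%d/%d)",
                              cmp$pct_incomplete[1], cmp$n_incomplete[1],
                              cmp$n_total[1]))
  }
  lines <- c(lines, "", "## Decoding", "",
             sprintf("- overall accuracy %.1f%% (chance %.1f%%)",
                     100 * dec$overall_accuracy, 100 * dec$chance),
             sprintf("- bootstrap mean %.1f%%, 95%% CI [%.1f, %.1f]%%, p vs chance %.3g",
                     100 * dec$bootstrap$mean, 100 * dec$bootstrap$ci_95[1],
                     100 * dec$bootstrap$ci_95[2],
                     dec$bootstrap$p_vs_chance))
  writeLines(lines, file.path(workdir, "report.md"))
  log_stage(workdir, "report", "report.md written", t0)
  invisible(workdir)
}

#' Run the full pipeline
#'
#' Executes the stages in order over one working directory.
#'
#' @param config configuration list (see [default_config()]).
#' @param workdir working directory.
#' @param stages character vector of stages to run, in canonical order.
#' @return the workdir, invisibly.
#' @export
run_pipeline <- function(config = default_config(), workdir,
                         stages = c("simulate", "maps", "stats", "domains",
                                    "decode", "report")) {
  all_stages <- c(simulate = stage_simulate, maps = stage_maps,
                  stats = stage_stats, domains = stage_domains,
                  decode = stage_decode, report = stage_report)
  bad <- setdiff(stages, names(all_stages))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (s in intersect(names(all_stages), stages)) all_stages[[s]](config, workdir)
  invisible(workdir)
}

#' Render a color-coded hue-angle map as PNG
#'
#' Preferred hue is encoded as color hue, selectivity magnitude as
#' brightness.
#'
#' @param vmap a `hue_vector_map`.
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
render_angle_map <- function(vmap, path) {
  ang <- vmap$angle; mag <- vmap$magnitude
  v <- mag / max(mag[is.finite(mag)], na.rm = TRUE)
  v[!is.finite(v)] <- 0
  hh <- ang / 360; hh[!is.finite(hh)] <- 0
  col <- grDevices::hsv(h = pmin(pmax(hh, 0), 1), s = 1,
                        v = pmin(pmax(v, 0), 1))
  img <- array(t(grDevices::col2rgb(col) / 255), dim = c(dim(ang), 3))
  grDevices::png(path, width = ncol(ang), height = nrow(ang))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
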