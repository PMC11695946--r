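# End-to-end orchestration: simulate -> preprocess -> traces -> events ->
# waves -> terminals -> report.  This is what the command-line `run`
# subcommand executes; every stage is also callable on its own.

#' Simulate a ground-truthed recording
#'
#' Convenience wrapper: geometry + schedule + rendered movie from one
#' config and seed.
#'
#' @param config a [ca_config()].
#' @param seed integer seed driving every random draw.
#' @param shot_noise,drift,express passed to [render_movie()].
#' @return a `ca_simulation` (see [render_movie()]).
#' @export
simulate_recording <- function(config = ca_config(), seed = 1,
                               shot_noise = TRUE, drift = TRUE,
                               express = c("ihc", "sc", "terminal")) {
  p <- config$synth
  geom <- generate_geometry(n_ihc = p$n_ihc, spacing = p$spacing_um,
                            arc_curvature = p$arc_curvature,
                            terminal_mean = p$terminal_mean,
                            terminal_sd = p$terminal_sd,
                            seed = seed)
  sched <- simulate_schedule(geom, params = p, duration_s = p$duration_s,
                             seed = seed + 1)
  render_movie(geom, sched, shot_noise = shot_noise, drift = drift,
               express = express, seed = seed + 2)
}

#' Preprocess a stack: frame QC, substitution, smoothing, drift correction
#'
#' Breathing/out-of-focus frames are detected and substituted on the raw
#' recording, where bout edges are sharp, before the 3D Gaussian filter is
#' applied; smoothing an uncorrected movie would smear each artifact into
#' its neighbouring frames.
#'
#' @param stack a [timelapse_stack()].
#' @param config a [ca_config()].
#' @param manual_list optional manual removal intervals.
#' @return list: `stack` (corrected, QC report attached), `qc`, `shifts`.
#' @export
preprocess_stack <- function(stack, config = ca_config(), manual_list = NULL) {
  pp <- config$preprocess
  qc <- detect_bad_frames(stack, qc_roi_fraction = pp$qc_roi_fraction,
                          prominence_k = pp$prominence_k,
                          artifact_max_width_s = pp$artifact_max_width_s,
                          template_threshold = pp$template_threshold,
                          manual_list = manual_list,
                          detrend_s = pp$detrend_s)
  sub <- apply_substitution(stack, qc)
  sm <- smooth_stack(sub, pp$smooth_sigma)
  cd <- correct_drift(sm, max_shift = pp$max_shift_px)
  cd$stack$qc <- qc
  list(stack = cd$stack, qc = qc, shifts = cd$shifts)
}

# order index and longitudinal coordinate for every IHC identity
ihc_positions <- function(geometry) {
  list(order = stats::setNames(geometry$ihc$order, geometry$ihc$identity),
       s_um = stats::setNames(geometry$ihc$s, geometry$ihc$identity))
}

#' Run the full analysis chain on a simulated recording
#'
#' Executes every stage of the pipeline on one synthetic recording and,
#' when `outdir` is given, writes the result tables (CSV/JSON) plus the
#' ground-truth sidecar.  The whole run is a pure function of
#' `(config, seed)`: two runs with the same arguments produce byte-identical
#' tables.
#'
#' @param config a [ca_config()].
#' @param seed integer seed.
#' @param outdir optional output directory for tables.
#' @param keep_stacks keep the full pixel data of the processed movies in
#'   the returned object (default FALSE: the frames of multi-minute movies
#'   dominate memory and the result tables do not need them).
#' @param terminals render and analyse the afferent-line sibling recording
#'   (default TRUE); the IHC/wave stages run either way.
#' @return invisible list with all intermediate objects and result tables.
#' @export
run_pipeline <- function(config = ca_config(), seed = 1, outdir = NULL,
                         keep_stacks = FALSE, terminals = TRUE) {
  # two sibling recordings of the same epithelium, mirroring the two mouse
  # lines of the study design: indicator in hair + supporting cells for the
  # IHC/wave analyses, indicator in afferent terminals for the terminal
  # analyses; one shared activity schedule and clock
  p <- config$synth
  geom <- generate_geometry(n_ihc = p$n_ihc, spacing = p$spacing_um,
                            arc_curvature = p$arc_curvature,
                            terminal_mean = p$terminal_mean,
                            terminal_sd = p$terminal_sd, seed = seed)
  sched <- simulate_schedule(geom, params = p, duration_s = p$duration_s,
                             seed = seed + 1)
  sim <- render_movie(geom, sched, express = c("ihc", "sc"), seed = seed + 2)
  pre <- preprocess_stack(sim$stack, config)
  sim$stack$frames <- NULL # raw pixels are no longer needed
  stk <- pre$stack

  ## IHC traces and events
  rois <- erode_rois(sim$ihc_rois, config$traces$erode_radius_px)
  ts <- extract_traces(stk, rois, report = pre$qc,
                       f0_rule = config$traces$f0_rule,
                       f0_percentile = config$traces$f0_percentile)
  dt <- detrend_traces(ts, config$traces$detrend_s)
  ev_cfg <- config$events
  transients <- detect_transients(dt, min_fdhm_s = ev_cfg$min_fdhm_s,
                                  amp_k = ev_cfg$amp_k,
                                  prominence_k = ev_cfg$prominence_k,
                                  false_rate_per_min = ev_cfg$false_rate_per_min,
                                  smooth_sigma_s = ev_cfg$smooth_sigma_s,
                                  min_separation_s = ev_cfg$min_separation_s)
  pos <- ihc_positions(sim$geometry)
  grouped <- group_events(transients, pos$order, window_s = ev_cfg$window_s,
                          gap_limit = ev_cfg$gap_limit,
                          linkage = ev_cfg$linkage)
  freq <- compute_frequency(transients, sim$schedule$duration_s,
                            min_duration_min = ev_cfg$min_duration_min)
  amp_class <- event_amplitude_by_class(grouped)
  corr <- correlation_analysis(dt, pos$s_um,
                               min_overlap_min = ev_cfg$min_duration_min,
                               distance_bin_um = ev_cfg$distance_bin_um)
  skipped <- lapply(which(grouped$events$class == "multiple"), function(e)
    find_skipped_cells(grouped$events[e, ], grouped$transients, pos$order,
                       amplitude_fraction = ev_cfg$skip_amplitude_fraction,
                       window_s = ev_cfg$window_s))

  ## waves and kymographs
  wv_cfg <- config$waves
  # restrict wave segmentation to the modiolar (GER) side of the axis and
  # exclude the hair-cell somata (dilated by the filter spread): waves live
  # in the supporting cells, and the IHC signal is analysed above
  dgrid <- dim(stk$frames)[1:2]
  pix_um <- cbind(rep((seq_len(dgrid[2]) - 1) * stk$pixel_size,
                      each = dgrid[1]),
                  rep((seq_len(dgrid[1]) - 1) * stk$pixel_size, dgrid[2]))
  ger_mask <- matrix(axis_transform(sim$axis, pix_um)$d > 2,
                     dgrid[1], dgrid[2])
  excl_r <- p$cell_radius_um + 2 * config$preprocess$smooth_sigma *
    stk$pixel_size
  for (i in seq_len(nrow(sim$geometry$ihc))) {
    r2 <- (pix_um[, 1] - sim$geometry$ihc$x[i])^2 +
      (pix_um[, 2] - sim$geometry$ihc$y[i])^2
    ger_mask[r2 <= excl_r^2] <- FALSE
  }
  wset <- segment_waves(stk, bin_factor = wv_cfg$bin_factor,
                        threshold = wv_cfg$threshold,
                        spot_sigma = wv_cfg$spot_sigma,
                        outline_sigma = wv_cfg$outline_sigma,
                        min_volume_voxels = wv_cfg$min_volume_voxels,
                        cell_diameter_um = wv_cfg$cell_diameter_um,
                        noise_floor_k = wv_cfg$noise_floor_k,
                        region_mask = ger_mask,
                        ignore_border_px = wv_cfg$ignore_border_px,
                        baseline_window_s = wv_cfg$baseline_window_s)
  waves <- quantify_wave(wset, sim$axis,
                         speed_estimator = wv_cfg$speed_estimator)
  ger_waves <- waves
  matches <- match_wave_to_ihc_events(ger_waves, grouped$events, pos$s_um,
                                      origin_window_um = wv_cfg$origin_window_um,
                                      lag_s = wv_cfg$match_lag_s)
  kymo_ihc <- build_kymograph(stk, sim$axis,
                              half_width_px = wv_cfg$kymo_half_width_px,
                              step_um = wv_cfg$kymo_step_um)
  ger_line <- cochlear_axis(axis_point(sim$axis,
                                       seq(0, axis_length(sim$axis), by = 5),
                                       12),
                            sim$axis$modiolar_sign)
  kymo_ger <- build_kymograph(stk, ger_line,
                              half_width_px = wv_cfg$kymo_half_width_px,
                              step_um = wv_cfg$kymo_step_um)

  sim_t <- t_rois <- tdt <- t_transients <- assignments <- NULL
  per_ihc <- recruitment <- term_freq <- side_freq <- pre_t <- NULL
  if (terminals) {
    ## terminals (on the afferent-line sibling recording, rendered only now
    ## that the first movie's heavy intermediates can be released; imaged at
    ## higher magnification, as needed to resolve individual boutons)
    if (!keep_stacks) pre$stack <- NULL
    rm(stk)
    sched_t <- sched
    sched_t$params$pixel_size_um <- p$terminal_pixel_size_um
    sim_t <- render_movie(geom, sched_t, express = "terminal", seed = seed + 3)
    tm_cfg <- config$terminals
    # segment puncta on the average of the unsmoothed recording: averaging
    # already suppresses shot noise, and the 3D filter would smear the tiny
    # puncta into the background
    mean_raw_t <- mean_image(sim_t$stack)
    pre_t <- preprocess_stack(sim_t$stack, config)
    sim_t$stack$frames <- NULL
    stk_t <- pre_t$stack
    t_rois <- segment_terminals(mean_raw_t,
                                tophat_radius_px = tm_cfg$tophat_radius_px,
                                spot_sigma = tm_cfg$spot_sigma,
                                outline_sigma = tm_cfg$outline_sigma,
                                min_area_px = tm_cfg$min_area_px)
    tts <- extract_traces(stk_t, t_rois, report = pre_t$qc)
    tdt <- detrend_traces(tts, config$traces$detrend_s)
    t_transients <- detect_transients(tdt, min_fdhm_s = ev_cfg$min_fdhm_s,
                                      amp_k = ev_cfg$amp_k,
                                      prominence_k = ev_cfg$prominence_k,
                                      false_rate_per_min = ev_cfg$false_rate_per_min,
                                      smooth_sigma_s = ev_cfg$smooth_sigma_s,
                                      min_separation_s = ev_cfg$min_separation_s)
    # all terminal-side coordinates live in the afferent recording's frame
    term_xy <- roi_centroids(t_rois, stk_t$pixel_size)
    ihc_xy <- data.frame(identity = sim_t$geometry$ihc$identity,
                         x = sim_t$geometry$ihc$x, y = sim_t$geometry$ihc$y)
    assignments <- assign_terminals(term_xy, ihc_xy, term_traces = tdt$dff,
                                    ihc_traces = dt$dff,
                                    ambiguity_margin_um = tm_cfg$ambiguity_margin_um)
    assignments$side <- classify_side(
      term_xy[match(assignments$terminal, term_xy$identity), c("x", "y")],
      sim_t$axis, tm_cfg$middle_half_width_um)
    per_ihc <- per_ihc_terminal_activity(assignments, tdt$dff, t_transients,
                                         sim$schedule$duration_s,
                                         merge_window_s = tm_cfg$merge_window_s)
    recruitment <- recruitment_analysis(grouped$events, t_transients,
                                        assignments,
                                        merge_window_s = tm_cfg$merge_window_s)
    if (!keep_stacks) pre_t$stack$frames <- NULL
    term_freq <- compute_frequency(t_transients, sim$schedule$duration_s,
                                   min_duration_min = 0)
    side_freq <- side_statistics(
      data.frame(terminal = term_freq$identity, value = term_freq$freq_per_min),
      assignments)
  }

  if (!keep_stacks) pre$stack <- NULL
  res <- list(sim = sim, sim_t = sim_t, pre = pre, traces = dt,
              transients = transients,
              grouped = grouped, frequency = freq, amp_class = amp_class,
              correlation = corr, skipped = skipped, wave_set = wset,
              waves = waves, ger_waves = ger_waves, matches = matches,
              kymo_ihc = kymo_ihc, kymo_ger = kymo_ger,
              terminal_traces = tdt, terminal_transients = t_transients,
              assignments = assignments, terminal_rois = t_rois,
              per_ihc = per_ihc,
              recruitment = recruitment, side_freq = side_freq)
  if (!is.null(outdir)) write_pipeline_tables(res, config, outdir)
  invisible(res)
}

# serialise every pipeline result table under outdir
write_pipeline_tables <- function(res, config, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_config(config, file.path(outdir, "config.yaml"))
  write_ground_truth(res$sim, file.path(outdir, "truth.json"))
  qc <- res$pre$qc
  jsonlite::write_json(
    list(removed = res$pre$qc$removed, method = res$pre$qc$method,
         substitution_source = res$pre$qc$substitution_source),
    file.path(outdir, "frame_qc.json"), digits = NA, auto_unbox = TRUE)
  write_tables(res$pre$shifts, file.path(outdir, "shifts.csv"))
  long <- data.frame(
    recording = res$traces$recording_id,
    cell = rep(colnames(res$traces$dff), each = nrow(res$traces$dff)),
    time_s = rep(res$traces$time, ncol(res$traces$dff)),
    dff = as.vector(res$traces$dff),
    interpolated = as.vector(res$traces$interpolated))
  write_tables(long, file.path(outdir, "traces.csv"))
  write_tables(res$transients, file.path(outdir, "transients.csv"))
  write_tables(res$grouped$events, file.path(outdir, "events.csv"))
  write_tables(res$frequency, file.path(outdir, "frequency.csv"))
  write_tables(res$amp_class, file.path(outdir, "amplitude_by_class.csv"))
  utils::write.csv(as.data.frame(res$correlation$r),
                   file.path(outdir, "correlation_matrix.csv"))
  if (!is.null(res$correlation$by_distance))
    write_tables(res$correlation$by_distance,
                 file.path(outdir, "correlation_by_distance.csv"))
  write_tables(res$waves, file.path(outdir, "waves.csv"))
  write_tables(res$matches, file.path(outdir, "wave_event_matches.csv"))
  if (!is.null(res$assignments)) {
    write_tables(res$assignments,
                 file.path(outdir, "terminal_assignments.csv"))
    write_tables(res$terminal_transients,
                 file.path(outdir, "terminal_transients.csv"))
    write_tables(res$recruitment$per_event,
                 file.path(outdir, "recruitment_per_event.csv"))
    write_tables(res$recruitment$by_class,
                 file.path(outdir, "recruitment_by_class.csv"))
  }
  invisible(outdir)
}
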