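# Ground-truthed activity schedules for the synthetic generator.

#' Default generator parameters
#'
#' The defaults reproduce the activity statistics of in vivo recordings of
#' the pre-hearing apical coil: intrinsic IHC transients at a fraction of an
#' event per minute with a transient FDHM of 1.5 s, GER calcium waves of
#' roughly 2.2 s duration, ~34 um longitudinal extent and 22 um/s expansion
#' speed, IHC-to-IHC lateral spread near 61 um/s, coordinated cohorts of
#' about 7 cells with occasional skipped cells, terminal coupling that is
#' stronger during multi-cell events and on the pillar side, plus breathing
#' artifacts and slow lateral drift.
#'
#' @return named list of generator defaults (the `synth` section of
#'   [ca_config()]).
#' @export
synth_defaults <- function() {
  list(
    # recording
    duration_s = 300,
    # geometry
    n_ihc = 20, spacing_um = 9, arc_curvature = 1 / 300,
    terminal_mean = 4, terminal_sd = 2,
    # IHC transients
    lambda_ind_per_min = 0.27,      # independent (uncoordinated) rate
    amp_ind = 0.25,                 # dF/F0 of an independent transient
    amp_coord_scale = 1.9,          # coordinated / independent amplitude
    amp_jitter_sd = 0.25,           # lognormal sd of amplitude jitter
    fdhm_s = 1.5,                   # rendered single-transient FDHM
    tau_rise_s = 0.05,
    # GER waves
    wave_rate_per_min = 0.8,
    wave_fdhm_mean_s = 2.24, wave_fdhm_sd_s = 1.0,
    wave_fdhm_clip_s = c(1.0, 5.0),
    wave_long_radius_um = 17, wave_radial_radius_um = 7,
    v_exp_um_s = 22, v_con_um_s = 15,
    wave_d_range_um = c(5, 20),
    wave_amp = 1.0,
    # coordinated events
    p_reach = 0.5,
    v_ihc_um_s = 61,
    cohort_mean = 7, cohort_sd = 4, cohort_range = c(3, 20),
    p_skip = 0.15,
    # terminal coupling
    p_single = 0.3, p_multiple = 0.8,
    side_p_scale = c(pillar = 1.0, modiolar = 0.5, middle = 0.75),
    terminal_amp = 0.4,
    side_amp_scale = c(pillar = 1.2, modiolar = 0.8, middle = 1.0),
    terminal_lag_s = 0.1,
    # artifacts and drift
    artifact_rate_per_min = 0.3,
    artifact_depth_range = c(0.3, 0.6),
    artifact_len_s = c(0.2, 0.8),
    artifact_shift_px = 0,
    drift_amp_px = 0.5, drift_period_s = 150,
    # rendering
    frame_rate = 10, pixel_size_um = 1,
    terminal_pixel_size_um = 0.5,    # afferent-line movies resolve puncta
    baseline_bg = 20, baseline_ihc = 100, baseline_sc = 60,
    baseline_terminal = 80,
    cell_radius_um = 3.5, terminal_sigma_um = 1.0,
    photon_gain = 1,
    trace_noise_sd = 0.04            # dF/F0 noise for trace-level rendering
  )
}

clipnorm <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Simulate a ground-truthed activity schedule
#'
#' Draws every hidden truth of a synthetic recording: independent per-IHC
#' transient times (homogeneous Poisson), GER wave records with their
#' expansion/contraction kinetics, coordinated multi-IHC events triggered by
#' a fraction `p_reach` of the waves (with contiguous cohorts, lateral
#' activation delays at speed `v_ihc_um_s` and randomly skipped interior
#' cells), Bernoulli-coupled terminal release events, breathing-artifact
#' bouts and a smooth drift path.  Identical `(geometry, params, duration,
#' seed)` give an identical schedule.
#'
#' Skipped cells are guaranteed a transient elsewhere in the recording (they
#' are silent during the event but not silent cells), and skipping is
#' restricted to interior cohort positions so that cohorts stay contiguous
#' apart from the skipped cells.
#'
#' @param geometry an [generate_geometry()] result.
#' @param params generator parameters, see [synth_defaults()]; pass a
#'   modified copy to change rates or speeds.
#' @param duration_s recording duration in seconds.
#' @param seed integer seed.
#' @return an object of class `activity_schedule` with data.frames
#'   `transients`, `waves`, `events`, `terminal_transients`, `artifacts`
#'   and a `drift` record.
#' @export
simulate_schedule <- function(geometry, params = synth_defaults(),
                              duration_s = 300, seed = 1) {
  p <- utils::modifyList(synth_defaults(), params)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (p$lambda_ind_per_min < 0 || p$wave_rate_per_min < 0)
    stop("rates must be >= 0")
  if (p$p_skip < 0 || p$p_skip > 1) stop("p_skip must be in [0, 1]")
  if (p$p_reach < 0 || p$p_reach > 1) stop("p_reach must be in [0, 1]")
  n_ihc <- nrow(geometry$ihc)
  with_seed(seed, {
    ## independent IHC transients
    n_ind <- stats::rpois(n_ihc, p$lambda_ind_per_min * duration_s / 60)
    tr <- data.frame(cell = rep(seq_len(n_ihc), n_ind),
                     time = stats::runif(sum(n_ind), 0, duration_s))
    tr$amplitude <- p$amp_ind * stats::rlnorm(nrow(tr), 0, p$amp_jitter_sd)
    tr$event_id <- rep(0L, nrow(tr))

    ## waves
    n_wave <- stats::rpois(1, p$wave_rate_per_min * duration_s / 60)
    r_eq <- sqrt(p$wave_long_radius_um * p$wave_radial_radius_um)
    waves <- data.frame(
      wave_id = seq_len(n_wave),
      t_start = sort(stats::runif(n_wave, 0, duration_s)),
      s0 = stats::runif(n_wave, 0.1, 0.9) * axis_length(geometry$axis),
      d0 = stats::runif(n_wave, p$wave_d_range_um[1], p$wave_d_range_um[2]),
      fdhm_target = clipnorm(n_wave, p$wave_fdhm_mean_s, p$wave_fdhm_sd_s,
                             p$wave_fdhm_clip_s[1], p$wave_fdhm_clip_s[2]))
    waves$a_long <- rep(p$wave_long_radius_um, n_wave)
    waves$b_rad <- rep(p$wave_radial_radius_um, n_wave)
    waves$t_exp <- rep(r_eq / p$v_exp_um_s, n_wave)
    waves$t_con <- rep(r_eq / p$v_con_um_s, n_wave)
    # plateau chosen so the pixel-average FDHM of the rendered trapezoidal
    # area profile matches the drawn target (area crosses half-max when the
    # equivalent radius passes r_max / sqrt(2))
    waves$t_plateau <- pmax(0, waves$fdhm_target -
                              (1 - 1 / sqrt(2)) * (waves$t_exp + waves$t_con))
    waves$amp <- rep(p$wave_amp, n_wave)
    waves$reaches <- if (n_wave) stats::runif(n_wave) < p$p_reach else logical()

    ## coordinated events initiated by the waves that reach the IHC row
    events <- data.frame(event_id = integer(), wave_id = integer(),
                         initiator = integer(), cohort_lo = integer(),
                         cohort_hi = integer())
    skipped <- list()
    ev_id <- 0L
    for (w in which(waves$reaches)) {
      ev_id <- ev_id + 1L
      init <- which.min(abs(geometry$ihc$s - waves$s0[w]))
      m <- round(clipnorm(1, p$cohort_mean, p$cohort_sd,
                          p$cohort_range[1], p$cohort_range[2]))
      left <- sample.int(m, 1) - 1L
      lo <- max(1L, init - left)
      hi <- min(n_ihc, lo + m - 1L)
      lo <- max(1L, hi - m + 1L)
      cohort <- lo:hi
      # skipped cells: interior positions only, at most 4, and never so many
      # that fewer than 3 cells participate
      interior <- setdiff(cohort, c(lo, hi, init))
      n_skip_max <- min(4L, length(interior), length(cohort) - 3L)
      sk <- integer()
      if (n_skip_max > 0) {
        cand <- interior[stats::runif(length(interior)) < p$p_skip]
        if (length(cand) > n_skip_max)
          cand <- sort(sample(cand, n_skip_max))
        sk <- cand
      }
      part <- setdiff(cohort, sk)
      t0 <- waves$t_start[w] + waves$t_exp[w] / 2
      tt <- t0 + abs(geometry$ihc$s[part] - geometry$ihc$s[init]) / p$v_ihc_um_s
      amp <- p$amp_ind * p$amp_coord_scale *
        stats::rlnorm(length(part), 0, p$amp_jitter_sd)
      tr <- rbind(tr, data.frame(cell = part, time = tt, amplitude = amp,
                                 event_id = ev_id))
      events <- rbind(events, data.frame(
        event_id = ev_id, wave_id = w, initiator = init,
        cohort_lo = lo, cohort_hi = hi))
      skipped[[ev_id]] <- sk
    }
    # every skipped cell must be active somewhere else in the recording
    if (length(skipped)) {
      for (e in seq_along(skipped)) for (cell in skipped[[e]]) {
        if (!any(tr$cell == cell & tr$event_id == 0L)) {
          ev <- events[events$event_id == e, ]
          t_ev <- waves$t_start[ev$wave_id]
          t_new <- stats::runif(1, 0, duration_s)
          guard <- 0L
          while (abs(t_new - t_ev) < 15 && guard < 50) {
            t_new <- stats::runif(1, 0, duration_s); guard <- guard + 1L
          }
          tr <- rbind(tr, data.frame(
            cell = cell, time = t_new,
            amplitude = p$amp_ind * stats::rlnorm(1, 0, p$amp_jitter_sd),
            event_id = 0L))
        }
      }
    }
    tr <- tr[tr$time >= 0 & tr$time < duration_s, ]
    tr <- tr[order(tr$time), ]
    rownames(tr) <- NULL
    tr$identity <- geometry$ihc$identity[tr$cell]

    ## terminal release events: Bernoulli coupling to parent transients
    tt_list <- list()
    term <- geometry$terminals
    if (nrow(tr) && nrow(term)) {
      for (j in seq_len(nrow(tr))) {
        cls <- if (tr$event_id[j] > 0L) "multiple" else "single"
        base_p <- if (cls == "multiple") p$p_multiple else p$p_single
        tj <- term[term$parent == tr$cell[j], ]
        if (!nrow(tj)) next
        pr <- base_p * p$side_p_scale[tj$side]
        hit <- stats::runif(nrow(tj)) < pr
        if (!any(hit)) next
        lag <- pmax(0, stats::rnorm(sum(hit), p$terminal_lag_s,
                                    p$terminal_lag_s / 2))
        tt_list[[length(tt_list) + 1L]] <- data.frame(
          terminal = tj$id[hit], parent = tr$cell[j],
          side = tj$side[hit],
          time = tr$time[j] + lag,
          amplitude = p$terminal_amp * p$side_amp_scale[tj$side[hit]] *
            stats::rlnorm(sum(hit), 0, p$amp_jitter_sd),
          parent_class = cls, parent_event = tr$event_id[j])
      }
    }
    term_tr <- if (length(tt_list)) do.call(rbind, tt_list) else
      data.frame(terminal = integer(), parent = integer(),
                 side = character(), time = numeric(), amplitude = numeric(),
                 parent_class = character(), parent_event = integer())
    term_tr <- term_tr[term_tr$time < duration_s, ]
    rownames(term_tr) <- NULL

    ## breathing artifact bouts and drift path
    n_art <- stats::rpois(1, p$artifact_rate_per_min * duration_s / 60)
    artifacts <- data.frame(
      start_s = sort(stats::runif(n_art, 1, max(1, duration_s - 2))),
      len_s = stats::runif(n_art, p$artifact_len_s[1], p$artifact_len_s[2]),
      depth = stats::runif(n_art, p$artifact_depth_range[1],
                           p$artifact_depth_range[2]),
      shift_px = stats::runif(n_art, 0, p$artifact_shift_px))
    drift <- list(amp_px = p$drift_amp_px, period_s = p$drift_period_s,
                  phase = stats::runif(1, 0, 2 * pi),
                  angle = stats::runif(1, 0, 2 * pi))

    structure(list(duration_s = duration_s, transients = tr, waves = waves,
                   events = events, skipped = skipped,
                   terminal_transients = term_tr,
                   artifacts = artifacts, drift = drift,
                   params = p, seed = seed),
              class = "activity_schedule")
  })
}

#' @export
print.activity_schedule <- function(x, ...) {
  cat(sprintf(paste0(
    "activity_schedule: %.0f s, %d IHC transients (%d coordinated events),",
    " %d waves, %d terminal transients, %d artifact bouts\n"),
    x$duration_s, nrow(x$transients), nrow(x$events), nrow(x$waves),
    nrow(x$terminal_transients), nrow(x$artifacts)))
  invisible(x)
}
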