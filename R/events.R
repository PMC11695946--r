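# Transient detection, multicell event grouping, frequencies, correlations.

#' Noise-calibrated amplitude floor for peak detection
#'
#' Smallest peak amplitude (in units of the processed trace's robust noise
#' SD) that noise alone exceeds at the target rate.  For an unsmoothed
#' trace this is the Gaussian upper quantile at
#' `1 - rate / (60 * frame_rate)`; for a Gaussian-smoothed trace it is the
#' level whose Rice upcrossing rate matches the target (the smoothed
#' process has Gaussian autocorrelation, so the characteristic frequency is
#' `1 / (2 * pi * sqrt(2) * sigma_t)` per sample).  Used as the default
#' amplitude floor of [detect_transients()], which controls the expected
#' false-detection rate on noise-dominated traces the way a z-test controls
#' its size.
#'
#' @param frame_rate samples per second.
#' @param false_rate_per_min target false-detection rate (events/min).
#' @param smooth_sigma_samples temporal Gaussian sigma (in samples) applied
#'   before peak finding; 0 for none.
#' @return threshold in noise-SD units of the processed trace.
#' @export
noise_amplitude_floor <- function(frame_rate, false_rate_per_min = 0.02,
                                  smooth_sigma_samples = 0) {
  p_sample <- false_rate_per_min / (60 * frame_rate)
  if (smooth_sigma_samples <= 0) return(stats::qnorm(1 - p_sample))
  nu0 <- 1 / (2 * pi * sqrt(2) * smooth_sigma_samples)
  sqrt(max(0, -2 * log(p_sample / nu0)))
}

detect_transients_vec <- function(v, frame_rate, interpolated = NULL,
                                  min_fdhm_s = 0.2, amp_k = 2,
                                  prominence_k = 2,
                                  false_rate_per_min = 0.02,
                                  smooth_sigma_s = 0.2,
                                  min_separation_s = 0.5) {
  empty <- data.frame(peak_time = numeric(), amplitude = numeric(),
                      prominence = numeric(), fdhm = numeric())
  if (length(v) < ceiling(min_fdhm_s * 4 * frame_rate)) return(empty)
  sig_t <- smooth_sigma_s * frame_rate
  vs <- if (sig_t > 0)
    as.vector(conv_cols(matrix(v, ncol = 1), gauss_kernel(sig_t))) else v
  sd_tr <- stats::sd(vs)
  sd_rob <- robust_sd(vs)
  if (!is.finite(sd_tr) || sd_tr == 0) return(empty)
  floor_amp <- sd_rob *
    noise_amplitude_floor(frame_rate, false_rate_per_min, sig_t)
  thr_amp <- max(amp_k * sd_tr, floor_amp)
  pk <- find_peaks(vs)
  pk <- pk[pk$prominence >= prominence_k * sd_rob & pk$value > thr_amp, ,
           drop = FALSE]
  if (!nrow(pk)) return(empty)
  # deduplicate ripples riding on one transient: greedy from the highest
  # peak, suppressing smaller peaks closer than the separation window
  if (nrow(pk) > 1 && min_separation_s > 0) {
    ord <- order(-pk$value)
    taken <- numeric()
    keep_sep <- logical(nrow(pk))
    for (j in ord) {
      t_j <- pk$index[j] / frame_rate
      if (!length(taken) || min(abs(taken - t_j)) >= min_separation_s) {
        keep_sep[j] <- TRUE
        taken <- c(taken, t_j)
      }
    }
    pk <- pk[keep_sep, , drop = FALSE]
  }
  # refine each peak to the raw-trace maximum nearby (the smoothing biases
  # the sharp-rise peak height down) and take the amplitude there; measure
  # the width on the smoothed trace, where noise dips cannot truncate the
  # half-maximum crossings, and remove the smoothing kernel's own width in
  # quadrature so brief spikes are not widened past the inclusion rule
  w_ref <- max(1L, as.integer(round(sig_t)))
  w_smooth <- 2.3548 * smooth_sigma_s
  keep <- logical(nrow(pk))
  fdhm <- amp <- numeric(nrow(pk))
  idx_raw <- integer(nrow(pk))
  for (j in seq_len(nrow(pk))) {
    win <- max(1L, pk$index[j] - w_ref):min(length(v), pk$index[j] + w_ref)
    p <- win[which.max(v[win])]
    idx_raw[j] <- p
    # median of the three samples at the raw peak: robust to the upward
    # bias of a bare maximum over noisy samples
    amp[j] <- stats::median(v[max(1L, p - 1L):min(length(v), p + 1L)])
    # the detrended trace has local baseline zero by construction, so the
    # half-maximum level is half the peak amplitude; the larger of the raw
    # and smoothed peak heights keeps the level honest both for smooth
    # transients (raw higher) and for sub-sample spikes (smoothed higher)
    level <- max(amp[j], vs[pk$index[j]]) / 2
    if (vs[pk$index[j]] > level) {
      w <- peak_width_at(vs, pk$index[j], level)
    } else {
      w <- peak_width_at(v, p, level)
    }
    w_meas <- w$width / frame_rate
    fdhm[j] <- sqrt(max(0, w_meas^2 - w_smooth^2))
    keep[j] <- fdhm[j] > min_fdhm_s
    if (keep[j] && !is.null(interpolated)) {
      span <- max(1L, floor(w$left)):min(length(v), ceiling(w$right))
      if (all(interpolated[span])) keep[j] <- FALSE
    }
  }
  out <- data.frame(peak_time = (idx_raw[keep] - 1) / frame_rate,
                    amplitude = amp[keep],
                    prominence = pk$prominence[keep],
                    fdhm = fdhm[keep])
  out <- out[!duplicated(out$peak_time), , drop = FALSE]
  out[order(out$peak_time), , drop = FALSE]
}

#' Detect calcium transients in detrended traces
#'
#' Peaks are located on a lightly smoothed copy of each detrended trace
#' (temporal Gaussian of `smooth_sigma_s`, matched to the indicator's rise
#' timescale) by topographic prominence, deduplicated with a minimum
#' separation window, and kept when they satisfy the three inclusion rules:
#' amplitude above `amp_k` times the SD of the trace, full duration at half
#' maximum (FDHM) above `min_fdhm_s`, and amplitude above the
#' noise-calibrated floor (see [noise_amplitude_floor()]), which fixes the
#' expected false-detection rate on noise.  Each peak is then refined to
#' the raw-trace maximum nearby, and the amplitude and FDHM are measured on
#' the unsmoothed detrended trace (half the peak amplitude above the zero
#' post-detrending baseline, linearly interpolated crossings) so the
#' detection smoothing does not bias the reported kinetics.  Peaks whose
#' half-width span lies entirely in interpolated
#' samples are rejected.  Detection never links across stitched-recording
#' boundaries.
#'
#' @param traces a detrended `trace_set` or `stitched_traces` (see
#'   [detrend_traces()]).
#' @param min_fdhm_s minimum FDHM in seconds (default 0.2).
#' @param amp_k amplitude threshold in trace SDs (default 2).
#' @param prominence_k prominence threshold in robust SDs (default 2).
#' @param false_rate_per_min target noise false-detection rate fixing the
#'   amplitude floor (default 0.02 events/min).
#' @param smooth_sigma_s temporal Gaussian sigma (seconds) applied before
#'   peak finding (default 0.2; 0 disables).
#' @param min_separation_s minimum separation between detected peaks of one
#'   cell; smaller peaks within the window are suppressed (default 0.5).
#' @return data.frame with one row per transient: `identity`,
#'   `recording_id`, `peak_time` (s, on the stitched clock), `amplitude`,
#'   `prominence`, `fdhm`.
#' @export
detect_transients <- function(traces, min_fdhm_s = 0.2, amp_k = 2,
                              prominence_k = 2, false_rate_per_min = 0.02,
                              smooth_sigma_s = 0.2, min_separation_s = 0.5) {
  st <- as_stitched(traces)
  out <- list()
  for (seg in st$segments) {
    for (id in colnames(seg$dff)) {
      tr <- detect_transients_vec(
        seg$dff[, id], seg$frame_rate,
        interpolated = seg$interpolated[, id],
        min_fdhm_s = min_fdhm_s, amp_k = amp_k,
        prominence_k = prominence_k,
        false_rate_per_min = false_rate_per_min,
        smooth_sigma_s = smooth_sigma_s,
        min_separation_s = min_separation_s)
      if (nrow(tr)) {
        tr$identity <- id
        tr$recording_id <- seg$recording_id
        tr$peak_time <- tr$peak_time + seg$start_time
        out[[length(out) + 1L]] <- tr
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(peak_time = numeric(), amplitude = numeric(),
               prominence = numeric(), fdhm = numeric(),
               identity = character(), recording_id = character())
  res <- res[order(res$peak_time), c("identity", "recording_id", "peak_time",
                                     "amplitude", "prominence", "fdhm")]
  rownames(res) <- NULL
  ca_log("detect_transients: %d transients in %d cells", nrow(res),
         length(unique(res$identity)))
  res
}

#' Per-cell transient frequency
#'
#' Total number of transients divided by the total recorded duration of the
#' cell across stitched recordings, in events/min.  Cells observed for less
#' than `min_duration_min` are excluded (reported with `eligible = FALSE`
#' and `freq_per_min = NA`) and logged.
#'
#' @param transients data.frame from [detect_transients()].
#' @param durations either a scalar duration in seconds (applied to every
#'   cell) or the `cells` data.frame of a `stitched_traces` (columns
#'   `identity`, `total_duration_s`).
#' @param min_duration_min eligibility threshold (default 5 minutes).
#' @return data.frame: `identity`, `n_transients`, `total_duration_min`,
#'   `freq_per_min`, `eligible`.
#' @export
compute_frequency <- function(transients, durations, min_duration_min = 5) {
  if (is.numeric(durations) && length(durations) == 1L) {
    if (durations <= 0) stop("duration must be positive")
    ids <- unique(transients$identity)
    durations <- data.frame(identity = ids,
                            total_duration_s = rep(durations, length(ids)))
  }
  n <- table(factor(transients$identity, levels = durations$identity))
  out <- data.frame(identity = durations$identity,
                    n_transients = as.integer(n),
                    total_duration_min = durations$total_duration_s / 60)
  out$eligible <- out$total_duration_min >= min_duration_min
  out$freq_per_min <- ifelse(out$eligible,
                             out$n_transients / out$total_duration_min, NA)
  if (any(!out$eligible))
    ca_log("compute_frequency: %d cell(s) below %g min excluded",
           sum(!out$eligible), min_duration_min)
  out
}

#' Group transients into single / pair / multiple cell events
#'
#' Transients are linked into one event when their peak times fall within
#' `window_s` of one another; with the default single linkage the relation
#' chains, which is what lets one event span a cohort of many cells
#' activating in sequence.  A linked cluster is then split positionally
#' wherever a run of strictly more than `gap_limit` consecutive
#' non-participating cells (counted in IHC order along the cochlear axis,
#' not in micrometres) separates participants.  Events are classed `single`
#' (1 cell), `pair` (2 cells) or `multiple` (3 or more).
#'
#' @param transients data.frame from [detect_transients()].
#' @param positions named integer vector: order index along the cochlear
#'   axis for every cell identity in the field of view (ties broken by
#'   longitudinal coordinate upstream).
#' @param window_s linkage window in seconds (default 2).
#' @param gap_limit maximum tolerated run of silent cells inside one event
#'   (default 4).
#' @param linkage `"single"` (chaining, default) or `"complete"` (every
#'   pair within the window).
#' @return list with `events` (data.frame: `event_id`, `class`, `n_cells`,
#'   `t_start`, `t_end`, and list-columns `cells`, `positions`) and
#'   `transients` (the input with an `event_id` column).
#' @export
group_events <- function(transients, positions, window_s = 2, gap_limit = 4,
                         linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  tr <- transients
  if (!nrow(tr))
    return(list(events = data.frame(event_id = integer(), class = character(),
                                    n_cells = integer(), t_start = numeric(),
                                    t_end = numeric()),
                transients = cbind(tr, event_id = integer())))
  if (!all(tr$identity %in% names(positions)))
    stop("positions missing for some cells")
  ord <- order(tr$peak_time)
  tr <- tr[ord, ]
  if (linkage == "single") {
    gaps <- diff(tr$peak_time) > window_s
    cl <- cumsum(c(1L, as.integer(gaps)))
  } else {
    if (nrow(tr) == 1L) cl <- 1L
    else {
      hc <- stats::hclust(stats::dist(tr$peak_time), method = "complete")
      cl <- stats::cutree(hc, h = window_s)
    }
  }
  ev_id <- 0L
  tr$event_id <- NA_integer_
  rows <- list()
  for (c0 in unique(cl)) {
    sel <- which(cl == c0)
    pos <- positions[tr$identity[sel]]
    upos <- sort(unique(pos))
    # split where more than gap_limit consecutive cells do not participate
    brk <- which(diff(upos) - 1 > gap_limit)
    grp_of <- cumsum(c(1L, as.integer(seq_along(upos)[-1] %in% (brk + 1L))))
    names(grp_of) <- as.character(upos)
    sub <- grp_of[as.character(pos)]
    for (g in unique(sub)) {
      ev_id <- ev_id + 1L
      m <- sel[sub == g]
      tr$event_id[m] <- ev_id
      cells <- unique(tr$identity[m])
      np <- length(unique(positions[cells]))
      rows[[ev_id]] <- data.frame(
        event_id = ev_id,
        class = if (np == 1L) "single" else if (np == 2L) "pair" else "multiple",
        n_cells = np,
        t_start = min(tr$peak_time[m]), t_end = max(tr$peak_time[m]))
      rows[[ev_id]]$cells <- list(cells)
      rows[[ev_id]]$positions <- list(unname(sort(positions[cells])))
    }
  }
  events <- do.call(rbind, rows)
  ca_log("group_events: %d transients -> %d events (%s)",
         nrow(tr), nrow(events),
         paste(names(table(events$class)), table(events$class),
               sep = ":", collapse = ", "))
  list(events = events, transients = tr)
}

#' Find skipped cells within a multiple event
#'
#' Cells positionally inside the cohort span of a multi-cell event that
#' either show no transient during the event window or only a substantially
#' reduced one (amplitude below `amplitude_fraction` of the cohort median),
#' yet are demonstrably not silent: they have at least one transient
#' elsewhere in the recording.
#'
#' @param event one row of the `events` table from [group_events()] with
#'   class `"multiple"`.
#' @param transients full transients table (with `event_id`).
#' @param positions named position vector (as in [group_events()]).
#' @param amplitude_fraction reduced-amplitude threshold relative to the
#'   cohort median (default 0.25).
#' @param window_s tolerance added around the event span (default 2).
#' @return character vector of skipped cell identities.
#' @export
find_skipped_cells <- function(event, transients, positions,
                               amplitude_fraction = 0.25, window_s = 2) {
  stopifnot(event$class == "multiple")
  prange <- range(unlist(event$positions))
  inside <- names(positions)[positions > prange[1] & positions < prange[2]]
  if (!length(inside)) return(character())
  t0 <- event$t_start - window_s; t1 <- event$t_end + window_s
  in_ev <- transients$peak_time >= t0 & transients$peak_time <= t1
  med_amp <- stats::median(transients$amplitude[
    in_ev & transients$identity %in% unlist(event$cells)])
  skipped <- character()
  for (id in inside) {
    amps <- transients$amplitude[in_ev & transients$identity == id]
    quiet <- !length(amps) ||
      max(amps) < amplitude_fraction * med_amp
    active_elsewhere <- any(transients$identity == id & !in_ev)
    if (quiet && active_elsewhere) skipped <- c(skipped, id)
  }
  skipped
}

#' Transient amplitudes pooled by parent event class
#'
#' @param grouped result of [group_events()].
#' @return data.frame: `class`, `n`, `mean_amplitude`, `sd_amplitude`.
#' @export
event_amplitude_by_class <- function(grouped) {
  tr <- grouped$transients
  cls <- grouped$events$class[match(tr$event_id, grouped$events$event_id)]
  out <- do.call(rbind, lapply(c("single", "pair", "multiple"), function(cl) {
    a <- tr$amplitude[cls == cl]
    data.frame(class = cl, n = length(a),
               mean_amplitude = if (length(a)) mean(a) else NA_real_,
               sd_amplitude = if (length(a) > 1) stats::sd(a) else NA_real_)
  }))
  out
}

#' Fisher-z average of correlation coefficients
#'
#' `tanh(mean(artanh(r)))`, with `|r| = 1` clamped just inside the domain.
#' The spread is reported the same way, as `tanh(SD(z))`.
#'
#' @param r numeric vector of correlation coefficients (NAs dropped).
#' @return list with `mean`, `sd`, `n`.
#' @export
fisher_average <- function(r) {
  r <- r[!is.na(r)]
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  list(mean = tanh(mean(z)),
       sd = if (length(z) > 1) tanh(stats::sd(z)) else NA_real_,
       n = length(z))
}

#' Pairwise correlation structure of the IHC traces
#'
#' Pearson correlation between every pair of detrended traces over their
#' simultaneously recorded samples, keeping a pair only when the overlap
#' reaches `min_overlap_min` (entries are otherwise NA, never imputed with
#' zero).  Summaries use the Fisher z-transformation.  The correlation-vs-
#' distance curve Fisher-averages pairs in distance bins; an optional
#' exponential fit `r(d) = r0 exp(-d / d0)` reports the decay length.
#'
#' @param traces a detrended `trace_set` or `stitched_traces`.
#' @param positions_um named numeric vector of longitudinal coordinates
#'   (micrometres) per cell identity.
#' @param min_overlap_min minimum simultaneous recording (default 5 min).
#' @param distance_bin_um width of the distance bins (default 10).
#' @param fit_decay fit the exponential decay (default TRUE).
#' @return list: `r` (matrix), `overlap_min` (matrix), `average` (Fisher
#'   summary of the off-diagonal pairs), `by_distance` (data.frame:
#'   `distance_um`, `r_mean`, `r_sd`, `n_pairs`), `d0_um` (decay length or
#'   NA), `r0`.
#' @export
correlation_analysis <- function(traces, positions_um, min_overlap_min = 5,
                                 distance_bin_um = 10, fit_decay = TRUE) {
  st <- as_stitched(traces)
  ids <- st$cells$identity
  if (length(ids) < 2) stop("need >= 2 cells")
  n <- length(ids)
  rmat <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  omat <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(rmat) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xi <- numeric(); xj <- numeric()
    for (seg in st$segments) {
      if (ids[i] %in% colnames(seg$dff) && ids[j] %in% colnames(seg$dff)) {
        xi <- c(xi, seg$dff[, ids[i]]); xj <- c(xj, seg$dff[, ids[j]])
      }
    }
    omat[i, j] <- omat[j, i] <- length(xi) / st$frame_rate / 60
    if (omat[i, j] >= min_overlap_min && stats::sd(xi) > 0 && stats::sd(xj) > 0)
      rmat[i, j] <- rmat[j, i] <- stats::cor(xi, xj)
  }
  pairs <- which(upper.tri(rmat), arr.ind = TRUE)
  rv <- rmat[pairs]
  avg <- fisher_average(rv)
  by_dist <- NULL; d0 <- NA_real_; r0 <- NA_real_
  if (!is.null(positions_um)) {
    dist_um <- abs(positions_um[ids[pairs[, 1]]] - positions_um[ids[pairs[, 2]]])
    ok <- !is.na(rv)
    if (any(ok)) {
      bin <- floor(dist_um[ok] / distance_bin_um)
      by_dist <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
        fa <- fisher_average(rv[ok][bin == b])
        data.frame(distance_um = (b + 0.5) * distance_bin_um,
                   r_mean = fa$mean, r_sd = fa$sd, n_pairs = fa$n)
      }))
      if (fit_decay && nrow(by_dist) >= 3 && any(by_dist$r_mean > 0)) {
        fit <- try(suppressWarnings(
          stats::nls(r_mean ~ r0 * exp(-distance_um / d0),
                     data = by_dist,
                     start = list(r0 = max(by_dist$r_mean),
                                  d0 = max(distance_bin_um * 3, 30)),
                     control = stats::nls.control(warnOnly = TRUE))),
          silent = TRUE)
        if (!inherits(fit, "try-error")) {
          cf <- stats::coef(fit)
          d0 <- unname(cf["d0"]); r0 <- unname(cf["r0"])
        }
      }
    }
  }
  list(r = rmat, overlap_min = omat, average = avg, by_distance = by_dist,
       d0_um = d0, r0 = r0)
}
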