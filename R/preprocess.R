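# Frame quality control and motion handling.

#' Smooth a stack with a 3D Gaussian filter
#'
#' Separable Gaussian smoothing with sigma = `sigma` pixels/frames in t, y
#' and x, mirror-padded at the boundaries so that the global mean is
#' preserved and a constant stack is left unchanged.
#'
#' @param stack a [timelapse_stack()] with at least 3 frames.
#' @param sigma Gaussian sigma, either a scalar (same in all three
#'   dimensions, default 2) or length-3 `(y, x, t)`.
#' @return the smoothed [timelapse_stack()].
#' @export
smooth_stack <- function(stack, sigma = 2) {
  stopifnot(inherits(stack, "timelapse_stack"))
  if (n_frames(stack) < 3L) stop("smoothing needs >= 3 frames")
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  stack$frames <- gauss_blur_3d(stack$frames, sigma)
  ca_log("smooth_stack: sigma = (%g, %g, %g)", sigma[1], sigma[2], sigma[3])
  stack
}

new_frame_qc <- function(removed, method, source, n_frames) {
  structure(list(removed = removed, method = method,
                 substitution_source = source, n_frames = n_frames),
            class = "frame_qc")
}

#' @export
print.frame_qc <- function(x, ...) {
  cat(sprintf("frame_qc: %d removed interval(s) of %d frames\n",
              nrow(x$removed), x$n_frames))
  for (i in seq_len(nrow(x$removed)))
    cat(sprintf("  [%d, %d) %s -> frame %d\n", x$removed[i, 1],
                x$removed[i, 2], x$method[i], x$substitution_source[i]))
  invisible(x)
}

# sliding normalised cross-correlation of template tpl against x
ncc_scan <- function(x, tpl) {
  n <- length(x); m <- length(tpl)
  if (m > n) return(numeric())
  tpl <- (tpl - mean(tpl))
  tn <- sqrt(sum(tpl^2))
  out <- numeric(n - m + 1)
  for (i in seq_len(n - m + 1)) {
    seg <- x[i:(i + m - 1)]
    seg <- seg - mean(seg)
    denom <- tn * sqrt(sum(seg^2))
    out[i] <- if (denom > 0) sum(seg * tpl) / denom else 0
  }
  out
}

#' Detect out-of-focus / breathing frames
#'
#' Computes the pixel-average fluorescence over a large central region of
#' interest, detrends it with a rolling median, and flags brief positive or
#' negative excursions whose prominence exceeds `prominence_k` times the
#' robust SD of the first-differenced trace.  Breathing and focus artifacts
#' are abrupt (a few frames); calcium signals are not, so excursions whose
#' full width at base exceeds `artifact_max_width_s` are left alone.
#' Flagged peaks are expanded to full-width-at-base intervals.  Template
#' matches (normalised cross-correlation against `template_bank` entries)
#' and manually supplied intervals are merged in.
#'
#' @param stack a [timelapse_stack()] (smooth first; see [smooth_stack()]).
#' @param qc_roi_fraction central fraction of the field used for the QC
#'   trace (default 0.8).
#' @param prominence_k prominence threshold in robust SDs (default 4).
#' @param artifact_max_width_s maximum full-width-at-base (seconds) for an
#'   excursion to count as an artifact rather than signal (default 1).
#' @param template_bank optional list of numeric trace snippets; positions
#'   where the detrended QC trace matches one with NCC at or above
#'   `template_threshold` are flagged.
#' @param template_threshold NCC threshold (default 0.8).
#' @param manual_list optional list of half-open `[start, end)` frame
#'   intervals to merge in with method `"manual"`.
#' @param detrend_s rolling-median window (seconds) for the QC trace.
#' @param smoothing_fwhm_s temporal FWHM (seconds) of any smoothing already
#'   applied to the stack; removed in quadrature from measured excursion
#'   widths so that smeared bouts are still recognised as brief (default 0).
#' @return a `frame_qc` report: disjoint sorted half-open intervals, the
#'   method that produced each, and the in-focus substitution source frame
#'   for each.
#' @export
detect_bad_frames <- function(stack, qc_roi_fraction = 0.8, prominence_k = 4,
                              artifact_max_width_s = 1.0,
                              template_bank = NULL, template_threshold = 0.8,
                              manual_list = NULL, detrend_s = 5,
                              smoothing_fwhm_s = 0) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$frames)
  nt <- d[3]
  my <- floor(d[1] * (1 - qc_roi_fraction) / 2)
  mx <- floor(d[2] * (1 - qc_roi_fraction) / 2)
  yy <- (my + 1):(d[1] - my); xx <- (mx + 1):(d[2] - mx)
  if (!length(yy) || !length(xx)) stop("qc ROI is empty")
  qc <- apply(stack$frames[yy, xx, , drop = FALSE], 3, mean)

  k <- 2L * floor(detrend_s * stack$frame_rate / 2) + 1L
  k <- max(3L, min(k, 2L * floor((nt - 1) / 2) + 1L))
  dtr <- qc - stats::runmed(qc, k, endrule = "median")
  # the larger of the two robust scales: first differences miss the slow
  # component of temporally smoothed noise, the detrended trace carries it
  sdr <- max(robust_sd(diff(qc)), robust_sd(dtr))
  # noise-free traces: any excursion is significant
  if (sdr == 0) sdr <- 1e-12

  ivs <- list(); methods <- character()
  for (sgn in c(1, -1)) {
    pk <- find_peaks(sgn * dtr)
    pk <- pk[pk$prominence >= prominence_k * sdr &
               pk$value >= prominence_k * sdr, ]
    for (j in seq_len(nrow(pk))) {
      # excursion width at half prominence, corrected for the smoothing
      # smear: breathing bouts stay brief, calcium signals stay long
      w <- peak_width_at(sgn * dtr, pk$index[j],
                         pk$value[j] - pk$prominence[j] / 2)
      w_s <- sqrt(max(0, (w$width / stack$frame_rate)^2 - smoothing_fwhm_s^2))
      if (w_s > artifact_max_width_s) next
      a <- max(1L, round(w$left)); b <- min(nt, round(w$right)) + 1L
      ivs[[length(ivs) + 1L]] <- c(a, b)
      methods <- c(methods, "prominence")
    }
  }
  if (!is.null(template_bank)) {
    for (tpl in template_bank) {
      sc <- ncc_scan(dtr, tpl)
      hits <- which(sc >= template_threshold)
      # keep local best within one template length
      while (length(hits)) {
        h <- hits[which.max(sc[hits])]
        ivs[[length(ivs) + 1L]] <- c(h, min(nt, h + length(tpl) - 1L) + 1L)
        methods <- c(methods, "template")
        hits <- hits[abs(hits - h) >= length(tpl)]
      }
    }
  }
  if (!is.null(manual_list)) {
    mm <- interval_matrix(manual_list)
    for (j in seq_len(nrow(mm))) {
      ivs[[length(ivs) + 1L]] <- mm[j, ]
      methods <- c(methods, "manual")
    }
  }

  if (!length(ivs)) {
    ca_log("detect_bad_frames: no artifact intervals (n = %d frames)", nt)
    return(new_frame_qc(interval_matrix(NULL), character(), integer(), nt))
  }
  raw <- interval_matrix(ivs)
  raw[, 1] <- pmax(1, raw[, 1]); raw[, 2] <- pmin(nt + 1, raw[, 2])
  merged <- merge_intervals(raw)
  method <- vapply(seq_len(nrow(merged)), function(i) {
    ov <- raw[, 1] < merged[i, 2] & raw[, 2] > merged[i, 1]
    paste(sort(unique(methods[ov])), collapse = "+")
  }, character(1))
  flag <- frames_in_intervals(merged, nt)
  if (all(flag)) stop("no in-focus frames")
  good <- which(!flag)
  source <- vapply(seq_len(nrow(merged)), function(i) {
    before <- good[good < merged[i, 1]]
    if (length(before)) max(before) else min(good[good >= merged[i, 2]])
  }, numeric(1))
  ca_log("detect_bad_frames: %d interval(s), %d/%d frames flagged",
         nrow(merged), sum(flag), nt)
  new_frame_qc(merged, method, as.integer(source), nt)
}

#' Substitute removed frames by the last in-focus frame
#'
#' Each flagged frame is replaced bit-exactly by its substitution source
#' (the last preceding in-focus frame; for an interval at the very start,
#' the first in-focus frame after it), preserving the timing of the
#' recording.  The report is attached to the stack so that trace extraction
#' can interpolate over the substituted samples.
#'
#' @param stack a [timelapse_stack()].
#' @param report a `frame_qc` from [detect_bad_frames()].
#' @return the substituted [timelapse_stack()] with `$qc` set.
#' @export
apply_substitution <- function(stack, report) {
  stopifnot(inherits(stack, "timelapse_stack"), inherits(report, "frame_qc"))
  if (report$n_frames != n_frames(stack))
    stop("report does not match stack frame count")
  for (i in seq_len(nrow(report$removed))) {
    src <- report$substitution_source[i]
    for (k in seq(report$removed[i, 1], report$removed[i, 2] - 1))
      stack$frames[, , k] <- stack$frames[, , src]
  }
  stack$qc <- report
  stack
}

# phase correlation: shift (dy, dx) such that frame[y, x] ~= ref[y-dy, x-dx]
phase_correlate <- function(frame, ref) {
  Fa <- stats::fft(frame); Fb <- stats::fft(ref)
  R <- Fa * Conj(Fb)
  R <- R / (Mod(R) + 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE))
  p <- which.max(cc)
  ny <- nrow(cc); nx <- ncol(cc)
  py <- (p - 1) %% ny + 1; pxi <- (p - 1) %/% ny + 1
  sub <- function(cvec, p, n) {
    cm <- cvec[(p - 2) %% n + 1]; c0 <- cvec[p]; cp <- cvec[p %% n + 1]
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else 0.5 * (cm - cp) / den
  }
  dy <- py - 1 + sub(cc[, pxi], py, ny)
  dx <- pxi - 1 + sub(cc[py, ], pxi, nx)
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dy, dx)
}

#' Correct lateral drift by rigid per-frame translation
#'
#' Estimates a single translation per frame by phase correlation against a
#' reference image (default: the frame average), refines it to subpixel
#' precision by parabolic interpolation of the correlation peak, and shifts
#' each frame back by bilinear interpolation.  The output is rescaled so its
#' global mean equals the input's.  Piecewise non-rigid registration is out
#' of scope; externally computed shift tables can be supplied instead of the
#' estimation step.
#'
#' @param stack a [timelapse_stack()].
#' @param reference reference image (matrix); default frame average.
#' @param max_shift maximum allowed shift in pixels; estimates at or beyond
#'   the boundary are clamped with a warning.  Must be below a quarter of
#'   the smaller image dimension.
#' @param shifts optional externally computed data.frame with columns
#'   `dy`, `dx` (one row per frame); skips estimation.
#' @return list with `stack` (corrected) and `shifts` (data.frame `frame`,
#'   `dy`, `dx`).
#' @export
correct_drift <- function(stack, reference = NULL, max_shift = 10,
                          shifts = NULL) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$frames)
  if (max_shift >= min(d[1:2]) / 4)
    stop("max_shift must be below a quarter of the image size")
  if (is.null(reference)) reference <- mean_image(stack)
  nt <- d[3]
  if (is.null(shifts)) {
    sh <- matrix(0, nt, 2)
    for (k in seq_len(nt))
      sh[k, ] <- phase_correlate(stack$frames[, , k], reference)
    if (any(abs(sh) >= max_shift)) {
      warning("estimated shift clamped at max_shift for ",
              sum(rowSums(abs(sh) >= max_shift) > 0), " frame(s)")
      sh <- pmin(pmax(sh, -max_shift), max_shift)
    }
    shifts <- data.frame(frame = seq_len(nt), dy = sh[, 1], dx = sh[, 2])
  }
  m_in <- mean(stack$frames)
  for (k in seq_len(nt)) {
    if (shifts$dy[k] != 0 || shifts$dx[k] != 0)
      stack$frames[, , k] <- translate_bilinear(stack$frames[, , k],
                                                shifts$dy[k], shifts$dx[k])
  }
  m_out <- mean(stack$frames)
  if (m_out > 0) stack$frames <- stack$frames * (m_in / m_out)
  ca_log("correct_drift: max |shift| = %.2f px, mean rescale %.4f",
         max(abs(c(shifts$dy, shifts$dx))), m_in / max(m_out, 1e-12))
  list(stack = stack, shifts = shifts)
}
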