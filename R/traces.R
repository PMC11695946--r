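# ROI trace extraction, dF/F0, detrending and stitching.

#' Extract dF/F0 fluorescence traces from a stack
#'
#' Pixel-averages each ROI per frame, linearly interpolates the samples that
#' fall inside removed-frame intervals (flagging them in the interpolated
#' mask), and normalises to dF/F0 = (F - F0) / F0.  F0 defaults to the 10th
#' percentile of the raw trace of each ROI within the recording, a low
#' quantile that is robust to active periods.
#'
#' @param stack a [timelapse_stack()] (after preprocessing).
#' @param rois a [roi_map()] (erode first; see [erode_rois()]).
#' @param report optional `frame_qc`; defaults to the one attached to the
#'   stack by [apply_substitution()], if any.
#' @param f0_rule `"percentile"` (default) or `"median"`.
#' @param f0_percentile percentile used when `f0_rule = "percentile"`.
#' @return an object of class `trace_set`: list with `time` (s), `dff`
#'   (frames x ROIs matrix, columns named by cell identity), `raw` (same
#'   for raw F), `interpolated` (logical matrix), `frame_rate`,
#'   `recording_id`, `start_time` (s, used by stitching) and `class_of`.
#' @export
extract_traces <- function(stack, rois, report = NULL,
                           f0_rule = c("percentile", "median"),
                           f0_percentile = 10) {
  stopifnot(inherits(stack, "timelapse_stack"), inherits(rois, "roi_map"))
  f0_rule <- match.arg(f0_rule)
  if (!identical(dim(rois$labels), dim(stack$frames)[1:2]))
    stop("ROI grid does not match stack frames")
  report <- report %||% stack$qc
  px <- roi_pixels(rois)
  if (!length(px)) stop("no ROIs to extract")
  nt <- n_frames(stack)
  # frame-by-frame accumulation avoids copying the whole movie
  sel <- unlist(px, use.names = FALSE)
  grp <- factor(rep(seq_along(px), lengths(px)))
  counts <- lengths(px)
  raw <- matrix(0, nt, length(px), dimnames = list(NULL, names(px)))
  for (k in seq_len(nt)) {
    fr <- stack$frames[, , k]
    raw[k, ] <- rowsum(fr[sel], grp)[, 1] / counts
  }
  interp <- matrix(FALSE, nt, ncol(raw))
  if (!is.null(report) && nrow(report$removed) > 0) {
    bad <- frames_in_intervals(report$removed, nt)
    interp[bad, ] <- TRUE
    good <- which(!bad)
    for (j in seq_len(ncol(raw)))
      raw[bad, j] <- stats::approx(good, raw[good, j], xout = which(bad),
                                   rule = 2)$y
  }
  f0 <- switch(f0_rule,
               percentile = apply(raw, 2, stats::quantile,
                                  probs = f0_percentile / 100, names = FALSE),
               median = apply(raw, 2, stats::median))
  ids <- rois$identity_of[colnames(raw)]
  bad_f0 <- which(f0 <= 0)
  if (length(bad_f0))
    stop("F0 <= 0 for ROI(s): ", paste(ids[bad_f0], collapse = ", "))
  dff <- sweep(sweep(raw, 2, f0, "-"), 2, f0, "/")
  cls <- stats::setNames(unname(rois$class_of[colnames(raw)]), unname(ids))
  colnames(dff) <- colnames(raw) <- colnames(interp) <- unname(ids)
  ca_log("extract_traces: %d ROIs x %d frames, %.1f%% interpolated",
         ncol(raw), nt, 100 * mean(interp))
  structure(list(time = frame_times(stack), dff = dff, raw = raw,
                 interpolated = interp, frame_rate = stack$frame_rate,
                 recording_id = stack$recording_id, start_time = 0,
                 class_of = cls),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set '%s': %d cells x %d samples @ %.3g fps\n",
              x$recording_id, ncol(x$dff), nrow(x$dff), x$frame_rate))
  invisible(x)
}

#' Detrend traces with a centred rolling median
#'
#' Subtracts a running median (window `window_s` seconds, shrinking at the
#' edges) from each trace, removing slow baseline drift while preserving
#' transients much shorter than the window.
#'
#' @param x a `trace_set` or a numeric vector/matrix of traces (columns).
#' @param window_s window length in seconds (must cover >= 3 samples).
#' @param frame_rate sampling rate; taken from the `trace_set` if given one.
#' @return object of the same shape with detrended dF/F0.
#' @export
detrend_traces <- function(x, window_s = 30, frame_rate = NULL) {
  if (inherits(x, "stitched_traces")) {
    x$segments <- lapply(x$segments, detrend_traces, window_s = window_s)
    return(x)
  }
  if (inherits(x, "trace_set")) {
    x$dff <- detrend_traces(x$dff, window_s, x$frame_rate)
    return(x)
  }
  if (is.null(frame_rate)) stop("frame_rate required for bare traces")
  k <- 2L * floor(window_s * frame_rate / 2) + 1L
  if (k < 3L) stop("detrend window must cover >= 3 samples")
  one <- function(v) {
    kk <- min(k, 2L * floor((length(v) - 1) / 2) + 1L)
    if (kk < 3L) return(v - stats::median(v))
    as.numeric(v - stats::runmed(v, kk, endrule = "median"))
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

#' Stitch repeated recordings of the same field of view
#'
#' Concatenates the traces of cells recorded in several successive
#' recordings, matching cells through their persistent identities (the
#' identity map of the ROI maps).  A cell absent from some recordings
#' contributes only the durations in which it was recorded.  Recording
#' boundaries are kept so that downstream peak detection never links
#' transients across a gap.
#'
#' @param trace_sets list of `trace_set`s in acquisition order.
#' @return an object of class `stitched_traces`: list with `segments` (the
#'   input trace sets, with cumulative `start_time`s), `cells` (data.frame:
#'   identity, total_duration_s, n_recordings) and `frame_rate`.
#' @export
stitch_recordings <- function(trace_sets) {
  stopifnot(length(trace_sets) >= 1,
            all(vapply(trace_sets, inherits, logical(1), "trace_set")))
  fr <- trace_sets[[1]]$frame_rate
  for (ts in trace_sets) if (abs(ts$frame_rate - fr) > 1e-9)
    stop("all recordings must share a frame rate")
  ids <- lapply(trace_sets, function(ts) colnames(ts$dff))
  for (i in seq_along(ids)) if (anyDuplicated(ids[[i]]))
    stop("identity collision within recording ", trace_sets[[i]]$recording_id)
  t0 <- 0
  for (i in seq_along(trace_sets)) {
    trace_sets[[i]]$start_time <- t0
    t0 <- t0 + nrow(trace_sets[[i]]$dff) / fr
  }
  all_ids <- unique(unlist(ids))
  dur <- vapply(all_ids, function(id) {
    sum(vapply(trace_sets, function(ts)
      if (id %in% colnames(ts$dff)) nrow(ts$dff) / fr else 0, numeric(1)))
  }, numeric(1))
  nrec <- vapply(all_ids, function(id)
    sum(vapply(trace_sets, function(ts) id %in% colnames(ts$dff),
               logical(1))), numeric(1))
  ca_log("stitch_recordings: %d recordings, %d cells, %.1f min total",
         length(trace_sets), length(all_ids), t0 / 60)
  structure(list(segments = trace_sets,
                 cells = data.frame(identity = all_ids,
                                    total_duration_s = unname(dur),
                                    n_recordings = unname(nrec)),
                 frame_rate = fr),
            class = "stitched_traces")
}

#' Build a trace set from a bare dF/F0 matrix
#'
#' Wraps externally computed (or [render_traces()]-produced) traces in the
#' container the detection and correlation functions expect.
#'
#' @param dff frames x cells matrix of dF/F0, columns named by cell
#'   identity.
#' @param frame_rate samples per second.
#' @param recording_id identifier used in stitching and result tables.
#' @param class_of optional named class vector per identity (default
#'   `"IHC"`).
#' @return a `trace_set` (see [extract_traces()]).
#' @export
as_trace_set <- function(dff, frame_rate, recording_id = "rec",
                         class_of = NULL) {
  stopifnot(is.matrix(dff), frame_rate > 0)
  if (is.null(colnames(dff)))
    colnames(dff) <- sprintf("C%02d", seq_len(ncol(dff)))
  if (is.null(class_of))
    class_of <- stats::setNames(rep("IHC", ncol(dff)), colnames(dff))
  structure(list(
    time = (seq_len(nrow(dff)) - 1) / frame_rate,
    dff = dff, raw = dff,
    interpolated = matrix(FALSE, nrow(dff), ncol(dff),
                          dimnames = list(NULL, colnames(dff))),
    frame_rate = frame_rate, recording_id = recording_id, start_time = 0,
    class_of = class_of),
    class = "trace_set")
}

#' Coerce traces to a stitched series
#' @param x a `trace_set` or `stitched_traces`.
#' @keywords internal
as_stitched <- function(x) {
  if (inherits(x, "stitched_traces")) return(x)
  if (inherits(x, "trace_set")) return(stitch_recordings(list(x)))
  stop("expected a trace_set or stitched_traces")
}
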