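# Supporting-cell calcium waves: 3D segmentation, geometry, kinetics.

# 2x2 (or n x n) spatial mean-binning of a (y, x, t) array
bin_stack <- function(arr, bin_factor) {
  if (bin_factor <= 1) return(arr)
  d <- dim(arr)
  ny <- d[1] %/% bin_factor; nx <- d[2] %/% bin_factor
  arr <- arr[seq_len(ny * bin_factor), seq_len(nx * bin_factor), , drop = FALSE]
  a <- array(arr, dim = c(bin_factor, ny, bin_factor * nx * d[3]))
  a <- colMeans(a)                       # (ny, bin * nx * t)
  a <- array(a, dim = c(ny, bin_factor, nx * d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- colMeans(a)                       # (ny, nx * t)
  array(a, dim = c(ny, nx, d[3]))
}

# 3D local maxima above a threshold: strictly greater than every other
# voxel within a box of the given radius (radius 1 = 26-neighbourhood).
# Two passes: cheap 26-neighbour maxima first, then each candidate is
# verified against its full box.
local_maxima_3d <- function(arr, thr, radius = 1L) {
  d <- dim(arr)
  nb <- array(-Inf, d)
  for (dy in -1:1) for (dx in -1:1) for (dt in -1:1) {
    if (dy == 0 && dx == 0 && dt == 0) next
    ys <- pmin(pmax(seq_len(d[1]) + dy, 1L), d[1])
    xs <- pmin(pmax(seq_len(d[2]) + dx, 1L), d[2])
    ts <- pmin(pmax(seq_len(d[3]) + dt, 1L), d[3])
    nb <- pmax(nb, arr[ys, xs, ts, drop = FALSE])
  }
  cand <- which(arr > nb & arr > thr, arr.ind = TRUE)
  r <- as.integer(radius)
  if (r <= 1L || nrow(cand) == 0L) return(cand)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ys <- max(1L, cand[i, 1] - r):min(d[1], cand[i, 1] + r)
    xs <- max(1L, cand[i, 2] - r):min(d[2], cand[i, 2] + r)
    ts <- max(1L, cand[i, 3] - r):min(d[3], cand[i, 3] + r)
    box <- arr[ys, xs, ts]
    v <- arr[cand[i, 1], cand[i, 2], cand[i, 3]]
    keep[i] <- sum(box >= v) == 1L # strictly the largest in its box
  }
  cand[keep, , drop = FALSE]
}

#' Segment calcium waves as 3D spatiotemporal objects
#'
#' The dF stack (each binned pixel minus its own rolling-median baseline,
#' window `baseline_window_s`, which tracks slow intensity changes such as
#' residual drift ripple while leaving few-second waves untouched) is
#' labelled with the Voronoi-Otsu scheme: a strongly smoothed copy provides local-maximum seeds, a lightly
#' smoothed copy is thresholded (Otsu on the dF distribution by default; a
#' scalar override is recorded in the result), and each suprathreshold voxel
#' is assigned to its nearest seed before 3D 26-connected components are
#' taken within each seed's territory.  Components below `min_volume_voxels`
#' or confined within a single-cell footprint (both spatial extents below
#' `cell_diameter_um`) are discarded and logged: transients in individual
#' isolated cells are not waves.
#'
#' @param stack a preprocessed [timelapse_stack()] of the GER field.
#' @param bin_factor spatial binning factor (default 2).
#' @param threshold `"otsu"` or a scalar dF threshold.
#' @param spot_sigma seed-detection Gaussian sigma in binned voxels
#'   (default 6); seeds are maxima over a neighbourhood of the same radius,
#'   so larger values give fewer, coarser objects.
#' @param outline_sigma outline Gaussian sigma in binned voxels (default 1).
#' @param min_volume_voxels minimum component volume (default 10).
#' @param cell_diameter_um single-cell confinement limit; set above one
#'   cell diameter plus the smoothing spread (default 15).
#' @param noise_floor_k the automatic threshold is never allowed below
#'   `noise_floor_k` robust SDs of the dF distribution, so that a
#'   recording without waves yields no spurious objects (default 6).
#' @param region_mask optional logical matrix on the unbinned `(y, x)` grid
#'   restricting segmentation, e.g. to the modiolar (GER) side of the
#'   cochlear axis, replacing the manual curation of mixed-label fields.
#' @param ignore_border_px unbinned border width zeroed before
#'   thresholding; rigid drift correction replicates edge rows, and the
#'   resulting intensity ripple must not segment as activity (default 3).
#' @param baseline_window_s per-pixel rolling-median baseline window in
#'   seconds (default 30); must be much longer than a wave.
#' @return an object of class `wave_set`: list with `waves` (list of voxel
#'   data.frames: `y`, `x`, `t` in binned-pixel / frame units), `dff` (the
#'   binned dF array), `bin_size_um`, `frame_rate`, `threshold_used`,
#'   `dims`.
#' @export
segment_waves <- function(stack, bin_factor = 2, threshold = "otsu",
                          spot_sigma = 6, outline_sigma = 1,
                          min_volume_voxels = 10, cell_diameter_um = 15,
                          noise_floor_k = 6, region_mask = NULL,
                          ignore_border_px = 3, baseline_window_s = 30) {
  stopifnot(inherits(stack, "timelapse_stack"), bin_factor >= 1)
  nt <- n_frames(stack)
  binned <- bin_stack(stack$frames, bin_factor)
  d <- dim(binned)
  M <- matrix(binned, ncol = nt)
  k <- 2L * floor(baseline_window_s * stack$frame_rate / 2) + 1L
  k <- max(3L, min(k, 2L * floor((nt - 1) / 2) + 1L))
  # constant end rule: shrinking end-windows would absorb a wave that is
  # already running at the first frame and hide its truncation
  for (i in seq_len(nrow(M)))
    M[i, ] <- M[i, ] - stats::runmed(M[i, ], k, endrule = "constant")
  dff <- array(M, dim = d)
  rm(M)
  keep2d <- matrix(TRUE, d[1], d[2])
  if (!is.null(region_mask)) {
    stopifnot(identical(dim(region_mask), dim(stack$frames)[1:2]))
    keep2d <- keep2d & (bin_stack(array(region_mask + 0,
                                        dim = c(dim(region_mask), 1L)),
                                  bin_factor)[, , 1] > 0.5)
  }
  if (ignore_border_px > 0) {
    b <- max(1L, ceiling(ignore_border_px / bin_factor))
    if (2 * b < min(d[1:2])) {
      border <- matrix(TRUE, d[1], d[2])
      border[(b + 1):(d[1] - b), (b + 1):(d[2] - b)] <- FALSE
      keep2d[border] <- FALSE
    }
  }
  if (!all(keep2d)) dff <- dff * as.vector(keep2d)
  sm_spot <- gauss_blur_3d(dff, rep(spot_sigma, 3))
  sm_out <- if (outline_sigma > 0) gauss_blur_3d(dff, rep(outline_sigma, 3))
            else dff
  thr <- if (identical(threshold, "otsu")) {
    max(otsu_threshold(sm_out), noise_floor_k * robust_sd(as.vector(dff)))
  } else as.numeric(threshold)
  mask <- sm_out > thr
  if (!any(mask)) {
    warning("wave segmentation: threshold leaves no foreground")
    return(structure(list(waves = list(), dff = dff,
                          bin_size_um = bin_factor * stack$pixel_size,
                          frame_rate = stack$frame_rate,
                          threshold_used = thr, dims = d),
                     class = "wave_set"))
  }
  seeds <- local_maxima_3d(sm_spot, thr, radius = ceiling(spot_sigma))
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(seeds) == 0) seeds <- vox[which.max(sm_spot[mask]), , drop = FALSE]
  # nearest-seed (Voronoi) territory, then components inside each territory
  lab <- integer(nrow(vox))
  block <- 100000L
  for (a in seq(1L, nrow(vox), by = block)) {
    b <- min(a + block - 1L, nrow(vox))
    dmat <- outer(vox[a:b, 1], seeds[, 1], "-")^2 +
      outer(vox[a:b, 2], seeds[, 2], "-")^2 +
      outer(vox[a:b, 3], seeds[, 3], "-")^2
    lab[a:b] <- max.col(-dmat, ties.method = "first")
  }
  waves <- list()
  bin_um <- bin_factor * stack$pixel_size
  n_small <- n_cell <- 0L
  for (sd_lab in unique(lab)) {
    v <- vox[lab == sd_lab, , drop = FALSE]
    comp <- label_components_3d(v, d)
    for (cid in unique(comp)) {
      vv <- v[comp == cid, , drop = FALSE]
      if (nrow(vv) < min_volume_voxels) { n_small <- n_small + 1L; next }
      ext_y <- (diff(range(vv[, 1])) + 1) * bin_um
      ext_x <- (diff(range(vv[, 2])) + 1) * bin_um
      if (ext_y < cell_diameter_um && ext_x < cell_diameter_um) {
        n_cell <- n_cell + 1L; next
      }
      waves[[length(waves) + 1L]] <-
        data.frame(y = vv[, 1], x = vv[, 2], t = vv[, 3])
    }
  }
  # order by onset frame for reproducible ids
  if (length(waves) > 1) {
    waves <- waves[order(vapply(waves, function(w) min(w$t), numeric(1)))]
  }
  ca_log("segment_waves: %d wave(s); filtered %d below volume, %d single-cell",
         length(waves), n_small, n_cell)
  structure(list(waves = waves, dff = dff, bin_size_um = bin_um,
                 frame_rate = stack$frame_rate, threshold_used = thr,
                 dims = d),
            class = "wave_set")
}

#' @export
print.wave_set <- function(x, ...) {
  cat(sprintf("wave_set: %d wave(s), %.3g um binned px, threshold %.4g\n",
              length(x$waves), x$bin_size_um, x$threshold_used))
  invisible(x)
}

# binned-pixel centre to micrometre coordinates
binned_xy_um <- function(vox, bin_um) {
  cbind(x = (vox$x - 0.5) * bin_um, y = (vox$y - 0.5) * bin_um)
}

#' Quantify the geometry and kinetics of segmented waves
#'
#' For each wave: per-frame area and its maximum; the footprint at maximal
#' expansion mapped into axis coordinates, giving the longitudinal and
#' radial extents and the centroid distance to the IHC row; the FDHM of the
#' pixel-average dF trace over the footprint (skipped when the wave touches
#' the first or last frame, since a truncated duration cannot be measured);
#' and the expansion / contraction speeds as the slope of the equivalent
#' radius `sqrt(area / pi)` against time from onset to the max-area frame
#' and from there to offset (the `"boundary"` estimator instead tracks the
#' maximal boundary distance from the wave centroid).
#'
#' @param wave_set a [segment_waves()] result.
#' @param axis the [cochlear_axis()] of the recording, in micrometres.
#' @param speed_estimator `"equivalent_radius"` (default) or `"boundary"`.
#' @return data.frame, one row per wave: `wave_id`, `onset_s`, `offset_s`,
#'   `max_area_um2`, `t_max_s`, `centroid_s_um`, `centroid_d_um`,
#'   `centroid_distance_um`, `longitudinal_extent_um`, `radial_extent_um`,
#'   `fdhm_s`, `expansion_speed_um_s`, `contraction_speed_um_s`,
#'   `boundary_truncated`, `n_voxels`, `manual` (FALSE here; see
#'   [add_manual_waves()]).
#' @export
quantify_wave <- function(wave_set, axis,
                          speed_estimator = c("equivalent_radius", "boundary")) {
  speed_estimator <- match.arg(speed_estimator)
  bin_um <- wave_set$bin_size_um
  fr <- wave_set$frame_rate
  nt <- wave_set$dims[3]
  px_area <- bin_um^2
  rows <- list()
  for (w in seq_along(wave_set$waves)) {
    vox <- wave_set$waves[[w]]
    stopifnot(nrow(vox) > 0)
    frames <- sort(unique(vox$t))
    area <- vapply(frames, function(k) sum(vox$t == k), numeric(1)) * px_area
    k_max <- frames[which.max(area)]
    foot <- vox[vox$t == k_max, ]
    xy <- binned_xy_um(foot, bin_um)
    sd_ax <- axis_transform(axis, xy)
    cen <- axis_transform(axis, matrix(colMeans(xy), 1))
    truncated <- min(frames) <= 1L || max(frames) >= nt
    fdhm <- NA_real_
    if (!truncated) {
      # pixel-average dF trace over the maximal footprint
      idx <- (foot$x - 1) * wave_set$dims[1] + foot$y
      M <- matrix(wave_set$dff, ncol = nt)
      trace <- colMeans(M[idx, , drop = FALSE])
      pw <- peak_width_at(trace - stats::median(trace), k_max,
                          (trace[k_max] - stats::median(trace)) / 2)
      if (!pw$truncated) fdhm <- pw$width / fr
    }
    tt <- frames / fr
    radius <- if (speed_estimator == "equivalent_radius") {
      sqrt(area / pi)
    } else {
      cx <- mean(binned_xy_um(vox, bin_um)[, 1])
      cy <- mean(binned_xy_um(vox, bin_um)[, 2])
      vapply(frames, function(k) {
        fxy <- binned_xy_um(vox[vox$t == k, ], bin_um)
        max(sqrt((fxy[, 1] - cx)^2 + (fxy[, 2] - cy)^2))
      }, numeric(1))
    }
    fit_speed <- function(sel) {
      # restrict to the moving part of the branch: radii between 10% and
      # 95% of the maximum, so neither plateau frames nor smoothing tails
      # dilute the slope
      sel <- sel & radius >= 0.1 * max(radius) & radius <= 0.95 * max(radius)
      if (sum(sel) < 2) return(NA_real_)
      unname(stats::coef(stats::lm(radius[sel] ~ tt[sel]))[2])
    }
    k_rise_end <- min(frames[radius >= 0.95 * max(radius)])
    k_fall_start <- max(frames[radius >= 0.95 * max(radius)])
    exp_sp <- fit_speed(frames <= k_rise_end)
    con_sp <- fit_speed(frames >= k_fall_start)
    if (is.na(exp_sp) || is.na(con_sp))
      ca_log("quantify_wave: wave %d speed undefined (max at wave boundary)", w)
    rows[[w]] <- data.frame(
      wave_id = w,
      onset_s = (min(frames) - 1) / fr, offset_s = max(frames) / fr,
      max_area_um2 = max(area), t_max_s = (k_max - 1) / fr,
      centroid_s_um = cen$s, centroid_d_um = cen$d,
      centroid_distance_um = abs(cen$d),
      longitudinal_extent_um = diff(range(sd_ax$s)) + bin_um,
      radial_extent_um = diff(range(sd_ax$d)) + bin_um,
      fdhm_s = fdhm,
      expansion_speed_um_s = exp_sp,
      contraction_speed_um_s = if (is.na(con_sp)) NA_real_ else abs(con_sp),
      boundary_truncated = truncated,
      n_voxels = nrow(vox), manual = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(wave_id = integer(), onset_s = numeric(),
                      offset_s = numeric(), max_area_um2 = numeric(),
                      t_max_s = numeric(), centroid_s_um = numeric(),
                      centroid_d_um = numeric(),
                      centroid_distance_um = numeric(),
                      longitudinal_extent_um = numeric(),
                      radial_extent_um = numeric(), fdhm_s = numeric(),
                      expansion_speed_um_s = numeric(),
                      contraction_speed_um_s = numeric(),
                      boundary_truncated = logical(), n_voxels = integer(),
                      manual = logical())
  out
}

#' Append manually drawn 2D wave outlines
#'
#' Waves missed by the automatic segmentation can be supplied as 2D label
#' outlines drawn at their maximal extension.  They contribute to wave
#' counts and extension statistics but never to kinetic properties (FDHM,
#' speeds), which cannot be measured from a single outline.
#'
#' @param wave_table a [quantify_wave()] table.
#' @param rois a [roi_map()] of 2D outlines (one label per wave).
#' @param axis the recording's [cochlear_axis()].
#' @param pixel_size micrometres per (unbinned) pixel of the outline image.
#' @return the augmented wave table, manual rows flagged `manual = TRUE`.
#' @export
add_manual_waves <- function(wave_table, rois, axis, pixel_size) {
  px <- roi_pixels(rois)
  ny <- nrow(rois$labels)
  rows <- lapply(seq_along(px), function(i) {
    idx <- px[[i]]
    yy <- ((idx - 1) %% ny) + 1; xx <- ((idx - 1) %/% ny) + 1
    xy <- cbind(x = (xx - 0.5) * pixel_size, y = (yy - 0.5) * pixel_size)
    sd_ax <- axis_transform(axis, xy)
    cen <- axis_transform(axis, matrix(colMeans(xy), 1))
    data.frame(wave_id = max(wave_table$wave_id, 0L) + i,
               onset_s = NA_real_, offset_s = NA_real_,
               max_area_um2 = length(idx) * pixel_size^2, t_max_s = NA_real_,
               centroid_s_um = cen$s, centroid_d_um = cen$d,
               centroid_distance_um = abs(cen$d),
               longitudinal_extent_um = diff(range(sd_ax$s)) + pixel_size,
               radial_extent_um = diff(range(sd_ax$d)) + pixel_size,
               fdhm_s = NA_real_, expansion_speed_um_s = NA_real_,
               contraction_speed_um_s = NA_real_, boundary_truncated = FALSE,
               n_voxels = length(idx), manual = TRUE)
  })
  rbind(wave_table, do.call(rbind, rows))
}

#' Wave frequency
#'
#' Number of waves divided by the recording duration, in waves/min.
#' Boundary-truncated waves count toward the frequency (only duration
#' statistics exclude them).
#'
#' @param wave_table a [quantify_wave()] table.
#' @param total_duration_s recording duration in seconds.
#' @export
wave_frequency <- function(wave_table, total_duration_s) {
  if (total_duration_s <= 0) stop("total_duration_s must be positive")
  nrow(wave_table) / (total_duration_s / 60)
}

#' Build a kymograph along a polyline
#'
#' Distance-time image: each column is the mean intensity over a transect
#' perpendicular to the polyline (half-width `half_width_px` pixels) at
#' arc-length samples spaced `step_um` apart, each row one frame.
#'
#' @param stack a [timelapse_stack()].
#' @param polyline a [cochlear_axis()] or an n x 2 vertex matrix
#'   (micrometres in the image frame).
#' @param half_width_px transect half-width in pixels (default 3).
#' @param step_um arc-length sampling step (default 1 um).
#' @return an object of class `kymograph`: list with `img` (frames x
#'   columns matrix), `s_um` (column arc-length centres), `step_um`,
#'   `frame_rate`.
#' @export
build_kymograph <- function(stack, polyline, half_width_px = 3, step_um = 1) {
  stopifnot(inherits(stack, "timelapse_stack"))
  axis <- if (inherits(polyline, "cochlear_axis")) polyline
          else cochlear_axis(polyline)
  L <- axis_length(axis)
  s_samp <- seq(0, L, by = step_um)
  px <- stack$pixel_size
  offs <- seq(-half_width_px, half_width_px) * px
  pts <- list()
  for (i in seq_along(s_samp))
    pts[[i]] <- axis_point(axis, rep(s_samp[i], length(offs)), offs)
  P <- do.call(rbind, pts)   # (n_s * n_off) x 2 micrometre positions
  col_px <- P[, 1] / px + 1; row_px <- P[, 2] / px + 1
  d <- dim(stack$frames)
  outside <- col_px < 1 | col_px > d[2] | row_px < 1 | row_px > d[1]
  if (any(outside)) {
    warning("kymograph polyline transects clipped at the field border")
    col_px <- pmin(pmax(col_px, 1), d[2])
    row_px <- pmin(pmax(row_px, 1), d[1])
  }
  y0 <- floor(row_px); x0 <- floor(col_px)
  y1 <- pmin(y0 + 1, d[1]); x1 <- pmin(x0 + 1, d[2])
  fy <- row_px - y0; fx <- col_px - x0
  nt <- d[3]
  M <- matrix(stack$frames, ncol = nt)
  iv <- function(yy, xx) (xx - 1) * d[1] + yy
  samp <- M[iv(y0, x0), , drop = FALSE] * (1 - fy) * (1 - fx) +
    M[iv(y1, x0), , drop = FALSE] * fy * (1 - fx) +
    M[iv(y0, x1), , drop = FALSE] * (1 - fy) * fx +
    M[iv(y1, x1), , drop = FALSE] * fy * fx
  grpmean <- rowsum(samp, rep(seq_along(s_samp), each = length(offs))) /
    length(offs)
  structure(list(img = t(grpmean), s_um = s_samp, step_um = step_um,
                 frame_rate = stack$frame_rate),
            class = "kymograph")
}

#' Measure longitudinal propagation speed on a kymograph
#'
#' Within a time-by-arclength box, the origin is the earliest suprathreshold
#' sample (threshold: half-way between the box minimum and maximum) and the
#' point of maximal expansion the suprathreshold sample farthest from the
#' origin along the arc; the speed is the space/time ratio of that line.
#' Events starting simultaneously with a breathing bout can have `dt = 0`,
#' in which case the speed is undefined (NA, logged).
#'
#' @param kymo a [build_kymograph()] result.
#' @param t_range length-2 time window, seconds.
#' @param s_range length-2 arc-length window, micrometres.
#' @return speed in um/s (NA when undefined).
#' @export
measure_kymo_speed <- function(kymo, t_range, s_range) {
  rows <- which((seq_len(nrow(kymo$img)) - 1) / kymo$frame_rate >= t_range[1] &
                (seq_len(nrow(kymo$img)) - 1) / kymo$frame_rate <= t_range[2])
  cols <- which(kymo$s_um >= s_range[1] & kymo$s_um <= s_range[2])
  if (length(rows) < 2 || length(cols) < 1) stop("degenerate event box")
  box <- kymo$img[rows, cols, drop = FALSE]
  thr <- (max(box) + min(box)) / 2
  supra <- which(box >= thr, arr.ind = TRUE)
  t_s <- (rows[supra[, 1]] - 1) / kymo$frame_rate
  s_s <- kymo$s_um[cols[supra[, 2]]]
  k0 <- t_s == min(t_s)
  s_origin <- mean(s_s[k0]); t_origin <- min(t_s)
  # expansion counts only beyond the footprint already present at onset
  r0 <- if (sum(k0) > 1) max(abs(s_s[k0] - s_origin)) else 0
  later <- t_s > t_origin
  if (!any(later)) {
    # the event is visible in a single frame (e.g. obscured by breathing)
    ca_log("measure_kymo_speed: dt = 0, speed undefined")
    return(NA_real_)
  }
  ds <- abs(s_s[later] - s_origin)
  dmax <- max(ds) - r0
  if (dmax <= kymo$step_um) return(0)
  at_max <- which(ds >= max(ds) - 1e-9)
  dt <- min(t_s[later][at_max]) - t_origin
  dmax / dt
}

#' Match segmented waves to IHC events
#'
#' Waves whose maximal-expansion centroid lies within `origin_window_um` of
#' the IHC row are matched to the IHC event (if any) whose time span
#' overlaps `[wave onset, wave offset + lag_s]`; when several events
#' overlap, the nearest in time is chosen and flagged.  Each record carries
#' the wave's longitudinal extent and the matched event's IHC activity span
#' (micrometres between the outermost participating IHCs), plus flags for
#' "reached the IHC area" (matched at all) and "coordinated >= 3 IHCs".
#'
#' @param wave_table a [quantify_wave()] table.
#' @param events the `events` table from [group_events()].
#' @param positions_um named numeric vector: longitudinal coordinate (um)
#'   per IHC identity.
#' @param origin_window_um eligibility window (default 35).
#' @param lag_s tolerated lag between wave offset and event span (default 2).
#' @return data.frame, one row per eligible wave: `wave_id`, `event_id`,
#'   `matched`, `ambiguous`, `wave_extent_um`, `ihc_span_um`,
#'   `coordinated`.
#' @export
match_wave_to_ihc_events <- function(wave_table, events, positions_um,
                                     origin_window_um = 35, lag_s = 2) {
  wt <- wave_table[!is.na(wave_table$centroid_distance_um) &
                     wave_table$centroid_distance_um <= origin_window_um, ]
  rows <- lapply(seq_len(nrow(wt)), function(i) {
    w <- wt[i, ]
    t0 <- w$onset_s; t1 <- w$offset_s + lag_s
    ov <- which(events$t_start <= t1 & events$t_end >= t0)
    ev_id <- NA_integer_; span <- NA_real_; coord <- FALSE; amb <- FALSE
    if (length(ov)) {
      amb <- length(ov) > 1
      ev <- ov[which.min(abs(events$t_start[ov] - t0))]
      ev_id <- events$event_id[ev]
      ids <- unlist(events$cells[ev])
      span <- diff(range(positions_um[ids]))
      coord <- events$n_cells[ev] >= 3
    }
    data.frame(wave_id = w$wave_id, event_id = ev_id,
               matched = !is.na(ev_id), ambiguous = amb,
               wave_extent_um = w$longitudinal_extent_um,
               ihc_span_um = span, coordinated = coord)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(wave_id = integer(), event_id = integer(),
                      matched = logical(), ambiguous = logical(),
                      wave_extent_um = numeric(), ihc_span_um = numeric(),
                      coordinated = logical())
  ca_log("match_wave_to_ihc_events: %d eligible wave(s), %d matched",
         nrow(out), sum(out$matched))
  out
}
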