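# SGN afferent terminals: segmentation, assignment, recruitment, asymmetry.

#' Segment terminal puncta from a mean image
#'
#' Grayscale white top-hat filtering (disc of `tophat_radius_px`) removes
#' the smooth background, then 2D Voronoi-Otsu labelling separates the
#' bright puncta:
#' local maxima of a spot-smoothed copy seed a nearest-seed partition of the
#' Otsu-thresholded outline-smoothed image.  Puncta below `min_area_px`
#' are discarded.
#'
#' @param mean_img average-intensity image (matrix), from at least 10
#'   frames.
#' @param tophat_radius_px top-hat disc radius in pixels, 10-20 at the
#'   instrument's native sampling (default 15; scale with pixel size).
#' @param spot_sigma,outline_sigma Voronoi-Otsu Gaussian sigmas (px).
#' @param min_area_px minimum punctum area (default 4 px).
#' @return a [roi_map()] with class `"terminal"` for every label (empty,
#'   with a warning, when nothing is found).
#' @export
segment_terminals <- function(mean_img, tophat_radius_px = 15,
                              spot_sigma = 1.5, outline_sigma = 1,
                              min_area_px = 4) {
  stopifnot(is.matrix(mean_img))
  if (tophat_radius_px < 1) stop("tophat_radius_px must be >= 1")
  th <- white_tophat(mean_img, tophat_radius_px)
  sm_spot <- gauss_blur_2d(th, spot_sigma)
  sm_out <- if (outline_sigma > 0) gauss_blur_2d(th, outline_sigma) else th
  thr <- otsu_threshold(sm_out)
  mask <- sm_out > thr
  lab_img <- matrix(0L, nrow(mean_img), ncol(mean_img))
  if (any(mask)) {
    a3 <- array(sm_spot, dim = c(dim(sm_spot), 1L))
    seeds <- local_maxima_3d(a3, thr)[, 1:2, drop = FALSE]
    pix <- which(mask, arr.ind = TRUE)
    if (nrow(seeds) == 0) seeds <- pix[which.max(sm_spot[mask]), , drop = FALSE]
    dmat <- outer(pix[, 1], seeds[, 1], "-")^2 +
      outer(pix[, 2], seeds[, 2], "-")^2
    terr <- max.col(-dmat, ties.method = "first")
    nlab <- 0L
    for (sd_lab in unique(terr)) {
      v <- pix[terr == sd_lab, , drop = FALSE]
      comp <- label_components_3d(cbind(v, 1L), c(dim(mean_img), 1L))
      for (cid in unique(comp)) {
        vv <- v[comp == cid, , drop = FALSE]
        if (nrow(vv) < min_area_px) next
        nlab <- nlab + 1L
        lab_img[vv] <- nlab
      }
    }
  }
  n <- max(lab_img)
  if (n == 0L) {
    warning("segment_terminals: no puncta found")
    return(structure(list(labels = lab_img,
                          class_of = stats::setNames(character(), character()),
                          identity_of = stats::setNames(character(), character())),
                     class = "roi_map"))
  }
  ca_log("segment_terminals: %d puncta (tophat radius %d px)", n,
         tophat_radius_px)
  roi_map(lab_img,
          class_of = stats::setNames(rep("terminal", n), seq_len(n)),
          identity_of = stats::setNames(sprintf("T_%03d", seq_len(n)),
                                        seq_len(n)))
}

#' Centroids of ROI labels in micrometres
#'
#' @param rois a [roi_map()].
#' @param pixel_size micrometres per pixel.
#' @return data.frame: `label`, `identity`, `x`, `y` (um).
#' @export
roi_centroids <- function(rois, pixel_size) {
  px <- roi_pixels(rois)
  ny <- nrow(rois$labels)
  do.call(rbind, lapply(names(px), function(lb) {
    idx <- px[[lb]]
    yy <- ((idx - 1) %% ny) + 1; xx <- ((idx - 1) %/% ny) + 1
    data.frame(label = as.integer(lb), identity = unname(rois$identity_of[lb]),
               x = (mean(xx) - 1) * pixel_size,
               y = (mean(yy) - 1) * pixel_size)
  }))
}

#' Assign terminals to IHCs by proximity, falling back to correlation
#'
#' A terminal is assigned to its nearest IHC when that IHC is closer than
#' the runner-up by more than `ambiguity_margin_um`; otherwise the terminal
#' is "in between" and the assignment goes to whichever of the two nearest
#' IHCs shows the higher trace correlation.  A tie in both distance and
#' correlation falls to the lower-index IHC and is flagged.
#'
#' @param term_xy data.frame of terminal centroids (`identity`, `x`, `y`,
#'   um), e.g. from [roi_centroids()].
#' @param ihc_xy data.frame of IHC centroids (`identity`, `x`, `y`, um).
#' @param term_traces,ihc_traces dF/F0 matrices (columns named by identity)
#'   for the correlation fallback; pass NULL to force pure proximity.
#' @param ambiguity_margin_um margin below which proximity is inconclusive
#'   (default 3).
#' @return data.frame: `terminal`, `parent`, `method` (`"proximity"` /
#'   `"correlation"`), `distance_um`, `flagged`.
#' @export
assign_terminals <- function(term_xy, ihc_xy, term_traces = NULL,
                             ihc_traces = NULL, ambiguity_margin_um = 3) {
  stopifnot(nrow(ihc_xy) >= 1)
  rows <- lapply(seq_len(nrow(term_xy)), function(i) {
    d <- sqrt((ihc_xy$x - term_xy$x[i])^2 + (ihc_xy$y - term_xy$y[i])^2)
    o <- order(d)
    flagged <- FALSE
    if (length(d) == 1L || d[o[2]] - d[o[1]] > ambiguity_margin_um) {
      parent <- o[1]; method <- "proximity"
    } else if (!is.null(term_traces) && !is.null(ihc_traces) &&
               term_xy$identity[i] %in% colnames(term_traces)) {
      tv <- term_traces[, term_xy$identity[i]]
      r2 <- vapply(o[1:2], function(j)
        stats::cor(tv, ihc_traces[, ihc_xy$identity[j]]), numeric(1))
      r2[is.na(r2)] <- 0
      if (abs(r2[1] - r2[2]) < 1e-12) {
        parent <- min(o[1:2]); flagged <- TRUE
      } else parent <- o[1:2][which.max(r2)]
      method <- "correlation"
    } else {
      parent <- o[1]; method <- "proximity"
      if (length(d) > 1L && d[o[2]] - d[o[1]] <= ambiguity_margin_um)
        flagged <- TRUE
    }
    data.frame(terminal = term_xy$identity[i],
               parent = ihc_xy$identity[parent], method = method,
               distance_um = d[parent], flagged = flagged)
  })
  out <- do.call(rbind, rows)
  ca_log("assign_terminals: %d terminals, %d by correlation, %d flagged",
         nrow(out), sum(out$method == "correlation"), sum(out$flagged))
  out
}

#' Classify terminal side around the IHC row
#'
#' The sign of the radial coordinate `d` relative to the cochlear axis
#' decides the side: beyond `+middle_half_width_um` is modiolar (toward the
#' nerve / GER), beyond the negative band pillar (toward the outer hair
#' cells), and the band in between `middle`.  Flipping the axis orientation
#' swaps modiolar and pillar exactly.
#'
#' @param xy n x 2 matrix or data.frame of terminal centroids (um).
#' @param axis a [cochlear_axis()].
#' @param middle_half_width_um half-width of the middle band (default 2).
#' @return character vector of side labels.
#' @export
classify_side <- function(xy, axis, middle_half_width_um = 2) {
  if (is.data.frame(xy)) xy <- cbind(xy$x, xy$y)
  d <- axis_transform(axis, xy)$d
  ifelse(d > middle_half_width_um, "modiolar",
         ifelse(d < -middle_half_width_um, "pillar", "middle"))
}

# chain-merge sorted peak times with a linkage window; returns cluster ids
chain_clusters <- function(times, window_s) {
  if (!length(times)) return(integer())
  cumsum(c(1L, as.integer(diff(sort(times)) > window_s)))
}

#' Per-IHC terminal activity
#'
#' Averages the dF/F0 traces of all terminals assigned to each IHC into one
#' "IHC" terminal trace, merges the peaks detected in different terminals of
#' the same IHC when they fall within `merge_window_s` of one another
#' (single-linkage chaining), and reports the merged-peak frequency.
#'
#' @param assignments an [assign_terminals()] table.
#' @param term_traces dF/F0 matrix, columns named by terminal identity.
#' @param term_transients detected terminal transients
#'   ([detect_transients()] table with terminal identities).
#' @param duration_s recording duration, seconds.
#' @param merge_window_s peak-merging window (default 1).
#' @return list: `avg_traces` (matrix, one column per IHC),
#'   `merged_peaks` (data.frame: `parent`, `time`, `n_terminals`),
#'   `frequency` (data.frame: `parent`, `n_peaks`, `freq_per_min`).
#' @export
per_ihc_terminal_activity <- function(assignments, term_traces,
                                      term_transients, duration_s,
                                      merge_window_s = 1) {
  parents <- unique(assignments$parent)
  avg <- vapply(parents, function(p) {
    members <- assignments$terminal[assignments$parent == p]
    members <- intersect(members, colnames(term_traces))
    rowMeans(term_traces[, members, drop = FALSE])
  }, numeric(nrow(term_traces)))
  colnames(avg) <- parents
  peaks <- list(); freq <- list()
  for (p in parents) {
    members <- assignments$terminal[assignments$parent == p]
    tt <- term_transients[term_transients$identity %in% members, ]
    tt <- tt[order(tt$peak_time), ]
    cl <- chain_clusters(tt$peak_time, merge_window_s)
    if (length(cl)) {
      mp <- data.frame(parent = p,
                       time = as.numeric(tapply(tt$peak_time, cl, mean)),
                       n_terminals = as.integer(
                         tapply(tt$identity, cl, function(v) length(unique(v)))))
      peaks[[p]] <- mp
      freq[[p]] <- data.frame(parent = p, n_peaks = nrow(mp),
                              freq_per_min = nrow(mp) / (duration_s / 60))
    } else {
      freq[[p]] <- data.frame(parent = p, n_peaks = 0L, freq_per_min = 0)
    }
  }
  list(avg_traces = avg,
       merged_peaks = if (length(peaks)) do.call(rbind, peaks) else
         data.frame(parent = character(), time = numeric(),
                    n_terminals = integer()),
       frequency = do.call(rbind, freq))
}

#' Terminal recruitment during single vs multiple IHC events
#'
#' For every IHC event and every participating IHC with visible terminals,
#' the fraction of that IHC's terminals showing a transient within the
#' event span (padded by `merge_window_s`) is computed, in total and split
#' by side.  Fractions are then summarised by event class, along with the
#' fraction of events that recruited the entire visible pool.  Middle-band
#' terminals count toward the totals but not toward either side.
#'
#' @param events `events` table from [group_events()].
#' @param term_transients detected terminal transients table.
#' @param assignments [assign_terminals()] table with a `side` column (add
#'   via [classify_side()]).
#' @param merge_window_s window padding (default 1).
#' @return list: `per_event` (data.frame: `event_id`, `class`, `parent`,
#'   `frac_total`, `frac_pillar`, `frac_modiolar`, `all_recruited`) and
#'   `by_class` (means and full-pool fractions per class).
#' @export
recruitment_analysis <- function(events, term_transients, assignments,
                                 merge_window_s = 1) {
  stopifnot("side" %in% names(assignments))
  rows <- list()
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    t0 <- ev$t_start - merge_window_s; t1 <- ev$t_end + merge_window_s
    for (ihc in unlist(ev$cells)) {
      terms <- assignments[assignments$parent == ihc, ]
      if (!nrow(terms)) { ca_log("recruitment: IHC %s has no terminals", ihc); next }
      active <- vapply(terms$terminal, function(tm)
        any(term_transients$identity == tm &
              term_transients$peak_time >= t0 &
              term_transients$peak_time <= t1), logical(1))
      fr <- function(side) {
        sel <- terms$side == side
        if (!any(sel)) NA_real_ else mean(active[sel])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev$event_id, class = ev$class, parent = ihc,
        n_terminals = nrow(terms),
        frac_total = mean(active),
        frac_pillar = fr("pillar"), frac_modiolar = fr("modiolar"),
        all_recruited = all(active))
    }
  }
  per_event <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(), class = character(),
               parent = character(), n_terminals = integer(),
               frac_total = numeric(), frac_pillar = numeric(),
               frac_modiolar = numeric(), all_recruited = logical())
  by_class <- do.call(rbind, lapply(c("single", "pair", "multiple"),
                                    function(cl) {
    pe <- per_event[per_event$class == cl, ]
    data.frame(class = cl, n = nrow(pe),
               frac_total = mean(pe$frac_total),
               frac_pillar = mean(pe$frac_pillar, na.rm = TRUE),
               frac_modiolar = mean(pe$frac_modiolar, na.rm = TRUE),
               frac_all_recruited = mean(pe$all_recruited))
  }))
  list(per_event = per_event, by_class = by_class)
}

#' Pillar vs modiolar paired statistics
#'
#' Per-IHC means of a terminal-level quantity (frequency or amplitude) on
#' the pillar and modiolar sides, compared with a paired Wilcoxon
#' signed-rank test over the IHCs possessing terminals on both sides.
#' Middle-band terminals are excluded from the contrast.  With fewer than 6
#' paired IHCs no p-value is reported.
#'
#' @param values data.frame with columns `terminal` and `value` (e.g.
#'   per-terminal frequency in events/min).
#' @param assignments [assign_terminals()] table with `side`.
#' @return list: `paired` (data.frame: `parent`, `pillar`, `modiolar`,
#'   `difference`), `n_pairs`, `median_difference`, `p_value` (NA when
#'   insufficient), `direction`.
#' @export
side_statistics <- function(values, assignments) {
  stopifnot("side" %in% names(assignments))
  df <- merge(assignments, values, by = "terminal")
  df <- df[df$side %in% c("pillar", "modiolar"), ]
  if (!nrow(df)) {
    ca_log("side_statistics: no terminals on the pillar/modiolar sides")
    return(list(paired = data.frame(), n_pairs = 0L,
                median_difference = NA_real_, p_value = NA_real_,
                direction = "none"))
  }
  agg <- stats::aggregate(value ~ parent + side, data = df, FUN = mean)
  wide <- stats::reshape(agg, idvar = "parent", timevar = "side",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (!all(c("pillar", "modiolar") %in% names(wide)))
    wide[setdiff(c("pillar", "modiolar"), names(wide))] <- NA_real_
  paired <- wide[!is.na(wide$pillar) & !is.na(wide$modiolar), ]
  paired$difference <- paired$pillar - paired$modiolar
  n <- nrow(paired)
  p <- NA_real_
  if (n >= 6 && any(paired$difference != 0))
    p <- stats::wilcox.test(paired$pillar, paired$modiolar,
                            paired = TRUE, exact = FALSE)$p.value
  else if (n < 6) ca_log("side_statistics: insufficient n (%d paired IHCs)", n)
  med <- if (n) stats::median(paired$difference) else NA_real_
  list(paired = paired, n_pairs = n, median_difference = med, p_value = p,
       direction = if (!is.na(med) && med > 0) "pillar > modiolar"
                   else if (!is.na(med) && med < 0) "modiolar > pillar"
                   else "none")
}
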