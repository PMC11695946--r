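#' Cochlear axis: the IHC-row polyline and its coordinate frame
#'
#' The polyline drawn along the inner-hair-cell row defines the natural
#' coordinate frame of the epithelium: `s` is the longitudinal arc-length
#' coordinate (micrometres along the row) and `d` the signed radial distance
#' from the row, positive toward the modiolar side where the greater
#' epithelial ridge (GER) lies and negative toward the pillar side.
#'
#' @param vertices n x 2 matrix of `(x, y)` vertex positions in micrometres,
#'   at least two distinct consecutive vertices.
#' @param modiolar_sign `+1` if the modiolar side is to the left of the
#'   direction of travel along the polyline (positive cross product),
#'   `-1` otherwise.
#' @return an object of class `cochlear_axis`.
#' @export
cochlear_axis <- function(vertices, modiolar_sign = 1) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("axis needs >= 2 (x, y) vertices")
  seg <- diff(vertices)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("consecutive axis vertices must be distinct")
  if (!modiolar_sign %in% c(-1, 1)) stop("modiolar_sign must be +1 or -1")
  structure(list(vertices = vertices, seg = seg, seg_len = len,
                 cum_len = c(0, cumsum(len)),
                 modiolar_sign = modiolar_sign),
            class = "cochlear_axis")
}

#' Map image coordinates to axis coordinates
#'
#' Projects points onto the axis polyline.
#'
#' @param axis a [cochlear_axis()].
#' @param xy n x 2 matrix of `(x, y)` positions (micrometres).
#' @return data.frame with columns `s` (arc length, um) and `d` (signed
#'   radial distance, um; positive modiolar).
#' @export
axis_transform <- function(axis, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- nrow(xy)
  best_d2 <- rep(Inf, n); best_s <- best_d <- numeric(n)
  for (i in seq_len(nrow(axis$seg))) {
    p0 <- axis$vertices[i, ]; v <- axis$seg[i, ]; L <- axis$seg_len[i]
    qx <- xy[, 1] - p0[1]; qy <- xy[, 2] - p0[2]
    tt <- pmin(pmax((qx * v[1] + qy * v[2]) / L^2, 0), 1)
    px <- tt * v[1]; py <- tt * v[2]
    d2 <- (qx - px)^2 + (qy - py)^2
    cross <- (v[1] * qy - v[2] * qx) / L
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- axis$cum_len[i] + tt[upd] * L
    best_d[upd] <- axis$modiolar_sign * sign(cross[upd]) * sqrt(d2[upd])
  }
  data.frame(s = best_s, d = best_d)
}

#' Map axis coordinates back to image coordinates
#'
#' Inverse of [axis_transform()] for points within the arc-length range.
#'
#' @inheritParams axis_transform
#' @param s,d axis coordinates (micrometres), recycled to common length.
#' @return n x 2 matrix of `(x, y)` positions.
#' @export
axis_point <- function(axis, s, d = 0) {
  k <- max(length(s), length(d))
  s <- rep_len(s, k); d <- rep_len(d, k)
  s <- pmin(pmax(s, 0), axis$cum_len[length(axis$cum_len)])
  out <- matrix(0, k, 2)
  for (j in seq_len(k)) {
    i <- max(1L, findInterval(s[j], axis$cum_len, rightmost.closed = TRUE))
    i <- min(i, nrow(axis$seg))
    tt <- (s[j] - axis$cum_len[i]) / axis$seg_len[i]
    u <- axis$seg[i, ] / axis$seg_len[i]
    normal <- axis$modiolar_sign * c(-u[2], u[1])
    out[j, ] <- axis$vertices[i, ] + tt * axis$seg[i, ] + d[j] * normal
  }
  out
}

axis_length <- function(axis) axis$cum_len[length(axis$cum_len)]

#' Flip the stated modiolar orientation of an axis
#' @param axis a [cochlear_axis()].
#' @export
flip_axis <- function(axis) {
  axis$modiolar_sign <- -axis$modiolar_sign
  axis
}

#' Generate a synthetic epithelium geometry
#'
#' Lays out a curved row of inner hair cells (IHCs) flanked on the modiolar
#' side by a band of GER supporting cells and, around each IHC, a handful of
#' punctate SGN afferent terminals.  The terminal count per IHC follows a
#' normal distribution clipped to `[1, 10]`; terminal side labels (modiolar /
#' pillar / middle) follow from the signed radial coordinate of each
#' punctum.
#'
#' @param n_ihc number of IHCs (>= 2).
#' @param spacing IHC centre-to-centre spacing, micrometres.
#' @param arc_curvature curvature of the row (1/um); 0 gives a straight row.
#' @param terminal_mean,terminal_sd mean and SD of the per-IHC terminal
#'   count before clipping.
#' @param terminal_clip length-2 clipping range for the terminal count.
#' @param terminal_radius length-2 range of distances (um) of terminal
#'   puncta from their parent IHC centroid.
#' @param middle_half_width_um half-width of the `middle` band used to label
#'   terminal sides in the ground truth.
#' @param ger_band length-2 range of radial distances (um) covered by the
#'   GER supporting-cell field on the modiolar side.
#' @param seed integer seed; the geometry is deterministic given
#'   `(arguments, seed)`.
#' @return an object of class `epithelium_geometry` with elements
#'   `ihc` (data.frame: id, identity, x, y, s, order), `axis`
#'   (a [cochlear_axis()]), `sc` (supporting-cell centroids), `terminals`
#'   (data.frame: id, identity, parent, x, y, d, side) and `ger_band`.
#' @export
generate_geometry <- function(n_ihc = 20, spacing = 9, arc_curvature = 1 / 300,
                              terminal_mean = 4, terminal_sd = 2,
                              terminal_clip = c(1, 10),
                              terminal_radius = c(2.5, 6),
                              middle_half_width_um = 2,
                              ger_band = c(5, 30),
                              seed = 1) {
  if (n_ihc < 2) stop("n_ihc must be >= 2")
  if (spacing <= 0) stop("spacing must be positive")
  with_seed(seed, {
    # IHC centroids along a circular arc; the arc centre sits on the
    # modiolar (+y) side, as the GER does in the apical coil
    if (arc_curvature == 0) {
      xs <- (seq_len(n_ihc) - 1) * spacing
      ys <- rep(0, n_ihc)
    } else {
      R <- 1 / arc_curvature
      th <- (seq_len(n_ihc) - (n_ihc + 1) / 2) * spacing / R
      xs <- R * sin(th)
      ys <- R - R * cos(th) + 0 # sagitta: row bows away from the arc centre
      ys <- -ys                 # keep the modiolar side at +y
      xs <- xs - min(xs)
      ys <- ys - min(ys)
    }
    axis <- cochlear_axis(cbind(xs, ys), modiolar_sign = 1)
    ihc <- data.frame(id = seq_len(n_ihc),
                      identity = sprintf("IHC_%02d", seq_len(n_ihc)),
                      x = xs, y = ys,
                      s = axis$cum_len[seq_len(n_ihc)],
                      order = seq_len(n_ihc))
    # supporting cells: jittered grid filling the GER band
    L <- axis_length(axis)
    grid <- expand.grid(s = seq(4, L - 4, by = 8),
                        d = seq(ger_band[1] + 3, ger_band[2] - 2, by = 8))
    jit_s <- stats::runif(nrow(grid), -1.5, 1.5)
    jit_d <- stats::runif(nrow(grid), -1.5, 1.5)
    sc_xy <- axis_point(axis, grid$s + jit_s, grid$d + jit_d)
    sc <- data.frame(id = seq_len(nrow(grid)),
                     identity = sprintf("SC_%03d", seq_len(nrow(grid))),
                     x = sc_xy[, 1], y = sc_xy[, 2])
    # afferent terminals: clipped-normal count, puncta ringed around the IHC
    n_term <- pmin(pmax(round(stats::rnorm(n_ihc, terminal_mean, terminal_sd)),
                        terminal_clip[1]), terminal_clip[2])
    tl <- vector("list", n_ihc)
    for (i in seq_len(n_ihc)) {
      ang <- stats::runif(n_term[i], 0, 2 * pi)
      rad <- stats::runif(n_term[i], terminal_radius[1], terminal_radius[2])
      tx <- ihc$x[i] + rad * cos(ang)
      ty <- ihc$y[i] + rad * sin(ang)
      tl[[i]] <- data.frame(parent = i, x = tx, y = ty)
    }
    term <- do.call(rbind, tl)
    td <- axis_transform(axis, cbind(term$x, term$y))$d
    side <- ifelse(td > middle_half_width_um, "modiolar",
                   ifelse(td < -middle_half_width_um, "pillar", "middle"))
    terminals <- data.frame(id = seq_len(nrow(term)),
                            identity = sprintf("T_%03d", seq_len(nrow(term))),
                            parent = term$parent,
                            parent_identity = ihc$identity[term$parent],
                            x = term$x, y = term$y, d = td, side = side)
    structure(list(ihc = ihc, axis = axis, sc = sc, terminals = terminals,
                   ger_band = ger_band, spacing = spacing, seed = seed),
              class = "epithelium_geometry")
  })
}

#' @export
print.epithelium_geometry <- function(x, ...) {
  cat(sprintf(
    "epithelium_geometry: %d IHCs (%.0f um row), %d SCs, %d terminals\n",
    nrow(x$ihc), axis_length(x$axis), nrow(x$sc), nrow(x$terminals)))
  invisible(x)
}
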