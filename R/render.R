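# Rendering of GCaMP-like fluorescence from an activity schedule.

#' Indicator impulse response
#'
#' Difference-of-exponentials kernel `exp(-t/tau_decay) - exp(-t/tau_rise)`,
#' normalised to unit peak.  The decay constant is parameterised through the
#' observable full duration at half maximum (FDHM) of a rendered single
#' transient rather than through the decay itself, via
#' [tau_decay_for_fdhm()].
#'
#' @param t times in seconds (kernel is zero for `t < 0`).
#' @param tau_rise,tau_decay time constants in seconds.
#' @return kernel values, unit peak.
#' @export
ca_kernel <- function(t, tau_rise = 0.05, tau_decay = 1) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- ifelse(t < 0, 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak)
  out
}

#' FDHM of the indicator kernel
#' @inheritParams ca_kernel
#' @return full duration at half maximum in seconds.
#' @export
kernel_fdhm <- function(tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  f <- function(t) ca_kernel(t, tau_rise, tau_decay) - 0.5
  left <- stats::uniroot(f, c(1e-9, tp), tol = 1e-10)$root
  right <- stats::uniroot(f, c(tp, tp + 30 * tau_decay), tol = 1e-10)$root
  right - left
}

#' Decay constant producing a target kernel FDHM
#' @param fdhm target full duration at half maximum, seconds.
#' @param tau_rise rise time constant, seconds.
#' @export
tau_decay_for_fdhm <- function(fdhm, tau_rise = 0.05) {
  stopifnot(fdhm > 2 * tau_rise)
  stats::uniroot(function(td) kernel_fdhm(tau_rise, td) - fdhm,
                 c(tau_rise * 1.01, 50 * fdhm), tol = 1e-9)$root
}

# superpose kernel transients on a regular time grid
superpose_kernel <- function(times, amps, t_grid, tau_rise, tau_decay) {
  y <- numeric(length(t_grid))
  if (!length(times)) return(y)
  dt <- t_grid[2] - t_grid[1]
  support <- ceiling((5 * tau_decay) / dt)
  for (j in seq_along(times)) {
    k0 <- findInterval(times[j], t_grid)
    idx <- max(1L, k0):min(length(t_grid), k0 + support)
    y[idx] <- y[idx] + amps[j] * ca_kernel(t_grid[idx] - times[j],
                                           tau_rise, tau_decay)
  }
  y
}

#' Render noise-carrying dF/F0 traces directly from a schedule
#'
#' The cheap, trace-level renderer: each scheduled transient contributes the
#' indicator kernel scaled by its amplitude to its cell's dF/F0 trace, and
#' i.i.d. Gaussian noise of SD `noise_sd` is added.  Frame-quality artifacts
#' and drift are image-level phenomena and are not represented here.
#'
#' @param geometry an [generate_geometry()] result.
#' @param schedule an [simulate_schedule()] result.
#' @param frame_rate frames per second (default from the schedule params).
#' @param noise_sd Gaussian noise SD in dF/F0 units; 0 for noise-free.
#' @param seed seed for the noise draw.
#' @return list with `time` (seconds), `ihc` (frames x cells matrix of
#'   dF/F0), `terminals` (frames x terminals matrix) and `frame_rate`.
#' @export
render_traces <- function(geometry, schedule, frame_rate = NULL,
                          noise_sd = NULL, seed = 1) {
  p <- schedule$params
  frame_rate <- frame_rate %||% p$frame_rate
  noise_sd <- noise_sd %||% p$trace_noise_sd
  tau_d <- tau_decay_for_fdhm(p$fdhm_s, p$tau_rise_s)
  t_grid <- seq(0, schedule$duration_s - 1 / frame_rate, by = 1 / frame_rate)
  n_ihc <- nrow(geometry$ihc)
  ihc <- matrix(0, length(t_grid), n_ihc)
  for (i in seq_len(n_ihc)) {
    sel <- schedule$transients$cell == i
    ihc[, i] <- superpose_kernel(schedule$transients$time[sel],
                                 schedule$transients$amplitude[sel],
                                 t_grid, p$tau_rise_s, tau_d)
  }
  n_term <- nrow(geometry$terminals)
  term <- matrix(0, length(t_grid), n_term)
  tt <- schedule$terminal_transients
  for (i in seq_len(n_term)) {
    sel <- tt$terminal == i
    term[, i] <- superpose_kernel(tt$time[sel], tt$amplitude[sel],
                                  t_grid, p$tau_rise_s, tau_d)
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      ihc <- ihc + stats::rnorm(length(ihc), 0, noise_sd)
      term <- term + stats::rnorm(length(term), 0, noise_sd)
    })
  }
  colnames(ihc) <- geometry$ihc$identity
  if (n_term) colnames(term) <- geometry$terminals$identity
  list(time = t_grid, ihc = ihc, terminals = term, frame_rate = frame_rate)
}

# bilinear translation of a matrix by (dy, dx) pixels, edge-clamped
translate_bilinear <- function(m, dy, dx) {
  if (dy == 0 && dx == 0) return(m)
  ny <- nrow(m); nx <- ncol(m)
  ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
  y0 <- pmin(pmax(floor(ys), 1L), ny); y1 <- pmin(y0 + 1L, ny)
  x0 <- pmin(pmax(floor(xs), 1L), nx); x1 <- pmin(x0 + 1L, nx)
  fy <- pmin(pmax(ys - floor(ys), 0), 1); fx <- pmin(pmax(xs - floor(xs), 0), 1)
  m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y1, x0, drop = FALSE]
  m01 <- m[y0, x1, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, ny, nx); wx <- matrix(fx, ny, nx, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m10 * wy * (1 - wx) +
    m01 * (1 - wy) * wx + m11 * wy * wx
}

# wave footprint factor (0..1) at scaled elliptical radius u, plateau
# inside u <= 1 with a Gaussian edge of width edge_um
wave_edge_factor <- function(u, a_t, edge_um = 2) {
  f <- numeric(length(u))
  f[u <= 1] <- 1
  out <- u > 1
  f[out] <- exp(-((u[out] - 1) * a_t / edge_um)^2 / 2)
  f
}

# piecewise-linear equivalent-radius fraction of a wave at time since onset
wave_rho <- function(dt, t_exp, t_plateau, t_con) {
  rho <- numeric(length(dt))
  grow <- dt >= 0 & dt < t_exp
  rho[grow] <- dt[grow] / t_exp
  flat <- dt >= t_exp & dt < t_exp + t_plateau
  rho[flat] <- 1
  con <- dt >= t_exp + t_plateau & dt < t_exp + t_plateau + t_con
  rho[con] <- 1 - (dt[con] - t_exp - t_plateau) / t_con
  rho
}

#' Render a full synthetic movie with its ground truth
#'
#' Renders the schedule as a GCaMP-like timelapse: a static baseline image
#' of IHCs, GER supporting cells and terminal puncta; transient kernels on
#' the IHC and terminal footprints; waves as expanding-then-contracting
#' elliptical plateaus (Gaussian edge) confined to the modiolar side;
#' breathing bouts as multiplicative whole-frame dimming (plus optional
#' shift); smooth sinusoidal lateral drift; and, last, Poisson shot noise on
#' photon counts.  Identical `(geometry, schedule, params, seed)` give a
#' bit-identical movie.
#'
#' @inheritParams render_traces
#' @param shot_noise apply Poisson shot noise (`FALSE` gives the noise-free
#'   expectation movie).
#' @param drift apply the schedule's drift path.
#' @param express which cell classes express the indicator, mirroring the
#'   mouse lines used for each experiment type: `c("ihc", "sc")` emulates a
#'   supporting-cell line (waves + hair cells), `"ihc"` a hair-cell line,
#'   `"terminal"` an afferent line.  Non-expressing classes are neither
#'   bright nor active.  Default: all three at once (an integrated world,
#'   convenient for demonstrations).
#' @param seed seed for the shot-noise draw.
#' @return an object of class `ca_simulation`: list with the rendered
#'   `stack` ([timelapse_stack()]), `ihc_rois` and `terminal_rois`
#'   ([roi_map()]s), `axis` (in image coordinates), `geometry` (shifted into
#'   image coordinates), `schedule`, and `artifact_frames` (half-open frame
#'   intervals actually dimmed).
#' @export
render_movie <- function(geometry, schedule, shot_noise = TRUE, drift = TRUE,
                         express = c("ihc", "sc", "terminal"), seed = 1) {
  express <- match.arg(express, several.ok = TRUE)
  p <- schedule$params
  fr <- p$frame_rate
  px <- p$pixel_size_um
  tau_d <- tau_decay_for_fdhm(p$fdhm_s, p$tau_rise_s)
  if (p$fdhm_s < 2 / fr)
    stop("kernel FDHM below two frame periods: transients would be unresolvable")

  ## field of view (micrometre frame shifted to image coordinates),
  ## covering the labelled structures of this line
  margin <- 8
  all_x <- geometry$ihc$x; all_y <- geometry$ihc$y
  if ("sc" %in% express) {
    all_x <- c(all_x, geometry$sc$x); all_y <- c(all_y, geometry$sc$y)
  }
  if ("terminal" %in% express) {
    all_x <- c(all_x, geometry$terminals$x)
    all_y <- c(all_y, geometry$terminals$y)
  }
  x0 <- min(all_x) - margin; y0 <- min(all_y) - margin
  geom <- geometry
  geom$ihc$x <- geom$ihc$x - x0; geom$ihc$y <- geom$ihc$y - y0
  geom$sc$x <- geom$sc$x - x0; geom$sc$y <- geom$sc$y - y0
  geom$terminals$x <- geom$terminals$x - x0
  geom$terminals$y <- geom$terminals$y - y0
  verts <- geometry$axis$vertices
  geom$axis <- cochlear_axis(cbind(verts[, 1] - x0, verts[, 2] - y0),
                             geometry$axis$modiolar_sign)
  nx <- ceiling((max(all_x) - x0 + margin) / px)
  ny <- ceiling((max(all_y) - y0 + margin) / px)
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  pix_xy <- cbind(rep(xs, each = ny), rep(ys, nx))
  sd_pix <- axis_transform(geom$axis, pix_xy)

  ## baseline image and label masks
  B <- matrix(p$baseline_bg, ny, nx)
  ihc_lab <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(geom$ihc))) {
    r2 <- (pix_xy[, 1] - geom$ihc$x[i])^2 + (pix_xy[, 2] - geom$ihc$y[i])^2
    m <- r2 <= p$cell_radius_um^2
    if ("ihc" %in% express) B[m] <- p$baseline_ihc
    ihc_lab[m] <- i
  }
  if ("sc" %in% express) {
    for (i in seq_len(nrow(geom$sc))) {
      r2 <- (pix_xy[, 1] - geom$sc$x[i])^2 + (pix_xy[, 2] - geom$sc$y[i])^2
      m <- r2 <= p$cell_radius_um^2 & ihc_lab == 0L
      B[m] <- pmax(B[m], p$baseline_sc)
    }
  }
  term_lab <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(geom$terminals))) {
    r2 <- (pix_xy[, 1] - geom$terminals$x[i])^2 +
      (pix_xy[, 2] - geom$terminals$y[i])^2
    if ("terminal" %in% express) {
      bump <- (p$baseline_terminal - p$baseline_bg) *
        exp(-r2 / (2 * p$terminal_sigma_um^2))
      B <- B + matrix(bump, ny, nx)
    }
    # terminal ROIs never include hair-cell body pixels, so the terminal
    # traces cannot inherit the presynaptic signal
    term_lab[r2 <= (1.5 * p$terminal_sigma_um)^2 & ihc_lab == 0L] <- i
  }

  ## time courses
  nt <- floor(schedule$duration_s * fr)
  t_grid <- (seq_len(nt) - 1) / fr
  clean <- render_traces(geom, schedule, frame_rate = fr, noise_sd = 0)
  M <- matrix(B, ny * nx, nt) # expectation movie, pixels x frames

  if ("ihc" %in% express) {
    for (i in seq_len(nrow(geom$ihc))) {
      pixi <- which(ihc_lab == i)
      if (length(pixi))
        M[pixi, ] <- M[pixi, ] * rep(1 + clean$ihc[seq_len(nt), i],
                                     each = length(pixi))
    }
  }
  if ("terminal" %in% express) {
    for (i in seq_len(nrow(geom$terminals))) {
      pixi <- which(term_lab == i)
      if (length(pixi))
        M[pixi, ] <- M[pixi, ] * rep(1 + clean$terminals[seq_len(nt), i],
                                     each = length(pixi))
    }
  }
  ## waves on the modiolar side (supporting-cell fluorophore only: never on
  ## hair-cell bodies or terminal puncta, which belong to other lines)
  ger_pix <- which(sd_pix$d >= 2 & ihc_lab == 0L & term_lab == 0L)
  if (!"sc" %in% express) ger_pix <- integer()
  for (w in seq_len(nrow(schedule$waves))) {
    if (!length(ger_pix)) break
    wv <- schedule$waves[w, ]
    t_tot <- wv$t_exp + wv$t_plateau + wv$t_con
    k_on <- max(1L, floor(wv$t_start * fr) + 1L)
    k_off <- min(nt, ceiling((wv$t_start + t_tot) * fr) + 1L)
    if (k_on > nt || k_off < 1L) next
    ds <- sd_pix$s[ger_pix] - wv$s0
    dd <- sd_pix$d[ger_pix] - wv$d0
    for (k in k_on:k_off) {
      rho <- wave_rho(t_grid[k] - wv$t_start, wv$t_exp, wv$t_plateau, wv$t_con)
      if (rho <= 0) next
      a_t <- wv$a_long * rho; b_t <- wv$b_rad * rho
      u <- sqrt((ds / a_t)^2 + (dd / b_t)^2)
      near <- which(u < 1 + 6 / a_t) # plateau plus edge support
      if (!length(near)) next
      f <- wave_edge_factor(u[near], a_t)
      idx <- ger_pix[near]
      M[idx, k] <- M[idx, k] * (1 + wv$amp * f)
    }
  }

  ## drift, artifacts, shot noise
  arr <- array(M, dim = c(ny, nx, nt))
  rm(M)
  art <- schedule$artifacts
  art_frames <- interval_matrix(NULL)
  if (nrow(art)) {
    a0 <- floor(art$start_s * fr) + 1L
    a1 <- pmin(nt + 1L, ceiling((art$start_s + art$len_s) * fr) + 1L)
    keep <- a0 <= nt & a1 > a0
    art_frames <- merge_intervals(interval_matrix(cbind(a0[keep], a1[keep])))
  }
  dr <- schedule$drift
  for (k in seq_len(nt)) {
    dyx <- c(0, 0)
    if (drift && dr$amp_px > 0) {
      s <- dr$amp_px * sin(2 * pi * t_grid[k] / dr$period_s + dr$phase)
      dyx <- s * c(sin(dr$angle), cos(dr$angle))
    }
    dim_f <- 1
    if (nrow(art)) {
      hit <- which(art$start_s <= t_grid[k] & t_grid[k] < art$start_s + art$len_s)
      if (length(hit)) {
        dim_f <- prod(1 - art$depth[hit])
        dyx <- dyx + sum(art$shift_px[hit]) * c(sin(dr$angle), cos(dr$angle))
      }
    }
    fr_img <- arr[, , k]
    if (any(dyx != 0)) fr_img <- translate_bilinear(fr_img, dyx[1], dyx[2])
    arr[, , k] <- fr_img * dim_f
  }
  if (shot_noise) {
    with_seed(seed, {
      # frame blocks bound the temporary allocations of the Poisson draw
      block <- max(1L, as.integer(2e7 %/% (ny * nx)))
      for (a in seq(1L, nt, by = block)) {
        b <- min(a + block - 1L, nt)
        arr[, , a:b] <- stats::rpois(length(arr[, , a:b]),
                                     arr[, , a:b] * p$photon_gain) /
          p$photon_gain
      }
    })
  }

  stack <- timelapse_stack(arr, frame_rate = fr, pixel_size = px,
                           recording_id = sprintf("sim_seed%d", schedule$seed))
  ihc_rois <- roi_map(ihc_lab,
                      class_of = stats::setNames(rep("IHC", nrow(geom$ihc)),
                                                 seq_len(nrow(geom$ihc))),
                      identity_of = stats::setNames(geom$ihc$identity,
                                                    seq_len(nrow(geom$ihc))))
  term_ids <- sort(unique(term_lab[term_lab > 0]))
  terminal_rois <- roi_map(term_lab,
                           class_of = stats::setNames(
                             rep("terminal", length(term_ids)), term_ids),
                           identity_of = stats::setNames(
                             geom$terminals$identity[term_ids], term_ids))
  ca_log("render_movie: %d x %d px, %d frames, %d waves, %d artifact bouts",
         ny, nx, nt, nrow(schedule$waves), nrow(art))
  structure(list(stack = stack, ihc_rois = ihc_rois,
                 terminal_rois = terminal_rois, axis = geom$axis,
                 geometry = geom, schedule = schedule,
                 artifact_frames = art_frames),
            class = "ca_simulation")
}

#' Write the ground-truth sidecar of a simulation as JSON
#'
#' One human-diffable JSON file listing every hidden truth of the rendered
#' movie: IHC/terminal geometry, transient times and amplitudes, wave
#' records, coordinated-event cohorts and skipped cells, terminal release
#' events, artifact frame intervals and the generator parameters.
#'
#' @param sim a [render_movie()] result.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(sim, path) {
  truth <- list(
    seed = sim$schedule$seed,
    duration_s = sim$schedule$duration_s,
    ihc = sim$geometry$ihc,
    terminals = sim$geometry$terminals,
    axis_vertices = unname(sim$geometry$axis$vertices),
    transients = sim$schedule$transients,
    waves = sim$schedule$waves,
    events = sim$schedule$events,
    skipped = sim$schedule$skipped,
    terminal_transients = sim$schedule$terminal_transients,
    artifacts = sim$schedule$artifacts,
    artifact_frames = sim$artifact_frames,
    drift = sim$schedule$drift,
    params = sim$schedule$params)
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
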