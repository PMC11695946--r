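# Shared fixtures: all synthetic, built in code at test time.

# wrap a dF/F0 matrix (frames x cells) as a trace_set
mk_trace_set <- function(m, frame_rate, recording_id = "rec1") {
  as_trace_set(m, frame_rate, recording_id)
}

# independent oracle for event grouping: exhaustive transitive closure on
# the pairwise |dt| <= window relation, then exhaustive positional gap
# splitting
brute_force_events <- function(times, cells, positions, window_s, gap_limit) {
  n <- length(times)
  if (n == 0) return(list())
  adj <- abs(outer(times, times, "-")) <= window_s
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- list()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    pos <- positions[cells[idx]]
    upos <- sort(unique(pos))
    grp <- cumsum(c(1, diff(upos) - 1 > gap_limit))
    for (g in unique(grp)) {
      members <- idx[pos %in% upos[grp == g]]
      out[[length(out) + 1L]] <- sort(members)
    }
  }
  out[order(vapply(out, min, numeric(1)))]
}

# canonical form of a grouping result for comparison with the oracle
grouping_partition <- function(grouped) {
  ev <- split(seq_len(nrow(grouped$transients)), grouped$transients$event_id)
  ev <- lapply(ev, sort)
  unname(ev[order(vapply(ev, min, numeric(1)))])
}

# a tiny noise-free stack with a single bright moving square, for IO and
# preprocessing tests
mk_plain_stack <- function(nt = 12, ny = 24, nx = 32, frame_rate = 10,
                           pixel_size = 1, value = 100) {
  arr <- array(10, dim = c(ny, nx, nt))
  arr[9:14, 13:18, ] <- value
  timelapse_stack(arr, frame_rate, pixel_size)
}

# render a bare disc/ellipse wave on a flat field, no cells, no noise:
# a growing-then-shrinking plateau whose truth is known analytically
mk_wave_stack <- function(ny = 60, nx = 120, frame_rate = 10, pixel_size = 1,
                          cx = 60, cy = 30, a = 20, b = 20,
                          v_exp = 22, v_con = 15, t_plateau = 0,
                          t_onset = 3, baseline = 20, amp = 60,
                          duration = 12) {
  nt <- duration * frame_rate
  arr <- array(baseline, dim = c(ny, nx, nt))
  r_eq <- sqrt(a * b)
  t_exp <- r_eq / v_exp; t_con <- r_eq / v_con
  yy <- matrix(seq_len(ny) - 1, ny, nx) * pixel_size
  xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE) * pixel_size
  for (k in seq_len(nt)) {
    t <- (k - 1) / frame_rate - t_onset
    rho <- cochleaCa:::wave_rho(t, t_exp, t_plateau, t_con)
    if (rho <= 0) next
    u <- sqrt(((xx - cx) / (a * rho))^2 + ((yy - cy) / (b * rho))^2)
    arr[, , k] <- baseline + amp * (u <= 1)
  }
  timelapse_stack(arr, frame_rate, pixel_size)
}

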