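# Activity schedules and rendering: determinism, conservation, kinetics.

test_that("empty and degenerate schedules behave as specified", {
  g <- generate_geometry(n_ihc = 6, seed = 1)
  p <- synth_defaults()
  p$lambda_ind_per_min <- 0; p$wave_rate_per_min <- 0
  s <- simulate_schedule(g, p, duration_s = 120, seed = 1)
  expect_equal(nrow(s$transients), 0)
  expect_equal(nrow(s$waves), 0)
  expect_equal(nrow(s$events), 0)
  p2 <- synth_defaults(); p2$p_reach <- 0; p2$wave_rate_per_min <- 3
  s2 <- simulate_schedule(g, p2, duration_s = 300, seed = 2)
  expect_gt(nrow(s2$waves), 0)
  expect_equal(nrow(s2$events), 0)
  p3 <- synth_defaults(); p3$p_skip <- 1.5
  expect_error(simulate_schedule(g, p3, 60, 1), "p_skip")
  expect_error(simulate_schedule(g, synth_defaults(), -5, 1), "duration")
})

test_that("independent transient counts follow the Poisson oracle", {
  g <- generate_geometry(n_ihc = 20, seed = 1)
  p <- synth_defaults()
  p$lambda_ind_per_min <- 1; p$wave_rate_per_min <- 0
  total <- 0
  for (s in 1:3) {
    sc <- simulate_schedule(g, p, duration_s = 1200, seed = s)
    total <- total + nrow(sc$transients)
  }
  expected <- 1 * 20 * 20 * 3 # 1/min x 20 cells x 20 min x 3 seeds
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("doubling the independent rate doubles the expected count", {
  g <- generate_geometry(n_ihc = 20, seed = 1)
  p1 <- synth_defaults(); p1$lambda_ind_per_min <- 0.5; p1$wave_rate_per_min <- 0
  p2 <- p1; p2$lambda_ind_per_min <- 1
  n1 <- n2 <- 0
  for (s in 1:5) {
    n1 <- n1 + nrow(simulate_schedule(g, p1, 1200, seed = s)$transients)
    n2 <- n2 + nrow(simulate_schedule(g, p2, 1200, seed = 100 + s)$transients)
  }
  expect_lt(abs(n2 - 2 * n1), 3 * sqrt(n2 + 4 * n1))
})

test_that("schedules and rendered movies are bit-identical across repeats", {
  g <- generate_geometry(n_ihc = 8, seed = 5)
  p <- synth_defaults(); p$duration_s <- 30
  s1 <- simulate_schedule(g, p, 30, seed = 9)
  s2 <- simulate_schedule(g, p, 30, seed = 9)
  expect_identical(s1, s2)
  m1 <- render_movie(g, s1, seed = 3)
  m2 <- render_movie(g, s2, seed = 3)
  expect_identical(m1$stack$frames, m2$stack$frames)
})

test_that("kernel FDHM parameterisation matches its closed form", {
  for (target in c(0.5, 1.0, 1.5, 3)) {
    td <- tau_decay_for_fdhm(target, 0.05)
    expect_equal(kernel_fdhm(0.05, td), target, tolerance = 1e-6)
  }
  # rejects unresolvable kinetics
  expect_error(tau_decay_for_fdhm(0.05, 0.05))
})

test_that("zero-noise rendering conserves the scheduled transients", {
  g <- generate_geometry(n_ihc = 10, seed = 2)
  p <- synth_defaults()
  p$lambda_ind_per_min <- 0.8; p$wave_rate_per_min <- 0
  p$artifact_rate_per_min <- 0; p$drift_amp_px <- 0
  s <- simulate_schedule(g, p, duration_s = 600, seed = 3)
  rt <- render_traces(g, s, noise_sd = 0)
  dt <- detrend_traces(mk_trace_set(rt$ihc, rt$frame_rate), 30)
  tr <- detect_transients(dt)
  # oracle bounds: same-cell peaks fuse when closer than the detector can
  # resolve, somewhere between the separation window and ~1 s for a 1.5 s
  # kernel
  fused <- function(w) sum(vapply(split(s$transients$time, s$transients$cell),
                                  function(tt) length(unique(
                                    cumsum(c(1, diff(sort(tt)) > w)))),
                                  numeric(1)))
  expect_lte(nrow(tr), fused(0.5))
  expect_gte(nrow(tr), fused(1.2))
  # every isolated scheduled transient is recovered at its time
  for (j in seq_len(nrow(s$transients))) {
    same <- s$transients$cell == s$transients$cell[j]
    gap <- abs(s$transients$time[same] - s$transients$time[j])
    if (sum(gap < 1) > 1) next
    id <- g$ihc$identity[s$transients$cell[j]]
    expect_true(any(tr$identity == id &
                      abs(tr$peak_time - s$transients$time[j]) < 0.5))
  }
})

test_that("a rendered single transient has the kernel amplitude and FDHM", {
  g <- generate_geometry(n_ihc = 4, seed = 2)
  p <- synth_defaults()
  sched <- simulate_schedule(g, within(p, {
    lambda_ind_per_min <- 0; wave_rate_per_min <- 0
    artifact_rate_per_min <- 0; drift_amp_px <- 0
  }), duration_s = 60, seed = 1)
  sched$transients <- data.frame(cell = 2L, time = 20, amplitude = 0.5,
                                 event_id = 0L, identity = g$ihc$identity[2])
  rt <- render_traces(g, sched, noise_sd = 0)
  tr <- detect_transients(detrend_traces(mk_trace_set(rt$ihc, rt$frame_rate), 30))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$amplitude, 0.5, tolerance = 0.05)
  expect_equal(tr$fdhm, 1.5, tolerance = 0.1)
})

test_that("artifact bouts dim whole frames by the configured depth", {
  g <- generate_geometry(n_ihc = 6, seed = 2)
  p <- synth_defaults()
  p$lambda_ind_per_min <- 0; p$wave_rate_per_min <- 0
  p$artifact_rate_per_min <- 0; p$drift_amp_px <- 0
  s <- simulate_schedule(g, p, duration_s = 30, seed = 1)
  s$artifacts <- data.frame(start_s = 10, len_s = 0.5, depth = 0.5,
                            shift_px = 0)
  m <- render_movie(g, s, shot_noise = FALSE, drift = FALSE)
  mu <- apply(m$stack$frames, 3, mean)
  dimmed <- frames_in <- 101:105 # frames [100,105): t in [10, 10.5)
  expect_equal(mu[dimmed] / mu[95], rep(0.5, 5), tolerance = 1e-9)
  expect_equal(mu[96], mu[110], tolerance = 1e-9)
  expect_equal(nrow(m$artifact_frames), 1)
  expect_equal(unname(m$artifact_frames[1, ]), c(101, 106))
})

test_that("empty schedule with zero noise renders the static baseline", {
  g <- generate_geometry(n_ihc = 6, seed = 2)
  p <- synth_defaults()
  p$lambda_ind_per_min <- 0; p$wave_rate_per_min <- 0
  p$artifact_rate_per_min <- 0; p$drift_amp_px <- 0
  s <- simulate_schedule(g, p, duration_s = 10, seed = 1)
  m <- render_movie(g, s, shot_noise = FALSE, drift = FALSE)
  f1 <- m$stack$frames[, , 1]
  for (k in c(2, 50, 100)) expect_identical(m$stack$frames[, , k], f1)
})
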