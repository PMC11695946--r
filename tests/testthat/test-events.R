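# Transient detection criteria, event grouping, frequencies, correlations.

fr <- 10
td15 <- tau_decay_for_fdhm(1.5, 0.05)

test_that("inclusion criteria reject brief and small peaks", {
  tg <- seq(0, 60 - 1 / fr, by = 1 / fr)
  # clean 1.0 s transient is found once with its FDHM
  td10 <- tau_decay_for_fdhm(1.0, 0.05)
  v <- 0.5 * ca_kernel(tg - 30, 0.05, td10)
  tr <- detect_transients(detrend_traces(mk_trace_set(cbind(A = v), fr), 30))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$fdhm, 1.0, tolerance = 0.1)
  # a transient with FDHM 0.15 s fails the 200 ms rule
  td015 <- tau_decay_for_fdhm(0.15, 0.01)
  v2 <- 0.5 * ca_kernel(tg - 30, 0.01, td015)
  tr2 <- detect_transients(detrend_traces(mk_trace_set(cbind(A = v2), fr), 30))
  expect_equal(nrow(tr2), 0)
  # amplitude below 2 SD of a busy trace is rejected: add one tiny peak to
  # a trace whose SD is dominated by large transients
  v3 <- 0.05 * ca_kernel(tg - 10, 0.05, td15)
  for (t0 in c(25, 35, 45)) v3 <- v3 + 0.8 * ca_kernel(tg - t0, 0.05, td15)
  tr3 <- detect_transients(detrend_traces(mk_trace_set(cbind(A = v3), fr), 30))
  expect_false(any(abs(tr3$peak_time - 10) < 2))
})

test_that("peaks inside interpolated-only spans are rejected", {
  tg <- seq(0, 60 - 1 / fr, by = 1 / fr)
  v <- 0.6 * ca_kernel(tg - 30, 0.05, td15)
  ts <- mk_trace_set(cbind(A = v), fr)
  ts$interpolated[288:322, 1] <- TRUE
  tr <- detect_transients(detrend_traces(ts, 30))
  expect_equal(nrow(tr), 0)
})

test_that("chained linkage and the positional gap rule follow the stated boundaries", {
  positions <- stats::setNames(1:12, paste0("C", sprintf("%02d", 1:12)))
  mk <- function(cells, times)
    data.frame(identity = paste0("C", sprintf("%02d", cells)),
               peak_time = times, amplitude = 1, prominence = 1, fdhm = 1,
               recording_id = "r")
  # chaining: 0, 1.9, 3.8 link into one multiple event
  g1 <- group_events(mk(1:3, c(0, 1.9, 3.8)), positions, window_s = 2)
  expect_equal(nrow(g1$events), 1)
  expect_equal(g1$events$class, "multiple")
  # complete linkage splits the same chain
  g1c <- group_events(mk(1:3, c(0, 1.9, 3.8)), positions, window_s = 2,
                      linkage = "complete")
  expect_gt(nrow(g1c$events), 1)
  # positional gap of 5 cells -> two events; gap of exactly 4 -> one event
  g2 <- group_events(mk(c(1, 2, 3, 9, 10, 11), rep(0, 6)), positions)
  expect_equal(nrow(g2$events), 2)
  g3 <- group_events(mk(c(1, 2, 3, 8, 9, 10), rep(0, 6)), positions)
  expect_equal(nrow(g3$events), 1)
  # class boundaries
  expect_equal(group_events(mk(5, 0), positions)$events$class, "single")
  expect_equal(group_events(mk(c(5, 6), c(0, 1)), positions)$events$class,
               "pair")
  # classes partition the transients
  g4 <- group_events(mk(c(1, 1, 2, 7, 8, 9), c(0, 1, 2, 30, 31, 32)),
                     positions)
  expect_false(anyNA(g4$transients$event_id))
  expect_equal(sum(vapply(split(g4$transients, g4$transients$event_id), nrow,
                          integer(1))), 6)
})

test_that("skipped cells are quiet during the event but active elsewhere", {
  positions <- stats::setNames(1:8, paste0("C", 1:8))
  tr <- data.frame(
    identity = c("C1", "C2", "C4", "C5", "C3", "C6"),
    peak_time = c(10, 10.5, 11, 11.2, 70, 200),
    amplitude = c(1, 1, 1, 1, 0.8, 0.5),
    prominence = 1, fdhm = 1, recording_id = "r")
  g <- group_events(tr, positions)
  ev <- g$events[g$events$class == "multiple", ][1, ]
  sk <- find_skipped_cells(ev, g$transients, positions)
  expect_equal(sk, "C3")
  # a silent-everywhere cell is NOT skipped
  tr2 <- tr[tr$identity != "C3", ]
  g2 <- group_events(tr2, positions)
  sk2 <- find_skipped_cells(g2$events[g2$events$class == "multiple", ][1, ],
                            g2$transients, positions)
  expect_equal(sk2, character(0))
  # substantially reduced amplitude counts as skipped (C3 fires weakly
  # during the event and normally later)
  tr3 <- rbind(tr, data.frame(identity = "C3", peak_time = 10.8,
                              amplitude = 0.1, prominence = 1, fdhm = 1,
                              recording_id = "r"))
  g3 <- group_events(tr3, positions)
  sk3 <- find_skipped_cells(g3$events[g3$events$class == "multiple", ][1, ],
                            g3$transients, positions)
  expect_equal(sk3, "C3")
})

test_that("amplitudes pool by event class and conserve counts", {
  positions <- stats::setNames(1:6, paste0("C", 1:6))
  tr <- data.frame(
    identity = c("C1", "C2", "C3", "C5", "C1"),
    peak_time = c(0, 0.5, 1.0, 50, 100),
    amplitude = c(0.5, 0.6, 0.4, 0.2, 0.3),
    prominence = 1, fdhm = 1, recording_id = "r")
  g <- group_events(tr, positions)
  ac <- event_amplitude_by_class(g)
  expect_equal(ac$n[ac$class == "multiple"], 3)
  expect_equal(ac$n[ac$class == "single"], 2)
  expect_equal(ac$mean_amplitude[ac$class == "multiple"], 0.5)
  expect_equal(sum(ac$n), nrow(tr))
  expect_true(is.na(ac$mean_amplitude[ac$class == "pair"]))
})

test_that("frequencies follow counts over eligible durations", {
  tr <- data.frame(identity = rep("A", 12), peak_time = seq(10, 560, 50),
                   amplitude = 1, prominence = 1, fdhm = 1,
                   recording_id = "r")
  f <- compute_frequency(tr, 600)
  expect_equal(f$freq_per_min, 1.2)
  # 4-minute cells are excluded
  f2 <- compute_frequency(tr, data.frame(identity = c("A", "B"),
                                         total_duration_s = c(600, 240)))
  expect_true(is.na(f2$freq_per_min[f2$identity == "B"]))
  expect_false(f2$eligible[f2$identity == "B"])
})

test_that("Fisher averaging matches its closed form", {
  expect_equal(fisher_average(c(0, 0.8))$mean, 0.5, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    r <- runif(sample(3:30, 1), -0.95, 0.95)
    fa <- fisher_average(r)
    expect_equal(fa$mean, tanh(mean(atanh(r))), tolerance = 1e-12)
    expect_equal(fa$sd, tanh(sd(atanh(r))), tolerance = 1e-12)
  }
  # |r| = 1 is clamped, not an error
  expect_lt(fisher_average(c(1, 0.5))$mean, 1)
})

test_that("correlation analysis excludes short overlaps and finds distance decay", {
  set.seed(11)
  fr <- 10
  n <- 12
  nt <- 6 * 60 * fr
  pos <- stats::setNames((0:(n - 1)) * 10, paste0("C", sprintf("%02d", 1:n)))
  # common drivers with coupling decaying over d0 = 40 um
  drivers <- matrix(rnorm(nt * n), nt, n)
  m <- matrix(0, nt, n, dimnames = list(NULL, names(pos)))
  for (i in 1:n) for (j in 1:n) {
    w <- exp(-abs(pos[i] - pos[j]) / 80) # sqrt of pairwise target decay
    m[, i] <- m[, i] + w * drivers[, j]
  }
  m <- m + matrix(rnorm(nt * n, 0, 0.5), nt, n)
  ca <- correlation_analysis(mk_trace_set(m, fr), pos)
  expect_equal(diag(ca$r), rep(1, n), ignore_attr = TRUE)
  expect_true(all(ca$r[upper.tri(ca$r)] > -1))
  # identical traces correlate at 1
  m2 <- cbind(A = m[, 1], B = m[, 1], C = m[, 3])
  ca2 <- correlation_analysis(mk_trace_set(m2, fr),
                              stats::setNames(c(0, 5, 40), c("A", "B", "C")))
  expect_equal(ca2$r["A", "B"], 1, tolerance = 1e-12, ignore_attr = TRUE)
  # r decreases with distance and the fit returns a positive decay length
  bd <- ca$by_distance
  expect_gt(bd$r_mean[1], bd$r_mean[nrow(bd)])
  expect_gt(ca$d0_um, 0)
  # pairs with < 5 min overlap are NA, not zero
  short <- stitch_recordings(list(
    mk_trace_set(m[1:1200, 1:2], fr, "r1"),
    mk_trace_set(m[1:3600, c(1, 3)], fr, "r2")))
  ca3 <- correlation_analysis(short, pos[1:3])
  expect_true(is.na(ca3$r["C01", "C02"]))
  expect_false(is.na(ca3$r["C01", "C03"]))
})
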