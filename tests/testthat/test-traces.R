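# ROI erosion, trace extraction, dF/F0, interpolation, detrending, stitching.

test_that("ROI erosion shrinks discs by the radius and drops thin labels", {
  lab <- matrix(0L, 40, 40)
  yy <- row(lab); xx <- col(lab)
  lab[(yy - 20)^2 + (xx - 20)^2 <= 10^2] <- 1L # disc radius 10
  lab[5, 3:12] <- 2L                           # 1-px-wide stripe
  rois <- roi_map(lab)
  er <- suppressMessages(erode_rois(rois, 2))
  expect_setequal(names(er$class_of), "1")
  # disc of radius 10 eroded by 2 ~ disc of radius 8 (+- 1 px discretisation)
  area <- sum(er$labels == 1L)
  expect_gt(area, pi * 7^2)
  expect_lt(area, pi * 9^2)
  # erosion is anti-extensive and keeps labels disjoint
  expect_true(all(rois$labels[er$labels == 1L] == 1L))
  expect_error(erode_rois(rois, 0.5), "radius")
  thin <- roi_map(matrix(c(0L, 1L, 0L, 0L), 2, 2))
  expect_error(suppressMessages(erode_rois(thin, 1)), "vanished")
})

test_that("dF/F0 extraction normalises against the low percentile", {
  arr <- array(100, dim = c(8, 8, 50))
  arr[3:5, 3:5, 21:25] <- 150 # transient on ROI pixels
  lab <- matrix(0L, 8, 8); lab[3:5, 3:5] <- 1L
  st <- timelapse_stack(arr, 10, 1)
  ts <- extract_traces(st, roi_map(lab))
  expect_equal(unname(ts$dff[1, 1]), 0)
  expect_equal(unname(ts$dff[21, 1]), 0.5)
  # invariance to a positive rescaling of the raw stack
  st2 <- st; st2$frames <- st2$frames * 3.7
  ts2 <- extract_traces(st2, roi_map(lab))
  expect_equal(ts2$dff, ts$dff, tolerance = 1e-12)
  # zero-baseline ROI is rejected by name
  arr0 <- arr; arr0[3:5, 3:5, ] <- 0
  expect_error(extract_traces(timelapse_stack(arr0, 10, 1), roi_map(lab)),
               "IHC_1")
})

test_that("removed frames are linearly interpolated and flagged", {
  arr <- array(0, dim = c(4, 4, 20))
  ramp <- c(rep(100, 9), 0, 0, 106, rep(106, 8)) # frames 10,11 garbage
  for (k in 1:20) arr[, , k] <- ramp[k]
  arr[, , 10] <- 500; arr[, , 11] <- 3
  lab <- matrix(1L, 4, 4)
  st <- timelapse_stack(arr, 10, 1)
  rep <- structure(list(removed = interval_matrix(list(c(10, 12))),
                        method = "manual", substitution_source = 9L,
                        n_frames = 20L), class = "frame_qc")
  ts <- extract_traces(st, roi_map(lab), report = rep)
  expect_equal(unname(ts$raw[10, 1]), 102)
  expect_equal(unname(ts$raw[11, 1]), 104)
  expect_true(all(ts$interpolated[10:11, 1]))
  expect_equal(mean(ts$interpolated[, 1]), 2 / 20)
})

test_that("detrending removes slow baselines but preserves transients", {
  fr <- 10
  tg <- seq(0, 120 - 1 / fr, by = 1 / fr)
  # constant input -> all zeros
  expect_equal(detrend_traces(rep(3, 500), 30, fr), rep(0, 500))
  # linear ramp residual bounded by slope x window / 2
  slope <- 0.01
  res <- detrend_traces(slope * tg, 30, fr)
  expect_lt(max(abs(res[150:1050])), slope * 30 / 2 + 1e-9)
  # a 1.5 s transient on a slow drift survives within 5%
  td <- tau_decay_for_fdhm(1.5, 0.05)
  v <- 0.5 * ca_kernel(tg - 60, 0.05, td) + 0.002 * tg
  dtv <- detrend_traces(v, 30, fr)
  expect_equal(max(dtv), 0.5, tolerance = 0.05)
})

test_that("stitching concatenates durations per cell identity", {
  m1 <- matrix(rnorm(600 * 3, 0, 0.01), 600,
               dimnames = list(NULL, c("A", "B", "C")))
  m2 <- matrix(rnorm(1200 * 2, 0, 0.01), 1200,
               dimnames = list(NULL, c("A", "C")))
  st <- stitch_recordings(list(mk_trace_set(m1, 10, "r1"),
                               mk_trace_set(m2, 10, "r2")))
  cells <- st$cells
  expect_equal(cells$total_duration_s[cells$identity == "A"], 180)
  expect_equal(cells$total_duration_s[cells$identity == "B"], 60)
  expect_equal(st$segments[[2]]$start_time, 60)
  # single recording is the identity operation
  one <- stitch_recordings(list(mk_trace_set(m1, 10, "r1")))
  expect_equal(one$cells$total_duration_s, rep(60, 3))
  # collision within a recording
  m3 <- m1; colnames(m3) <- c("A", "A", "C")
  expect_error(stitch_recordings(list(mk_trace_set(m3, 10, "r3"))),
               "collision")
})

test_that("frequencies are invariant to splitting a recording into stitched halves", {
  fr <- 10
  td <- tau_decay_for_fdhm(1.5, 0.05)
  tg <- seq(0, 600 - 1 / fr, by = 1 / fr)
  set.seed(5)
  times <- sort(runif(12, 20, 580))
  v <- rnorm(length(tg), 0, 0.03)
  for (t0 in times) v <- v + 0.4 * ca_kernel(tg - t0, 0.05, td)
  m <- matrix(v, ncol = 1, dimnames = list(NULL, "A"))
  whole <- detect_transients(detrend_traces(mk_trace_set(m, fr), 30, fr))
  halves <- stitch_recordings(list(
    mk_trace_set(m[1:3000, , drop = FALSE], fr, "r1"),
    mk_trace_set(m[3001:6000, , drop = FALSE], fr, "r2")))
  halves <- detect_transients(detrend_traces(halves, 30))
  f1 <- compute_frequency(whole, 600)
  f2 <- compute_frequency(halves,
                          data.frame(identity = "A", total_duration_s = 600))
  # identical counts unless a transient straddles the cut
  expect_lte(abs(f1$n_transients - f2$n_transients), 1)
  expect_equal(f1$freq_per_min, 12 / 10, tolerance = 0.2)
})
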