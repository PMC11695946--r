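# Wave segmentation, geometry/kinetics quantification, kymographs.

test_that("a single rendered wave is segmented as one object overlapping truth", {
  st <- mk_wave_stack()
  ws <- segment_waves(st, ignore_border_px = 0)
  expect_equal(length(ws$waves), 1)
  # voxel overlap with the analytic footprint at maximal expansion
  ax <- cochlear_axis(rbind(c(0, 0), c(120, 0)))
  qw <- quantify_wave(ws, ax)
  expect_equal(qw$max_area_um2, pi * 20^2, tolerance = 0.15)
  expect_false(qw$boundary_truncated)
})

test_that("two distant waves are separate objects; tiny blobs are excluded", {
  st <- mk_wave_stack()
  st2 <- mk_wave_stack(cx = 60 + 0, cy = 30)
  # second wave 100 um away, overlapping in time
  arr <- st$frames
  arr2 <- mk_wave_stack(cx = 15, cy = 30, a = 12, b = 12)$frames
  both <- timelapse_stack(pmax(arr, arr2), 10, 1)
  ws <- segment_waves(both, ignore_border_px = 0)
  expect_equal(length(ws$waves), 2)
  # a transient confined to one cell-sized footprint is not a wave
  one_cell <- mk_wave_stack(a = 4, b = 4, v_exp = 8, v_con = 8)
  ws2 <- segment_waves(one_cell, ignore_border_px = 0)
  expect_equal(length(ws2$waves), 0)
})

test_that("expansion and contraction speeds recover the generative rates", {
  st <- mk_wave_stack(v_exp = 22, v_con = 15)
  ws <- segment_waves(st, ignore_border_px = 0)
  ax <- cochlear_axis(rbind(c(0, 0), c(120, 0)))
  qw <- quantify_wave(ws, ax)
  expect_equal(qw$expansion_speed_um_s, 22, tolerance = 0.05)
  expect_equal(qw$contraction_speed_um_s, 15, tolerance = 0.05)
  # equivalent-radius estimator is stable across pixel sizes when the
  # binning keeps the working resolution near 2 um per binned pixel
  for (px in c(0.5, 2)) {
    stp <- mk_wave_stack(pixel_size = px, ny = 60 / px, nx = 120 / px,
                         cx = 60, cy = 30)
    wsp <- segment_waves(stp, bin_factor = max(1, round(2 / px)),
                         ignore_border_px = 0)
    qwp <- quantify_wave(wsp, ax)
    expect_equal(qwp$expansion_speed_um_s, 22, tolerance = 0.05)
  }
})

test_that("elliptical footprints give extents and centroid in axis coordinates", {
  # ellipse with 2a = 34 um along the row, 2b = 14 um radially, centred
  # 12 um on the modiolar side
  st <- mk_wave_stack(a = 17, b = 7, cx = 60, cy = 42, t_plateau = 2)
  ax <- cochlear_axis(rbind(c(0, 30), c(120, 30))) # row at y = 30, modiolar +y
  ws <- segment_waves(st, ignore_border_px = 0)
  expect_equal(length(ws$waves), 1)
  qw <- quantify_wave(ws, ax)
  bin <- ws$bin_size_um
  expect_equal(qw$longitudinal_extent_um, 34, tolerance = bin / 34)
  expect_equal(qw$radial_extent_um, 14, tolerance = bin / 14)
  expect_equal(qw$centroid_distance_um, 12, tolerance = bin / 12)
  expect_gt(qw$centroid_d_um, 0) # modiolar side
  expect_equal(qw$fdhm_s, 2 + 0.29 * (sqrt(17 * 7) / 22 + sqrt(17 * 7) / 15),
               tolerance = 0.15)
})

test_that("segmentation is equivariant to spatial translation", {
  st <- mk_wave_stack(cx = 50, cy = 25, a = 14, b = 14)
  st_shift <- mk_wave_stack(cx = 58, cy = 31, a = 14, b = 14)
  ws <- segment_waves(st, ignore_border_px = 0)
  wss <- segment_waves(st_shift, ignore_border_px = 0)
  v1 <- ws$waves[[1]]; v2 <- wss$waves[[1]]
  v2$x <- v2$x - 8 / ws$bin_size_um
  v2$y <- v2$y - 6 / ws$bin_size_um
  key <- function(v) sort(paste(v$y, v$x, v$t))
  expect_gt(length(intersect(key(v1), key(v2))) /
              length(union(key(v1), key(v2))), 0.9)
})

test_that("boundary-truncated waves count toward frequency but not duration", {
  st <- mk_wave_stack(t_onset = -0.5, t_plateau = 2) # starts before frame 1
  ws <- segment_waves(st, ignore_border_px = 0)
  ax <- cochlear_axis(rbind(c(0, 0), c(120, 0)))
  qw <- quantify_wave(ws, ax)
  expect_true(qw$boundary_truncated[1])
  expect_true(is.na(qw$fdhm_s[1]))
  expect_equal(wave_frequency(qw, 120), 0.5)
  expect_equal(wave_frequency(qw[0, ], 600), 0)
  expect_error(wave_frequency(qw, 0), "positive")
})

test_that("manual 2D outlines contribute geometry but no kinetics", {
  st <- mk_wave_stack()
  ws <- segment_waves(st, ignore_border_px = 0)
  ax <- cochlear_axis(rbind(c(0, 0), c(120, 0)))
  qw <- quantify_wave(ws, ax)
  lab <- matrix(0L, 60, 120)
  lab[20:34, 80:109] <- 1L # 30 x 15 px outline
  qa <- add_manual_waves(qw, roi_map(lab), ax, pixel_size = 1)
  expect_equal(nrow(qa), nrow(qw) + 1)
  man <- qa[qa$manual, ]
  expect_equal(man$longitudinal_extent_um, 30, tolerance = 0.05)
  expect_true(is.na(man$expansion_speed_um_s))
  expect_equal(wave_frequency(qa, 120), 1)
})

test_that("kymographs read propagation speed as a ridge slope", {
  fr <- 10
  nt <- 60
  arr <- array(10, dim = c(40, 150, nt))
  # bar sweeping along x at 60 um/s starting at x = 10 um, t = 1 s
  for (k in seq_len(nt)) {
    t <- (k - 1) / fr
    x0 <- 10 + 60 * (t - 1)
    if (t >= 1 && x0 < 140) {
      cols <- which(abs((seq_len(150) - 1) - x0) <= 3)
      arr[16:24, cols, k] <- 100
    }
  }
  st <- timelapse_stack(arr, fr, 1)
  ky <- build_kymograph(st, rbind(c(0, 20), c(149, 20)), half_width_px = 3,
                        step_um = 1)
  # static image gives identical rows; moving bar a sloped ridge
  expect_equal(ncol(ky$img), 150)
  sp <- measure_kymo_speed(ky, t_range = c(0.8, 4), s_range = c(5, 145))
  expect_equal(sp, 60, tolerance = 0.1)
  # a stationary blob has zero speed
  arr2 <- array(10, dim = c(40, 150, nt))
  arr2[16:24, 70:72, 21:40] <- 100
  ky2 <- build_kymograph(timelapse_stack(arr2, fr, 1),
                         rbind(c(0, 20), c(149, 20)))
  expect_lt(measure_kymo_speed(ky2, c(0, 6), c(60, 80)), 1.1)
  # static input: all rows identical
  ky3 <- build_kymograph(timelapse_stack(array(7, dim = c(20, 50, 5)), fr, 1),
                         rbind(c(0, 10), c(49, 10)))
  expect_true(all(apply(ky3$img, 2, function(cl) all(cl == cl[1]))))
  expect_equal(ncol(ky3$img), 50)
})

test_that("waves are matched to IHC events within the origin window", {
  wt <- data.frame(wave_id = 1:3,
                   onset_s = c(10, 40, 70), offset_s = c(13, 43, 73),
                   centroid_distance_um = c(12, 50, 12),
                   centroid_d_um = c(12, 50, 12),
                   longitudinal_extent_um = c(30, 30, 30))
  pos <- stats::setNames(seq(0, 90, by = 10), paste0("C", 1:10))
  events <- data.frame(event_id = 1:2, class = c("multiple", "single"),
                       n_cells = c(4, 1),
                       t_start = c(11, 100), t_end = c(12.5, 100.5))
  events$cells <- list(paste0("C", 2:5), "C8")
  m <- match_wave_to_ihc_events(wt, events, pos)
  expect_equal(nrow(m), 2) # wave 2 is outside the 35 um window
  expect_true(m$matched[m$wave_id == 1])
  expect_equal(m$ihc_span_um[m$wave_id == 1], 30)
  expect_true(m$coordinated[m$wave_id == 1])
  expect_false(m$matched[m$wave_id == 3]) # no temporally overlapping event
})
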