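# Frame QC, substitution, smoothing, drift correction.

test_that("3D Gaussian smoothing preserves constants, mass and offsets", {
  const <- timelapse_stack(array(7, dim = c(12, 12, 8)), 10, 1)
  sm <- smooth_stack(const)
  expect_equal(sm$frames, const$frames, tolerance = 1e-12)
  # single bright voxel spreads into a mass-preserving blob
  arr <- array(0, dim = c(21, 21, 11))
  arr[11, 11, 6] <- 1000
  st <- timelapse_stack(arr, 10, 1)
  sm2 <- smooth_stack(st)
  expect_lt(max(sm2$frames), 1000)
  expect_equal(sum(sm2$frames), 1000, tolerance = 1)
  expect_equal(which.max(sm2$frames), which.max(arr))
  # linearity: adding a constant shifts the output by the same constant
  st3 <- timelapse_stack(arr + 5, 10, 1)
  sm3 <- smooth_stack(st3)
  expect_equal(sm3$frames, sm2$frames + 5, tolerance = 1e-9)
  expect_error(smooth_stack(timelapse_stack(array(1, c(4, 4, 2)), 10, 1)),
               "3 frames")
})

test_that("clean movies yield an empty QC report", {
  st <- mk_plain_stack(nt = 100)
  rep <- detect_bad_frames(st)
  expect_equal(nrow(rep$removed), 0)
})

test_that("injected dimming bouts are detected and expanded to full intervals", {
  st <- mk_plain_stack(nt = 200)
  st$frames[, , 101:105] <- st$frames[, , 101:105] * 0.5
  rep <- detect_bad_frames(st)
  expect_gte(nrow(rep$removed), 1)
  flagged <- frames_in_intervals(rep$removed, 200)
  expect_true(all(flagged[101:105]))
  # no more than a couple of shoulder frames beyond the bout
  expect_lte(sum(flagged), 9)
  expect_match(rep$method[1], "prominence")
})

test_that("manual intervals are honoured and merged", {
  st <- mk_plain_stack(nt = 60)
  rep <- detect_bad_frames(st, manual_list = list(c(1, 4)))
  expect_equal(nrow(rep$removed), 1)
  expect_equal(unname(rep$removed[1, ]), c(1, 4))
  expect_equal(rep$method, "manual")
  # a leading interval substitutes the first in-focus frame after it
  expect_equal(rep$substitution_source, 4L)
})

test_that("template search flags recurring artifact shapes", {
  st <- mk_plain_stack(nt = 300)
  dip <- c(-0.2, -0.5, -0.5, -0.2)
  for (k0 in c(50, 150, 250)) {
    for (j in seq_along(dip))
      st$frames[, , k0 + j - 1] <- st$frames[, , k0 + j - 1] * (1 + dip[j])
  }
  # weaker than the prominence threshold on purpose: disable prominence
  rep <- detect_bad_frames(st, prominence_k = 1e6,
                           template_bank = list(dip * mean(st$frames[, , 1])))
  flagged <- frames_in_intervals(rep$removed, 300)
  expect_true(all(flagged[c(50:53, 150:153, 250:253)]))
  expect_true(all(grepl("template", rep$method)))
})

test_that("substitution copies the last in-focus frame bit-exactly and is idempotent", {
  st <- mk_plain_stack(nt = 60)
  set.seed(1)
  st$frames <- st$frames + array(rnorm(length(st$frames), 0, 1)^2,
                                 dim = dim(st$frames))
  dimmed <- st
  dimmed$frames[, , 21:25] <- dimmed$frames[, , 21:25] * 0.4
  rep <- detect_bad_frames(dimmed)
  sub <- apply_substitution(dimmed, rep)
  expect_equal(n_frames(sub), 60)
  src <- rep$substitution_source[1]
  for (k in seq(rep$removed[1, 1], rep$removed[1, 2] - 1))
    expect_identical(sub$frames[, , k], sub$frames[, , src])
  # re-running detection on the substituted stack finds nothing new there
  rep2 <- detect_bad_frames(sub)
  flagged2 <- frames_in_intervals(rep2$removed, 60)
  expect_false(any(flagged2[21:25]))
  # empty report leaves the stack unchanged
  empty <- detect_bad_frames(mk_plain_stack(nt = 60))
  st2 <- apply_substitution(st, empty)
  expect_identical(st2$frames, st$frames)
})

test_that("all frames flagged is an error", {
  st <- mk_plain_stack(nt = 10)
  expect_error(detect_bad_frames(st, manual_list = list(c(1, 11))),
               "no in-focus frames")
})

test_that("drift correction recovers constructed translations to subpixel accuracy", {
  set.seed(3)
  base <- matrix(0, 48, 48)
  base[15:20, 10:40] <- 80
  base[30:40, 22:28] <- 120
  base <- base + matrix(runif(48 * 48, 0, 5), 48, 48)
  arr <- array(rep(base, 10), dim = c(48, 48, 10))
  # frame 4 translated by (3, -2): content moved down 3 px, left 2 px
  arr[, , 4] <- cochleaCa:::translate_bilinear(base, -3, 2)
  st <- timelapse_stack(arr, 10, 1)
  res <- correct_drift(st, reference = base, max_shift = 8)
  expect_equal(res$shifts$dy[4], 3, tolerance = 0.25)
  expect_equal(res$shifts$dx[4], -2, tolerance = 0.25)
  expect_equal(res$shifts$dy[1], 0, tolerance = 0.25)
  # mean preserved within 0.1%
  expect_equal(mean(res$stack$frames), mean(arr), tolerance = 1e-3)
  # corrected frame matches the reference away from the borders
  expect_equal(res$stack$frames[10:38, 10:38, 4], arr[10:38, 10:38, 1],
               tolerance = 0.15 * mean(base))
  expect_error(correct_drift(st, max_shift = 20), "quarter")
})

test_that("zero-drift stacks report zero shifts", {
  st <- mk_plain_stack(nt = 8)
  res <- correct_drift(st, max_shift = 5)
  expect_true(all(abs(res$shifts$dy) < 0.05))
  expect_true(all(abs(res$shifts$dx) < 0.05))
})
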