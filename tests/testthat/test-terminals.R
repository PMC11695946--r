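# Terminal segmentation, assignment, side classification, recruitment.

test_that("well-separated rendered puncta segment with accurate centroids", {
  set.seed(4)
  ny <- 60; nx <- 90
  centres <- cbind(x = rep(seq(10, 80, by = 14), 2),
                   y = rep(c(20, 40), each = 6)) +
    matrix(runif(24, -2, 2), 12, 2)
  img <- matrix(20, ny, nx)
  yy <- matrix(seq_len(ny) - 1, ny, nx); xx <- matrix(seq_len(nx) - 1, ny, nx,
                                                      byrow = TRUE)
  for (i in 1:12)
    img <- img + 60 * exp(-((xx - centres[i, 1])^2 +
                            (yy - centres[i, 2])^2) / (2 * 1.5^2))
  rois <- segment_terminals(img, tophat_radius_px = 10)
  expect_equal(length(rois$class_of), 12)
  cen <- roi_centroids(rois, 1)
  for (i in 1:12) {
    d <- sqrt((cen$x - centres[i, 1])^2 + (cen$y - centres[i, 2])^2)
    expect_lte(min(d), 1)
  }
  # a smooth background gradient changes no detections
  grad <- matrix(seq(0, 30, length.out = nx), ny, nx, byrow = TRUE)
  rois2 <- segment_terminals(img + grad, tophat_radius_px = 10)
  expect_equal(length(rois2$class_of), 12)
  # flat image: zero labels, with a warning
  expect_warning(r0 <- segment_terminals(matrix(5, 40, 40)), "no puncta")
  expect_equal(length(r0$class_of), 0)
})

test_that("proximity assigns unambiguous terminals; correlation settles the rest", {
  ihc_xy <- data.frame(identity = c("A", "B"), x = c(0, 12), y = c(0, 0))
  term_xy <- data.frame(identity = c("t1", "t2"),
                        x = c(3, 6), y = c(0, 0))
  # t1: 3 um from A, 9 um from B -> proximity; t2 equidistant -> correlation
  set.seed(2)
  n <- 2000
  base <- matrix(rnorm(3 * n), n, 3)
  ihc_tr <- cbind(A = base[, 1], B = base[, 2])
  term_tr <- cbind(t1 = base[, 3],
                   t2 = 0.7 * base[, 2] + 0.2 * base[, 3]) # follows B
  asg <- assign_terminals(term_xy, ihc_xy, term_tr, ihc_tr,
                          ambiguity_margin_um = 3)
  expect_equal(asg$parent[asg$terminal == "t1"], "A")
  expect_equal(asg$method[asg$terminal == "t1"], "proximity")
  expect_equal(asg$parent[asg$terminal == "t2"], "B")
  expect_equal(asg$method[asg$terminal == "t2"], "correlation")
  # every terminal is assigned exactly once
  expect_equal(sort(asg$terminal), c("t1", "t2"))
})

test_that("assignment accuracy reaches 95% on 500 synthetic terminals", {
  # half-hour recordings, as stitched fields provide in practice: the
  # correlation fallback discriminates through the sparse independent
  # transients, so it needs observation time
  correct <- 0; total <- 0
  for (seed in 1:3) {
    g <- generate_geometry(n_ihc = 45, seed = seed)
    p <- synth_defaults()
    sched <- simulate_schedule(g, p, duration_s = 1800, seed = seed + 10)
    rt <- render_traces(g, sched, seed = seed + 20)
    asg <- assign_terminals(
      data.frame(identity = g$terminals$identity,
                 x = g$terminals$x, y = g$terminals$y),
      data.frame(identity = g$ihc$identity, x = g$ihc$x, y = g$ihc$y),
      rt$terminals, rt$ihc)
    truth <- g$terminals$parent_identity[
      match(asg$terminal, g$terminals$identity)]
    correct <- correct + sum(asg$parent == truth)
    total <- total + nrow(asg)
  }
  expect_gte(total, 500)
  expect_gte(correct / total, 0.95)
})

test_that("side classification follows the signed radial coordinate exactly", {
  ax <- cochlear_axis(rbind(c(0, 0), c(100, 0)))
  xy <- rbind(c(50, 6), c(50, -6), c(50, 0), c(50, 2.5), c(50, -1.9))
  side <- classify_side(xy, ax, middle_half_width_um = 2)
  expect_equal(side, c("modiolar", "pillar", "middle", "modiolar", "middle"))
  # flipping the axis orientation swaps modiolar and pillar exactly
  side_f <- classify_side(xy, flip_axis(ax), 2)
  swap <- c(modiolar = "pillar", pillar = "modiolar", middle = "middle")
  expect_equal(side_f, unname(swap[side]))
  # synthetic ground truth agrees outside the middle band
  g <- generate_geometry(n_ihc = 30, seed = 3)
  side_g <- classify_side(cbind(g$terminals$x, g$terminals$y), g$axis, 2)
  off_band <- abs(g$terminals$d) > 2
  expect_equal(side_g[off_band], g$terminals$side[off_band])
})

test_that("per-IHC terminal peaks merge by 1-second chaining", {
  asg <- data.frame(terminal = c("t1", "t2", "t3"),
                    parent = c("A", "A", "A"), side = "pillar")
  tm <- matrix(rnorm(300 * 3, 0, 0.01), 300,
               dimnames = list(NULL, c("t1", "t2", "t3")))
  tt <- data.frame(identity = c("t1", "t2", "t3", "t1", "t2"),
                   peak_time = c(0, 0.8, 1.6, 10, 11.5),
                   amplitude = 1, prominence = 1, fdhm = 1,
                   recording_id = "r")
  act <- per_ihc_terminal_activity(asg, tm, tt, duration_s = 60)
  # chain 0, 0.8, 1.6 -> one merged peak; 10 and 11.5 stay separate
  expect_equal(act$frequency$n_peaks, 3L)
  expect_equal(act$merged_peaks$n_terminals[1], 3L)
  # identical member traces average to themselves
  tm2 <- cbind(t1 = tm[, 1], t2 = tm[, 1], t3 = tm[, 1])
  act2 <- per_ihc_terminal_activity(asg, tm2, tt, 60)
  expect_equal(unname(act2$avg_traces[, "A"]), unname(tm[, 1]))
})

test_that("recruitment fractions are bounded, side-split and conserve totals", {
  events <- data.frame(event_id = 1:2, class = c("single", "multiple"),
                       n_cells = c(1, 3), t_start = c(10, 40),
                       t_end = c(10, 42))
  events$cells <- list("A", c("A", "B", "C"))
  asg <- data.frame(terminal = paste0("t", 1:6),
                    parent = rep(c("A", "B", "C"), each = 2),
                    side = rep(c("pillar", "modiolar"), 3))
  tt <- data.frame(identity = c("t1", "t3", "t4"),
                   peak_time = c(40.5, 41, 41.2),
                   amplitude = 1, prominence = 1, fdhm = 1,
                   recording_id = "r")
  rec <- recruitment_analysis(events, tt, asg)
  pe <- rec$per_event
  expect_true(all(pe$frac_total >= 0 & pe$frac_total <= 1))
  # event 1 (single): terminal t1 silent at t = 10
  expect_equal(pe$frac_total[pe$event_id == 1], 0)
  # event 2: A recruits t1 only (1/2), B both (2/2), C none
  e2 <- pe[pe$event_id == 2, ]
  expect_equal(sort(e2$frac_total), c(0, 0.5, 1))
  expect_equal(rec$by_class$frac_total[rec$by_class$class == "multiple"],
               0.5)
  expect_equal(rec$by_class$frac_all_recruited[
    rec$by_class$class == "multiple"], 1 / 3)
  # all terminals silent -> all fractions zero
  rec0 <- recruitment_analysis(events, tt[0, ], asg)
  expect_true(all(rec0$per_event$frac_total == 0))
})

test_that("paired side statistics detect a pillar excess and respect antisymmetry", {
  set.seed(6)
  n_ihc <- 50
  asg <- data.frame(terminal = paste0("t", seq_len(2 * n_ihc)),
                    parent = rep(paste0("I", seq_len(n_ihc)), each = 2),
                    side = rep(c("pillar", "modiolar"), n_ihc))
  # pillar frequencies twice the modiolar ones
  vals <- data.frame(terminal = asg$terminal,
                     value = rpois(2 * n_ihc,
                                   rep(c(2, 1), n_ihc)) + 0.01)
  ss <- side_statistics(vals, asg)
  expect_equal(ss$n_pairs, n_ihc)
  expect_gt(ss$median_difference, 0)
  expect_lt(ss$p_value, 0.05)
  expect_equal(ss$direction, "pillar > modiolar")
  # swapping the labels negates the median difference
  asg2 <- asg
  asg2$side <- ifelse(asg$side == "pillar", "modiolar", "pillar")
  ss2 <- side_statistics(vals, asg2)
  expect_equal(ss2$median_difference, -ss$median_difference)
  # identical sides: median difference zero, insufficient-n path
  few <- side_statistics(vals[1:8, ], asg[1:8, ])
  expect_true(is.na(few$p_value))
})
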