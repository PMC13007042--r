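test_that("effective circular diameter reproduces the printed bin boundaries", {
  expect_equal(round(effective_diameter(0.02), 2), 0.16)
  expect_equal(round(effective_diameter(0.09), 2), 0.34)
  expect_equal(round(effective_diameter(0.3), 2), 0.62)
  expect_equal(effective_diameter(pi), 2)
  expect_error(effective_diameter(-1), ">= 0")
})

test_that("instance extraction uses 8-connectivity per slice", {
  labs <- array(0L, c(2, 5, 5))
  labs[1, 2, 2] <- 1L; labs[1, 3, 3] <- 1L       # diagonal touch: one component
  labs[1, 2, 5] <- 1L                            # separated: second component
  inst <- extract_instances(labs, 1L, spacing_um = 11.4)
  expect_equal(nrow(inst$instances), 2L)
  expect_setequal(inst$instances$n_voxels, c(2L, 1L))
  expect_equal(inst$instances$area_mm2, inst$instances$n_voxels * (11.4 / 1000)^2)

  labs[1, 2, 2] <- 0L  # now a gap between the two pixels
  inst2 <- extract_instances(labs, 1L)
  expect_equal(nrow(inst2$instances), 2L)

  ph <- default_phantom()
  tree_n <- sum(vapply(ph$centerlines, function(tr) tr$z0 <= 1, TRUE))
  expect_equal(nrow(extract_instances(ph$labels, 1L)$instances), tree_n)
  expect_error(extract_instances(labs, 99L), "out of range")
})

test_that("instance matching counts TP/FP/FN and keeps the matching one-to-one", {
  # perfect prediction
  ph <- default_phantom()
  gsl <- extract_instances(ph$labels, 1L)
  m <- match_instances(gsl, gsl, 0.95)
  expect_equal(m$f1, 1)
  expect_equal(m$fp + m$fn, 0L)

  # empty prediction against 3 ground-truth fascicles
  g3 <- matrix(0L, 12, 12); g3[2, 2] <- 1L; g3[6, 6] <- 1L; g3[10, 10] <- 1L
  gmap <- nervect:::.cc2d(g3 == 1L, 8L)
  emap <- nervect:::.cc2d(matrix(FALSE, 12, 12), 8L)
  m2 <- match_instances(gmap, emap, 0.7)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 0L, 3L))
  expect_equal(m2$f1, 0)

  # constructed: one pair IoU 0.8, second prediction overlaps the other GT at 0.3
  gt <- matrix(0L, 10, 20)
  gt[1:10, 1:5] <- 1L    # GT A: 50 px
  gt[1:10, 11:14] <- 1L  # GT B: 40 px
  pr <- matrix(0L, 10, 20)
  pr[1:8, 1:5] <- 1L     # pred 1 vs A: inter 40, union 50 -> IoU 0.8
  pr[1:6, 13:16] <- 1L   # pred 2 vs B: inter 12(2 cols x 6), union 40+24-12=52 -> ~0.23
  gmap2 <- nervect:::.cc2d(gt == 1L, 8L)
  pmap2 <- nervect:::.cc2d(pr == 1L, 8L)
  m3 <- match_instances(gmap2, pmap2, 0.7)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1L, 1L, 1L))
  expect_equal(m3$f1, 2 * 1 / (2 * 1 + 1 + 1))

  expect_error(match_instances(gmap2, pmap2, 0.3), "0.5")

  # one-to-one at t >= 0.5 on random masks
  set.seed(23)
  for (i in 1:10) {
    gm <- nervect:::.cc2d(matrix(stats::runif(16 * 16) < 0.35, 16, 16), 8L)
    pm <- nervect:::.cc2d(matrix(stats::runif(16 * 16) < 0.35, 16, 16), 8L)
    mm <- match_instances(gm, pm, 0.5)
    expect_false(any(duplicated(mm$pairs$gt)))
    expect_false(any(duplicated(mm$pairs$pred)))
  }
})

test_that("the F1 curve is 1 for a perfect prediction and non-increasing in t", {
  ph <- default_phantom()
  curve <- f1_curve(ph$labels, ph$labels)
  expect_true(all(curve$mean_f1 == 1))
  expect_equal(curve$threshold, seq(0.5, 0.95, by = 0.05))

  # erode the prediction per slice (drop the contour pixels of each fascicle)
  labs <- ph$labels$labels
  pred <- labs
  for (z in seq_len(dim(labs)[1])) {
    f <- labs[z, , ] == 1L
    pred[z, , ][f & nervect:::slice_contour(f)] <- 2L
  }
  curve2 <- f1_curve(labs, pred)
  expect_true(all(diff(curve2$mean_f1) <= 1e-12))
  # slice-by-slice brute-force matching oracle
  bins <- size_bins()
  zs <- seq(1, dim(labs)[1], by = bins$slice_interval)
  for (t in c(0.5, 0.75, 0.9)) {
    bf <- mean(vapply(zs, function(z)
      bf_instance_f1(bf_cc2d(labs[z, , ] == 1L), bf_cc2d(pred[z, , ] == 1L), t), 0))
    expect_equal(curve2$mean_f1[abs(curve2$threshold - t) < 1e-9], bf)
  }
})

test_that("over- and under-segmentation follow the majority-cover rule", {
  ph <- default_phantom()
  perf <- over_under_segmentation(ph$labels, ph$labels)
  expect_equal(perf$over_rate, 0)
  expect_equal(perf$under_rate, 0)

  # one GT disc split into two predicted half-discs (plus an intact control)
  gt <- array(0L, c(1, 20, 20))
  gt[1, 3:12, 3:12] <- 1L
  gt[1, 16:19, 16:19] <- 1L
  pred <- gt
  pred[1, 3:12, 7] <- 0L  # cut the big square in two
  ou <- over_under_segmentation(gt, pred, t = 0.7)
  expect_equal(ou$over_rate, 1 / 2)   # one of two GT fascicles affected
  expect_equal(ou$under_rate, 0)

  # two GT discs covered by one predicted blob
  gt2 <- array(0L, c(1, 20, 20))
  gt2[1, 3:8, 3:8] <- 1L
  gt2[1, 3:8, 12:17] <- 1L
  pred2 <- array(0L, c(1, 20, 20))
  pred2[1, 3:8, 3:17] <- 1L
  ou2 <- over_under_segmentation(gt2, pred2, t = 0.7)
  expect_equal(ou2$under_rate, 1)     # both GT fascicles merged
})

test_that("missed fascicles are binned by ground-truth area", {
  ph <- default_phantom()
  perf <- missed_by_size(ph$labels, ph$labels)
  expect_true(all(perf$n_missed == 0L))

  # one missed fascicle per size bin on a single constructed slice
  # (areas in mm^2 at 11.4 um spacing: px * 1.2996e-4)
  px_per_mm2 <- 1 / (11.4 / 1000)^2
  sides <- ceiling(sqrt(c(0.01, 0.05, 0.15, 0.4) * px_per_mm2))
  gt <- array(0L, c(1, 160, 160))
  offs <- c(2, 30, 60, 100)
  for (i in seq_along(sides))
    gt[1, offs[i]:(offs[i] + sides[i] - 1), 2:(1 + sides[i])] <- 1L
  pred <- array(0L, c(1, 160, 160))
  miss <- missed_by_size(gt, pred, t = 0.7, spacing_um = 11.4)
  expect_equal(miss$n_missed, c(1L, 1L, 1L, 1L))
  expect_equal(miss$miss_fraction, c(1, 1, 1, 1))

  # a missed 0.05 mm^2 fascicle lands in the "small" bin
  expect_equal(unname(bin_of_area(0.05)), "small")
})
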