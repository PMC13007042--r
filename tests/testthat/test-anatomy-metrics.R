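test_that("the skeleton is a subset of the mask and a thin line is its own skeleton", {
  set.seed(24)
  for (i in 1:8) {
    m <- rand_mask(c(6, 6, 6), 0.4)
    sk <- skeletonize_mask(m)
    expect_true(all(!sk | m))  # Sk(F) subset of F
  }
  line <- array(FALSE, c(30, 5, 5)); line[, 3, 3] <- TRUE
  expect_identical(skeletonize_mask(line), line)
  # a thick straight tube thins to a connected curve spanning z
  tube <- array(FALSE, c(20, 9, 9)); tube[, 3:7, 3:7] <- TRUE
  sk <- skeletonize_mask(tube)
  expect_true(all(apply(sk, 1, sum) >= 1))
  cc <- nervect:::.cc3d(sk, 26L)
  expect_equal(attr(cc, "n"), 1L)
})

test_that("clDice is 1 for identical masks, 0 for disjoint ones, and hand-countable on lines", {
  tube <- array(FALSE, c(16, 7, 7)); tube[, 3:5, 3:5] <- TRUE
  expect_equal(as.numeric(cldice(tube, tube)), 1)

  a <- array(FALSE, c(10, 8, 8)); a[, 2, 2] <- TRUE
  b <- array(FALSE, c(10, 8, 8)); b[, 6, 6] <- TRUE
  expect_equal(as.numeric(cldice(a, b)), 0)

  # prediction = the ground-truth line missing its middle third:
  # T_prec = 1 (P inside G), T_sens = 20/30
  g <- array(FALSE, c(30, 5, 5)); g[, 3, 3] <- TRUE
  p <- g; p[11:20, 3, 3] <- FALSE
  ts <- 20 / 30
  expect_equal(as.numeric(cldice(p, g)), 2 * 1 * ts / (1 + ts))

  expect_equal(as.numeric(cldice(a & FALSE, b & FALSE)), 1)
  expect_equal(as.numeric(cldice(a & FALSE, b)), 0)
})

test_that("anatomical error rate counts exposed fascicles and abrupt transitions", {
  ph <- default_phantom()
  expect_equal(anatomical_error_rate(ph$labels)$rate, 0)

  # a bare fascicle voxel among F foreground voxels
  labs <- array(0L, c(5, 9, 9))
  labs[, 3:7, 3:7] <- 2L
  labs[, 5, 5] <- 1L          # compliant tube
  labs[3, 1, 1] <- 1L         # exposed fascicle voxel
  res <- anatomical_error_rate(labs)
  n_fg <- sum(labs != 0L)
  expect_gte(res$rate, 1 / n_fg)
  expect_true(res$mask[3, 1, 1])
  # exact count: only the exposed voxel is anomalous here
  expect_equal(res$n_errors, 1L)

  # a one-slice fascicle plate sandwiched between epineurium slices
  labs2 <- array(2L, c(5, 6, 6))
  labs2[3, 2:5, 2:5] <- 1L
  res2 <- anatomical_error_rate(labs2)
  expect_true(all(res2$mask[3, 2:5, 2:5]))
  expect_equal(res2$n_errors, 16L)

  expect_error(anatomical_error_rate(array(0L, c(3, 3, 3))), "no foreground")
})

test_that("inter-slice BF score measures contour stability", {
  base <- matrix(0L, 16, 16); base[5:12, 5:12] <- 1L
  vol <- array(0L, c(4, 16, 16)); for (z in 1:4) vol[z, , ] <- base
  expect_equal(interslice_bf(vol, 1L)$mean_bf, 1)

  # contour shifted by 5 px between slices, tau = 1 -> that pair scores 0
  vol2 <- array(0L, c(2, 24, 24))
  vol2[1, 3:8, 3:8] <- 1L
  vol2[2, 14:19, 14:19] <- 1L
  expect_equal(interslice_bf(vol2, 1L)$mean_bf, 0)

  # contour shifted by 2 px: matches the exhaustive pixel-distance oracle
  vol3 <- array(0L, c(2, 16, 16))
  vol3[1, 5:12, 5:12] <- 1L
  vol3[2, 7:14, 5:12] <- 1L
  got <- interslice_bf(vol3, 1L)$mean_bf
  b0 <- nervect:::slice_contour(vol3[1, , ] == 1L)
  b1 <- nervect:::slice_contour(vol3[2, , ] == 1L)
  expect_equal(got, bf_bf_score(b0, b1, 1))
  expect_gt(got, 0); expect_lt(got, 1)

  expect_error(interslice_bf(vol3, 2L), "absent")
  expect_error(interslice_bf(vol3[1, , , drop = FALSE], 1L), "2 slices")
})

test_that("translation jitter strictly lowers the inter-slice BF score", {
  ph <- default_phantom()
  labs <- ph$labels$labels
  set.seed(25)
  jit <- labs
  for (z in seq_len(dim(labs)[1])) {
    dy <- sample(-2:2, 1); dx <- sample(-2:2, 1)
    sl <- matrix(0L, dim(labs)[2], dim(labs)[3])
    ys <- seq_len(dim(labs)[2]); xs <- seq_len(dim(labs)[3])
    ys_src <- ys - dy; xs_src <- xs - dx
    oky <- ys_src >= 1 & ys_src <= dim(labs)[2]
    okx <- xs_src >= 1 & xs_src <= dim(labs)[3]
    sl[ys[oky], xs[okx]] <- labs[z, ys_src[oky], xs_src[okx]]
    jit[z, , ] <- sl
  }
  expect_lt(interslice_bf(jit, 1L)$mean_bf, interslice_bf(labs, 1L)$mean_bf)
})

test_that("a hand-built Y junction is detected as exactly one split", {
  vol <- array(0L, c(6, 16, 16))
  for (z in 1:3) vol[z, 6:10, 6:10] <- 1L            # single square tube
  for (z in 4:6) {                                   # two children
    vol[z, 6:10, 4:7] <- 1L
    vol[z, 6:10, 9:12] <- 1L
  }
  tr <- detect_split_merge_events(vol, spacing_um = 11.4)
  expect_equal(tr$n_split, 1L)
  expect_equal(tr$n_merge, 0L)
  expect_equal(tr$events$z, 3)
  expect_equal(tr$length_mm, 6 * 11.4 / 1000)

  straight <- array(0L, c(6, 12, 12)); straight[, 4:8, 4:8] <- 1L
  tr0 <- detect_split_merge_events(straight, spacing_um = 11.4)
  expect_equal(tr0$n_split + tr0$n_merge, 0L)
})

test_that("phantom split/merge schedules are recovered exactly", {
  ph <- cached_phantom("events21", event_phantom_spec(21L, 2L, 1L))
  tr <- detect_split_merge_events(ph$labels)
  expect_equal(tr$n_split, 2L)
  expect_equal(tr$n_merge, 1L)
  # detected z within the junction neighbourhood of the scheduled z
  sched <- sort(ph$events$z_index)
  expect_equal(sort(tr$events$z), sched)
})

test_that("event-rate deviation is the mean absolute rate difference", {
  ph <- cached_phantom("events21", event_phantom_spec(21L, 2L, 1L))
  gt <- detect_split_merge_events(ph$labels)
  expect_equal(as.numeric(event_rate_deviation(gt, gt)), 0)

  # one extra split over 2 mm, merges equal: (0.5 + 0)/2
  mk_track <- function(ns, nm, L) {
    structure(list(events = tibble::tibble(), n_split = ns, n_merge = nm,
                   length_mm = L, r_split = ns / L, r_merge = nm / L),
              class = "event_track")
  }
  d <- event_rate_deviation(mk_track(3L, 2L, 2), mk_track(2L, 2L, 2))
  expect_equal(as.numeric(d), 0.25)
  # symmetric in the sign of the difference
  d2 <- event_rate_deviation(mk_track(1L, 2L, 2), mk_track(2L, 2L, 2))
  expect_equal(as.numeric(d2), 0.25)
  expect_equal(attr(d2, "pct"), 100 * 0.25 / 1)
  expect_error(event_rate_deviation(mk_track(1L, 1L, 2), mk_track(1L, 1L, 3)),
               "lengths differ")
})
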