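test_that("phantom generation is bit-identical under a fixed seed", {
  ph1 <- default_phantom()
  ph2 <- generate_phantom(phantom_spec(seed = 5L))
  expect_identical(ph1$labels$labels, ph2$labels$labels)
  expect_identical(ph1$image$data, ph2$image$data)
  expect_identical(ph1$events, ph2$events)

  tr1 <- build_centerline_tree(phantom_spec(seed = 9L))
  tr2 <- build_centerline_tree(phantom_spec(seed = 9L))
  expect_identical(tr1$tracks, tr2$tracks)
})

test_that("an event-free schedule yields full-length centerlines and an empty ledger", {
  spec <- phantom_spec(n_fascicles_initial = 3L, n_splits = 0L, n_merges = 0L, seed = 2L)
  tree <- build_centerline_tree(spec)
  expect_length(tree$tracks, 3L)
  expect_equal(nrow(tree$events), 0L)
  for (tr in tree$tracks) {
    expect_identical(c(tr$z0, tr$z1), c(1L, spec$shape[1]))
    expect_false(anyNA(tr$center[tr$z0:tr$z1, ]))
  }
})

test_that("the event ledger matches the schedule by construction", {
  spec <- event_phantom_spec(3L, n_splits = 2L, n_merges = 1L)
  tree <- build_centerline_tree(spec)
  expect_equal(sum(tree$events$kind == "split"), 2L)
  expect_equal(sum(tree$events$kind == "merge"), 1L)
  expect_true(all(diff(sort(tree$events$z_index)) >= 4))
})

test_that("infeasible packing fails with a bounded-retry error", {
  spec <- phantom_spec(n_fascicles_initial = 40L,
                       fascicle_radius_range_um = c(100, 110), seed = 1L)
  expect_error(build_centerline_tree(spec), "infeasible packing")
})

test_that("rasterized phantoms satisfy the anatomical constraints", {
  ph <- default_phantom()
  expect_equal(sum(critical_voxel_map(ph$labels)), 0L)
  expect_equal(anatomical_error_rate(ph$labels)$rate, 0)
  # ellipse smaller than the frame leaves background
  expect_gt(mean(ph$labels$labels == 0L), 0)
  expect_gt(sum(ph$labels$labels == 1L), 0)
})

test_that("a straight axial tube rasterizes to per-slice discs of area ~ pi r^2", {
  spec <- phantom_spec(n_fascicles_initial = 1L, n_splits = 0L, n_merges = 0L,
                       wobble_amplitude_um = 0, radius_wobble_frac = 0,
                       fascicle_radius_range_um = c(80, 80), seed = 3L)
  tree <- build_centerline_tree(spec)
  labs <- rasterize_phantom(tree, spec)
  r <- 80 / spec$spacing_um
  for (z in c(1L, 16L, 32L)) {
    inst <- extract_instances(labs, z)
    expect_equal(nrow(inst$instances), 1L)
    area_vox <- inst$instances$n_voxels
    # within one voxel-ring of the ideal disc area
    expect_lt(abs(area_vox - pi * r^2), 2 * pi * r + 2)
  }
})

test_that("rendered intensity is the class means when noise and bias are off", {
  spec <- phantom_spec(noise_sd = 0, bias_field_amplitude = 0, seed = 4L)
  ph <- generate_phantom(spec)
  img <- ph$image$data; labs <- ph$labels$labels
  expect_setequal(unique(as.vector(img)), c(2000L, 22000L, 12000L))
  expect_true(all(img[labs == 1L] == 22000L))
  expect_true(all(img[labs == 0L] == 2000L))
  expect_identical(generate_phantom(spec)$image$data, img)
})

test_that("per-class intensity histograms match the Gaussian noise model", {
  # class means far from the clip limits so sample moments are unbiased
  spec <- phantom_spec(intensity_means = c(background = 8000, fascicle = 22000,
                                           epineurium = 14000),
                       noise_sd = 1500, bias_field_amplitude = 0, seed = 6L)
  ph <- generate_phantom(spec)
  img <- ph$image$data; labs <- ph$labels$labels
  for (cls in 0:2) {
    v <- img[labs == cls]
    expect_gt(length(v), 1e4)
    mu <- c(8000, 22000, 14000)[cls + 1]
    expect_lt(abs(mean(v) - mu), 4 * 1500 / sqrt(length(v)) + 1)
    expect_lt(abs(stats::sd(v) - 1500), 0.05 * 1500)
  }
})

test_that("phantoms spanning the four size bins produce areas in each bin", {
  # narrow radius ranges aimed at each bin center (caliber wobble off)
  cases <- list(
    list(r = c(55, 65), bin = "tiny", frame = 64L, semi = 300),
    list(r = c(115, 130), bin = "small", frame = 96L, semi = 450),
    list(r = c(210, 230), bin = "medium", frame = 128L, semi = 600),
    list(r = c(330, 350), bin = "large", frame = 192L, semi = 900))
  bins <- size_bins()
  for (cs in cases) {
    spec <- phantom_spec(shape = c(8L, cs$frame, cs$frame),
                         n_fascicles_initial = 1L, n_splits = 0L, n_merges = 0L,
                         fascicle_radius_range_um = cs$r,
                         nerve_ellipse_semiaxes_um = c(cs$semi, cs$semi),
                         radius_wobble_frac = 0, seed = 8L)
    ph <- generate_phantom(spec)
    inst <- extract_instances(ph$labels, 4L)
    expect_equal(unname(bin_of_area(inst$instances$area_mm2, bins)), cs$bin)
  }
})

test_that("default-scale phantom generation is fast enough for interactive use", {
  t0 <- Sys.time()
  generate_phantom(phantom_spec(shape = c(32L, 128L, 128L), seed = 77L))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
})

test_that("phantom_spec rejects inconsistent geometry and schedules", {
  expect_error(phantom_spec(n_fascicles_initial = 2L, n_splits = 1L, n_merges = 1L),
               "n_fascicles_initial")
  expect_error(phantom_spec(fascicle_radius_range_um = c(400, 700)), "cannot fit")
  expect_error(phantom_spec(shape = c(6L, 128L, 128L), n_splits = 1L), "too short")
})
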