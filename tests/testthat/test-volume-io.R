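test_that("TIFF stacks round-trip integer volumes bit-exactly with (z, y, x) axis order", {
  set.seed(1)
  arr <- array(sample.int(32767L, 4 * 8 * 8, replace = TRUE), dim = c(4, 8, 8))
  v <- intensity_volume(arr)
  path <- tempfile(fileext = ".tif")
  save_volume(v, path, "tiff-stack")
  back <- load_volume(path, "tiff-stack", type = "intensity")
  expect_identical(back$data, arr)

  # a tall multi-page stack keeps pages as z and (y, x) in-plane
  arr2 <- array(0L, dim = c(64, 24, 48))
  arr2[10, 3, 40] <- 1234L
  path2 <- tempfile(fileext = ".tif")
  save_volume(intensity_volume(arr2), path2, "tiff-stack")
  back2 <- load_volume(path2, "tiff-stack")
  expect_identical(dim(back2$data), c(64L, 24L, 48L))
  expect_identical(back2$data[10, 3, 40], 1234L)
})

test_that("label volumes round-trip as 8-bit TIFF and out-of-range labels are rejected", {
  labs <- array(sample(0:2, 3 * 6 * 6, replace = TRUE), dim = c(3, 6, 6))
  lv <- label_volume(labs)
  path <- tempfile(fileext = ".tif")
  save_volume(lv, path, "tiff-stack")
  back <- load_volume(path, "tiff-stack", type = "label")
  expect_identical(back$labels, lv$labels)

  bad <- array(0L, dim = c(2, 4, 4)); bad[1, 1, 1] <- 3L
  path_bad <- tempfile(fileext = ".tif")
  nervect:::write_tiff_stack(bad, path_bad, bits = 8L)
  expect_error(load_volume(path_bad, "tiff-stack", type = "label"),
               "outside \\{0, 1, 2\\}")
})

test_that("OME-Zarr round-trips signed 16-bit volumes, TIFF rejects negatives", {
  set.seed(2)
  arr <- array(as.integer(sample(-32768:32767, 5 * 7 * 9, replace = TRUE)),
               dim = c(5, 7, 9))
  v <- intensity_volume(arr)
  zdir <- tempfile("zarr")
  save_volume(v, zdir, "ome-zarr")
  back <- load_volume(zdir, "ome-zarr", type = "intensity")
  expect_identical(back$data, arr)
  expect_true(file.exists(file.path(zdir, ".zattrs")))  # OME multiscales group

  expect_error(save_volume(v, tempfile(fileext = ".tif"), "tiff-stack"),
               "negative")

  labs <- label_volume(array(sample(0:2, 4 * 4 * 4, TRUE), dim = c(4, 4, 4)))
  zdir2 <- tempfile("zarr")
  save_volume(labs, zdir2, "ome-zarr")
  expect_identical(load_volume(zdir2, type = "label")$labels, labs$labels)
})

test_that("missing files and unwritable destinations raise errors", {
  expect_error(load_volume(tempfile(), "tiff-stack"), "no such file")
  blocker <- tempfile(); writeLines("x", blocker)
  v <- intensity_volume(array(0L, dim = c(2, 2, 2)))
  expect_error(save_volume(v, file.path(blocker, "out.tif"), "tiff-stack"))
  expect_error(save_volume(v, file.path(blocker, "z"), "ome-zarr"))
})

test_that("normalize_intensity clips to [0, 32767] and rescales to the unit interval", {
  vals <- c(-500, 0, 16384, 32767, 40000)
  out <- normalize_intensity(array(vals, c(5, 1, 1)))[, 1, 1]
  expect_equal(out, c(0, 0, 16384 / 32767, 1, 1))
  expect_true(all(out >= 0 & out <= 1))

  # idempotent up to the rescale
  set.seed(3)
  arr <- array(sample(-1000:40000, 200), dim = c(8, 5, 5))
  n1 <- normalize_intensity(arr)
  n2 <- normalize_intensity(array(round(n1 * 32767), dim = dim(arr)))
  expect_equal(n2, n1, tolerance = 1 / 32767)
})

test_that("combine_labels applies the fascicle-overwrites-epineurium rule", {
  f <- array(FALSE, c(2, 3, 3)); e <- array(FALSE, c(2, 3, 3))
  f[1, 1, 1] <- TRUE; e[1, 1, 1] <- TRUE   # both -> fascicle
  e[1, 2, 2] <- TRUE                       # only epineurium
  out <- combine_labels(f, e)
  expect_identical(out$labels[1, 1, 1], 1L)
  expect_identical(out$labels[1, 2, 2], 2L)
  expect_identical(out$labels[2, 3, 3], 0L)
  expect_error(combine_labels(f, array(FALSE, c(2, 3, 4))), "differ")

  # fascicle voxels in the output iff in the fascicle mask
  set.seed(4)
  f2 <- rand_mask(c(4, 6, 6), 0.4); e2 <- rand_mask(c(4, 6, 6), 0.4)
  out2 <- combine_labels(f2, e2)
  expect_identical(out2$labels == 1L, f2)
})

test_that("volume constructors enforce their invariants", {
  expect_error(intensity_volume(array(0, c(2, 2))), "3D")
  expect_error(intensity_volume(array(0, c(2, 2, 2)), spacing_um = -1), "positive")
  expect_error(label_volume(array(5L, c(2, 2, 2))), "outside")
})
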