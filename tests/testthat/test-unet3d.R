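test_that("architecture stride arithmetic matches the full-scale configuration", {
  cfg <- paper_arch_config()
  cum <- nervect:::cumulative_strides(cfg)
  # total downsampling z/16, y/64, x/64; bottleneck of a 32 x 256 x 256 patch
  expect_equal(cum[cfg$n_stages, ], c(16L, 64L, 64L))
  expect_equal(c(32, 256, 256) / cum[cfg$n_stages, ], c(2, 4, 4))
  # encoder stage i extent = input / cumulative stride through stage i
  for (i in seq_len(cfg$n_stages))
    expect_equal(c(32, 256, 256) %% cum[i, ], c(0, 0, 0))
  expect_error(nervect:::check_divisible(c(30, 256, 256), cfg), "not divisible")
})

test_that("a network maps (z,y,x,1) input to (z,y,x,n_classes) scores with the right bottleneck", {
  cfg <- scaled_arch_config()  # strides (1,1,1),(2,2,2),(2,2,2),(1,2,2)
  net <- build_network(cfg, seed = 1)
  x <- array(stats::runif(16 * 64 * 64), c(16, 64, 64, 1))
  fw <- nervect:::forward_unet(net, x, keep_cache = TRUE)
  expect_equal(dim(fw$logits), c(16L, 64L, 64L, 3L))
  # bottleneck = deepest encoder output: 16/4 x 64/8 x 64/8
  bottleneck <- fw$cache[["enc4"]]$b$nrm$y
  expect_equal(dim(bottleneck)[1:3], c(4L, 8L, 8L))
  expect_error(nervect:::forward_unet(net, array(0, c(15, 64, 64, 1))),
               "not divisible")
})

test_that("poly learning-rate schedule follows lr0 (1 - e/e_max)^0.9", {
  cfg <- training_config()
  expect_equal(poly_lr(0, cfg), 0.01)
  expect_equal(poly_lr(499, cfg), 0.01 * (1 / 500)^0.9)
  lr <- poly_lr(0:499, cfg)
  expect_true(all(diff(lr) < 0))
  expect_error(poly_lr(500, cfg), "e < e_max")
  expect_error(poly_lr(-1, cfg), "e < e_max")
})

test_that("patch sampling honours the foreground fraction and is seeded", {
  ph <- cached_phantom("train1", train_phantom_spec(31L))
  cfg <- scaled_training_config(patch_size = tiny_patch, seed = 1L,
                                foreground_patch_fraction = 0.33)
  set.seed(42)
  draws <- sample_training_patches(list(ph), cfg, n = 200)
  has_fg <- vapply(draws, function(d) any(d$lab != 0L), TRUE)
  # at least the forced fraction, within binomial 3 sigma
  expect_gte(mean(has_fg), 0.33 - 3 * sqrt(0.33 * 0.67 / 200))

  set.seed(7); a <- sample_training_patches(list(ph), cfg, n = 5)
  set.seed(7); b <- sample_training_patches(list(ph), cfg, n = 5)
  expect_identical(a, b)

  # degenerate all-background corpus: forcing foreground must fail
  empty <- list(image = array(0L, c(8, 48, 48)), labels = array(0L, c(8, 48, 48)))
  cfg_all_fg <- scaled_training_config(patch_size = tiny_patch,
                                       foreground_patch_fraction = 1)
  set.seed(1)
  expect_error(sample_training_patches(list(empty), cfg_all_fg, n = 5),
               "no foreground")
})

test_that("slice rotation preserves dimensions, labels and the zero-angle identity", {
  set.seed(16)
  img <- array(stats::runif(6 * 20 * 20), c(6, 20, 20))
  lab <- array(sample(0:2, 6 * 20 * 20, TRUE), c(6, 20, 20))
  expect_equal(nervect:::rotate_slices(img, 0, "bilinear"), img, tolerance = 1e-12)
  rot <- nervect:::rotate_slices(lab, 12, "nearest", fill = 0L)
  expect_identical(dim(rot), dim(lab))
  expect_true(all(rot %in% 0:2))
})

test_that("training runs are deterministic and the topology term is the only ablation difference", {
  phs <- lapply(41:42, function(s) cached_phantom(paste0("t", s), train_phantom_spec(s)))
  arch <- tiny_arch()
  cfg <- scaled_training_config(patch_size = tiny_patch, batch_size = 2L,
                                epochs = 2L, iters_per_epoch = 2L,
                                val_patches_per_epoch = 2L, seed = 3L)
  m1 <- train_model(phs[1], phs[2], arch, cfg, augmentation_config(),
                    scaled_loss_config(tiny_patch))
  m2 <- train_model(phs[1], phs[2], arch, cfg, augmentation_config(),
                    scaled_loss_config(tiny_patch))
  expect_identical(m1$log, m2$log)
  expect_identical(m1$net$params, m2$net$params)
  expect_equal(nrow(m1$log), 2L)
  expect_true(all(is.finite(m1$log$total)))

  # lambda = 0 with the topo branch active consumes the same RNG stream as
  # the ablation, so the conventional loss terms match bitwise
  mz <- train_model(phs[1], phs[2], arch, cfg, augmentation_config(),
                    loss_config(lambda_topo = 0))
  ma <- train_model(phs[1], phs[2], arch, cfg, augmentation_config(),
                    loss_config(use_topo = FALSE))
  expect_identical(mz$log$l_ce, ma$log$l_ce)
  expect_identical(mz$log$l_dice, ma$log$l_dice)
  expect_identical(mz$net$params, ma$net$params)
})

test_that("a short training run reduces the Dice loss", {
  phs <- lapply(41:42, function(s) cached_phantom(paste0("t", s), train_phantom_spec(s)))
  cfg <- scaled_training_config(patch_size = tiny_patch, batch_size = 2L,
                                epochs = 8L, iters_per_epoch = 4L,
                                val_patches_per_epoch = 0L, seed = 5L)
  m <- train_model(phs[1], phs[2], tiny_arch(), cfg, augmentation_config(),
                   scaled_loss_config(tiny_patch))
  expect_lt(m$log$l_dice[8], m$log$l_dice[1])
  gl <- glance(m)
  expect_equal(gl$epochs, 8L)
  expect_true(gl$use_topo)
})
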