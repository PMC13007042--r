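test_that("critical_voxel_map flags exactly the 26-adjacent fascicle/background pairs", {
  # compliant geometry: fascicle cube wrapped in a one-voxel epineurium shell
  labs <- array(0L, c(7, 7, 7))
  labs[2:6, 2:6, 2:6] <- 2L
  labs[3:5, 3:5, 3:5] <- 1L
  expect_equal(sum(critical_voxel_map(labs)), 0L)

  # single fascicle voxel diagonally adjacent to background: both flagged
  labs2 <- array(2L, c(3, 3, 3))
  labs2[1, 1, 1] <- 0L
  labs2[2, 2, 2] <- 1L
  v <- critical_voxel_map(labs2)
  expect_true(v[1, 1, 1] && v[2, 2, 2])
  expect_equal(sum(v), 2L)

  # no fascicle voxels: vacuously empty
  labs3 <- array(sample(c(0L, 2L), 4^3, TRUE), c(4, 4, 4))
  expect_equal(sum(critical_voxel_map(labs3)), 0L)

  expect_error(critical_voxel_map(array(3L, c(2, 2, 2))), "outside")
})

test_that("critical_voxel_map agrees with an exhaustive 26-neighbor scan", {
  set.seed(11)
  for (i in 1:25) {
    labs <- rand_labels(c(8, 8, 8))
    expect_identical(critical_voxel_map(labs), bf_critical(labs),
                     info = paste("random volume", i))
  }
})

test_that("soft Dice loss matches direct-sum evaluation and its limits", {
  cfg <- loss_config()
  # perfect one-hot prediction: loss at the smoothing order
  g <- one_hot(array(c(rep(0L, 9), rep(1L, 9), rep(2L, 9)), c(3, 3, 3)))
  expect_lt(dice_loss(g, g, cfg), 1e-4)

  # uniform prediction vs a label grid with every class present
  set.seed(12)
  labs <- rand_labels(c(3, 3, 3))
  labs[1:3] <- 0:2  # guarantee presence
  g2 <- one_hot(labs)
  p_unif <- array(1 / 3, dim = c(3, 3, 3, 3))
  manual <- mean(sapply(2:3, function(c) {
    pc <- p_unif[, , , c]; gc <- g2[, , , c]
    1 - (2 * sum(pc * gc) + cfg$dice_smooth) / (sum(pc) + sum(gc) + cfg$dice_smooth)
  }))
  expect_equal(dice_loss(p_unif, g2, cfg), manual)

  # fully disjoint foreground: loss ~ 1
  labs_a <- array(1L, c(2, 2, 2)); labs_b <- array(2L, c(2, 2, 2))
  expect_gt(dice_loss(one_hot(labs_a), one_hot(labs_b), cfg), 0.999)

  expect_error(dice_loss(p_unif, g2[, , 1:2, , drop = FALSE]), "differ")
})

test_that("topology loss is the cross-entropy restricted to the critical map", {
  set.seed(13)
  labs <- rand_labels(c(3, 3, 3))
  g <- one_hot(labs)
  p <- array(stats::runif(27 * 3, 0.1, 1), c(3, 3, 3, 3))
  p <- p / as.vector(p[, , , 1] + p[, , , 2] + p[, , , 3])

  v_empty <- array(FALSE, c(3, 3, 3))
  expect_identical(topology_loss(p, g, v_empty), 0)

  v_all <- array(TRUE, c(3, 3, 3))
  expect_equal(topology_loss(p, g, v_all, loss_config(topo_normalize = "all")),
               cross_entropy(p, g))
  expect_equal(topology_loss(p, g, v_all, loss_config(topo_normalize = "critical")),
               cross_entropy(p, g))

  # single flagged voxel with p(correct class) = 0.5, averaged over flagged
  p1 <- array(0, c(1, 1, 1, 3)); p1[1, 1, 1, ] <- c(0.5, 0.3, 0.2)
  g1 <- array(0, c(1, 1, 1, 3)); g1[1, 1, 1, 1] <- 1
  v1 <- array(TRUE, c(1, 1, 1))
  expect_equal(topology_loss(p1, g1, v1, loss_config(topo_normalize = "critical")),
               -log(0.5))
})

test_that("the compound loss decomposes exactly and the ablation switch works", {
  # compliant argmax prediction: V empty so total == L_CE + L_Dice
  ph_labs <- default_phantom()$labels$labels[1:8, 1:32, 1:32]
  g <- one_hot(ph_labs)
  p <- 0.9 * g + 0.1 / 3  # soft but argmax-compliant
  out <- compound_loss(p, g, loss_config())
  expect_identical(out$l_topo, 0)
  expect_equal(out$total, out$l_ce + out$l_dice)

  # lambda 0 equals the ablation total
  set.seed(14)
  labs <- rand_labels(c(4, 4, 4))
  gr <- one_hot(labs)
  pr <- array(stats::runif(64 * 3, 0.05, 1), c(4, 4, 4, 3))
  pr <- pr / as.vector(pr[, , , 1] + pr[, , , 2] + pr[, , , 3])
  expect_equal(compound_loss(pr, gr, loss_config(lambda_topo = 0))$total,
               compound_loss(pr, gr, loss_config(use_topo = FALSE))$total)

  # violating prediction: total - (ce + dice) == lambda * topo
  out2 <- compound_loss(pr, gr, loss_config(lambda_topo = 1e6))
  expect_gt(out2$n_critical, 0)
  expect_equal(out2$total - (out2$l_ce + out2$l_dice), 1e6 * out2$l_topo)
})

test_that("adding a violating fascicle voxel strictly increases the topology loss", {
  labs <- array(0L, c(5, 7, 7))
  labs[, 3:5, 3:5] <- 2L
  labs[, 4, 4] <- 1L           # compliant tube
  g <- one_hot(labs)
  mk_p <- function(lab_arr) 0.9 * one_hot(lab_arr) + 0.1 / 3
  base <- compound_loss(mk_p(labs), g, loss_config())
  expect_identical(base$l_topo, 0)
  labs_bad <- labs
  labs_bad[3, 1, 1] <- 1L      # bare fascicle voxel in background
  worse <- compound_loss(mk_p(labs_bad), g, loss_config())
  expect_gt(worse$l_topo, base$l_topo)
})

test_that("analytic loss gradients match finite differences", {
  ns <- asNamespace("nervect")
  set.seed(15)
  labs <- rand_labels(c(3, 4, 4))
  g <- one_hot(labs)
  logits <- array(stats::rnorm(48 * 3), c(3, 4, 4, 3))
  for (cfg in list(loss_config(use_topo = FALSE),
                   loss_config(lambda_topo = 5, topo_normalize = "all"),
                   loss_config(lambda_topo = 2, topo_normalize = "critical"))) {
    lg <- ns$loss_grad_logits(logits, g, cfg)
    idx <- sample(length(logits), 8)
    for (i in idx) {
      e <- 1e-6
      l1 <- logits; l1[i] <- logits[i] + e
      l2 <- logits; l2[i] <- logits[i] - e
      num <- (ns$loss_grad_logits(l1, g, cfg)$components$total -
                ns$loss_grad_logits(l2, g, cfg)$components$total) / (2 * e)
      expect_lt(abs(num - lg$grad[i]), 1e-5 * max(1, abs(num)))
    }
  }
})
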