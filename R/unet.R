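#' Network architecture configuration
#'
#' Describes an encoder-decoder 3D U-Net: per-stage feature widths and
#' downsampling strides, two 3x3x3 convolutions per stage, instance
#' normalization and leaky ReLU throughout, no dropout. The decoder mirrors
#' the encoder with skip connections at matching stages and transposed
#' convolutions (kernel = stride) for upsampling.
#'
#' @param n_stages Number of encoder stages.
#' @param features_per_stage Integer vector of feature widths, one per stage.
#' @param strides_per_stage List of `(z, y, x)` stride triples; the first
#'   stage keeps full resolution.
#' @param kernel Convolution kernel size (fixed 3x3x3).
#' @param n_classes Output classes (background, fascicle, epineurium).
#' @param in_channels Input channels (single-channel grayscale).
#' @return An object of class `arch_config`.
#' @seealso [paper_arch_config()], [scaled_arch_config()]
#' @export
arch_config <- function(n_stages, features_per_stage, strides_per_stage,
                        kernel = c(3L, 3L, 3L), n_classes = 3L, in_channels = 1L) {
  if (length(features_per_stage) != n_stages || length(strides_per_stage) != n_stages)
    stop("features and strides must both have length n_stages")
  if (any(vapply(strides_per_stage, length, 0L) != 3L))
    stop("each stride must be a (z, y, x) triple")
  structure(list(n_stages = as.integer(n_stages),
                 features = as.integer(features_per_stage),
                 strides = lapply(strides_per_stage, as.integer),
                 kernel = as.integer(kernel), n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "arch_config")
}

#' Full-scale architecture
#'
#' The 7-stage configuration used on real microCT volumes: features
#' 32, 64, 128, 256, 320, 320, 320; strides (1,1,1), then (2,2,2) for stages
#' 2-5 and (1,2,2) for stages 6-7 (total downsampling z/16, y/64, x/64).
#' GPU-scale; see [scaled_arch_config()] for the desk default.
#' @return An `arch_config`.
#' @export
paper_arch_config <- function() {
  arch_config(7L, c(32L, 64L, 128L, 256L, 320L, 320L, 320L),
              list(c(1, 1, 1), c(2, 2, 2), c(2, 2, 2), c(2, 2, 2), c(2, 2, 2),
                   c(1, 2, 2), c(1, 2, 2)))
}

#' Desk-scale architecture
#'
#' A 4-stage network (features 8, 16, 32, 64) sized for CPU training on
#' phantoms with 16 x 64 x 64 patches.
#' @return An `arch_config`.
#' @export
scaled_arch_config <- function() {
  arch_config(4L, c(8L, 16L, 32L, 64L),
              list(c(1, 1, 1), c(2, 2, 2), c(2, 2, 2), c(1, 2, 2)))
}

# Cumulative stride product per axis through stage i.
cumulative_strides <- function(cfg) {
  out <- matrix(1L, cfg$n_stages, 3)
  acc <- c(1L, 1L, 1L)
  for (i in seq_len(cfg$n_stages)) {
    acc <- acc * cfg$strides[[i]]
    out[i, ] <- acc
  }
  out
}

#' Build (initialize) a segmentation network
#'
#' Allocates He-initialized convolution weights, unit-gamma instance-norm
#' parameters and zero biases for the configured U-Net. The returned network
#' maps a `(z, y, x, 1)` input to `(z, y, x, n_classes)` class scores;
#' spatial dimensions must be divisible by the total stride product.
#'
#' @param cfg An [arch_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `nervect_net` (parameter list + config).
#' @export
build_network <- function(cfg = scaled_arch_config(), seed = 1L) {
  with_seed(seed, {
    k <- prod(cfg$kernel)
    he <- function(fan_in, nrow, ncol) matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
    params <- list()
    add_conv <- function(name, cin, cout, ksz = k) {
      params[[paste0(name, "_w")]] <<- he(ksz * cin, ksz * cin, cout)
      params[[paste0(name, "_b")]] <<- rep(0, cout)
      params[[paste0(name, "_g")]] <<- rep(1, cout)
      params[[paste0(name, "_be")]] <<- rep(0, cout)
    }
    ch <- cfg$in_channels
    for (i in seq_len(cfg$n_stages)) {
      f <- cfg$features[i]
      add_conv(sprintf("enc%da", i), ch, f)
      add_conv(sprintf("enc%db", i), f, f)
      ch <- f
    }
    for (i in seq.int(cfg$n_stages - 1L, 1L)) {
      f <- cfg$features[i]
      s <- prod(cfg$strides[[i + 1]])
      params[[sprintf("up%d_w", i)]] <- he(cfg$features[i + 1], s * cfg$features[i + 1], f)
      params[[sprintf("up%d_b", i)]] <- rep(0, f)
      add_conv(sprintf("dec%da", i), 2L * f, f)
      add_conv(sprintf("dec%db", i), f, f)
    }
    params[["head_w"]] <- he(cfg$features[1], cfg$features[1], cfg$n_classes)
    params[["head_b"]] <- rep(0, cfg$n_classes)
    structure(list(params = params, cfg = cfg, seed = seed), class = "nervect_net")
  })
}

#' @export
print.nervect_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<nervect_net> %d-stage 3D U-Net, features %s, %s parameters\n",
              x$cfg$n_stages, paste(x$cfg$features, collapse = "/"),
              format(np, big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------- layers

lrelu_slope <- 0.01
in_eps <- 1e-5

conv_block_forward <- function(x, params, name, stride, kernel) {
  w <- params[[paste0(name, "_w")]]
  y <- .conv3d_forward(x, w, params[[paste0(name, "_b")]], kernel, stride, c(1L, 1L, 1L))
  nrm <- .in_lrelu_forward(y, params[[paste0(name, "_g")]], params[[paste0(name, "_be")]],
                           lrelu_slope, in_eps)
  list(y = nrm$y, cache = list(x = x, nrm = nrm, stride = stride, name = name))
}

conv_block_backward <- function(gy, cache, params, kernel, grads) {
  name <- cache$name
  nb <- .in_lrelu_backward(gy, cache$nrm$y, cache$nrm$xhat, cache$nrm$inv_std,
                           params[[paste0(name, "_g")]], lrelu_slope)
  cb <- .conv3d_backward(cache$x, params[[paste0(name, "_w")]], nb$gx, kernel,
                         cache$stride, c(1L, 1L, 1L))
  grads[[paste0(name, "_w")]] <- grads[[paste0(name, "_w")]] + cb$gw
  grads[[paste0(name, "_b")]] <- grads[[paste0(name, "_b")]] + cb$gb
  grads[[paste0(name, "_g")]] <- grads[[paste0(name, "_g")]] + nb$ggamma
  grads[[paste0(name, "_be")]] <- grads[[paste0(name, "_be")]] + nb$gbeta
  list(gx = cb$gx, grads = grads)
}

check_divisible <- function(dims, cfg) {
  tot <- cumulative_strides(cfg)[cfg$n_stages, ]
  if (any(dims %% tot != 0))
    stop(sprintf("input %s not divisible by total stride %s",
                 paste(dims, collapse = "x"), paste(tot, collapse = "x")))
}

# Forward pass for one sample. x: (z,y,x,in_channels). Returns logits and,
# if keep_cache, everything backward needs.
forward_unet <- function(net, x, keep_cache = FALSE) {
  cfg <- net$cfg; p <- net$params; kern <- cfg$kernel
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  check_divisible(dim(x)[1:3], cfg)
  skips <- vector("list", cfg$n_stages)
  caches <- list()
  cur <- x
  for (i in seq_len(cfg$n_stages)) {
    ba <- conv_block_forward(cur, p, sprintf("enc%da", i), cfg$strides[[i]], kern)
    bb <- conv_block_forward(ba$y, p, sprintf("enc%db", i), c(1L, 1L, 1L), kern)
    skips[[i]] <- bb$y
    if (keep_cache) caches[[sprintf("enc%d", i)]] <- list(a = ba$cache, b = bb$cache)
    cur <- bb$y
  }
  for (i in seq.int(cfg$n_stages - 1L, 1L)) {
    up <- .convtr3d_forward(cur, p[[sprintf("up%d_w", i)]], p[[sprintf("up%d_b", i)]],
                            cfg$strides[[i + 1]])
    cat_in <- array(c(up, skips[[i]]), dim = c(dim(up)[1:3], dim(up)[4] + dim(skips[[i]])[4]))
    da <- conv_block_forward(cat_in, p, sprintf("dec%da", i), c(1L, 1L, 1L), kern)
    db <- conv_block_forward(da$y, p, sprintf("dec%db", i), c(1L, 1L, 1L), kern)
    if (keep_cache)
      caches[[sprintf("dec%d", i)]] <- list(up_in = cur, a = da$cache, b = db$cache,
                                            n_up = dim(up)[4])
    cur <- db$y
  }
  logits <- .conv3d_forward(cur, p[["head_w"]], p[["head_b"]],
                            c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  if (keep_cache) caches[["head_in"]] <- cur
  list(logits = logits, cache = if (keep_cache) caches else NULL)
}

backward_unet <- function(net, cache, glogits) {
  cfg <- net$cfg; p <- net$params; kern <- cfg$kernel
  S <- cfg$n_stages
  grads <- lapply(p, function(q) if (is.matrix(q)) matrix(0, nrow(q), ncol(q)) else numeric(length(q)))
  hb <- .conv3d_backward(cache[["head_in"]], p[["head_w"]], glogits,
                         c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  grads[["head_w"]] <- hb$gw
  grads[["head_b"]] <- hb$gb

  # Decoder, shallowest stage first. `gcur` is the gradient with respect to
  # the decoder output at stage i (stage 1 = network head input); after the
  # loop it holds the gradient at the bottleneck encoder output skips[[S]].
  gcur <- hb$gx
  gskip <- vector("list", S)  # gradient flowing into each encoder skip
  for (i in seq_len(S - 1L)) {
    dc <- cache[[sprintf("dec%d", i)]]
    r <- conv_block_backward(gcur, dc$b, p, kern, grads); grads <- r$grads
    r <- conv_block_backward(r$gx, dc$a, p, kern, grads); grads <- r$grads
    g_cat <- r$gx
    n_up <- dc$n_up
    g_up <- g_cat[, , , seq_len(n_up), drop = FALSE]
    gskip[[i]] <- g_cat[, , , seq.int(n_up + 1L, dim(g_cat)[4]), drop = FALSE]
    ub <- .convtr3d_backward(dc$up_in, p[[sprintf("up%d_w", i)]], g_up, cfg$strides[[i + 1]])
    grads[[sprintf("up%d_w", i)]] <- ub$gw
    grads[[sprintf("up%d_b", i)]] <- ub$gb
    gcur <- ub$gx
  }

  # Encoder, deepest stage first. skips[[i]] feeds both the concat at
  # decoder stage i (gskip) and, for i < S, the next encoder stage (gcur).
  for (i in seq.int(S, 1L)) {
    g_out <- if (i == S) gcur else gcur + gskip[[i]]
    ec <- cache[[sprintf("enc%d", i)]]
    r <- conv_block_backward(g_out, ec$b, p, kern, grads); grads <- r$grads
    r <- conv_block_backward(r$gx, ec$a, p, kern, grads); grads <- r$grads
    gcur <- r$gx
  }
  grads
}

#' Polynomial learning-rate schedule
#'
#' \eqn{lr(e) = lr_0 (1 - e/e_{max})^{0.9}}: strictly decreasing from
#' `lr0` at epoch 0.
#'
#' @param e Zero-based epoch index, `0 <= e < e_max`.
#' @param cfg A [training_config()] (uses `lr0`, `epochs`, `poly_exponent`).
#' @return The learning rate for epoch `e`.
#' @examples
#' poly_lr(0, training_config())
#' @export
poly_lr <- function(e, cfg = training_config()) {
  if (any(e < 0) || any(e >= cfg$epochs)) stop("epoch index must satisfy 0 <= e < e_max")
  cfg$lr0 * (1 - e / cfg$epochs)^cfg$poly_exponent
}

#' Training configuration
#'
#' Defaults reproduce the full-scale protocol: 32 x 256 x 256 patches, batch
#' 4, 500 epochs of 250 mini-batch iterations, 33% foreground-guaranteed
#' patch sampling, SGD with Nesterov momentum 0.99, initial learning rate
#' 0.01 with polynomial (0.9) decay, and 50 validation patches per epoch.
#' Gradient norms are clipped at 12, the fixed protocol of the training
#' framework the recipe follows.
#'
#' @param patch_size `(z, y, x)` patch in voxels.
#' @param batch_size Patches per mini-batch.
#' @param epochs Total epochs `e_max`.
#' @param iters_per_epoch Mini-batch iterations per epoch.
#' @param foreground_patch_fraction Fraction of patches forced to contain at
#'   least one foreground voxel.
#' @param momentum Nesterov momentum.
#' @param lr0 Initial learning rate.
#' @param poly_exponent Polynomial decay exponent.
#' @param val_patches_per_epoch Patches drawn from the validation volumes for
#'   in-training validation (patches, not full volumes).
#' @param grad_clip_norm Global gradient-norm ceiling (`Inf` disables).
#' @param seed Seed covering initialization, sampling and augmentation.
#' @return An object of class `training_config`.
#' @seealso [scaled_training_config()]
#' @export
training_config <- function(patch_size = c(32L, 256L, 256L), batch_size = 4L,
                            epochs = 500L, iters_per_epoch = 250L,
                            foreground_patch_fraction = 0.33, momentum = 0.99,
                            lr0 = 0.01, poly_exponent = 0.9,
                            val_patches_per_epoch = 50L, grad_clip_norm = 12,
                            seed = 1L) {
  if (foreground_patch_fraction < 0 || foreground_patch_fraction > 1)
    stop("`foreground_patch_fraction` must lie in [0, 1]")
  if (lr0 <= 0) stop("`lr0` must be positive")
  structure(list(patch_size = as.integer(patch_size), batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), iters_per_epoch = as.integer(iters_per_epoch),
                 foreground_patch_fraction = foreground_patch_fraction,
                 momentum = momentum, lr0 = lr0, poly_exponent = poly_exponent,
                 val_patches_per_epoch = as.integer(val_patches_per_epoch),
                 grad_clip_norm = grad_clip_norm, seed = as.integer(seed)),
            class = "training_config")
}

#' Desk-scale training configuration
#'
#' 16 x 64 x 64 patches, batch 2, 30 epochs of 6 iterations, 8 validation
#' patches per epoch: a CPU-sized run for phantom corpora.
#' @param ... Overrides passed to [training_config()].
#' @return A `training_config`.
#' @export
scaled_training_config <- function(...) {
  args <- list(patch_size = c(16L, 64L, 64L), batch_size = 2L, epochs = 30L,
               iters_per_epoch = 6L, val_patches_per_epoch = 8L)
  do.call(training_config, utils::modifyList(args, list(...)))
}

#' Augmentation configuration
#'
#' The three augmentation families of the training protocol: random rotation
#' about the z axis, additive Gaussian noise, and contrast scaling, each
#' applied independently with its own probability.
#'
#' @param rotate `list(p, max_deg)`.
#' @param noise `list(p, sd)` (sd as a fraction of the unit dynamic range).
#' @param contrast `list(p, range)`.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotate = list(p = 0.2, max_deg = 15),
                                noise = list(p = 0.2, sd = 0.1),
                                contrast = list(p = 0.2, range = c(0.75, 1.25))) {
  probs <- c(rotate$p, noise$p, contrast$p)
  if (any(probs < 0 | probs > 1)) stop("augmentation probabilities must lie in [0, 1]")
  structure(list(rotate = rotate, noise = noise, contrast = contrast),
            class = "augmentation_config")
}

# Rotate every z-slice of a (z,y,x) array about the slice center.
rotate_slices <- function(arr, angle_deg, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  d <- dim(arr)
  ny <- d[2]; nx <- d[3]
  th <- angle_deg * pi / 180
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  gy <- rep(seq_len(ny), times = nx) - cy
  gx <- rep(seq_len(nx), each = ny) - cx
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  out <- array(fill, dim = d)
  if (interp == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= ny & rx >= 1 & rx <= nx
    idx <- (rx[ok] - 1L) * ny + ry[ok]
    for (z in seq_len(d[1])) {
      sl <- matrix(fill, ny, nx)
      sl[ok] <- as.vector(arr[z, , ])[idx]
      out[z, , ] <- sl
    }
  } else {
    ok <- sy >= 1 & sy <= ny & sx >= 1 & sx <= nx
    y0 <- pmin(floor(sy), ny - 1); x0 <- pmin(floor(sx), nx - 1)
    fy <- sy - y0; fx <- sx - x0
    i00 <- (x0[ok] - 1L) * ny + y0[ok]
    w00 <- (1 - fy[ok]) * (1 - fx[ok]); w10 <- fy[ok] * (1 - fx[ok])
    w01 <- (1 - fy[ok]) * fx[ok];       w11 <- fy[ok] * fx[ok]
    for (z in seq_len(d[1])) {
      v <- as.vector(arr[z, , ])
      sl <- matrix(fill, ny, nx)
      sl[ok] <- v[i00] * w00 + v[i00 + 1L] * w10 + v[i00 + ny] * w01 + v[i00 + ny + 1L] * w11
      out[z, , ] <- sl
    }
  }
  out
}

augment_patch <- function(img, lab, aug) {
  if (is.null(aug)) return(list(img = img, lab = lab))
  if (stats::runif(1) < aug$rotate$p) {
    ang <- stats::runif(1, -aug$rotate$max_deg, aug$rotate$max_deg)
    img <- rotate_slices(img, ang, "bilinear", fill = 0)
    lab <- rotate_slices(lab, ang, "nearest", fill = 0L)
    storage.mode(lab) <- "integer"
  }
  if (stats::runif(1) < aug$noise$p)
    img <- img + stats::rnorm(length(img), 0, stats::runif(1, 0, aug$noise$sd))
  if (stats::runif(1) < aug$contrast$p) {
    f <- stats::runif(1, aug$contrast$range[1], aug$contrast$range[2])
    m <- mean(img)
    img <- m + (img - m) * f
  }
  img <- pmin(pmax(img, 0), 1)
  list(img = img, lab = lab)
}

# Normalize corpus entries to list(image = 3D [0,1] array, labels = int array).
as_training_pair <- function(v) {
  if (inherits(v, "phantom_truth"))
    return(list(image = normalize_intensity(v$image), labels = v$labels$labels))
  if (is.list(v) && !is.null(v$image) && !is.null(v$labels))
    return(list(image = normalize_intensity(v$image), labels = as_label_array(v$labels)))
  stop("corpus entries must be phantom_truth objects or list(image=, labels=)")
}

pad_to <- function(arr, target, fill = 0) {
  d <- dim(arr)
  if (all(d >= target)) return(arr)
  nd <- pmax(d, target)
  out <- array(fill, dim = nd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out
}

#' Sample training patches
#'
#' Draws `(image, label)` patches at random origins from a corpus of paired
#' volumes; a `foreground_patch_fraction` share of the draws is forced to
#' contain at least one foreground voxel (fascicle or epineurium) by
#' centering near a randomly chosen foreground voxel. Volumes smaller than
#' the patch are zero-padded. Fully seeded via the caller's RNG state.
#'
#' @param volumes List of `phantom_truth` objects or `list(image, labels)`
#'   pairs.
#' @param cfg A [training_config()].
#' @param n Number of patches to draw.
#' @return List of `list(img, lab)` patches (image normalized to `[0, 1]`).
#' @export
sample_training_patches <- function(volumes, cfg, n = cfg$batch_size) {
  if (!length(volumes)) stop("empty volume list")
  pairs <- lapply(volumes, as_training_pair)
  ps <- cfg$patch_size
  pairs <- lapply(pairs, function(pr) {
    list(image = pad_to(pr$image, ps, 0), labels = {
      lb <- pad_to(pr$labels, ps, 0L); storage.mode(lb) <- "integer"; lb
    })
  })
  fg_idx <- lapply(pairs, function(pr) which(pr$labels != 0L))
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    vi <- sample.int(length(pairs), 1L)
    pr <- pairs[[vi]]
    d <- dim(pr$labels)
    force_fg <- stats::runif(1) < cfg$foreground_patch_fraction
    if (force_fg && !length(fg_idx[[vi]])) {
      others <- which(vapply(fg_idx, length, 0L) > 0)
      if (!length(others)) stop("foreground patch requested but corpus contains no foreground voxels")
      vi <- others[sample.int(length(others), 1L)]
      pr <- pairs[[vi]]; d <- dim(pr$labels)
    }
    if (force_fg) {
      pos <- arrayInd(fg_idx[[vi]][sample.int(length(fg_idx[[vi]]), 1L)], d)
      org <- pmin(pmax(as.integer(pos) - ps %/% 2L, 1L), d - ps + 1L)
    } else {
      org <- vapply(seq_len(3L), function(a) sample.int(d[a] - ps[a] + 1L, 1L), 0L)
    }
    zi <- org[1]:(org[1] + ps[1] - 1L)
    yi <- org[2]:(org[2] + ps[2] - 1L)
    xi <- org[3]:(org[3] + ps[3] - 1L)
    draws[[i]] <- list(img = pr$image[zi, yi, xi, drop = FALSE],
                       lab = pr$labels[zi, yi, xi, drop = FALSE])
  }
  draws
}

#' Train a 3D U-Net
#'
#' Runs the full patch-based protocol: per epoch, `iters_per_epoch`
#' mini-batches of augmented patches, compound-loss gradients, SGD with
#' Nesterov momentum under the polynomial learning-rate schedule, then
#' in-training validation on patches drawn from the validation volumes. The
#' whole run (initialization, sampling, augmentation) is driven by
#' `train_cfg$seed`; with `loss_cfg$use_topo = FALSE` the run consumes an
#' identical patch sequence, so ablation pairs differ only in the loss term.
#'
#' @param train_volumes,val_volumes Lists of `phantom_truth` objects or
#'   `list(image, labels)` pairs.
#' @param arch_cfg An [arch_config()].
#' @param train_cfg A [training_config()].
#' @param aug_cfg An [augmentation_config()] or `NULL` to disable.
#' @param loss_cfg A [loss_config()].
#' @param net Optional pre-built [build_network()] result (defaults to a
#'   fresh network seeded from `train_cfg$seed`).
#' @param verbose Print a line per epoch.
#' @return An object of class `nervect_model`: trained parameters plus a
#'   per-epoch log tibble (`epoch`, `lr`, `l_ce`, `l_dice`, `l_topo`,
#'   `total`, `val_dice`).
#' @export
train_model <- function(train_volumes, val_volumes, arch_cfg = scaled_arch_config(),
                        train_cfg = scaled_training_config(),
                        aug_cfg = augmentation_config(),
                        loss_cfg = loss_config(), net = NULL, verbose = FALSE) {
  if (!length(train_volumes) || !length(val_volumes))
    stop("need at least one training and one validation volume")
  check_divisible(train_cfg$patch_size, arch_cfg)
  if (is.null(net)) net <- build_network(arch_cfg, seed = train_cfg$seed)
  with_seed(train_cfg$seed + 1L, {
    velocity <- lapply(net$params, function(q) if (is.matrix(q)) matrix(0, nrow(q), ncol(q)) else numeric(length(q)))
    log_rows <- vector("list", train_cfg$epochs)
    for (e in seq_len(train_cfg$epochs) - 1L) {
      lr <- poly_lr(e, train_cfg)
      ep <- c(l_ce = 0, l_dice = 0, l_topo = 0, total = 0)
      for (it in seq_len(train_cfg$iters_per_epoch)) {
        batch <- sample_training_patches(train_volumes, train_cfg, train_cfg$batch_size)
        grads <- NULL
        for (s in batch) {
          as_ <- augment_patch(s$img, s$lab, aug_cfg)
          x <- as_$img; dim(x) <- c(dim(x), 1L)
          g1 <- one_hot(as_$lab, arch_cfg$n_classes)
          fw <- forward_unet(net, x, keep_cache = TRUE)
          lg <- loss_grad_logits(fw$logits, g1, loss_cfg)
          if (!is.finite(lg$components$total))
            stop(sprintf("training diverged (non-finite loss at epoch %d)", e))
          bw <- backward_unet(net, fw$cache, lg$grad)
          grads <- if (is.null(grads)) bw else mapply(`+`, grads, bw, SIMPLIFY = FALSE)
          ep <- ep + c(lg$components$l_ce, lg$components$l_dice,
                       lg$components$l_topo, lg$components$total)
        }
        grads <- lapply(grads, `/`, length(batch))
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
        if (is.finite(train_cfg$grad_clip_norm) && gn > train_cfg$grad_clip_norm)
          grads <- lapply(grads, `*`, train_cfg$grad_clip_norm / gn)
        mu <- train_cfg$momentum
        for (nm in names(net$params)) {
          velocity[[nm]] <- mu * velocity[[nm]] + grads[[nm]]
          net$params[[nm]] <- net$params[[nm]] - lr * (grads[[nm]] + mu * velocity[[nm]])
        }
      }
      ep <- ep / (train_cfg$iters_per_epoch * train_cfg$batch_size)
      # in-training validation on patches, not full volumes
      vd <- NA_real_
      if (train_cfg$val_patches_per_epoch > 0L) {
        vp <- sample_training_patches(val_volumes, train_cfg, train_cfg$val_patches_per_epoch)
        ds <- vapply(vp, function(s) {
          x <- s$img; dim(x) <- c(dim(x), 1L)
          pr <- softmax4(forward_unet(net, x)$logits)
          1 - dice_loss(pr, one_hot(s$lab, arch_cfg$n_classes), loss_cfg)
        }, 0)
        vd <- mean(ds)
      }
      log_rows[[e + 1L]] <- tibble::tibble(epoch = e, lr = lr, l_ce = ep[["l_ce"]],
                                           l_dice = ep[["l_dice"]], l_topo = ep[["l_topo"]],
                                           total = ep[["total"]], val_dice = vd)
      if (verbose)
        message(sprintf("epoch %3d lr %.5f ce %.4f dice %.4f topo %.3g val %.4f",
                        e, lr, ep[["l_ce"]], ep[["l_dice"]], ep[["l_topo"]], vd))
    }
    structure(list(net = net, log = do.call(rbind, log_rows),
                   arch_cfg = arch_cfg, train_cfg = train_cfg,
                   aug_cfg = aug_cfg, loss_cfg = loss_cfg),
              class = "nervect_model")
  })
}

#' @export
print.nervect_model <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<nervect_model> trained %d epochs; final val_dice %.3f, final train total %.4f\n",
              n, x$log$val_dice[n], x$log$total[n]))
  invisible(x)
}
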