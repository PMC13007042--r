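#' Blending configuration for sliding-window inference
#'
#' @param patch_size `(z, y, x)` patch in voxels.
#' @param overlap_fraction Fractional overlap between neighboring patches in
#'   every dimension (default 0.25).
#' @param sigma_rel Gaussian blending width relative to the patch edge length
#'   per axis (default 0.125).
#' @return An object of class `blend_config`.
#' @export
blend_config <- function(patch_size = c(16L, 64L, 64L), overlap_fraction = 0.25,
                         sigma_rel = 0.125) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must lie in [0, 1)")
  if (sigma_rel <= 0) stop("`sigma_rel` must be positive")
  structure(list(patch_size = as.integer(patch_size),
                 overlap_fraction = overlap_fraction, sigma_rel = sigma_rel),
            class = "blend_config")
}

#' Gaussian patch weight map
#'
#' Separable Gaussian centered at the patch center with per-axis standard
#' deviation `sigma_rel * axis length`; the center voxel has weight 1 and
#' every weight is strictly positive.
#'
#' @param patch_size `(z, y, x)` voxel counts.
#' @param sigma_rel Relative Gaussian width.
#' @return A 3D weight array.
#' @examples
#' w <- gaussian_weight_map(c(8, 8, 8))
#' w[4:5, 4:5, 4:5]  # near-center weights
#' @export
gaussian_weight_map <- function(patch_size, sigma_rel = 0.125) {
  if (any(patch_size < 1)) stop("patch sizes must be positive")
  ax <- lapply(patch_size, function(n) {
    c0 <- (n + 1) / 2
    exp(-0.5 * ((seq_len(n) - c0) / (sigma_rel * n))^2)
  })
  outer(outer(ax[[1]], ax[[2]]), ax[[3]])
}

#' Tile a volume into overlapping patch origins
#'
#' Origins advance by `round(patch_size * (1 - overlap))` per axis and the
#' final patch per axis is clamped to the boundary, so every voxel is covered
#' by at least one patch.
#'
#' @param shape `(z, y, x)` volume extent in voxels (must be >= the patch in
#'   every axis; pad smaller volumes first).
#' @param blend A [blend_config()].
#' @return Integer matrix of 1-based `(z, y, x)` patch origins, one row per
#'   patch.
#' @export
tile_volume <- function(shape, blend) {
  ps <- blend$patch_size
  if (any(shape < ps)) stop("volume smaller than patch; pad first")
  axis_origins <- function(n, p) {
    stride <- max(1L, as.integer(round(p * (1 - blend$overlap_fraction))))
    org <- seq.int(1L, by = stride, length.out = ceiling((n - p) / stride) + 1L)
    org <- pmin(org, n - p + 1L)
    unique(org)
  }
  oz <- axis_origins(shape[1], ps[1])
  oy <- axis_origins(shape[2], ps[2])
  ox <- axis_origins(shape[3], ps[3])
  as.matrix(expand.grid(z = oz, y = oy, x = ox, KEEP.OUT.ATTRS = FALSE))
}

#' Predict a full volume by Gaussian-blended sliding-window inference
#'
#' Normalizes the intensity volume, tiles it into overlapping patches, runs
#' the network on each patch, and merges per-voxel class scores as
#' \eqn{\sum w \cdot s / \sum w} with the Gaussian weight map. Labels are the
#' per-voxel argmax of the blended scores.
#'
#' @param vol An [intensity_volume()] (or bare array on the native 16-bit
#'   scale).
#' @param model A trained `nervect_model` or bare `nervect_net`.
#' @param blend A [blend_config()]; defaults to the model's training patch
#'   size with 25% overlap.
#' @param blend_space Blend softmax probabilities (default) or raw logits.
#' @return List with `labels` (a [label_volume()]) and `probs`
#'   (`(z, y, x, class)` array of blended scores).
#' @export
predict_volume <- function(vol, model, blend = NULL,
                           blend_space = c("probs", "logits")) {
  blend_space <- match.arg(blend_space)
  net <- if (inherits(model, "nervect_model")) model$net else model
  if (!inherits(net, "nervect_net")) stop("`model` must be a nervect_model or nervect_net")
  if (is.null(blend)) {
    ps <- if (inherits(model, "nervect_model")) model$train_cfg$patch_size else c(16L, 64L, 64L)
    blend <- blend_config(patch_size = ps)
  }
  img <- normalize_intensity(vol)
  spacing <- spacing_of(vol)
  d0 <- dim(img)
  img <- pad_to(img, blend$patch_size, 0)
  d <- dim(img)
  k <- net$cfg$n_classes
  w <- gaussian_weight_map(blend$patch_size, blend$sigma_rel)
  acc <- array(0, dim = c(d, k))
  wsum <- array(0, dim = d)
  origins <- tile_volume(d, blend)
  ps <- blend$patch_size
  for (r in seq_len(nrow(origins))) {
    o <- origins[r, ]
    zi <- o[1]:(o[1] + ps[1] - 1L); yi <- o[2]:(o[2] + ps[2] - 1L); xi <- o[3]:(o[3] + ps[3] - 1L)
    x <- img[zi, yi, xi, drop = FALSE]
    dim(x) <- c(dim(x), 1L)
    logits <- forward_unet(net, x)$logits
    if (!all(is.finite(logits))) stop("non-finite network output")
    sc <- if (blend_space == "probs") softmax4(logits) else logits
    for (c in seq_len(k)) acc[zi, yi, xi, c] <- acc[zi, yi, xi, c] + w * sc[, , , c]
    wsum[zi, yi, xi] <- wsum[zi, yi, xi] + w
  }
  for (c in seq_len(k)) acc[, , , c] <- acc[, , , c] / wsum
  acc <- acc[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), , drop = FALSE]
  labs <- argmax4(acc)
  list(labels = label_volume(labs, spacing), probs = acc)
}
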