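#' Surface voxels of a binary mask
#'
#' Voxels of the mask with at least one face (6-)neighbor outside the mask;
#' voxels on the volume boundary count as surface (the outside of the grid is
#' background).
#'
#' @param mask Logical 3D array (or [label_volume()] + `class_id`).
#' @param class_id Class to extract when `mask` is a label volume.
#' @return Logical 3D array.
#' @export
surface_voxels <- function(mask, class_id = NULL) {
  m <- as_mask(mask, class_id)
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  shift_ok <- function(axis, delta) {
    out <- array(FALSE, dim = d)
    n <- d[axis]
    if (n == 1L) return(out)  # neighbor always outside -> stays FALSE
    idx_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_dst <- idx_src
    if (delta > 0) { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    else { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <- m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (delta in c(-1L, 1L))
    interior <- interior & shift_ok(axis, delta)
  m & !interior
}

#' Dice similarity coefficient
#'
#' Volumetric overlap `2|P & G| / (|P| + |G|)`; defined as 1 when both masks
#' are empty.
#'
#' @param p_mask,g_mask Binary grids of equal shape (prediction, truth).
#' @return Scalar in `[0, 1]`.
#' @examples
#' a <- array(FALSE, c(2, 2, 2)); a[1, 1, 1] <- a[1, 1, 2] <- TRUE
#' b <- array(FALSE, c(2, 2, 2)); b[1, 1, 1] <- b[2, 1, 1] <- TRUE
#' dice_coefficient(a, b)  # 2*1/(2+2)
#' @export
dice_coefficient <- function(p_mask, g_mask) {
  p <- as_mask(p_mask); g <- as_mask(g_mask)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(1)
  2 * sum(p & g) / (np + ng)
}

#' Surface Dice similarity coefficient
#'
#' Fraction of each segmentation's surface lying within distance `tau` of
#' the other's surface:
#' `(|B(P,tau) & S(G)| + |B(G,tau) & S(P)|) / (|S(P)| + |S(G)|)`,
#' with border regions evaluated on the voxel lattice via the Euclidean
#' distance transform.
#'
#' @param p_mask,g_mask Binary grids of equal shape.
#' @param tau Distance tolerance in voxels (default 1).
#' @return Scalar in `[0, 1]`; `1` (with attribute `empty = TRUE`) when both
#'   masks are empty.
#' @export
surface_dice <- function(p_mask, g_mask, tau = 1) {
  p <- as_mask(p_mask); g <- as_mask(g_mask)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  if (tau < 0) stop("`tau` must be >= 0")
  sp <- surface_voxels(p); sg <- surface_voxels(g)
  nsp <- sum(sp); nsg <- sum(sg)
  if (nsp + nsg == 0) return(structure(1, empty = TRUE))
  if (nsp == 0 || nsg == 0) return(0)
  dp <- sqrt(.edt_sq(sp))  # distance of every voxel to S(P)
  dg <- sqrt(.edt_sq(sg))
  (sum(dp[sg] <= tau) + sum(dg[sp] <= tau)) / (nsp + nsg)
}

#' Average symmetric surface distance
#'
#' Mean over both surfaces of each surface voxel's distance to the nearest
#' voxel of the other surface, reported in micrometres.
#'
#' @param p_mask,g_mask Nonempty binary grids of equal shape.
#' @param spacing_um Isotropic voxel spacing in micrometres.
#' @return Scalar distance in micrometres (0 iff the surfaces coincide).
#' @export
assd <- function(p_mask, g_mask, spacing_um = 11.4) {
  p <- as_mask(p_mask); g <- as_mask(g_mask)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  if (!sum(p) || !sum(g)) stop("ASSD is undefined for an empty mask")
  sp <- surface_voxels(p); sg <- surface_voxels(g)
  dp <- sqrt(.edt_sq(sp))
  dg <- sqrt(.edt_sq(sg))
  (sum(dg[sp]) + sum(dp[sg])) / (sum(sp) + sum(sg)) * spacing_um
}

#' Per-class confusion statistics
#'
#' Binary IoU, sensitivity and specificity of one class of a predicted
#' segmentation against the ground truth.
#'
#' @param pred,truth [label_volume()]s or label arrays of equal shape.
#' @param class_id Class to score (1 fascicle, 2 epineurium).
#' @return A tibble with `class`, `iou`, `sensitivity`, `specificity`.
#' @export
confusion_stats <- function(pred, truth, class_id) {
  p <- as_label_array(pred); g <- as_label_array(truth)
  if (!identical(dim(p), dim(g))) stop("label shapes differ")
  pm <- p == class_id; gm <- g == class_id
  tp <- sum(pm & gm); fp <- sum(pm & !gm); fn <- sum(!pm & gm); tn <- sum(!pm & !gm)
  tibble::tibble(
    class = class_id,
    iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}
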