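# Brute-force reference implementations used as independent oracles.
# All operate on small (<= 8^3) grids by direct enumeration -- no distance
# transforms, no component linking, no shared code with the package paths
# they check.

rand_mask <- function(dims, p = 0.3) array(stats::runif(prod(dims)) < p, dim = dims)

rand_labels <- function(dims, probs = c(0.5, 0.25, 0.25)) {
  array(sample(0:2, prod(dims), replace = TRUE, prob = probs), dim = dims)
}

# Coordinates (n x 3) of TRUE voxels.
mask_coords <- function(m) which(m, arr.ind = TRUE)

# Surface voxels by direct 6-neighbor check (outside the grid = background).
bf_surface <- function(m) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!m[z, y, x]) next
    for (off in list(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0), c(0,0,-1), c(0,0,1))) {
      q <- c(z, y, x) + off
      outside <- any(q < 1) || any(q > d)
      if (outside || !m[q[1], q[2], q[3]]) { out[z, y, x] <- TRUE; break }
    }
  }
  out
}

# All-pairs minimum Euclidean distance from each row of `a` to set `b`.
bf_min_dists <- function(a, b) {
  apply(a, 1, function(p) {
    sqrt(min(colSums((t(b) - p)^2)))
  })
}

bf_dice <- function(p, g) {
  if (sum(p) + sum(g) == 0) return(1)
  2 * sum(p & g) / (sum(p) + sum(g))
}

bf_surface_dice <- function(p, g, tau = 1) {
  sp <- mask_coords(bf_surface(p)); sg <- mask_coords(bf_surface(g))
  if (nrow(sp) + nrow(sg) == 0) return(1)
  if (nrow(sp) == 0 || nrow(sg) == 0) return(0)
  (sum(bf_min_dists(sg, sp) <= tau) + sum(bf_min_dists(sp, sg) <= tau)) /
    (nrow(sp) + nrow(sg))
}

bf_assd <- function(p, g, spacing = 11.4) {
  sp <- mask_coords(bf_surface(p)); sg <- mask_coords(bf_surface(g))
  (sum(bf_min_dists(sp, sg)) + sum(bf_min_dists(sg, sp))) /
    (nrow(sp) + nrow(sg)) * spacing
}

bf_confusion <- function(pred, truth, cid) {
  pm <- pred == cid; gm <- truth == cid
  tp <- sum(pm & gm); fp <- sum(pm & !gm); fn <- sum(!pm & gm); tn <- sum(!pm & !gm)
  c(iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    sens = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    spec = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

# 26-neighbor fascicle/background violation scan by direct enumeration.
bf_critical <- function(labs) {
  d <- dim(labs)
  out <- array(FALSE, dim = d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (labs[z, y, x] != 1L) next
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (!dz && !dy && !dx) next
      q <- c(z + dz, y + dy, x + dx)
      if (any(q < 1) || any(q > d)) next
      if (labs[q[1], q[2], q[3]] == 0L) {
        out[z, y, x] <- TRUE
        out[q[1], q[2], q[3]] <- TRUE
      }
    }
  }
  out
}

# clDice from the formula, given skeletons (checks the counting, not the
# thinning).
bf_cldice <- function(sk_p, sk_g, p, g) {
  t_prec <- sum(sk_p & g) / sum(sk_p)
  t_sens <- sum(sk_g & p) / sum(sk_g)
  if (t_prec + t_sens == 0) return(0)
  2 * t_prec * t_sens / (t_prec + t_sens)
}

# BF score between two 2D contour masks by all-pairs pixel distances.
bf_bf_score <- function(b0, b1, tau = 1) {
  c0 <- which(b0, arr.ind = TRUE); c1 <- which(b1, arr.ind = TRUE)
  if (nrow(c0) == 0 || nrow(c1) == 0) return(0)
  prec <- mean(bf_min_dists(c0, c1) <= tau)
  rec <- mean(bf_min_dists(c1, c0) <= tau)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Per-slice instance F1 by exhaustive pair enumeration over two 2D component
# maps (greedy on IoU; unique at t >= 0.5).
bf_instance_f1 <- function(gmap, pmap, t) {
  ng <- max(gmap); np <- max(pmap)
  tp <- 0
  if (ng > 0 && np > 0) {
    for (i in seq_len(ng)) for (j in seq_len(np)) {
      inter <- sum(gmap == i & pmap == j)
      uni <- sum(gmap == i | pmap == j)
      if (uni > 0 && inter / uni >= t) tp <- tp + 1
    }
  }
  fp <- np - tp; fn <- ng - tp
  if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

# 2D connected components, 8-connectivity, by repeated flood fill in R.
bf_cc2d <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    if (!m[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      c0 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        q <- c0 + c(di, dj)
        if (any(q < 1) || q[1] > nrow(m) || q[2] > ncol(m)) next
        if (m[q[1], q[2]] && !lab[q[1], q[2]]) {
          lab[q[1], q[2]] <- nxt
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}
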