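#' Skeletonize a 3D binary mask
#'
#' Medial curve skeleton by sequential 3D thinning: simple border voxels
#' (Malandain-Bertrand characterization: one 26-connected foreground
#' component and one 6-connected background component in the neighborhood)
#' are deleted in six directional subiterations per pass, preserving curve
#' endpoints, until stable. The skeleton is always a subset of the mask and
#' preserves its connectivity.
#'
#' @param mask Logical 3D array (or [label_volume()] + `class_id`).
#' @param class_id Class to skeletonize when `mask` is a label volume.
#' @return Logical 3D array.
#' @export
skeletonize_mask <- function(mask, class_id = NULL) {
  m <- as_mask(mask, class_id)
  .skeletonize3d(m)
}

#' Centerline Dice (clDice)
#'
#' Harmonic mean of topology precision
#' \eqn{T_{prec} = |Sk(F_P) \cap F_G| / |Sk(F_P)|} and topology sensitivity
#' \eqn{T_{sens} = |Sk(F_G) \cap F_P| / |Sk(F_G)|}: measures preserved
#' anatomical connectivity rather than bulk overlap.
#'
#' @param f_p,f_g Binary fascicle masks (prediction, ground truth).
#' @return Scalar in `[0, 1]`; 1 when both masks are empty (attribute
#'   `empty`), 0 when exactly one is.
#' @export
cldice <- function(f_p, f_g) {
  p <- as_mask(f_p); g <- as_mask(f_g)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  if (!sum(p) && !sum(g)) return(structure(1, empty = TRUE))
  if (!sum(p) || !sum(g)) return(0)
  sk_p <- .skeletonize3d(p)
  sk_g <- .skeletonize3d(g)
  if (!sum(sk_p) || !sum(sk_g)) {
    warning("degenerate: empty skeleton on a nonempty mask")
    return(structure(NA_real_, degenerate = TRUE))
  }
  t_prec <- sum(sk_p & g) / sum(sk_p)
  t_sens <- sum(sk_g & p) / sum(sk_g)
  if (t_prec + t_sens == 0) return(0)
  2 * t_prec * t_sens / (t_prec + t_sens)
}

#' Anatomical error rate
#'
#' Fraction of foreground (fascicle + epineurium) voxels participating in a
#' structural abnormality: (1) exposed fascicle voxels 26-adjacent to
#' background, and (2) abrupt transitions along the nerve -- per-slice
#' 8-connected components of a foreground class with no same-class
#' continuation in either adjacent slice (single-slice aberrations, such as
#' a one-slice fascicle plate amid epineurium). The component-level rule
#' keeps the sub-voxel boundary jitter of a smoothly varying structure,
#' which legitimately changes single edge voxels between slices, from being
#' scored as anatomical error.
#'
#' @param pred A [label_volume()] or label array.
#' @return List (class `anatomy_errors`) with `rate`, `n_errors`,
#'   `n_foreground` and the logical `mask` of erroneous voxels.
#' @export
anatomical_error_rate <- function(pred) {
  labs <- as_label_array(pred)
  fg <- labs != 0L
  n_fg <- sum(fg)
  if (n_fg == 0) stop("anatomical error rate undefined: no foreground voxels")
  exposed <- critical_voxel_map(labs) & labs == 1L
  abrupt <- array(FALSE, dim = dim(labs))
  nz <- dim(labs)[1]
  if (nz >= 3) {
    for (z in 2:(nz - 1)) {
      for (cls in 1:2) {
        m <- labs[z, , ] == cls
        if (!any(m)) next
        cmap <- .cc2d(m, 8L)
        prev <- labs[z - 1, , ] == cls
        nxt <- labs[z + 1, , ] == cls
        for (id in seq_len(attr(cmap, "n"))) {
          inside <- cmap == id
          if (!any(prev[inside]) && !any(nxt[inside]))
            abrupt[z, , ][inside] <- TRUE
        }
      }
    }
  }
  mask <- (exposed | abrupt) & fg
  n_err <- sum(mask)
  structure(list(rate = n_err / n_fg, n_errors = n_err, n_foreground = n_fg,
                 mask = mask),
            class = "anatomy_errors")
}

#' @export
print.anatomy_errors <- function(x, ...) {
  cat(sprintf("<anatomy_errors> %d / %d foreground voxels anomalous (rate %.4g)\n",
              x$n_errors, x$n_foreground, x$rate))
  invisible(x)
}

# One-pixel-wide contour of a 2D mask: mask minus its 4-neighborhood erosion
# (the resulting contour is 8-connected along the boundary).
slice_contour <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  er <- m
  er[1, ] <- FALSE; er[nr, ] <- FALSE; er[, 1] <- FALSE; er[, nc] <- FALSE
  if (nr > 2 && nc > 2) {
    inner <- m[2:(nr - 1), 2:(nc - 1)] &
      m[1:(nr - 2), 2:(nc - 1)] & m[3:nr, 2:(nc - 1)] &
      m[2:(nr - 1), 1:(nc - 2)] & m[2:(nr - 1), 3:nc]
    er[2:(nr - 1), 2:(nc - 1)] <- inner
  }
  m & !er
}

# Euclidean distance of every pixel to the nearest TRUE pixel of a 2D mask.
dist_to_2d <- function(m) {
  arr <- array(m, dim = c(1L, nrow(m), ncol(m)))
  sqrt(.edt_sq(arr))[1, , ]
}

#' Inter-slice boundary consistency (BF score)
#'
#' For each pair of adjacent slices, the boundary F1 between their one-pixel
#' contours: precision and recall count contour pixels within Euclidean
#' distance `tau` of the other slice's contour ("within single-pixel
#' tolerance": the comparison is `d <= tau`), combined as a harmonic mean.
#' Quantifies contour stability (lack of jitter) along the nerve.
#'
#' @param pred A [label_volume()] or label array with at least 2 slices.
#' @param class_id Class whose contours are traced (1 fascicle,
#'   2 epineurium).
#' @param tau Distance tolerance in pixels (default 1).
#' @return List (class `interslice_bf`) with `mean_bf` and `profile` (tibble
#'   `z`, `bf`); pairs where both contours are empty are skipped, pairs where
#'   exactly one is empty score 0.
#' @export
interslice_bf <- function(pred, class_id = 1L, tau = 1) {
  labs <- as_label_array(pred)
  nz <- dim(labs)[1]
  if (nz < 2) stop("need at least 2 slices")
  if (!any(labs == class_id)) stop("class ", class_id, " absent from all slices")
  contours <- lapply(seq_len(nz), function(z) slice_contour(labs[z, , ] == class_id))
  rows <- list()
  for (z in seq_len(nz - 1L)) {
    b0 <- contours[[z]]; b1 <- contours[[z + 1L]]
    n0 <- sum(b0); n1 <- sum(b1)
    if (n0 == 0 && n1 == 0) next
    if (n0 == 0 || n1 == 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(z = z, bf = 0)
      next
    }
    d1 <- dist_to_2d(b1)
    d0 <- dist_to_2d(b0)
    prec <- sum(d1[b0] <= tau) / n0
    rec <- sum(d0[b1] <= tau) / n1
    bf <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    rows[[length(rows) + 1L]] <- tibble::tibble(z = z, bf = bf)
  }
  profile <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(z = integer(), bf = numeric())
  structure(list(mean_bf = if (nrow(profile)) mean(profile$bf) else NA_real_,
                 profile = profile, class_id = class_id, tau = tau),
            class = "interslice_bf")
}

#' @export
print.interslice_bf <- function(x, ...) {
  cat(sprintf("<interslice_bf> class %d, tau %g: mean BF %.4f over %d slice pairs\n",
              x$class_id, x$tau, x$mean_bf, nrow(x$profile)))
  invisible(x)
}

#' Detect fascicle split/merge events
#'
#' Links per-slice 8-connected fascicle components between consecutive
#' slices by voxel overlap. A split at `z` is one component at `z`
#' overlapping two or more components at `z + 1`; a merge is two or more
#' components at `z` overlapping one at `z + 1`. Repeated detections of the
#' same junction (same kind, within `merge_window` slices and
#' `dedupe_radius_px` of each other) collapse to one event. Event rates are
#' per millimetre of nerve (z extent times spacing).
#'
#' @param labels A [label_volume()] or label array.
#' @param min_overlap_px Minimum voxel overlap to link components.
#' @param min_overlap_frac Minimum overlap as a fraction of the smaller
#'   component's area; suppresses incidental single-digit-pixel overlaps
#'   between distinct neighboring fascicles that drift across slices.
#' @param merge_window De-duplication window in slices.
#' @param dedupe_radius_px De-duplication radius in pixels.
#' @param spacing_um Voxel spacing override.
#' @return An object of class `event_track`: tibble of events (`kind`, `z`,
#'   `y`, `x`), counts `n_split`/`n_merge`, segment length `length_mm`, and
#'   rates `r_split`/`r_merge` (events per mm).
#' @export
detect_split_merge_events <- function(labels, min_overlap_px = 1L,
                                      min_overlap_frac = 0.25,
                                      merge_window = 3L, dedupe_radius_px = 8,
                                      spacing_um = NULL) {
  labs <- as_label_array(labels)
  nz <- dim(labs)[1]
  if (nz < 2) stop("need at least 2 slices")
  sp <- if (is.null(spacing_um)) spacing_of(labels) else spacing_um
  maps <- lapply(seq_len(nz), function(z) .cc2d(labs[z, , ] == 1L, 8L))
  raw <- list()
  centroid <- function(map, id) {
    w <- which(map == id, arr.ind = TRUE)
    colMeans(w)
  }
  for (z in seq_len(nz - 1L)) {
    m0 <- maps[[z]]; m1 <- maps[[z + 1L]]
    if (attr(m0, "n") == 0L || attr(m1, "n") == 0L) next
    both <- m0 > 0L & m1 > 0L
    if (!any(both)) next
    tab <- table(paste(m0[both], m1[both]))
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    links <- data.frame(a = as.integer(parts[, 1]), b = as.integer(parts[, 2]),
                        n = as.integer(tab))
    sz0 <- tabulate(m0[m0 > 0L], nbins = attr(m0, "n"))
    sz1 <- tabulate(m1[m1 > 0L], nbins = attr(m1, "n"))
    smaller <- pmin(sz0[links$a], sz1[links$b])
    links <- links[links$n >= min_overlap_px &
                     links$n >= min_overlap_frac * smaller, , drop = FALSE]
    if (!nrow(links)) next
    for (a in unique(links$a)) {      # splits: one at z -> many at z+1
      kids <- links$b[links$a == a]
      if (length(kids) >= 2L) {
        ctr <- centroid(m0, a)
        raw[[length(raw) + 1L]] <- data.frame(kind = "split", z = z,
                                              y = ctr[1], x = ctr[2])
      }
    }
    for (b in unique(links$b)) {      # merges: many at z -> one at z+1
      pars <- links$a[links$b == b]
      if (length(pars) >= 2L) {
        ctr <- centroid(m1, b)
        raw[[length(raw) + 1L]] <- data.frame(kind = "merge", z = z,
                                              y = ctr[1], x = ctr[2])
      }
    }
  }
  events <- if (length(raw)) do.call(rbind, raw)
  else data.frame(kind = character(), z = integer(), y = numeric(), x = numeric())
  # de-duplicate repeated detections of the same junction
  if (nrow(events) > 1L) {
    events <- events[order(events$kind, events$z), ]
    keep <- rep(TRUE, nrow(events))
    for (i in seq_len(nrow(events))) {
      if (!keep[i]) next
      for (j in seq_len(i - 1L)) {
        if (!keep[j] || events$kind[j] != events$kind[i]) next
        if (abs(events$z[i] - events$z[j]) <= merge_window &&
            sqrt((events$y[i] - events$y[j])^2 + (events$x[i] - events$x[j])^2) <= dedupe_radius_px) {
          keep[i] <- FALSE
          break
        }
      }
    }
    events <- events[keep, , drop = FALSE]
  }
  events <- tibble::as_tibble(events)
  length_mm <- nz * sp / 1000
  n_split <- sum(events$kind == "split")
  n_merge <- sum(events$kind == "merge")
  structure(list(events = events, n_split = n_split, n_merge = n_merge,
                 length_mm = length_mm,
                 r_split = n_split / length_mm, r_merge = n_merge / length_mm),
            class = "event_track")
}

#' @export
print.event_track <- function(x, ...) {
  cat(sprintf("<event_track> %d splits, %d merges over %.3f mm (%.2f, %.2f events/mm)\n",
              x$n_split, x$n_merge, x$length_mm, x$r_split, x$r_merge))
  invisible(x)
}

#' Split/merge event-rate deviation
#'
#' Average absolute difference between predicted and ground-truth event
#' rates: \eqn{(|\Delta R_{split}| + |\Delta R_{merge}|)/2} in events per
#' millimetre. The attribute `pct` reports the same deviation as a
#' percentage of the mean ground-truth event rate (when that rate is
#' positive).
#'
#' @param pred_track,gt_track [detect_split_merge_events()] results over the
#'   same segment length.
#' @return Scalar deviation in events/mm, with attribute `pct`.
#' @export
event_rate_deviation <- function(pred_track, gt_track) {
  if (!inherits(pred_track, "event_track") || !inherits(gt_track, "event_track"))
    stop("arguments must be event_track objects")
  if (abs(pred_track$length_mm - gt_track$length_mm) > 1e-9)
    stop("segment lengths differ")
  dev <- (abs(pred_track$r_split - gt_track$r_split) +
            abs(pred_track$r_merge - gt_track$r_merge)) / 2
  gt_mean <- (gt_track$r_split + gt_track$r_merge) / 2
  structure(dev, pct = if (gt_mean > 0) 100 * dev / gt_mean else NA_real_)
}
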