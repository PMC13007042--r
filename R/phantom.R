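#' Phantom specification
#'
#' Parameters of the synthetic plexiform-nerve phantom: an epineurium annulus
#' (elliptical nerve cross section) enclosing several fascicle tubes that run
#' along z with smooth caliber and centerline wobble, plus a schedule of
#' split and merge events. Defaults describe a desk-scale nerve segment at
#' the 11.4 um spacing of the target microCT data.
#'
#' @param shape `(z, y, x)` voxel counts.
#' @param spacing_um Isotropic voxel edge length in micrometres.
#' @param n_fascicles_initial Number of fascicles present at the first slice.
#'   Must be at least `n_splits + 2 * n_merges` so every track takes part in
#'   at most one event.
#' @param fascicle_radius_range_um Range the per-fascicle tube radii are
#'   drawn from (uniformly).
#' @param nerve_ellipse_semiaxes_um Semi-axes `(a, b)` of the nerve ellipse
#'   along y and x.
#' @param epineurium_margin_um Minimum epineurium thickness between any
#'   fascicle and the background.
#' @param n_splits,n_merges Number of scheduled split / merge events.
#' @param wobble_amplitude_um Per-slice centerline perturbation scale.
#' @param radius_wobble_frac Smooth along-z caliber variation (fraction of
#'   the base radius).
#' @param transition_slices Length of the Y-junction transition at each
#'   event, in slices; the per-slice component count changes by exactly one
#'   at a single z.
#' @param intensity_means Named class means (`background`, `fascicle`,
#'   `epineurium`) on the 16-bit scale; defaults give the fascicle-bright
#'   contrast of PTA-stained microCT.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param bias_field_amplitude Relative amplitude of the smooth multiplicative
#'   low-frequency bias field.
#' @param seed Integer seed; regeneration with the same seed is bit-identical.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 128L, 128L),
                         spacing_um = 11.4,
                         n_fascicles_initial = 8L,
                         fascicle_radius_range_um = c(35, 110),
                         nerve_ellipse_semiaxes_um = c(600, 600),
                         epineurium_margin_um = 34.2,
                         n_splits = 1L,
                         n_merges = 1L,
                         wobble_amplitude_um = 11.4,
                         radius_wobble_frac = 0.2,
                         transition_slices = 6L,
                         intensity_means = c(background = 2000, fascicle = 22000, epineurium = 12000),
                         noise_sd = 1500,
                         bias_field_amplitude = 0.1,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing_um = spacing_um,
               n_fascicles_initial = as.integer(n_fascicles_initial),
               fascicle_radius_range_um = fascicle_radius_range_um,
               nerve_ellipse_semiaxes_um = nerve_ellipse_semiaxes_um,
               epineurium_margin_um = epineurium_margin_um,
               n_splits = as.integer(n_splits), n_merges = as.integer(n_merges),
               wobble_amplitude_um = wobble_amplitude_um,
               radius_wobble_frac = radius_wobble_frac,
               transition_slices = as.integer(transition_slices),
               intensity_means = intensity_means, noise_sd = noise_sd,
               bias_field_amplitude = bias_field_amplitude, seed = seed)
  if (length(spec$shape) != 3L || any(spec$shape < 1L)) stop("`shape` must be 3 positive voxel counts")
  if (any(fascicle_radius_range_um <= 0)) stop("fascicle radii must be positive")
  if (spec$n_splits < 0 || spec$n_merges < 0) stop("event counts must be >= 0")
  if (spec$n_fascicles_initial < spec$n_splits + 2L * spec$n_merges)
    stop("need n_fascicles_initial >= n_splits + 2*n_merges so each track has at most one event")
  rmax_vox <- fascicle_radius_range_um[2] / spacing_um
  margin_vox <- epineurium_margin_um / spacing_um
  if (min(nerve_ellipse_semiaxes_um / spacing_um) <= rmax_vox + margin_vox + 1)
    stop("fascicle tubes cannot fit inside the nerve ellipse minus margin")
  semi_vox <- nerve_ellipse_semiaxes_um / spacing_um
  if (semi_vox[1] >= (shape[2] - 1) / 2 || semi_vox[2] >= (shape[3] - 1) / 2)
    stop("nerve ellipse exceeds the (y, x) frame; enlarge `shape` or shrink the semi-axes")
  n_events <- spec$n_splits + spec$n_merges
  if (n_events > 0 && spec$shape[1] - 6L < (n_events - 1L) * 4L + 1L)
    stop("volume too short in z for the scheduled events")
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels at %.3g um; %d fascicles (r %.0f-%.0f um), %d splits, %d merges, seed %d\n",
              paste(x$shape, collapse = " x "), x$spacing_um,
              x$n_fascicles_initial, x$fascicle_radius_range_um[1],
              x$fascicle_radius_range_um[2], x$n_splits, x$n_merges, x$seed))
  invisible(x)
}

# Run `expr` under a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth unit-variance noise along z (moving-average filtered white noise).
smooth_noise <- function(n, window = 5L) {
  if (n == 1L) return(rnorm(1))
  x <- rnorm(n + 2L * window)
  sm <- stats::filter(x, rep(1 / (2 * window + 1), 2 * window + 1), sides = 2)
  sm <- sm[(window + 1):(window + n)]
  s <- stats::sd(sm)
  if (!is.finite(s) || s < 1e-12) rep(0, n) else as.numeric(sm) / s
}

smoothstep <- function(t) t * t * (3 - 2 * t)

#' Build the phantom centerline tree
#'
#' Lays out fascicle "lanes" inside the nerve ellipse, draws smooth wobbling
#' centerlines along z, and weaves the scheduled split/merge Y-junctions into
#' them. Geometry is constructed so that at every event the per-slice
#' component count changes by exactly one at a single z, and no two
#' non-merging tubes come closer than the sum of their radii plus one voxel.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `tracks` (per-fascicle centerline paths and radii, in
#'   voxel coordinates), `events` (tibble: `kind`, `z_index`, `parents`,
#'   `children`) and the voxel-unit geometry used.
#' @export
build_centerline_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, build_centerline_tree_impl(spec))
}

build_centerline_tree_impl <- function(spec) {
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  sp <- spec$spacing_um
  geom <- list(a = spec$nerve_ellipse_semiaxes_um[1] / sp,
               b = spec$nerve_ellipse_semiaxes_um[2] / sp,
               cy = (ny + 1) / 2, cx = (nx + 1) / 2,
               margin = spec$epineurium_margin_um / sp,
               wob = spec$wobble_amplitude_um / sp)
  rrange <- spec$fascicle_radius_range_um / sp
  n_init <- spec$n_fascicles_initial

  for (attempt in seq_len(50L)) {
    radii <- stats::runif(n_init, rrange[1], rrange[2])
    lanes <- sample_lanes(n_init, radii, geom)
    if (is.null(lanes)) next
    tree <- try(weave_tracks(spec, lanes, radii, geom, nz), silent = TRUE)
    if (inherits(tree, "try-error")) next
    if (tracks_collide(tree$tracks, nz)) next
    return(tree)
  }
  stop("infeasible packing: could not place the fascicles inside the nerve ellipse after 50 attempts")
}

# A lane center is admissible if its disc (radius + margin + wobble) stays
# inside the ellipse and keeps clearance from every existing lane.
lane_ok <- function(cand, r, lanes, radii, geom) {
  ae <- geom$a - r - geom$margin - geom$wob
  be <- geom$b - r - geom$margin - geom$wob
  if (ae <= 0 || be <= 0) return(FALSE)
  if (((cand[1] - geom$cy) / ae)^2 + ((cand[2] - geom$cx) / be)^2 > 1) return(FALSE)
  if (!is.null(lanes) && nrow(lanes)) {
    dd <- sqrt(rowSums((lanes - matrix(cand, nrow(lanes), 2, byrow = TRUE))^2))
    if (any(dd < radii + r + 4 + 2 * geom$wob)) return(FALSE)
  }
  TRUE
}

# Rejection-sample lane centers with pairwise clearance; NULL on failure.
sample_lanes <- function(n, radii, geom) {
  lanes <- matrix(NA_real_, 0L, 2)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try_i in seq_len(200L)) {
      u <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
      ae <- geom$a - radii[k] - geom$margin - geom$wob
      be <- geom$b - radii[k] - geom$margin - geom$wob
      if (ae <= 0 || be <= 0) return(NULL)
      cand <- c(geom$cy + ae * u * sin(th), geom$cx + be * u * cos(th))
      if (lane_ok(cand, radii[k], lanes, radii[seq_len(k - 1L)], geom)) {
        lanes <- rbind(lanes, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  unname(lanes)
}

# Overwrite center[zs, ] with a bounded-step walk that starts at `start` on
# zs[1] and converges onto the pre-existing path (per-slice displacement
# <= step_max keeps consecutive discs overlapping).
walk_path <- function(center, zs, start, step_max) {
  pos <- start
  center[zs[1], ] <- pos
  for (z in zs[-1]) {
    delta <- center[z, ] - pos
    nd <- sqrt(sum(delta^2))
    pos <- if (nd <= step_max) center[z, ] else pos + delta / nd * step_max
    center[z, ] <- pos
  }
  center
}

# Blend radius[zs] from r0 at zs[1] back into the existing values over Tt.
relax_radius <- function(radius, zs, r0, Tt) {
  for (i in seq_along(zs)) {
    s <- smoothstep(min(1, (i - 1) / Tt))
    radius[zs[i]] <- (1 - s) * r0 + s * radius[zs[i]]
    if (s >= 1) break
  }
  radius
}

weave_tracks <- function(spec, lanes, radii, geom, nz) {
  n_init <- spec$n_fascicles_initial
  n_events <- spec$n_splits + spec$n_merges
  Tt <- spec$transition_slices
  wob <- geom$wob

  mk_base_center <- function(lane, r) {
    w <- cbind(smooth_noise(nz), smooth_noise(nz)) * wob
    ctr <- cbind(lane[1] + w[, 1], lane[2] + w[, 2])
    ae <- geom$a - r - geom$margin; be <- geom$b - r - geom$margin
    rho <- sqrt(((ctr[, 1] - geom$cy) / ae)^2 + ((ctr[, 2] - geom$cx) / be)^2)
    over <- rho > 1
    if (any(over)) {
      ctr[over, 1] <- geom$cy + (ctr[over, 1] - geom$cy) / rho[over]
      ctr[over, 2] <- geom$cx + (ctr[over, 2] - geom$cx) / rho[over]
    }
    ctr
  }
  mk_base_radius <- function(r)
    pmax(r * (1 + spec$radius_wobble_frac * smooth_noise(nz)), 1.5)

  # event schedule: distinct z, separated by >= 4 slices
  kinds <- character(0); zs_ev <- integer(0)
  if (n_events > 0L) {
    window <- seq.int(4L, nz - 3L)
    ok <- FALSE
    for (i in seq_len(200L)) {
      zs_ev <- sort(sample(window, n_events))
      if (n_events == 1L || all(diff(zs_ev) >= 4L)) { ok <- TRUE; break }
    }
    if (!ok) {
      zs_ev <- as.integer(round(seq(window[1], window[length(window)], length.out = n_events)))
      if (n_events > 1L && any(diff(zs_ev) < 4L)) stop("cannot schedule events with enough separation")
    }
    kinds <- sample(c(rep("split", spec$n_splits), rep("merge", spec$n_merges)))
  }

  tracks <- lapply(seq_len(n_init), function(k) {
    list(id = paste0("f", k), lane = lanes[k, ], base_r = radii[k],
         z0 = 1L, z1 = nz,
         center = mk_base_center(lanes[k, ], radii[k]),
         radius = mk_base_radius(radii[k]))
  })
  names(tracks) <- vapply(tracks, `[[`, "", "id")
  available <- names(tracks)   # tracks not yet used by any event
  next_id <- n_init
  ev_rows <- list()
  all_lanes <- lanes; all_radii <- radii   # grows as children are added

  for (e in seq_along(kinds)) {
    ze <- zs_ev[e]
    if (kinds[e] == "split") {
      # fork the thickest available fascicle whose neighborhood has room for
      # the child's lane (children of thick parents stay well-resolved)
      rads <- vapply(available, function(id) tracks[[id]]$base_r, 0)
      placed <- FALSE
      for (pid in available[order(rads, decreasing = TRUE)]) {
        A <- tracks[[pid]]
        rc <- max(3, A$base_r / sqrt(2))
        rsw <- 1.8 * rc                   # parent caliber just before the fork:
        # wide enough that both child discs keep a solid footprint overlap
        step_max <- max(1.2, 0.6 * rc)
        others <- do.call(rbind, lapply(tracks, `[[`, "lane"))
        other_r <- vapply(tracks, `[[`, 0, "base_r")
        for (try_i in seq_len(60L)) {
          th <- stats::runif(1, 0, 2 * pi)
          d <- stats::runif(1, rsw + rc + 4 + 2 * wob, rsw + rc + 14 + 2 * wob)
          cand <- A$lane + d * c(sin(th), cos(th))
          if (lane_ok(cand, rc, others, other_r, geom)) { placed <- TRUE; break }
        }
        if (placed) break
      }
      if (!placed) stop("no room for a split child lane")
      available <- setdiff(available, pid)
      next_id <- next_id + 1L
      cid <- paste0("f", next_id)
      all_lanes <- rbind(all_lanes, cand); all_radii <- c(all_radii, rc)

      u <- cand - A$lane; u <- u / sqrt(sum(u^2))
      o <- rc + 1.2
      fork <- A$center[ze - 1L, ]       # children straddle the parent's last position
      A$radius <- relax_radius(A$radius, seq.int(ze - 1L, A$z0), max(rsw, A$radius[ze - 1L]), Tt)
      B <- list(id = cid, lane = cand, base_r = rc, z0 = ze, z1 = nz,
                center = mk_base_center(cand, rc), radius = mk_base_radius(rc))
      A$center <- walk_path(A$center, ze:nz, fork - u * o, step_max)
      B$center <- walk_path(B$center, ze:nz, fork + u * o, step_max)
      A$radius <- relax_radius(A$radius, ze:nz, rc, Tt)
      B$radius <- relax_radius(B$radius, ze:nz, rc, Tt)
      tracks[[pid]] <- A
      tracks[[cid]] <- B
      ev_rows[[length(ev_rows) + 1L]] <-
        tibble::tibble(kind = "split", z_index = ze - 1L, parents = pid,
                       children = paste(pid, cid, sep = ","))
    } else {  # merge the closest available pair
      if (length(available) < 2L) stop("no available track pair for merge")
      pts <- do.call(rbind, lapply(available, function(id) tracks[[id]]$lane))
      dd <- as.matrix(stats::dist(pts)); diag(dd) <- Inf
      ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      aid <- available[ij[1]]; bid <- available[ij[2]]
      available <- setdiff(available, c(aid, bid))
      A <- tracks[[aid]]; B <- tracks[[bid]]
      rc <- max(3, min(A$base_r, B$base_r) / sqrt(2))
      rm_ <- max(sqrt(A$base_r^2 + B$base_r^2), 1.8 * rc)
      step_max <- max(1.2, 0.6 * rc)
      u <- B$lane - A$lane; u <- u / sqrt(sum(u^2))
      o <- rc + 1.2
      meet <- A$center[ze, ]
      # children shrink to rc and walk (backwards in z) onto the fork offsets
      A$center <- walk_path(A$center, seq.int(ze - 1L, A$z0), meet - u * o, step_max)
      B$center <- walk_path(B$center, seq.int(ze - 1L, B$z0), meet + u * o, step_max)
      A$radius <- relax_radius(A$radius, seq.int(ze - 1L, A$z0), rc, Tt)
      B$radius <- relax_radius(B$radius, seq.int(ze - 1L, B$z0), rc, Tt)
      # merged caliber relaxes from rm back to A\'s base
      A$radius <- relax_radius(A$radius, ze:nz, rm_, Tt)
      B$z1 <- ze - 1L
      tracks[[aid]] <- A
      tracks[[bid]] <- B
      ev_rows[[length(ev_rows) + 1L]] <-
        tibble::tibble(kind = "merge", z_index = ze - 1L,
                       parents = paste(aid, bid, sep = ","), children = aid)
    }
  }

  # per-slice containment: discs (with their actual per-slice radius, which
  # can exceed the lane budget around an event) must stay margin-deep inside
  # the ellipse
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    for (z in tr$z0:tr$z1) {
      ae <- geom$a - tr$radius[z] - geom$margin
      be <- geom$b - tr$radius[z] - geom$margin
      if (ae <= 1 || be <= 1) stop("fascicle too large for the nerve ellipse")
      rho <- sqrt(((tr$center[z, 1] - geom$cy) / ae)^2 + ((tr$center[z, 2] - geom$cx) / be)^2)
      if (rho > 1) {
        tr$center[z, 1] <- geom$cy + (tr$center[z, 1] - geom$cy) / rho
        tr$center[z, 2] <- geom$cx + (tr$center[z, 2] - geom$cx) / rho
      }
    }
    tracks[[nm]] <- tr
  }

  events <- if (length(ev_rows)) do.call(rbind, ev_rows)
  else tibble::tibble(kind = character(), z_index = integer(),
                      parents = character(), children = character())
  events <- events[order(events$z_index), , drop = FALSE]
  list(tracks = tracks, events = events, geometry = geom, spec = spec)
}

# Pairwise clearance check on every slice: non-touching tubes must keep at
# least one voxel of epineurium between them (center distance >= r_i+r_j+1.9;
# event pairs satisfy this by construction during their transitions).
tracks_collide <- function(tracks, nz) {
  for (z in seq_len(nz)) {
    act <- Filter(function(tr) tr$z0 <= z && z <= tr$z1, tracks)
    if (length(act) < 2L) next
    ctr <- do.call(rbind, lapply(act, function(tr) tr$center[z, ]))
    rad <- vapply(act, function(tr) tr$radius[z], 0)
    dd <- as.matrix(stats::dist(ctr))
    lim <- outer(rad, rad, `+`) + 1.9
    diag(lim) <- 0
    if (any(dd < lim - 1e-9)) return(TRUE)
  }
  FALSE
}

#' Rasterize phantom centerlines into a label volume
#'
#' Fascicle voxels are the union of per-slice discs around each active
#' centerline; epineurium is the nerve ellipse minus the fascicles. The
#' construction keeps every fascicle voxel's full 26-neighborhood free of
#' background, which is verified before returning.
#'
#' @param tree Output of [build_centerline_tree()].
#' @param spec The [phantom_spec()] used to build `tree`.
#' @return A [label_volume()].
#' @export
rasterize_phantom <- function(tree, spec = tree$spec) {
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  g <- tree$geometry
  ys <- seq_len(ny); xs <- seq_len(nx)
  ell <- outer(((ys - g$cy) / g$a)^2, rep(1, nx)) + outer(rep(1, ny), ((xs - g$cx) / g$b)^2)
  epimask <- ell <= 1
  labs <- array(0L, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) {
    sl <- ifelse(epimask, 2L, 0L)
    for (tr in tree$tracks) {
      if (tr$z0 > z || z > tr$z1) next
      c0 <- tr$center[z, ]; r <- tr$radius[z]
      y0 <- max(1L, floor(c0[1] - r)); y1 <- min(ny, ceiling(c0[1] + r))
      x0 <- max(1L, floor(c0[2] - r)); x1 <- min(nx, ceiling(c0[2] + r))
      yy <- y0:y1; xx <- x0:x1
      d2 <- outer((yy - c0[1])^2, rep(1, length(xx))) + outer(rep(1, length(yy)), (xx - c0[2])^2)
      sub <- sl[yy, xx]
      sub[d2 <= r^2] <- 1L
      sl[yy, xx] <- sub
    }
    labs[z, , ] <- sl
  }
  if (any(labs == 1L)) {
    viol <- .critical_scan(labs)
    if (any(viol)) stop("tube exits nerve region: rasterized fascicle touches background")
  }
  label_volume(labs, spec$spacing_um)
}

#' Render a microCT-like intensity volume from labels
#'
#' Each voxel gets its class mean, modulated by a smooth multiplicative
#' low-frequency bias field, plus additive Gaussian noise, clipped to
#' `[0, 32767]` and rounded to 16-bit integers.
#'
#' @param labels A [label_volume()] or bare label array.
#' @param spec A [phantom_spec()] providing class means, noise and bias
#'   settings.
#' @param seed Seed for the noise stream (defaults to `spec$seed + 1`).
#' @return An [intensity_volume()].
#' @export
render_intensity <- function(labels, spec, seed = spec$seed + 1L) {
  labs <- as_label_array(labels)
  mns <- spec$intensity_means[c("background", "fascicle", "epineurium")]
  if (anyNA(mns)) stop("`intensity_means` must be named background/fascicle/epineurium")
  with_seed(seed, {
    img <- array(mns[as.vector(labs) + 1L], dim = dim(labs))
    if (spec$bias_field_amplitude > 0) {
      d <- dim(labs)
      field1d <- function(n) {
        fr <- stats::runif(1, 0.5, 1.5); ph <- stats::runif(1, 0, 2 * pi)
        cos(2 * pi * fr * seq(0, 1, length.out = n) + ph)
      }
      bz <- field1d(d[1]); by <- field1d(d[2]); bx <- field1d(d[3])
      bias <- outer(outer(bz, by), bx) / 3 +
        (outer(outer(rep(1, d[1]), field1d(d[2])), field1d(d[3]))) / 3
      img <- img * (1 + spec$bias_field_amplitude * bias)
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    img <- array(as.integer(round(pmin(pmax(img, 0), 32767))), dim = dim(labs))
    intensity_volume(img, spec$spacing_um)
  })
}

#' Generate a complete phantom
#'
#' Composes [build_centerline_tree()], [rasterize_phantom()] and
#' [render_intensity()] into a ground-truth bundle: intensity volume, label
#' volume, the split/merge event ledger, and the centerlines.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth`: list with `image`, `labels`,
#'   `events`, `centerlines` and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(16, 64, 64),
#'                                     n_fascicles_initial = 3,
#'                                     n_splits = 0, n_merges = 0, seed = 7))
#' ph$labels
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  tree <- build_centerline_tree(spec)
  labels <- rasterize_phantom(tree, spec)
  image <- render_intensity(labels, spec)
  structure(list(image = image, labels = labels, events = tree$events,
                 centerlines = lapply(tree$tracks, function(tr)
                   list(id = tr$id, z0 = tr$z0, z1 = tr$z1,
                        center = tr$center[tr$z0:tr$z1, , drop = FALSE],
                        radius = tr$radius[tr$z0:tr$z1])),
                 spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s; %d fascicle tracks, %d splits, %d merges (seed %d)\n",
              paste(x$spec$shape, collapse = " x "), length(x$centerlines),
              sum(x$events$kind == "split"), sum(x$events$kind == "merge"),
              x$spec$seed))
  invisible(x)
}
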