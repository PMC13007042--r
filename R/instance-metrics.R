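#' Fascicle size bins
#'
#' Cross-sectional area boundaries (mm^2) separating tiny / small / medium /
#' large fascicles, and the slice sampling interval used for the per-slice
#' detection metrics.
#'
#' @param boundaries_mm2 Strictly increasing area boundaries; defaults
#'   0.02, 0.09 and 0.3 mm^2 (effective circular diameters 0.16, 0.34 and
#'   0.62 mm).
#' @param slice_interval Evaluate every this-many slices (default 8, about
#'   0.1 mm at 11.4 um spacing).
#' @return An object of class `size_bins`.
#' @export
size_bins <- function(boundaries_mm2 = c(0.02, 0.09, 0.3), slice_interval = 8L) {
  if (is.unsorted(boundaries_mm2, strictly = TRUE))
    stop("bin boundaries must be strictly increasing")
  structure(list(boundaries_mm2 = boundaries_mm2,
                 labels = c("tiny", "small", "medium", "large"),
                 slice_interval = as.integer(slice_interval)),
            class = "size_bins")
}

#' Map cross-sectional areas to size-bin labels
#'
#' @param area_mm2 Areas in mm^2.
#' @param bins A [size_bins()].
#' @return Character vector of bin labels (tiny/small/medium/large).
#' @export
bin_of_area <- function(area_mm2, bins = size_bins()) {
  bins$labels[findInterval(area_mm2, bins$boundaries_mm2) + 1L]
}

#' Effective circular diameter
#'
#' Diameter of the circle with the same area as a fascicle cross section:
#' \eqn{d = 2\sqrt{A/\pi}}, in mm.
#'
#' @param area_mm2 Cross-sectional area(s) in mm^2.
#' @return Diameter(s) in mm.
#' @examples
#' round(effective_diameter(c(0.02, 0.09, 0.3)), 2)
#' @export
effective_diameter <- function(area_mm2) {
  if (any(area_mm2 < 0)) stop("area must be >= 0")
  2 * sqrt(area_mm2 / pi)
}

#' Extract fascicle instances from one cross section
#'
#' 8-connectivity connected components of the fascicle mask (`labels == 1`)
#' in slice `z`.
#'
#' @param labels A [label_volume()] or label array.
#' @param z Slice index (1-based).
#' @param spacing_um Voxel spacing (taken from the volume when available).
#' @return List with `map` (integer `(y, x)` component map) and `instances`
#'   (tibble: `id`, `z`, `n_voxels`, `area_mm2`).
#' @export
extract_instances <- function(labels, z, spacing_um = NULL) {
  arr <- as_label_array(labels)
  if (z < 1 || z > dim(arr)[1]) stop("slice index out of range")
  sp <- if (is.null(spacing_um)) spacing_of(labels) else spacing_um
  sl <- arr[z, , ] == 1L
  map <- .cc2d(sl, 8L)
  n <- attr(map, "n")
  counts <- if (n > 0) tabulate(map[map > 0L], nbins = n) else integer(0)
  list(map = map,
       instances = tibble::tibble(
         id = seq_len(n), z = as.integer(z), n_voxels = counts,
         area_mm2 = counts * (sp / 1000)^2))
}

# IoU table between all overlapping GT/pred component pairs on one slice.
pair_ious <- function(gt_map, pred_map) {
  both <- gt_map > 0L & pred_map > 0L
  ng <- attr(gt_map, "n"); np <- attr(pred_map, "n")
  if (!sum(both) || ng == 0L || np == 0L)
    return(tibble::tibble(gt = integer(0), pred = integer(0),
                          inter = integer(0), iou = numeric(0)))
  key <- paste(gt_map[both], pred_map[both])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  gt_id <- as.integer(parts[, 1]); pred_id <- as.integer(parts[, 2])
  inter <- as.integer(tab)
  gsz <- tabulate(gt_map[gt_map > 0L], nbins = ng)
  psz <- tabulate(pred_map[pred_map > 0L], nbins = np)
  tibble::tibble(gt = gt_id, pred = pred_id, inter = inter,
                 iou = inter / (gsz[gt_id] + psz[pred_id] - inter))
}

#' Match fascicle instances between truth and prediction on one slice
#'
#' Pairs with `IoU >= t` are true positives; at `t >= 0.5` each ground-truth
#' fascicle has at most one match and vice versa, so the matching is
#' one-to-one. `F1(t) = 2 TP / (TP + FP + FN)` (equivalently
#' `2 TP / (2 TP + FP + FN)` of precision-recall form -- the detection-F1
#' convention in which TP appears once in the denominator sum).
#'
#' @param gt_slice,pred_slice Outputs of [extract_instances()] for the same
#'   slice, or integer component maps.
#' @param t IoU threshold in `[0.5, 1]`.
#' @return List (class `instance_match`) with `threshold`, `pairs` (tibble
#'   `gt`, `pred`, `iou`), `tp`, `fp`, `fn` and `f1`.
#' @export
match_instances <- function(gt_slice, pred_slice, t = 0.5) {
  if (t < 0.5 || t > 1) stop("IoU threshold must lie in [0.5, 1] (uniqueness requires t >= 0.5)")
  gm <- if (is.list(gt_slice)) gt_slice$map else gt_slice
  pm <- if (is.list(pred_slice)) pred_slice$map else pred_slice
  ious <- pair_ious(gm, pm)
  pairs <- ious[ious$iou >= t, c("gt", "pred", "iou")]
  tp <- nrow(pairs)
  fp <- attr(pm, "n") - tp
  fn <- attr(gm, "n") - tp
  f1 <- if (tp + fp + fn == 0) 1 else 2 * tp / (tp + fp + fn + tp)
  structure(list(threshold = t, pairs = pairs, tp = tp, fp = fp, fn = fn, f1 = f1),
            class = "instance_match")
}

sampled_slices <- function(nz, bins) seq.int(1L, nz, by = bins$slice_interval)

#' F1 detection curve over IoU thresholds
#'
#' Mean per-slice instance F1 at thresholds 0.50 to 0.95 (step 0.05),
#' evaluated at the bin sampling interval and averaged across the volume.
#' Slices with neither ground-truth nor predicted fascicles contribute no
#' terms.
#'
#' @param gt,pred [label_volume()]s or label arrays.
#' @param thresholds IoU thresholds.
#' @param bins A [size_bins()] (provides the slice interval).
#' @return Tibble with `threshold`, `mean_f1` and `n_slices`.
#' @export
f1_curve <- function(gt, pred, thresholds = seq(0.5, 0.95, by = 0.05),
                     bins = size_bins()) {
  ga <- as_label_array(gt); pa <- as_label_array(pred)
  if (!identical(dim(ga), dim(pa))) stop("label shapes differ")
  zs <- sampled_slices(dim(ga)[1], bins)
  per_slice <- lapply(zs, function(z) {
    gsl <- extract_instances(ga, z); psl <- extract_instances(pa, z)
    if (attr(gsl$map, "n") == 0L && attr(psl$map, "n") == 0L) return(NULL)
    ious <- pair_ious(gsl$map, psl$map)
    vapply(thresholds, function(t) {
      tp <- sum(ious$iou >= t)
      fp <- attr(psl$map, "n") - tp
      fn <- attr(gsl$map, "n") - tp
      2 * tp / (tp + fp + fn + tp)
    }, 0)
  })
  per_slice <- per_slice[!vapply(per_slice, is.null, TRUE)]
  if (!length(per_slice))
    return(tibble::tibble(threshold = thresholds, mean_f1 = NA_real_, n_slices = 0L))
  m <- do.call(rbind, per_slice)
  tibble::tibble(threshold = thresholds, mean_f1 = colMeans(m), n_slices = nrow(m))
}

#' Over- and under-segmentation rates
#'
#' At IoU threshold `t` (default 0.7): a ground-truth fascicle is
#' over-segmented when it has no one-to-one match and at least two predicted
#' components each lie mostly (majority of their own area) inside it; a
#' predicted component under-segments when at least two ground-truth
#' fascicles each lie mostly inside it. Rates are affected ground-truth
#' fascicles over total ground-truth fascicles, computed at the slice
#' sampling interval and averaged; slices without ground-truth fascicles are
#' skipped.
#'
#' @param gt,pred Label volumes or arrays.
#' @param t IoU threshold for the one-to-one matching.
#' @param bins A [size_bins()].
#' @return Tibble with `over_rate`, `under_rate`, `n_slices`.
#' @export
over_under_segmentation <- function(gt, pred, t = 0.7, bins = size_bins()) {
  ga <- as_label_array(gt); pa <- as_label_array(pred)
  if (!identical(dim(ga), dim(pa))) stop("label shapes differ")
  zs <- sampled_slices(dim(ga)[1], bins)
  rates <- lapply(zs, function(z) {
    gsl <- extract_instances(ga, z); psl <- extract_instances(pa, z)
    ng <- attr(gsl$map, "n")
    if (ng == 0L) return(NULL)
    np <- attr(psl$map, "n")
    ious <- pair_ious(gsl$map, psl$map)
    matched_gt <- unique(ious$gt[ious$iou >= t])
    gsz <- tabulate(gsl$map[gsl$map > 0L], nbins = ng)
    psz <- tabulate(psl$map[psl$map > 0L], nbins = max(np, 1L))
    # majority-cover relations
    pred_in_gt <- ious[ious$inter > psz[ious$pred] / 2, ]  # pred mostly inside gt
    gt_in_pred <- ious[ious$inter > gsz[ious$gt] / 2, ]    # gt mostly inside pred
    over_gt <- setdiff(names(which(table(pred_in_gt$gt) >= 2L)), as.character(matched_gt))
    under_preds <- as.integer(names(which(table(gt_in_pred$pred) >= 2L)))
    under_gt <- unique(gt_in_pred$gt[gt_in_pred$pred %in% under_preds])
    c(over = length(over_gt) / ng, under = length(under_gt) / ng)
  })
  rates <- rates[!vapply(rates, is.null, TRUE)]
  if (!length(rates))
    return(tibble::tibble(over_rate = NA_real_, under_rate = NA_real_, n_slices = 0L))
  m <- do.call(rbind, rates)
  tibble::tibble(over_rate = mean(m[, "over"]), under_rate = mean(m[, "under"]),
                 n_slices = nrow(m))
}

#' Missed-fascicle fraction by size bin
#'
#' Ground-truth fascicles without a match at IoU threshold `t` (false
#' negatives), binned by their cross-sectional area; the fraction per bin is
#' relative to the total ground-truth fascicles in that bin over the sampled
#' slices.
#'
#' @param gt,pred Label volumes or arrays.
#' @param t IoU threshold (default 0.7).
#' @param bins A [size_bins()].
#' @param spacing_um Voxel spacing override.
#' @return Tibble with `bin`, `n_gt`, `n_missed`, `miss_fraction`.
#' @export
missed_by_size <- function(gt, pred, t = 0.7, bins = size_bins(), spacing_um = NULL) {
  ga <- as_label_array(gt); pa <- as_label_array(pred)
  if (!identical(dim(ga), dim(pa))) stop("label shapes differ")
  sp <- if (is.null(spacing_um)) spacing_of(gt) else spacing_um
  zs <- sampled_slices(dim(ga)[1], bins)
  n_gt <- stats::setNames(numeric(4), bins$labels)
  n_missed <- n_gt
  for (z in zs) {
    gsl <- extract_instances(ga, z, sp); psl <- extract_instances(pa, z, sp)
    ng <- attr(gsl$map, "n")
    if (ng == 0L) next
    ious <- pair_ious(gsl$map, psl$map)
    matched_gt <- unique(ious$gt[ious$iou >= t])
    binlab <- bin_of_area(gsl$instances$area_mm2, bins)
    for (i in seq_len(ng)) {
      n_gt[binlab[i]] <- n_gt[binlab[i]] + 1
      if (!(i %in% matched_gt)) n_missed[binlab[i]] <- n_missed[binlab[i]] + 1
    }
  }
  tibble::tibble(bin = factor(bins$labels, levels = bins$labels),
                 n_gt = as.integer(n_gt), n_missed = as.integer(n_missed),
                 miss_fraction = ifelse(n_gt > 0, n_missed / n_gt, NA_real_))
}
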