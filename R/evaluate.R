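#' Evaluate a predicted segmentation against ground truth
#'
#' Computes the full metric suite: per-class Dice, surface Dice, ASSD, IoU,
#' sensitivity and specificity; fascicle instance detection (F1 curve over
#' IoU thresholds, over/under-segmentation, size-stratified miss rates);
#' and the anatomy-aware metrics (clDice, anatomical error rate, inter-slice
#' BF score, split/merge event-rate deviation).
#'
#' @param pred,truth [label_volume()]s (or label arrays) of equal shape.
#' @param spacing_um Voxel spacing override (defaults to the volumes').
#' @param tau Surface-Dice and BF tolerance in voxels/pixels.
#' @param bins A [size_bins()].
#' @param thresholds IoU thresholds for the F1 curve.
#' @return An object of class `nervect_eval`: list of result tables; its
#'   [generics::tidy()] method returns one long tibble (`metric`, `class`,
#'   `value`).
#' @export
evaluate_segmentation <- function(pred, truth, spacing_um = NULL, tau = 1,
                                  bins = size_bins(),
                                  thresholds = seq(0.5, 0.95, by = 0.05)) {
  pa <- as_label_array(pred); ga <- as_label_array(truth)
  if (!identical(dim(pa), dim(ga))) stop("prediction and truth shapes differ")
  sp <- if (!is.null(spacing_um)) spacing_um else spacing_of(pred)

  class_names <- c("fascicle", "epineurium")
  overlap <- do.call(rbind, lapply(1:2, function(cid) {
    pm <- pa == cid; gm <- ga == cid
    cs <- confusion_stats(pa, ga, cid)
    tibble::tibble(
      class = class_names[cid],
      dsc = dice_coefficient(pm, gm),
      surface_dsc = as.numeric(surface_dice(pm, gm, tau)),
      assd_um = if (sum(pm) && sum(gm)) assd(pm, gm, sp) else NA_real_,
      iou = cs$iou, sensitivity = cs$sensitivity, specificity = cs$specificity)
  }))

  f1 <- f1_curve(ga, pa, thresholds, bins)
  ou <- over_under_segmentation(ga, pa, t = 0.7, bins = bins)
  miss <- missed_by_size(ga, pa, t = 0.7, bins = bins, spacing_um = sp)

  cl <- as.numeric(cldice(pa == 1L, ga == 1L))
  aer <- anatomical_error_rate(pa)
  bf <- lapply(1:2, function(cid)
    if (any(pa == cid)) interslice_bf(pa, cid, tau) else NULL)
  gt_track <- detect_split_merge_events(ga, spacing_um = sp)
  pred_track <- detect_split_merge_events(pa, spacing_um = sp)
  dev <- event_rate_deviation(pred_track, gt_track)

  structure(list(
    overlap = overlap,
    f1_curve = f1,
    over_under = ou,
    missed_by_size = miss,
    cldice = cl,
    anatomical_error_rate = aer$rate,
    bf_fascicle = if (!is.null(bf[[1]])) bf[[1]]$mean_bf else NA_real_,
    bf_epineurium = if (!is.null(bf[[2]])) bf[[2]]$mean_bf else NA_real_,
    bf_profiles = bf,
    gt_track = gt_track, pred_track = pred_track,
    event_rate_deviation = as.numeric(dev),
    event_rate_deviation_pct = attr(dev, "pct"),
    spacing_um = sp, tau = tau),
    class = "nervect_eval")
}

#' @export
print.nervect_eval <- function(x, ...) {
  cat("<nervect_eval>\n")
  cat(sprintf("  fascicle:   DSC %.4f  surface DSC %.4f  ASSD %s um  clDice %.4f\n",
              x$overlap$dsc[1], x$overlap$surface_dsc[1],
              format(x$overlap$assd_um[1], digits = 4), x$cldice))
  cat(sprintf("  epineurium: DSC %.4f  surface DSC %.4f  ASSD %s um\n",
              x$overlap$dsc[2], x$overlap$surface_dsc[2],
              format(x$overlap$assd_um[2], digits = 4)))
  cat(sprintf("  anatomical error rate %.4g; BF fascicle %.4f; mean F1@0.5 %.4f\n",
              x$anatomical_error_rate, x$bf_fascicle, x$f1_curve$mean_f1[1]))
  cat(sprintf("  events: pred %d/%d vs gt %d/%d (split/merge); rate deviation %.4g /mm\n",
              x$pred_track$n_split, x$pred_track$n_merge,
              x$gt_track$n_split, x$gt_track$n_merge, x$event_rate_deviation))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `nervect_eval`.
#' @param ... Unused.
#' @return Long tibble with `metric`, `class`, `value`.
#' @export
tidy.nervect_eval <- function(x, ...) {
  rows <- list()
  for (i in 1:2) {
    cl <- x$overlap$class[i]
    for (m in c("dsc", "surface_dsc", "assd_um", "iou", "sensitivity", "specificity"))
      rows[[length(rows) + 1L]] <- tibble::tibble(metric = m, class = cl,
                                                  value = x$overlap[[m]][i])
  }
  add <- function(metric, value, class = "fascicle")
    rows[[length(rows) + 1L]] <<- tibble::tibble(metric = metric, class = class, value = value)
  for (i in seq_len(nrow(x$f1_curve)))
    add(sprintf("f1@%.2f", x$f1_curve$threshold[i]), x$f1_curve$mean_f1[i])
  add("over_segmentation_rate", x$over_under$over_rate)
  add("under_segmentation_rate", x$over_under$under_rate)
  for (i in seq_len(nrow(x$missed_by_size)))
    add(sprintf("miss_rate_%s", x$missed_by_size$bin[i]), x$missed_by_size$miss_fraction[i])
  add("cldice", x$cldice)
  add("anatomical_error_rate", x$anatomical_error_rate, class = "foreground")
  add("interslice_bf", x$bf_fascicle)
  add("interslice_bf", x$bf_epineurium, class = "epineurium")
  add("event_rate_deviation_per_mm", x$event_rate_deviation)
  add("event_rate_deviation_pct", x$event_rate_deviation_pct)
  do.call(rbind, rows)
}

#' Write an evaluation report as JSON
#'
#' @param x A `nervect_eval`.
#' @param path Output JSON path.
#' @param seed Seed recorded in the report header.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path, seed = NA_integer_) {
  td <- tidy.nervect_eval(x)
  out <- list(schema = "nervect-eval/1", seed = seed,
              spacing_um = x$spacing_um, tau = x$tau,
              metrics = td,
              events = list(pred = x$pred_track$events, gt = x$gt_track$events))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Glance at a trained model
#'
#' @param x A `nervect_model`.
#' @param ... Unused.
#' @return One-row tibble: epochs trained, final learning rate, final loss
#'   components and validation Dice.
#' @export
glance.nervect_model <- function(x, ...) {
  n <- nrow(x$log)
  tibble::tibble(epochs = n, lr_final = x$log$lr[n],
                 l_ce = x$log$l_ce[n], l_dice = x$log$l_dice[n],
                 l_topo = x$log$l_topo[n], total = x$log$total[n],
                 val_dice = x$log$val_dice[n],
                 use_topo = x$loss_cfg$use_topo,
                 lambda_topo = x$loss_cfg$lambda_topo)
}

#' Tidy a trained model's per-epoch log
#'
#' @param x A `nervect_model`.
#' @param ... Unused.
#' @return The per-epoch log tibble.
#' @export
tidy.nervect_model <- function(x, ...) x$log

#' Tidy an event track
#'
#' @param x An `event_track`.
#' @param ... Unused.
#' @return The events tibble.
#' @export
tidy.event_track <- function(x, ...) x$events

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
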