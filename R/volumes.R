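#' Intensity volume
#'
#' A single-channel 3D grayscale volume in native signed 16-bit range, indexed
#' `(z, y, x)` with `z` the nerve's longitudinal axis, together with its
#' isotropic voxel spacing in micrometres.
#'
#' @param data 3D numeric array indexed `(z, y, x)`.
#' @param spacing_um Isotropic voxel edge length in micrometres (default 11.4,
#'   the spacing of the microCT acquisitions this package targets).
#' @return An object of class `intensity_volume`: a list with elements `data`
#'   and `spacing_um`.
#' @examples
#' v <- intensity_volume(array(0L, dim = c(4, 8, 8)))
#' dim(v$data)
#' @export
intensity_volume <- function(data, spacing_um = 11.4) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array indexed (z, y, x)")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("`spacing_um` must be a single positive number")
  structure(list(data = data, spacing_um = as.numeric(spacing_um)),
            class = "intensity_volume")
}

#' Label volume
#'
#' A 3-class voxel grid indexed `(z, y, x)`: 0 = background, 1 = fascicle,
#' 2 = epineurium. Used for both ground-truth and predicted segmentations.
#'
#' @param labels 3D integer array with values in `{0, 1, 2}`.
#' @param spacing_um Isotropic voxel edge length in micrometres.
#' @return An object of class `label_volume`: a list with elements `labels`
#'   and `spacing_um`.
#' @examples
#' lv <- label_volume(array(0L, dim = c(4, 8, 8)))
#' table(lv$labels)
#' @export
label_volume <- function(labels, spacing_um = 11.4) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array indexed (z, y, x)")
  if (any(dim(labels) < 1L)) stop("all three dimensions must be >= 1")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), 0:2)
  if (length(bad))
    stop("label values outside {0, 1, 2}: ", paste(bad, collapse = ", "))
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("`spacing_um` must be a single positive number")
  structure(list(labels = labels, spacing_um = as.numeric(spacing_um)),
            class = "label_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_volume> %d x %d x %d (z, y, x), %.3g um/voxel, range [%s, %s]\n",
              d[1], d[2], d[3], x$spacing_um,
              format(min(x$data)), format(max(x$data))))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(as.vector(x$labels) + 1L, nbins = 3L)
  cat(sprintf("<label_volume> %d x %d x %d (z, y, x), %.3g um/voxel; background %d, fascicle %d, epineurium %d\n",
              d[1], d[2], d[3], x$spacing_um, tab[1], tab[2], tab[3]))
  invisible(x)
}

# Accept a label_volume or a bare array; return the integer array.
as_label_array <- function(x) {
  if (inherits(x, "label_volume")) return(x$labels)
  if (inherits(x, "intensity_volume")) stop("expected labels, got an intensity volume")
  x <- as.array(x)
  storage.mode(x) <- "integer"
  x
}

# Accept an intensity_volume or a bare array; return the numeric array.
as_intensity_array <- function(x) {
  if (inherits(x, "intensity_volume")) return(x$data)
  if (inherits(x, "label_volume")) stop("expected an intensity volume, got labels")
  as.array(x)
}

# Binary mask coercion: logical array from mask / labels==class.
as_mask <- function(x, class_id = NULL) {
  if (inherits(x, "label_volume")) {
    if (is.null(class_id)) stop("`class_id` required when passing a label volume")
    return(x$labels == class_id)
  }
  x <- as.array(x)
  if (is.logical(x)) return(x)
  if (!is.null(class_id)) return(x == class_id)
  x != 0
}

spacing_of <- function(x, default = 11.4) {
  if (inherits(x, c("intensity_volume", "label_volume"))) x$spacing_um else default
}
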