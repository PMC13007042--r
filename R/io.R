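#' Read a 3D volume from disk
#'
#' Reads a multi-page TIFF stack or an OME-Zarr array into an
#' [intensity_volume()] or [label_volume()]. Axis order is always `(z, y, x)`:
#' TIFF pages are z-slices, each a `(y, x)` matrix.
#'
#' @param path File (TIFF) or directory (OME-Zarr) path.
#' @param format `"tiff-stack"` or `"ome-zarr"`; `NULL` guesses from the path
#'   (directories are treated as Zarr).
#' @param type `"intensity"` or `"label"`. Label files with values outside
#'   `{0, 1, 2}` are rejected.
#' @param spacing_um Voxel spacing to attach when the file carries none.
#' @return An `intensity_volume` or `label_volume`.
#' @seealso [save_volume()]
#' @export
load_volume <- function(path, format = NULL, type = c("intensity", "label"),
                        spacing_um = 11.4) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (is.null(format)) format <- if (dir.exists(path)) "ome-zarr" else "tiff-stack"
  format <- match.arg(format, c("tiff-stack", "ome-zarr"))
  arr <- switch(format,
    "tiff-stack" = read_tiff_stack(path),
    "ome-zarr"   = read_zarr_volume(path))
  if (type == "label") label_volume(arr, spacing_um)
  else intensity_volume(arr, spacing_um)
}

#' Write a 3D volume to disk
#'
#' Integer grids round-trip bit-exactly: intensities are stored as 16-bit
#' samples, labels as 8-bit. The TIFF container is unsigned, so negative
#' intensities (reconstruction artifacts in raw scans) can only be stored via
#' OME-Zarr, which uses a signed 16-bit dtype.
#'
#' @param vol An [intensity_volume()] or [label_volume()].
#' @param path Destination file (TIFF) or directory (OME-Zarr).
#' @param format `"tiff-stack"` or `"ome-zarr"`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path, format = NULL) {
  if (!inherits(vol, c("intensity_volume", "label_volume")))
    stop("`vol` must be an intensity_volume or label_volume")
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff-stack" else "ome-zarr"
  format <- match.arg(format, c("tiff-stack", "ome-zarr"))
  is_label <- inherits(vol, "label_volume")
  arr <- if (is_label) vol$labels else vol$data
  if (format == "tiff-stack") {
    write_tiff_stack(arr, path, bits = if (is_label) 8L else 16L)
  } else {
    write_zarr_volume(arr, path, dtype = if (is_label) "|u1" else "<i2")
  }
  invisible(path)
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0L, dim = c(length(pages), ny, nx))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    if (!is.matrix(p)) stop("TIFF page ", z, " is not single-channel")
    if (nrow(p) != ny || ncol(p) != nx) stop("TIFF pages differ in size")
    arr[z, , ] <- p
  }
  storage.mode(arr) <- "integer"
  arr
}

write_tiff_stack <- function(arr, path, bits = 16L) {
  rng <- range(arr)
  maxv <- if (bits == 16L) 65535 else 255
  if (rng[1] < 0)
    stop("TIFF stacks store unsigned samples; negative values need format = \"ome-zarr\"")
  if (rng[2] > maxv) stop("values exceed ", bits, "-bit range")
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / maxv)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none"),
                 error = function(e) stop("cannot write TIFF at ", path, ": ", conditionMessage(e)))
  invisible(ok)
}

#' Normalize microCT intensities to the unit interval
#'
#' Clips the native 16-bit intensities to `[0, 32767]` and rescales to
#' `[0, 1]`. Clipping removes negative values, which in reconstructed scans
#' are artifacts outside the tissue. The operation is idempotent up to the
#' rescale: re-normalizing `round(out * 32767)` reproduces `out`.
#'
#' @param vol An [intensity_volume()] or bare 3D array.
#' @return A 3D numeric array with values in `[0, 1]`.
#' @examples
#' normalize_intensity(array(c(-500, 0, 16384, 32767, 40000), c(5, 1, 1)))[, 1, 1]
#' @export
normalize_intensity <- function(vol) {
  arr <- as_intensity_array(vol)
  pmin(pmax(arr, 0), 32767) / 32767
}

#' Combine fascicle and epineurium masks into a label volume
#'
#' Fascicle labels overwrite epineurium where the two masks overlap.
#'
#' @param fascicle_mask,epineurium_mask Binary 3D grids of equal shape.
#' @param spacing_um Voxel spacing for the result.
#' @return A [label_volume()] with 1 where fascicle, else 2 where epineurium,
#'   else 0.
#' @export
combine_labels <- function(fascicle_mask, epineurium_mask, spacing_um = 11.4) {
  f <- as_mask(fascicle_mask); e <- as_mask(epineurium_mask)
  if (!identical(dim(f), dim(e))) stop("mask shapes differ")
  out <- array(0L, dim = dim(f))
  out[e] <- 2L
  out[f] <- 1L
  label_volume(out, spacing_um)
}
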