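# Minimal Zarr v2 store (directory layout, uncompressed C-order chunks)
# with a single-scale OME-Zarr group wrapper. Supports the three dtypes this
# package writes: "<i2" (intensity), "|u1" (labels), "<f8" (probabilities).
# Chunked along z so large stacks never require one monolithic chunk file.

zarr_dtype_info <- function(dtype) {
  switch(dtype,
    "<i2" = list(size = 2L, what = integer(), signed = TRUE),
    "|u1" = ,
    "<u1" = list(size = 1L, what = integer(), signed = FALSE),
    "<f8" = list(size = 8L, what = numeric(), signed = TRUE),
    stop("unsupported Zarr dtype: ", dtype))
}

write_zarr_volume <- function(arr, path, dtype = "<i2", chunk_z = 16L) {
  d <- dim(arr)
  if (length(d) != 3L) stop("Zarr writer expects a 3D array")
  if (dtype == "<i2" && (min(arr) < -32768 || max(arr) > 32767))
    stop("values exceed signed 16-bit range")
  if (dtype %in% c("|u1", "<u1") && (min(arr) < 0 || max(arr) > 255))
    stop("values exceed 8-bit range")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  arr_dir <- file.path(path, "0")
  dir.create(arr_dir, showWarnings = FALSE)

  writeLines(jsonlite::toJSON(list(zarr_format = 2L), auto_unbox = TRUE),
             file.path(path, ".zgroup"))
  multiscales <- list(list(
    version = "0.4", name = basename(path),
    axes = list(list(name = "z", type = "space", unit = "micrometer"),
                list(name = "y", type = "space", unit = "micrometer"),
                list(name = "x", type = "space", unit = "micrometer")),
    datasets = list(list(path = "0"))))
  writeLines(jsonlite::toJSON(list(multiscales = multiscales), auto_unbox = TRUE),
             file.path(path, ".zattrs"))

  chunk_z <- min(as.integer(chunk_z), d[1])
  meta <- list(zarr_format = 2L, shape = d, chunks = c(chunk_z, d[2], d[3]),
               dtype = dtype, compressor = NULL, fill_value = 0L,
               order = "C", filters = NULL)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             file.path(arr_dir, ".zarray"))

  info <- zarr_dtype_info(dtype)
  n_chunks <- ceiling(d[1] / chunk_z)
  for (ci in seq_len(n_chunks)) {
    z0 <- (ci - 1L) * chunk_z + 1L
    z1 <- min(ci * chunk_z, d[1])
    block <- arr[z0:z1, , , drop = FALSE]
    if (nrow(block) < chunk_z) {  # pad final chunk to full chunk shape
      pad <- array(0, dim = c(chunk_z - (z1 - z0 + 1L), d[2], d[3]))
      block <- array(c(aperm(block, c(2, 3, 1)), aperm(pad, c(2, 3, 1))), dim = c(d[2], d[3], chunk_z))
      block <- aperm(block, c(3, 1, 2))
    }
    # C order for shape (z, y, x): x fastest
    vec <- as.vector(aperm(block, c(3, 2, 1)))
    con <- file(file.path(arr_dir, sprintf("%d.0.0", ci - 1L)), "wb")
    if (is.integer(info$what)) {
      writeBin(as.integer(round(vec)), con, size = info$size, endian = "little")
    } else {
      writeBin(as.numeric(vec), con, size = info$size, endian = "little")
    }
    close(con)
  }
  invisible(path)
}

read_zarr_volume <- function(path) {
  arr_dir <- if (file.exists(file.path(path, ".zarray"))) path else file.path(path, "0")
  meta_file <- file.path(arr_dir, ".zarray")
  if (!file.exists(meta_file)) stop("not a Zarr array or OME-Zarr group: ", path)
  meta <- jsonlite::fromJSON(meta_file)
  if (!is.null(meta$compressor)) stop("compressed Zarr chunks are not supported")
  if (meta$order != "C") stop("only C-order Zarr arrays are supported")
  d <- as.integer(meta$shape); ch <- as.integer(meta$chunks)
  if (length(d) != 3L) stop("expected a 3D Zarr array")
  if (ch[2] != d[2] || ch[3] != d[3]) stop("only z-chunked arrays are supported")
  info <- zarr_dtype_info(meta$dtype)
  arr <- array(if (is.integer(info$what)) 0L else 0, dim = d)
  n_chunks <- ceiling(d[1] / ch[1])
  for (ci in seq_len(n_chunks)) {
    f <- file.path(arr_dir, sprintf("%d.0.0", ci - 1L))
    if (!file.exists(f)) stop("missing Zarr chunk: ", f)
    con <- file(f, "rb")
    vec <- readBin(con, info$what, n = prod(c(ch[1], d[2], d[3])),
                   size = info$size, signed = info$signed, endian = "little")
    close(con)
    block <- aperm(array(vec, dim = c(d[3], d[2], ch[1])), c(3, 2, 1))
    z0 <- (ci - 1L) * ch[1] + 1L
    z1 <- min(ci * ch[1], d[1])
    arr[z0:z1, , ] <- block[seq_len(z1 - z0 + 1L), , , drop = FALSE]
  }
  arr
}
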