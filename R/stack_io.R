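#' Multichannel 3D image stack
#'
#' Container for a multichannel confocal z-stack with physical voxel
#' spacing. Intensities are stored as a 4-axis array ordered
#' (channel, z, y, x). All physical coordinates used in this package are
#' (z, y, x) in micrometres measured from the corner of voxel (0, 0, 0),
#' with voxel centers at `(i + 0.5) * spacing`.
#'
#' @param intensities 4-axis numeric array ordered (channel, z, y, x),
#'   finite and non-negative.
#' @param voxel_spacing numeric `(dz, dy, dx)` in micrometres, all > 0.
#' @param channel_names character vector of unique channel labels, one
#'   per channel.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(intensities, voxel_spacing, channel_names) {
  if (length(dim(intensities)) != 4L)
    stopf("intensities must be a 4-axis array (channel, z, y, x)")
  if (!all(is.finite(intensities)))
    stopf("intensities must be finite")
  if (any(intensities < 0))
    stopf("intensities must be non-negative")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stopf("voxel_spacing must be three strictly positive values (dz, dy, dx)")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(intensities)[1])
    stopf("channel_names length (%d) does not match channel axis (%d)",
          length(channel_names), dim(intensities)[1])
  if (anyDuplicated(channel_names))
    stopf("channel names must be unique")
  structure(
    list(intensities = intensities,
         voxel_spacing = voxel_spacing,
         channel_names = channel_names),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_stack> %d channel(s) [%s], %d x %d x %d voxels (z,y,x)\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  voxel spacing (dz, dy, dx): %.3g x %.3g x %.3g um\n",
              x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$intensities)

#' Extract one channel of a stack
#'
#' @param stack an [image_stack()].
#' @param name exact channel label (names are matched exactly, including
#'   whitespace).
#' @return a 3-axis (z, y, x) intensity array carrying the stack's voxel
#'   spacing in attribute `"voxel_spacing"`.
#' @export
get_channel <- function(stack, name) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(name, stack$channel_names)
  if (is.na(i))
    stopf("unknown channel '%s' (available: %s)", name,
          paste(stack$channel_names, collapse = ", "))
  g <- stack$intensities[i, , , , drop = FALSE]
  dim(g) <- dim(stack$intensities)[2:4]
  attr(g, "voxel_spacing") <- stack$voxel_spacing
  g
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Write a stack as multi-page TIFF with a YAML sidecar
#'
#' Pages are written channel-major (all z-planes of channel 1, then
#' channel 2, ...). Integer-valued stacks up to 65535 are stored as
#' 16-bit samples and round-trip exactly; other data are stored as
#' 32-bit float samples scaled to the unit range. Voxel spacing, channel
#' names and the intensity scale go into a `.yaml` sidecar next to the
#' TIFF.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written with the same
#'   basename and extension `.yaml`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$intensities)
  v <- stack$intensities
  integral <- all(v == round(v)) && max(v) <= 65535
  if (integral) {
    scale <- 65535
    bps <- 16L
  } else {
    scale <- max(v, 1)
    bps <- 32L
  }
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ci in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      m <- v[ci, zi, , ]
      dim(m) <- d[3:4]
      pages[[k]] <- m / scale
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bps)
  meta <- list(
    spacing = as.numeric(stack$voxel_spacing),
    channels = as.list(stack$channel_names),
    n_z = as.integer(d[2]),
    dtype = if (integral) "uint16" else "float32",
    scale = scale)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads a TIFF written by [write_stack()] (multi-page TIFF plus YAML
#' sidecar carrying spacing and channel names). A bare TIFF without a
#' sidecar is read as a single-channel z-stack; its voxel spacing must
#' then be supplied through `spacing_override` and channels are named
#' `"ch0"`.
#'
#' @param path TIFF file path.
#' @param spacing_override optional `(dz, dy, dx)` in micrometres used
#'   when (and only when) the file carries no spacing metadata.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("unreadable TIFF '%s': %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    spacing <- as.numeric(meta$spacing)
    channels <- as.character(unlist(meta$channels))
    nz <- as.integer(meta$n_z)
    scale <- as.numeric(meta$scale %||% 1)
    dtype <- meta$dtype %||% "float32"
  } else {
    if (is.null(spacing_override))
      stopf("'%s' has no spacing metadata and no spacing_override was given",
            path)
    spacing <- as.numeric(spacing_override)
    channels <- "ch0"
    nz <- np
    scale <- 1
    dtype <- "raw"
  }
  if (!is.null(spacing_override)) spacing <- as.numeric(spacing_override)
  nc <- length(channels)
  if (nc * nz != np)
    stopf("page count %d does not match %d channel(s) x %d z-plane(s)",
          np, nc, nz)
  if (nz < 1L) stopf("stack must contain at least one z-plane")
  dyx <- dim(pages[[1]])[1:2]
  arr <- array(0, dim = c(nc, nz, dyx[1], dyx[2]))
  k <- 1L
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      m <- pages[[k]]
      if (length(dim(m)) == 3L) m <- m[, , 1]   # collapse grayscale triplets
      arr[ci, zi, , ] <- if (identical(dtype, "uint16")) round(m * scale)
                         else m * scale
      k <- k + 1L
    }
  }
  image_stack(arr, spacing, channels)
}
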