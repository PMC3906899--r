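# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Otsu threshold of an intensity sample
#'
#' Thin wrapper around [EBImage::otsu()] operating on a plain numeric
#' vector. The histogram is built over the observed intensity range with
#' 256 levels. A constant sample returns its single value.
#'
#' @param v numeric vector of intensities.
#' @return a single threshold on the intensity scale of `v`.
#' @keywords internal
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stopf("no finite intensities for Otsu thresholding")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  EBImage::otsu(matrix(v, ncol = 1L), range = rng, levels = 256L)
}

# Resolve a threshold argument: "otsu" or a fixed numeric value.
# Fixed values must lie within the intensity range of `v`.
resolve_threshold <- function(threshold, v, check_range = TRUE) {
  if (is.character(threshold)) {
    if (!identical(threshold, "otsu"))
      stopf("unknown threshold rule '%s' (use \"otsu\" or a number)", threshold)
    return(otsu_threshold(v))
  }
  thr <- as.numeric(threshold)
  if (length(thr) != 1L || !is.finite(thr))
    stopf("fixed threshold must be a single finite number")
  if (check_range) {
    rng <- range(v, finite = TRUE)
    if (thr < rng[1] || thr > rng[2])
      stopf("fixed threshold %.4g outside intensity range [%.4g, %.4g]",
            thr, rng[1], rng[2])
  }
  thr
}

# Gaussian blur of a (nz, ny, nx) array with per-axis sigma in micrometres.
blur_um <- function(arr, spacing, sigma_um) {
  if (all(sigma_um <= 0)) return(arr)
  d <- dim(arr)
  out <- cpp_gauss_blur3(as.numeric(arr), as.integer(d),
                         as.numeric(sigma_um / spacing))
  array(out, dim = d)
}

# Shoelace area of an (n x 2) polygon (columns y, x), absolute value.
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Signed shoelace area; sign encodes vertex orientation.
polygon_area_signed <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# md5 of a serialized R object (used for config provenance).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}
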