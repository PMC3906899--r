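#' Detect DRAQ5-stained nuclei as 3D spot objects
#'
#' Smooths the nuclear channel with an isotropic 0.5 um Gaussian (in
#' physical space), thresholds it, labels 26-connected voxel components,
#' and represents each component as a spot: intensity-weighted centroid
#' in micrometres, voxel count, total intensity, and volume-equivalent
#' sphere diameter `(6 V / pi)^(1/3)` with `V = voxel_count * dz*dy*dx`.
#' Only spots strictly larger than `min_diameter` are retained (the
#' conventional "> 3 um" nucleus filter; a spot of exactly 3 um is
#' excluded). Optional splitting of touching nuclei assigns the voxels
#' of a component to its smoothed-intensity local maxima by nearest
#' seed.
#'
#' @param stack an [image_stack()].
#' @param channel nuclear channel label (default `"DRAQ5"`).
#' @param min_diameter strict lower diameter bound in um (default 3).
#' @param threshold `"otsu"` or a fixed intensity value.
#' @param split_touching split merged components at intensity maxima
#'   separated by more than `min_diameter` (off by default).
#' @param smoothing_sigma Gaussian smoothing in um.
#' @return a data.frame of class `spot_table` with columns `z`, `y`,
#'   `x` (um), `equivalent_diameter`, `voxel_count`, `total_intensity`,
#'   `compartment` (initially `"unclassified"`).
#' @export
detect_nuclei <- function(stack, channel = "DRAQ5", min_diameter = 3,
                          threshold = "otsu", split_touching = FALSE,
                          smoothing_sigma = 0.5) {
  if (min_diameter <= 0) stopf("min_diameter must be positive")
  v <- get_channel(stack, channel)
  sp <- stack$voxel_spacing
  sm <- blur_um(v, sp, rep(smoothing_sigma, 3))
  thr <- resolve_threshold(threshold, sm, check_range = FALSE)
  mask <- sm >= thr
  empty <- spot_table(data.frame(
    z = numeric(0), y = numeric(0), x = numeric(0),
    equivalent_diameter = numeric(0), voxel_count = integer(0),
    total_intensity = numeric(0), compartment = character(0),
    stringsAsFactors = FALSE))
  if (!any(mask) || max(sm) == min(sm)) return(empty)
  d <- dim(v)
  lab <- cpp_label3(as.logical(mask), as.integer(d), 26L)
  dim(lab) <- d
  if (split_touching) lab <- split_components(lab, sm, sp, min_diameter)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)

  idx <- which(lab > 0L)
  comp <- lab[idx]
  zi <- ((idx - 1L) %% d[1]) + 1L
  yi <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  xi <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  w <- v[idx]
  wsum <- tapply(w, comp, sum)
  vox <- tabulate(comp, nbins = nlab)
  safe_w <- ifelse(wsum > 0, wsum, vox)  # fall back to unweighted centroid
  cz <- tapply(w * (zi - 0.5) * sp[1], comp, sum) / safe_w
  cy <- tapply(w * (yi - 0.5) * sp[2], comp, sum) / safe_w
  cx <- tapply(w * (xi - 0.5) * sp[3], comp, sum) / safe_w
  if (any(wsum == 0)) {
    z0 <- tapply((zi - 0.5) * sp[1], comp, mean)
    y0 <- tapply((yi - 0.5) * sp[2], comp, mean)
    x0 <- tapply((xi - 0.5) * sp[3], comp, mean)
    cz[wsum == 0] <- z0[wsum == 0]
    cy[wsum == 0] <- y0[wsum == 0]
    cx[wsum == 0] <- x0[wsum == 0]
  }
  vol <- vox * prod(sp)
  eqd <- (6 * vol / pi)^(1 / 3)
  keep <- eqd > min_diameter
  spot_table(data.frame(
    z = as.numeric(cz)[keep], y = as.numeric(cy)[keep],
    x = as.numeric(cx)[keep],
    equivalent_diameter = eqd[keep], voxel_count = vox[keep],
    total_intensity = as.numeric(wsum)[keep],
    compartment = rep("unclassified", sum(keep)),
    stringsAsFactors = FALSE))
}

spot_table <- function(df) {
  structure(df, class = c("spot_table", "data.frame"))
}

# Split labelled components at well-separated local intensity maxima.
split_components <- function(lab, sm, sp, min_diameter) {
  d <- dim(lab)
  out <- lab
  next_lab <- max(lab)
  for (comp in seq_len(max(lab))) {
    idx <- which(lab == comp)
    if (length(idx) < 8L) next
    zi <- ((idx - 1L) %% d[1]) + 1L
    yi <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
    xi <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
    pz <- (zi - 0.5) * sp[1]; py <- (yi - 0.5) * sp[2]; px <- (xi - 0.5) * sp[3]
    ints <- sm[idx]
    ord <- order(ints, decreasing = TRUE)
    seeds <- integer(0)
    for (k in ord) {
      if (!length(seeds)) { seeds <- k; next }
      dd <- sqrt((pz[seeds] - pz[k])^2 + (py[seeds] - py[k])^2 +
                 (px[seeds] - px[k])^2)
      if (all(dd > min_diameter) && ints[k] > 0.8 * ints[ord[1]])
        seeds <- c(seeds, k)
    }
    if (length(seeds) < 2L) next
    # nearest-seed assignment
    assign <- vapply(seq_along(idx), function(k) {
      dd <- (pz[seeds] - pz[k])^2 + (py[seeds] - py[k])^2 +
            (px[seeds] - px[k])^2
      which.min(dd)
    }, integer(1))
    for (s in 2:length(seeds)) {
      next_lab <- next_lab + 1L
      out[idx[assign == s]] <- next_lab
    }
  }
  out
}

#' Classify spots into vessel compartments
#'
#' Assigns each spot, by its centroid, to one of three compartments
#' defined by the nested basement-membrane surfaces: inside the
#' endothelial-BM mesh is `luminal`; between the endothelial and
#' parenchymal BM meshes is `perivascular`; outside the parenchymal BM
#' is `parenchymal` (reported, but conventionally excluded from
#' vessel-associated counts). Labels are exhaustive and exclusive.
#'
#' @param spots a `spot_table` from [detect_nuclei()].
#' @param endo_mesh,parench_mesh watertight [surface_mesh()] objects;
#'   the endothelial mesh must be nested inside the parenchymal mesh
#'   (validated by sampling endothelial vertices).
#' @return the spot table with the `compartment` column filled in.
#' @export
classify_spots <- function(spots, endo_mesh, parench_mesh) {
  stopifnot(inherits(endo_mesh, "surface_mesh"),
            inherits(parench_mesh, "surface_mesh"))
  if (!isTRUE(attr(endo_mesh, "watertight")) ||
      !isTRUE(attr(parench_mesh, "watertight")))
    stopf("both meshes must be watertight")
  nvert <- nrow(endo_mesh$vertices)
  samp <- endo_mesh$vertices[seq(1L, nvert, length.out = min(nvert, 200L)), ,
                             drop = FALSE]
  if (!all(point_inside(parench_mesh, samp)))
    stopf("endothelial mesh is not nested inside the parenchymal mesh")
  if (nrow(spots) == 0L) return(spots)
  pts <- as.matrix(spots[, c("z", "y", "x")])
  in_endo <- point_inside(endo_mesh, pts)
  in_par <- point_inside(parench_mesh, pts)
  spots$compartment <- ifelse(in_endo, "luminal",
                              ifelse(in_par, "perivascular", "parenchymal"))
  spots
}

#' 3D spread profile of classified spots
#'
#' For each compartment and each spatial axis: the median centroid
#' position, the maximum spread above the median
#' (`max(coord) - median`), the minimum spread below it
#' (`median - min(coord)`), and the spot count — the numbers summarised
#' by box-and-whisker "vantage" plots of luminal and perivascular cells.
#' Absent compartments are reported with count 0.
#'
#' @param spots a classified `spot_table`.
#' @return a data.frame of class `spread_profile` with columns
#'   `compartment`, `axis`, `n`, `median`, `spread_max`, `spread_min`.
#' @export
spread_profile <- function(spots) {
  comps <- c("luminal", "perivascular", "parenchymal")
  axes <- c(x = "x", y = "y", z = "z")
  rows <- list()
  for (cp in comps) {
    sub <- spots[spots$compartment == cp, , drop = FALSE]
    for (ax in names(axes)) {
      if (nrow(sub) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          compartment = cp, axis = ax, n = 0L, median = NA_real_,
          spread_max = 0, spread_min = 0, stringsAsFactors = FALSE)
      } else {
        v <- sub[[ax]]
        md <- median(v)
        rows[[length(rows) + 1L]] <- data.frame(
          compartment = cp, axis = ax, n = nrow(sub), median = md,
          spread_max = max(v) - md, spread_min = md - min(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("spread_profile", "data.frame"))
}

#' Counts of spots per compartment
#'
#' @param spots a classified `spot_table`.
#' @return named integer vector over luminal, perivascular, parenchymal.
#' @export
compartment_counts <- function(spots) {
  comps <- c("luminal", "perivascular", "parenchymal")
  out <- vapply(comps, function(cp) sum(spots$compartment == cp), integer(1))
  names(out) <- comps
  out
}
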