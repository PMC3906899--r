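#' Specification of a synthetic vessel phantom
#'
#' Describes a straight venule running along the z-axis of the grid:
#' nested endothelial and parenchymal basement-membrane (BM) tubes
#' labelled in a Laminin-1 channel, a junctional claudin-5 lattice on the
#' endothelial tube with a configurable retained-coverage fraction, and
#' DRAQ5-stained nuclei placed in the luminal, perivascular and
#' parenchymal compartments. The default grid emulates a spinal venule
#' imaged as 60 z-slices at 1 um increments with sub-micron xy sampling.
#'
#' @param grid_shape integer `(nz, ny, nx)` voxel counts.
#' @param voxel_spacing `(dz, dy, dx)` in micrometres, all > 0.
#' @param lumen_radius,endo_bm_radius,parench_bm_radius tube radii in um;
#'   must be strictly increasing and fit inside the grid.
#' @param cln5_coverage fraction in `[0, 1]` of junctional lattice
#'   segments retained (1 = continuous junctions, lower values emulate
#'   the fragmented staining of inflamed vessels).
#' @param junction_line_width width of the junctional lines in um.
#' @param n_nuclei named integer vector
#'   `c(luminal = , perivascular = , parenchymal = )`.
#' @param nucleus_diameter_mean,nucleus_diameter_sd nucleus diameter
#'   distribution in um.
#' @param channel_gains named peak intensities; channels present here are
#'   rendered. Recognised names: `Lam1`, `CLN-5`, `DRAQ5`, `CD31`,
#'   `GFAP`, `CCL2`.
#' @param background_level constant background intensity added to every
#'   channel.
#' @param blur_sigma Gaussian blur `(sz, sy, sx)` in um, applied before
#'   noise.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`. Poisson
#'   noise is applied to signal + background; detector output is
#'   quantised to integer counts in all cases.
#' @param noise_sd standard deviation for `"gaussian"` noise.
#' @param seed integer seed controlling lattice-gap sampling, nucleus
#'   placement and noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(60L, 160L, 160L),
                         voxel_spacing = c(1.0, 0.3, 0.3),
                         lumen_radius = 6,
                         endo_bm_radius = 8,
                         parench_bm_radius = 18,
                         cln5_coverage = 1.0,
                         junction_line_width = 0.9,
                         n_nuclei = c(luminal = 0L, perivascular = 0L,
                                      parenchymal = 0L),
                         nucleus_diameter_mean = 6,
                         nucleus_diameter_sd = 0.4,
                         channel_gains = c(Lam1 = 200, `CLN-5` = 180,
                                           DRAQ5 = 220),
                         background_level = 4,
                         blur_sigma = c(0.5, 0.35, 0.35),
                         noise_model = c("poisson", "gaussian", "none"),
                         noise_sd = 3,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stopf("grid_shape must be three voxel counts >= 4")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stopf("voxel_spacing must be strictly positive")
  if (!(lumen_radius < endo_bm_radius && endo_bm_radius < parench_bm_radius))
    stopf("radii must satisfy lumen < endothelial BM < parenchymal BM")
  half_extent <- min(grid_shape[2] * voxel_spacing[2],
                     grid_shape[3] * voxel_spacing[3]) / 2
  if (parench_bm_radius >= half_extent)
    stopf("parenchymal BM radius (%.1f um) does not fit in the grid (%.1f um half-extent)",
          parench_bm_radius, half_extent)
  if (cln5_coverage < 0 || cln5_coverage > 1)
    stopf("cln5_coverage must lie in [0, 1]")
  req <- c("luminal", "perivascular", "parenchymal")
  if (!all(req %in% names(n_nuclei)))
    stopf("n_nuclei needs named counts for %s", paste(req, collapse = ", "))
  n_nuclei <- as.integer(n_nuclei[req])
  names(n_nuclei) <- req
  if (any(n_nuclei < 0)) stopf("nucleus counts must be non-negative")
  if (nucleus_diameter_mean <= 0) stopf("nucleus diameter must be positive")
  if (is.null(names(channel_gains)) || anyDuplicated(names(channel_gains)))
    stopf("channel_gains must have unique names")
  structure(
    list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
         lumen_radius = lumen_radius, endo_bm_radius = endo_bm_radius,
         parench_bm_radius = parench_bm_radius,
         cln5_coverage = cln5_coverage,
         junction_line_width = junction_line_width,
         n_nuclei = n_nuclei,
         nucleus_diameter_mean = nucleus_diameter_mean,
         nucleus_diameter_sd = nucleus_diameter_sd,
         channel_gains = channel_gains,
         background_level = background_level,
         blur_sigma = as.numeric(blur_sigma),
         noise_model = noise_model, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s at (%s) um, radii %g/%g/%g um\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_spacing, collapse = ", "),
              x$lumen_radius, x$endo_bm_radius, x$parench_bm_radius))
  cat(sprintf("  CLN-5 coverage %.2f; nuclei L/P/Pa = %d/%d/%d; noise %s; seed %d\n",
              x$cln5_coverage, x$n_nuclei[1], x$n_nuclei[2], x$n_nuclei[3],
              x$noise_model, x$seed))
  invisible(x)
}

#' Named phantom presets
#'
#' Presets encode the qualitative experimental regimes used throughout
#' the package's validation: a healthy vessel with continuous junctions
#' and no vessel-associated cellularity (`naive`), wild-type disease at
#' an early and a peak time point (`wt_d9`, `wt_d16`), an
#' astrocyte-CCL2-knockout-like regime with relatively preserved
#' junctions but dense perivascular cuffing (`astro_ko_d16`), and an
#' endothelial-CCL2-knockout-like regime with intermediate junctional
#' loss and leukocytes stalled in the lumen (`endo_ko_d16`). Presets
#' differ only in `cln5_coverage` and `n_nuclei`.
#'
#' @param name one of `"naive"`, `"wt_d9"`, `"wt_d16"`,
#'   `"astro_ko_d16"`, `"endo_ko_d16"`.
#' @param seed integer seed passed to [phantom_spec()].
#' @param ... further arguments forwarded to [phantom_spec()] (e.g.
#'   `noise_model`).
#' @return a valid [phantom_spec()].
#' @export
phantom_preset <- function(name, seed = 1L, ...) {
  presets <- list(
    naive        = list(cov = 1.00, n = c(0L, 0L, 2L)),
    wt_d9        = list(cov = 0.40, n = c(0L, 5L, 4L)),
    wt_d16       = list(cov = 0.20, n = c(0L, 8L, 5L)),
    astro_ko_d16 = list(cov = 0.40, n = c(0L, 8L, 2L)),
    endo_ko_d16  = list(cov = 0.35, n = c(5L, 3L, 2L)))
  if (!name %in% names(presets))
    stopf("unknown preset '%s' (one of %s)", name,
          paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  phantom_spec(cln5_coverage = p$cov,
               n_nuclei = c(luminal = p$n[1], perivascular = p$n[2],
                            parenchymal = p$n[3]),
               seed = seed, ...)
}

# ---- internal geometry helpers ------------------------------------------

# Circular wrap-around distance between angles (radians).
ang_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Deterministic junctional lattice layout on the endothelial tube:
# circumferential rings and longitudinal lines split into whole segments
# (ring arcs between adjacent longitudinal angles; line pieces between
# adjacent rings). The layout depends only on the spec geometry, never on
# the seed, so phantoms that differ only in coverage share one lattice.
lattice_layout <- function(spec) {
  dz <- spec$voxel_spacing[1]
  lz <- spec$grid_shape[1] * dz
  ring_spacing <- 6
  n_long <- 12L
  z_rings <- seq(ring_spacing / 2, lz - ring_spacing / 2, by = ring_spacing)
  # snap rings onto voxel-center planes so each ring renders at least one
  # z-slice regardless of the z sampling
  z_rings <- (round(z_rings / dz - 0.5) + 0.5) * dz
  theta_long <- seq(0, 2 * pi, length.out = n_long + 1L)[-(n_long + 1L)]
  list(z_rings = z_rings, theta_long = theta_long, n_long = n_long)
}

#' Generate a synthetic vessel phantom
#'
#' Renders the multichannel stack described by a [phantom_spec()] and
#' returns it together with complete ground truth (per-slice BM contour
#' polygons, analytic closed-cylinder surface areas, nucleus records and
#' the realised claudin-5 coverage). Rendering order is: ideal geometry,
#' Gaussian blur, constant background, noise, quantisation to integer
#' detector counts. Identical spec + seed gives bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `stack` ([image_stack()]) and
#'   `ground_truth` (class `phantom_truth`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  zc <- (seq_len(nz) - 0.5) * sp[1]
  yc <- (seq_len(ny) - 0.5) * sp[2]
  xc <- (seq_len(nx) - 0.5) * sp[3]
  cy <- ny * sp[2] / 2
  cx <- nx * sp[3] / 2
  lz <- nz * sp[1]

  dy <- yc - cy
  dx <- xc - cx
  r2d <- sqrt(outer(dy^2, dx^2, `+`))      # (ny, nx) radial distance
  th2d <- atan2(matrix(dx, ny, nx, byrow = TRUE), matrix(dy, ny, nx))

  bm_width <- 0.8                            # BM shell thickness, um
  shell2d <- function(r, w) abs(r2d - r) <= w / 2
  rep_z <- function(m2d, values = 1) {
    a <- array(0, dim = d)
    idx <- which(m2d)
    for (zi in seq_len(nz)) a[zi, , ][idx] <- values
    a
  }

  gains <- spec$channel_gains
  channels <- names(gains)
  ideal <- list()

  # --- nuclei placement (first RNG consumer) -----------------------------
  margin <- 1.0        # minimum clearance nucleus surface <-> any surface
  sep_gap <- 2.5       # minimum surface-to-surface gap between nuclei
  placed <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                       diameter = numeric(0), compartment = character(0),
                       stringsAsFactors = FALSE)
  draw_radius <- function() {
    dia <- rnorm(1, spec$nucleus_diameter_mean, spec$nucleus_diameter_sd)
    dia <- min(max(dia, spec$nucleus_diameter_mean - 3 * spec$nucleus_diameter_sd),
               spec$nucleus_diameter_mean + 3 * spec$nucleus_diameter_sd)
    dia / 2
  }
  for (comp in c("luminal", "perivascular", "parenchymal")) {
    n_want <- spec$n_nuclei[[comp]]
    got <- 0L
    tries <- 0L
    while (got < n_want) {
      tries <- tries + 1L
      if (tries > 20000L)
        stopf("could not place %s nuclei with the required margins", comp)
      rn <- draw_radius()
      z0 <- runif(1, rn + margin, lz - rn - margin)
      if (comp == "luminal") {
        rmax <- spec$endo_bm_radius - rn - margin
        if (rmax <= 0) next
        rad <- sqrt(runif(1)) * rmax
        th <- runif(1, 0, 2 * pi)
      } else if (comp == "perivascular") {
        rmin <- spec$endo_bm_radius + rn + margin
        rmax <- spec$parench_bm_radius - rn - margin
        if (rmax <= rmin) next
        rad <- runif(1, rmin, rmax)
        th <- runif(1, 0, 2 * pi)
      } else {
        y0 <- runif(1, rn + margin, ny * sp[2] - rn - margin)
        x0 <- runif(1, rn + margin, nx * sp[3] - rn - margin)
        rad <- sqrt((y0 - cy)^2 + (x0 - cx)^2)
        if (rad < spec$parench_bm_radius + rn + margin) next
        th <- atan2(x0 - cx, y0 - cy)
      }
      y0 <- cy + rad * cos(th)
      x0 <- cx + rad * sin(th)
      if (y0 < rn + margin || y0 > ny * sp[2] - rn - margin ||
          x0 < rn + margin || x0 > nx * sp[3] - rn - margin) next
      if (nrow(placed) > 0) {
        dd <- sqrt((placed$z - z0)^2 + (placed$y - y0)^2 + (placed$x - x0)^2)
        if (any(dd < placed$diameter / 2 + rn + sep_gap)) next
      }
      placed <- rbind(placed, data.frame(
        z = z0, y = y0, x = x0, diameter = 2 * rn, compartment = comp,
        stringsAsFactors = FALSE))
      got <- got + 1L
    }
  }

  # --- CLN-5 lattice with whole-segment gap removal ----------------------
  realized_coverage <- NA_real_
  if ("CLN-5" %in% channels) {
    lay <- lattice_layout(spec)
    w <- spec$junction_line_width
    re <- spec$endo_bm_radius
    shell_idx2d <- which(abs(r2d - re) <= w / 2)
    th_s <- th2d[shell_idx2d]
    # ring hit per z-slice, longitudinal hit per shell pixel
    ring_of_z <- sapply(zc, function(z) {
      i <- which.min(abs(lay$z_rings - z))
      if (abs(lay$z_rings[i] - z) <= w / 2) i else 0L
    })
    arc_of_px <- findInterval(th_s %% (2 * pi),
                              c(lay$theta_long, 2 * pi), rightmost.closed = TRUE)
    arc_of_px[arc_of_px > lay$n_long] <- 1L
    long_d <- sapply(lay$theta_long, function(t0) ang_dist(th_s, t0)) * re
    long_hit <- apply(long_d, 1, function(r) {
      i <- which.min(r)
      if (r[i] <= w / 2) i else 0L
    })
    interval_of_z <- findInterval(zc, lay$z_rings) + 1L  # 1..n_rings+1
    n_rings <- length(lay$z_rings)
    n_ring_seg <- n_rings * lay$n_long
    n_long_seg <- lay$n_long * (n_rings + 1L)
    n_seg <- n_ring_seg + n_long_seg
    # per-voxel segment id over the (shell pixel, z) grid; 0 = not lattice
    seg_id <- matrix(0L, nrow = length(shell_idx2d), ncol = nz)
    for (zi in seq_len(nz)) {
      ri <- ring_of_z[zi]
      if (ri > 0L) {
        seg_id[, zi] <- (ri - 1L) * lay$n_long + arc_of_px
      } else {
        on_long <- long_hit > 0L
        seg_id[on_long, zi] <- n_ring_seg +
          (long_hit[on_long] - 1L) * (n_rings + 1L) + interval_of_z[zi]
      }
    }
    seg_counts <- tabulate(seg_id[seg_id > 0L], nbins = n_seg)
    present <- which(seg_counts > 0L)
    m_keep <- round(spec$cln5_coverage * length(present))
    keep <- if (m_keep >= length(present)) present
            else sort(sample(present, m_keep))
    keep_mask <- rep(FALSE, n_seg)
    keep_mask[keep] <- TRUE
    realized_coverage <- if (sum(seg_counts) > 0)
      sum(seg_counts[keep]) / sum(seg_counts) else NA_real_
    cl <- array(0, dim = d)
    for (zi in seq_len(nz)) {
      sel <- seg_id[, zi]
      hit <- sel > 0L & keep_mask[pmax(sel, 1L)]
      if (any(hit)) {
        sl <- cl[zi, , ]
        sl[shell_idx2d[hit]] <- gains[["CLN-5"]]
        cl[zi, , ] <- sl
      }
    }
    ideal[["CLN-5"]] <- cl
  }

  if ("Lam1" %in% channels) {
    m <- shell2d(spec$endo_bm_radius, bm_width) |
         shell2d(spec$parench_bm_radius, bm_width)
    ideal[["Lam1"]] <- rep_z(m, gains[["Lam1"]])
  }
  if ("CD31" %in% channels) {
    ideal[["CD31"]] <- rep_z(shell2d(spec$endo_bm_radius - 1, bm_width),
                             gains[["CD31"]])
  }
  if ("GFAP" %in% channels) {
    m <- r2d >= spec$parench_bm_radius + 0.5 &
         r2d <= spec$parench_bm_radius + 3.0
    ideal[["GFAP"]] <- rep_z(m, gains[["GFAP"]])
  }
  if ("CCL2" %in% channels) {
    ideal[["CCL2"]] <- rep_z(shell2d(spec$endo_bm_radius - 1, 0.6),
                             gains[["CCL2"]])
  }
  if ("DRAQ5" %in% channels) {
    dr <- array(0, dim = d)
    if (nrow(placed) > 0) {
      for (i in seq_len(nrow(placed))) {
        rn <- placed$diameter[i] / 2
        zi <- which(abs(zc - placed$z[i]) <= rn)
        yi <- which(abs(yc - placed$y[i]) <= rn)
        xi <- which(abs(xc - placed$x[i]) <= rn)
        if (!length(zi) || !length(yi) || !length(xi)) next
        dz2 <- (zc[zi] - placed$z[i])^2
        dy2 <- (yc[yi] - placed$y[i])^2
        dx2 <- (xc[xi] - placed$x[i])^2
        sub <- outer(dz2, outer(dy2, dx2, `+`), `+`) <= rn^2
        blk <- dr[zi, yi, xi, drop = FALSE]
        blk[sub] <- gains[["DRAQ5"]]
        dr[zi, yi, xi] <- blk
      }
    }
    ideal[["DRAQ5"]] <- dr
  }

  # --- blur, background, noise, quantisation -----------------------------
  arr <- array(0, dim = c(length(channels), d))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    img <- ideal[[ch]] %||% array(0, dim = d)
    img <- blur_um(img, sp, spec$blur_sigma)
    img <- img + spec$background_level
    img <- switch(spec$noise_model,
      none = round(img),
      gaussian = round(pmax(img + rnorm(length(img), 0, spec$noise_sd), 0)),
      poisson = array(rpois(length(img), pmax(img, 0)), dim = d))
    arr[ci, , , ] <- img
  }
  stack <- image_stack(arr, sp, channels)

  # --- ground truth ------------------------------------------------------
  circle_polys <- function(r, n_vert = 96L) {
    th <- seq(0, 2 * pi, length.out = n_vert + 1L)[-(n_vert + 1L)]
    poly <- cbind(y = cy + r * cos(th), x = cx + r * sin(th))
    lapply(seq_len(nz) - 1L, function(z) list(z_index = z, polygon = poly))
  }
  analytic_area <- function(r) 2 * pi * r * lz + 2 * pi * r^2
  truth <- structure(list(
    polygons = list(endothelial_bm = circle_polys(spec$endo_bm_radius),
                    parenchymal_bm = circle_polys(spec$parench_bm_radius)),
    analytic_area = c(endothelial_bm = analytic_area(spec$endo_bm_radius),
                      parenchymal_bm = analytic_area(spec$parench_bm_radius)),
    nuclei = placed,
    realized_cln5_coverage = realized_coverage,
    center = c(y = cy, x = cx), length = lz,
    radii = c(lumen = spec$lumen_radius, endothelial_bm = spec$endo_bm_radius,
              parenchymal_bm = spec$parench_bm_radius),
    seed = spec$seed), class = "phantom_truth")

  list(stack = stack, ground_truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> radii %g/%g/%g um, length %g um, %d nuclei, coverage %.3f\n",
              x$radii[1], x$radii[2], x$radii[3], x$length, nrow(x$nuclei),
              x$realized_cln5_coverage))
  invisible(x)
}

#' Ground-truth contour set of a phantom surface
#'
#' Converts the per-slice polygons recorded in a phantom's ground truth
#' into a [contour_set()] that can be lofted directly, bypassing
#' image-based contour extraction.
#'
#' @param truth a `phantom_truth` object from [generate_phantom()].
#' @param surface `"endothelial_bm"` or `"parenchymal_bm"`.
#' @return a [contour_set()].
#' @export
ground_truth_contours <- function(truth,
                                  surface = c("endothelial_bm",
                                              "parenchymal_bm")) {
  surface <- match.arg(surface)
  contour_set(surface, truth$polygons[[surface]])
}

#' Write a phantom to disk
#'
#' Writes the stack via [write_stack()] and the ground truth as JSON.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param name basename for the output files.
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_stack(phantom$stack, file.path(dir, paste0(name, ".tif")))
  gt <- phantom$ground_truth
  gt_json <- list(
    analytic_area = as.list(gt$analytic_area),
    nuclei = gt$nuclei,
    realized_cln5_coverage = gt$realized_cln5_coverage,
    radii = as.list(gt$radii), length = gt$length,
    center = as.list(gt$center), seed = gt$seed)
  jsonlite::write_json(gt_json, file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
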