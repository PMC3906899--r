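#' Per-slice contour set for one vessel surface
#'
#' Ordered closed polygons, one per consecutive confocal z-slice, tracing
#' a basement-membrane boundary. This is the exchange object between
#' slice-wise tracing (automated via [extract_slice_contours()] or
#' supplied by the user) and 3D surface lofting.
#'
#' @param surface_name label, conventionally `"endothelial_bm"` or
#'   `"parenchymal_bm"`.
#' @param contours list of `list(z_index =, polygon =)` entries; polygons
#'   are `(n >= 3) x 2` matrices of (y, x) vertices in micrometres,
#'   without a repeated closing vertex; z indices (0-based) must be
#'   strictly increasing and consecutive.
#' @return an object of class `contour_set`.
#' @export
contour_set <- function(surface_name, contours) {
  if (length(contours) < 2L)
    stopf("a contour set needs at least 2 slices")
  z <- vapply(contours, function(ct) as.integer(ct$z_index), integer(1))
  if (any(diff(z) != 1L))
    stopf("slice z indices must be strictly increasing and consecutive")
  for (ct in contours) {
    p <- ct$polygon
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      stopf("each polygon must be an (n >= 3) x 2 matrix of (y, x) vertices")
    if (polygon_area(p) <= 0)
      stopf("degenerate polygon (zero area) at slice %d", ct$z_index)
  }
  structure(list(surface_name = surface_name, contours = contours),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  z <- vapply(x$contours, function(ct) ct$z_index, integer(1))
  cat(sprintf("<contour_set> '%s': %d slices (z %d..%d)\n",
              x$surface_name, length(z), min(z), max(z)))
  invisible(x)
}

# Fill holes in a 2D binary mask: background components (4-connected)
# not touching the image border are interior holes.
fill_holes2d <- function(mask) {
  d <- dim(mask)
  bg <- cpp_label3(as.logical(!mask), c(1L, d), 6L)
  dim(bg) <- d
  border <- unique(c(bg[1, ], bg[d[1], ], bg[, 1], bg[, d[2]]))
  border <- border[border > 0L]
  holes <- bg > 0L & !(bg %in% border)
  mask | holes
}

#' Trace vessel contours in every z-slice of a channel
#'
#' Automated replacement for manual slice-by-slice contour tracing. Each
#' slice is smoothed in-plane, thresholded (Otsu over the whole channel,
#' or a fixed value), reduced to one connected foreground component
#' (chosen by area rank, so nested tubes labelled in the same channel
#' can be separated), hole-filled, and its outer boundary extracted as a
#' sub-pixel iso-contour in micrometre (y, x) coordinates. Slices
#' without a usable component are skipped; the longest consecutive run
#' of usable slices is returned.
#'
#' @param stack an [image_stack()].
#' @param channel channel label carrying the boundary stain (Laminin-1
#'   by default in the pipeline; CD31 is a common alternative for the
#'   endothelial surface).
#' @param threshold `"otsu"` or a fixed intensity value (must lie within
#'   the channel's intensity range).
#' @param smoothing_sigma in-plane Gaussian smoothing in um applied
#'   before thresholding.
#' @param component_rank which foreground component to trace, by
#'   decreasing area: 1 = largest (outer tube when both basement
#'   membranes share a channel), 2 = second largest (inner tube).
#' @param surface_name label stored on the returned [contour_set()].
#' @return a [contour_set()].
#' @export
extract_slice_contours <- function(stack, channel, threshold = "otsu",
                                   smoothing_sigma = 0.4,
                                   component_rank = 1L,
                                   surface_name = "surface") {
  v <- get_channel(stack, channel)
  if (max(v) == min(v))
    stopf("channel '%s' has no contrast: fewer than 2 usable slices", channel)
  sp <- stack$voxel_spacing
  sm <- blur_um(v, sp, c(0, smoothing_sigma, smoothing_sigma))
  thr <- resolve_threshold(threshold, v)
  d <- dim(v)
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]

  contours <- list()
  usable <- logical(d[1])
  for (zi in seq_len(d[1])) {
    mask <- sm[zi, , ] >= thr
    if (!any(mask)) next
    lab <- cpp_label3(as.logical(mask), c(1L, d[2], d[3]), 26L)
    dim(lab) <- d[2:3]
    sizes <- tabulate(lab[lab > 0L])
    if (length(sizes) < component_rank) next
    comp <- order(sizes, decreasing = TRUE)[component_rank]
    m <- fill_holes2d(lab == comp)
    m01 <- matrix(as.numeric(m), d[2], d[3])
    cls <- grDevices::contourLines(x = yc, y = xc, z = m01, levels = 0.5)
    if (!length(cls)) next
    areas <- vapply(cls, function(cl) polygon_area(cbind(cl$x, cl$y)),
                    numeric(1))
    best <- cls[[which.max(areas)]]
    poly <- cbind(y = best$x, x = best$y)
    # contourLines closes the loop by repeating the first vertex
    if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
    if (nrow(poly) < 3L || polygon_area(poly) <= 0) next
    usable[zi] <- TRUE
    contours[[zi]] <- list(z_index = zi - 1L, polygon = poly)
  }
  if (sum(usable) < 2L)
    stopf("fewer than 2 usable slices in channel '%s'", channel)
  # longest consecutive run of usable slices
  r <- rle(usable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  run <- starts[best]:ends[best]
  if (length(run) < 2L)
    stopf("fewer than 2 consecutive usable slices in channel '%s'", channel)
  contour_set(surface_name, contours[run])
}

# Resample a closed polygon to m vertices equally spaced by arc length,
# orientation normalised to positive signed area.
resample_polygon <- function(p, m) {
  if (polygon_area_signed(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  pc <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(pc)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- (seq_len(m) - 1L) / m * total
  cbind(approx(s, pc[, 1], xout = target, rule = 2)$y,
        approx(s, pc[, 2], xout = target, rule = 2)$y)
}

# Best cyclic offset aligning ring b to ring a (minimal total squared
# vertex displacement). Returns the rotated ring.
align_ring <- function(a, b) {
  m <- nrow(a)
  best_k <- 0L
  best_cost <- Inf
  for (k in 0L:(m - 1L)) {
    idx <- ((seq_len(m) - 1L + k) %% m) + 1L
    cost <- sum((a - b[idx, , drop = FALSE])^2)
    if (cost < best_cost) { best_cost <- cost; best_k <- k }
  }
  idx <- ((seq_len(m) - 1L + best_k) %% m) + 1L
  b[idx, , drop = FALSE]
}

#' Closed triangulated surface mesh
#'
#' @param vertices `n x 3` matrix of (z, y, x) micrometre coordinates.
#' @param triangles `m x 3` integer matrix of 1-based vertex indices.
#' @param surface_name label.
#' @return an object of class `surface_mesh` with attributes `watertight`
#'   (every edge shared by exactly two triangles, consistently oriented).
#' @export
surface_mesh <- function(vertices, triangles, surface_name = "surface") {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  if (ncol(vertices) != 3L) stopf("vertices must be n x 3 (z, y, x)")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stopf("triangle indices out of range")
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         surface_name = surface_name),
                    class = "surface_mesh")
  attr(mesh, "watertight") <- is_watertight(mesh)
  mesh
}

# Watertight & consistently oriented: every undirected edge appears in
# exactly two triangles, and as two opposite directed edges.
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  de <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key_dir <- paste(de[, 1], de[, 2])
  key_und <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  all(table(key_und) == 2L) && !anyDuplicated(key_dir)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> '%s': %d vertices, %d triangles, %swatertight, area %.1f um^2\n",
              x$surface_name, nrow(x$vertices), nrow(x$triangles),
              if (isTRUE(attr(x, "watertight"))) "" else "NOT ",
              cpp_mesh_area(x$vertices, x$triangles - 1L)))
  invisible(x)
}

#' Loft per-slice contours into a closed 3D surface
#'
#' Reproduces the step of merging traced z-slice contours into a 3D
#' contour surface. Each polygon is resampled to `ring_vertices` points
#' by arc length, consecutive rings are rotationally aligned by minimal
#' total vertex displacement over the cyclic offset, adjacent rings are
#' joined with `2 * ring_vertices` triangles, and the first and last
#' rings are capped with centroid fans so the surface is watertight.
#' End caps are part of the surface (and of its area): the convention is
#' fixed and cancels in density ratios.
#'
#' @param contours a [contour_set()].
#' @param spacing `(dz, dy, dx)` voxel spacing in um; contours at slice
#'   `z_index` are placed at physical z `(z_index + 0.5) * dz`.
#' @param ring_vertices number of vertices per ring (M >= 8).
#' @return a watertight [surface_mesh()] with outward-facing normals.
#' @export
loft_surface <- function(contours, spacing, ring_vertices = 64L) {
  stopifnot(inherits(contours, "contour_set"))
  m <- as.integer(ring_vertices)
  if (m < 8L) stopf("ring_vertices must be >= 8")
  dz <- as.numeric(spacing)[1]
  n <- length(contours$contours)
  rings <- vector("list", n)
  zpos <- numeric(n)
  for (i in seq_len(n)) {
    ct <- contours$contours[[i]]
    rings[[i]] <- resample_polygon(ct$polygon, m)
    zpos[i] <- (ct$z_index + 0.5) * dz
  }
  for (i in 2:n) rings[[i]] <- align_ring(rings[[i - 1]], rings[[i]])

  nv <- n * m
  V <- matrix(0, nv + 2L, 3L)
  for (i in seq_len(n))
    V[((i - 1L) * m + 1L):(i * m), ] <- cbind(zpos[i], rings[[i]])
  V[nv + 1L, ] <- c(zpos[1], colMeans(rings[[1]]))
  V[nv + 2L, ] <- c(zpos[n], colMeans(rings[[n]]))

  tri <- matrix(0L, 2L * m * (n - 1L) + 2L * m, 3L)
  t <- 0L
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * m
    b <- i * m
    for (j in seq_len(m)) {
      j2 <- if (j == m) 1L else j + 1L
      tri[t + 1L, ] <- c(a + j, a + j2, b + j2)
      tri[t + 2L, ] <- c(a + j, b + j2, b + j)
      t <- t + 2L
    }
  }
  for (j in seq_len(m)) {            # bottom cap
    j2 <- if (j == m) 1L else j + 1L
    tri[t + 1L, ] <- c(nv + 1L, j2, j)
    t <- t + 1L
  }
  top <- (n - 1L) * m
  for (j in seq_len(m)) {            # top cap
    j2 <- if (j == m) 1L else j + 1L
    tri[t + 1L, ] <- c(nv + 2L, top + j, top + j2)
    t <- t + 1L
  }
  if (cpp_mesh_volume(V, tri - 1L) < 0) tri <- tri[, c(1, 3, 2)]
  surface_mesh(V, tri, contours$surface_name)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas in um^2. A non-watertight mesh is signalled
#' with a warning but its area is still returned.
#'
#' @param mesh a [surface_mesh()].
#' @return surface area in um^2.
#' @export
mesh_surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!isTRUE(attr(mesh, "watertight")))
    warning("mesh is not watertight; area may be unreliable", call. = FALSE)
  cpp_mesh_area(mesh$vertices, mesh$triangles - 1L)
}

#' Point-in-mesh test
#'
#' Ray-crossing parity test against a closed surface, with a
#' deterministic tie rule: points within `1e-9` um of the surface count
#' as inside.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param points a length-3 (z, y, x) vector or an `n x 3` matrix of
#'   micrometre coordinates.
#' @return a logical vector, one entry per point.
#' @export
point_inside <- function(mesh, points) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  cpp_points_in_mesh(mesh$vertices, mesh$triangles - 1L,
                     as.matrix(points), 1e-9)
}

# Logical (nz, ny, nx) array marking voxels whose centers fall inside
# the mesh; only centers within the mesh bounding box are tested.
voxel_inside_mask <- function(mesh, grid_shape, spacing) {
  d <- as.integer(grid_shape)
  sp <- as.numeric(spacing)
  ctrs <- lapply(1:3, function(a) (seq_len(d[a]) - 0.5) * sp[a])
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  idx <- lapply(1:3, function(a)
    which(ctrs[[a]] >= bb_lo[a] - sp[a] & ctrs[[a]] <= bb_hi[a] + sp[a]))
  out <- array(FALSE, dim = d)
  if (any(lengths(idx) == 0L)) return(out)
  g <- expand.grid(z = ctrs[[1]][idx[[1]]], y = ctrs[[2]][idx[[2]]],
                   x = ctrs[[3]][idx[[3]]])
  ins <- point_inside(mesh, as.matrix(g))
  sub <- array(ins, dim = lengths(idx))
  out[idx[[1]], idx[[2]], idx[[3]]] <- sub
  out
}

#' Read/write contour sets as JSON
#'
#' Exchange format: `{surface_name, slices: [{z, polygon: [[y, x], ...]}]}`
#' with coordinates in micrometres.
#'
#' @param contours a [contour_set()].
#' @param path JSON file path.
#' @return `write_contours_json` returns `path` invisibly;
#'   `read_contours_json` returns a [contour_set()].
#' @export
write_contours_json <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  slices <- lapply(contours$contours, function(ct)
    list(z = ct$z_index, polygon = unname(ct$polygon)))
  jsonlite::write_json(list(surface_name = contours$surface_name,
                            slices = slices),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  contours <- lapply(seq_len(nrow(obj$slices)), function(i) {
    poly <- obj$slices$polygon[[i]]
    colnames(poly) <- c("y", "x")
    list(z_index = as.integer(obj$slices$z[i]), polygon = poly)
  })
  contour_set(obj$surface_name, contours)
}

#' Export a mesh as Wavefront OBJ
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", mesh$surface_name), con)
  # OBJ is x y z; our columns are (z, y, x)
  writeLines(sprintf("v %.6f %.6f %.6f",
                     mesh$vertices[, 3], mesh$vertices[, 2],
                     mesh$vertices[, 1]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  invisible(path)
}
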