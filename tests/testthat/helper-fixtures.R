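# Shared fixture builders. Everything is generated in code; no files.

# Circular contour set: radius r (um) about center (cy, cx), one contour
# per z index, n_vert polygon vertices.
circle_contours <- function(r, z_indices, center = c(20, 20), n_vert = 96,
                            name = "surface") {
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  poly <- cbind(y = center[1] + r * cos(th), x = center[2] + r * sin(th))
  contour_set(name, lapply(z_indices, function(z)
    list(z_index = z, polygon = poly)))
}

# Lofted circular cylinder: radius r, spanning L um along z at dz = 1.
cylinder_mesh <- function(r, L = 60, M = 64, center = c(20, 20),
                          name = "cylinder") {
  loft_surface(circle_contours(r, 0:L, center, name = name),
               spacing = c(1, 0.3, 0.3), ring_vertices = M)
}

# Small, fast phantom spec for unit tests (24 z-slices, 28.8 um wide).
small_spec <- function(...) {
  args <- list(grid_shape = c(24L, 96L, 96L),
               voxel_spacing = c(1, 0.3, 0.3),
               lumen_radius = 4, endo_bm_radius = 6, parench_bm_radius = 13,
               nucleus_diameter_mean = 4, nucleus_diameter_sd = 0.2)
  over <- list(...)
  do.call(phantom_spec, c(over, args[!names(args) %in% names(over)]))
}

# Match detected spots to ground-truth nuclei by nearest center; returns
# the truth compartment for each spot (or NA when nothing is close).
match_truth_compartment <- function(spots, truth, max_dist = 3) {
  vapply(seq_len(nrow(spots)), function(i) {
    dd <- sqrt((truth$z - spots$z[i])^2 + (truth$y - spots$y[i])^2 +
               (truth$x - spots$x[i])^2)
    j <- which.min(dd)
    if (dd[j] <= max_dist) truth$compartment[j] else NA_character_
  }, character(1))
}

# Independent spreadsheet-style recomputation of the cohort summary from
# the raw score matrix (rows = mice), used as an oracle.
oracle_summary <- function(score_mat, last_day) {
  n <- nrow(score_mat)
  onsets <- numeric(n)
  for (i in seq_len(n)) {
    s <- score_mat[i, ]
    o <- NA
    for (d in seq_len(length(s) - 1)) {
      if (s[d] >= 1 && s[d + 1] >= 1) { o <- d; break }
    }
    onsets[i] <- if (is.na(o)) last_day + 1 else o
  }
  daily <- apply(score_mat, 2, mean)
  list(incidence = sum(onsets <= last_day) / n,
       mdo = sum(onsets) / n,
       mean_max = mean(apply(score_mat, 1, max)),
       di = 100 * sum(daily) / (sum(onsets) / n))
}
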