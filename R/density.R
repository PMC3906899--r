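#' Claudin-5 staining density inside a vessel surface
#'
#' Computes the tight-junction density statistic: total above-threshold
#' claudin-5 intensity of voxels whose centers lie inside the closed
#' vessel surface, divided by the surface area of that surface
#' (intensity per um^2). A voxel belongs to the vessel iff its center is
#' inside the mesh; there is no partial-voxel weighting. The default
#' threshold is Otsu computed over inside-mesh voxels only; a fixed
#' intensity value may be supplied instead.
#'
#' @param stack an [image_stack()].
#' @param mesh a watertight [surface_mesh()] (conventionally the
#'   endothelial-BM surface).
#' @param channel claudin-5 channel label.
#' @param threshold `"otsu"` or a fixed intensity value.
#' @param vessel_id,group,day labels carried into the result row.
#' @return a one-row data.frame of class `density_result` with columns
#'   `vessel_id`, `group`, `day`, `total_intensity`, `surface_area`,
#'   `density`, `threshold_used`.
#' @export
cln5_density <- function(stack, mesh, channel = "CLN-5",
                         threshold = "otsu", vessel_id = "vessel",
                         group = NA_character_, day = NA_character_) {
  v <- get_channel(stack, channel)
  inside <- voxel_inside_mask(mesh, dim(v), stack$voxel_spacing)
  if (!any(inside)) stopf("no voxel centers fall inside the mesh")
  vin <- v[inside]
  thr <- resolve_threshold(threshold, vin, check_range = FALSE)
  total <- sum(vin[vin >= thr])
  area <- mesh_surface_area(mesh)
  if (area <= 0) stopf("mesh surface area must be positive")
  structure(
    data.frame(vessel_id = vessel_id, group = group, day = day,
               total_intensity = total, surface_area = area,
               density = total / area, threshold_used = thr,
               stringsAsFactors = FALSE),
    class = c("density_result", "data.frame"))
}

#' Percent change between two density results
#'
#' `100 * (test - reference) / reference` on the density values, i.e.
#' the convention under which a drop from density 10 to 4 is reported
#' as -60%.
#'
#' @param reference,test `density_result` rows (or any objects with a
#'   `density` field); the reference density must be positive.
#' @return percent change (a bare number).
#' @export
percent_change <- function(reference, test) {
  r <- reference$density
  t <- test$density
  if (!is.finite(r) || r <= 0) stopf("reference density must be positive")
  100 * (t - r) / r
}

#' Channel overlap fraction
#'
#' Fraction of above-threshold voxels of channel `a` that are also above
#' threshold in channel `b` — a simple quantitative proxy for the
#' qualitative colocalization of two stains (e.g. CCL2 with CD31 or
#' GFAP). Returns 0 with attribute `flagged = TRUE` when channel `a` has
#' no above-threshold voxels.
#'
#' @param stack an [image_stack()].
#' @param channel_a,channel_b channel labels.
#' @param threshold_a,threshold_b `"otsu"` or fixed values, per channel.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(stack, channel_a, channel_b,
                             threshold_a = "otsu", threshold_b = "otsu") {
  va <- get_channel(stack, channel_a)
  vb <- get_channel(stack, channel_b)
  ma <- va >= resolve_threshold(threshold_a, va, check_range = FALSE)
  mb <- vb >= resolve_threshold(threshold_b, vb, check_range = FALSE)
  na <- sum(ma)
  if (na == 0L) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sum(ma & mb) / na
}

#' Compare claudin-5 densities across experimental groups
#'
#' One-way ANOVA on per-vessel densities across groups, followed by
#' Bonferroni-adjusted pairwise t tests (pooled SD), together with group
#' means +/- SEM.
#'
#' @param results a data.frame of stacked `density_result` rows (use
#'   `rbind`) with at least 2 groups of at least 2 vessels each.
#' @return an object of class `group_comparison` with elements `groups`
#'   (n, mean, sem per group), `anova` (F, df, p) and `pairwise`
#'   (long-format Bonferroni-adjusted p values).
#' @export
compare_density_groups <- function(results) {
  df <- as.data.frame(results)
  if (!all(c("density", "group") %in% names(df)))
    stopf("results must contain 'density' and 'group' columns")
  df$group <- factor(df$group)
  counts <- table(df$group)
  if (length(counts) < 2L) stopf("need at least 2 groups")
  if (any(counts < 2L))
    stopf("every group needs at least 2 vessels (got: %s)",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  fit <- aov(density ~ group, data = df)
  an <- summary(fit)[[1]]
  pw <- pairwise.t.test(df$density, df$group,
                        p.adjust.method = "bonferroni", pool.sd = TRUE)
  pmat <- pw$p.value
  pairs <- do.call(rbind, lapply(rownames(pmat), function(a)
    do.call(rbind, lapply(colnames(pmat), function(b) {
      p <- pmat[a, b]
      if (is.na(p)) NULL
      else data.frame(group_a = a, group_b = b, p_adj = p,
                      stringsAsFactors = FALSE)
    }))))
  grp <- do.call(rbind, lapply(split(df$density, df$group), function(v)
    data.frame(n = length(v), mean = mean(v),
               sem = sd(v) / sqrt(length(v)))))
  grp <- cbind(group = rownames(grp), grp)
  rownames(grp) <- NULL
  structure(list(
    groups = grp,
    anova = list(F = an[["F value"]][1],
                 df = unname(an[["Df"]]),
                 p = an[["Pr(>F)"]][1]),
    pairwise = pairs),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (one-way ANOVA + Bonferroni pairwise)\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
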