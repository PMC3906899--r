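#' Analysis configuration for one vessel
#'
#' Central knobs of the per-vessel pipeline. By default both basement
#' membranes are traced from the Laminin-1 channel, separating the
#' nested tubes by component area rank (largest = parenchymal BM,
#' second = endothelial BM). Supplying `contours` (a list with elements
#' `endothelial_bm` and `parenchymal_bm`, each a [contour_set()])
#' bypasses image-based extraction, mirroring a manual tracing workflow.
#'
#' @param cln5_channel,nuclei_channel channel labels for the claudin-5
#'   and nuclear stains.
#' @param contour_channel channel used for automated contour tracing.
#' @param endo_component_rank,parench_component_rank area ranks used to
#'   pick the endothelial and parenchymal tubes in `contour_channel`.
#' @param contour_threshold,density_threshold,nuclei_threshold `"otsu"`
#'   or fixed intensity values for the respective stages.
#' @param contour_smoothing in-plane smoothing (um) before tracing.
#' @param ring_vertices vertices per lofted ring.
#' @param min_diameter strict nucleus diameter filter in um.
#' @param split_touching split merged nuclei (see [detect_nuclei()]).
#' @param contours optional pre-traced contour sets (see above).
#' @return a list of class `vessel_config`.
#' @export
vessel_config <- function(cln5_channel = "CLN-5",
                          nuclei_channel = "DRAQ5",
                          contour_channel = "Lam1",
                          endo_component_rank = 2L,
                          parench_component_rank = 1L,
                          contour_threshold = "otsu",
                          density_threshold = "otsu",
                          nuclei_threshold = "otsu",
                          contour_smoothing = 0.4,
                          ring_vertices = 64L,
                          min_diameter = 3,
                          split_touching = FALSE,
                          contours = NULL) {
  structure(list(
    cln5_channel = cln5_channel, nuclei_channel = nuclei_channel,
    contour_channel = contour_channel,
    endo_component_rank = as.integer(endo_component_rank),
    parench_component_rank = as.integer(parench_component_rank),
    contour_threshold = contour_threshold,
    density_threshold = density_threshold,
    nuclei_threshold = nuclei_threshold,
    contour_smoothing = contour_smoothing,
    ring_vertices = as.integer(ring_vertices),
    min_diameter = min_diameter,
    split_touching = isTRUE(split_touching),
    contours = contours), class = "vessel_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage: %s] %s", stage, conditionMessage(e)))
}

#' Run the full per-vessel analysis
#'
#' Orchestrates contour extraction (or supplied contours) for both
#' basement-membrane surfaces, surface lofting, claudin-5 density,
#' nucleus detection, compartment classification, spread profiling, and
#' assembles everything into a single report. Deterministic given
#' stack + config. Stage failures are re-signalled with the stage name.
#'
#' @param stack an [image_stack()].
#' @param config a [vessel_config()].
#' @param vessel_id,group,day labels carried into the report.
#' @return an object of class `vessel_report` with elements `density`
#'   (a `density_result` row), `counts` (per-compartment spot counts),
#'   `spots`, `spread` and `provenance` (config hash, software version).
#' @export
analyze_vessel <- function(stack, config = vessel_config(),
                           vessel_id = "vessel", group = NA_character_,
                           day = NA_character_) {
  stopifnot(inherits(stack, "image_stack"), inherits(config, "vessel_config"))
  if (!is.null(config$contours)) {
    endo_ct <- config$contours$endothelial_bm
    par_ct <- config$contours$parenchymal_bm
    if (is.null(endo_ct) || is.null(par_ct))
      stopf("[stage: contours] supplied contours need both endothelial_bm and parenchymal_bm")
  } else {
    par_ct <- with_stage("contour extraction (parenchymal BM)",
      extract_slice_contours(stack, config$contour_channel,
                             threshold = config$contour_threshold,
                             smoothing_sigma = config$contour_smoothing,
                             component_rank = config$parench_component_rank,
                             surface_name = "parenchymal_bm"))
    endo_ct <- with_stage("contour extraction (endothelial BM)",
      extract_slice_contours(stack, config$contour_channel,
                             threshold = config$contour_threshold,
                             smoothing_sigma = config$contour_smoothing,
                             component_rank = config$endo_component_rank,
                             surface_name = "endothelial_bm"))
  }
  endo_mesh <- with_stage("surface lofting (endothelial BM)",
    loft_surface(endo_ct, stack$voxel_spacing, config$ring_vertices))
  par_mesh <- with_stage("surface lofting (parenchymal BM)",
    loft_surface(par_ct, stack$voxel_spacing, config$ring_vertices))
  density <- with_stage("claudin-5 density",
    cln5_density(stack, endo_mesh, channel = config$cln5_channel,
                 threshold = config$density_threshold,
                 vessel_id = vessel_id, group = group, day = day))
  spots <- with_stage("nucleus detection",
    detect_nuclei(stack, channel = config$nuclei_channel,
                  min_diameter = config$min_diameter,
                  threshold = config$nuclei_threshold,
                  split_touching = config$split_touching))
  spots <- with_stage("compartment classification",
    classify_spots(spots, endo_mesh, par_mesh))
  spread <- spread_profile(spots)
  structure(list(
    vessel_id = vessel_id, group = group, day = day,
    density = density,
    counts = compartment_counts(spots),
    spots = spots, spread = spread,
    endo_mesh = endo_mesh, parench_mesh = par_mesh,
    provenance = list(
      config_hash = object_hash(config),
      version = as.character(packageVersion("vesselquant")))),
    class = "vessel_report")
}

#' @export
print.vessel_report <- function(x, ...) {
  cat(sprintf("<vessel_report> '%s' (group %s, day %s)\n",
              x$vessel_id, x$group, x$day))
  cat(sprintf("  CLN-5 density %.3f intensity/um^2 (area %.1f um^2, threshold %.3g)\n",
              x$density$density, x$density$surface_area,
              x$density$threshold_used))
  cat(sprintf("  spots: %d luminal, %d perivascular, %d parenchymal\n",
              x$counts["luminal"], x$counts["perivascular"],
              x$counts["parenchymal"]))
  cat(sprintf("  config %s, vesselquant %s\n",
              substr(x$provenance$config_hash, 1, 8), x$provenance$version))
  invisible(x)
}

#' Run a multi-vessel study
#'
#' Analyses a set of vessels (phantom specs or image stacks), stacks the
#' per-vessel results into a study table, and — when at least two groups
#' with two or more vessels each are present — applies the claudin-5
#' density group comparison (ANOVA + Bonferroni).
#'
#' @param vessels list of entries, each a list with either `spec` (a
#'   [phantom_spec()], generated on the fly) or `stack` (an
#'   [image_stack()]), plus optional `vessel_id`, `group`, `day`.
#' @param config a [vessel_config()].
#' @return an object of class `study_result` with elements `table`
#'   (per-vessel densities and compartment counts), `comparison`
#'   (a `group_comparison` or `NULL`), and `reports`.
#' @export
run_study <- function(vessels, config = vessel_config()) {
  if (!length(vessels)) stopf("no vessels supplied")
  reports <- vector("list", length(vessels))
  for (i in seq_along(vessels)) {
    v <- vessels[[i]]
    stack <- if (!is.null(v$stack)) v$stack
             else if (!is.null(v$spec)) generate_phantom(v$spec)$stack
             else stopf("vessel %d has neither 'stack' nor 'spec'", i)
    reports[[i]] <- analyze_vessel(
      stack, config,
      vessel_id = v$vessel_id %||% sprintf("vessel%02d", i),
      group = v$group %||% NA_character_,
      day = v$day %||% NA_character_)
  }
  tab <- do.call(rbind, lapply(reports, function(r)
    cbind(as.data.frame(r$density),
          data.frame(luminal = r$counts["luminal"],
                     perivascular = r$counts["perivascular"],
                     parenchymal = r$counts["parenchymal"],
                     row.names = NULL))))
  groups <- unique(tab$group[!is.na(tab$group)])
  comparison <- NULL
  if (length(groups) >= 2L &&
      all(table(tab$group) >= 2L)) {
    comparison <- compare_density_groups(tab)
  } else {
    warning("fewer than 2 groups with >= 2 vessels: summary only, no tests",
            call. = FALSE)
  }
  structure(list(table = tab, comparison = comparison, reports = reports),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d vessels\n", nrow(x$table)))
  print(x$table[, c("vessel_id", "group", "density", "luminal",
                    "perivascular", "parenchymal")], row.names = FALSE)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Write study outputs to disk
#'
#' Per-vessel table as CSV and the group comparison (if any) as JSON.
#'
#' @param study a `study_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(study$table, file.path(dir, "vessels.csv"), row.names = FALSE)
  if (!is.null(study$comparison)) {
    cmp <- study$comparison
    jsonlite::write_json(
      list(groups = cmp$groups, anova = cmp$anova, pairwise = cmp$pairwise),
      file.path(dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
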