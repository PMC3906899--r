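test_that("an empty channel yields an empty spot list", {
  st <- image_stack(array(0, dim = c(1, 10, 20, 20)), c(1, 0.3, 0.3),
                    "DRAQ5")
  spots <- detect_nuclei(st)
  expect_identical(nrow(spots), 0L)
  expect_error(detect_nuclei(st, min_diameter = 0), "positive")
})

test_that("a 6-um nucleus is recovered as one spot with faithful size and centroid", {
  spec <- phantom_spec(grid_shape = c(24L, 120L, 120L),
                       lumen_radius = 4, endo_bm_radius = 6,
                       parench_bm_radius = 15,
                       n_nuclei = c(luminal = 0, perivascular = 1,
                                    parenchymal = 0),
                       nucleus_diameter_mean = 6, nucleus_diameter_sd = 0,
                       noise_model = "none", seed = 8L)
  ph <- generate_phantom(spec)
  spots <- detect_nuclei(ph$stack)
  expect_identical(nrow(spots), 1L)
  expect_lt(abs(spots$equivalent_diameter / 6 - 1), 0.10)
  truth <- ph$ground_truth$nuclei
  dist <- sqrt((spots$z - truth$z)^2 + (spots$y - truth$y)^2 +
               (spots$x - truth$x)^2)
  expect_lt(dist, 0.5)
})

test_that("the strict 3-um filter removes small nuclei", {
  spec <- small_spec(n_nuclei = c(luminal = 0, perivascular = 1,
                                  parenchymal = 0),
                     nucleus_diameter_mean = 2, nucleus_diameter_sd = 0,
                     noise_model = "none", seed = 8L)
  ph <- generate_phantom(spec)
  expect_identical(nrow(detect_nuclei(ph$stack)), 0L)
  # strictness: a component whose equivalent diameter equals the cutoff
  # exactly is excluded
  arr <- array(0, dim = c(1, 12, 30, 30))
  arr[1, 4:8, 10:14, 10:17] <- 100           # 5*5*8 = 200 voxels
  st <- image_stack(arr, c(1, 0.3, 0.3), "DRAQ5")
  cutoff <- (6 * 200 * prod(c(1, 0.3, 0.3)) / pi)^(1 / 3)
  spots_all <- detect_nuclei(st, min_diameter = 0.1, threshold = 50,
                             smoothing_sigma = 0)
  expect_identical(nrow(spots_all), 1L)
  expect_equal(spots_all$equivalent_diameter, cutoff)
  expect_identical(nrow(detect_nuclei(st, min_diameter = cutoff,
                                      threshold = 50,
                                      smoothing_sigma = 0)), 0L)
})

test_that("raising the diameter filter never increases the spot count", {
  ph <- generate_phantom(phantom_preset("wt_d16", seed = 12L))
  counts <- vapply(c(1, 2, 3, 4, 5, 6, 8),
                   function(md) nrow(detect_nuclei(ph$stack,
                                                   min_diameter = md)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("spots are classified by centroid against the nested tubes", {
  endo <- cylinder_mesh(5, L = 20, M = 48, name = "endothelial_bm")
  par <- cylinder_mesh(8, L = 20, M = 48, name = "parenchymal_bm")
  spots <- structure(
    data.frame(z = c(10, 10, 10), y = 20 + c(0, 6.5, 10), x = c(20, 20, 20),
               equivalent_diameter = 5, voxel_count = 100L,
               total_intensity = 1, compartment = "unclassified"),
    class = c("spot_table", "data.frame"))
  lab <- classify_spots(spots, endo, par)
  expect_identical(lab$compartment,
                   c("luminal", "perivascular", "parenchymal"))
  # labels partition the retained spots
  expect_identical(sum(compartment_counts(lab)), nrow(lab))
  # empty list passes through
  empty <- spots[0, , drop = FALSE]
  expect_identical(nrow(classify_spots(empty, endo, par)), 0L)
  # swapped meshes violate nesting
  expect_error(classify_spots(spots, par, endo), "nested")
})

test_that("detected phantom spots carry their ground-truth compartment labels", {
  ph <- generate_phantom(phantom_preset("endo_ko_d16", seed = 31L))
  em <- loft_surface(ground_truth_contours(ph$ground_truth, "endothelial_bm"),
                     ph$stack$voxel_spacing, 64)
  pm <- loft_surface(ground_truth_contours(ph$ground_truth, "parenchymal_bm"),
                     ph$stack$voxel_spacing, 64)
  spots <- classify_spots(detect_nuclei(ph$stack), em, pm)
  truth_labels <- match_truth_compartment(spots, ph$ground_truth$nuclei)
  expect_true(all(!is.na(truth_labels)))
  expect_identical(spots$compartment, truth_labels)
  expect_gt(compartment_counts(spots)[["luminal"]], 0L)
})

test_that("spread profile summarises median and spreads per axis", {
  mk_spots <- function(z, y, x, comp) structure(
    data.frame(z = z, y = y, x = x, equivalent_diameter = 5,
               voxel_count = 10L, total_intensity = 1, compartment = comp),
    class = c("spot_table", "data.frame"))
  single <- spread_profile(mk_spots(5, 5, 5, "luminal"))
  lum <- single[single$compartment == "luminal", ]
  expect_true(all(lum$spread_max == 0) && all(lum$spread_min == 0))
  expect_true(all(single[single$compartment == "perivascular", "n"] == 0))
  tri <- spread_profile(mk_spots(c(10, 20, 30), c(1, 1, 1), c(2, 2, 2),
                                 "luminal"))
  zrow <- tri[tri$compartment == "luminal" & tri$axis == "z", ]
  expect_equal(zrow$median, 20)
  expect_equal(zrow$spread_max, 10)
  expect_equal(zrow$spread_min, 10)
})

test_that("luminal cells appear only in the endothelial-knockout regime", {
  ph_endo <- generate_phantom(phantom_preset("endo_ko_d16", seed = 41L))
  ph_wt <- generate_phantom(phantom_preset("wt_d16", seed = 41L))
  classify_of <- function(ph) {
    em <- loft_surface(ground_truth_contours(ph$ground_truth,
                                             "endothelial_bm"),
                       ph$stack$voxel_spacing, 48)
    pm <- loft_surface(ground_truth_contours(ph$ground_truth,
                                             "parenchymal_bm"),
                       ph$stack$voxel_spacing, 48)
    compartment_counts(classify_spots(detect_nuclei(ph$stack), em, pm))
  }
  endo_counts <- classify_of(ph_endo)
  wt_counts <- classify_of(ph_wt)
  expect_gt(endo_counts[["luminal"]], 0L)
  expect_identical(wt_counts[["luminal"]], 0L)
  expect_lt(endo_counts[["perivascular"]], wt_counts[["perivascular"]])
})
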