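make_block_stack <- function(value = 100, n_on = 1000) {
  # 1000 voxels at `value` centred in the lumen of a 20-um cylinder grid
  arr <- array(0, dim = c(1, 30, 100, 100))
  on <- 0L
  for (z in 10:19) for (y in 60:69) for (x in 60:69) {
    if (on >= n_on) break
    arr[1, z, y, x] <- value
    on <- on + 1L
  }
  image_stack(arr, c(1, 0.3, 0.3), "CLN-5")
}

test_that("density is total above-threshold inside intensity per unit area", {
  st <- make_block_stack()
  mesh <- loft_surface(circle_contours(12, 0:29, center = c(15, 15)),
                       c(1, 0.3, 0.3), 64)
  res <- cln5_density(st, mesh, threshold = 1)
  expect_equal(res$total_intensity, 100 * 1000)
  expect_equal(res$density, res$total_intensity / res$surface_area)
  expect_equal(res$density, 1e5 / mesh_surface_area(mesh))
  # empty channel: zero total, zero density
  st0 <- image_stack(array(0, dim = c(1, 30, 100, 100)), c(1, 0.3, 0.3),
                     "CLN-5")
  res0 <- cln5_density(st0, mesh, threshold = 1)
  expect_equal(res0$total_intensity, 0)
  expect_equal(res0$density, 0)
})

test_that("density scales linearly with intensity", {
  st1 <- make_block_stack(value = 50)
  st3 <- make_block_stack(value = 150)
  mesh <- loft_surface(circle_contours(12, 0:29, center = c(15, 15)),
                       c(1, 0.3, 0.3), 48)
  d1 <- cln5_density(st1, mesh, threshold = 1)$density
  d3 <- cln5_density(st3, mesh, threshold = 1)$density
  expect_equal(d3, 3 * d1)
})

test_that("noise-free coverage pair recovers the density ratio", {
  mk <- function(f) phantom_spec(cln5_coverage = f, background_level = 0,
                                 noise_model = "none", seed = 5L)
  ph1 <- generate_phantom(mk(1))
  mesh <- loft_surface(ground_truth_contours(ph1$ground_truth,
                                             "endothelial_bm"),
                       ph1$stack$voxel_spacing, 64)
  d1 <- cln5_density(ph1$stack, mesh, threshold = 1)$density
  ph5 <- generate_phantom(mk(0.5))
  d5 <- cln5_density(ph5$stack, mesh, threshold = 1)$density
  expect_lt(abs(d5 / d1 / 0.5 - 1), 0.07)
})

test_that("percent change follows the reporting convention", {
  r <- list(density = 10)
  expect_equal(percent_change(r, list(density = 4)), -60)
  expect_equal(percent_change(r, r), 0)
  expect_equal(percent_change(r, list(density = 8.1)), -19)
  expect_error(percent_change(list(density = 0), r), "positive")
})

test_that("overlap fraction handles identity, disjoint and empty masks", {
  arr <- array(0, dim = c(3, 4, 6, 6))
  arr[1, 1:2, , ] <- 10            # A
  arr[2, 1:2, , ] <- 10            # B identical support to A
  arr[3, 3:4, , ] <- 10            # C disjoint from A
  st <- image_stack(arr, c(1, 1, 1), c("A", "B", "C"))
  expect_equal(overlap_fraction(st, "A", "A", 1, 1), 1.0)
  expect_equal(overlap_fraction(st, "A", "B", 1, 1), 1.0)
  expect_equal(overlap_fraction(st, "A", "C", 1, 1), 0.0)
  empty <- overlap_fraction(st, "A", "B", 11, 1)   # nothing above 11 in A
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "flagged"))
})

test_that("endothelial CCL2 shows no spillover into the GFAP parenchymal mask", {
  spec <- small_spec(channel_gains = c(Lam1 = 200, CCL2 = 140, GFAP = 150,
                                       `CLN-5` = 180, DRAQ5 = 220),
                     noise_model = "none", seed = 6L)
  ph <- generate_phantom(spec)
  ov <- overlap_fraction(ph$stack, "CCL2", "GFAP")
  expect_lte(as.numeric(ov), 0.05)
})

test_that("group comparison reproduces null, separated and Bonferroni cases", {
  row <- function(g, d) data.frame(vessel_id = "v", group = g, day = NA,
                                   total_intensity = 1, surface_area = 1,
                                   density = d, threshold_used = 1)
  # identical groups
  same <- do.call(rbind, c(lapply(1:4, function(i) row("a", 5)),
                           lapply(1:4, function(i) row("b", 5))))
  same$density <- same$density + rep(c(-0.01, 0.01), 4)   # equal jitter
  cmp <- compare_density_groups(same)
  expect_gt(cmp$anova$p, 0.99)
  # well-separated groups
  set.seed(1)
  sep <- do.call(rbind, c(lapply(1:4, function(i) row("a", rnorm(1, 0, 0.01))),
                          lapply(1:4, function(i) row("b", rnorm(1, 10, 0.01)))))
  expect_lt(compare_density_groups(sep)$pairwise$p_adj[1], 0.05)
  # three groups: Bonferroni factor equals the 3 pairwise comparisons
  set.seed(2)
  three <- do.call(rbind, lapply(c("a", "b", "c"), function(g)
    do.call(rbind, lapply(1:4, function(i)
      row(g, rnorm(1, match(g, c("a", "b", "c")), 0.5))))))
  cmp3 <- compare_density_groups(three)
  raw <- pairwise.t.test(three$density, factor(three$group),
                         p.adjust.method = "none", pool.sd = TRUE)$p.value
  adj <- pairwise.t.test(three$density, factor(three$group),
                         p.adjust.method = "bonferroni",
                         pool.sd = TRUE)$p.value
  expect_equal(adj["b", "a"], min(1, 3 * raw["b", "a"]))
  expect_identical(nrow(cmp3$pairwise), 3L)
  # validation
  expect_error(compare_density_groups(row("a", 1)), "2 groups")
  expect_error(compare_density_groups(rbind(row("a", 1), row("a", 2),
                                            row("b", 1))), "at least 2 vessels")
})
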