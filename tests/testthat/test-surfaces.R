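test_that("slice contour of a filled disk recovers its area", {
  # one disk of radius 10 um per slice; oracle = foreground pixel count
  d <- c(1L, 3L, 140L, 140L)
  arr <- array(0, dim = d)
  yc <- (seq_len(140) - 0.5) * 0.3
  r2 <- outer((yc - 21)^2, (yc - 21)^2, `+`)
  disk <- r2 <= 10^2
  for (z in 1:3) arr[1, z, , ][disk] <- 200
  st <- image_stack(arr, c(1, 0.3, 0.3), "Lam1")
  cs <- extract_slice_contours(st, "Lam1", threshold = 100,
                               smoothing_sigma = 0)
  a <- vesselquant:::polygon_area(cs$contours[[1]]$polygon)
  oracle <- sum(disk) * 0.3^2
  expect_lt(abs(a / oracle - 1), 0.02)
  expect_lt(abs(a / (pi * 100) - 1), 0.05)
})

test_that("largest-component rule keeps the bigger of two disks", {
  d <- c(1L, 2L, 140L, 140L)
  arr <- array(0, dim = d)
  yc <- (seq_len(140) - 0.5) * 0.3
  big <- outer((yc - 14)^2, (yc - 14)^2, `+`) <= 10^2
  small <- outer((yc - 33)^2, (yc - 33)^2, `+`) <= 4^2
  for (z in 1:2) arr[1, z, , ][big | small] <- 200
  st <- image_stack(arr, c(1, 0.3, 0.3), "Lam1")
  cs <- extract_slice_contours(st, "Lam1", threshold = 100,
                               smoothing_sigma = 0)
  a <- vesselquant:::polygon_area(cs$contours[[1]]$polygon)
  expect_lt(abs(a / (pi * 100) - 1), 0.05)
  # rank 2 selects the smaller disk
  cs2 <- extract_slice_contours(st, "Lam1", threshold = 100,
                                smoothing_sigma = 0, component_rank = 2)
  a2 <- vesselquant:::polygon_area(cs2$contours[[1]]$polygon)
  expect_lt(abs(a2 / (pi * 16) - 1), 0.10)
})

test_that("contour extraction fails cleanly without usable slices", {
  arr <- array(0, dim = c(1, 3, 20, 20))
  st <- image_stack(arr, c(1, 0.3, 0.3), "Lam1")
  expect_error(extract_slice_contours(st, "Lam1", threshold = 1),
               "outside intensity range|usable")
})

test_that("lofted circular contours stay on the cylinder of radius r", {
  mesh <- cylinder_mesh(10, L = 20, M = 64)
  ring_idx <- seq_len(nrow(mesh$vertices) - 2)   # exclude cap centroids
  rad <- sqrt((mesh$vertices[ring_idx, 2] - 20)^2 +
              (mesh$vertices[ring_idx, 3] - 20)^2)
  expect_true(all(abs(rad - 10) / 10 < 0.01))
  expect_true(attr(mesh, "watertight"))
})

test_that("two square contours loft to a watertight prism with 2M side triangles", {
  sq <- cbind(y = c(0, 0, 4, 4), x = c(0, 4, 4, 0))
  cs <- contour_set("prism", list(list(z_index = 0L, polygon = sq),
                                  list(z_index = 1L, polygon = sq)))
  M <- 16L
  mesh <- loft_surface(cs, spacing = c(1, 1, 1), ring_vertices = M)
  expect_true(attr(mesh, "watertight"))
  expect_identical(nrow(mesh$triangles), 2L * M + 2L * M)  # sides + caps
  # area: two 4x4 caps + 4 sides of 4x1
  expect_equal(mesh_surface_area(mesh), 2 * 16 + 4 * 4, tolerance = 1e-6)
})

test_that("ring alignment makes lofting invariant to contour start point", {
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  poly_at <- function(shift) {
    idx <- ((seq_along(th) - 1 + shift) %% length(th)) + 1
    cbind(y = 20 + 10 * cos(th[idx]), x = 20 + 8 * sin(th[idx]))
  }
  base <- contour_set("s", lapply(0:5, function(z)
    list(z_index = z, polygon = poly_at(0))))
  set.seed(3)
  rot <- contour_set("s", lapply(0:5, function(z)
    list(z_index = z, polygon = poly_at(sample(0:95, 1)))))
  a0 <- mesh_surface_area(loft_surface(base, c(1, 0.3, 0.3), 48))
  a1 <- mesh_surface_area(loft_surface(rot, c(1, 0.3, 0.3), 48))
  expect_lt(abs(a1 / a0 - 1), 0.001)
})

test_that("mesh area matches closed forms and scales quadratically", {
  # unit cube: 8 vertices, 12 triangles, area 6
  v <- as.matrix(expand.grid(z = 0:1, y = 0:1, x = 0:1))
  tri <- matrix(c(1,3,4, 1,4,2, 5,8,7, 5,6,8,   # z faces
                  1,2,6, 1,6,5, 3,8,4, 3,7,8,   # y faces
                  1,7,3, 1,5,7, 2,4,8, 2,8,6),  # x faces
                ncol = 3, byrow = TRUE)
  cube <- surface_mesh(v, tri, "cube")
  expect_true(attr(cube, "watertight"))
  expect_equal(mesh_surface_area(cube), 6)
  cube2 <- surface_mesh(v * 2, tri, "cube2")
  expect_identical(mesh_surface_area(cube2), 4 * mesh_surface_area(cube))
})

test_that("non-watertight meshes are signalled but still measured", {
  v <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  single <- surface_mesh(v, matrix(c(1, 2, 3), 1), "tri")
  expect_false(attr(single, "watertight"))
  expect_warning(a <- mesh_surface_area(single), "watertight")
  expect_equal(a, 0.5)
})

test_that("point_inside agrees with the analytic cylinder membership test", {
  mesh <- cylinder_mesh(10, L = 60, M = 64)
  expect_true(point_inside(mesh, c(30, 20 + 5, 20)))
  expect_false(point_inside(mesh, c(30, 20 + 15, 20)))
  set.seed(7)
  pts <- cbind(runif(10000, -5, 65), runif(10000, 2, 38), runif(10000, 2, 38))
  ins <- point_inside(mesh, pts)
  truth <- pts[, 1] >= 0.5 & pts[, 1] <= 60.5 &
    sqrt((pts[, 2] - 20)^2 + (pts[, 3] - 20)^2) <= 10
  expect_gte(mean(ins == truth), 0.995)
})

test_that("lofted cylinder area converges to the closed form as M grows", {
  analytic <- 2 * pi * 10 * 60 + 2 * pi * 100
  errs <- vapply(c(16, 32, 64, 128), function(M)
    abs(mesh_surface_area(cylinder_mesh(10, L = 60, M = M)) - analytic),
    numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("phantom endothelial mesh is nested inside the parenchymal mesh", {
  ph <- generate_phantom(small_spec(seed = 4L))
  em <- loft_surface(ground_truth_contours(ph$ground_truth, "endothelial_bm"),
                     ph$stack$voxel_spacing, 48)
  pm <- loft_surface(ground_truth_contours(ph$ground_truth, "parenchymal_bm"),
                     ph$stack$voxel_spacing, 48)
  expect_true(all(point_inside(pm, em$vertices)))
})

test_that("contour sets round-trip through the JSON exchange format", {
  cs <- circle_contours(7, 0:4, name = "endothelial_bm")
  f <- tempfile(fileext = ".json")
  write_contours_json(cs, f)
  rt <- read_contours_json(f)
  expect_identical(rt$surface_name, "endothelial_bm")
  expect_equal(rt$contours[[3]]$polygon, cs$contours[[3]]$polygon,
               ignore_attr = TRUE)
  unlink(f)
})

test_that("degenerate contour inputs are rejected", {
  sq <- cbind(c(0, 0, 4, 4), c(0, 4, 4, 0))
  expect_error(contour_set("s", list(list(z_index = 0L, polygon = sq))),
               "at least 2 slices")
  expect_error(contour_set("s", list(list(z_index = 0L, polygon = sq),
                                     list(z_index = 2L, polygon = sq))),
               "consecutive")
  line <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(contour_set("s", list(list(z_index = 0L, polygon = line),
                                     list(z_index = 1L, polygon = line))),
               "degenerate")
})
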