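# The alpha-shape volume kernel: construction, voxel and tetra volumes,
# and their agreement.

test_that("the alpha complex of cube corners fills the cube", {
  pts <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  shape <- build_alpha_shape(pts, alpha = 10)
  expect_equal(volume_by_tetra(shape), 0.001, tolerance = 1e-9)  # 1 mm^3
  expect_true(point_in_complex(shape, c(0.5, 0.5, 0.5)))
  expect_false(point_in_complex(shape, c(2, 2, 2)))
  expect_true(point_in_complex(shape, pts[1, ]))   # boundary vertex inside
})

test_that("alpha separates distant clusters and bridges them when large", {
  pts <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
               as.matrix(expand.grid(0:1, 0:1, 0:1)) + matrix(rep(c(10, 0, 0), each = 8), ncol = 3))
  small <- build_alpha_shape(pts, alpha = 1)
  expect_equal(volume_by_tetra(small), 0.002, tolerance = 1e-9)  # two unit cubes
  big <- build_alpha_shape(pts, alpha = 100)
  expect_gt(volume_by_tetra(big), 0.002)
  expect_equal(volume_by_tetra(big) * 1000, convex_hull_volume(pts),
               tolerance = 1e-9)
})

test_that("degenerate clouds and over-small alpha are rejected", {
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(build_alpha_shape(flat, 1), class = "cavex_error_degenerate")
  pts <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10
  err <- tryCatch(build_alpha_shape(pts, alpha = 0.5), error = identity)
  expect_s3_class(err, "cavex_error_empty_complex")
  expect_true(is.finite(err$smallest_alpha))
  expect_error(build_alpha_shape(pts, alpha = -1), class = "cavex_error_alpha")
})

test_that("voxel volume matches the analytic cube and loses a vertex shell", {
  g <- seq(0, 10, by = 1)
  surf <- as.matrix(expand.grid(g, g, g))
  surf <- surf[surf[, 1] %in% c(0, 10) | surf[, 2] %in% c(0, 10) |
                 surf[, 3] %in% c(0, 10), ]
  shape <- build_alpha_shape(surf, alpha = Inf)
  # no COI vertices: plain centre-in-complex counting
  v_free <- volume_by_voxels(shape, matrix(numeric(), 0, 3), spacing = 0.5)$volume_cm3
  expect_equal(v_free, 1.0, tolerance = 0.03)
  # the surface cloud empties a one-voxel-thick shell (~ area x spacing)
  area <- 600
  last <- NULL
  for (s in c(0.5, 0.25)) {
    v <- volume_by_voxels(shape, surf, spacing = s)$volume_cm3
    deficit <- 1.0 - v
    expect_gt(deficit, 0)
    expect_equal(deficit, area * s / 1000, tolerance = 0.6)
    if (!is.null(last)) expect_lt(deficit, last)  # converges as spacing shrinks
    last <- deficit
  }
  expect_error(volume_by_voxels(shape, surf, spacing = 5),
               class = "cavex_error_spacing")
})

test_that("tetra volume is exact for closed forms", {
  e <- 10
  tetra <- rbind(c(0, 0, 0), c(e, 0, 0), c(e / 2, e * sqrt(3) / 2, 0),
                 c(e / 2, e * sqrt(3) / 6, e * sqrt(6) / 3))
  shape <- build_alpha_shape(tetra, alpha = Inf)
  expect_equal(volume_by_tetra(shape), e^3 / (6 * sqrt(2)) / 1000, tolerance = 1e-9)
})

test_that("icv recovers the hollow-sphere cavity from its wall", {
  b <- get_phantom("hollow-sphere")
  wall <- hollow_wall(b)                          # the R = 20 cavity wall
  rep <- icv(wall, alpha = 25, spacing = 0.5)
  expect_equal(rep$volume_tetra_cm3, 4 / 3 * pi * 20^3 / 1000, tolerance = 0.03)
  expect_equal(rep$volume_voxel_cm3, rep$volume_tetra_cm3, tolerance = 0.1)
  expect_identical(rep$n_cells, 1L)
})

test_that("icv with multiple = TRUE measures cells separately", {
  s <- get_phantom("two-cell-slab")
  cells <- cavex:::merge_meshes(slab_cells(s), name = "cells")
  rep <- icv(cells, alpha = 12, spacing = 0.6, multiple = TRUE)
  expect_identical(rep$n_cells, 2L)
  expect_equal(sort(rep$per_cell_volumes), c(0.8, 1.5), tolerance = 0.01)
  expect_equal(rep$volume_tetra_cm3, 2.3, tolerance = 0.01)
})

test_that("the alpha -> Inf complex volume equals the convex hull volume", {
  set.seed(41)
  for (n in c(60, 300, 1200)) {
    pts <- matrix(runif(3 * n, -5, 5), ncol = 3)
    shape <- build_alpha_shape(pts, alpha = Inf)
    expect_equal(volume_by_tetra(shape) * 1000, convex_hull_volume(pts),
                 tolerance = 1e-9)
  }
})

test_that("complex volume is monotone in alpha and rigid-motion invariant", {
  set.seed(42)
  pts <- matrix(runif(3 * 150, 0, 20), ncol = 3)
  vols <- vapply(c(2, 4, 8, 16, Inf),
                 function(a) tryCatch(volume_by_tetra(build_alpha_shape(pts, a)),
                                      error = function(e) 0), 0)
  expect_true(all(diff(vols) >= -1e-12))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- pts %*% t(R) + matrix(rep(c(3, -2, 9), each = nrow(pts)), ncol = 3)
  expect_equal(volume_by_tetra(build_alpha_shape(moved, 8)),
               volume_by_tetra(build_alpha_shape(pts, 8)), tolerance = 1e-6)
})
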