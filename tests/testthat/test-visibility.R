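# Line-of-sight selection: single-POV masks, the brute-force oracle,
# scanner emulation and internal-surface separation.

test_that("a sphere is fully visible from its centre", {
  sph <- icosphere(2L, radius = 10)
  mask <- visible_from_pov(sph, c(0, 0, 0))
  expect_true(all(mask))
  expect_identical(n_faces(extract_visible_submesh(sph, mask)), n_faces(sph))
})

test_that("an inner shell occludes the outer one from the centre", {
  b <- get_phantom("hollow-sphere")     # outer R = 40 shell + inner R = 20 wall
  mask <- visible_from_pov(b$mesh, c(0, 0, 0))
  r <- sqrt(rowSums(b$mesh$vertices^2))
  expect_true(all(mask[r < 30]))        # cavity wall fully visible
  expect_true(all(!mask[r > 30]))       # outer shell fully occluded
})

test_that("accelerated visibility equals the brute-force oracle outside a sphere", {
  sph <- icosphere(2L, radius = 10)     # 320 faces
  pov <- c(30, 0, 0)
  fast <- visible_from_pov(sph, pov, method = "bvh")
  slow <- visible_from_pov(sph, pov, method = "brute")
  expect_identical(as.logical(fast), as.logical(slow))
  # from distance d the visible cap holds (1 - R/d)/2 of the sphere: 1/3 at
  # d = 3R, plus a discretisation margin on a 320-face sphere
  frac <- mean(fast)
  expect_gte(frac, 0.30)
  expect_lte(frac, 0.45)
})

test_that("visibility is monotone in the POV set", {
  b <- get_phantom("orbit-fossa")
  set.seed(31)
  p1 <- matrix(c(30, 6, 30), ncol = 3)
  for (i in 1:5) {
    extra <- matrix(rnorm(9, sd = 30), ncol = 3)
    m1 <- cavex:::visible_from_povs(b$mesh, p1)
    m2 <- cavex:::visible_from_povs(b$mesh, rbind(p1, extra))
    expect_true(all(m2[as.logical(m1)]))   # adding POVs never unmarks
  }
})

test_that("face rules control bleed-through of partially visible faces", {
  sph <- icosphere(2L, radius = 10)
  mask <- visible_from_pov(sph, c(30, 0, 0))
  n_all <- n_faces(extract_visible_submesh(sph, mask, "all"))
  n_maj <- n_faces(extract_visible_submesh(sph, mask, "majority"))
  n_any <- n_faces(extract_visible_submesh(sph, mask, "any"))
  expect_true(n_all <= n_maj && n_maj <= n_any)
  none <- structure(rep(FALSE, n_vertices(sph)), class = "visibility_mask")
  expect_error(extract_visible_submesh(sph, none), class = "cavex_error_pov_outside")
})

test_that("scanner emulation sees all of a convex mesh and none of an enclosed wall", {
  cube <- make_box_mesh(c(0, 0, 0), c(10, 10, 10))
  expect_true(all(scanner_visibility(cube, n_views = 42L)))
  b <- get_phantom("hollow-sphere")
  mask <- scanner_visibility(b$mesh, n_views = 162L)
  r <- sqrt(rowSums(b$mesh$vertices^2))
  expect_true(all(!mask[r < 30]))
  expect_true(all(mask[r > 30]))
  expect_equal(nrow(attr(mask, "povs")), 162L)
})

test_that("internal surfaces come back as volume-ordered components", {
  cube <- make_box_mesh(c(0, 0, 0), c(10, 10, 10))
  expect_length(internal_surfaces(cube, scanner_visibility(cube, n_views = 42L),
                                  min_faces = 4L), 0L)
  b <- get_phantom("hollow-sphere")
  cells <- internal_surfaces(b$mesh, scanner_visibility(b$mesh, n_views = 162L))
  expect_length(cells, 1L)
  expect_equal(abs(signed_volume(cells[[1]])), 4 / 3 * pi * 20^3, tolerance = 0.01)
  s <- get_phantom("two-cell-slab")
  cells2 <- internal_surfaces(s$mesh, scanner_visibility(s$mesh, n_views = 162L))
  expect_length(cells2, 2L)
  # sorted by enclosed volume, biggest first
  expect_equal(abs(signed_volume(cells2[[1]])), 1500, tolerance = 1e-6)
  expect_equal(abs(signed_volume(cells2[[2]])), 800, tolerance = 1e-6)
})
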