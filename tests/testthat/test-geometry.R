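# Planes from landmark triplets, half-space cutting with triangle
# splitting, connected components and the signed-volume oracle.

test_that("plane_from_landmarks follows operand order and rejects collinear points", {
  pl <- plane_from_landmarks(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$origin, c(0, 0, 0))
  pl2 <- plane_from_landmarks(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  expect_equal(pl2$normal, c(0, 0, -1), tolerance = 1e-12)
  expect_error(plane_from_landmarks(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "cavex_error_collinear")
})

test_that("plane construction is equivariant under rigid motion", {
  set.seed(11)
  for (i in 1:5) {
    a <- runif(3); b <- runif(3); cc <- runif(3)
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rx %*% Rz
    t0 <- runif(3, -5, 5)
    p1 <- plane_from_landmarks(a, b, cc)
    p2 <- plane_from_landmarks(R %*% a + t0, R %*% b + t0, R %*% cc + t0)
    expect_equal(as.numeric(R %*% p1$normal), p2$normal, tolerance = 1e-9)
    expect_equal(as.numeric(R %*% p1$origin + t0), p2$origin, tolerance = 1e-9)
  }
})

test_that("cutting a cube splits straddling triangles exactly", {
  cube <- unit_cube()
  # half box: bottom 1 + four half sides = 3.0 mm^2 of area
  half <- cut_mesh_by_plane(cube, cut_spec(
    plane_from_landmarks(c(0, 0, 0.5), c(1, 0, 0.5), c(0, 1, 0.5)), "negative"))
  expect_equal(mesh_area(half), 3.0, tolerance = 1e-9)
  expect_true(all(half$vertices[, 3] <= 0.5 + 1e-9))
  # plane entirely outside: unchanged
  whole <- cut_mesh_by_plane(cube, cut_spec(
    plane_from_landmarks(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2)), "negative"))
  expect_equal(mesh_area(whole), 6.0, tolerance = 1e-12)
  expect_equal(n_faces(whole), 12L)
  # plane leaving nothing
  expect_error(
    cut_mesh_by_plane(cube, cut_spec(
      plane_from_landmarks(c(0, 0, -1), c(1, 0, -1), c(0, 1, -1)), "negative")),
    class = "cavex_error_empty_cut")
})

test_that("a cut sequence folds left to right and reports the failing index", {
  cube <- unit_cube()
  mid <- function(ax) {
    o <- c(0.5, 0.5, 0.5)
    pts <- diag(3)[-ax, , drop = FALSE]
    pl <- plane_from_landmarks(o, o + pts[1, ], o + pts[2, ])
    # keep the lower half-space whichever way the triplet normal points
    cut_spec(pl, if (pl$normal[ax] > 0) "negative" else "positive")
  }
  octant <- apply_cut_sequence(cube, list(mid(1), mid(2), mid(3)))
  bb <- apply(octant$vertices, 2, range)
  expect_equal(unname(bb[2, ]), c(0.5, 0.5, 0.5), tolerance = 1e-9)
  expect_length(attr(octant, "cut_log"), 3L)

  err <- tryCatch(apply_cut_sequence(cube, list(
    mid(1),
    cut_spec(plane_from_landmarks(c(0, 0, -1), c(1, 0, -1), c(0, 1, -1)), "negative"))),
    error = identity)
  expect_s3_class(err, "cavex_error_empty_cut")
  expect_match(conditionMessage(err), "cut 2 of 2")
})

test_that("cutting conserves area exactly when triangles are split", {
  cube <- unit_cube()
  a0 <- mesh_area(cube)
  set.seed(21)
  for (i in 1:10) {
    o <- runif(3, 0.2, 0.8)
    n <- rnorm(3)
    b1 <- rnorm(3); b1 <- b1 - sum(b1 * n) / sum(n * n) * n
    b2 <- c(n[2] * b1[3] - n[3] * b1[2], n[3] * b1[1] - n[1] * b1[3],
            n[1] * b1[2] - n[2] * b1[1])
    pl <- plane_from_landmarks(o, o + b1, o + b2)
    pos <- cut_mesh_by_plane(cube, cut_spec(pl, "positive"))
    neg <- cut_mesh_by_plane(cube, cut_spec(pl, "negative"))
    expect_equal(mesh_area(pos) + mesh_area(neg), a0, tolerance = 1e-9)
  }
})

test_that("connected components partition faces by shared vertices", {
  two <- cavex:::merge_meshes(list(make_box_mesh(), make_box_mesh(c(3, 0, 0), c(4, 1, 1))))
  comps <- connected_components(two)
  expect_length(comps, 2L)
  expect_equal(vapply(comps, n_faces, 1L), c(12L, 12L))
  expect_length(connected_components(icosphere(2L)), 1L)
})

test_that("signed_volume matches closed forms and rejects open meshes", {
  expect_equal(signed_volume(unit_cube()), 1.0, tolerance = 1e-12)
  sph <- icosphere(4L, radius = 10)
  expect_equal(signed_volume(sph), 4 / 3 * pi * 1000, tolerance = 0.005)
  open_cube <- trimesh(unit_cube()$vertices, unit_cube()$faces[-1, ])
  expect_error(signed_volume(open_cube), class = "cavex_error_orientation")
})

test_that("signed_volume is invariant under rigid motion and decimation", {
  sph <- icosphere(3L, radius = 7)
  v0 <- signed_volume(sph)
  set.seed(5)
  th <- runif(1, 0, 2 * pi)
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- cavex:::transform_mesh(sph, R, c(10, -4, 2))
  expect_equal(signed_volume(moved), v0, tolerance = 1e-9)
  dec <- decimate_mesh(icosphere(5L, radius = 7), n_faces(sph))
  expect_lt(abs(signed_volume(dec) - signed_volume(icosphere(5L, radius = 7))) /
              signed_volume(icosphere(5L, radius = 7)), 0.02)
})
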