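# Readers/writers for PLY, STL, OBJ; landmark CSV; decimation.

test_that("PLY round-trips a cube losslessly", {
  cube <- unit_cube()
  p <- withr::local_tempfile(fileext = ".ply")
  save_mesh(cube, p)
  back <- load_mesh(p)
  expect_equal(n_vertices(back), 8L)
  expect_equal(n_faces(back), 12L)
  expect_equal(back$vertices, cube$vertices, tolerance = 1e-6)
  expect_equal(back$faces, cube$faces)
})

test_that("binary STL stores facets independently (no merging on load)", {
  cube <- unit_cube()
  p <- withr::local_tempfile(fileext = ".stl")
  save_mesh(cube, p, binary = TRUE)
  back <- load_mesh(p)
  expect_equal(n_faces(back), 12L)
  expect_equal(n_vertices(back), 36L)   # 3 per facet, duplicated
  # explicit weld recovers the shared-vertex cube
  expect_equal(n_vertices(weld_vertices(back)), 8L)
  expect_equal(abs(signed_volume(weld_vertices(back))), 1, tolerance = 1e-6)
})

test_that("ascii STL round-trips coordinates", {
  cube <- unit_cube()
  p <- withr::local_tempfile(fileext = ".stl")
  save_mesh(cube, p, binary = FALSE)
  back <- load_mesh(p)
  expect_equal(n_faces(back), 12L)
  got <- back$vertices[order(back$vertices[, 1], back$vertices[, 2], back$vertices[, 3]), ]
  expect_true(max(abs(range(got) - c(0, 1))) < 1e-6)
})

test_that("OBJ round-trips and flags 0-based face indices", {
  cube <- unit_cube()
  p <- withr::local_tempfile(fileext = ".obj")
  save_mesh(cube, p)
  back <- load_mesh(p)
  expect_equal(back$vertices, cube$vertices, tolerance = 1e-6)
  expect_equal(back$faces, cube$faces)
  bad <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 0 1 2"), bad)
  expect_error(load_mesh(bad), class = "cavex_error_mesh_index")
})

test_that("unreadable and empty meshes are rejected with informative errors", {
  expect_error(load_mesh(file.path(tempdir(), "nope.ply")), class = "cavex_error_io")
  p <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not a ply"), p)
  expect_error(load_mesh(p), class = "cavex_error_format")
  # PLY with zero faces
  p2 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property double x", "property double y", "property double z",
               "element face 0", "property list uchar int vertex_indices",
               "end_header", "0 0 0"), p2)
  expect_error(load_mesh(p2), class = "cavex_error_empty_mesh")
  expect_error(trimesh(matrix(0, 1, 3), matrix(integer(), 0, 3)),
               class = "cavex_error_empty_mesh")
})

test_that("landmark CSV honours order, schema and duplicates", {
  b <- get_phantom("full-suite")
  p <- withr::local_tempfile(fileext = ".csv")
  save_landmarks(b$landmarks, p)
  lms <- load_landmarks(p, schema_id = "icex18")
  expect_equal(lms$label, icex18_labels())
  expect_equal(as.matrix(as.data.frame(lms)[, c("x", "y", "z")]),
               as.matrix(as.data.frame(b$landmarks)[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # free 3-point configuration needs no schema
  free <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x,y,z", "a,0,0,0", "b,1,0,0", "c,0,1,0"), free)
  expect_equal(nrow(load_landmarks(free)), 3L)
  # duplicated label
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x,y,z", "bregma,0,0,0", "bregma,1,0,0"), dup)
  expect_error(load_landmarks(dup), class = "cavex_error_landmark_schema")
  # missing labels are listed
  few <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x,y,z", "bregma,0,0,0"), few)
  err <- tryCatch(load_landmarks(few, schema_id = "icex18"), error = identity)
  expect_s3_class(err, "cavex_error_landmark_schema")
  expect_match(conditionMessage(err), "nasion")
})

test_that("decimation hits the target count and preserves volume and extent", {
  small <- unit_cube()
  expect_identical(decimate_mesh(small, 500000L), small)
  expect_error(decimate_mesh(small, 3), class = "cavex_error_decimate")

  sph <- icosphere(6L, radius = 10)     # 81,920 faces
  expect_equal(n_faces(sph), 81920L)
  dec <- decimate_mesh(sph, 20000L)
  expect_gte(n_faces(dec), 19800L)
  expect_lte(n_faces(dec), 20200L)
  v0 <- signed_volume(sph)
  v1 <- signed_volume(dec)
  expect_lt(abs(v1 - v0) / v0, 0.02)
  d0 <- cavex:::bbox_diagonal(sph)
  expect_lt(abs(cavex:::bbox_diagonal(dec) - d0) / d0, 0.01)
})
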