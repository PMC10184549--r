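# The phantom generator: watertightness, analytic truths, determinism.

test_that("phantom shells are closed, oriented solids with the expected volume", {
  nb <- get_phantom("nasal-block")
  expect_true(cavex:::is_closed_mesh(nb$mesh))
  expect_equal(signed_volume(nb$mesh), 60^3 - 20^3, tolerance = 1e-9)
  tc <- get_phantom("two-cell-slab")
  expect_true(cavex:::is_closed_mesh(tc$mesh))
  expect_equal(signed_volume(tc$mesh), 80 * 50 * 24 - 1500 - 800, tolerance = 1e-9)
  for (k in c("hollow-sphere", "orbit-fossa", "palate-dome", "full-suite")) {
    b <- get_phantom(k)
    expect_true(cavex:::is_closed_mesh(b$mesh), label = paste(k, "closed"))
    expect_gt(signed_volume(b$mesh), 0)
  }
})

test_that("analytic truths agree with the meshed cavity walls", {
  b <- get_phantom("hollow-sphere")
  expect_equal(b$truth$cavity, 33.5103, tolerance = 1e-4)
  wall <- hollow_wall(b)
  # inscribed-polyhedron volume is within 1% of the sphere volume
  expect_equal(abs(signed_volume(wall)) / 1000, b$truth$cavity, tolerance = 0.01)
  tc <- get_phantom("two-cell-slab")
  expect_equal(tc$truth$cell1, 1.5)
  expect_equal(tc$truth$cell2, 0.8)
  comps <- slab_cells(tc)
  expect_equal(sort(vapply(comps, function(m) abs(signed_volume(m)), 0)),
               c(800, 1500), tolerance = 1e-9)
})

test_that("the full suite carries the 18-landmark scheme and five recipes", {
  b <- get_phantom("full-suite")
  expect_identical(b$landmarks$label, icex18_labels())
  expect_identical(attr(b$landmarks, "schema_id"), "icex18")
  expect_named(b$specs, c("nasal_cavity", "maxillary_sinus_R", "orbit_R",
                          "palate", "frontal_sinus"))
  expect_identical(names(b$truth), names(b$specs))
  modes <- vapply(b$specs, `[[`, 1L, "mode")
  expect_identical(unname(modes), c(1L, 1L, 2L, 3L, 4L))
  expect_length(b$specs$nasal_cavity$cuts, 5L)
  expect_length(b$specs$maxillary_sinus_R$cuts, 6L)
  expect_length(b$specs$frontal_sinus$cuts, 2L)
})

test_that("generation is deterministic", {
  a <- make_phantom("two-cell-slab", seed = 7L)
  b <- make_phantom("two-cell-slab", seed = 7L)
  expect_identical(a, b)
})

test_that("evaluate_extraction keys results against truths", {
  b <- get_phantom("two-cell-slab")
  fake <- list(sinus = list(report = list(volume_tetra_cm3 = 2.3)))
  tab <- evaluate_extraction(b, fake)
  expect_equal(tab$rel_error, 0)
  expect_true(all(tab$pass))
  expect_error(evaluate_extraction(b, list()), class = "cavex_error_keying")
})
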