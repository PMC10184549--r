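# The four extraction modes and the batch protocol driver.

test_that("enclosed-cavity extraction finds the hollow-sphere wall", {
  b <- get_phantom("hollow-sphere")
  coi <- extract_enclosed_cavity(b$mesh)
  expect_true(all(sqrt(rowSums(coi$vertices^2)) < 21))   # only the cavity wall
  rep <- icv(coi, alpha = 25, spacing = 0.8)
  expect_equal(rep$volume_tetra_cm3, b$truth$cavity, tolerance = 0.03)
  seedpt <- attr(coi, "seed_point")
  expect_lt(sqrt(sum(seedpt^2)), 20)                     # seed inside the cavity
  expect_error(extract_enclosed_cavity(make_box_mesh(c(0, 0, 0), c(10, 10, 10))),
               class = "cavex_error_no_cavity")
})

test_that("mode 1 cuts, extracts and measures enclosed cavities", {
  nb <- get_phantom("nasal-block")
  res <- run_mode1(nb$mesh, nb$landmarks, nb$specs$cavity)
  expect_equal(res$report$volume_tetra_cm3, nb$truth$cavity, tolerance = 0.05)
  expect_identical(vapply(res$log, `[[`, "", "step"), c("cut", "extract", "icv"))
  # flipping a keep side mis-crops the mesh: either nothing is left at some
  # cut or no enclosed cavity remains in the kept region
  bad <- nb$specs$cavity
  bad$cuts[[2]]$keep <- if (bad$cuts[[2]]$keep == "positive") "negative" else "positive"
  err <- tryCatch(run_mode1(nb$mesh, nb$landmarks, bad), error = identity)
  expect_s3_class(err, "cavex_error")
  # contradictory planes empty the mesh and report the offending index
  contradict <- nb$specs$cavity
  contradict$cuts <- list(
    list(labels = contradict$cuts[[4]]$labels,   # z-plane at 15, keep below
         keep = setdiff(c("positive", "negative"), contradict$cuts[[4]]$keep)),
    list(labels = contradict$cuts[[5]]$labels,   # z-plane at 45, keep above
         keep = setdiff(c("positive", "negative"), contradict$cuts[[5]]$keep)))
  err2 <- tryCatch(run_mode1(nb$mesh, nb$landmarks, contradict), error = identity)
  expect_s3_class(err2, "cavex_error_empty_cut")
  expect_match(conditionMessage(err2), "cut 2 of 2")
})

test_that("mode 2 extracts an open fossa from the rim-landmark barycentre", {
  b <- get_phantom("orbit-fossa")
  res <- run_mode2(b$mesh, b$landmarks, b$specs$fossa)
  expect_equal(res$report$volume_tetra_cm3, b$truth$fossa, tolerance = 0.05)
  # collinear POV landmarks are fine: the barycentre needs no non-collinearity
  lms_lin <- landmark_config(b$landmarks$label,
                             rbind(c(30, 4, 30), c(30, 6, 30), c(30, 8, 30)))
  r_lin <- run_mode2(b$mesh, lms_lin, b$specs$fossa)
  expect_equal(r_lin$report$volume_tetra_cm3, b$truth$fossa, tolerance = 0.05)
})

test_that("mode 3 equals mode 2 once the teeth are gone", {
  p3 <- get_phantom("palate-dome")
  r3 <- run_mode3(p3$mesh, p3$landmarks, p3$specs$palate)
  expect_equal(r3$report$volume_tetra_cm3, p3$truth$palate, tolerance = 0.05)
  p2 <- get_phantom("palate-dome", teeth = FALSE)
  r2 <- run_mode2(p2$mesh, p2$landmarks, p2$specs$palate)
  expect_equal(r2$report$volume_tetra_cm3, r3$report$volume_tetra_cm3,
               tolerance = 0.02)
})

test_that("mode 4 separates cells and honours the multiple flag", {
  s <- get_phantom("two-cell-slab")
  r_all <- run_mode4(s$mesh, s$landmarks, s$specs$sinus)
  expect_identical(r_all$report$n_cells, 2L)
  expect_equal(sort(r_all$report$per_cell_volumes), c(0.8, 1.5), tolerance = 0.05)
  one <- s$specs$sinus
  one$multiple <- FALSE
  r_big <- run_mode4(s$mesh, s$landmarks, one)
  expect_identical(r_big$report$n_cells, 1L)
  expect_equal(r_big$report$volume_tetra_cm3, 1.5, tolerance = 0.05)
  # a solid slab has no sinus: zero-volume report with a warning
  solid <- make_box_mesh(c(0, 0, 0), c(80, 50, 24))
  expect_warning(r0 <- run_mode4(solid, s$landmarks, s$specs$sinus),
                 class = "cavex_warning_no_sinus")
  expect_identical(r0$report$n_cells, 0L)
  expect_identical(r0$report$volume_tetra_cm3, 0)
})

test_that("mode_spec validates its shape constraints", {
  expect_error(mode_spec("x", 5), class = "cavex_error_spec")
  expect_error(mode_spec("x", 2, cuts = list(list(labels = c("a", "b", "c"),
                                                  keep = "positive")),
                         pov_labels = c("a", "b", "c")),
               class = "cavex_error_spec")
  expect_error(mode_spec("x", 3, pov_labels = c("a", "b", "c")),
               class = "cavex_error_spec")   # missing alveolar cut
  expect_error(mode_spec("x", 4, cuts = list(list(labels = c("a", "b", "c"),
                                                  keep = "positive"))),
               class = "cavex_error_spec")   # needs exactly two cuts
  b <- get_phantom("nasal-block")
  alien <- b$specs$cavity
  alien$cuts[[1]]$labels <- c("no", "such", "landmark")
  expect_error(run_mode1(b$mesh, b$landmarks, alien), class = "cavex_error_spec")
})

test_that("the batch driver survives a bad spec and writes its artefacts", {
  b <- get_phantom("nasal-block")
  bad <- b$specs$cavity
  bad$cavity_name <- "broken"
  bad$cuts[[1]]$keep <- "negative"          # empties the mesh immediately
  outdir <- withr::local_tempdir()
  out <- run_icex(b$mesh, b$landmarks, list(b$specs$cavity, bad), outdir = outdir,
                  interactive_export = FALSE)
  expect_length(out$results, 1L)
  expect_length(out$failures, 1L)
  expect_named(out$failures, "broken")
  expect_true(file.exists(file.path(outdir, "cavity_coi.ply")))
  expect_true(file.exists(file.path(outdir, "cavity_alpha.ply")))
  expect_true(file.exists(file.path(outdir, "results.csv")))
  # the exported COI re-measures identically after a reload (editing loop)
  reloaded <- load_mesh(file.path(outdir, "cavity_coi.ply"))
  rep <- icv(reloaded, alpha = 15, spacing = 0.75)
  expect_equal(rep$volume_tetra_cm3, out$results$cavity$report$volume_tetra_cm3,
               tolerance = 1e-6)
})

test_that("identical inputs give identical reports", {
  b <- get_phantom("orbit-fossa")
  r1 <- run_mode2(b$mesh, b$landmarks, b$specs$fossa)
  r2 <- run_mode2(b$mesh, b$landmarks, b$specs$fossa)
  expect_identical(r1$report$volume_voxel_cm3, r2$report$volume_voxel_cm3)
  expect_identical(r1$report$volume_tetra_cm3, r2$report$volume_tetra_cm3)
})
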