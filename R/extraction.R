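# Orchestration of the four extraction modes: cut -> select/extract the
# cavity of interest -> alpha-shape volume -> export.

#' Extract the wall of an enclosed cavity
#'
#' Finds an interior point of a fully enclosed void (the endocast-style
#' pathway): axis-aligned rays are cast through the solid, midpoints of the
#' intervals between consecutive surface crossings become seed candidates,
#' candidates that can see open space (any probe ray escaping the mesh) are
#' discarded, and the enclosed candidate with the largest clearance to the
#' surface wins. The cavity wall is the union of the surfaces visible from
#' the winning seed and up to six surrounding POVs (offset by
#' `0.25 x clearance x param1`).
#'
#' @param mesh a [trimesh()] (typically an already-cut bone region).
#' @param n_seed_candidates approximate number of interior candidates to
#'   generate.
#' @param param1 scale factor on the POV offset radius.
#' @param offset_eps see [visible_from_pov()].
#' @param seed integer; fixes the surrounding-POV directions.
#' @return the cavity-wall [trimesh()] with attribute `seed_point`.
#' @export
extract_enclosed_cavity <- function(mesh, n_seed_candidates = 64L, param1 = 1,
                                    offset_eps = 1e-4, seed = 1L) {
  validate_trimesh(mesh)
  bb <- mesh_bbox(mesh)
  span <- bb[2, ] - bb[1, ]
  diag_len <- sqrt(sum(span^2))
  k <- max(2L, ceiling(sqrt(n_seed_candidates / 3)))
  origins <- NULL
  dirs <- NULL
  for (ax in 1:3) {
    u <- (seq_len(k) - 0.5) / k
    o1 <- bb[1, (ax %% 3) + 1] + u * span[(ax %% 3) + 1]
    o2 <- bb[1, (ax + 1) %% 3 + 1] + u * span[(ax + 1) %% 3 + 1]
    g <- expand.grid(o1 = o1, o2 = o2)
    o <- matrix(0, nrow(g), 3)
    o[, (ax %% 3) + 1] <- g$o1
    o[, (ax + 1) %% 3 + 1] <- g$o2
    o[, ax] <- bb[1, ax] - 0.05 * max(diag_len, 1)
    d <- matrix(0, nrow(g), 3)
    d[, ax] <- 1
    origins <- rbind(origins, o)
    dirs <- rbind(dirs, d)
  }
  tmax <- 2 * diag_len
  hits <- .C_ray_hits(mesh$vertices, mesh$faces - 1L, origins, dirs, tmax)
  cands <- NULL
  for (r in seq_along(hits)) {
    ts <- hits[[r]]
    if (length(ts) < 2) next
    ts <- ts[c(TRUE, diff(ts) > 1e-7 * tmax)]  # merge edge-tie duplicates
    if (length(ts) < 2) next
    mid_t <- (ts[-1] + ts[-length(ts)]) / 2
    cands <- rbind(cands, origins[r, , drop = FALSE][rep(1, length(mid_t)), ] +
                     mid_t %o% dirs[r, ])
  }
  if (is.null(cands) || nrow(cands) == 0) {
    abort_cavex("no interior interval found: mesh encloses no cavity",
                "cavex_error_no_cavity")
  }
  # enclosedness: all probe rays must hit the mesh
  probe <- rbind(diag(3), -diag(3),
                 matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), ncol = 3,
                        byrow = TRUE) / sqrt(3))
  enclosed <- rep(TRUE, nrow(cands))
  for (d in seq_len(nrow(probe))) {
    hh <- .C_ray_hits(mesh$vertices, mesh$faces - 1L, cands,
                      probe[rep(d, nrow(cands)), , drop = FALSE], tmax)
    enclosed <- enclosed & lengths(hh) > 0
  }
  if (!any(enclosed)) {
    abort_cavex("no enclosed interior point found: mesh encloses no cavity",
                "cavex_error_no_cavity")
  }
  cands <- cands[enclosed, , drop = FALSE]
  # a cavity wall faces its void (normals toward the seed under the
  # outward-from-bone orientation convention); a point inside solid bone
  # sees triangle backs. Keep candidates that mostly face them.
  facing <- rep(0, nrow(cands))
  v <- mesh$vertices
  f <- mesh$faces
  for (d in seq_len(nrow(probe))) {
    fh <- .C_first_hit(v, f - 1L, cands,
                       probe[rep(d, nrow(cands)), , drop = FALSE], tmax)
    fi <- fh$face + 1L
    ok <- fi > 0L
    a <- v[f[fi[ok], 1], , drop = FALSE]
    b <- v[f[fi[ok], 2], , drop = FALSE]
    cc <- v[f[fi[ok], 3], , drop = FALSE]
    e1 <- b - a
    e2 <- cc - a
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    facing[ok] <- facing[ok] + (nrm %*% probe[d, ] < 0)
  }
  toward <- facing >= nrow(probe) / 2
  if (!any(toward)) {
    abort_cavex(
      "interior voids face away from every seed (solid bone, no cavity)",
      "cavex_error_no_cavity")
  }
  cands <- cands[toward, , drop = FALSE]
  clearance <- sqrt(.C_min_dist2(mesh$vertices, cands))
  best <- which.max(clearance)
  seed_pt <- cands[best, ]
  r_jit <- 0.25 * clearance[best] * param1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  jd <- matrix(rnorm(18), ncol = 3)
  jd <- jd / sqrt(rowSums(jd^2))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  povs <- rbind(seed_pt, sweep(jd * r_jit, 2, -seed_pt))
  mask <- visible_from_povs(mesh, povs, offset_eps = offset_eps)
  out <- extract_visible_submesh(mesh, mask, face_rule = "all")
  attr(out, "seed_point") <- seed_pt
  attr(out, "povs") <- povs
  out
}

extraction_result <- function(coi, report, spec, log, qc_render_path = NA_character_) {
  structure(list(coi = coi,
                 alpha_mesh = if (length(report$shapes))
                   alpha_boundary_mesh_multi(report$shapes,
                                             paste0(spec$cavity_name, "_alpha"))
                 else NULL,
                 report = report, qc_render_path = qc_render_path, log = log),
            class = "extraction_result")
}

alpha_boundary_mesh_multi <- function(shapes, name) {
  merge_meshes(lapply(shapes, alpha_boundary_mesh), name = name)
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("extraction_result: COI %d faces; ", if (is.null(x$coi)) 0L else n_faces(x$coi)))
  print(x$report)
  invisible(x)
}

# empty report for the legitimate "no sinus" outcome
zero_volume_report <- function(alpha, spacing) {
  structure(list(volume_voxel_cm3 = 0, volume_tetra_cm3 = 0,
                 alpha = alpha %||% NA_real_, spacing = spacing %||% NA_real_,
                 n_cells = 0L, per_cell_volumes = numeric(), shapes = list()),
            class = "volume_report")
}

spec_alpha <- function(spec, coi) {
  a <- spec$alpha %||% default_alpha(coi)
  a * spec$param2
}

#' Run extraction Mode 1 (cut + enclosed cavity)
#'
#' Applies the spec's cutting sequence, extracts the enclosed cavity wall
#' with [extract_enclosed_cavity()], and measures it with [icv()]. Used for
#' the nasal cavity (5 planes) and each maxillary sinus (6 planes).
#'
#' @param mesh a [trimesh()] of the whole bone.
#' @param lms a [landmark_config()].
#' @param spec a [mode_spec()] with `mode = 1`.
#' @return an `extraction_result`.
#' @export
run_mode1 <- function(mesh, lms, spec) {
  stopifnot(inherits(spec, "mode_spec"))
  if (spec$mode != 1L) abort_cavex("spec is not mode 1", "cavex_error_spec")
  validate_spec_labels(spec, lms)
  log <- list()
  step <- function(what, ...) log[[length(log) + 1L]] <<- c(list(step = what), list(...))
  cut <- apply_cut_sequence(mesh, resolve_cuts(spec$cuts, lms))
  step("cut", n_cuts = length(spec$cuts), n_faces = n_faces(cut))
  coi <- tryCatch(
    extract_enclosed_cavity(cut, param1 = spec$param1, seed = spec_seed(spec)),
    cavex_error_no_cavity = function(e) {
      abort_cavex(sprintf("[%s] %s", spec$cavity_name, conditionMessage(e)),
                  "cavex_error_no_cavity")
    })
  coi$name <- paste0(spec$cavity_name, "_coi")
  step("extract", n_faces = n_faces(coi),
       seed_point = attr(coi, "seed_point"))
  report <- icv(coi, alpha = spec_alpha(spec, coi), spacing = spec$spacing,
                multiple = FALSE, seed = spec_seed(spec))
  step("icv", alpha = report$alpha, volume_tetra_cm3 = report$volume_tetra_cm3)
  extraction_result(coi, report, spec, log)
}

#' Run extraction Mode 2 (single POV)
#'
#' The barycentre of the three `pov_labels` landmarks is the point of view;
#' the surface visible from it is the cavity of interest. No cutting. Used
#' for the orbits and the edentulous palate.
#'
#' @inheritParams run_mode1
#' @param mesh_is_cut internal: mesh already carries the mode-3 alveolar cut.
#' @return an `extraction_result`.
#' @export
run_mode2 <- function(mesh, lms, spec, mesh_is_cut = FALSE) {
  stopifnot(inherits(spec, "mode_spec"))
  if (spec$mode != 2L && !mesh_is_cut) {
    abort_cavex("spec is not mode 2", "cavex_error_spec")
  }
  validate_spec_labels(spec, lms)
  log <- list()
  step <- function(what, ...) log[[length(log) + 1L]] <<- c(list(step = what), list(...))
  pov <- colMeans(landmark_position(lms, spec$pov_labels))
  step("pov", pov = pov, labels = spec$pov_labels)
  mask <- visible_from_pov(mesh, pov)
  coi <- tryCatch(
    extract_visible_submesh(mesh, mask, face_rule = "all"),
    cavex_error_pov_outside = function(e) {
      abort_cavex(sprintf(
        "[%s] nothing visible from the POV: it lies outside the cavity; review the landmarks %s",
        spec$cavity_name, paste(spec$pov_labels, collapse = ", ")),
        "cavex_error_pov_outside")
    })
  coi$name <- paste0(spec$cavity_name, "_coi")
  step("extract", n_faces = n_faces(coi))
  report <- icv(coi, alpha = spec_alpha(spec, coi), spacing = spec$spacing,
                multiple = FALSE, seed = spec_seed(spec))
  step("icv", alpha = report$alpha, volume_tetra_cm3 = report$volume_tetra_cm3)
  extraction_result(coi, report, spec, log)
}

#' Run extraction Mode 3 (alveolar cut + POV)
#'
#' Removes the upper teeth with the single alveolar-limit plane, then
#' proceeds exactly as Mode 2. Used for the upper oral cavity when teeth
#' are present.
#'
#' @inheritParams run_mode1
#' @return an `extraction_result`.
#' @export
run_mode3 <- function(mesh, lms, spec) {
  stopifnot(inherits(spec, "mode_spec"))
  if (spec$mode != 3L) abort_cavex("spec is not mode 3", "cavex_error_spec")
  validate_spec_labels(spec, lms)
  cut <- cut_mesh_by_plane(mesh, resolve_cuts(list(spec$alveolar_cut), lms)[[1]])
  res <- run_mode2(cut, lms, spec, mesh_is_cut = TRUE)
  res$log <- c(list(list(step = "alveolar_cut", n_faces = n_faces(cut))), res$log)
  res
}

#' Run extraction Mode 4 (slab + scanner emulation)
#'
#' Two cuts isolate the bone slab; multi-viewpoint visibility separates its
#' external surface from internal (pneumatised) cells; the cells are
#' measured all together (`multiple = TRUE`) or only the biggest. An empty
#' internal set yields a zero-volume report with a warning — a valid
#' anatomical outcome (unpneumatised frontal bone in infants).
#'
#' @inheritParams run_mode1
#' @param n_views,min_faces see [scanner_visibility()] and
#'   [internal_surfaces()].
#' @return an `extraction_result`.
#' @export
run_mode4 <- function(mesh, lms, spec, n_views = 642L, min_faces = 50L) {
  stopifnot(inherits(spec, "mode_spec"))
  if (spec$mode != 4L) abort_cavex("spec is not mode 4", "cavex_error_spec")
  validate_spec_labels(spec, lms)
  log <- list()
  step <- function(what, ...) log[[length(log) + 1L]] <<- c(list(step = what), list(...))
  cut <- apply_cut_sequence(mesh, resolve_cuts(spec$cuts, lms))
  step("cut", n_cuts = 2L, n_faces = n_faces(cut))
  mask <- scanner_visibility(cut, n_views = n_views)
  step("scan", n_views = nrow(attr(mask, "povs")), n_invisible = sum(!mask))
  cells <- internal_surfaces(cut, mask, min_faces = min_faces)
  if (length(cells) == 0L) {
    warn_cavex(sprintf("[%s] no internal cell found: reporting zero volume",
                       spec$cavity_name), "cavex_warning_no_sinus")
    step("cells", n_cells = 0L)
    return(extraction_result(NULL, zero_volume_report(spec$alpha, spec$spacing),
                             spec, log))
  }
  if (!spec$multiple) cells <- cells[1]
  coi <- merge_meshes(cells, name = paste0(spec$cavity_name, "_coi"))
  step("cells", n_cells = length(cells), n_faces = n_faces(coi))
  report <- icv(coi, alpha = spec_alpha(spec, coi), spacing = spec$spacing,
                multiple = spec$multiple, seed = spec_seed(spec))
  step("icv", alpha = report$alpha, volume_tetra_cm3 = report$volume_tetra_cm3)
  extraction_result(coi, report, spec, log)
}

#' Run the full extraction protocol
#'
#' Decimates the mesh once (500,000-triangle default), runs every
#' [mode_spec()] against it, optionally writes the COI and alpha-shape
#' meshes (`<cavity>_coi.ply`, `<cavity>_alpha.ply`), a QC render and a
#' cumulative `results.csv` into `outdir`. Per-spec failures are collected
#' and reported; the run continues.
#'
#' @param mesh a [trimesh()].
#' @param lms a [landmark_config()].
#' @param specs list of [mode_spec()] objects.
#' @param outdir output directory, or `NULL` to skip all file output.
#' @param interactive_export ask before writing meshes (interactive
#'   sessions only); in batch use files are always written.
#' @param decimation_target triangle budget for the initial decimation.
#' @return list with `results` (named list of `extraction_result`),
#'   `failures` (named list of error conditions), `results_table`
#'   (data frame, one row per successful cavity).
#' @export
run_icex <- function(mesh, lms, specs, outdir = NULL, interactive_export = FALSE,
                     decimation_target = 500000L) {
  validate_trimesh(mesh)
  if (inherits(specs, "mode_spec")) specs <- list(specs)
  for (s in specs) validate_spec_labels(s, lms)
  mesh <- decimate_mesh(mesh, decimation_target)
  results <- list()
  failures <- list()
  rows <- list()
  for (s in specs) {
    res <- tryCatch(
      switch(s$mode, run_mode1(mesh, lms, s), run_mode2(mesh, lms, s),
             run_mode3(mesh, lms, s), run_mode4(mesh, lms, s)),
      cavex_error = function(e) e)
    if (inherits(res, "cavex_error")) {
      failures[[s$cavity_name]] <- res
      next
    }
    results[[s$cavity_name]] <- res
    rows[[s$cavity_name]] <- data.frame(
      specimen = mesh$name, cavity = s$cavity_name, mode = s$mode,
      alpha = res$report$alpha, spacing = res$report$spacing,
      n_cells = res$report$n_cells,
      volume_voxel_cm3 = res$report$volume_voxel_cm3,
      volume_tetra_cm3 = res$report$volume_tetra_cm3,
      stringsAsFactors = FALSE)
    if (!is.null(outdir)) {
      do_export <- TRUE
      if (interactive_export && interactive()) {
        ans <- readline(sprintf("export meshes for '%s'? (y/n) ", s$cavity_name))
        do_export <- tolower(trimws(ans)) %in% c("y", "yes")
      }
      if (do_export) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        if (!is.null(res$coi)) {
          save_mesh(res$coi, file.path(outdir, paste0(s$cavity_name, "_coi.ply")))
        }
        if (!is.null(res$alpha_mesh)) {
          save_mesh(res$alpha_mesh, file.path(outdir, paste0(s$cavity_name, "_alpha.ply")))
        }
        qc <- file.path(outdir, paste0(s$cavity_name, "_qc.png"))
        try(qc_render(res$coi, res$alpha_mesh, qc), silent = TRUE)
        results[[s$cavity_name]]$qc_render_path <- qc
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame()
  if (!is.null(outdir) && length(rows)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(outdir, "results.csv")
    write.csv(format(tab, digits = 10), csv, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      lapply(results, function(r) r$report[c("volume_voxel_cm3", "volume_tetra_cm3",
                                             "alpha", "spacing", "n_cells",
                                             "per_cell_volumes")]),
      file.path(outdir, "results.json"), auto_unbox = TRUE, digits = NA)
  }
  if (length(failures)) {
    message(sprintf("run_icex: %d of %d spec(s) failed: %s",
                    length(failures), length(specs),
                    paste(names(failures), collapse = ", ")))
  }
  list(results = results, failures = failures, results_table = tab)
}

# three orthographic projections of COI vertices + alpha boundary edges
qc_render <- function(coi, alpha_mesh, path) {
  grDevices::png(path, width = 1200, height = 420)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(2, 2, 2, 0.5))
  planes <- list(c(1, 2), c(1, 3), c(2, 3))
  names(planes) <- c("xy", "xz", "yz")
  for (nm in names(planes)) {
    ax <- planes[[nm]]
    graphics::plot(coi$vertices[, ax], pch = ".", col = "grey40", asp = 1,
                   main = nm, xlab = "", ylab = "")
    if (!is.null(alpha_mesh)) {
      f <- alpha_mesh$faces
      v <- alpha_mesh$vertices
      graphics::segments(v[f[, 1], ax[1]], v[f[, 1], ax[2]],
                         v[f[, 2], ax[1]], v[f[, 2], ax[2]],
                         col = grDevices::adjustcolor("red", 0.15))
    }
  }
  invisible(path)
}
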