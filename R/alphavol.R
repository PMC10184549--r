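# The volume kernel: 3D alpha-shape of the cavity-of-interest (COI) vertex
# cloud and volume estimation by empty-voxel counting, with an exact
# tetrahedron-sum cross-check.

#' Build a 3D alpha-shape
#'
#' Delaunay-tetrahedralises the point cloud and keeps the tetrahedra with
#' circumradius `<= alpha`. `alpha = Inf` keeps everything, so the complex
#' volume equals the convex-hull volume; smaller alpha values fit the
#' envelope more tightly to the cloud. Near-degenerate (sliver) tetrahedra
#' are assigned infinite circumradius and are therefore dropped for any
#' finite alpha.
#'
#' @param points numeric matrix (`n x 3`), mm; at least 4 affinely
#'   independent points.
#' @param alpha radius threshold in mm (> 0, may be `Inf`).
#' @param seed integer; fixes the insertion order of the triangulation.
#' @return object of class `alpha_shape`: list with `points`, `tetrahedra`
#'   (kept, 1-based), `circumradii`, `alpha`, `boundary_faces`.
#' @export
build_alpha_shape <- function(points, alpha, seed = 1L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    abort_cavex("alpha must be a single positive length (mm)", "cavex_error_alpha")
  }
  pts <- unique(points)
  if (nrow(pts) < 4) {
    abort_cavex("alpha-shape needs at least 4 distinct points", "cavex_error_degenerate")
  }
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] <= 1e-9 * max(sv[1], 1e-300)) {
    abort_cavex("degenerate (coplanar) point cloud", "cavex_error_degenerate")
  }
  tets <- .C_delaunay3d(pts, as.integer(seed)) + 1L
  radii <- .C_circumradii(pts, tets - 1L)
  keep <- if (is.infinite(alpha)) rep(TRUE, nrow(tets)) else radii <= alpha
  if (!any(keep)) {
    workable <- min(radii[is.finite(radii)])
    abort_cavex(
      sprintf("alpha = %g keeps no tetrahedron; smallest workable alpha is %.6g mm",
              alpha, workable),
      "cavex_error_empty_complex", smallest_alpha = workable
    )
  }
  kept <- tets[keep, , drop = FALSE]
  structure(list(points = pts, tetrahedra = kept,
                 circumradii = radii[keep], alpha = alpha,
                 boundary_faces = complex_boundary(kept)),
            class = "alpha_shape")
}

# faces belonging to exactly one kept tetrahedron (1-based vertex triples)
complex_boundary <- function(tets) {
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  s1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  s3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  s2 <- faces[, 1] + faces[, 2] + faces[, 3] - s1 - s3
  nv <- max(s3) + 1
  key <- (as.numeric(s1) * nv + s2) * nv + s3
  cnt <- ave(key, key, FUN = length)
  faces[cnt == 1, , drop = FALSE]
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf("alpha_shape: %d points, %d tetrahedra kept (alpha = %g mm), %d boundary faces\n",
              nrow(x$points), nrow(x$tetrahedra), x$alpha, nrow(x$boundary_faces)))
  invisible(x)
}

# boundary of the complex as a trimesh (for export / QC)
alpha_boundary_mesh <- function(shape, name = "alpha") {
  trimesh(shape$points, shape$boundary_faces, name = name, validate = FALSE)
}

#' Point-in-complex test
#'
#' `TRUE` where the query point lies in any kept tetrahedron (barycentric
#' tolerance `-1e-12` relative, so boundary points are inside).
#'
#' @param shape an [build_alpha_shape()] result.
#' @param p numeric length-3 point, or an `n x 3` matrix of points.
#' @return logical vector.
#' @export
point_in_complex <- function(shape, p) {
  p <- matrix(as.numeric(p), ncol = 3)
  .C_points_in_tets(shape$points, shape$tetrahedra - 1L, p)
}

#' Volume by empty-voxel counting
#'
#' Lays a voxel grid of the given spacing over the complex (plus one
#' spacing of margin) and counts the voxels whose centre is inside the
#' complex AND whose cube contains no vertex of the surrounding COI cloud —
#' the "empty voxels" reading of cavity volume. Vertex-to-voxel assignment
#' uses the half-open convention `[low, high)` per axis so the cubes
#' partition space deterministically.
#'
#' @param shape an [build_alpha_shape()] result.
#' @param coi_vertices the COI vertex cloud whose presence empties a voxel
#'   (usually `shape$points`).
#' @param spacing voxel edge length, mm; must be at most a tenth of the
#'   complex bounding-box diagonal.
#' @param voxel_budget refuse grids larger than this many voxels.
#' @return list with `volume_cm3` and `grid` (origin, spacing, dims,
#'   `inside_alpha`, `contains_vertex` as logical arrays).
#' @export
volume_by_voxels <- function(shape, coi_vertices = shape$points, spacing,
                             voxel_budget = 5e8) {
  bb <- apply(shape$points[unique(as.vector(shape$tetrahedra)), , drop = FALSE],
              2, range)
  diag_len <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  if (!is.numeric(spacing) || spacing <= 0 || spacing > diag_len / 10) {
    abort_cavex(
      sprintf("spacing must be in (0, %.4g] mm (bounding-box diagonal / 10)",
              diag_len / 10),
      "cavex_error_spacing"
    )
  }
  origin <- bb[1, ] - spacing
  dims <- as.integer(ceiling((bb[2, ] + spacing - origin) / spacing))
  if (prod(as.numeric(dims)) > voxel_budget) {
    abort_cavex(
      sprintf("voxel grid %s exceeds the budget of %g voxels; increase spacing",
              paste(dims, collapse = "x"), voxel_budget),
      "cavex_error_voxel_budget"
    )
  }
  vox <- .C_voxelize(shape$points, shape$tetrahedra - 1L,
                     as.matrix(coi_vertices), origin, spacing, dims)
  n_empty <- sum(vox$inside & !vox$hasvert)
  list(volume_cm3 = n_empty * spacing^3 / 1000,
       grid = list(origin = origin, spacing = spacing, dims = dims,
                   inside_alpha = vox$inside, contains_vertex = vox$hasvert))
}

#' Volume by tetrahedron sum
#'
#' Exact volume of the kept complex, `sum |tet| / 1000` in cm^3. The
#' cross-check oracle for the voxel estimate.
#'
#' @param shape an [build_alpha_shape()] result.
#' @return volume in cm^3.
#' @export
volume_by_tetra <- function(shape) {
  if (nrow(shape$tetrahedra) == 0L) {
    abort_cavex("empty complex", "cavex_error_empty_complex")
  }
  sum(.C_tet_volumes(shape$points, shape$tetrahedra - 1L)) / 1000
}

#' Convex-hull volume of a point cloud
#'
#' Quickhull volume in mm^3; the independent oracle for the
#' `alpha -> Inf` limit of [build_alpha_shape()].
#'
#' @param points numeric matrix (`n x 3`), mm.
#' @return volume in mm^3.
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .C_convex_hull(points)$volume
}

# data-driven default: twice the 95th percentile of COI edge lengths
default_alpha <- function(mesh) {
  2 * as.numeric(quantile(edge_lengths(mesh), 0.95, names = FALSE))
}

#' Internal cavity volume (Icv kernel)
#'
#' Builds the alpha-shape around the cavity-of-interest mesh and reports its
#' volume both by empty-voxel counting and by the exact tetrahedron sum
#' (cm^3). With `multiple = TRUE` each connected component of the COI is
#' measured separately (multi-cell sinuses) and the totals are sums over
#' cells; with `multiple = FALSE` a single alpha-shape is built over all COI
#' vertices.
#'
#' @param coi the cavity-of-interest [trimesh()] (typically an extraction
#'   result, or a mesh re-loaded after editing elsewhere).
#' @param alpha alpha radius in mm; `NULL` uses twice the 95th percentile of
#'   the COI edge lengths. Override per cavity for tight fits.
#' @param spacing voxel spacing in mm; `NULL` uses `alpha / 20` (clamped to
#'   the voxel budget).
#' @param multiple measure connected components separately.
#' @param seed integer; deterministic triangulation order.
#' @return object of class `volume_report`: `volume_voxel_cm3`,
#'   `volume_tetra_cm3`, `alpha`, `spacing`, `n_cells`, `per_cell_volumes`
#'   (tetra cm^3 per cell), `shapes` (the per-cell alpha-shapes).
#' @export
icv <- function(coi, alpha = NULL, spacing = NULL, multiple = FALSE, seed = 1L) {
  validate_trimesh(coi)
  if (is.null(alpha)) alpha <- default_alpha(coi)
  if (!is.numeric(alpha) || alpha <= 0) {
    abort_cavex("alpha must be positive", "cavex_error_alpha")
  }
  if (is.null(spacing)) spacing <- alpha / 20
  parts <- if (multiple) connected_components(coi) else list(coi)
  vol_vox <- 0
  vol_tet <- 0
  per_cell <- numeric(length(parts))
  shapes <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    shape <- tryCatch(
      build_alpha_shape(parts[[i]]$vertices, alpha, seed = seed),
      cavex_error = function(e) {
        abort_cavex(sprintf("component %d: %s", i, conditionMessage(e)),
                    class(e)[1], component = i)
      })
    vt <- volume_by_tetra(shape)
    sp <- min(spacing, bbox_diagonal(parts[[i]]) / 10)
    vv <- volume_by_voxels(shape, parts[[i]]$vertices, sp)$volume_cm3
    per_cell[i] <- vt
    vol_tet <- vol_tet + vt
    vol_vox <- vol_vox + vv
    shapes[[i]] <- shape
  }
  structure(list(volume_voxel_cm3 = vol_vox, volume_tetra_cm3 = vol_tet,
                 alpha = alpha, spacing = spacing,
                 n_cells = length(parts), per_cell_volumes = per_cell,
                 shapes = shapes),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("volume_report: %.4f cm^3 (voxel) / %.4f cm^3 (tetra), alpha %.3g mm, spacing %.3g mm, %d cell(s)\n",
              x$volume_voxel_cm3, x$volume_tetra_cm3, x$alpha, x$spacing, x$n_cells))
  if (x$n_cells > 1) {
    cat("  per-cell tetra volumes (cm^3):",
        paste(sprintf("%.4f", x$per_cell_volumes), collapse = ", "), "\n")
  }
  invisible(x)
}
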