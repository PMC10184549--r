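# Line-of-sight surface selection: single-POV visible-surface extraction
# (the orbit/palate pathway) and multi-viewpoint laser-scanner emulation
# whose complement yields internal surfaces (the sinus pathway).

#' Vertex visibility from a point of view
#'
#' Marks each vertex visible if and only if the open segment from the POV to
#' the vertex (shortened by `offset_eps` at both ends) intersects no
#' triangle of the mesh; triangles incident to the target vertex are
#' excluded from the occlusion test. Ties (a ray through an edge) count as
#' occlusion. `method = "bvh"` uses a bounding-volume hierarchy;
#' `method = "brute"` is the all-pairs oracle with the identical
#' per-triangle predicate, kept for verification.
#'
#' @param mesh a [trimesh()].
#' @param pov numeric length-3 point of view, mm.
#' @param offset_eps segment shortening at both ends, mm; avoids self-hit
#'   false occlusion on mm-scale anatomy without a watertight assumption.
#' @param method `"bvh"` (accelerated) or `"brute"` (oracle).
#' @return object of class `visibility_mask`: logical vector over vertices
#'   with attribute `povs` (the POV matrix).
#' @export
visible_from_pov <- function(mesh, pov, offset_eps = 1e-4, method = c("bvh", "brute")) {
  method <- match.arg(method)
  validate_trimesh(mesh)
  pov <- matrix(as.numeric(pov), ncol = 3)
  if (!all(is.finite(pov))) {
    abort_cavex("POV must be finite", "cavex_error_pov")
  }
  vis <- if (method == "bvh") {
    .C_visibility(mesh$vertices, mesh$faces - 1L, pov, offset_eps, TRUE)
  } else {
    .C_visibility_brute(mesh$vertices, mesh$faces - 1L, pov, offset_eps)
  }
  structure(as.logical(vis), povs = pov, class = "visibility_mask")
}

# visibility from any of several POVs (early exit per vertex)
visible_from_povs <- function(mesh, povs, offset_eps = 1e-4) {
  povs <- matrix(as.numeric(povs), ncol = 3)
  vis <- .C_visibility(mesh$vertices, mesh$faces - 1L, povs, offset_eps, TRUE)
  structure(as.logical(vis), povs = povs, class = "visibility_mask")
}

#' Extract the sub-mesh selected by a visibility mask
#'
#' Keeps faces according to `face_rule`: `"all"` (every corner visible; the
#' conservative default that avoids bleeding through cavity ostia), `"any"`,
#' or `"majority"` (at least two corners, for heavily decimated meshes).
#' Unreferenced vertices are dropped.
#'
#' @param mesh a [trimesh()].
#' @param mask a `visibility_mask` from [visible_from_pov()].
#' @param face_rule `"all"`, `"any"` or `"majority"`.
#' @return the visible [trimesh()].
#' @export
extract_visible_submesh <- function(mesh, mask, face_rule = c("all", "any", "majority")) {
  face_rule <- match.arg(face_rule)
  if (length(mask) != nrow(mesh$vertices)) {
    abort_cavex("mask length does not match mesh vertex count", "cavex_error_mask")
  }
  vis <- as.logical(mask)
  cnt <- vis[mesh$faces[, 1]] + vis[mesh$faces[, 2]] + vis[mesh$faces[, 3]]
  keep <- switch(face_rule, all = cnt == 3L, any = cnt >= 1L, majority = cnt >= 2L)
  if (!any(keep)) {
    abort_cavex("no visible faces: the POV lies outside the cavity",
                "cavex_error_pov_outside")
  }
  submesh(mesh, which(keep), name = mesh$name)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to the sphere: 12, 42, 162, 642, 2562...
#' vertices for levels 0, 1, 2, 3, 4. Used for scanner viewpoints, phantom
#' shells and decimation tests.
#'
#' @param level subdivision level (each level quadruples the face count).
#' @param radius sphere radius, mm.
#' @param center sphere centre.
#' @return a [trimesh()] with outward-oriented faces.
#' @export
icosphere <- function(level = 3L, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, t, 0, 1, t, 0, -1, -t, 0, 1, -t, 0,
                0, -1, t, 0, 1, t, 0, -1, -t, 0, 1, -t,
                t, 0, -1, t, 0, 1, -t, 0, -1, -t, 0, 1),
              ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
                2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
                4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
                5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2),
              ncol = 3, byrow = TRUE)
  for (i in seq_len(level)) {
    nv <- nrow(v)
    mids <- new.env(hash = TRUE)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- mids[[key]]
      if (!is.null(got)) return(got)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- matrix(p, ncol = 3)
      nv <<- nv + 1L
      mids[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (j in seq_len(nrow(f))) {
      a <- f[j, 1]; b <- f[j, 2]; cc <- f[j, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * j - 3, ] <- c(a, ab, ca)
      newf[4 * j - 2, ] <- c(b, bc, ab)
      newf[4 * j - 1, ] <- c(cc, ca, bc)
      newf[4 * j, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  trimesh(sweep(v * radius, 2, -as.numeric(center)), f,
          name = sprintf("icosphere%d", level), validate = FALSE)
}

#' Multi-viewpoint (laser-scanner emulation) visibility
#'
#' Surrounds the mesh with points of view placed at the vertices of a
#' subdivided icosahedron (uniform on the sphere) of radius
#' `radius_factor x` the bounding-sphere radius about the mesh centroid,
#' and marks a vertex visible if it is seen from at least one POV. The
#' invisible complement is the internal (e.g. pneumatised) surface.
#'
#' @param mesh a [trimesh()].
#' @param n_views requested number of viewpoints; rounded up to the nearest
#'   icosahedral subdivision size (12, 42, 162, 642, 2562).
#' @param radius_factor scan-sphere radius as a multiple of the
#'   bounding-sphere radius.
#' @param offset_eps see [visible_from_pov()].
#' @return a `visibility_mask` with attribute `povs`.
#' @export
scanner_visibility <- function(mesh, n_views = 642L, radius_factor = 1.5,
                               offset_eps = 1e-4) {
  validate_trimesh(mesh)
  sizes <- c(12L, 42L, 162L, 642L, 2562L)
  level <- which(sizes >= n_views)[1]
  if (is.na(level)) level <- length(sizes)
  ctr <- mesh_centroid(mesh)
  r <- sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
  povs <- icosphere(level - 1L, radius = radius_factor * r, center = ctr)$vertices
  visible_from_povs(mesh, povs, offset_eps = offset_eps)
}

#' Internal surfaces (invisible components)
#'
#' Connected components of the sub-mesh invisible from every scanner
#' viewpoint, with at least `min_faces` faces, sorted by descending volume
#' of their alpha-shape closure — so the caller can take the biggest
#' pneumatised cell or all of them. An empty list is a valid outcome: a
#' solid bone has no sinus.
#'
#' @param mesh a [trimesh()].
#' @param mask a `visibility_mask` from [scanner_visibility()].
#' @param min_faces drop components smaller than this.
#' @return list of [trimesh()] objects, largest enclosed volume first.
#' @export
internal_surfaces <- function(mesh, mask, min_faces = 50L) {
  if (length(mask) != nrow(mesh$vertices)) {
    abort_cavex("mask length does not match mesh vertex count", "cavex_error_mask")
  }
  inv <- !as.logical(mask)
  cnt <- inv[mesh$faces[, 1]] + inv[mesh$faces[, 2]] + inv[mesh$faces[, 3]]
  keep <- cnt == 3L
  if (!any(keep)) return(list())
  inv_mesh <- submesh(mesh, which(keep), name = sprintf("%s_internal", mesh$name))
  comps <- connected_components(inv_mesh)
  comps <- Filter(function(m) n_faces(m) >= min_faces, comps)
  if (length(comps) == 0L) return(list())
  vols <- vapply(comps, function(m) hull_closure_volume(m$vertices), 0)
  comps[order(-vols)]
}

# convex-hull volume of a vertex cloud (mm^3); cheap closure-volume proxy
# used only for ordering components
hull_closure_volume <- function(points) {
  if (nrow(points) < 4) return(0)
  out <- tryCatch(.C_convex_hull(points), error = function(e) NULL)
  if (is.null(out)) 0 else out$volume
}
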