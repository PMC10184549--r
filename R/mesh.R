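# The triangle-mesh container and exact geometric utilities on it.

#' Triangle surface mesh
#'
#' Constructs a `trimesh`: a triangle surface in millimetres, the substrate of
#' every operation in the package. Vertices are an `n x 3` numeric matrix and
#' faces an `m x 3` integer matrix of 1-based vertex indices. Orientation
#' consistency is not assumed (cut meshes are open and may be non-manifold);
#' operations that need a closed, consistently oriented surface (such as
#' [signed_volume()]) check for it explicitly.
#'
#' @param vertices numeric matrix (`n x 3`), coordinates in mm.
#' @param faces integer matrix (`m x 3`), 1-based vertex indices.
#' @param name optional text label carried through extractions and reports.
#' @param validate check invariants (finite coordinates, indices in range,
#'   no degenerate face). Set to `FALSE` only on internally generated data.
#' @return an object of class `trimesh` with elements `vertices`, `faces`,
#'   `name`.
#' @export
trimesh <- function(vertices, faces, name = "mesh", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) {
    abort_cavex("vertices must be an n x 3 matrix", "cavex_error_mesh")
  }
  if (ncol(faces) != 3L) {
    abort_cavex("faces must be an m x 3 matrix", "cavex_error_mesh")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces, name = as.character(name)[1]),
                 class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

validate_trimesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) {
    abort_cavex("mesh has zero faces", "cavex_error_empty_mesh")
  }
  if (!all(is.finite(v))) {
    abort_cavex("mesh has non-finite vertex coordinates", "cavex_error_mesh")
  }
  if (nrow(f) > 0L) {
    rng <- range(f)
    if (rng[1] < 1L || rng[2] > nrow(v)) {
      abort_cavex(
        sprintf("face indices out of range [1, %d] (found %d..%d)",
                nrow(v), rng[1], rng[2]),
        "cavex_error_mesh_index"
      )
    }
    degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(degen)) {
      abort_cavex(
        sprintf("%d degenerate face(s) with repeated vertex indices (first at row %d)",
                sum(degen), which(degen)[1]),
        "cavex_error_mesh_degenerate"
      )
    }
  }
  invisible(mesh)
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("trimesh '%s': %d vertices, %d faces\n", x$name,
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

n_faces <- function(mesh) nrow(mesh$faces)
n_vertices <- function(mesh) nrow(mesh$vertices)

mesh_bbox <- function(mesh) apply(mesh$vertices, 2, range)

bbox_diagonal <- function(mesh) {
  bb <- mesh_bbox(mesh)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Total surface area of a mesh
#'
#' Exact sum of triangle areas (mm^2), used by the cut-conservation checks.
#'
#' @param mesh a [trimesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

edge_lengths <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume `sum(det(v0, v1, v2) / 6)` in mm^3, positive for
#' outward orientation. The mesh must be closed and consistently oriented
#' (every directed edge matched by its reverse); open or non-manifold input
#' is an error. This is the package's exact volume oracle.
#'
#' @param mesh a [trimesh()].
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  validate_trimesh(mesh)
  st <- .C_edge_status(mesh$faces - 1L)
  if (!st$closed_oriented) {
    abort_cavex(
      sprintf("mesh is not closed and consistently oriented (%d boundary, %d non-manifold edges)",
              st$n_boundary_edges, st$n_nonmanifold_edges),
      "cavex_error_orientation"
    )
  }
  .C_signed_volume(mesh$vertices, mesh$faces - 1L)
}

is_closed_mesh <- function(mesh) {
  isTRUE(.C_edge_status(mesh$faces - 1L)$closed_oriented)
}

#' Connected components of a mesh
#'
#' Partitions faces by shared-vertex adjacency and returns one sub-mesh per
#' component, sorted by descending face count. Needed by the multi-cell
#' sinus pathway, where one invisible surface may hold several pneumatised
#' cells.
#'
#' @param mesh a [trimesh()].
#' @return list of [trimesh()] objects, largest (by face count) first.
#' @export
connected_components <- function(mesh) {
  if (n_faces(mesh) == 0L) return(list())
  lab <- .C_face_components(mesh$faces - 1L, nrow(mesh$vertices))
  groups <- split(seq_len(n_faces(mesh)), lab)
  groups <- groups[order(-lengths(groups))]
  lapply(seq_along(groups), function(i) {
    submesh(mesh, groups[[i]], name = sprintf("%s_comp%d", mesh$name, i))
  })
}

# faces: integer vector of face row indices to keep; drops unreferenced vertices
submesh <- function(mesh, faces, name = mesh$name) {
  f <- mesh$faces[faces, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(remap[f], ncol = 3), name = name, validate = FALSE)
}

#' Merge coincident vertices
#'
#' Welds vertices closer than `tol` (by coordinate rounding), dropping faces
#' that become degenerate. STL files store each facet independently, so
#' welding is required before any operation that relies on shared-vertex
#' connectivity; it is deliberately not applied on load because merging
#' changes the voxel "contains a vertex" emptiness tests.
#'
#' @param mesh a [trimesh()].
#' @param tol welding tolerance in mm.
#' @return a [trimesh()] with merged vertices.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(idx[mesh$faces], ncol = 3)
  degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  if (nrow(f) == 0L) {
    abort_cavex("welding left no faces", "cavex_error_empty_mesh")
  }
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(newv))
  remap[used] <- seq_along(used)
  trimesh(newv[used, , drop = FALSE], matrix(remap[f], ncol = 3),
          name = mesh$name, validate = FALSE)
}

# rigid-motion helper used by tests and phantoms
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  trimesh(sweep(mesh$vertices %*% t(rotation), 2, -translation),
          mesh$faces, name = mesh$name, validate = FALSE)
}

# concatenate meshes into one (vertex indices offset); no welding
merge_meshes <- function(..., name = "merged") {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "trimesh")) {
    ms <- ms[[1]]
  }
  vs <- lapply(ms, `[[`, "vertices")
  off <- cumsum(c(0L, vapply(vs, nrow, 1L)))
  fs <- mapply(function(m, o) m$faces + o, ms, off[-length(off)], SIMPLIFY = FALSE)
  trimesh(do.call(rbind, vs), do.call(rbind, fs), name = name, validate = FALSE)
}
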