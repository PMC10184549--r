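# Cutting planes from landmark triplets and half-space mesh cutting.

#' Plane through three points
#'
#' Builds the cutting plane through three non-collinear landmarks. The
#' normal is `normalize((b - a) x (c - a))` and the origin is `a`, so the
#' operand order fixes the orientation; which half-space is retained is
#' chosen separately via [cut_spec()].
#'
#' @param a,b,c 3D points (numeric length-3), mm.
#' @param generators optional character vector of the three landmark labels
#'   the plane came from (carried for logging).
#' @return object of class `plane` with `origin`, `normal`, `generators`.
#' @export
plane_from_landmarks <- function(a, b, c, generators = NULL) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  if (length(a) != 3 || length(b) != 3 || length(c) != 3 ||
      !all(is.finite(c(a, b, c)))) {
    abort_cavex("plane generators must be three finite 3D points",
                "cavex_error_geometry")
  }
  u <- b - a
  v <- c - a
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  area2 <- sqrt(sum(n^2))
  if (area2 / 2 <= 1e-9) {
    gen <- if (is.null(generators)) {
      sprintf("(%s), (%s), (%s)", paste(signif(a, 6), collapse = ","),
              paste(signif(b, 6), collapse = ","), paste(signif(c, 6), collapse = ","))
    } else paste(generators, collapse = ", ")
    abort_cavex(sprintf("collinear plane generators: %s", gen),
                "cavex_error_collinear")
  }
  structure(list(origin = a, normal = n / area2,
                 generators = generators %||% character()),
            class = "plane")
}

# plane from three landmark labels of a configuration
plane_from_labels <- function(lms, labels) {
  p <- landmark_position(lms, labels)
  plane_from_landmarks(p[1, ], p[2, ], p[3, ], generators = labels)
}

#' Cut specification
#'
#' Pairs a [plane_from_landmarks()] plane with the half-space to keep:
#' `keep = "positive"` retains points with `dot(x - origin, normal) >= 0`,
#' `"negative"` the other side. Vertices within 1e-9 mm of the plane are
#' kept on both sides.
#'
#' @param plane a `plane`.
#' @param keep `"positive"` or `"negative"`.
#' @return object of class `cut_spec`.
#' @export
cut_spec <- function(plane, keep = c("positive", "negative")) {
  keep <- match.arg(keep)
  if (!inherits(plane, "plane")) {
    abort_cavex("plane must be a 'plane' object", "cavex_error_geometry")
  }
  structure(list(plane = plane, keep = keep), class = "cut_spec")
}

#' Cut a mesh by a plane
#'
#' Keeps the part of the mesh in the requested half-space. Triangles
#' straddling the plane are split exactly, with the new vertices on the
#' plane (within 1e-6 mm) and welded along the cut, rather than dropped
#' whole — whole-triangle dropping biases cavity openings by up to one
#' triangle size. The result may be open.
#'
#' @param mesh a [trimesh()].
#' @param spec a [cut_spec()].
#' @return the cut [trimesh()].
#' @export
cut_mesh_by_plane <- function(mesh, spec) {
  validate_trimesh(mesh)
  if (!inherits(spec, "cut_spec")) {
    abort_cavex("spec must be a 'cut_spec'", "cavex_error_geometry")
  }
  keep_sign <- if (spec$keep == "positive") 1L else -1L
  res <- .C_cut_mesh(mesh$vertices, mesh$faces - 1L, spec$plane$origin,
                     spec$plane$normal, keep_sign, 1e-9)
  if (nrow(res$faces) == 0L) {
    abort_cavex(
      sprintf("cut by plane [origin %s, normal %s, keep %s] leaves an empty mesh (mis-specified plane?)",
              paste(signif(spec$plane$origin, 4), collapse = ","),
              paste(signif(spec$plane$normal, 4), collapse = ","), spec$keep),
      "cavex_error_empty_cut"
    )
  }
  trimesh(res$vertices, res$faces + 1L, name = mesh$name, validate = FALSE)
}

#' Apply an ordered sequence of cuts
#'
#' Left-fold of [cut_mesh_by_plane()]; the cut order matters for open
#' intermediate results and is recorded in the returned mesh's `cut_log`
#' attribute. An empty intermediate result is reported with the index of
#' the offending cut.
#'
#' @param mesh a [trimesh()].
#' @param specs list of [cut_spec()] objects.
#' @return the cut [trimesh()] with attribute `cut_log`.
#' @export
apply_cut_sequence <- function(mesh, specs) {
  if (length(specs) == 0L) {
    abort_cavex("cut sequence must contain at least one cut", "cavex_error_geometry")
  }
  log <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    mesh <- tryCatch(cut_mesh_by_plane(mesh, specs[[i]]), cavex_error_empty_cut = function(e) {
      abort_cavex(sprintf("cut %d of %d: %s", i, length(specs), conditionMessage(e)),
                  c("cavex_error_empty_cut"), index = i)
    })
    log[[i]] <- list(index = i,
                     origin = specs[[i]]$plane$origin,
                     normal = specs[[i]]$plane$normal,
                     keep = specs[[i]]$keep,
                     generators = specs[[i]]$plane$generators,
                     n_faces_after = n_faces(mesh))
  }
  attr(mesh, "cut_log") <- log
  mesh
}
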