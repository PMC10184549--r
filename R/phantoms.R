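# Deterministic phantom "crania": watertight shell solids containing
# cavities with closed-form volumes, plus auto-placed landmarks and
# ready-made extraction recipes, so every mode and the volume kernel are
# testable end to end with no imaging data.
#
# Construction notes: every face of a phantom is assembled from grid
# patches that sample shared, per-axis break vectors, so adjacent patches
# meet vertex-for-vertex (no T-junctions) and a single weld produces a
# 2-manifold. Openings (orbit socket, palate, tooth sockets) are carried by
# annulus patches between two nested convex loops. Face orientation is not
# tracked during assembly; a final pass orients each component consistently
# and points the outer shell outward and every cavity wall into its void.

# ------------------------------------------------------------------ lattices

# multiples of h covering [lo, hi] plus required breakpoints
lattice_breaks <- function(lo, hi, h, extra = numeric()) {
  g <- seq(ceiling(lo / h) * h, floor(hi / h) * h, by = h)
  sort(unique(c(lo, hi, g[g > lo & g < hi], extra[extra > lo & extra < hi])))
}

# subset of a global break vector spanning [lo, hi]
sub_breaks <- function(breaks, lo, hi) {
  sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
}

# ------------------------------------------------------------------ patches

# quad grid patch: map(u, v) -> c(x, y, z)
patch_grid <- function(us, vs, map) {
  nu <- length(us)
  nv <- length(vs)
  verts <- matrix(NA_real_, nu * nv, 3)
  for (j in seq_len(nv)) {
    for (i in seq_len(nu)) verts[(j - 1) * nu + i, ] <- map(us[i], vs[j])
  }
  ij <- expand.grid(i = seq_len(nu - 1), j = seq_len(nv - 1))
  a <- (ij$j - 1) * nu + ij$i
  faces <- rbind(cbind(a, a + 1L, a + nu + 1L), cbind(a, a + nu + 1L, a + nu))
  trimesh(verts, faces, validate = FALSE)
}

# closed CCW rectangle-boundary loop in 2D param space, on given breaks
rect_loop <- function(x0, x1, y0, y1, xs, ys) {
  xs <- sub_breaks(xs, x0, x1)
  ys <- sub_breaks(ys, y0, y1)
  rbind(cbind(xs[-length(xs)], y0),
        cbind(x1, ys[-length(ys)]),
        cbind(rev(xs)[-length(xs)], y1),
        cbind(x0, rev(ys)[-length(ys)]))
}

circle_loop <- function(cx, cy, r, n = 48L) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# triangulated annulus between two nested convex loops (2D param space),
# walked by merged angle around the inner centre; map lifts to 3D
annulus_patch <- function(outer, inner, map) {
  ctr <- colMeans(inner)
  ao <- atan2(outer[, 2] - ctr[2], outer[, 1] - ctr[1])
  ai <- atan2(inner[, 2] - ctr[2], inner[, 1] - ctr[1])
  outer <- outer[order(ao), , drop = FALSE]
  inner <- inner[order(ai), , drop = FALSE]
  ao <- sort(ao)
  ai <- sort(ai)
  n <- nrow(outer)
  m <- nrow(inner)
  faces <- matrix(0L, n + m, 3)
  io <- 1L
  ii <- 1L
  next_ang <- function(a, i) if (i < length(a)) a[i + 1] else a[1] + 2 * pi
  for (k in seq_len(n + m)) {
    adv_outer <- if (io > n) FALSE else if (ii > m) TRUE else
      next_ang(ao, io) <= next_ang(ai, ii)
    if (adv_outer) {
      faces[k, ] <- c(io, io %% n + 1L, n + (ii - 1L) %% m + 1L)
      io <- io + 1L
    } else {
      faces[k, ] <- c(n + ii %% m + 1L, n + ii, (io - 1L) %% n + 1L)
      ii <- ii + 1L
    }
  }
  pts2 <- rbind(outer, inner)
  verts <- t(apply(pts2, 1, function(p) map(p[1], p[2])))
  trimesh(verts, faces, validate = FALSE)
}

# convex polygon region triangulated as a fan from an interior point
fan_patch <- function(loop2, centre2, map) {
  n <- nrow(loop2)
  verts <- t(apply(rbind(loop2, centre2), 1, function(p) map(p[1], p[2])))
  faces <- cbind(seq_len(n), c(seq_len(n)[-1], 1L), n + 1L)
  trimesh(verts, faces, validate = FALSE)
}

# the six faces of an axis-aligned box as grid patches on given breaks
box_patches <- function(lo, hi, h, skip = character(),
                        xs = NULL, ys = NULL, zs = NULL) {
  xs <- if (is.null(xs)) lattice_breaks(lo[1], hi[1], h) else sub_breaks(xs, lo[1], hi[1])
  ys <- if (is.null(ys)) lattice_breaks(lo[2], hi[2], h) else sub_breaks(ys, lo[2], hi[2])
  zs <- if (is.null(zs)) lattice_breaks(lo[3], hi[3], h) else sub_breaks(zs, lo[3], hi[3])
  ps <- list()
  if (!"zmin" %in% skip) ps$zmin <- patch_grid(xs, ys, function(u, v) c(u, v, lo[3]))
  if (!"zmax" %in% skip) ps$zmax <- patch_grid(xs, ys, function(u, v) c(u, v, hi[3]))
  if (!"ymin" %in% skip) ps$ymin <- patch_grid(xs, zs, function(u, v) c(u, lo[2], v))
  if (!"ymax" %in% skip) ps$ymax <- patch_grid(xs, zs, function(u, v) c(u, hi[2], v))
  if (!"xmin" %in% skip) ps$xmin <- patch_grid(ys, zs, function(u, v) c(lo[1], u, v))
  if (!"xmax" %in% skip) ps$xmax <- patch_grid(ys, zs, function(u, v) c(hi[1], u, v))
  ps
}

# UV hemisphere bowl over a rim circle; rim ring coordinates coincide with
# circle_loop() points of the same n (up to fp) for welding
hemisphere_patch <- function(center3, r, axis_dir, n_az = 48L, n_pol = 10L) {
  w <- axis_dir / sqrt(sum(axis_dir^2))
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  th <- 2 * pi * (seq_len(n_az) - 1) / n_az
  phis <- seq(0, pi / 2, length.out = n_pol + 1L)[-(n_pol + 1L)]
  verts <- matrix(NA_real_, n_az * length(phis) + 1L, 3)
  for (j in seq_along(phis)) {
    rho <- r * cos(phis[j])
    hgt <- r * sin(phis[j])
    for (i in seq_len(n_az)) {
      verts[(j - 1) * n_az + i, ] <- center3 + rho * cos(th[i]) * u +
        rho * sin(th[i]) * v + hgt * w
    }
  }
  pole <- n_az * length(phis) + 1L
  verts[pole, ] <- center3 + r * w
  fl <- list()
  for (j in seq_len(length(phis) - 1L)) {
    i <- seq_len(n_az)
    a <- (j - 1) * n_az + i
    b <- (j - 1) * n_az + i %% n_az + 1L
    cc <- a + n_az
    d <- j * n_az + i %% n_az + 1L
    fl[[j]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  top <- (length(phis) - 1L) * n_az
  i <- seq_len(n_az)
  fl[[length(fl) + 1L]] <- cbind(top + i, top + i %% n_az + 1L, pole)
  trimesh(verts, do.call(rbind, fl), validate = FALSE)
}

# open cylinder between two parallel rim circles (axis +y here)
collar_patch <- function(cx, cz, r, y0, y1, n_az = 48L, n_len = 4L) {
  th <- 2 * pi * (seq_len(n_az) - 1) / n_az
  patch_grid(seq_len(n_az + 1L), seq(y0, y1, length.out = n_len),
             function(i, y) {
               a <- th[(as.integer(i) - 1L) %% n_az + 1L]
               c(cx + r * cos(a), y, cz + r * sin(a))
             })
}

# ------------------------------------------------------- orientation fixing

# orient every component consistently; the largest-|volume| component gets
# outward normals, all others point into their void (outward from the solid)
orient_solid <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  he_face <- rep.int(seq_len(m), 3)
  nv <- nrow(mesh$vertices)
  key <- pmin(he_from, he_to) * (nv + 1) + pmax(he_from, he_to)
  ord <- order(key)
  k_s <- key[ord]
  runs <- rle(k_s)
  if (any(runs$lengths > 2)) {
    abort_cavex("phantom assembly produced a non-manifold edge", "cavex_error_phantom")
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pair_sel <- runs$lengths == 2L
  r1 <- ord[starts[pair_sel]]
  r2 <- ord[ends[pair_sel]]
  f1 <- he_face[r1]
  f2 <- he_face[r2]
  same_dir <- he_from[r1] == he_from[r2]   # same raw traversal direction
  # adjacency lists
  adj_to <- c(f2, f1)
  adj_same <- c(same_dir, same_dir)
  adj_from <- c(f1, f2)
  o <- order(adj_from)
  adj_to <- adj_to[o]
  adj_same <- adj_same[o]
  ptr <- c(0L, cumsum(tabulate(adj_from[o], nbins = m)))
  flipped <- logical(m)
  seen <- logical(m)
  comp_id <- integer(m)
  ncomp <- 0L
  queue <- integer(m)
  for (start in seq_len(m)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    qh <- 1L
    qt <- 1L
    queue[1] <- start
    seen[start] <- TRUE
    comp_id[start] <- ncomp
    while (qh <= qt) {
      fc <- queue[qh]
      qh <- qh + 1L
      rng <- seq.int(ptr[fc] + 1L, ptr[fc + 1L], length.out = ptr[fc + 1L] - ptr[fc])
      for (e in rng) {
        f2_ <- adj_to[e]
        if (seen[f2_]) next
        # consistent orientation needs opposite traversal; same raw
        # direction means exactly one of the pair must be flipped
        flipped[f2_] <- xor(adj_same[e], flipped[fc])
        seen[f2_] <- TRUE
        comp_id[f2_] <- ncomp
        qt <- qt + 1L
        queue[qt] <- f2_
      }
    }
  }
  f[flipped, ] <- f[flipped, c(1, 3, 2)]
  out <- trimesh(mesh$vertices, f, name = mesh$name, validate = FALSE)
  vols <- vapply(seq_len(ncomp), function(ci) {
    .C_signed_volume(out$vertices, out$faces[comp_id == ci, , drop = FALSE] - 1L)
  }, 0)
  outer <- which.max(abs(vols))
  for (ci in seq_len(ncomp)) {
    want_pos <- ci == outer
    if ((vols[ci] > 0) != want_pos) {
      sel <- comp_id == ci
      out$faces[sel, ] <- out$faces[sel, c(1, 3, 2)]
    }
  }
  out
}

finish_phantom <- function(patches, name) {
  orient_solid(weld_vertices(merge_meshes(patches, name = name)))
}

# --------------------------------------------------------------- dome recess

# downward-opening dome: box rise from z = 0 to z = rise over the rectangular
# opening, topped by a half-cylinder vault along y; end caps are convex fans
dome_patches <- function(x0, x1, y0, y1, rise, xs, ys, n_arc = 24L) {
  r <- (x1 - x0) / 2
  cx <- (x0 + x1) / 2
  th <- seq(0, pi, length.out = n_arc + 1L)
  ys_sub <- sub_breaks(ys, y0, y1)
  xs_sub <- sub_breaks(xs, x0, x1)
  vault <- patch_grid(th, ys_sub,
                      function(a, y) c(cx + r * cos(a), y, rise + r * sin(a)))
  zl <- seq(0, rise, length.out = 3L)
  side1 <- patch_grid(ys_sub, zl, function(y, z) c(x0, y, z))
  side2 <- patch_grid(ys_sub, zl, function(y, z) c(x1, y, z))
  cap <- function(yy) {
    # tombstone outline (convex): bottom on the x lattice, sides through the
    # wall z levels, arc matching the vault ring
    loop <- rbind(
      cbind(xs_sub[-length(xs_sub)], 0),
      cbind(x1, zl[-length(zl)]),
      cbind(cx + r * cos(th), rise + r * sin(th))[-(n_arc + 1L), ],
      cbind(x0, rev(zl))[-length(zl), , drop = FALSE]
    )
    fan_patch(loop, c(cx, rise / 2), function(u, v) c(u, yy, v))
  }
  list(vault, side1, side2, cap(y0), cap(y1))
}

# ------------------------------------------------------------- phantom kinds

#' Generate a phantom with known cavity volumes
#'
#' Builds a deterministic, watertight surrogate "cranium" whose cavities
#' have closed-form volumes, together with auto-placed landmarks and
#' ready-made [mode_spec()] recipes:
#' \describe{
#'   \item{`hollow-sphere`}{spherical shell with a concentric spherical
#'     cavity (`4/3 pi r^3`); a mode-1 recipe with one tangent (no-op)
#'     cutting plane exercises the enclosed-cavity pathway.}
#'   \item{`nasal-block`}{cube with an enclosed box cavity and a 5-plane
#'     mode-1 recipe.}
#'   \item{`orbit-fossa`}{block with an open socket (cylindrical collar +
#'     hemisphere) and three rim landmarks for mode 2.}
#'   \item{`palate-dome`}{block with a downward-opening dome (box +
#'     half-cylinder vault), tooth-like protrusions around the opening, an
#'     alveolar plane and POV landmarks for mode 3 (set `teeth = FALSE` for
#'     the edentulous mode-2 variant).}
#'   \item{`two-cell-slab`}{slab enclosing two box cells of different
#'     volumes, with two tangent cutting planes for mode 4.}
#'   \item{`full-suite`}{a 120 x 140 x 100 mm "cranium" carrying all five
#'     cavity types — nasal cavity, right maxillary sinus, right orbit,
#'     palate with teeth, and a two-cell frontal sinus in the cranial-vault
#'     sandwich above an endocranial void — with the full 18-landmark
#'     configuration and one recipe per cavity.}
#' }
#' Cavity walls are offset from every cutting plane by at least 3 mm so
#' plane shifts of the order of observer error cannot graze them. Geometry
#' is fully deterministic: identical arguments give byte-identical output.
#'
#' @param kind phantom kind, see Details.
#' @param mesh_resolution scale factor on mesh density (1 = default; the
#'   shared lattices require the default for exact patch matching, so
#'   changing it is reserved for the sphere-based phantoms).
#' @param teeth `palate-dome` only: include the tooth row (mode 3 recipe)
#'   or not (mode 2 recipe).
#' @param r_out,r_in `hollow-sphere` radii (mm).
#' @param seed stored in the bundle for provenance; generation itself is
#'   deterministic.
#' @return a `phantom_bundle`: list with `mesh` ([trimesh()]), `landmarks`
#'   ([landmark_config()]), `truth` (named list, analytic volumes in cm^3),
#'   `specs` (named list of [mode_spec()]), `kind`, `seed`.
#' @export
make_phantom <- function(kind = c("hollow-sphere", "nasal-block", "orbit-fossa",
                                  "palate-dome", "two-cell-slab", "full-suite"),
                         mesh_resolution = 1, teeth = TRUE,
                         r_out = 40, r_in = 20, seed = 1L) {
  kind <- match.arg(kind)
  if (mesh_resolution <= 0) {
    abort_cavex("mesh_resolution must be positive", "cavex_error_phantom")
  }
  b <- switch(kind,
    "hollow-sphere" = phantom_hollow_sphere(mesh_resolution, r_out, r_in),
    "nasal-block" = phantom_nasal_block(mesh_resolution),
    "orbit-fossa" = phantom_orbit_fossa(mesh_resolution),
    "palate-dome" = phantom_palate_dome(mesh_resolution, teeth),
    "two-cell-slab" = phantom_two_cell_slab(mesh_resolution),
    "full-suite" = phantom_full_suite(mesh_resolution)
  )
  b$kind <- kind
  b$seed <- as.integer(seed)
  class(b) <- "phantom_bundle"
  b
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("phantom_bundle '%s': %d faces, %d landmarks, %d cavity truth value(s)\n",
              x$kind, n_faces(x$mesh), nrow(x$landmarks), length(x$truth)))
  for (nm in names(x$truth)) cat(sprintf("  %-20s %8.4f cm^3\n", nm, x$truth[[nm]]))
  invisible(x)
}

# cut whose keep side is resolved against the triplet's actual normal
keep_for <- function(lms, labels, direction) {
  p <- landmark_position(lms, labels)
  pl <- plane_from_landmarks(p[1, ], p[2, ], p[3, ], generators = labels)
  if (sum(pl$normal * direction) >= 0) "positive" else "negative"
}

cut_towards <- function(lms, labels, direction) {
  list(labels = labels, keep = keep_for(lms, labels, direction))
}

phantom_hollow_sphere <- function(res, r_out, r_in) {
  if (r_in >= r_out) {
    abort_cavex("r_in must be smaller than r_out", "cavex_error_phantom")
  }
  lvl_out <- max(2L, min(4L, 3L + round(log2(res))))
  lvl_in <- max(3L, min(5L, 4L + round(log2(res))))
  outer <- icosphere(lvl_out, radius = r_out)
  inner <- icosphere(lvl_in, radius = r_in)
  inner$faces <- inner$faces[, c(1, 3, 2)]   # normals into the cavity
  mesh <- merge_meshes(list(outer, inner), name = "hollow_sphere")
  x0 <- -(r_out + 5)
  lms <- landmark_config(
    c("LM1", "LM2", "LM3"),
    rbind(c(x0, 0, 0), c(x0, 10, 0), c(x0, 0, 10)))
  spec <- mode_spec("cavity", 1L,
                    cuts = list(cut_towards(lms, c("LM1", "LM2", "LM3"), c(1, 0, 0))),
                    alpha = 1.25 * r_in, spacing = r_in / 20)
  list(mesh = mesh, landmarks = lms,
       truth = list(cavity = 4 / 3 * pi * r_in^3 / 1000),
       specs = list(cavity = spec))
}

phantom_nasal_block <- function(res) {
  shell <- box_patches(c(0, 0, 0), c(60, 60, 60), 4 / res)
  cav <- box_patches(c(20, 20, 20), c(40, 40, 40), 2.5 / res)
  mesh <- finish_phantom(c(shell, cav), "nasal_block")
  pos <- rbind(c(15, 45, 45), c(15, 5, 15), c(15, 45, 15),
               c(45, 45, 15), c(45, 5, 45), c(45, 45, 45))
  lms <- landmark_config(paste0("LM", 1:6), pos)
  cuts <- list(
    cut_towards(lms, c("LM1", "LM2", "LM3"), c(1, 0, 0)),    # x >= 15
    cut_towards(lms, c("LM4", "LM5", "LM6"), c(-1, 0, 0)),   # x <= 45
    cut_towards(lms, c("LM1", "LM3", "LM4"), c(0, -1, 0)),   # y <= 45
    cut_towards(lms, c("LM2", "LM3", "LM4"), c(0, 0, 1)),    # z >= 15
    cut_towards(lms, c("LM1", "LM5", "LM6"), c(0, 0, -1)))   # z <= 45
  spec <- mode_spec("cavity", 1L, cuts = cuts, alpha = 15, spacing = 0.75)
  list(mesh = mesh, landmarks = lms, truth = list(cavity = 8),
       specs = list(cavity = spec))
}

phantom_orbit_fossa <- function(res) {
  h <- 3 / res
  n_az <- max(24L, round(48 * res))
  r <- 12
  depth <- 6
  cx <- 30
  cz <- 30
  gx <- lattice_breaks(0, 60, h, extra = c(cx - r - 3, cx + r + 3))
  gy <- lattice_breaks(0, 40, h)
  gz <- lattice_breaks(0, 60, h, extra = c(cz - r - 3, cz + r + 3))
  shell <- box_patches(c(0, 0, 0), c(60, 40, 60), h, skip = "ymin",
                       xs = gx, ys = gy, zs = gz)
  ff <- function(u, v) c(u, 0, v)
  front <- list(
    patch_grid(sub_breaks(gx, 0, cx - r - 3), sub_breaks(gz, 0, 60), ff),
    patch_grid(sub_breaks(gx, cx + r + 3, 60), sub_breaks(gz, 0, 60), ff),
    patch_grid(sub_breaks(gx, cx - r - 3, cx + r + 3), sub_breaks(gz, 0, cz - r - 3), ff),
    patch_grid(sub_breaks(gx, cx - r - 3, cx + r + 3), sub_breaks(gz, cz + r + 3, 60), ff),
    annulus_patch(rect_loop(cx - r - 3, cx + r + 3, cz - r - 3, cz + r + 3, gx, gz),
                  circle_loop(cx, cz, r, n_az), ff))
  collar <- collar_patch(cx, cz, r, 0, depth, n_az = n_az)
  bowl <- hemisphere_patch(c(cx, depth, cz), r, c(0, 1, 0),
                           n_az = n_az, n_pol = max(8L, round(10 * res)))
  mesh <- finish_phantom(c(shell, front, list(collar, bowl)), "orbit_fossa")
  rim <- function(a) c(cx + r * cos(a), depth, cz + r * sin(a))
  lms <- landmark_config(
    c("rim_sup", "rim_inf_med", "rim_inf_lat"),
    rbind(rim(pi / 2), rim(pi * 7 / 6), rim(pi * 11 / 6)))
  spec <- mode_spec("fossa", 2L,
                    pov_labels = c("rim_sup", "rim_inf_med", "rim_inf_lat"),
                    alpha = 16, spacing = 0.8)
  truth <- (pi * r^2 * depth + 2 / 3 * pi * r^3) / 1000
  list(mesh = mesh, landmarks = lms, truth = list(fossa = truth),
       specs = list(fossa = spec))
}

phantom_palate_dome <- function(res, teeth = TRUE) {
  h <- 3.5 / res
  open_x <- c(20, 50)
  open_y <- c(10, 40)
  rise <- 6
  tooth_x <- list(c(22, 28), c(32, 38), c(42, 48))
  strip_x <- c(17, 30, 40, 53)
  gx <- lattice_breaks(0, 70, h,
                       extra = c(17, 53, open_x, unlist(tooth_x), strip_x))
  gy <- lattice_breaks(0, 50, h, extra = c(2, 5, 7, open_y, 43))
  gz <- lattice_breaks(0, 30, h)
  shell <- box_patches(c(0, 0, 0), c(70, 50, 30), h, skip = "zmin",
                       xs = gx, ys = gy, zs = gz)
  bf <- function(u, v) c(u, v, 0)
  bottom <- list(
    patch_grid(sub_breaks(gx, 0, 17), sub_breaks(gy, 0, 50), bf),
    patch_grid(sub_breaks(gx, 53, 70), sub_breaks(gy, 0, 50), bf),
    patch_grid(sub_breaks(gx, 17, 53), sub_breaks(gy, 43, 50), bf),
    annulus_patch(rect_loop(17, 53, 7, 43, gx, gy),
                  rect_loop(open_x[1], open_x[2], open_y[1], open_y[2], gx, gy),
                  bf))
  extras <- list()
  if (teeth) {
    for (k in 1:3) {
      tx <- tooth_x[[k]]
      extras[[length(extras) + 1L]] <- annulus_patch(
        rect_loop(strip_x[k], strip_x[k + 1], 0, 7, gx, gy),
        rect_loop(tx[1], tx[2], 2, 5, gx, gy), bf)
      tb <- box_patches(c(tx[1], 2, -6), c(tx[2], 5, 0), h, skip = "zmax",
                        xs = gx, ys = gy)
      extras <- c(extras, unname(tb))
    }
  } else {
    bottom[[length(bottom) + 1L]] <-
      patch_grid(sub_breaks(gx, 17, 53), sub_breaks(gy, 0, 7), bf)
  }
  dome <- dome_patches(open_x[1], open_x[2], open_y[1], open_y[2], rise,
                       xs = gx, ys = gy, n_arc = max(16L, round(24 * res)))
  mesh <- finish_phantom(c(shell, bottom, extras, dome),
                         if (teeth) "palate_dome" else "palate_dome_edentulous")
  lms <- landmark_config(
    c("hp_corner_R", "hp_corner_L", "prosthion", "alv1", "alv2", "alv3"),
    rbind(c(25, 36, 8), c(45, 36, 8), c(35, 13, 8),
          c(5, 25, -2), c(65, 5, -2), c(65, 45, -2)))
  pov <- c("hp_corner_R", "hp_corner_L", "prosthion")
  spec <- if (teeth) {
    mode_spec("palate", 3L,
              alveolar_cut = cut_towards(lms, c("alv1", "alv2", "alv3"), c(0, 0, 1)),
              pov_labels = pov, alpha = 20, spacing = 1)
  } else {
    mode_spec("palate", 2L, pov_labels = pov, alpha = 20, spacing = 1)
  }
  r <- (open_x[2] - open_x[1]) / 2
  truth <- ((open_x[2] - open_x[1]) * (open_y[2] - open_y[1]) * rise +
              pi * r^2 / 2 * (open_y[2] - open_y[1])) / 1000
  list(mesh = mesh, landmarks = lms, truth = list(palate = truth),
       specs = list(palate = spec))
}

phantom_two_cell_slab <- function(res) {
  shell <- box_patches(c(0, 0, 0), c(80, 50, 24), 4 / res)
  cell1 <- box_patches(c(20, 20, 7), c(35, 30, 17), 2.5 / res)
  cell2 <- box_patches(c(50, 20, 7), c(58, 30, 17), 2.5 / res)
  mesh <- finish_phantom(c(shell, cell1, cell2), "two_cell_slab")
  pos <- rbind(c(-2, 5, 5), c(-2, 45, 5), c(-2, 25, 20),
               c(82, 5, 5), c(82, 45, 5), c(82, 25, 20))
  lms <- landmark_config(paste0("LM", 1:6), pos)
  cuts <- list(cut_towards(lms, c("LM1", "LM2", "LM3"), c(1, 0, 0)),
               cut_towards(lms, c("LM4", "LM5", "LM6"), c(-1, 0, 0)))
  spec <- mode_spec("sinus", 4L, cuts = cuts, multiple = TRUE,
                    alpha = 12, spacing = 0.6)
  list(mesh = mesh, landmarks = lms,
       truth = list(cell1 = 1.5, cell2 = 0.8, sinus = 2.3),
       specs = list(sinus = spec))
}

phantom_full_suite <- function(res) {
  h <- 4 / res
  hc <- 2.5 / res
  n_az <- max(32L, round(48 * res))
  or_ctr <- c(30, 60)   # (x, z) on the front face
  or_r <- 12
  or_depth <- 6
  tooth_x <- list(c(48, 54), c(58, 64), c(68, 74))
  strip_x <- c(46.5, 56.5, 66.5, 76)
  gx <- lattice_breaks(0, 120, h, extra = c(
    or_ctr[1] - or_r - 6, or_ctr[1] + or_r + 6,
    42, 45, 75, 78, strip_x, unlist(tooth_x)))
  gy <- lattice_breaks(0, 140, h, extra = c(1, 4, 5, 8, 38, 41))
  gz <- lattice_breaks(0, 100, h, extra = c(or_ctr[2] - or_r - 6, or_ctr[2] + or_r + 6))
  shell <- box_patches(c(0, 0, 0), c(120, 140, 100), h,
                       skip = c("ymin", "zmin"), xs = gx, ys = gy, zs = gz)

  # front face (y = 0) with the right-orbit socket opening
  x_lo <- or_ctr[1] - or_r - 6
  x_hi <- or_ctr[1] + or_r + 6
  z_lo <- or_ctr[2] - or_r - 6
  z_hi <- or_ctr[2] + or_r + 6
  ff <- function(u, v) c(u, 0, v)
  front <- list(
    patch_grid(sub_breaks(gx, 0, x_lo), sub_breaks(gz, 0, 100), ff),
    patch_grid(sub_breaks(gx, x_hi, 120), sub_breaks(gz, 0, 100), ff),
    patch_grid(sub_breaks(gx, x_lo, x_hi), sub_breaks(gz, 0, z_lo), ff),
    patch_grid(sub_breaks(gx, x_lo, x_hi), sub_breaks(gz, z_hi, 100), ff),
    annulus_patch(rect_loop(x_lo, x_hi, z_lo, z_hi, gx, gz),
                  circle_loop(or_ctr[1], or_ctr[2], or_r, n_az), ff))
  collar <- collar_patch(or_ctr[1], or_ctr[2], or_r, 0, or_depth, n_az = n_az)
  bowl <- hemisphere_patch(c(or_ctr[1], or_depth, or_ctr[2]), or_r, c(0, 1, 0),
                           n_az = n_az, n_pol = max(8L, round(10 * res)))

  # bottom face (z = 0): palate opening and tooth row
  bfm <- function(u, v) c(u, v, 0)
  bottom <- list(
    patch_grid(sub_breaks(gx, 0, 42), sub_breaks(gy, 0, 140), bfm),
    patch_grid(sub_breaks(gx, 78, 120), sub_breaks(gy, 0, 140), bfm),
    patch_grid(sub_breaks(gx, 42, 78), sub_breaks(gy, 41, 140), bfm),
    patch_grid(sub_breaks(gx, 42, 46.5), sub_breaks(gy, 0, 5), bfm),
    patch_grid(sub_breaks(gx, 76, 78), sub_breaks(gy, 0, 5), bfm),
    annulus_patch(rect_loop(42, 78, 5, 41, gx, gy),
                  rect_loop(45, 75, 8, 38, gx, gy), bfm))
  teeth <- list()
  for (k in 1:3) {
    tx <- tooth_x[[k]]
    teeth[[length(teeth) + 1L]] <- annulus_patch(
      rect_loop(strip_x[k], strip_x[k + 1], 0, 5, gx, gy),
      rect_loop(tx[1], tx[2], 1, 4, gx, gy), bfm)
    tb <- box_patches(c(tx[1], 1, -6), c(tx[2], 4, 0), h, skip = "zmax",
                      xs = gx, ys = gy)
    teeth <- c(teeth, unname(tb))
  }
  dome <- dome_patches(45, 75, 8, 38, 6, xs = gx, ys = gy,
                       n_arc = max(16L, round(24 * res)))

  # enclosed cavities (independent closed components; local lattices)
  endo <- box_patches(c(2, 2, 74), c(118, 138, 84), h)
  nc <- box_patches(c(49, 7, 27), c(71, 27, 45), hc)
  ms <- box_patches(c(79, 7, 27), c(98, 27, 43), hc)
  fs1 <- box_patches(c(34, 40, 87), c(54, 60, 97), hc)
  fs2 <- box_patches(c(66, 40, 87), c(82, 60, 97), hc)

  mesh <- finish_phantom(c(shell, front, list(collar, bowl), bottom, teeth,
                           dome, endo, nc, ms, fs1, fs2), "full_suite")

  rim <- function(a) c(or_ctr[1] + or_r * cos(a), or_depth, or_ctr[2] + or_r * sin(a))
  labels <- icex18_labels()
  pos <- rbind(
    bregma = c(75, 150, 20),
    nasion = c(45, 31, 48),
    subspinale = c(75, 31, 24),
    lacrimale_R = rim(pi / 2),
    lacrimale_L = c(45, 2, 24),
    frontomalare_orbitale_R = rim(pi * 7 / 6),
    frontomalare_orbitale_L = c(45, 150, 80),
    vomer_wing_tip_R = c(75, 2, 80),
    vomer_wing_tip_L = c(102, 2, 48),
    hard_palate_corner_R = c(50, 34, -2),
    hard_palate_corner_L = c(70, 34, 8),
    maxillopalatine_margin_R = c(102, 31, 80),
    maxillopalatine_margin_L = c(102, 31, 24),
    superior_orbital_fissure_R = rim(pi * 11 / 6),
    superior_orbital_fissure_L = c(102, 150, 48),
    last_molar_margin_R = c(45, 2, -2),
    last_molar_margin_L = c(75, 2, -2),
    prosthion = c(60, 12, 8))
  stopifnot(identical(rownames(pos), labels))
  lms <- landmark_config(labels, pos, schema_id = "icex18")

  x45 <- c("lacrimale_L", "nasion", "frontomalare_orbitale_L")
  x75 <- c("vomer_wing_tip_R", "subspinale", "bregma")
  x102 <- c("vomer_wing_tip_L", "maxillopalatine_margin_R", "maxillopalatine_margin_L")
  y2 <- c("lacrimale_L", "vomer_wing_tip_R", "vomer_wing_tip_L")
  y31 <- c("nasion", "subspinale", "maxillopalatine_margin_R")
  y150 <- c("frontomalare_orbitale_L", "bregma", "superior_orbital_fissure_L")
  zalv <- c("hard_palate_corner_R", "last_molar_margin_R", "last_molar_margin_L")
  z24 <- c("lacrimale_L", "subspinale", "maxillopalatine_margin_L")
  z48 <- c("nasion", "vomer_wing_tip_L", "superior_orbital_fissure_L")
  z80 <- c("frontomalare_orbitale_L", "vomer_wing_tip_R", "maxillopalatine_margin_R")

  specs <- list(
    nasal_cavity = mode_spec("nasal_cavity", 1L, cuts = list(
      cut_towards(lms, x45, c(1, 0, 0)),
      cut_towards(lms, x75, c(-1, 0, 0)),
      cut_towards(lms, y31, c(0, -1, 0)),
      cut_towards(lms, z24, c(0, 0, 1)),
      cut_towards(lms, z48, c(0, 0, -1))), alpha = 15, spacing = 0.75),
    maxillary_sinus_R = mode_spec("maxillary_sinus_R", 1L, cuts = list(
      cut_towards(lms, x75, c(1, 0, 0)),
      cut_towards(lms, x102, c(-1, 0, 0)),
      cut_towards(lms, y2, c(0, 1, 0)),
      cut_towards(lms, y31, c(0, -1, 0)),
      cut_towards(lms, z24, c(0, 0, 1)),
      cut_towards(lms, z48, c(0, 0, -1))), alpha = 15, spacing = 0.75),
    orbit_R = mode_spec("orbit_R", 2L,
      pov_labels = c("lacrimale_R", "frontomalare_orbitale_R",
                     "superior_orbital_fissure_R"),
      alpha = 16, spacing = 0.8),
    palate = mode_spec("palate", 3L,
      alveolar_cut = cut_towards(lms, zalv, c(0, 0, 1)),
      pov_labels = c("hard_palate_corner_R", "hard_palate_corner_L", "prosthion"),
      alpha = 20, spacing = 1),
    frontal_sinus = mode_spec("frontal_sinus", 4L, cuts = list(
      cut_towards(lms, z80, c(0, 0, 1)),
      cut_towards(lms, y150, c(0, -1, 0))),
      multiple = TRUE, alpha = 12, spacing = 0.6))

  truth <- list(
    nasal_cavity = 22 * 20 * 18 / 1000,
    maxillary_sinus_R = 19 * 20 * 16 / 1000,
    orbit_R = (pi * or_r^2 * or_depth + 2 / 3 * pi * or_r^3) / 1000,
    palate = (30 * 30 * 6 + pi * 15^2 / 2 * 30) / 1000,
    frontal_sinus = (20 * 20 * 10 + 16 * 20 * 10) / 1000)

  list(mesh = mesh, landmarks = lms, truth = truth, specs = specs)
}

#' Compare extraction results against phantom ground truth
#'
#' Per-cavity relative error of the tetra-sum volume against the phantom's
#' analytic truth, with a pass/fail column at the stated tolerance.
#'
#' @param bundle a [make_phantom()] bundle.
#' @param results named list of `extraction_result` objects (e.g.
#'   `run_icex(...)$results`); names must match the bundle's spec keys.
#' @param tolerance allowed `|relative error|`.
#' @return data frame with columns `cavity`, `truth_cm3`, `volume_cm3`,
#'   `rel_error`, `pass`.
#' @export
evaluate_extraction <- function(bundle, results, tolerance = 0.05) {
  keys <- names(bundle$specs)
  missing <- setdiff(keys, names(results))
  if (length(missing)) {
    abort_cavex(sprintf("missing result(s) for: %s", paste(missing, collapse = ", ")),
                "cavex_error_keying")
  }
  rows <- lapply(keys, function(k) {
    if (is.null(bundle$truth[[k]])) {
      abort_cavex(sprintf("no truth value for cavity '%s'", k), "cavex_error_keying")
    }
    v <- results[[k]]$report$volume_tetra_cm3
    tr <- bundle$truth[[k]]
    data.frame(cavity = k, truth_cm3 = tr, volume_cm3 = v,
               rel_error = (v - tr) / tr, pass = abs(v - tr) / tr <= tolerance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
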