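# shared fixtures: small canonical meshes and cached phantoms/extractions

# welded axis-aligned box: 8 vertices, 12 consistently outward faces
make_box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1), name = "box") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  # corners indexed by (x, y, z) bit order of expand.grid
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6))   # x = hi
  trimesh(v, f, name = name)
}

unit_cube <- function() make_box_mesh()

# memoised phantoms / suite extraction so expensive fixtures build once
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

get_phantom <- function(kind, ...) {
  key <- paste(kind, ..., sep = "|")
  cached(key, make_phantom(kind, ...))
}

get_suite_run <- function() {
  cached("suite_run", {
    b <- get_phantom("full-suite")
    run_icex(b$mesh, b$landmarks, b$specs)
  })
}

# components of a phantom mesh ordered by bounding-box diagonal, smallest
# first: cavity walls come before the outer shell regardless of face count
components_by_extent <- function(mesh) {
  comps <- connected_components(mesh)
  d <- vapply(comps, function(m) cavex:::bbox_diagonal(m), 0)
  comps[order(d)]
}

# the spherical cavity wall of the hollow-sphere phantom
hollow_wall <- function(bundle) components_by_extent(bundle$mesh)[[1]]

# the two cell walls of the two-cell slab, biggest cell first
slab_cells <- function(bundle) {
  comps <- components_by_extent(bundle$mesh)[1:2]
  vols <- vapply(comps, function(m) abs(signed_volume(m)), 0)
  comps[order(-vols)]
}
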