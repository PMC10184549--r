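# Readers and writers for the three surface formats used in virtual
# anthropology pipelines: PLY (ascii + binary little-endian), STL
# (ascii + binary) and OBJ (v/f records, 1-based).

#' Load a surface mesh
#'
#' Reads a PLY, STL or OBJ file into a [trimesh()]. The format is inferred
#' from the file extension unless `expected_format` is given. Duplicate
#' vertices are NOT merged (binary STL stores every facet independently);
#' call [weld_vertices()] explicitly when connectivity is needed, because
#' merging changes the voxel emptiness tests downstream.
#'
#' @param path file path.
#' @param expected_format one of `"ply"`, `"stl"`, `"obj"`, or `NULL` to use
#'   the file extension.
#' @return a [trimesh()].
#' @export
load_mesh <- function(path, expected_format = NULL) {
  if (!file.exists(path)) {
    abort_cavex(sprintf("mesh file not found: %s", path), "cavex_error_io")
  }
  fmt <- tolower(expected_format %||% tools::file_ext(path))
  mesh <- switch(fmt,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    abort_cavex(sprintf("unsupported mesh format '%s' (%s)", fmt, path),
                "cavex_error_format")
  )
  mesh$name <- tools::file_path_sans_ext(basename(path))
  validate_trimesh(mesh)
  mesh
}

#' Save a surface mesh
#'
#' Writes a [trimesh()] as PLY (ascii), STL (ascii or binary) or OBJ,
#' inferred from the extension. Round-tripping through PLY or OBJ preserves
#' coordinates to better than 1e-6 mm; binary STL stores 32-bit floats and
#' is only offered for interchange.
#'
#' @param mesh a [trimesh()].
#' @param path output path ending in `.ply`, `.stl` or `.obj`.
#' @param binary use the binary variant where the format has one (STL).
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, binary = FALSE) {
  validate_trimesh(mesh)
  fmt <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(fmt,
      ply = write_ply(mesh, path),
      stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
      obj = write_obj(mesh, path),
      abort_cavex(sprintf("unsupported mesh format '%s' (%s)", fmt, path),
                  "cavex_error_format")
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    if (inherits(ok, "cavex_error")) stop(ok)
    abort_cavex(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
                "cavex_error_io")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || !nzchar(a[1])) b else a

#' Decimate a mesh to a target face count
#'
#' Quadric edge-collapse simplification, chosen because it preserves
#' enclosed-cavity topology better than vertex clustering. Meshes already at
#' or below the target are returned unchanged. Whole-cranium meshes are
#' downsampled to 500,000 triangles at the start of the extraction protocol
#' to bound computation.
#'
#' @param mesh a [trimesh()].
#' @param target_faces target triangle count (>= 4).
#' @return the decimated [trimesh()] (face count within 1% of the target
#'   for closed meshes well above it).
#' @export
decimate_mesh <- function(mesh, target_faces = 500000L) {
  validate_trimesh(mesh)
  if (!is.numeric(target_faces) || target_faces < 4) {
    abort_cavex("target_faces must be at least 4", "cavex_error_decimate")
  }
  if (n_faces(mesh) <= target_faces) return(mesh)
  res <- .C_decimate(mesh$vertices, mesh$faces - 1L, as.integer(target_faces))
  trimesh(res$vertices, res$faces + 1L, name = mesh$name, validate = FALSE)
}

# ---------------------------------------------------------------- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1, warn = FALSE)
  if (!identical(trimws(magic), "ply")) {
    abort_cavex(sprintf("%s line 1: not a PLY file (magic '%s')", path, magic),
                "cavex_error_format")
  }
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame(type, name))
  cur <- NULL
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    lineno <- lineno + 1L
    if (length(ln) == 0) {
      abort_cavex(sprintf("%s line %d: unexpected end of header", path, lineno),
                  "cavex_error_format")
    }
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[length(elements) + 1L]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) {
        abort_cavex(sprintf("%s line %d: property before element", path, lineno),
                    "cavex_error_format")
      }
      cur$props[[length(cur$props) + 1L]] <- tok[-1]
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[length(elements) + 1L]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    abort_cavex(sprintf("%s: unsupported PLY format '%s'", path, fmt %||% "<none>"),
                "cavex_error_format")
  }

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64")) {
      readBin(con, "double", n = n, size = sz, endian = "little")
    } else {
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  }

  vertices <- NULL
  faces <- NULL
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    pos <- 0L
    for (el in elements) {
      lines <- rest[pos + seq_len(el$count)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        nums <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
        pn <- vapply(el$props, function(p) p[length(p)], "")
        ix <- match(c("x", "y", "z"), pn)
        if (anyNA(ix)) {
          abort_cavex(sprintf("%s: vertex element lacks x/y/z", path),
                      "cavex_error_format")
        }
        vertices <- nums[, ix, drop = FALSE]
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(tk) {
          n <- as.integer(tk[1])
          idx <- as.integer(tk[1 + seq_len(n)])
          if (n == 3L) idx else NULL  # fan-triangulate below
        }))
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        pn <- vapply(el$props, function(p) p[length(p)], "")
        pt <- vapply(el$props, function(p) p[1], "")
        if (any(pt == "list")) {
          abort_cavex(sprintf("%s: list property on vertex element unsupported", path),
                      "cavex_error_format")
        }
        raw <- matrix(NA_real_, nrow = el$count, ncol = length(pn))
        for (i in seq_len(el$count)) {
          for (j in seq_along(pn)) raw[i, j] <- read_scalar(pt[j], 1L)
        }
        ix <- match(c("x", "y", "z"), pn)
        vertices <- raw[, ix, drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1]]
        if (p[1] != "list") {
          abort_cavex(sprintf("%s: face element without list property", path),
                      "cavex_error_format")
        }
        cnt_type <- p[2]
        idx_type <- p[3]
        fl <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          n <- read_scalar(cnt_type, 1L)
          fl[[i]] <- read_scalar(idx_type, n)
        }
        faces <- do.call(rbind, lapply(fl, function(x) if (length(x) == 3L) x else NULL))
      } else {
        # skip unknown element payload (scalar properties only)
        pt <- vapply(el$props, function(p) p[1], "")
        for (i in seq_len(el$count)) for (t in pt) read_scalar(t, 1L)
      }
    }
  }
  if (is.null(vertices)) {
    abort_cavex(sprintf("%s: no vertex element", path), "cavex_error_format")
  }
  if (is.null(faces) || nrow(faces) == 0) {
    abort_cavex(sprintf("%s: mesh has zero faces", path), "cavex_error_empty_mesh")
  }
  trimesh(vertices, faces + 1L, validate = FALSE)
}

write_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vl <- sprintf("%.10g %.10g %.10g",
                mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  writeLines(vl, con)
  f0 <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  invisible(path)
}

# ---------------------------------------------------------------- STL ----

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 count, 50-byte records; ascii starts
  # with "solid" AND parses as text (binary headers may also start "solid")
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = 80)
  n_tri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  looks_binary <- length(n_tri) == 1 && !is.na(n_tri) && sz == 84 + 50 * n_tri
  close(con)
  if (looks_binary) read_stl_binary(path, n_tri) else read_stl_ascii(path)
}

read_stl_binary <- function(path, n_tri) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 84))
  v <- matrix(NA_real_, nrow = 3 * n_tri, ncol = 3)
  for (i in seq_len(n_tri)) {
    rec <- readBin(con, "double", n = 12, size = 4, endian = "little")
    v[3 * i - 2, ] <- rec[4:6]
    v[3 * i - 1, ] <- rec[7:9]
    v[3 * i, ] <- rec[10:12]
    invisible(readBin(con, "raw", n = 2))
  }
  if (n_tri == 0) {
    abort_cavex(sprintf("%s: mesh has zero faces", path), "cavex_error_empty_mesh")
  }
  trimesh(v, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE), validate = FALSE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vix <- grep("^\\s*vertex\\s", lines)
  if (length(vix) == 0 || length(vix) %% 3 != 0) {
    abort_cavex(
      sprintf("%s line %d: malformed ascii STL (%d vertex records)",
              path, if (length(vix)) vix[length(vix)] else 1L, length(vix)),
      if (length(vix) == 0) "cavex_error_empty_mesh" else "cavex_error_format"
    )
  }
  v <- do.call(rbind, lapply(strsplit(trimws(lines[vix]), "\\s+"),
                             function(tk) as.numeric(tk[2:4])))
  if (anyNA(v)) {
    abort_cavex(sprintf("%s: unparseable vertex coordinates", path),
                "cavex_error_format")
  }
  trimesh(v, matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE), validate = FALSE)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  nl <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  blocks <- sprintf(
    "facet normal %.10g %.10g %.10g\n outer loop\n  vertex %.10g %.10g %.10g\n  vertex %.10g %.10g %.10g\n  vertex %.10g %.10g %.10g\n endloop\nendfacet",
    nx / nl, ny / nl, nz / nl,
    v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
    v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
    v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(blocks, con)
  writeLines(sprintf("endsolid %s", mesh$name), con)
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", paste("cavex binary STL", mesh$name)))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    nrm <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
             (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
             (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeBin(c(nrm, p1, p2, p3), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vsel <- grepl("^v\\s", lines)
  fsel <- grepl("^f\\s", lines)
  v <- do.call(rbind, lapply(strsplit(trimws(lines[vsel]), "\\s+"),
                             function(tk) as.numeric(tk[2:4])))
  if (is.null(v)) {
    abort_cavex(sprintf("%s: no vertex records", path), "cavex_error_format")
  }
  fl <- lines[fsel]
  if (length(fl) == 0) {
    abort_cavex(sprintf("%s: mesh has zero faces", path), "cavex_error_empty_mesh")
  }
  frows <- lapply(seq_along(fl), function(i) {
    tk <- strsplit(trimws(fl[i]), "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tk, "/"), `[[`, "", 1))
    if (anyNA(idx)) {
      abort_cavex(sprintf("%s: unparseable face record '%s'", path, fl[i]),
                  "cavex_error_format")
    }
    neg <- idx < 0
    idx[neg] <- nrow(v) + 1L + idx[neg]   # OBJ relative indexing
    if (any(idx < 1L | idx > nrow(v))) {
      abort_cavex(
        sprintf("%s: face index %d out of range [1, %d] (OBJ is 1-based) in '%s'",
                path, idx[idx < 1L | idx > nrow(v)][1], nrow(v), fl[i]),
        "cavex_error_mesh_index"
      )
    }
    if (length(idx) == 3L) {
      matrix(idx, ncol = 3)
    } else {  # fan-triangulate polygons
      do.call(rbind, lapply(2:(length(idx) - 1L),
                            function(k) c(idx[1], idx[k], idx[k + 1])))
    }
  })
  trimesh(v, do.call(rbind, frows), validate = FALSE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cavex OBJ export: %s", mesh$name), con)
  writeLines(sprintf("v %.10g %.10g %.10g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}
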