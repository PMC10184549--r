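# Labelled anatomical landmark configurations: the 18-point cranial scheme
# used by the full extraction protocol, plus free-form configurations.

#' The 18 cranial landmarks of the full configuration
#'
#' Labels, in sampling order, of the landmark scheme that anchors every
#' cutting plane and point of view of the full cranial protocol: bregma,
#' nasion, subspinale, the paired lacrimale, frontomalare orbitale, vomer
#' wing tips, posterolateral hard-palate corners, maxillopalatine-suture
#' margins, superior orbital fissures and last-molar alveolus margins, and
#' prosthion.
#'
#' @return character vector of 18 labels.
#' @export
icex18_labels <- function() {
  c("bregma", "nasion", "subspinale",
    "lacrimale_R", "lacrimale_L",
    "frontomalare_orbitale_R", "frontomalare_orbitale_L",
    "vomer_wing_tip_R", "vomer_wing_tip_L",
    "hard_palate_corner_R", "hard_palate_corner_L",
    "maxillopalatine_margin_R", "maxillopalatine_margin_L",
    "superior_orbital_fissure_R", "superior_orbital_fissure_L",
    "last_molar_margin_R", "last_molar_margin_L",
    "prosthion")
}

#' Landmark configuration
#'
#' An ordered, labelled set of 3D points (mm). With `schema_id = "icex18"`
#' the labels must be exactly the 18 of [icex18_labels()]; any other (or
#' `NULL`) schema admits a free configuration with unique labels.
#'
#' @param labels character vector of unique labels.
#' @param positions numeric matrix (`n x 3`), mm.
#' @param schema_id optional schema tag; `"icex18"` turns on schema checks.
#' @return object of class `landmark_config`: data frame with columns
#'   `label`, `x`, `y`, `z` and attribute `schema_id`.
#' @export
landmark_config <- function(labels, positions, schema_id = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  labels <- as.character(labels)
  if (ncol(positions) != 3L || nrow(positions) != length(labels)) {
    abort_cavex("positions must be an n x 3 matrix matching labels",
                "cavex_error_landmarks")
  }
  if (!all(is.finite(positions))) {
    abort_cavex("landmark positions must be finite", "cavex_error_landmarks")
  }
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    abort_cavex(sprintf("duplicate landmark label(s): %s",
                        paste(unique(dup), collapse = ", ")),
                "cavex_error_landmark_schema")
  }
  if (identical(schema_id, "icex18")) {
    want <- icex18_labels()
    missing <- setdiff(want, labels)
    extra <- setdiff(labels, want)
    if (length(missing) || length(extra)) {
      abort_cavex(sprintf(
        "configuration does not match schema 'icex18'%s%s",
        if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
        if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""),
        "cavex_error_landmark_schema")
    }
    if (!identical(labels, want)) {
      abort_cavex("schema 'icex18' requires labels in their stated order",
                  "cavex_error_landmark_schema")
    }
  }
  out <- data.frame(label = labels, x = positions[, 1], y = positions[, 2],
                    z = positions[, 3], stringsAsFactors = FALSE)
  structure(out, schema_id = schema_id, class = c("landmark_config", "data.frame"))
}

#' Load landmarks from CSV
#'
#' Reads a plain CSV with header `label,x,y,z` (comma separator, dot
#' decimal). Row order is preserved; when `schema_id` is given the labels
#' are validated against that schema.
#'
#' @param path CSV file path.
#' @param schema_id optional schema tag (see [landmark_config()]).
#' @return a [landmark_config()].
#' @export
load_landmarks <- function(path, schema_id = NULL) {
  if (!file.exists(path)) {
    abort_cavex(sprintf("landmark file not found: %s", path), "cavex_error_io")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort_cavex(sprintf("%s: expected header label,x,y,z (got: %s)",
                        path, paste(names(df), collapse = ",")),
                "cavex_error_landmark_schema")
  }
  landmark_config(df$label, as.matrix(df[, c("x", "y", "z")]), schema_id = schema_id)
}

#' Save landmarks to CSV
#'
#' @param lms a [landmark_config()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_landmarks <- function(lms, path) {
  write.csv(as.data.frame(lms)[, c("label", "x", "y", "z")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("landmark_config: %d points%s\n", nrow(x),
              if (!is.null(attr(x, "schema_id")))
                sprintf(" (schema '%s')", attr(x, "schema_id")) else ""))
  print.data.frame(head(as.data.frame(x), 20))
  invisible(x)
}

# positions (k x 3) of the given labels, in the order requested
landmark_position <- function(lms, labels) {
  ix <- match(labels, lms$label)
  if (anyNA(ix)) {
    abort_cavex(sprintf("unknown landmark label(s): %s",
                        paste(labels[is.na(ix)], collapse = ", ")),
                "cavex_error_landmarks")
  }
  as.matrix(as.data.frame(lms)[ix, c("x", "y", "z"), drop = FALSE])
}

#' Perturb landmark positions
#'
#' Adds isotropic Gaussian noise (sd `sigma` mm) to every landmark — the
#' package's stand-in for inter/intra-observer placement error in
#' robustness checks. Phantom landmarks themselves are generated at exact
#' analytic positions so correctness tests stay separate from noise tests.
#'
#' @param lms a [landmark_config()].
#' @param sigma standard deviation of the perturbation, mm.
#' @param seed integer seed for reproducibility.
#' @return a perturbed [landmark_config()] (same labels and schema).
#' @export
jitter_landmarks <- function(lms, sigma = 0.5, seed = 1L) {
  pos <- as.matrix(as.data.frame(lms)[, c("x", "y", "z")])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pos <- pos + matrix(rnorm(length(pos), sd = sigma), ncol = 3)
  landmark_config(lms$label, pos, schema_id = attr(lms, "schema_id"))
}
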