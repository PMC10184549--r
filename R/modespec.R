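# Declarative per-cavity extraction recipes.

#' Extraction recipe for one cavity
#'
#' A `mode_spec` describes how one cavity of interest is extracted:
#' \describe{
#'   \item{mode 1}{`cuts` isolate the bone region that houses an enclosed
#'     cavity (5 planes for the nasal cavity, 6 per maxillary sinus); no
#'     POV labels.}
#'   \item{mode 2}{no cuts; `pov_labels` are the three landmarks whose
#'     barycentre is the point of view.}
#'   \item{mode 3}{`alveolar_cut` removes the teeth, then as mode 2.}
#'   \item{mode 4}{exactly two `cuts` isolate a slab; internal cells are
#'     measured all together (`multiple = TRUE`) or only the biggest.}
#' }
#' Each cut is a list `list(labels = c(a, b, c), keep = "positive"|"negative")`
#' of landmark labels; planes are built when the spec is resolved against a
#' configuration. `param1` scales the POV jitter radius of the
#' enclosed-cavity extractor and `param2` scales alpha, both defaulting to
#' 1 and intended for per-specimen adjustment (e.g. unusually large cavities).
#'
#' @param cavity_name text label used in reports and output file names.
#' @param mode integer 1-4.
#' @param cuts list of cuts as above (modes 1 and 4).
#' @param pov_labels character vector of exactly three landmark labels
#'   (modes 2 and 3).
#' @param alveolar_cut single cut (mode 3).
#' @param multiple mode 4: measure all cells instead of the biggest.
#' @param alpha alpha radius, mm (`NULL`: data-driven default).
#' @param spacing voxel spacing, mm (`NULL`: `alpha / 20`).
#' @param param1,param2 dimensionless scale factors (see Details).
#' @return object of class `mode_spec`.
#' @export
mode_spec <- function(cavity_name, mode, cuts = list(), pov_labels = NULL,
                      alveolar_cut = NULL, multiple = FALSE, alpha = NULL,
                      spacing = NULL, param1 = 1, param2 = 1) {
  if (!is.numeric(mode) || length(mode) != 1L || !(mode %in% 1:4)) {
    abort_cavex("mode must be one of 1, 2, 3, 4", "cavex_error_spec")
  }
  mode <- as.integer(mode)
  chk_cut <- function(ct, what) {
    if (!is.list(ct) || is.null(ct$labels) || length(ct$labels) != 3L ||
        is.null(ct$keep) || !ct$keep %in% c("positive", "negative")) {
      abort_cavex(sprintf(
        "%s must be list(labels = <3 landmark labels>, keep = 'positive'|'negative')",
        what), "cavex_error_spec")
    }
  }
  for (i in seq_along(cuts)) chk_cut(cuts[[i]], sprintf("cuts[[%d]]", i))
  if (!is.null(alveolar_cut)) chk_cut(alveolar_cut, "alveolar_cut")
  if (mode == 1L) {
    if (length(cuts) < 1L) {
      abort_cavex("mode 1 requires at least one cut", "cavex_error_spec")
    }
    if (!is.null(pov_labels)) {
      abort_cavex("mode 1 takes no pov_labels", "cavex_error_spec")
    }
  } else if (mode == 2L) {
    if (length(cuts) != 0L) {
      abort_cavex("mode 2 requires cuts to be empty (planes and keep are NULL)",
                  "cavex_error_spec")
    }
    if (is.null(pov_labels) || length(pov_labels) != 3L) {
      abort_cavex("mode 2 requires exactly three pov_labels", "cavex_error_spec")
    }
  } else if (mode == 3L) {
    if (is.null(pov_labels) || length(pov_labels) != 3L) {
      abort_cavex("mode 3 requires exactly three pov_labels", "cavex_error_spec")
    }
    if (is.null(alveolar_cut)) {
      abort_cavex("mode 3 requires an alveolar_cut", "cavex_error_spec")
    }
    if (length(cuts) != 0L) {
      abort_cavex("mode 3 takes only the alveolar cut", "cavex_error_spec")
    }
  } else {
    if (length(cuts) != 2L) {
      abort_cavex("mode 4 requires exactly two cuts", "cavex_error_spec")
    }
    if (!is.null(pov_labels)) {
      abort_cavex("mode 4 takes no pov_labels", "cavex_error_spec")
    }
  }
  if (!is.null(alpha) && (!is.numeric(alpha) || alpha <= 0)) {
    abort_cavex("alpha must be positive", "cavex_error_spec")
  }
  if (!is.null(spacing) && (!is.numeric(spacing) || spacing <= 0)) {
    abort_cavex("spacing must be positive", "cavex_error_spec")
  }
  structure(list(cavity_name = as.character(cavity_name)[1], mode = mode,
                 cuts = cuts, pov_labels = pov_labels,
                 alveolar_cut = alveolar_cut, multiple = isTRUE(multiple),
                 alpha = alpha, spacing = spacing,
                 param1 = param1, param2 = param2),
            class = "mode_spec")
}

#' @export
print.mode_spec <- function(x, ...) {
  cat(sprintf("mode_spec '%s': mode %d, %d cut(s)%s%s, alpha %s, multiple %s\n",
              x$cavity_name, x$mode,
              length(x$cuts) + as.integer(!is.null(x$alveolar_cut)),
              if (!is.null(x$pov_labels))
                sprintf(", POV = mean(%s)", paste(x$pov_labels, collapse = ", ")) else "",
              if (!is.null(x$alveolar_cut)) " (+alveolar)" else "",
              if (is.null(x$alpha)) "auto" else format(x$alpha), x$multiple))
  invisible(x)
}

# check that every label the spec mentions exists in the configuration
validate_spec_labels <- function(spec, lms) {
  labs <- c(unlist(lapply(spec$cuts, `[[`, "labels")), spec$pov_labels,
            spec$alveolar_cut$labels)
  missing <- setdiff(labs, lms$label)
  if (length(missing)) {
    abort_cavex(sprintf("spec '%s' references unknown landmark(s): %s",
                        spec$cavity_name, paste(missing, collapse = ", ")),
                "cavex_error_spec")
  }
  invisible(TRUE)
}

# resolve the label cuts of a spec into cut_spec objects
resolve_cuts <- function(cuts, lms) {
  lapply(cuts, function(ct) {
    cut_spec(plane_from_labels(lms, ct$labels), keep = ct$keep)
  })
}

# deterministic 32-bit seed from a spec (cavity name + mode + parameters),
# so jittered POVs are reproducible for identical specs
spec_seed <- function(spec) {
  s <- 0
  for (ch in utf8ToInt(spec$cavity_name)) s <- (s * 31 + ch) %% 2147483629
  s <- (s * 31 + spec$mode) %% 2147483629
  s <- (s * 31 + round(1000 * (spec$param1 + spec$param2))) %% 2147483629
  as.integer(s + 1)
}
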