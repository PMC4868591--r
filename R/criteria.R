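#' Target taxon terms
#'
#' Builds the validated set of terms that define target leaves. A tree tip
#' is a target when at least one term occurs as an exact, case-sensitive
#' substring of its label. Because matching is by substring, no term may be
#' a substring of another (e.g. `"plantae"` together with `"Viridiplantae"`
#' is rejected: every tip matched by the longer term is also matched by the
#' shorter one, making the query ambiguous).
#'
#' @param terms Either a character vector of terms or a single
#'   comma-separated string (`"Rhodophyta,Viridiplantae"`). Surrounding
#'   whitespace per term is trimmed; empty terms are invalid.
#' @return An object of class `"target_spec"`: a character vector of terms.
#' @examples
#' target_spec("Rhodophyta,Viridiplantae,Stramenopiles")
#' @export
target_spec <- function(terms) {
  if (inherits(terms, "target_spec")) return(terms)
  if (!is.character(terms) || length(terms) == 0L) {
    stop("'terms' must be a non-empty character vector or comma-separated string",
         call. = FALSE)
  }
  if (length(terms) == 1L && grepl(",", terms, fixed = TRUE)) {
    terms <- strsplit(terms, ",", fixed = TRUE)[[1]]
  }
  terms <- trimws(terms)
  if (any(!nzchar(terms))) {
    stop("target terms must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(terms)) {
    stop("duplicate target terms: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      if (i != j && grepl(terms[i], terms[j], fixed = TRUE)) {
        stop("target terms must be unique: '", terms[i],
             "' is a substring of '", terms[j], "'", call. = FALSE)
      }
    }
  }
  structure(terms, class = "target_spec")
}

#' Clade-sorting thresholds
#'
#' Bundles the thresholds that decide whether a candidate clade qualifies.
#'
#' * `min_support` -- minimum support for a qualifying clade, on the file's
#'   native scale (0--1 or 0--100). Nodes with no support value count as 0.
#' * `min_prop_target` -- minimum proportion of *all* target leaves in the
#'   tree that must fall inside the clade. At 1.0 a strict monophyly of the
#'   target group is enforced; low values accept narrowly defined clades.
#' * `clade_exclusivity` -- minimum proportion of a Non-Exclusive clade's
#'   own leaves that must be targets; must be `< 1` (at 1.0 the clade would
#'   contain no non-target leaves and hence be Exclusive, so 1.0 is
#'   rejected).
#' * `clades_sorted` -- which clade families to search for: `"E"`
#'   (Exclusive), `"NE"` (Non-Exclusive) or both.
#'
#' @param min_support Non-negative number, default 0.
#' @param min_prop_target Number in \[0, 1\], default 0.7.
#' @param clade_exclusivity Number in \[0, 1), default 0.9.
#' @param clades_sorted Character vector, subset of `c("E", "NE")`, or a
#'   single comma-separated string. Default both.
#' @return An object of class `"sort_criteria"`.
#' @examples
#' sort_criteria(min_support = 90, min_prop_target = 1.0, clades_sorted = "E")
#' @export
sort_criteria <- function(min_support = 0,
                          min_prop_target = 0.7,
                          clade_exclusivity = 0.9,
                          clades_sorted = c("E", "NE")) {
  if (inherits(min_support, "sort_criteria")) return(min_support)
  if (!is.numeric(min_support) || length(min_support) != 1L ||
      is.na(min_support) || min_support < 0) {
    stop("'min_support' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(min_prop_target) || length(min_prop_target) != 1L ||
      is.na(min_prop_target) ||
      min_prop_target < 0 || min_prop_target > 1) {
    stop("'min_prop_target' must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(clade_exclusivity) || length(clade_exclusivity) != 1L ||
      is.na(clade_exclusivity) || clade_exclusivity < 0) {
    stop("'clade_exclusivity' must be a single number in [0, 1)", call. = FALSE)
  }
  if (clade_exclusivity >= 1) {
    stop("'clade_exclusivity' must be < 1.0: specification of 1.0 is not ",
         "allowed (a clade with no non-target leaves is Exclusive, not ",
         "Non-Exclusive)", call. = FALSE)
  }
  if (length(clades_sorted) == 1L && grepl(",", clades_sorted, fixed = TRUE)) {
    clades_sorted <- strsplit(clades_sorted, ",", fixed = TRUE)[[1]]
  }
  clades_sorted <- unique(trimws(clades_sorted))
  if (length(clades_sorted) == 0L || !all(clades_sorted %in% c("E", "NE"))) {
    stop("'clades_sorted' must be a non-empty subset of c(\"E\", \"NE\")",
         call. = FALSE)
  }
  structure(
    list(min_support = min_support,
         min_prop_target = min_prop_target,
         clade_exclusivity = clade_exclusivity,
         clades_sorted = clades_sorted),
    class = "sort_criteria"
  )
}

#' @export
print.sort_criteria <- function(x, ...) {
  cat("Clade-sorting criteria:\n")
  cat("  min_support:       ", x$min_support, "\n")
  cat("  min_prop_target:   ", x$min_prop_target, "\n")
  cat("  clade_exclusivity: ", x$clade_exclusivity, "\n")
  cat("  clades_sorted:     ", paste(x$clades_sorted, collapse = ","), "\n")
  invisible(x)
}
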