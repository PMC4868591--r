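#' Sort a directory of phylogenetic tree files by target clade content
#'
#' Classifies every tree file in `in_dir` whose name ends with `extension`
#' (non-recursive, lexicographic order) with [classify_tree()], then lists,
#' copies (`mode = "c"`) or moves (`mode = "m"`) the qualifying files into
#' a structured output directory created inside `in_dir`:
#'
#' ```
#' in_dir/out_dir/Exclusive/                 trees with an Exclusive clade
#' in_dir/out_dir/Exclusive/All_Exclusive/   trees whose every leaf is a target
#' in_dir/out_dir/Non_Exclusive/             trees with only Non-Exclusive clades
#' ```
#'
#' In list mode (`"l"`, the default) no directories are created and no
#' files are relocated; the classification lists returned are identical
#' across the three modes. A file that carries both an Exclusive and a
#' Non-Exclusive clade is filed under `Exclusive/` (one file, one
#' location), but all of its qualifying clades appear in the log.
#' Subdirectories are only created for the clade families requested in
#' `clades_sorted`.
#'
#' Every run writes a tab-separated log `in_dir/<out_dir>.log` (also in
#' list mode) with one record per qualifying clade: source file, tag,
#' support, target/non-target counts, within-clade target proportion,
#' proportion of the tree's targets contained, and the semicolon-joined
#' leaf labels. Unparseable files are recorded in the log as skipped and
#' the run continues.
#'
#' @param target_groups Target terms ([target_spec()] or coercible); the
#'   only argument without a default.
#' @param in_dir Input directory containing the tree files. Default: the
#'   current working directory.
#' @param out_dir Name of the output directory created within `in_dir`
#'   in move/copy mode. Default `"Sorted_Trees"`.
#' @param mode `"l"` (list, default), `"c"` (copy) or `"m"` (move).
#' @param extension Literal file-name suffix of tree files, default `".tre"`.
#' @param min_support,min_prop_target,clade_exclusivity,clades_sorted
#'   Threshold arguments, see [sort_criteria()].
#' @param criteria Alternatively, a prebuilt [sort_criteria()] object
#'   (overrides the individual threshold arguments).
#' @return An object of class `"sort_report"`: a list with
#'   `all_exclusive`, `exclusive` (includes the All Exclusive subset),
#'   `non_exclusive` and `skipped` file-name vectors, a data frame
#'   `actions` (`file`, `destination`; empty in list mode), `clades`
#'   (the per-clade log as a data frame) and `log_path`.
#' @examples
#' \dontrun{
#' rep <- sort_trees("Rhodophyta,Viridiplantae", in_dir = "trees",
#'                   min_support = 90, mode = "l")
#' rep$exclusive
#' }
#' @export
sort_trees <- function(target_groups,
                       in_dir = ".",
                       out_dir = "Sorted_Trees",
                       mode = c("l", "c", "m"),
                       extension = ".tre",
                       min_support = 0,
                       min_prop_target = 0.7,
                       clade_exclusivity = 0.9,
                       clades_sorted = c("E", "NE"),
                       criteria = NULL) {
  mode <- match.arg(mode)
  targets <- target_spec(target_groups)
  if (is.null(criteria)) {
    criteria <- sort_criteria(min_support, min_prop_target,
                              clade_exclusivity, clades_sorted)
  } else {
    criteria <- sort_criteria(criteria)
  }
  if (!dir.exists(in_dir)) {
    stop("input directory does not exist: ", in_dir, call. = FALSE)
  }
  if (!nzchar(out_dir) || basename(out_dir) != out_dir) {
    stop("'out_dir' must be a plain directory name, created within 'in_dir'",
         call. = FALSE)
  }
  files <- sort(list.files(in_dir, pattern = paste0(rx_escape(extension), "$"),
                           full.names = FALSE))
  files <- files[!dir.exists(file.path(in_dir, files))]
  if (length(files) == 0L) {
    stop("no files with extension '", extension, "' found in ", in_dir,
         call. = FALSE)
  }

  want_e <- "E" %in% criteria$clades_sorted
  want_ne <- "NE" %in% criteria$clades_sorted

  all_exclusive <- character(0)
  exclusive <- character(0)
  non_exclusive <- character(0)
  skipped <- character(0)
  log_rows <- list()

  for (f in files) {
    cls <- tryCatch(
      classify_tree(file.path(in_dir, f), targets, criteria),
      error = function(e) e
    )
    if (inherits(cls, "error")) {
      skipped <- c(skipped, f)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        file = f, tag = "SKIPPED", support = NA_real_,
        n_target = NA_integer_, n_nontarget = NA_integer_,
        prop_within = NA_real_, prop_of_tree_targets = NA_real_,
        leaves = conditionMessage(cls), stringsAsFactors = FALSE
      )
      next
    }
    if ("ALL_EXCLUSIVE" %in% cls$labels) all_exclusive <- c(all_exclusive, f)
    if ("EXCLUSIVE" %in% cls$labels) exclusive <- c(exclusive, f)
    if ("NON_EXCLUSIVE" %in% cls$labels) non_exclusive <- c(non_exclusive, f)
    if (nrow(cls$clades)) {
      log_rows[[length(log_rows) + 1L]] <-
        cbind(file = f, cls$clades, stringsAsFactors = FALSE)
    }
  }

  clades <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(file = character(0), tag = character(0),
               support = numeric(0), n_target = integer(0),
               n_nontarget = integer(0), prop_within = numeric(0),
               prop_of_tree_targets = numeric(0), leaves = character(0),
               stringsAsFactors = FALSE)
  }
  # stable record order: file name, then clade size (large first)
  if (nrow(clades)) {
    ord <- order(clades$file, -(ifelse(is.na(clades$n_target), 0,
                                       clades$n_target) +
                                ifelse(is.na(clades$n_nontarget), 0,
                                       clades$n_nontarget)),
                 clades$leaves)
    clades <- clades[ord, , drop = FALSE]
    rownames(clades) <- NULL
  }

  log_path <- file.path(in_dir, paste0(out_dir, ".log"))
  write_clade_log(clades, log_path)

  actions <- data.frame(file = character(0), destination = character(0),
                        stringsAsFactors = FALSE)
  if (mode %in% c("m", "c")) {
    root <- file.path(in_dir, out_dir)
    dir.create(root, showWarnings = FALSE)
    if (want_e) {
      dir.create(file.path(root, "Exclusive"), showWarnings = FALSE)
      dir.create(file.path(root, "Exclusive", "All_Exclusive"),
                 showWarnings = FALSE)
    }
    if (want_ne) {
      dir.create(file.path(root, "Non_Exclusive"), showWarnings = FALSE)
    }
    dest_of <- function(f) {
      if (f %in% all_exclusive) return(file.path(root, "Exclusive",
                                                 "All_Exclusive", f))
      # Exclusive takes precedence over Non-Exclusive for dual-labelled trees
      if (f %in% exclusive) return(file.path(root, "Exclusive", f))
      file.path(root, "Non_Exclusive", f)
    }
    hits <- unique(c(exclusive, non_exclusive))
    hits <- files[files %in% hits]  # keep lexicographic order
    for (f in hits) {
      dest <- dest_of(f)
      if (file.exists(dest) && mode == "m") {
        stop("destination file already exists: ", dest, call. = FALSE)
      }
      # copy mode overwrites, so re-running the same job is idempotent
      ok <- file.copy(file.path(in_dir, f), dest, overwrite = TRUE,
                      copy.date = TRUE)
      if (!ok) stop("failed to copy ", f, " to ", dest, call. = FALSE)
      if (mode == "m") file.remove(file.path(in_dir, f))
      actions[nrow(actions) + 1L, ] <- c(f, dest)
    }
  }

  structure(
    list(all_exclusive = all_exclusive,
         exclusive = exclusive,
         non_exclusive = non_exclusive,
         skipped = skipped,
         actions = actions,
         clades = clades,
         log_path = log_path,
         mode = mode),
    class = "sort_report"
  )
}

# per-clade TSV log; deterministic, header always present
write_clade_log <- function(clades, path) {
  num <- function(x) ifelse(is.na(x), "NA", format(x, digits = 10,
                                                   scientific = FALSE,
                                                   trim = TRUE))
  lines <- paste("file", "tag", "support", "n_target", "n_nontarget",
                 "prop_within", "prop_of_tree_targets", "leaves",
                 sep = "\t")
  if (nrow(clades)) {
    body <- paste(clades$file, clades$tag, num(clades$support),
                  ifelse(is.na(clades$n_target), "NA", clades$n_target),
                  ifelse(is.na(clades$n_nontarget), "NA", clades$n_nontarget),
                  num(clades$prop_within),
                  num(clades$prop_of_tree_targets),
                  clades$leaves, sep = "\t")
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @export
print.sort_report <- function(x, ...) {
  cat("Tree sorting report (mode:", x$mode, ")\n")
  cat("  Exclusive trees:     ", length(x$exclusive), "\n")
  cat("  ... All Exclusive:   ", length(x$all_exclusive), "\n")
  cat("  Non-Exclusive trees: ", length(x$non_exclusive), "\n")
  if (length(x$skipped)) cat("  skipped (unparseable):", length(x$skipped), "\n")
  cat("  log:", x$log_path, "\n")
  invisible(x)
}

rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
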