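#' Parse a phylogenetic tree from Newick or extended Newick text
#'
#' Reads a single tree from a character string in either standard Newick or
#' extended Newick (eNewick) dialect and returns an [ape::read.tree()]-style
#' `"phylo"` object. The two dialects differ only in where a node's support
#' value lives: standard Newick writes it as the internal node label before
#' the colon (`)95:0.3`), eNewick encloses it in square brackets after the
#' branch length (`):0.3[95]`). The dialect is auto-detected from the
#' presence of a bracketed token directly after a branch length; eNewick
#' input is rewritten to standard Newick via [convert_enewick()] before
#' parsing.
#'
#' Support values are kept on the file's native scale (0--1 or 0--100);
#' no rescaling ever happens at parse time. Internal nodes without a label
#' carry absent support (the empty string in `$node.label`), which
#' downstream classification treats as support 0. Non-numeric internal
#' labels are preserved but also count as absent support.
#'
#' @param text A single character string containing one complete tree
#'   terminated by `";"`.
#' @return An object of class `"phylo"` with an additional attribute
#'   `source_dialect`, either `"newick"` or `"enewick"`.
#' @seealso [convert_enewick()], [write_tree()], [read_tree_file()]
#' @examples
#' parse_tree("((A:1,B:1)99:1,C:1);")
#' parse_tree("((A:1,B:1):1[99],C:1);")   # same tree, eNewick dialect
#' @export
parse_tree <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("'text' must be a single character string", call. = FALSE)
  }
  text <- trimws(text)
  if (!nzchar(text)) {
    stop("parse error: empty input", call. = FALSE)
  }
  check_newick_syntax(text)
  dialect <- detect_dialect(text)
  newick <- if (dialect == "enewick") convert_enewick(text) else text
  phy <- tryCatch(
    ape::read.tree(text = newick),
    error = function(e) stop("parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("parse error: not a valid Newick tree", call. = FALSE)
  if (inherits(phy, "multiPhylo")) {
    stop("parse error: multiple trees in input; one tree per string expected",
         call. = FALSE)
  }
  if (any(!nzchar(phy$tip.label))) {
    stop("parse error: empty tip label", call. = FALSE)
  }
  attr(phy, "source_dialect") <- dialect
  phy
}

#' Read a single tree file
#'
#' Convenience wrapper around [parse_tree()] for one-tree-per-file input.
#'
#' @param path Path to a file holding one Newick or eNewick tree.
#' @return A `"phylo"` object as from [parse_tree()].
#' @export
read_tree_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  text <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- parse_tree(text)
  attr(tr, "source_file") <- path
  tr
}

#' Convert an extended Newick tree string to standard Newick
#'
#' Applies the placement rewrite that distinguishes the two dialects: every
#' token `):L[S]` (branch length `L`, bracketed support `S` on an internal
#' node) becomes `)S:L`, i.e. the support moves from a bracket after the
#' branch length to a node label before the colon. Topology, labels and
#' branch lengths are preserved byte-for-byte apart from the rewrite. The
#' function is idempotent: standard Newick input is returned unchanged with
#' a warning.
#'
#' Hybrid-node network syntax (`#H` tags) is not supported and is rejected;
#' the eNewick dialect is accepted here solely as an alternative encoding of
#' node support. A bracketed value that does not follow an internal node's
#' branch length (e.g. on a tip) is a conversion error, as is a bracket with
#' no preceding branch length.
#'
#' @param text A single character string containing one eNewick tree.
#' @return A standard Newick string parseable by [ape::read.tree()].
#' @examples
#' convert_enewick("((A:1,B:1):0.5[90],C:1);")
#' @export
convert_enewick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("'text' must be a single character string", call. = FALSE)
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("conversion error: empty input", call. = FALSE)
  check_newick_syntax(text)
  if (grepl("#H", text, fixed = TRUE)) {
    stop("conversion error: hybrid-node eNewick (#H tags) is not supported; ",
         "only ':length[support]' annotations are handled", call. = FALSE)
  }
  if (!grepl("[", text, fixed = TRUE)) {
    warning("input contains no bracketed support values; ",
            "already standard Newick, returned unchanged", call. = FALSE)
    return(text)
  }
  # internal node: `):L[S]` -> `)S:L`
  out <- gsub("\\):([^][,():;]+)\\[([^][]*)\\]", ")\\2:\\1", text)
  if (grepl("[", out, fixed = TRUE)) {
    offset <- regexpr("[", out, fixed = TRUE)[1]
    stop("conversion error: bracketed support not attached to an internal ",
         "node's branch length (near character ", offset, ")", call. = FALSE)
  }
  out
}

#' Serialize a tree to standard Newick
#'
#' Emits standard Newick with any support values as internal node labels
#' before the colon. `parse_tree(write_tree(t))` reproduces `t` in topology,
#' tip labels, supports and branch lengths (within numeric formatting
#' precision). Trees whose nodes carry no labels are written without node
#' labels, so absent support stays absent.
#'
#' @param tree A `"phylo"` object.
#' @param digits Number of significant digits for branch lengths.
#' @return A single Newick string terminated by `";"`.
#' @export
write_tree <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Serialize a tree to extended Newick
#'
#' Writes the tree as standard Newick, then moves every numeric internal
#' node label into a square bracket after that node's branch length
#' (`)S:L` becomes `):L[S]`). Nodes without a numeric label and nodes
#' without a branch length (normally only the root) are left unannotated.
#'
#' @inheritParams write_tree
#' @return A single eNewick string.
#' @export
write_enewick <- function(tree, digits = 10) {
  s <- write_tree(tree, digits = digits)
  num <- "[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?"
  gsub(sprintf("\\)(%s):(%s)", num, num), "):\\2[\\1]", s)
}

#' Numeric support values of a tree's internal nodes
#'
#' Extracts `$node.label` as numeric support on the file's native scale.
#' Absent or non-numeric labels yield `NA`; classification treats `NA`
#' as support 0.
#'
#' @param tree A `"phylo"` object.
#' @return Numeric vector of length `tree$Nnode` (root first).
#' @export
node_support <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(lab))
  sup[!is.na(sup) & sup < 0] <- NA_real_
  sup
}

# Dialect auto-detection: a bracketed token immediately after a branch
# length marks eNewick.
detect_dialect <- function(text) {
  if (grepl(":[^][,():;]+\\[", text)) "enewick" else "newick"
}

# Minimal structural validation with character offsets, run before handing
# the string to the parser: balanced parentheses/brackets and a ";"
# terminator.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  bracket <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("parse error: unbalanced ')' at character ", i, call. = FALSE)
      }
    } else if (ch == "[") bracket <- bracket + 1L
    else if (ch == "]") {
      bracket <- bracket - 1L
      if (bracket < 0L) {
        stop("parse error: unbalanced ']' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("parse error: unbalanced parentheses (", depth,
         " unclosed '(' at end of input)", call. = FALSE)
  }
  if (bracket > 0L) {
    stop("parse error: unbalanced '[' at end of input", call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop("parse error: missing ';' terminator at character ",
         nchar(text), call. = FALSE)
  }
  invisible(TRUE)
}
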