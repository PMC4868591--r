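#' Partition a tree's tips into target and non-target leaves
#'
#' A tip is a target iff at least one term of `targets` occurs as an exact,
#' case-sensitive substring of its label. The partition is exhaustive and
#' disjoint; finding zero targets is a legal outcome.
#'
#' @param tree A `"phylo"` object.
#' @param targets A [target_spec()] (or anything coercible to one).
#' @return A logical vector along `tree$tip.label`: `TRUE` for targets.
#' @examples
#' tr <- parse_tree("((Rhodophyta_Gs:1,Viridiplantae_At:1)99:1,Cyanobacteria_Syn:1);")
#' match_targets(tr, target_spec("Rhodophyta,Viridiplantae"))
#' @export
match_targets <- function(tree, targets) {
  stopifnot(inherits(tree, "phylo"))
  targets <- target_spec(targets)
  is_target <- rep(FALSE, length(tree$tip.label))
  for (term in targets) {
    is_target <- is_target | grepl(term, tree$tip.label, fixed = TRUE)
  }
  names(is_target) <- tree$tip.label
  is_target
}

#' Enumerate both sides of every internal edge of the unrooted topology
#'
#' No assumption about the root of the input file is made: trees are
#' treated as unrooted, so clade membership on *both* sides of each
#' internal edge is considered. Each internal edge of the unrooted topology
#' yields a complementary pair of candidate clades that partition the full
#' tip set and share the support value annotated on that edge. When the
#' rooted file representation has a bifurcating root, its two child edges
#' are the same unrooted edge; the pair is emitted once, carrying whichever
#' of the two child-node supports is present (the larger if both are).
#' Pendant edges (one side a single tip) are not internal edges and yield
#' no candidates, so every candidate has at least 2 leaves. The root node
#' itself contributes no candidate.
#'
#' @param tree A `"phylo"` object with at least 4 tips (smaller trees have
#'   no internal edge on the unrooted topology and yield an empty result).
#' @return A list of candidate clades; each element is a list with fields
#'   `tips` (integer tip indices), `labels` (character), `support` (numeric,
#'   `NA` when absent), `edge_id` (integer identifying the unrooted internal
#'   edge, shared by the two complementary candidates).
#' @export
enumerate_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4L) return(list())
  sup <- node_support(tree)
  root <- n + 1L

  # tip sets under each internal node, by postorder accumulation
  tips_under <- clade_tip_sets(tree)

  nodes <- seq_len(tree$Nnode) + n
  sizes <- lengths(tips_under)

  # a bifurcating root makes its two (internal) children the same unrooted
  # edge; keep one representative with the merged support
  drop_node <- integer(0)
  root_children <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(root_children) == 2L && all(root_children > n)) {
    c1 <- root_children[1]; c2 <- root_children[2]
    s1 <- sup[c1 - n]; s2 <- sup[c2 - n]
    sup[c1 - n] <- if (is.na(s1)) s2 else if (is.na(s2)) s1 else max(s1, s2)
    drop_node <- c2
  }

  keep <- nodes != root & sizes >= 2L & sizes <= n - 2L & !(nodes %in% drop_node)
  out <- vector("list", 2L * sum(keep))
  k <- 0L
  edge_id <- 0L
  all_tips <- seq_len(n)
  for (v in nodes[keep]) {
    edge_id <- edge_id + 1L
    inside <- tips_under[[v - n]]
    outside <- all_tips[-inside]
    s <- sup[v - n]
    k <- k + 1L
    out[[k]] <- list(tips = inside, labels = tree$tip.label[inside],
                     support = s, edge_id = edge_id)
    k <- k + 1L
    out[[k]] <- list(tips = outside, labels = tree$tip.label[outside],
                     support = s, edge_id = edge_id)
  }
  out
}

# tip indices under each internal node (list indexed by node - Ntip),
# single postorder pass
clade_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  res <- vector("list", tree$Nnode)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1]; child <- edge[i, 2]
    kid_tips <- if (child <= n) child else res[[child - n]]
    res[[par - n]] <- c(res[[par - n]], kid_tips)
  }
  lapply(res, sort)
}

#' Classify one candidate clade against the sorting criteria
#'
#' A candidate is **Exclusive** when it contains only target leaves (at
#' least two of them), its support meets `min_support`, and it holds at
#' least `min_prop_target` of all target leaves in the tree. It is
#' **Non-Exclusive** when at least one non-target ("interrupting") leaf is
#' present but the within-clade target proportion is at least
#' `clade_exclusivity` (and below 1 by construction), with the same support
#' and tree-wide proportion requirements. Otherwise it is tagged `"NONE"`.
#' Threshold comparisons are inclusive (`>=`) and exact: no epsilon is
#' applied, so a clade at exactly the threshold qualifies.
#'
#' @param clade A list with fields `n_target`, `n_nontarget`, `support`
#'   (NA allowed, treated as 0) and `prop_of_tree_targets`, e.g. one
#'   element of the output of [tally_candidates()].
#' @param criteria A [sort_criteria()] object.
#' @return One of `"EXCLUSIVE"`, `"NON_EXCLUSIVE"`, `"NONE"`.
#' @export
classify_clade <- function(clade, criteria = sort_criteria()) {
  criteria <- sort_criteria(criteria)
  n_t <- clade$n_target
  n_nt <- clade$n_nontarget
  sup <- clade$support
  if (is.null(sup) || is.na(sup)) sup <- 0
  size <- n_t + n_nt
  prop_within <- if (size > 0) n_t / size else 0
  p_tree <- clade$prop_of_tree_targets
  if (sup < criteria$min_support) return("NONE")
  if (is.na(p_tree) || p_tree < criteria$min_prop_target) return("NONE")
  if (n_nt == 0L) {
    if (n_t >= 2L) return("EXCLUSIVE")
    return("NONE")
  }
  if (prop_within >= criteria$clade_exclusivity && prop_within < 1) {
    return("NON_EXCLUSIVE")
  }
  "NONE"
}

#' Tally target composition of candidate clades
#'
#' Augments each candidate from [enumerate_bipartitions()] with the counts
#' the classification criteria operate on: targets inside (`n_target`),
#' interrupting non-targets (`n_nontarget`), the within-clade target
#' proportion (`prop_within`) and the fraction of the tree's total target
#' leaves held by the clade (`prop_of_tree_targets`). Duplicate tip labels
#' are counted per leaf, not per unique label.
#'
#' @param candidates Output of [enumerate_bipartitions()].
#' @param is_target Logical vector over tips as from [match_targets()].
#' @return The candidate list with tally fields added.
#' @export
tally_candidates <- function(candidates, is_target) {
  total_targets <- sum(is_target)
  lapply(candidates, function(cl) {
    n_t <- sum(is_target[cl$tips])
    size <- length(cl$tips)
    cl$n_target <- n_t
    cl$n_nontarget <- size - n_t
    cl$prop_within <- if (size > 0) n_t / size else 0
    cl$prop_of_tree_targets <-
      if (total_targets > 0) n_t / total_targets else NA_real_
    cl
  })
}

#' Classify a whole tree
#'
#' Runs the full per-tree pipeline: match target leaves, enumerate both
#' sides of every internal edge of the unrooted topology, tally and
#' classify each candidate, then label the tree. The result is invariant
#' to how the input file happens to be rooted.
#'
#' Labels assigned:
#' * `EXCLUSIVE` -- some candidate clade is Exclusive and `"E"` is in
#'   `clades_sorted`.
#' * `ALL_EXCLUSIVE` -- every tip of the tree is a target leaf (decided by
#'   leaf composition alone, no support or proportion check) and `"E"` is
#'   requested; always accompanied by `EXCLUSIVE` since All Exclusive trees
#'   are a subset of Exclusive trees.
#' * `NON_EXCLUSIVE` -- some candidate is Non-Exclusive and `"NE"` is
#'   requested.
#'
#' A tree with zero target leaves is a valid input and yields empty labels.
#'
#' @param tree A `"phylo"` object (or a tree-file path).
#' @param targets A [target_spec()] or coercible.
#' @param criteria A [sort_criteria()] object.
#' @return An object of class `"tree_classification"`: a list with
#'   `labels` (character subset of the three tags), `clades` (a data frame
#'   of qualifying candidate clades with columns `tag`, `support`,
#'   `n_target`, `n_nontarget`, `prop_within`, `prop_of_tree_targets`,
#'   `leaves`), `n_tips`, `n_targets`, and `source_file` (NA unless the
#'   tree was read from a file).
#' @examples
#' tr <- parse_tree("((Rho_a:1,(Rho_b:1,Rho_c:1)80:1)99:1,(Cya_x:1,Pro_y:1):1);")
#' classify_tree(tr, "Rho")
#' @export
classify_tree <- function(tree, targets, criteria = sort_criteria()) {
  if (is.character(tree) && length(tree) == 1L) tree <- read_tree_file(tree)
  stopifnot(inherits(tree, "phylo"))
  targets <- target_spec(targets)
  criteria <- sort_criteria(criteria)

  is_target <- match_targets(tree, targets)
  candidates <- tally_candidates(enumerate_bipartitions(tree), is_target)
  tags <- vapply(candidates, classify_clade, character(1), criteria = criteria)

  want_e <- "E" %in% criteria$clades_sorted
  want_ne <- "NE" %in% criteria$clades_sorted
  keep <- (tags == "EXCLUSIVE" & want_e) | (tags == "NON_EXCLUSIVE" & want_ne)

  labels <- character(0)
  if (want_e && any(tags == "EXCLUSIVE")) labels <- c(labels, "EXCLUSIVE")
  all_target <- length(is_target) > 0 && all(is_target)
  if (want_e && all_target) {
    labels <- unique(c("ALL_EXCLUSIVE", labels, "EXCLUSIVE"))
  }
  if (want_ne && any(tags == "NON_EXCLUSIVE")) {
    labels <- c(labels, "NON_EXCLUSIVE")
  }

  kept <- candidates[keep]
  clades <- data.frame(
    tag = tags[keep],
    support = vapply(kept, function(cl) {
      if (is.na(cl$support)) 0 else cl$support
    }, numeric(1)),
    n_target = vapply(kept, `[[`, integer(1), "n_target"),
    n_nontarget = vapply(kept, `[[`, integer(1), "n_nontarget"),
    prop_within = vapply(kept, `[[`, numeric(1), "prop_within"),
    prop_of_tree_targets = vapply(kept, `[[`, numeric(1),
                                  "prop_of_tree_targets"),
    leaves = vapply(kept, function(cl) paste(cl$labels, collapse = ";"),
                    character(1)),
    stringsAsFactors = FALSE
  )
  # deterministic order: large clades first, support as tie-break
  if (nrow(clades) > 0) {
    ord <- order(-(clades$n_target + clades$n_nontarget), -clades$support,
                 clades$leaves)
    clades <- clades[ord, , drop = FALSE]
    rownames(clades) <- NULL
  }

  src <- attr(tree, "source_file")
  structure(
    list(labels = labels,
         clades = clades,
         n_tips = length(tree$tip.label),
         n_targets = sum(is_target),
         source_file = if (is.null(src)) NA_character_ else src),
    class = "tree_classification"
  )
}

#' @export
print.tree_classification <- function(x, ...) {
  cat("Tree classification",
      if (!is.na(x$source_file)) paste0("(", x$source_file, ")"), "\n")
  cat("  tips:", x$n_tips, " targets:", x$n_targets, "\n")
  cat("  labels:",
      if (length(x$labels)) paste(x$labels, collapse = ", ") else "(none)",
      "\n")
  if (nrow(x$clades)) {
    cat("  qualifying clades:\n")
    print(x$clades[, c("tag", "support", "n_target", "n_nontarget",
                       "prop_within", "prop_of_tree_targets")], ...)
  }
  invisible(x)
}
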