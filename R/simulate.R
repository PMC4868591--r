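#' Simulate one benchmark tree with an embedded exclusive target clade
#'
#' Builds a benchmark tree of exactly `x` leaves by the fixed recipe used
#' for scalability testing:
#'
#' 1. draw a random bifurcating base topology with `round(1.05 * x)` tips
#'    (random sequential addition);
#' 2. designate one internal clade of `round(0.2 * x)` tips as the target
#'    clade and label its tips with `target_term`;
#' 3. swap (randomly permute) the labels of all non-target leaves, drawn
#'    from a fixed vocabulary of lineage-like group names none of which
#'    contains `target_term`;
#' 4. prune `round(0.05 * x)` randomly chosen terminal branches external to
#'    the target clade (degree-2 nodes are suppressed), leaving `x` tips;
#' 5. assign `support_fill` to every internal node (the root, which has no
#'    branch in the rooted representation, is left unannotated) and draw
#'    branch lengths uniformly in (0, 1].
#'
#' The result contains exactly one maximal all-target clade of
#' `round(0.2 * x)` leaves holding 100% of the tree's targets, so sorting
#' with any `min_support <= support_fill` and default thresholds classifies
#' it Exclusive. With `negative_control = TRUE` the target clade is simply
#' omitted: all `x` tips carry non-target labels and no label contains
#' `target_term`.
#'
#' Uses the current RNG state; seed via `set.seed()` or use
#' [simulate_set()] which seeds explicitly.
#'
#' @param x Number of leaves in the final tree; at least 20 (a multiple of
#'   20 keeps `0.2 * x` and `0.05 * x` integral).
#' @param target_term Substring embedded in every target tip label.
#' @param support_fill Support value written on every internal node,
#'   default 100.
#' @param negative_control If `TRUE`, omit the target clade.
#' @return A `"phylo"` object with `x` tips.
#' @examples
#' set.seed(1)
#' tr <- simulate_tree(100)
#' classify_tree(tr, "Targetia")$labels
#' @export
simulate_tree <- function(x,
                          target_term = "Targetia",
                          support_fill = 100,
                          negative_control = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 20) {
    stop("'x' must be a single number >= 20", call. = FALSE)
  }
  x <- as.integer(round(x))
  base_n <- as.integer(round(1.05 * x))
  drop_n <- as.integer(round(0.05 * x))
  k <- as.integer(round(0.2 * x))
  if (base_n - drop_n != x) {
    stop("tip-count arithmetic failed for x = ", x,
         ": round(1.05x) - round(0.05x) != x; choose a multiple of 20",
         call. = FALSE)
  }
  if (any(vapply(nontarget_vocab, grepl, logical(1), x = target_term,
                 fixed = TRUE)) ||
      any(grepl(target_term, nontarget_vocab, fixed = TRUE))) {
    stop("'target_term' collides with the non-target label vocabulary",
         call. = FALSE)
  }

  if (negative_control) {
    phy <- ape::rtree(base_n)
    phy$tip.label <- nontarget_labels(base_n)
    is_target_tip <- rep(FALSE, base_n)
  } else {
    # backbone with a placeholder tip that the target subtree replaces
    backbone <- ape::rtree(base_n - k + 1L)
    backbone$tip.label <- c("@placeholder@",
                            nontarget_labels(base_n - k))[
                              sample.int(base_n - k + 1L)]
    target_sub <- ape::rtree(k)
    target_sub$tip.label <- paste0(target_term, "_taxon", seq_len(k))
    phy <- ape::bind.tree(backbone, target_sub,
                          where = which(backbone$tip.label == "@placeholder@"))
    is_target_tip <- grepl(target_term, phy$tip.label, fixed = TRUE)
    if (sum(is_target_tip) != k) {
      stop("internal error: target clade construction failed", call. = FALSE)
    }
  }

  # swap non-target labels at random
  nt <- which(!is_target_tip)
  phy$tip.label[nt] <- phy$tip.label[nt][sample.int(length(nt))]

  # prune terminal branches external to the target clade
  if (drop_n > 0L) {
    drop_tips <- phy$tip.label[sample(which(!is_target_tip), drop_n)]
    phy <- ape::drop.tip(phy, drop_tips)
  }

  phy$node.label <- c("", rep(format(support_fill), phy$Nnode - 1L))
  phy$edge.length <- round(stats::runif(nrow(phy$edge), 0.0001, 1), 4)
  phy
}

#' Simulate a benchmark set of tree files
#'
#' Writes `n` simulated trees (see [simulate_tree()]) as one eNewick file
#' each (extension `.tre`) plus a tab-separated `manifest.tsv` mapping each
#' file name to its ground-truth label (`"exclusive"` or `"negative"`).
#' With `replicate_topology = TRUE` (the benchmark design: a single
#' technical replicate) all `n` files contain the identical tree; with
#' `FALSE` each file is an independent draw. Runs are deterministic: the
#' same `spec` and `seed` produce byte-identical files.
#'
#' @inheritParams simulate_tree
#' @param n Number of tree files to write.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer random seed.
#' @param replicate_topology If `TRUE` (default), all files share one tree.
#' @param prefix File-name prefix, default `"tree"`.
#' @return Invisibly, the character vector of tree-file paths; the
#'   manifest path is attached as attribute `"manifest"`.
#' @examples
#' d <- tempfile("sim")
#' simulate_set(x = 40, n = 3, out_dir = d, seed = 7)
#' list.files(d)
#' @export
simulate_set <- function(x, n, out_dir, seed,
                         target_term = "Targetia",
                         support_fill = 100,
                         negative_control = FALSE,
                         replicate_topology = TRUE,
                         prefix = "tree") {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("'n' must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  names <- sprintf("%s_%0*d.tre", prefix, max(4L, nchar(n)), seq_len(n))
  paths <- file.path(out_dir, names)
  if (any(file.exists(paths))) {
    stop("output files already exist in ", out_dir, call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (replicate_topology) {
    one <- write_enewick(simulate_tree(x, target_term, support_fill,
                                       negative_control))
    for (p in paths) writeLines(one, p)
  } else {
    for (p in paths) {
      writeLines(write_enewick(simulate_tree(x, target_term, support_fill,
                                             negative_control)), p)
    }
  }
  manifest <- file.path(out_dir, "manifest.tsv")
  truth <- if (negative_control) "negative" else "exclusive"
  writeLines(c("file\tlabel", paste(names, truth, sep = "\t")), manifest)
  out <- paths
  attr(out, "manifest") <- manifest
  invisible(out)
}

# lineage-like non-target vocabulary; numbered suffixes keep labels unique
nontarget_vocab <- c(
  "Proteobacteria", "Cyanobacteria", "Haptophyceae", "Opisthokonta",
  "Amoebozoa", "Euglenozoa", "Alveolata", "Rhizaria", "Excavata",
  "Fungi", "Metazoa", "Cryptophyta", "Glaucophyta", "Firmicutes",
  "Actinobacteria", "Bacteroidetes", "Chlorobi", "Spirochaetes",
  "Thermotogae", "Crenarchaeota"
)

nontarget_labels <- function(m) {
  grp <- rep_len(nontarget_vocab, m)
  paste0(grp, "_sp", seq_len(m))
}
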