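# shared helpers: random well-formed test trees and brute-force oracles

# random rooted tree with distinct numeric supports on internal nodes; the
# two root-child nodes describe the same unrooted edge, so when both are
# internal they get the same support (a well-formed file states one value
# per split)
random_support_tree <- function(n_tips, supports = NULL) {
  phy <- ape::rtree(n_tips)
  n <- n_tips
  if (is.null(supports)) {
    supports <- sample(10:100, phy$Nnode, replace = TRUE)
  }
  lab <- as.character(supports)
  lab[1] <- ""  # root
  root_children <- phy$edge[phy$edge[, 1] == n + 1L, 2]
  internal_rc <- root_children[root_children > n]
  if (length(internal_rc) == 2L) {
    lab[internal_rc - n] <- lab[internal_rc[1] - n]
  }
  phy$node.label <- lab
  phy
}

# all rooted representations of a tree's unrooted topology: rooted at each
# internal node and on each tip's pendant edge
all_rootings <- function(phy) {
  n <- length(phy$tip.label)
  out <- list()
  for (nd in seq_len(phy$Nnode) + n) {
    out[[length(out) + 1L]] <- tryCatch(
      ape::root(phy, node = nd, edgelabel = TRUE),
      error = function(e) NULL
    )
  }
  for (tip in seq_len(n)) {
    out[[length(out) + 1L]] <- tryCatch(
      ape::root(phy, outgroup = tip, edgelabel = TRUE, resolve.root = TRUE),
      error = function(e) NULL
    )
  }
  Filter(Negate(is.null), out)
}

# canonical key of a set of tip labels
clade_key <- function(labels) paste(sort(labels), collapse = "|")

# brute-force oracle: the union, over all rootings at internal nodes, of
# every non-root rooted clade with between 2 and n-2 tips (as label sets)
oracle_bipartition_keys <- function(phy) {
  n <- length(phy$tip.label)
  keys <- character(0)
  for (nd in seq_len(phy$Nnode) + n) {
    r <- tryCatch(ape::root(phy, node = nd, edgelabel = TRUE),
                  error = function(e) NULL)
    if (is.null(r)) next
    root <- length(r$tip.label) + 1L
    sets <- cladesift:::clade_tip_sets(r)
    for (v in seq_len(r$Nnode) + length(r$tip.label)) {
      if (v == root) next
      sz <- length(sets[[v - length(r$tip.label)]])
      if (sz >= 2L && sz <= n - 2L) {
        keys <- c(keys, clade_key(r$tip.label[sets[[v - length(r$tip.label)]]]))
      }
    }
  }
  sort(unique(keys))
}

# small example tree used across files: the 30-leaf scenario with a
# 24-leaf clade of 23 targets plus one interrupting Haptophyceae leaf,
# support 99, and six non-target leaves outside
interrupted_clade_tree <- function(inside_targets = 23, interrupting = 1,
                                   outside_nontargets = 6, support = 99) {
  inside <- c(paste0("Rhodophyta_t", seq_len(inside_targets)),
              if (interrupting > 0)
                paste0("Haptophyceae_i", seq_len(interrupting)))
  outside <- paste0("Proteobacteria_o", seq_len(outside_nontargets))
  ladder <- function(labs) {
    s <- paste0(labs[1], ":1")
    for (l in labs[-1]) s <- sprintf("(%s,%s:1):1", s, l)
    s
  }
  # support goes on the node subtending the inside clade
  inside_str <- sprintf("(%s,%s:1)%s:1", ladder(inside[-length(inside)]),
                        inside[length(inside)], support)
  parse_tree(sprintf("(%s,%s,%s:1);", inside_str,
                     ladder(outside[-length(outside)]),
                     outside[length(outside)]))
}

expect_same_classification <- function(a, b) {
  expect_setequal(a$labels, b$labels)
  expect_equal(nrow(a$clades), nrow(b$clades))
}
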