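test_that("match_targets partitions tips by case-sensitive substring", {
  tr <- parse_tree(
    "((Rhodophyta_Gs:1,Viridiplantae_At:1)99:1,Cyanobacteria_Syn:1);")
  hit <- match_targets(tr, "Rhodophyta,Viridiplantae")
  expect_equal(sum(hit), 2L)
  expect_false(hit[["Cyanobacteria_Syn"]])
  # case-sensitive: lowercase term does not match
  expect_equal(sum(match_targets(tr, "rhodophyta")), 0L)
  # zero targets found is a legal outcome
  expect_equal(sum(match_targets(tr, "Glaucophyta")), 0L)
})

test_that("target_spec rejects terms that are substrings of each other", {
  expect_error(target_spec("plantae,Viridiplantae"), "substring")
  expect_error(target_spec(c("Rhodo", "Rhodophyta")), "substring")
  expect_error(target_spec("A,,B"), "non-empty")
  expect_error(target_spec("A,B,A"), "duplicate|substring")
  expect_silent(target_spec("Rhodophyta,Viridiplantae,Stramenopiles"))
})

test_that("enumerate_bipartitions emits both sides of each internal edge", {
  # single internal edge of the unrooted 4-tip topology: both sides, same
  # support, even though only one side carries the label in the file
  cands <- enumerate_bipartitions(parse_tree("((A:1,B:1)95:1,(C:1,D:1):1);"))
  expect_length(cands, 2L)
  keys <- vapply(cands, function(cl) clade_key(cl$labels), character(1))
  expect_setequal(keys, c("A|B", "C|D"))
  expect_equal(vapply(cands, `[[`, numeric(1), "support"), c(95, 95))
  expect_equal(unique(vapply(cands, `[[`, integer(1), "edge_id")), 1L)

  # trees below 4 tips have no internal edge
  expect_length(enumerate_bipartitions(parse_tree("((A:1,B:1)9:1,C:1);")), 0L)

  # basal trifurcation: root contributes no candidate
  cands5 <- enumerate_bipartitions(
    parse_tree("((A:1,B:1)90:1,(C:1,D:1)80:1,E:1);"))
  keys5 <- vapply(cands5, function(cl) clade_key(cl$labels), character(1))
  expect_setequal(keys5, c("A|B", "C|D|E", "C|D", "A|B|E"))
})

test_that("complementary candidates partition the tip set", {
  set.seed(11)
  for (i in 1:15) {
    phy <- random_support_tree(sample(4:20, 1))
    cands <- enumerate_bipartitions(phy)
    ids <- vapply(cands, `[[`, integer(1), "edge_id")
    for (e in unique(ids)) {
      pair <- cands[ids == e]
      expect_length(pair, 2L)
      expect_length(intersect(pair[[1]]$tips, pair[[2]]$tips), 0L)
      expect_setequal(c(pair[[1]]$tips, pair[[2]]$tips),
                      seq_along(phy$tip.label))
      expect_equal(pair[[1]]$support, pair[[2]]$support)
      expect_gte(length(pair[[1]]$tips), 2L)
      expect_gte(length(pair[[2]]$tips), 2L)
    }
  }
})

test_that("candidate set matches the brute-force all-rootings oracle", {
  set.seed(23)
  for (i in 1:12) {
    phy <- random_support_tree(sample(4:10, 1))
    got <- sort(unique(vapply(enumerate_bipartitions(phy),
                              function(cl) clade_key(cl$labels),
                              character(1))))
    expect_identical(got, oracle_bipartition_keys(phy))
  }
})

make_clade <- function(n_target, n_nontarget, support, prop_tree) {
  list(n_target = n_target, n_nontarget = n_nontarget,
       support = support, prop_of_tree_targets = prop_tree)
}

test_that("classify_clade implements the Exclusive/Non-Exclusive rules", {
  d <- sort_criteria()
  # 23 targets + 1 interrupting leaf, all tree targets inside: 23/24 >= 0.9
  expect_identical(classify_clade(make_clade(23, 1, 99, 1), d),
                   "NON_EXCLUSIVE")
  # within-clade proportion 0.79 fails the default exclusivity of 0.9
  expect_identical(classify_clade(make_clade(19, 5, 99, 1), d), "NONE")
  # narrowly defined all-target clade: 4 of 29 targets fails default 0.7 ...
  expect_identical(classify_clade(make_clade(4, 0, 99, 4 / 29), d), "NONE")
  # ... but qualifies when min_prop_target is set very low
  expect_identical(
    classify_clade(make_clade(4, 0, 99, 4 / 29),
                   sort_criteria(min_prop_target = 0.1)),
    "EXCLUSIVE")
  # absent support counts as zero: fails any positive min_support
  expect_identical(
    classify_clade(make_clade(5, 0, NA, 1), sort_criteria(min_support = 1)),
    "NONE")
  expect_identical(classify_clade(make_clade(5, 0, NA, 1), d), "EXCLUSIVE")
  # a lone target tip is not a clade
  expect_identical(classify_clade(make_clade(1, 0, 99, 1), d), "NONE")
  # thresholds are inclusive and exact: 9/10 is exactly 0.9
  expect_identical(classify_clade(make_clade(9, 1, 99, 1), d),
                   "NON_EXCLUSIVE")
  expect_identical(
    classify_clade(make_clade(9, 1, 90, 1), sort_criteria(min_support = 90)),
    "NON_EXCLUSIVE")
  expect_identical(
    classify_clade(make_clade(9, 1, 89.9, 1),
                   sort_criteria(min_support = 90)),
    "NONE")
})

test_that("no clade is both Exclusive and Non-Exclusive, and raising any
           threshold never turns NONE into a hit", {
  set.seed(31)
  for (i in 1:200) {
    cl <- make_clade(sample(0:20, 1), sample(0:5, 1),
                     sample(c(NA, 0, 50, 90, 100), 1), stats::runif(1))
    base <- sort_criteria(min_support = sample(c(0, 50, 90), 1),
                          min_prop_target = stats::runif(1),
                          clade_exclusivity = stats::runif(1, 0, 0.99))
    tag <- classify_clade(cl, base)
    expect_true(tag %in% c("EXCLUSIVE", "NON_EXCLUSIVE", "NONE"))
    if (tag == "NONE") {
      stricter <- sort_criteria(
        min_support = base$min_support + 5,
        min_prop_target = min(1, base$min_prop_target + 0.1),
        clade_exclusivity = min(0.999, base$clade_exclusivity + 0.005))
      expect_identical(classify_clade(cl, stricter), "NONE")
    }
  }
})

test_that("classify_tree labels trees and keeps qualifying clades", {
  # all-target tree: All Exclusive (and hence Exclusive) regardless of
  # support on any single edge
  allt <- parse_tree("((Rho_a:1,Rho_b:1):1,(Rho_c:1,Rho_d:1):1);")
  cls <- classify_tree(allt, "Rho")
  expect_setequal(cls$labels, c("ALL_EXCLUSIVE", "EXCLUSIVE"))

  # the 30-leaf scenario: 29 targets, 24 of them in a support-99 exclusive
  # clade (24/29 ~ 0.83 >= 0.7) -> Exclusive
  tr <- interrupted_clade_tree(inside_targets = 24, interrupting = 0,
                               outside_nontargets = 6, support = 99)
  # five stray targets outside the clade: 29 targets in total
  stray <- paste0("Proteobacteria_o", 1:5)
  tr$tip.label[match(stray, tr$tip.label)] <-
    paste0("Rhodophyta_stray", 1:5)
  cls2 <- classify_tree(tr, "Rhodophyta",
                        sort_criteria(min_support = 90))
  expect_true("EXCLUSIVE" %in% cls2$labels)
  expect_false("ALL_EXCLUSIVE" %in% cls2$labels)
  top <- cls2$clades[1, ]
  expect_equal(top$n_target, 24L)
  expect_equal(top$n_nontarget, 0L)
  expect_equal(top$support, 99)

  # zero target leaves: valid, empty labels
  none <- classify_tree(allt, "Glaucophyta")
  expect_length(none$labels, 0L)
  expect_equal(nrow(none$clades), 0L)

  # clades_sorted filters both labels and retained clades
  ne_tree <- interrupted_clade_tree()
  only_e <- classify_tree(ne_tree, "Rhodophyta",
                          sort_criteria(min_support = 90,
                                        clades_sorted = "E"))
  expect_false("NON_EXCLUSIVE" %in% only_e$labels)
  expect_false(any(only_e$clades$tag == "NON_EXCLUSIVE"))
})

test_that("min_prop_target = 1 enforces strict target monophyly", {
  strict <- sort_criteria(min_prop_target = 1)
  # all 24 targets inside one clade -> passes
  tr <- interrupted_clade_tree(inside_targets = 24, interrupting = 0,
                               outside_nontargets = 6, support = 99)
  expect_true("EXCLUSIVE" %in% classify_tree(tr, "Rhodophyta", strict)$labels)
  # one stray target outside the clade -> fails
  tr$tip.label[tr$tip.label == "Proteobacteria_o1"] <- "Rhodophyta_stray"
  tr2 <- parse_tree(write_tree(tr))
  expect_false("EXCLUSIVE" %in%
                 classify_tree(tr2, "Rhodophyta", strict)$labels)
})

test_that("classification is invariant to the rooting of the input file", {
  set.seed(57)
  for (i in 1:8) {
    phy <- random_support_tree(sample(6:10, 1))
    # half the tips are targets
    n <- length(phy$tip.label)
    phy$tip.label <- paste0(
      sample(c(rep("Targetia_t", ceiling(n / 2)),
               rep("Othergroup_o", floor(n / 2)))), seq_len(n))
    crit <- sort_criteria(min_support = sample(c(0, 50), 1),
                          min_prop_target = 0.5)
    ref <- classify_tree(phy, "Targetia", crit)
    for (r in all_rootings(phy)) {
      expect_same_classification(classify_tree(r, "Targetia", crit), ref)
    }
  }
})
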