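---
title: "Methods: classifying unrooted trees by target clade composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying unrooted trees by target clade composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`cladesift` answers one question per tree file: does this tree contain a
strongly supported clade that unites the user's target taxa? A *target
leaf* is a tip whose label contains any of the user terms as an exact,
case-sensitive substring; terms must be pairwise non-nested (no term a
substring of another), since with substring semantics a nested pair
makes the query ambiguous.

No assumption about the root of the input file is made. A rooted Newick
file is only one drawing of an unrooted topology, so the unit of
assessment is the *bipartition*: removing one internal edge splits the
leaves into two disjoint sets, and both sides are candidate clades
carrying that edge's support. Assessing both sides is what makes the
classification invariant to the file's rooting; the test suite checks
this invariance exhaustively over all rootings of small trees, against a
brute-force oracle that re-roots with `ape::root(..., edgelabel = TRUE)`
and pools every rooted clade.

A candidate with `t` targets and `i` non-targets in a tree with `T`
targets in total is **Exclusive** when `i = 0`, `t >= 2`,
`support >= min_support` and `t/T >= min_prop_target`; it is
**Non-Exclusive** when `i >= 1`, `t/(t+i) >= clade_exclusivity` (hence
`< 1`), with the same support and `t/T` conditions. A tree is labelled
by the best evidence it contains, and is additionally **All Exclusive**
when every leaf is a target.

## Tunable parameters

* `min_support` (default 0, unitless, on the file's native scale):
  minimum support for a qualifying clade. Support is whatever the file
  records — bootstrap percentages (0–100), posterior probabilities
  (0–1), or similar — and is deliberately never rescaled: the user knows
  the scale of their own files, and rescaling silently would corrupt
  mixed-scale directories. Nodes without a (numeric) label count as
  support 0, so the default threshold of 0 lets unsupported clades
  qualify; raise it to the scale you actually use (e.g. 90 for
  bootstrap, 0.95 for posteriors).
* `min_prop_target` (default 0.7, proportion in [0, 1]): the fraction
  of *all* target leaves in the tree that the clade must contain. This
  is the whole-tree context guard: at 1.0 strict monophyly of the target
  group is enforced, at low values (e.g. 0.1) narrowly defined clades
  that strand most targets elsewhere qualify. 0.7 is a compromise
  default intended as guidance, not dogma.
* `clade_exclusivity` (default 0.9, proportion in [0, 1)): the minimum
  within-clade target fraction for a Non-Exclusive clade, i.e. at most
  `1 - clade_exclusivity` of the clade may be interrupting leaves. The
  value 1.0 is rejected by construction: with no interrupting leaves the
  clade is Exclusive, and accepting 1.0 would collapse the two
  categories.
* `clades_sorted` (default both `E` and `NE`): which clade families to
  search for; also controls which output subdirectories are created.

## Numerical choices

Threshold comparisons are inclusive (`>=`) and *exact* — no epsilon.
The compared quantities are small rationals (`23/24`, `9/10`), and an
epsilon would silently change boundary cases such as a within-clade
proportion of exactly 0.9. Candidate clades need at least two leaves: a
lone tip "uniting" the targets is biologically vacuous, so single-leaf
bipartition sides are never candidates, and a 3-tip unrooted tree
(which has no internal edge) can only be All Exclusive. When the rooted
file has a bifurcating root, its two child edges are one unrooted edge;
the candidate pair is emitted once, carrying whichever child-node
support is present (the larger if a malformed file states two different
values for the same split). Duplicate tip labels are legal and counted
per leaf, which keeps the proportion arithmetic consistent with leaf
counts.

## Batch sorting and the log

`sort_trees()` scans one directory non-recursively for files ending in
`extension` (default `.tre`), in lexicographic order for deterministic
output. List mode (`l`, the default) touches nothing; copy (`c`) and
move (`m`) relocate hits into `out_dir/Exclusive/`,
`out_dir/Exclusive/All_Exclusive/` and `out_dir/Non_Exclusive/` inside
the input directory. A tree carrying both an Exclusive and a
Non-Exclusive clade is filed under `Exclusive/` — one file, one location,
mirroring the All-Exclusive-inside-Exclusive nesting — while the log
records *all* of its qualifying clades. Where the contract was genuinely
open we chose: copy mode overwrites colliding destination files so that
re-running a job is idempotent, whereas move mode treats a collision as
an error; the log (`<out_dir>.log`, written in the input directory in
every mode, header always present) is tab-separated with a fixed column
order (`file`, `tag`, `support`, `n_target`, `n_nontarget`,
`prop_within`, `prop_of_tree_targets`, `leaves`), which is this
package's own layout decision. Unparseable files are recorded as
`SKIPPED` rows and the run continues, so one corrupt file cannot abort a
ten-thousand-tree screen.

## eNewick conversion

The extended Newick dialect handled here is exactly the support-value
placement variant: `):L[S]` instead of `)S:L`. Conversion is a single
byte-preserving rewrite, idempotent on standard Newick (returned
unchanged with a warning). A bracket that does not follow an internal
node's branch length is an error — in particular a bracket with no
preceding branch length, since the rule is defined only relative to a
branch length. Hybrid-node (`#H`) network syntax is rejected rather than
mis-parsed: phylogenetic networks are out of scope.

## What the simulator emulates — and what it does not

`simulate_tree(x)` reproduces the benchmark recipe used for scalability
and recovery testing: a random bifurcating base topology of
`round(1.05·x)` tips by random sequential addition (`ape::rtree`), one
internal clade of `round(0.2·x)` tips relabelled with the target term,
random permutation of the non-target labels, pruning of `round(0.05·x)`
random terminal branches external to the target clade (degree-2 nodes
suppressed, so the tip arithmetic is exact: `round(1.05x) − round(0.05x)
= x`), support `support_fill` (default 100) on every internal node, and
uniform branch lengths in (0, 1]. Negative controls simply omit the
target clade. Files are written in eNewick with a ground-truth manifest,
and `replicate_topology = TRUE` replicates one topology across the set
(a single technical replicate, the benchmark design), which is why a
whole positive set stands or falls together.

Choices the recipe left open, fixed here once: the base topology source
(uniform random addition — the sorting cost depends on the number of
trees and leaves, not on a particular shape), the uniform support fill
(real support values are irrelevant to recovery at `min_support = 0`
and configurable for threshold exercises), the non-target vocabulary (a
fixed list of lineage-like names, none containing the target term, so
no accidental substring hits), branch lengths rounded to 4 decimals
(keeps serialized files free of scientific notation), and the root node
carrying no support label — the root has no branch in the rooted
representation, and the bracket-after-branch-length rule has nowhere to
put a value for it.

What the simulator does *not* emulate: realistic sequence evolution,
heterogeneous support values, rogue taxa, or the label noise of
empirical datasets. A green recovery test therefore establishes that the
pipeline finds a clade that is present by construction and reports
nothing when it is absent — it says nothing about behaviour on noisy
empirical trees, which is governed by the thresholds above and must be
validated per study.

## Known limitations

* Newick and eNewick only — no NEXUS, PhyloXML or multi-tree files; one
  tree per file.
* Target matching is literal substring matching; no regular expressions.
* Directory scanning is flat (non-recursive) by design.
* Support values are compared on whatever scale the files use; mixing
  0–1 and 0–100 files in one run with a positive `min_support` is a
  user error the package cannot detect.
* The empirical comparison against other sorting tools requires external
  datasets and is out of scope here; the package's evidence is the
  simulated ground-truth recovery plus the property suite (rooting
  invariance, bipartition-oracle equivalence, round-trip identity,
  threshold monotonicity, file-count conservation), all computed by the
  tests themselves.
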