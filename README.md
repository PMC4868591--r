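# cladesift

Sorting phylogenetic trees by target clade composition.

## The problem

Phylogenomic pipelines routinely produce thousands of single-gene trees
that must be screened for a feature of interest — typically a strongly
supported clade uniting a set of "target" taxa, as evidence of monophyly
or of reticulate evolution such as lateral gene transfer (LGT).
`cladesift` classifies each tree in a directory by the clades it
contains, with two properties that distinguish it from naive clade
matching:

1. **No rooting assumption.** Every tree is treated as unrooted: for
   each internal edge, *both* leaf-set sides of the bipartition are
   assessed as candidate clades, and both share that edge's support
   value. The classification of a tree is therefore invariant to how the
   input file happens to be rooted.
2. **Whole-tree context.** A candidate clade is judged not only on its
   own composition and support but on the fraction of the tree's *total*
   target leaves it contains, so a narrowly defined clade that strands
   most targets elsewhere on the tree does not qualify.

## The classification rule

Let a tree have `T` target leaves in total (a leaf is a target when any
user term occurs as an exact, case-sensitive substring of its label).
For a candidate clade with `t` target and `i` non-target ("interrupting")
leaves and support `s`:

- **Exclusive (E):** `i = 0`, `t ≥ 2`, `s ≥ min_support`, and
  `t / T ≥ min_prop_target`.
- **Non-Exclusive (NE):** `i ≥ 1`,
  `t / (t + i) ≥ clade_exclusivity` (and necessarily `< 1`),
  `s ≥ min_support`, and `t / T ≥ min_prop_target`.
- **All Exclusive:** a tree whose *every* leaf is a target; a subset of
  the Exclusive trees, decided by leaf composition alone.

Defaults: `min_support = 0` (absent support counts as 0, native scale —
bootstrap 0–100 or posterior 0–1, never rescaled), `min_prop_target =
0.7`, `clade_exclusivity = 0.9` (values of 1.0 are rejected: a clade
with no interrupting leaves is Exclusive, not Non-Exclusive).

## Worked example

```r
library(cladesift)
tr <- parse_tree(paste0(
  "(((Rhodophyta_Gs:1,(Viridiplantae_At:1,Rhodophyta_Cm:1)95:1)99:1,",
  "Haptophyceae_Eh:1)97:1,(Cyanobacteria_Syn:1,Proteobacteria_Ec:1)88:1);"))
classify_tree(tr, "Rhodophyta,Viridiplantae",
              sort_criteria(min_support = 90, min_prop_target = 0.5))
```

```
Tree classification 
  tips: 6  targets: 3 
  labels: EXCLUSIVE 
  qualifying clades:
        tag support n_target n_nontarget prop_within prop_of_tree_targets
1 EXCLUSIVE      99        3           0           1            1.0000000
2 EXCLUSIVE      95        2           0           1            0.6666667
```

The support-99 clade holds all three targets and no interrupting leaf,
so the tree is labelled Exclusive; the support-95 sub-clade also
qualifies at `min_prop_target = 0.5` because it holds 2 of the 3
targets. At the default 0.7 only the first clade would qualify.

Batch sorting over a directory of simulated benchmark trees (100 leaves
each, a known 20-leaf target clade embedded):

```r
d <- file.path(tempdir(), "demo")
simulate_set(x = 100, n = 10, out_dir = d, seed = 42,
             replicate_topology = FALSE)
unlink(file.path(d, "manifest.tsv"))
sort_trees("Targetia", in_dir = d, mode = "l")
```

```
Tree sorting report (mode: l )
  Exclusive trees:      10 
  ... All Exclusive:    0 
  Non-Exclusive trees:  6 
  log: /tmp/.../demo/Sorted_Trees.log 
```

All ten trees contain the embedded Exclusive clade; six additionally
carry a Non-Exclusive clade (the target clade plus one adjacent
non-target leaf — at 20/21 ≈ 0.95 it clears the 0.9 exclusivity bound,
and every simulated edge has support 100). With `mode = "m"` or `"c"`
the hits are relocated into
`Sorted_Trees/Exclusive/`, `Sorted_Trees/Exclusive/All_Exclusive/` and
`Sorted_Trees/Non_Exclusive/`; in every mode a tab-separated per-clade
log `Sorted_Trees.log` is written next to the input files:

```
file	tag	support	n_target	n_nontarget	prop_within	prop_of_tree_targets	leaves
tree_0001.tre	NON_EXCLUSIVE	100	20	1	0.9523809524	1.00	Targetia_taxon1;...;Amoebozoa_sp65
tree_0001.tre	EXCLUSIVE	100	20	0	1.0000000000	1.00	Targetia_taxon1;...;Targetia_taxon20
```

## Extended Newick conversion

Standard Newick stores a node's support as an internal node label before
the colon (`)95:0.3`); the extended Newick (eNewick) dialect emitted by
some inference programs brackets it after the branch length
(`):0.3[95]`). `convert_enewick()` rewrites the latter to the former;
`parse_tree()` auto-detects the dialect. Hybrid-node network syntax
(`#H` tags) is out of scope and rejected.

```r
convert_enewick("((A:1,B:1):0.5[90],C:1);")
#> [1] "((A:1,B:1)90:0.5,C:1);"
```

## Command line

An `Rscript` front end is installed at `exec/cladesift`:

```sh
cladesift sort --targets "Rhodophyta,Viridiplantae" --in-dir trees \
    --min-support 90 --min-prop-target 1.0 --clades E
cladesift convert --in tree.etre --out tree.tre
cladesift simulate --x 100 --n 1000 --seed 7 --out-dir bench
```

Sorting defaults to non-destructive list mode; moves require an explicit
`--mode m`. Exit status 0 means success (zero hits included), 2 a
usage/validation error, 1 a fatal runtime error.

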