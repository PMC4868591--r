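Package: cladesift
Title: Sorting Phylogenetic Trees by Target Clade Composition
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens directories of phylogenetic trees for strongly
    supported clades uniting user-defined target taxa. Trees are treated
    as unrooted: both leaf-set sides of every internal edge are assessed
    as candidate clades, and each tree is classified as containing
    Exclusive clades (target leaves only), All Exclusive (every leaf a
    target), or Non-Exclusive clades (a bounded fraction of interrupting
    non-target leaves). Qualifying tree files can be listed, copied, or
    moved into a structured output directory with a per-clade log.
    Includes a converter from extended Newick (support values bracketed
    after branch lengths) to standard Newick, a seeded benchmark tree
    simulator that embeds a known exclusive target clade, and a
    command-line interface for batch automation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 3.5.0)
Imports:
    ape,
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
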