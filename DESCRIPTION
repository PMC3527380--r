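Package: mtparsimony
Title: Maximum-Parsimony Analysis of Human Mitochondrial Haplogroups with
    Minimality Certificates and Rho-Based Founder Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rCRS-anchored analysis of complete human mitochondrial
    genomes: alignment masking and parsimony-informative site reports, exact
    Fitch/Sankoff tree scoring, heuristic most-parsimonious tree search by
    stepwise addition and tree bisection-reconnection, partition-based lower
    bounds that certify global minimality of a parsimony score, branch-by-branch
    mutation mapping with transition/transversion and synonymous/non-synonymous
    annotation against the revised Cambridge Reference Sequence coordinate
    frame, rho-statistic founder-age (TMRCA) estimation under a synonymous
    molecular clock, and a coalescent/star-genealogy sequence simulator so
    every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
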