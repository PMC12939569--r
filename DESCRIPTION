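Package: pepprospect
Title: In Silico Prospecting of ACE-Inhibitory Peptides from Collagen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for computer-aided discovery of
    angiotensin-converting-enzyme (ACE) inhibitory peptides from collagen
    alpha-chains. Simulates single- and multi-enzyme proteolysis under a
    cleavage-specificity rule grammar, profiles precursors and hydrolysates
    against a reference database of bioactive peptides (occurrence frequency
    A and theoretical degree of hydrolysis), runs a candidate filter cascade
    (novelty, toxicity/allergenicity, classifier activity votes, docking
    energy versus a reference ligand) with a full audit trail, computes a
    physicochemical property panel (molecular weight, net charge,
    isoelectric point, hydrophobicity), and performs a network-pharmacology
    hub-gene consensus over eight topological centralities plus
    hypergeometric enrichment. Ships a synthetic-data generator that plants
    known peptides, annotation outcomes and network hubs with ground truth
    so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
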