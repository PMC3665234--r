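Package: ctnpharm
Title: Compound-Target Network Pharmacology for Herbal Prescriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Network-pharmacology workflow for multi-constituent herbal
    prescriptions: formula-level metabolite candidate enumeration with
    monoisotopic mass matching of LC-MS features, Tanimoto fingerprint
    screening of constituents against an ATC- and target-annotated drug
    library, information-content (Lin) similarity of ATC codes and target
    therapeutic similarity, bipartite compound-target network construction,
    degree and clustering summaries with Cytoscape-compatible export,
    two-sided hypergeometric annotation enrichment, and docking-score
    threshold triage. Ships a synthetic-data generator with known ground
    truth for recovery benchmarking, and packaged fixtures for the
    Yuanhu Zhitong prescription (constituents, observed metabolite
    features, docking scores).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
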