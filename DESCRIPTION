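Package: gbaNet
Title: Guilt-by-Association Prioritization of Disease Candidate Proteins
        in Weighted Protein-Protein Interaction Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Constructs disease-specific protein-protein interaction
        networks by nearest-neighbor expansion from seed proteins, weights
        every interaction by both its database confidence and a Gene
        Ontology functional similarity (information-content based Resnik,
        Lin or relevance term measures combined by best-match average),
        and ranks candidate proteins by a guilt-by-association disease
        relevance score that rewards in-network neighbors and penalizes
        promiscuous out-of-network connections.  Includes leave-one-out
        cross-validation with rank-ratio ROC/AUC, an (alpha, beta) grid
        search for the score's weighting constants, hypergeometric
        gene-set enrichment of top-ranked candidates, seed-set overlap
        reports, a fully seeded synthetic-study generator with a planted
        disease module, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph, yaml, optparse
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 'utils.R' 'AllClasses.R' 'io.R' 'similarity.R' 'network.R'
        'score.R' 'evaluation.R' 'grid.R' 'simulate.R' 'cli.R'
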