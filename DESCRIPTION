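Package: GOcondense
Title: Redundancy Reduction and Semantic Summarization of Gene Ontology Term Lists
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Condenses long lists of Gene Ontology (GO) terms, such as the output
    of functional-enrichment analyses, by clustering semantically similar terms
    and selecting cluster representatives guided by user-supplied p-values or
    enrichments. Implements information content from annotation corpora (GAF or
    frequency tables), the four most-informative-common-ancestor similarity
    measures (Resnik, Lin, Jiang-Conrath, SimRel), a greedy redundancy-reduction
    algorithm with dispensability and uniqueness scores, multidimensional
    scaling layouts for semantic scatterplots, thresholded similarity graphs
    with XGMML/GraphML export, treemap supercluster hierarchies, and keyword
    (tag-cloud) statistics. Ships a synthetic ontology/annotation generator so
    the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: GO, Annotation, Clustering, Visualization
RoxygenNote: 7.3.3
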