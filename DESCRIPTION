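Package: orabench
Title: Benchmarking Gene Ontology Overrepresentation Results by Semantic Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the biological informativeness of Gene Ontology (GO)
    overrepresentation-analysis results rather than their raw statistics. Parses
    OBO ontologies and GAF/GMT annotations into a typed directed acyclic graph
    with true-path annotation propagation; provides a reference
    overrepresentation engine (hypergeometric and EASE statistics,
    Benjamini-Hochberg correction, minimum-gene filtering); computes Wang's
    graph-based semantic similarity between terms; scores any enrichment tool's
    output against known target terms via a semantic-similarity confusion
    matrix (accuracy, false-positive rate), target identification and ranking,
    and top-k term-specificity profiles (annotation size, ontology depth);
    clusters enriched terms with Markov Clustering over the Wang-similarity
    network; and generates miniature synthetic ontologies, annotations, and
    planted-target benchmark gene lists so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
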