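Package: acealign
Title: Ontology Alignment with an Adaptive Compact Evolutionary Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns pairs of biological and environmental ontologies (class
    hierarchies with labels, e.g. ENVO, SWEET, PTO, FLOPO subsets) by searching
    the space of 0-1 aligning matrices with a compact evolutionary algorithm.
    Candidate alignments are scored with reference-free quality metrics (the
    harmonic mean of a normalized alignment size and the mean correspondence
    confidence), entity confidences come from a hybrid lexical similarity that
    combines thesaurus synonymy with character n-gram matching, and
    subsumption-based contradiction reasoning against high-confidence anchor
    mappings prunes the search space. Multiple probability matrices are
    maintained adaptively to escape local optima. Includes readers for OWL
    RDF/XML class hierarchies and a plain tabular dialect, an OAEI
    Alignment-format writer, a synthetic benchmark generator with known
    reference alignments, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
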