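Package: sbol3
Title: SBOL3 Genetic Design Data Model, RDF Serialization, Validation and Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An implementation of the Synthetic Biology Open Language version 3
    (SBOL3) data standard for multi-scale biological designs. Provides the
    ontology-backed object model (Component, Sequence, the Feature hierarchy,
    Interactions, Constraints, Interfaces and the other top-level classes), a
    bidirectional mapping to an RDF graph with Turtle, N-Triples, JSON-LD and
    RDF/XML serializations, a structural validator with a stable rule registry,
    an evaluation engine for identity and Allen-interval sequence constraints,
    converters from GenBank, FASTA and SBOL2-style documents, programmatic
    builders for reference genetic designs (auto-regulatory device, toggle
    switch, multicellular sender/receiver system, CRISPRi NOR gate,
    combinatorial promoter library), and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
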