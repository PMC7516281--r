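# sbol3 — the SBOL3 genetic design data model in R

Engineered biological designs are more than annotated sequences: a genetic
toggle switch is two transcription units *plus* the mutual repression
between them; a sender/receiver consortium is two cell types *plus* the
signalling molecule they share. Flat formats (FASTA, GenBank, GFF) cannot
carry that functional and multi-scale information, which is what the
Synthetic Biology Open Language version 3 (SBOL3) — an RDF-based community
data standard — was designed for. This package is an R implementation of
SBOL3 for anyone who needs to build, validate, exchange or migrate such
design descriptions: tool builders, registry maintainers, and synthetic
biologists scripting their design workflows.

What it provides:

* **The object model.** The ten main top-level classes
  (`Component`, `Sequence`, `CombinatorialDerivation`, `Implementation`,
  `Experiment`, `ExperimentalData`, `Model`, `Collection`, `Attachment`,
  PROV-O `Activity`) plus the `Namespace` utility class, the five Feature
  subtypes (`SubComponent`, `SequenceFeature`, `LocalSubComponent`,
  `ExternallyDefined`, `ComponentReference`), Locations (`Range` with
  1-based inclusive coordinates, `Cut`, `EntireSequence`), Interactions,
  Constraints and Interfaces. A single `Component` holds structure and
  function together; identity follows the required
  `<namespace>/<displayId>` URI scheme, with `rewrite_namespace()` for
  relocating documents.
* **RDF graph I/O.** `to_graph()`/`from_graph()` plus lossless
  serialization to Turtle, canonical (sorted) N-Triples, JSON-LD and
  RDF/XML; foreign annotations and unknown extension classes survive round
  trips.
* **A validator.** Twenty structural and vocabulary rules with stable ids
  (`SBOL3-URI-001`, ...), deterministic ordered findings, lenient/strict
  modes, and offline ontology-term checks against shipped SO/SBO/GO
  subsets.
* **A constraint engine.** The identity / sequential / topological
  restriction vocabularies; `allen_relation()` classifies integer ranges
  into the Allen interval relations under the discrete convention
  `meets(a, b) ⇔ a.end + 1 = b.start`, and `evaluate_constraint()` decides
  `holds` / `violated` / `notEvaluable` from the available ground data.
* **Converters.** GenBank import/export (feature-table-identical round
  trip, `complement`/`join`/fuzzy locations), FASTA import, and an SBOL2 →
  SBOL3 migrator that collapses the SBOL2 ModuleDefinition/MapsTo
  "explode" pattern into the unified Component representation.
* **Reference designs** (`sbol_fixtures()`): an auto-regulatory unit, the
  genetic toggle switch, a multicellular AHL sender/receiver system, a
  CRISPRi NOR gate and a combinatorial promoter library — all built in
  code, deterministic, and validating cleanly.
* **A CLI** (`inst/cli/sbol3-tools`, or `sbol_cli()` from R): `validate`,
  `convert`, `stats`, `check`, `rewrite-ns`, `fixtures`.

## A worked example

Build the NOR-gate design — one Component with four SubComponents (two
gRNA inputs, the regulated DNA region, the gRNA output) and an Interface —
then validate and serialize it:

```r
library(sbol3)

doc <- build_nor_gate()
doc
#> SBOL3 document: 6 top-level object(s)
#>   sbol_component: 5
#>   sbol_sequence: 1

gate <- document_lookup(doc, "http://example.com/norgate/nor_gate")
gate
#> <sbol_component> http://example.com/norgate/nor_gate
#>   displayId: nor_gate
#>   features: 4  interactions: 0  constraints: 0

length(gate$interface$inputs)   # the two gRNA inputs
#> [1] 2
length(gate$interface$outputs)  # the single gRNA output
#> [1] 1

validate_document(doc)
#> 0 finding(s)

cat(substr(serialize_sbol(doc, "turtle"), 1, 320))
#> @prefix sbol: <http://sbols.org/v3#> .
#> @prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
#> @prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
#> @prefix prov: <http://www.w3.org/ns/prov#> .
#>
#> <http://example.com/norgate/gRNA_in1>
#>     a sbol:Component ;
#>     sbol:displayId "gRNA_in1" ;
#>     sbol:hasNamespace <http://example.com/norgate> ...
```

The six top-level objects are the gate, its three gRNA Components, the
regulated DNA region and that region's Sequence; the `0 finding(s)` line
means every structural rule passes. Constraints are evaluated rather than
just stored — in the multicellular fixture the `verifyIdentical` constraint
linking the sender's and receiver's AHL features resolves both sides to
the same ChEBI record:

```r
check_all(build_multicellular_system())$status
#> [1] "holds"        "notEvaluable" "notEvaluable"

allen_relation(loc_range("http://ex/s", 1, 5), loc_range("http://ex/s", 6, 10))
#> [1] "meets"
```

(The two `notEvaluable` rows are the topological cell-contains-AHL
constraints: representable and vocabulary-checked, but there is no
geometry to compute them from.)

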