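---
title: "The SBOL3 data model in R: design, validation and conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SBOL3 data model in R: design, validation and conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbol3)
```

## What this package models

The Synthetic Biology Open Language, version 3 (SBOL3), is an RDF-based
community standard for describing engineered biological designs across
scales — from a single promoter to multicellular systems of interacting
genetic circuits. Its central simplification over SBOL2 is that structure
and function live in one class: a single `Component` owns both the
structural parts (Features, optionally placed at Locations on a Sequence)
and the functional statements about them (Interactions between
participating Features, Constraints, an optional Interface). This package
implements that object model, its mapping to an RDF graph with four
concrete serializations, a structural validator, an evaluator for the
constraint system, and converters from GenBank, FASTA and SBOL2-style
documents.

The ten main top-level classes span the design–build–test–learn workflow:
`Component`, `Sequence` and `CombinatorialDerivation` describe designs;
`Implementation` stands for a physical artifact (a plasmid prep, a glycerol
stock); `Experiment` and `ExperimentalData` link test-stage data;
`Model` points at an external model file (e.g. SBML); `Collection`,
`Attachment` and the PROV-O `Activity` tie everything together.
`Namespace` is an additional utility class used only for identifier
management, which is why `sbol_top_level_types()` carries a `main` flag:
the registry holds eleven classes, ten of them main workflow classes.

## Identity

Every object is named by an absolute URI of the form
`<namespace>[/<local path>]/<displayId>`, with a `displayId` restricted to
`[A-Za-z_][A-Za-z0-9_]*`. Children extend their owner's URI by one
`/<displayId>` segment; the constructors assign child URIs at attachment
time, so the child-URI closure cannot be violated through the public API.
Three deliberate choices:

* **Versioning is not modelled.** Version segments embedded in a prefix
  (`.../toggleswitch/1/lacI`) or in a displayId (`lacI_1`) are accepted and
  never interpreted. The standard leaves version placement to tooling; the
  null position is the only one that round-trips all inputs losslessly.
* **Longest-prefix wins** when several registered namespaces match a URI in
  `decompose_uri()`, because it is the only deterministic choice.
* **ASCII URIs only.** Internationalized identifiers are rejected with a
  clear error rather than half-supported.

`rewrite_namespace()` rewrites the namespace portion of every URI and every
internal reference in a document, keeps local paths and displayIds, checks
for collisions, and is exactly invertible — the property the test suite
verifies on every fixture.

## The RDF mapping and its serializations

`to_graph()` emits one `rdf:type` triple per object and one triple per
field value, driven by a single schema table that both directions of the
mapping share. SBOL-owned object-valued properties use the `has...`
convention (`sbol:hasFeature`, `sbol:hasInteraction`); literal-valued and
reference properties are lowercase (`sbol:displayId`, `sbol:instanceOf`);
class IRIs start uppercase; and properties taken from external ontologies
keep their own names (`prov:wasDerivedFrom` is never aliased). A test
audits these conventions over the whole vocabulary. Annotations in foreign
namespaces are carried verbatim in both directions, and subjects whose
`rdf:type` is unknown survive as opaque extension objects, so third-party
data is never silently dropped.

Four serializations are supported: Turtle, N-Triples, JSON-LD and RDF/XML.
Numerical and formatting choices worth knowing:

* **Canonical N-Triples** (lexicographically sorted lines) is the normative
  diff format; `canonical_ntriples()` is stable across rebuilds of the same
  document, which makes documents version-control friendly.
* **JSON-LD** is written in flattened form with a single `@context`
  mapping the standard prefixes. The standard names JSON as a target
  without fixing a dialect; context-based flattened JSON-LD is this
  package's interpretation, chosen because generic RDF tools parse it
  unmodified (the test suite confirms this with an independent RDF stack).
* **Ordered lists.** RDF triples are unordered; the only ordered field in
  the model (`Component.sequences`) gets an explicit ordering annotation in
  a non-SBOL extension namespace, and only when it has more than one
  element.
* Everything is UTF-8; SBOL graphs contain no blank nodes, so graph
  isomorphism reduces to triple-set equality (`graph_isomorphic()`).

## Validation

`validate_document()` runs a fixed registry of twenty rules covering URI
structure, the child-URI closure, displayId syntax, type/role totality,
location sanity (including Range bounds against sequence length),
restriction-vocabulary membership, constraint and participation locality,
interface locality and disjointness, reference closure, combinatorial
derivation well-formedness, and document-wide URI uniqueness. Problems are
findings, never exceptions; all rules always run; the output order (subject
URI, then rule id) is deterministic.

Two rules are vocabulary *recommendations* rather than structural
requirements: Component types should come from the Systems Biology
Ontology or Gene Ontology, and roles from SO/SBO/GO. These produce
warnings in the default `lenient` mode and escalate to errors in `strict`
mode — the standard recommends but does not mandate the ontologies, so the
severity split is package policy, stated here explicitly. Term membership
is checked against small curated, versioned subsets of SO, SBO and GO
shipped with the package (`ontology_terms()`), not live lookups: validation
must work offline, and the subsets cover the terms the reference designs
need plus the common part roles. A term outside the subsets but inside an
ontology's identifiers.org namespace is accepted; only terms outside those
namespaces are flagged. An Interaction with no Participations carries no
information but is not forbidden by the standard, so it is a warning.

## Constraints and the discrete Allen relations

A `Constraint` links a subject and an object Feature through a restriction
from one of three closed families: identity (`verifyIdentical`,
`differentFrom`, `replaces`), sequential (the Allen interval relations plus
the two orientation relations) and topological (spatial relations between
physical regions — disjointness, containment, boundary contact). Where the
sequential and topological families share a name (`contains`,
`strictlyContains`, `meets`, `overlaps`) the IRIs are kept distinct by
prefixing the topological local name with `spatially`, because the two
meanings (positions on a shared linear sequence vs. physical space) must
not be conflated in a graph.

`allen_relation()` classifies an ordered pair of ranges under integer,
1-based, both-ends-inclusive coordinates. On integers two ranges cannot
share a boundary *point*, so adjacency is defined arithmetically:
`meets(a, b)` iff `a$end + 1 == b$start`, and `strictlyPrecedes` requires a
gap. The function returns one of **twelve mutually exclusive, jointly
exhaustive names** covering Allen's thirteen base relations: the eight
forward names (`strictlyPrecedes`, `meets`, `overlaps`, `starts`,
`finishes`, `equals`, `contains`, `strictlyContains`) and four inverses
(`precededBy`, `metBy`, `overlappedBy`, `during`). The name `contains`
deliberately folds the two base relations in which the subject contains the
object while sharing exactly one boundary (Allen's *startedBy* and
*finishedBy*); their converses are `starts` and `finishes`. The partition
and inversion properties are verified by exhaustively enumerating every
range pair with endpoints in 1..8 (1296 ordered pairs — small enough to be
instant, large enough that every relation class occurs many times) against
an independent oracle written in set arithmetic rather than endpoint
comparisons.

`precedes`, inherited from SBOL2, predates the refined Allen list and is
evaluated as the union `strictlyPrecedes ∪ meets` — the only reading
consistent with the refined relations. (The rejected alternative, treating
`precedes` as a primitive with its own geometry, would break the partition
property.) The restriction `contains` accepts both `contains` and
`strictlyContains` observations but not `equals`; sharing *both*
boundaries is identity of extent, not containment.

`evaluate_constraint()` computes what the ground data permits:
sequential restrictions need exactly one `Range` on each side (on the same,
non-circular sequence — circular topology is not modelled, so such
constraints come back `notEvaluable` rather than wrong); orientation
restrictions need `orientation` set on both features; `verifyIdentical`
resolves both features — through `ComponentReference` chains if necessary —
to a definition IRI and, when both definitions carry sequence elements,
also compares those; `differentFrom` is its negation. `replaces` is an
instruction to a derivation process, not a testable state, and the whole
topological family has no geometry to compute against; both are
representable, vocabulary-checked and reported `notEvaluable` with an
explanatory detail string.

## Converters

**GenBank.** Import maps a flat feature table onto one DNA-typed Component
(`SBO:0000251`), one Sequence, and one located `SequenceFeature` per table
row. Coordinates are copied verbatim: GenBank and this package share the
1-based inclusive convention, which is precisely what makes the
import/export round trip feature-table-identical. Supported location
dialects are `a..b`, a single base, `complement(...)` (becoming
reverse-complement orientation) and `join(...)` (multiple Ranges on one
feature); fuzzy `<a`/`>b` bounds are clamped to the sequence with a
warning; anything else is an explicit error rather than a guess. Feature
keys map to Sequence Ontology roles through a shipped table; unmapped keys
get the generic `sequence_feature` role plus a warning, and the original
key is retained as an annotation so export reproduces it. Export refuses
protein Components (GenBank export here is nucleotide-only) and omits
unlocated SubComponents with a warning, since a flat file has nowhere to
put them.

**FASTA.** Records become Sequences with residues upper-cased and the
encoding inferred from the alphabet (IUPAC DNA vs protein), with an
explicit override for ambiguous alphabets. File reading goes through
Biostrings.

**SBOL2 migration.** The migrator consumes a minimal snapshot covering
exactly the classes the mapping needs — ComponentDefinition,
ModuleDefinition, Sequence, component/functional-component instances,
SequenceAnnotation, MapsTo, Interaction — built in code or read from SBOL2
RDF/XML by `read_sbol2()` (a purpose-built reader, not a general SBOL2
library). Definitions become Components (ModuleDefinitions typed as
functional entities, `SBO:0000241`); instances become SubComponents;
SequenceAnnotations become locations on their linked part or standalone
SequenceFeatures; FunctionalComponent directions populate the Interface
(`in` → inputs, `out` → outputs, `inout` → both); trailing URI version
segments are folded into the namespace prefix; the SBOL2 `access` field has
no SBOL3 home and is dropped with a report entry.

The interesting case is MapsTo. SBOL2's separation of structure and
function forces the "explode" pattern: a module re-imports inner parts of
its instantiated definitions as module-level copies and declares each copy
identical to the original via MapsTo. When the migrator sees that pattern —
the MapsTo's remote end lives in a definition instantiated in the same
module — it *collapses* it: the exposed part is lifted to a single direct
SubComponent of the migrated module Component (named after the part, and
removed from the migrated definition so each element exists once), and
interaction participations are rewired to it. A MapsTo that does not fit
the pattern becomes a `ComponentReference`. The migration report accounts
for every input object and satisfies `MapsTo = collapsed + emitted
references`; on the toggle-switch example all four MapsTo links collapse
and the result contains zero ComponentReferences.

## The reference designs

`sbol_fixtures()` builds five deterministic documents (fixed URIs under
`http://example.com/...`, no randomness) that serve as the test corpus:

* an auto-regulatory transcription unit (promoter, RBS, CDS, terminator;
  one inhibition Interaction from the CDS to its own promoter);
* the genetic toggle switch, with all eight parts as direct SubComponents
  of one parent Component alongside the two mutual-repression Interactions.
  Nesting the two transcription units as opaque SubComponents *and* wiring
  the cross-unit repressions by direct participation are jointly
  impossible — a repressor in one unit targets a promoter in the other — so
  the fixture takes the flat composition, which is what lets every element
  appear exactly once with no identity-mapping objects;
* a multicellular sender/receiver system communicating via the
  quorum-signalling molecule AHL: subsystems carry the functional-
  compartment role (`SBO:0000289`), cell features are typed `GO:0005623`
  with the physical-compartment role (`SBO:0000290`), AHL appears in both
  subsystems as an `ExternallyDefined` feature pointing at its ChEBI
  record, containment is expressed with topological constraints, and a
  `verifyIdentical` constraint through two ComponentReferences states that
  both AHL instances are the same molecule (it evaluates to `holds`);
* a CRISPRi NOR gate: four SubComponents (two gRNA inputs, the regulated
  DNA region whose definition holds two binding sites, a promoter and the
  output-gRNA coding sequence, and the gRNA output) and an Interface with
  two inputs and one output;
* a combinatorial promoter library: a template whose promoter slot is a
  `LocalSubComponent` placeholder, bound by a `CombinatorialDerivation`
  with cardinality `one` to three promoter variants;
  `enumerate_derivation()` expands it to variant-product many designs.

Part sequences are short synthetic placeholders (18–51 nt, recognisable
consensus-like strings) so that Range arithmetic and sequence-length
validation are exercised without shipping real accessions. That is also
the honest limit of what passing tests show: the fixtures exercise the
*data model* — identity, ownership, serialization, validation, constraint
evaluation — not the biology. They contain no real sequence data, no
fuzzy annotations beyond the synthetic GenBank fixture's, and no
adversarial RDF from foreign tools; conformance of this package on them
does not imply every community-generated SBOL3 file parses.

## Degenerate inputs and numerical conventions

Ranges require `1 <= start <= end`; a cut position addresses the gap after
residue `at` with `at = 0` meaning "before the first residue". Zero-length
features are therefore expressed with `Cut`, never with an empty Range.
Empty documents serialize to empty (but valid) files in all four formats.
`document_lookup()` signals absence with `NULL`, not an error; reference
*resolution* (`resolve_reference()`) errors on dangling links and detects
cycles by tracking the chain. Sub-sequence excision on SubComponents
("sourceLocations") is not implemented; locations place whole features
only.

## Known limitations

* Topological constraints are representable and validated but never
  evaluated; there is no spatial model.
* Constraint checking is exactly that — checking; there is no constraint
  solver or design repair.
* `enumerate_derivation()` handles cardinalities `one` and `zeroOrOne` and
  direct variant sets; unbounded cardinalities and variant collections /
  nested derivations are rejected explicitly.
* The SBOL2 reader covers the migration surface only; SBOL1 import, export
  back to SBOL2, and GFF3 are out of scope.
* The Turtle parser covers the common subset this package and mainstream
  tools emit (prefixes, qnames, literals with datatypes, punctuation,
  comments, bare integers), not the full grammar (no multi-line literals,
  collections or blank-node property lists — the SBOL3 mapping produces
  none of these).
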