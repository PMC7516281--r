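# Programmatic builders for the reference designs used as the test corpus:
# an auto-regulatory transcription unit, the Gardner toggle switch, a
# multicellular AHL sender/receiver system, a CRISPRi NOR gate and a
# combinatorial promoter library template. All fixtures are deterministic
# (fixed URIs and placeholder sequences, no randomness) and validate with
# zero errors.

# short synthetic placeholder part sequences (20-60 nt) so Range invariants
# are exercised without real accessions
.PART_SEQS <- c(
  promoter   = "TTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGC",
  rbs        = "AAAGAGGAGAAATACTAG",
  cds        = "ATGGTGAGCAAGGGCGAGGAGCTGTTCACCGGGGTGGTGCCCATCCTGGTC",
  terminator = "CCAGGCATCAAATAAAACGAAAGGCTCAGTCGAAAGACTGGGCCTTTCGTT"
)

.part_component <- function(ns, displayId, role_name, seq_letters) {
  terms <- ontology_terms()
  s <- sbol_sequence(ns, paste0(displayId, "_seq"), elements = seq_letters,
                     encoding = ENCODING_IUPAC_DNA)
  cmp <- sbol_component(ns, displayId, types = terms$SBO[["dna"]],
                        roles = terms$SO[[role_name]], sequences = s$uri)
  list(component = cmp, sequence = s)
}

# add a device component composed of the given parts laid out contiguously on
# a device-level sequence; returns list(doc, component, feature_uris)
.compose_device <- function(doc, ns, displayId, parts, roles) {
  terms <- ontology_terms()
  elements <- paste(vapply(parts, function(p) p$sequence$elements, character(1)),
                    collapse = "")
  dev_seq <- sbol_sequence(ns, paste0(displayId, "_seq"), elements = elements,
                           encoding = ENCODING_IUPAC_DNA)
  dev <- sbol_component(ns, displayId, types = terms$SBO[["dna"]],
                        roles = roles, sequences = dev_seq$uri)
  pos <- 1L
  for (p in parts) {
    len <- nchar(p$sequence$elements)
    sc <- sub_component(p$component$displayId,
                        instanceOf = p$component$uri,
                        roles = p$component$roles,
                        orientation = "inline",
                        locations = loc_range(dev_seq$uri, pos, pos + len - 1L))
    dev <- add_feature(dev, sc)
    pos <- pos + len
  }
  doc <- doc_add(doc, dev_seq)
  list(doc = doc, component = dev, sequence = dev_seq)
}

.add_parts <- function(doc, parts) {
  for (p in parts) {
    doc <- doc_add(doc, p$sequence)
    doc <- doc_add(doc, p$component)
  }
  doc
}

#' Auto-regulatory device fixture
#'
#' One transcription unit (promoter, RBS, CDS, terminator as SubComponents
#' located on the unit's sequence) in which the transcription factor encoded
#' by the CDS represses its own promoter, captured by a single inhibition
#' Interaction between the CDS and promoter features.
#'
#' @return an `sbol_document`.
#' @export
build_autoregulatory_device <- function() {
  ns <- "http://example.com/autoreg"
  terms <- ontology_terms()
  parts <- list(
    .part_component(ns, "pReg", "promoter", .PART_SEQS[["promoter"]]),
    .part_component(ns, "rbs1", "ribosome_entry_site", .PART_SEQS[["rbs"]]),
    .part_component(ns, "repR", "CDS", .PART_SEQS[["cds"]]),
    .part_component(ns, "term1", "terminator", .PART_SEQS[["terminator"]])
  )
  doc <- sbol_document()
  doc <- .add_parts(doc, parts)
  dev <- .compose_device(doc, ns, "autoreg_device", parts,
                         roles = terms$SO[["engineered_region"]])
  doc <- dev$doc
  cmp <- dev$component
  furi <- function(id) cmp$features[[id]]$uri
  cmp <- add_interaction(cmp, "autorepression",
                         types = terms$SBO[["inhibition"]],
                         participations = list(
                           list(roles = terms$SBO[["inhibitor"]],
                                participant = furi("repR")),
                           list(roles = terms$SBO[["inhibited"]],
                                participant = furi("pReg"))))
  doc_add(doc, cmp)
}

#' Toggle-switch fixture
#'
#' The classic two-gene mutual-repression switch. Structure and function
#' co-exist in one parent Component: the eight parts (two promoters, two
#' RBSs, the lacI and tetR CDSs, two terminators) are direct SubComponents
#' located on the switch sequence, and the two repression Interactions
#' (lacI represses pLac's partner promoter circuitry and vice versa)
#' reference those SubComponents directly — every element of the system
#' appears exactly once and no identity-mapping objects (ComponentReferences)
#' are needed.
#'
#' @return an `sbol_document`.
#' @export
build_toggle_switch <- function() {
  ns <- "http://example.com/toggleswitch"
  terms <- ontology_terms()
  parts <- list(
    .part_component(ns, "pTet", "promoter", .PART_SEQS[["promoter"]]),
    .part_component(ns, "rbs_lacI", "ribosome_entry_site", .PART_SEQS[["rbs"]]),
    .part_component(ns, "lacI", "CDS", .PART_SEQS[["cds"]]),
    .part_component(ns, "term_lacI", "terminator", .PART_SEQS[["terminator"]]),
    .part_component(ns, "pLac", "promoter", .PART_SEQS[["promoter"]]),
    .part_component(ns, "rbs_tetR", "ribosome_entry_site", .PART_SEQS[["rbs"]]),
    .part_component(ns, "tetR", "CDS", .PART_SEQS[["cds"]]),
    .part_component(ns, "term_tetR", "terminator", .PART_SEQS[["terminator"]])
  )
  doc <- sbol_document()
  doc <- .add_parts(doc, parts)
  dev <- .compose_device(doc, ns, "toggle_switch", parts,
                         roles = terms$SO[["engineered_region"]])
  doc <- dev$doc
  cmp <- dev$component
  furi <- function(id) cmp$features[[id]]$uri
  # LacI (expressed from pTet) represses pLac; TetR (from pLac) represses pTet
  cmp <- add_interaction(cmp, "lacI_represses_pLac",
                         types = terms$SBO[["inhibition"]],
                         participations = list(
                           list(roles = terms$SBO[["inhibitor"]],
                                participant = furi("lacI")),
                           list(roles = terms$SBO[["inhibited"]],
                                participant = furi("pLac"))))
  cmp <- add_interaction(cmp, "tetR_represses_pTet",
                         types = terms$SBO[["inhibition"]],
                         participations = list(
                           list(roles = terms$SBO[["inhibitor"]],
                                participant = furi("tetR")),
                           list(roles = terms$SBO[["inhibited"]],
                                participant = furi("pTet"))))
  doc_add(doc, cmp)
}

AHL_CHEBI <- "https://identifiers.org/CHEBI:55474"  # N-acyl homoserine lactone

.cell_system_component <- function(ns, displayId) {
  terms <- ontology_terms()
  cmp <- sbol_component(ns, displayId,
                        types = terms$SBO[["functional_entity"]],
                        roles = terms$SBO[["functional_compartment"]])
  cell <- local_sub_component("cell", types = terms$GO[["cell"]],
                              roles = terms$SBO[["physical_compartment"]])
  ahl <- externally_defined("AHL", types = terms$SBO[["simple_chemical"]],
                            definition = AHL_CHEBI)
  cmp <- add_feature(cmp, cell)
  cmp <- add_feature(cmp, ahl)
  # spatial structure: the cell contains the signalling molecule
  add_constraint(cmp, "cell_contains_AHL",
                 restriction = restriction_vocabulary()$topological[["contains"]],
                 subject = cmp$features[["cell"]]$uri,
                 object = cmp$features[["AHL"]]$uri)
}

#' Multicellular sender/receiver fixture
#'
#' Two cell-scale subsystems communicating through the small molecule AHL.
#' Each subsystem Component carries the functional-compartment role
#' (SBO:0000289) and contains a cell feature typed GO:0005623 (cell) with
#' the physical-compartment role (SBO:0000290) plus an ExternallyDefined AHL
#' feature pointing at its ChEBI record; spatial containment is expressed
#' with topological constraints. The overall system Component holds sender
#' and receiver SubComponents, reaches their AHL features through
#' ComponentReferences, and asserts with a verifyIdentical Constraint that
#' the two AHL instances are the same molecule.
#'
#' @return an `sbol_document`.
#' @export
build_multicellular_system <- function() {
  ns <- "http://example.com/multicellular"
  terms <- ontology_terms()
  sender <- .cell_system_component(ns, "sender_system")
  receiver <- .cell_system_component(ns, "receiver_system")
  system <- sbol_component(ns, "multicellular_system",
                           types = terms$SBO[["functional_entity"]])
  system <- add_feature(system, sub_component("sender", instanceOf = sender$uri))
  system <- add_feature(system, sub_component("receiver", instanceOf = receiver$uri))
  system <- add_feature(system, component_reference(
    "AHL_from_sender", inChildOf = system$features[["sender"]]$uri,
    refersTo = sender$features[["AHL"]]$uri))
  system <- add_feature(system, component_reference(
    "AHL_at_receiver", inChildOf = system$features[["receiver"]]$uri,
    refersTo = receiver$features[["AHL"]]$uri))
  system <- add_constraint(system, "shared_AHL",
                           restriction = "verifyIdentical",
                           subject = system$features[["AHL_from_sender"]]$uri,
                           object = system$features[["AHL_at_receiver"]]$uri)
  sbol_document(sender, receiver, system)
}

#' CRISPRi NOR-gate fixture
#'
#' A NOR logic gate as one Component with four SubComponents: two gRNA
#' inputs, the regulated DNA region (whose definition comprises two gRNA
#' binding sites, a promoter and the output-gRNA coding sequence as located
#' SequenceFeatures) and the gRNA output. The gate's Interface declares the
#' two inputs and one output.
#'
#' @return an `sbol_document`.
#' @export
build_nor_gate <- function() {
  ns <- "http://example.com/norgate"
  terms <- ontology_terms()
  grna <- function(id) sbol_component(ns, id, types = terms$SBO[["rna"]],
                                      roles = terms$SO[["sgRNA"]])
  in1 <- grna("gRNA_in1"); in2 <- grna("gRNA_in2"); out <- grna("gRNA_out")

  gate_elements <- paste0("AATTCCGG", "GGCCAATT",
                          .PART_SEQS[["promoter"]],
                          "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGC")
  gate_seq <- sbol_sequence(ns, "gate_dna_seq", elements = gate_elements,
                            encoding = ENCODING_IUPAC_DNA)
  gate_dna <- sbol_component(ns, "gate_dna", types = terms$SBO[["dna"]],
                             roles = terms$SO[["engineered_region"]],
                             sequences = gate_seq$uri)
  plen <- nchar(.PART_SEQS[["promoter"]])
  spans <- list(site1 = c(1L, 8L), site2 = c(9L, 16L),
                promoter = c(17L, 16L + plen),
                gRNA_out_cds = c(17L + plen, nchar(gate_elements)))
  roles <- c(site1 = "protein_binding_site", site2 = "protein_binding_site",
             promoter = "promoter", gRNA_out_cds = "sgRNA")
  for (id in names(spans)) {
    gate_dna <- add_feature(gate_dna, sequence_feature(
      id, locations = loc_range(gate_seq$uri, spans[[id]][1], spans[[id]][2]),
      roles = terms$SO[[roles[[id]]]]))
  }

  gate <- sbol_component(ns, "nor_gate", types = terms$SBO[["functional_entity"]])
  gate <- add_feature(gate, sub_component("input1", instanceOf = in1$uri))
  gate <- add_feature(gate, sub_component("input2", instanceOf = in2$uri))
  gate <- add_feature(gate, sub_component("dna_region", instanceOf = gate_dna$uri))
  gate <- add_feature(gate, sub_component("output", instanceOf = out$uri))
  gate <- set_interface(gate,
                        inputs = c(gate$features[["input1"]]$uri,
                                   gate$features[["input2"]]$uri),
                        outputs = gate$features[["output"]]$uri)
  sbol_document(in1, in2, out, gate_seq, gate_dna, gate)
}

#' Combinatorial promoter-library template fixture
#'
#' A transcription-unit template whose promoter position is a
#' LocalSubComponent placeholder ("put a promoter in this location"), bound
#' by a CombinatorialDerivation to three concrete promoter variants with
#' cardinality one.
#'
#' @return an `sbol_document`.
#' @export
build_combinatorial_template <- function() {
  ns <- "http://example.com/library"
  terms <- ontology_terms()
  gfp <- .part_component(ns, "gfp", "CDS", .PART_SEQS[["cds"]])
  template <- sbol_component(ns, "tu_template", types = terms$SBO[["dna"]],
                             roles = terms$SO[["engineered_region"]])
  template <- add_feature(template, local_sub_component(
    "promoter_slot", types = terms$SBO[["dna"]],
    roles = terms$SO[["promoter"]]))
  template <- add_feature(template, sub_component("gfp",
                                                  instanceOf = gfp$component$uri))
  variants <- lapply(c("pTac", "pTrc", "pBad"), function(id)
    .part_component(ns, id, "promoter", .PART_SEQS[["promoter"]]))
  cd <- combinatorial_derivation(ns, "promoter_library",
                                 template = template$uri,
                                 strategy = "enumerate")
  cd <- add_variable_feature(cd, "promoter_choice",
                             variable = template$features[["promoter_slot"]]$uri,
                             cardinality = "one",
                             variants = vapply(variants, function(v)
                               v$component$uri, character(1)))
  doc <- sbol_document()
  doc <- .add_parts(doc, c(list(gfp), variants))
  doc <- doc_add(doc, template)
  doc_add(doc, cd)
}

#' All fixtures as a named list
#'
#' @return named list of `sbol_document`s.
#' @export
sbol_fixtures <- function() {
  list(autoregulatory = build_autoregulatory_device(),
       toggle_switch = build_toggle_switch(),
       multicellular = build_multicellular_system(),
       nor_gate = build_nor_gate(),
       combinatorial = build_combinatorial_template())
}

#' Write the fixture corpus to disk
#'
#' @param dir output directory (created if needed).
#' @param format serialization format for the files.
#' @return invisibly, the written paths.
#' @export
export_fixtures <- function(dir, format = "turtle") {
  .check_format(format)
  ext <- c(turtle = "ttl", ntriples = "nt", jsonld = "jsonld",
           rdfxml = "rdf")[[format]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  fx <- sbol_fixtures()
  for (nm in names(fx)) {
    p <- file.path(dir, paste0(nm, ".", ext))
    write_sbol(fx[[nm]], p, format)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Enumerate a CombinatorialDerivation
#'
#' Expands the template by substituting each VariableFeature's placeholder
#' with its variants. Cardinalities `one` (exactly one variant) and
#' `zeroOrOne` (a variant or omission) are enumerable; unbounded
#' cardinalities are rejected. The number of derived designs is the product
#' of the per-variable choice counts.
#'
#' @param doc an `sbol_document` containing the derivation and its template.
#' @param cd an `sbol_combinatorial_derivation` or its URI.
#' @return list of derived `sbol_component`s (displayIds `<template>_v1`...).
#' @export
enumerate_derivation <- function(doc, cd) {
  if (is.character(cd)) cd <- document_lookup(doc, cd)
  stopifnot(inherits(cd, "sbol_combinatorial_derivation"))
  template <- document_lookup(doc, cd$template)
  if (is.null(template)) stop("template does not resolve: ", cd$template,
                              call. = FALSE)
  choices <- lapply(cd$variableFeatures, function(vf) {
    if (length(vf$variantCollections) || length(vf$variantDerivations))
      stop("only direct variants are enumerable", call. = FALSE)
    opts <- as.list(vf$variants)
    if (identical(vf$cardinality, CARDINALITY[["zeroOrOne"]]))
      opts <- c(opts, list(NA_character_))
    else if (!identical(vf$cardinality, CARDINALITY[["one"]]))
      stop("unbounded cardinality cannot be enumerated: ", vf$cardinality,
           call. = FALSE)
    list(variable = vf$variable, options = opts)
  })
  grid <- expand.grid(lapply(choices, function(ch) seq_along(ch$options)))
  out <- list()
  for (i in seq_len(max(1L, nrow(grid)))) {
    derived <- template
    derived$displayId <- paste0(template$displayId, "_v", i)
    derived$uri <- compose_uri(cd$namespace, derived$displayId)
    derived$derivedFrom <- c(template$uri, cd$uri)
    if (nrow(grid)) for (j in seq_along(choices)) {
      ch <- choices[[j]]
      pick <- ch$options[[grid[i, j]]]
      slot_id <- names(which(vapply(template$features, `[[`, character(1),
                                    "uri") == ch$variable))
      derived$features[[slot_id]] <- NULL
      if (!is.na(pick)) {
        derived <- add_feature(derived, sub_component(slot_id, instanceOf = pick))
      }
    }
    derived <- .assign_uris(derived, dirname_uri = NULL)
    out[[length(out) + 1L]] <- derived
  }
  out
}
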