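# One dedicated mutated document per validation rule, each violating exactly
# that rule (the one-fault-one-finding matrix). Objects are plain lists, so
# faults are injected by direct field mutation after construction.

.mut_ns <- "http://example.com/mut"
.mut_dna <- function() ontology_terms()$SBO[["dna"]]

rule_mutations <- function() {
  ns <- .mut_ns
  dna <- .mut_dna()
  so <- ontology_terms()$SO
  sbo <- ontology_terms()$SBO

  base_seq <- function() sbol_sequence(ns, "s1", elements = "ACGTACGTACGTACGTACGT")

  list(
    `SBOL3-URI-001` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp$namespace <- "http://other.org"
      sbol_document(cmp)
    },
    `SBOL3-URI-002` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_feature(cmp, local_sub_component("f1", types = dna))
      cmp$features[["f1"]]$uri <- paste0(cmp$uri, "/zzz")
      sbol_document(cmp)
    },
    `SBOL3-ID-001` = function() {
      s <- base_seq()
      s$displayId <- "1bad"
      s$uri <- paste0(ns, "/1bad")
      sbol_document(s)
    },
    `SBOL3-TYPE-001` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp$types <- character(0)
      sbol_document(cmp)
    },
    `SBOL3-TYPE-002` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_feature(cmp, local_sub_component("p", types = dna))
      cmp$features[["p"]]$types <- character(0)
      sbol_document(cmp)
    },
    `SBOL3-LOC-001` = function() {
      s <- base_seq()
      cmp <- sbol_component(ns, "c1", dna, sequences = s$uri)
      cmp <- add_feature(cmp, sequence_feature("sf", loc_range(s$uri, 1, 5),
                                               roles = so[["promoter"]]))
      cmp$features[["sf"]]$locations <- list()
      sbol_document(s, cmp)
    },
    `SBOL3-LOC-002` = function() {
      s <- base_seq()
      cmp <- sbol_component(ns, "c1", dna, sequences = s$uri)
      cmp <- add_feature(cmp, sequence_feature("sf", loc_range(s$uri, 1, 5),
                                               roles = so[["promoter"]]))
      cmp$features[["sf"]]$locations[[1]]$end <- 99L
      sbol_document(s, cmp)
    },
    `SBOL3-SEQ-001` = function() {
      s <- base_seq()
      s$encoding <- NULL
      sbol_document(s)
    },
    `SBOL3-RESTR-001` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_feature(cmp, local_sub_component("f1", types = dna))
      cmp <- add_feature(cmp, local_sub_component("f2", types = dna))
      cmp <- add_constraint(cmp, "k1", "precedes",
                            cmp$features[["f1"]]$uri, cmp$features[["f2"]]$uri)
      cmp$constraints[["k1"]]$restriction <- "http://ex/frobnicates"
      sbol_document(cmp)
    },
    `SBOL3-CONS-001` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_feature(cmp, local_sub_component("f1", types = dna))
      cmp <- add_feature(cmp, local_sub_component("f2", types = dna))
      cmp <- add_constraint(cmp, "k1", "precedes",
                            cmp$features[["f1"]]$uri, cmp$features[["f2"]]$uri)
      cmp$constraints[["k1"]]$object <- cmp$constraints[["k1"]]$subject
      sbol_document(cmp)
    },
    `SBOL3-PART-001` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_feature(cmp, local_sub_component("f1", types = dna))
      cmp <- add_interaction(cmp, "i1", sbo[["inhibition"]],
                             list(list(roles = sbo[["inhibitor"]],
                                       participant = cmp$features[["f1"]]$uri)))
      cmp$interactions[["i1"]]$participations[[1]]$participant <-
        "http://other.org/elsewhere"
      sbol_document(cmp)
    },
    `SBOL3-INT-001` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_interaction(cmp, "i1", sbo[["inhibition"]], list())
      sbol_document(cmp)
    },
    `SBOL3-IFACE-001` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_feature(cmp, local_sub_component("f1", types = dna))
      cmp <- set_interface(cmp, inputs = cmp$features[["f1"]]$uri)
      cmp$interface$inputs <- "http://other.org/elsewhere"
      sbol_document(cmp)
    },
    `SBOL3-CREF-001` = function() {
      defA <- sbol_component(ns, "defA", dna)
      defA <- add_feature(defA, local_sub_component("x", types = dna))
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_feature(cmp, sub_component("sc", instanceOf = defA$uri))
      # refersTo resolves in the document but is not a feature of defA
      cmp <- add_feature(cmp, component_reference(
        "cr", inChildOf = cmp$features[["sc"]]$uri, refersTo = defA$uri))
      sbol_document(defA, cmp)
    },
    `SBOL3-REF-001` = function() {
      cmp <- sbol_component(ns, "c1", dna)
      cmp <- add_feature(cmp, sub_component("sc",
                                            instanceOf = paste0(ns, "/missing")))
      sbol_document(cmp)
    },
    `SBOL3-CD-001` = function() {
      template <- sbol_component(ns, "tpl", dna)
      template <- add_feature(template, local_sub_component(
        "slot", types = dna, roles = so[["promoter"]]))
      variant <- sbol_component(ns, "v1", dna, roles = so[["promoter"]])
      cd <- combinatorial_derivation(ns, "lib", template = template$uri)
      cd <- add_variable_feature(cd, "vf", template$features[["slot"]]$uri,
                                 variants = variant$uri)
      cd$variableFeatures[["vf"]]$variants <- character(0)
      sbol_document(template, variant, cd)
    },
    `SBOL3-NS-001` = function() {
      n <- sbol_namespace(paste0(ns, "ns"))
      n$uri <- paste0(n$uri, "/")
      sbol_document(n)
    },
    `SBOL3-DOC-001` = function() {
      c1 <- sbol_component(ns, "c1", dna)
      c2 <- sbol_component(ns, "c2", dna)
      doc <- sbol_document(c1, c2)
      doc$top_levels[[2]]$uri <- c1$uri
      doc$top_levels[[2]]$displayId <- "c1"
      doc
    },
    `SBOL3-VOCAB-001` = function() {
      cmp <- sbol_component(ns, "c1", "http://example.org/madeUpType")
      sbol_document(cmp)
    },
    `SBOL3-VOCAB-002` = function() {
      cmp <- sbol_component(ns, "c1", dna,
                            roles = "http://example.org/madeUpRole")
      sbol_document(cmp)
    }
  )
}
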