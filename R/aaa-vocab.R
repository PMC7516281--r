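# Namespaces, the class/property vocabulary driving RDF (de)serialization,
# restriction vocabularies, and curated ontology term subsets.

SBOL3_NS <- "http://sbols.org/v3#"
RDF_NS   <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
XSD_NS   <- "http://www.w3.org/2001/XMLSchema#"
PROV_NS  <- "http://www.w3.org/ns/prov#"

sbol <- function(local) paste0(SBOL3_NS, local)
prov <- function(local) paste0(PROV_NS, local)
xsd  <- function(local) paste0(XSD_NS, local)
RDF_TYPE <- paste0(RDF_NS, "type")

#' Default prefix map used by serializers
#' @return named character vector mapping prefix to namespace IRI
#' @export
sbol_prefixes <- function() {
  c(sbol = SBOL3_NS, rdf = RDF_NS, xsd = XSD_NS, prov = PROV_NS)
}

## ---- Top-level class registry -------------------------------------------

# The data model's TopLevel classes. `main` marks the ten main classes of the
# design-build-test-learn workflow; Namespace is a utility class.
.top_level_registry <- data.frame(
  class = c("sbol_component", "sbol_sequence", "sbol_combinatorial_derivation",
            "sbol_implementation", "sbol_experiment", "sbol_experimental_data",
            "sbol_model", "sbol_collection", "sbol_attachment", "sbol_activity",
            "sbol_namespace"),
  type_iri = c(sbol("Component"), sbol("Sequence"), sbol("CombinatorialDerivation"),
               sbol("Implementation"), sbol("Experiment"), sbol("ExperimentalData"),
               sbol("Model"), sbol("Collection"), sbol("Attachment"),
               paste0(PROV_NS, "Activity"), sbol("Namespace")),
  main = c(rep(TRUE, 10), FALSE),
  stringsAsFactors = FALSE
)

#' Registry of TopLevel classes
#'
#' The SBOL3 data model has ten main top-level classes covering the
#' design-build-test-learn workflow (Component, Sequence,
#' CombinatorialDerivation, Implementation, Experiment, ExperimentalData,
#' Model, Collection, Attachment, Activity) plus the Namespace utility class.
#'
#' @param main_only if TRUE, return only the ten main workflow classes.
#' @return data.frame with columns `class`, `type_iri`, `main`.
#' @export
sbol_top_level_types <- function(main_only = FALSE) {
  if (main_only) .top_level_registry[.top_level_registry$main, , drop = FALSE]
  else .top_level_registry
}

## ---- Serialization schema ------------------------------------------------

# One entry per concrete class. Fields:
#   pred : predicate IRI
#   kind : "literal" | "int" | "iri" | "child"
#   many : logical (repeated values allowed)
# Order of fields is the order triples are emitted (before canonical sorting).
.f <- function(pred, kind, many = FALSE) list(pred = pred, kind = kind, many = many)

.identified_fields <- list(
  displayId   = .f(sbol("displayId"), "literal"),
  name        = .f(sbol("name"), "literal"),
  description = .f(sbol("description"), "literal"),
  derivedFrom = .f(prov("wasDerivedFrom"), "iri", TRUE),
  generatedBy = .f(prov("wasGeneratedBy"), "iri", TRUE)
)
.top_level_fields <- c(.identified_fields, list(
  namespace = .f(sbol("hasNamespace"), "iri")
))
.feature_fields <- c(.identified_fields, list(
  roles       = .f(sbol("role"), "iri", TRUE),
  orientation = .f(sbol("orientation"), "iri")
))
.location_fields <- c(.identified_fields, list(
  sequence = .f(sbol("hasSequence"), "iri")
))

.sbol_schema <- list(
  sbol_component = list(
    type_iri = sbol("Component"),
    fields = c(.top_level_fields, list(
      types        = .f(sbol("type"), "iri", TRUE),
      roles        = .f(sbol("role"), "iri", TRUE),
      sequences    = .f(sbol("hasSequence"), "iri", TRUE),
      models       = .f(sbol("hasModel"), "iri", TRUE),
      features     = .f(sbol("hasFeature"), "child", TRUE),
      interactions = .f(sbol("hasInteraction"), "child", TRUE),
      constraints  = .f(sbol("hasConstraint"), "child", TRUE),
      interface    = .f(sbol("hasInterface"), "child")
    ))
  ),
  sbol_sequence = list(
    type_iri = sbol("Sequence"),
    fields = c(.top_level_fields, list(
      elements = .f(sbol("elements"), "literal"),
      encoding = .f(sbol("encoding"), "iri")
    ))
  ),
  sbol_sub_component = list(
    type_iri = sbol("SubComponent"),
    fields = c(.feature_fields, list(
      instanceOf = .f(sbol("instanceOf"), "iri"),
      locations  = .f(sbol("hasLocation"), "child", TRUE)
    ))
  ),
  sbol_sequence_feature = list(
    type_iri = sbol("SequenceFeature"),
    fields = c(.feature_fields, list(
      locations = .f(sbol("hasLocation"), "child", TRUE)
    ))
  ),
  sbol_local_sub_component = list(
    type_iri = sbol("LocalSubComponent"),
    fields = c(.feature_fields, list(
      types = .f(sbol("type"), "iri", TRUE)
    ))
  ),
  sbol_externally_defined = list(
    type_iri = sbol("ExternallyDefined"),
    fields = c(.feature_fields, list(
      types      = .f(sbol("type"), "iri", TRUE),
      definition = .f(sbol("definition"), "iri")
    ))
  ),
  sbol_component_reference = list(
    type_iri = sbol("ComponentReference"),
    fields = c(.feature_fields, list(
      inChildOf = .f(sbol("inChildOf"), "iri"),
      refersTo  = .f(sbol("refersTo"), "iri")
    ))
  ),
  sbol_range = list(
    type_iri = sbol("Range"),
    fields = c(.location_fields, list(
      start = .f(sbol("start"), "int"),
      end   = .f(sbol("end"), "int")
    ))
  ),
  sbol_cut = list(
    type_iri = sbol("Cut"),
    fields = c(.location_fields, list(
      at = .f(sbol("at"), "int")
    ))
  ),
  sbol_entire_sequence = list(
    type_iri = sbol("EntireSequence"),
    fields = .location_fields
  ),
  sbol_interaction = list(
    type_iri = sbol("Interaction"),
    fields = c(.identified_fields, list(
      types          = .f(sbol("type"), "iri", TRUE),
      participations = .f(sbol("hasParticipation"), "child", TRUE)
    ))
  ),
  sbol_participation = list(
    type_iri = sbol("Participation"),
    fields = c(.identified_fields, list(
      roles       = .f(sbol("role"), "iri", TRUE),
      participant = .f(sbol("participant"), "iri")
    ))
  ),
  sbol_constraint = list(
    type_iri = sbol("Constraint"),
    fields = c(.identified_fields, list(
      restriction = .f(sbol("restriction"), "iri"),
      subject     = .f(sbol("subject"), "iri"),
      object      = .f(sbol("object"), "iri")
    ))
  ),
  sbol_interface = list(
    type_iri = sbol("Interface"),
    fields = c(.identified_fields, list(
      inputs         = .f(sbol("input"), "iri", TRUE),
      outputs        = .f(sbol("output"), "iri", TRUE),
      nondirectionals = .f(sbol("nondirectional"), "iri", TRUE)
    ))
  ),
  sbol_combinatorial_derivation = list(
    type_iri = sbol("CombinatorialDerivation"),
    fields = c(.top_level_fields, list(
      template         = .f(sbol("template"), "iri"),
      strategy         = .f(sbol("strategy"), "iri"),
      variableFeatures = .f(sbol("hasVariableFeature"), "child", TRUE)
    ))
  ),
  sbol_variable_feature = list(
    type_iri = sbol("VariableFeature"),
    fields = c(.identified_fields, list(
      variable           = .f(sbol("variable"), "iri"),
      cardinality        = .f(sbol("cardinality"), "iri"),
      variants           = .f(sbol("variant"), "iri", TRUE),
      variantCollections = .f(sbol("variantCollection"), "iri", TRUE),
      variantDerivations = .f(sbol("variantDerivation"), "iri", TRUE)
    ))
  ),
  sbol_implementation = list(
    type_iri = sbol("Implementation"),
    fields = c(.top_level_fields, list(
      built = .f(sbol("built"), "iri")
    ))
  ),
  sbol_experiment = list(
    type_iri = sbol("Experiment"),
    fields = c(.top_level_fields, list(
      members = .f(sbol("member"), "iri", TRUE)
    ))
  ),
  sbol_experimental_data = list(
    type_iri = sbol("ExperimentalData"),
    fields = c(.top_level_fields, list(
      attachments = .f(sbol("hasAttachment"), "iri", TRUE)
    ))
  ),
  sbol_model = list(
    type_iri = sbol("Model"),
    fields = c(.top_level_fields, list(
      source    = .f(sbol("source"), "iri"),
      language  = .f(sbol("language"), "iri"),
      framework = .f(sbol("framework"), "iri")
    ))
  ),
  sbol_collection = list(
    type_iri = sbol("Collection"),
    fields = c(.top_level_fields, list(
      members = .f(sbol("member"), "iri", TRUE)
    ))
  ),
  sbol_attachment = list(
    type_iri = sbol("Attachment"),
    fields = c(.top_level_fields, list(
      source        = .f(sbol("source"), "iri"),
      format        = .f(sbol("format"), "iri"),
      size          = .f(sbol("size"), "int"),
      hash          = .f(sbol("hash"), "literal"),
      hashAlgorithm = .f(sbol("hashAlgorithm"), "literal")
    ))
  ),
  sbol_activity = list(
    type_iri = paste0(PROV_NS, "Activity"),
    fields = c(.top_level_fields, list(
      types   = .f(sbol("type"), "iri", TRUE),
      endedAt = .f(prov("endedAtTime"), "literal"),
      usages  = .f(prov("qualifiedUsage"), "child", TRUE)
    ))
  ),
  sbol_usage = list(
    type_iri = paste0(PROV_NS, "Usage"),
    fields = c(.identified_fields, list(
      entity = .f(prov("entity"), "iri"),
      roles  = .f(sbol("role"), "iri", TRUE)
    ))
  ),
  sbol_namespace = list(
    type_iri = sbol("Namespace"),
    fields = .top_level_fields
  )
)

# rdf:type IRI -> R class
.type_to_class <- local({
  m <- vapply(.sbol_schema, function(s) s$type_iri, character(1))
  # prov:Usage and prov:Activity are distinct classes sharing the PROV namespace
  stats::setNames(names(m), m)
})

# Annotation predicate used to record the order of multi-valued ordered fields
# (only Component.sequences is ordered); lives outside the SBOL namespace.
SBOL3R_EXT_NS <- "http://rsbol.org/ext#"
PRED_ORDER <- paste0(SBOL3R_EXT_NS, "memberOrder")

## ---- Enumerations --------------------------------------------------------

ORIENTATION_INLINE  <- sbol("inline")
ORIENTATION_REVCOMP <- sbol("reverseComplement")

STRATEGY_ENUMERATE <- sbol("enumerate")
STRATEGY_SAMPLE    <- sbol("sample")

CARDINALITY <- c(one = sbol("one"), oneOrMore = sbol("oneOrMore"),
                 zeroOrMore = sbol("zeroOrMore"), zeroOrOne = sbol("zeroOrOne"))

ACTIVITY_TYPES <- c(design = sbol("design"), build = sbol("build"),
                    test = sbol("test"), learn = sbol("learn"))

ENCODING_IUPAC_DNA     <- "https://identifiers.org/edam:format_1207"
ENCODING_IUPAC_PROTEIN <- "https://identifiers.org/edam:format_1208"

## ---- Restriction vocabularies -------------------------------------------

#' Constraint restriction vocabularies
#'
#' Three closed families of restriction terms usable on a Constraint:
#' identity (verifyIdentical, differentFrom, replaces), sequential (the
#' Allen-interval relations over sequence positions, plus the orientation
#' relations), and topological (spatial relations between physical regions
#' without holes). Names shared between the sequential and topological
#' families are distinct IRIs: the topological homonyms carry a `spatially`
#' prefix in the IRI local name.
#'
#' @return named list of three named character vectors of IRIs.
#' @export
restriction_vocabulary <- function() {
  list(
    identity = c(verifyIdentical = sbol("verifyIdentical"),
                 differentFrom   = sbol("differentFrom"),
                 replaces        = sbol("replaces")),
    sequential = c(precedes         = sbol("precedes"),
                   strictlyPrecedes = sbol("strictlyPrecedes"),
                   meets            = sbol("meets"),
                   overlaps         = sbol("overlaps"),
                   contains         = sbol("contains"),
                   strictlyContains = sbol("strictlyContains"),
                   equals           = sbol("equals"),
                   finishes         = sbol("finishes"),
                   starts           = sbol("starts"),
                   sameOrientationAs     = sbol("sameOrientationAs"),
                   oppositeOrientationAs = sbol("oppositeOrientationAs")),
    topological = c(isDisjointFrom   = sbol("isDisjointFrom"),
                    strictlyContains = sbol("spatiallyStrictlyContains"),
                    contains         = sbol("spatiallyContains"),
                    meets            = sbol("spatiallyMeets"),
                    covers           = sbol("covers"),
                    overlaps         = sbol("spatiallyOverlaps"))
  )
}

.all_restrictions <- function() unlist(restriction_vocabulary(), use.names = FALSE)

## ---- Curated ontology term subsets --------------------------------------

.term <- function(ont, id) paste0("https://identifiers.org/", ont, ":", id)

#' Curated ontology term subsets used for vocabulary validation
#'
#' Small, versioned subsets of the Sequence Ontology (part roles), Systems
#' Biology Ontology (molecular species, interaction and participant types,
#' compartments) and Gene Ontology (cellular components) sufficient for the
#' designs this package models and validates. Membership checks are against
#' these shipped lists; no network lookup is performed.
#'
#' @return named list with elements `SO`, `SBO`, `GO` (named character IRIs).
#' @export
ontology_terms <- function() {
  list(
    SO = c(promoter            = .term("SO", "0000167"),
           ribosome_entry_site = .term("SO", "0000139"),
           CDS                 = .term("SO", "0000316"),
           terminator          = .term("SO", "0000141"),
           sequence_feature    = .term("SO", "0000110"),
           gene                = .term("SO", "0000704"),
           engineered_region   = .term("SO", "0000804"),
           origin_of_replication = .term("SO", "0000296"),
           primer_binding_site = .term("SO", "0005850"),
           operator            = .term("SO", "0000057"),
           protein_binding_site = .term("SO", "0000410"),
           sgRNA               = .term("SO", "0001998"),
           five_prime_UTR      = .term("SO", "0000204"),
           insulator           = .term("SO", "0000627")),
    SBO = c(dna                 = .term("SBO", "0000251"),
            rna                 = .term("SBO", "0000250"),
            protein             = .term("SBO", "0000252"),
            simple_chemical     = .term("SBO", "0000247"),
            noncovalent_complex = .term("SBO", "0000254"),
            functional_entity   = .term("SBO", "0000241"),
            physical_compartment  = .term("SBO", "0000290"),
            functional_compartment = .term("SBO", "0000289"),
            inhibition          = .term("SBO", "0000169"),
            stimulation         = .term("SBO", "0000170"),
            degradation         = .term("SBO", "0000179"),
            genetic_production  = .term("SBO", "0000589"),
            control             = .term("SBO", "0000168"),
            inhibitor           = .term("SBO", "0000020"),
            inhibited           = .term("SBO", "0000642"),
            stimulator          = .term("SBO", "0000459"),
            stimulated          = .term("SBO", "0000643"),
            template            = .term("SBO", "0000645"),
            product             = .term("SBO", "0000011"),
            reactant            = .term("SBO", "0000010"),
            modifier            = .term("SBO", "0000019"),
            modified            = .term("SBO", "0000644")),
    GO = c(cell               = .term("GO", "0005623"),
           cellular_component = .term("GO", "0005575"),
           membrane           = .term("GO", "0016020"),
           nucleus            = .term("GO", "0005634"))
  )
}

# prefix tests against the identifiers.org resolver namespaces
.is_term_of <- function(iri, ont) startsWith(iri, paste0("https://identifiers.org/", ont, ":"))

## ---- GenBank feature key <-> SO role map --------------------------------

.genbank_so_map <- c(
  promoter     = "promoter",
  RBS          = "ribosome_entry_site",
  CDS          = "CDS",
  terminator   = "terminator",
  gene         = "gene",
  misc_feature = "sequence_feature",
  rep_origin   = "origin_of_replication",
  primer_bind  = "primer_binding_site",
  protein_bind = "protein_binding_site",
  operator     = "operator",
  `5'UTR`      = "five_prime_UTR"
)

genbank_key_to_role <- function(key) {
  so <- ontology_terms()$SO
  nm <- .genbank_so_map[key]
  if (is.na(nm)) NA_character_ else unname(so[nm])
}

role_to_genbank_key <- function(role_iri) {
  so <- ontology_terms()$SO
  nm <- names(so)[match(role_iri, so)]
  if (length(nm) == 0 || is.na(nm)) return("misc_feature")
  key <- names(.genbank_so_map)[match(nm, .genbank_so_map)]
  if (is.na(key)) "misc_feature" else key
}
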