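# The SBOL3 object model: Identified/TopLevel base, Component and the Feature
# hierarchy, Locations, Interactions, Constraints, Interfaces, the remaining
# top-level classes, and the Document container.
#
# Objects are plain lists with S3 class vectors. Child objects are created
# detached (uri = NA) and receive their URI — <owner uri>/<displayId> — when
# attached to an owner, which keeps the child-URI closure invariant true by
# construction.

.CHILD_FIELDS <- c("features", "interactions", "constraints", "interface",
                   "locations", "participations", "variableFeatures", "usages")

.child_list_fields <- setdiff(.CHILD_FIELDS, "interface")

.new_identified <- function(class, displayId = NULL, name = NULL,
                            description = NULL, ...) {
  if (!is.null(displayId) && !validate_display_id(displayId))
    stop("invalid displayId: ", displayId, call. = FALSE)
  obj <- list(uri = NA_character_, displayId = displayId, name = name,
              description = description, derivedFrom = character(0),
              generatedBy = character(0), annotations = list(), ...)
  class(obj) <- c(class, .class_parents(class))
  obj
}

.class_parents <- function(class) {
  feature_classes <- c("sbol_sub_component", "sbol_sequence_feature",
                       "sbol_local_sub_component", "sbol_externally_defined",
                       "sbol_component_reference")
  location_classes <- c("sbol_range", "sbol_cut", "sbol_entire_sequence")
  top_classes <- .top_level_registry$class
  parents <- "sbol_identified"
  if (class %in% feature_classes) parents <- c("sbol_feature", parents)
  if (class %in% location_classes) parents <- c("sbol_location", parents)
  if (class %in% top_classes) parents <- c("sbol_top_level", parents)
  parents
}

# explicit name/description parameters: passing them through `...` would let
# R partially match `name` against `namespace`
.new_top_level <- function(class, namespace, displayId, name = NULL,
                           description = NULL) {
  obj <- .new_identified(class, displayId = displayId, name = name,
                         description = description)
  obj$uri <- compose_uri(namespace, displayId)
  obj$namespace <- namespace
  obj
}

.check_term_set <- function(x, what) {
  x <- unique(as.character(x))
  if (length(x) == 0) stop(what, " must be a non-empty set of term IRIs", call. = FALSE)
  if (!all(.is_absolute_iri(x)))
    stop(what, " must contain absolute IRIs", call. = FALSE)
  x
}

## ---- Top-level constructors ---------------------------------------------

#' Create a Component
#'
#' The universal SBOL3 design unit, covering every scale from a DNA part to a
#' multicellular system. Structure (features, sequences) and function
#' (interactions) co-exist in the same object.
#'
#' @param namespace absolute IRI prefix, no trailing slash.
#' @param displayId identifier matching `[A-Za-z_][A-Za-z0-9_]*`.
#' @param types non-empty set of ontology term IRIs (SBO for molecular
#'   species, e.g. `SBO:0000251` for DNA; GO for cells).
#' @param roles optional set of ontology term IRIs (SO part roles, SBO
#'   compartment roles, ...).
#' @param sequences optional ordered character vector of Sequence URIs.
#' @param name,description optional label / free text.
#' @return an object of class `sbol_component`.
#' @export
#' @examples
#' so <- ontology_terms()$SO; sbo <- ontology_terms()$SBO
#' cmp <- sbol_component("http://example.com/toggleswitch", "lacI", sbo[["dna"]],
#'                       roles = so[["CDS"]])
#' cmp$uri
sbol_component <- function(namespace, displayId, types, roles = character(0),
                           sequences = character(0), name = NULL,
                           description = NULL) {
  types <- .check_term_set(types, "Component types")
  obj <- .new_top_level("sbol_component", namespace, displayId,
                       name = name, description = description)
  obj$types <- types
  obj$roles <- unique(as.character(roles))
  obj$sequences <- as.character(sequences)
  obj$models <- character(0)
  obj$features <- list()
  obj$interactions <- list()
  obj$constraints <- list()
  obj$interface <- NULL
  obj
}

#' Create a Sequence
#'
#' @param namespace,displayId identity, as for [sbol_component()].
#' @param elements optional residue string.
#' @param encoding IRI naming the residue alphabet; required when `elements`
#'   is given. Defaults to IUPAC DNA when elements look like DNA.
#' @param name optional label.
#' @return an object of class `sbol_sequence`.
#' @export
sbol_sequence <- function(namespace, displayId, elements = NULL,
                          encoding = NULL, name = NULL) {
  obj <- .new_top_level("sbol_sequence", namespace, displayId, name = name)
  if (!is.null(elements)) {
    elements <- toupper(elements)
    if (is.null(encoding)) encoding <- .infer_encoding(elements)
    .check_elements(elements, encoding)
  }
  obj$elements <- elements
  obj$encoding <- encoding
  obj
}

.DNA_CHARS <- strsplit("ACGTURYSWKMBDHVN", "")[[1]]
.PROT_CHARS <- strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO*", "")[[1]]

.infer_encoding <- function(elements) {
  ch <- unique(strsplit(elements, "")[[1]])
  if (all(ch %in% c("A", "C", "G", "T", "U", "N"))) return(ENCODING_IUPAC_DNA)
  if (all(ch %in% .PROT_CHARS)) return(ENCODING_IUPAC_PROTEIN)
  stop("cannot infer sequence encoding from alphabet; pass `encoding`", call. = FALSE)
}

.check_elements <- function(elements, encoding) {
  legal <- switch(encoding,
                  "https://identifiers.org/edam:format_1207" = .DNA_CHARS,
                  "https://identifiers.org/edam:format_1208" = .PROT_CHARS,
                  NULL)
  if (is.null(legal)) return(invisible(TRUE)) # unknown encoding: no alphabet check
  ch <- unique(strsplit(elements, "")[[1]])
  bad <- setdiff(ch, legal)
  if (length(bad))
    stop("sequence elements contain characters illegal under the encoding: ",
         paste(bad, collapse = ""), call. = FALSE)
  invisible(TRUE)
}

#' @export
#' @rdname top_levels
sbol_namespace <- function(uri) {
  if (!.is_absolute_iri(uri) || endsWith(uri, "/"))
    stop("Namespace URI must be absolute with no trailing '/'", call. = FALSE)
  dec <- strsplit(uri, "/", fixed = TRUE)[[1]]
  obj <- .new_identified("sbol_namespace")
  obj$uri <- uri
  obj$namespace <- uri
  obj
}

#' Other top-level constructors
#'
#' Constructors for the build/test/learn and utility top-level classes:
#' Implementation (a physical artifact such as a plasmid sample), Experiment
#' and ExperimentalData (test-stage linkage), Model (external model file),
#' Collection, Attachment (external data file link), Activity (PROV-O
#' provenance record) and Namespace.
#'
#' @param namespace,displayId identity, as for [sbol_component()].
#' @param uri for `sbol_namespace`, the namespace IRI itself.
#' @param built,members,attachments,source,language,framework,format,size,hash,hashAlgorithm,types,usages,endedAt,name class-specific fields.
#' @name top_levels
NULL

#' @export
#' @rdname top_levels
sbol_implementation <- function(namespace, displayId, built = NULL, name = NULL) {
  obj <- .new_top_level("sbol_implementation", namespace, displayId, name = name)
  obj$built <- built
  obj
}

#' @export
#' @rdname top_levels
sbol_experiment <- function(namespace, displayId, members = character(0)) {
  obj <- .new_top_level("sbol_experiment", namespace, displayId)
  obj$members <- as.character(members)
  obj
}

#' @export
#' @rdname top_levels
sbol_experimental_data <- function(namespace, displayId, attachments = character(0)) {
  obj <- .new_top_level("sbol_experimental_data", namespace, displayId)
  obj$attachments <- as.character(attachments)
  obj
}

#' @export
#' @rdname top_levels
sbol_model <- function(namespace, displayId, source, language = NULL,
                       framework = NULL) {
  if (!.is_absolute_iri(source))
    stop("Model source must be an absolute IRI", call. = FALSE)
  obj <- .new_top_level("sbol_model", namespace, displayId)
  obj$source <- source
  obj$language <- language
  obj$framework <- framework
  obj
}

#' @export
#' @rdname top_levels
sbol_collection <- function(namespace, displayId, members = character(0),
                            name = NULL) {
  obj <- .new_top_level("sbol_collection", namespace, displayId, name = name)
  obj$members <- as.character(members)
  obj
}

#' @export
#' @rdname top_levels
sbol_attachment <- function(namespace, displayId, source, format = NULL,
                            size = NULL, hash = NULL, hashAlgorithm = NULL) {
  if (!.is_absolute_iri(source))
    stop("Attachment source must be an absolute IRI", call. = FALSE)
  if (!is.null(size) && size < 0) stop("Attachment size must be >= 0", call. = FALSE)
  obj <- .new_top_level("sbol_attachment", namespace, displayId)
  obj$source <- source; obj$format <- format
  obj$size <- if (is.null(size)) NULL else as.integer(size)
  obj$hash <- hash; obj$hashAlgorithm <- hashAlgorithm
  obj
}

#' @export
#' @rdname top_levels
sbol_activity <- function(namespace, displayId, types = character(0),
                          usages = list(), endedAt = NULL) {
  obj <- .new_top_level("sbol_activity", namespace, displayId)
  obj$types <- as.character(types)
  obj$endedAt <- endedAt  # RFC 3339 text
  obj$usages <- list()
  for (u in usages) {
    stopifnot(!is.null(u$entity))
    usage <- .new_identified("sbol_usage",
                             displayId = paste0("usage_", length(obj$usages) + 1L))
    usage$entity <- u$entity
    usage$roles <- unique(as.character(u$roles %||% character(0)))
    obj$usages[[usage$displayId]] <- usage
  }
  obj <- .assign_uris(obj, dirname_uri = NULL)
  obj
}

#' Create a CombinatorialDerivation
#'
#' A design pattern over a template Component in which variable features can
#' be bound to sets of variants.
#'
#' @param namespace,displayId identity.
#' @param template URI of the template Component.
#' @param strategy `"enumerate"`, `"sample"` or NULL.
#' @return an object of class `sbol_combinatorial_derivation`.
#' @export
combinatorial_derivation <- function(namespace, displayId, template,
                                     strategy = NULL) {
  if (!is.null(strategy))
    strategy <- switch(strategy, enumerate = STRATEGY_ENUMERATE,
                       sample = STRATEGY_SAMPLE,
                       stop("unknown strategy: ", strategy, call. = FALSE))
  obj <- .new_top_level("sbol_combinatorial_derivation", namespace, displayId)
  obj$template <- template
  obj$strategy <- strategy
  obj$variableFeatures <- list()
  obj
}

#' Add a VariableFeature to a CombinatorialDerivation
#'
#' @param cd an `sbol_combinatorial_derivation`.
#' @param displayId identifier for the new VariableFeature.
#' @param variable URI of a Feature of the template Component.
#' @param cardinality one of `"one"`, `"oneOrMore"`, `"zeroOrMore"`, `"zeroOrOne"`.
#' @param variants,variantCollections,variantDerivations URI sets; at least
#'   one must be non-empty.
#' @return the modified CombinatorialDerivation.
#' @export
add_variable_feature <- function(cd, displayId, variable, cardinality = "one",
                                 variants = character(0),
                                 variantCollections = character(0),
                                 variantDerivations = character(0)) {
  stopifnot(inherits(cd, "sbol_combinatorial_derivation"))
  card <- CARDINALITY[cardinality]
  if (is.na(card)) stop("unknown cardinality: ", cardinality, call. = FALSE)
  if (length(variants) + length(variantCollections) + length(variantDerivations) == 0)
    stop("a VariableFeature needs at least one variant, variant collection or variant derivation",
         call. = FALSE)
  vf <- .new_identified("sbol_variable_feature", displayId = displayId)
  vf$variable <- variable
  vf$cardinality <- unname(card)
  vf$variants <- as.character(variants)
  vf$variantCollections <- as.character(variantCollections)
  vf$variantDerivations <- as.character(variantDerivations)
  if (displayId %in% names(cd$variableFeatures))
    stop("duplicate VariableFeature displayId: ", displayId, call. = FALSE)
  vf <- .assign_uris(vf, cd$uri)
  cd$variableFeatures[[displayId]] <- vf
  cd
}

## ---- Features and locations ---------------------------------------------

.new_feature <- function(class, displayId, roles = character(0),
                         orientation = NULL, name = NULL) {
  if (!is.null(orientation))
    orientation <- switch(orientation,
                          inline = ORIENTATION_INLINE,
                          reverseComplement = ORIENTATION_REVCOMP,
                          stop("orientation must be 'inline' or 'reverseComplement'",
                               call. = FALSE))
  obj <- .new_identified(class, displayId = displayId, name = name)
  obj$roles <- unique(as.character(roles))
  obj$orientation <- orientation
  obj
}

#' Feature constructors
#'
#' Features are elements of interest within a Component and the unit that
#' Interactions and Constraints relate. Five subtypes exist:
#' \describe{
#'   \item{`sub_component`}{a hierarchical part-subpart relationship to a
#'     definition Component, optionally located on the parent's sequence.}
#'   \item{`sequence_feature`}{a located annotation (restriction site, -35
#'     box, ...) with no hierarchical existence; at least one location is
#'     mandatory.}
#'   \item{`local_sub_component`}{a placeholder defined only by its local
#'     relationships, e.g. a combinatorial template variable ("put a promoter
#'     here").}
#'   \item{`externally_defined`}{an element canonically defined outside SBOL,
#'     e.g. a ChEBI small molecule or UniProt protein.}
#'   \item{`component_reference`}{a reference through a SubComponent to a
#'     Feature of its definition, usable directly in Interactions and
#'     Constraints; chains across layers are allowed.}
#' }
#'
#' @param displayId identifier, unique among the future parent's children.
#' @param instanceOf,definition,types,roles,orientation,locations,inChildOf,refersTo,name subtype fields; see above.
#' @return a detached feature object; attach with [add_feature()].
#' @name features
NULL

#' @export
#' @rdname features
sub_component <- function(displayId, instanceOf, roles = character(0),
                          orientation = NULL, locations = list(), name = NULL) {
  if (!.is_absolute_iri(instanceOf))
    stop("instanceOf must be an absolute IRI", call. = FALSE)
  obj <- .new_feature("sbol_sub_component", displayId, roles, orientation, name)
  obj$instanceOf <- instanceOf
  obj$locations <- .name_locations(locations)
  obj
}

#' @export
#' @rdname features
sequence_feature <- function(displayId, locations, roles = character(0),
                             orientation = NULL, name = NULL) {
  locations <- .name_locations(locations)
  if (length(locations) == 0)
    stop("a SequenceFeature must be associated with at least one location",
         call. = FALSE)
  obj <- .new_feature("sbol_sequence_feature", displayId, roles, orientation, name)
  obj$locations <- locations
  obj
}

#' @export
#' @rdname features
local_sub_component <- function(displayId, types, roles = character(0),
                                orientation = NULL, name = NULL) {
  types <- .check_term_set(types, "LocalSubComponent types")
  obj <- .new_feature("sbol_local_sub_component", displayId, roles, orientation, name)
  obj$types <- types
  obj
}

#' @export
#' @rdname features
externally_defined <- function(displayId, types, definition,
                               roles = character(0), name = NULL) {
  types <- .check_term_set(types, "ExternallyDefined types")
  if (!.is_absolute_iri(definition))
    stop("definition must be an absolute IRI into an external database", call. = FALSE)
  obj <- .new_feature("sbol_externally_defined", displayId, roles,
                      orientation = NULL, name = name)
  obj$types <- types
  obj$definition <- definition
  obj
}

#' @export
#' @rdname features
component_reference <- function(displayId, inChildOf, refersTo,
                                roles = character(0), name = NULL) {
  obj <- .new_feature("sbol_component_reference", displayId, roles,
                      orientation = NULL, name = name)
  obj$inChildOf <- inChildOf
  obj$refersTo <- refersTo
  obj
}

#' Location constructors
#'
#' Locations place a Feature on a Sequence. `loc_range` uses 1-based,
#' both-ends-inclusive coordinates (GenBank-compatible); `loc_cut` addresses
#' the gap between residues `at` and `at + 1` (0-based, `at = 0` is before
#' the first residue); `loc_entire_sequence` spans the whole sequence.
#'
#' @param sequence URI of the Sequence the location refers to.
#' @param start,end,at integer coordinates.
#' @return a detached location object.
#' @name locations
NULL

#' @export
#' @rdname locations
loc_range <- function(sequence, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("Range requires 1 <= start <= end (got ", start, "..", end, ")",
         call. = FALSE)
  obj <- .new_identified("sbol_range")
  obj$sequence <- sequence; obj$start <- start; obj$end <- end
  obj
}

#' @export
#' @rdname locations
loc_cut <- function(sequence, at) {
  at <- as.integer(at)
  if (is.na(at) || at < 0L) stop("Cut position must be >= 0", call. = FALSE)
  obj <- .new_identified("sbol_cut")
  obj$sequence <- sequence; obj$at <- at
  obj
}

#' @export
#' @rdname locations
loc_entire_sequence <- function(sequence) {
  obj <- .new_identified("sbol_entire_sequence")
  obj$sequence <- sequence
  obj
}

.name_locations <- function(locations) {
  if (inherits(locations, "sbol_location")) locations <- list(locations)
  if (length(locations) == 0) return(list())
  for (i in seq_along(locations)) {
    if (!inherits(locations[[i]], "sbol_location"))
      stop("locations must be location objects", call. = FALSE)
    if (is.null(locations[[i]]$displayId))
      locations[[i]]$displayId <- paste0("loc_", i)
  }
  stats::setNames(locations, vapply(locations, `[[`, character(1), "displayId"))
}

## ---- URI assignment and ownership ---------------------------------------

.assign_uris <- function(obj, dirname_uri) {
  if (!is.null(dirname_uri)) {
    if (is.null(obj$displayId))
      stop("owned child objects need a displayId", call. = FALSE)
    obj$uri <- paste0(dirname_uri, "/", obj$displayId)
  }
  for (f in .child_list_fields) {
    if (length(obj[[f]]) == 0) next
    obj[[f]] <- lapply(obj[[f]], .assign_uris, dirname_uri = obj$uri)
  }
  if (!is.null(obj$interface))
    obj$interface <- .assign_uris(obj$interface, obj$uri)
  obj
}

# all owned descendants of obj (depth-first), as a flat list
sbol_children <- function(obj) {
  kids <- list()
  for (f in .child_list_fields) kids <- c(kids, unname(obj[[f]]))
  if (!is.null(obj$interface)) kids <- c(kids, list(obj$interface))
  kids
}

sbol_descendants <- function(obj) {
  out <- list()
  for (k in sbol_children(obj)) out <- c(out, list(k), sbol_descendants(k))
  out
}

.feature_displayIds <- function(component) names(component$features)

#' Add a Feature to a Component
#'
#' Attaches a detached feature; its URI becomes
#' `<component uri>/<displayId>`, and likewise for its owned locations.
#'
#' @param parent an `sbol_component`.
#' @param feature a detached feature from one of the [features] constructors.
#' @return the modified Component.
#' @export
add_feature <- function(parent, feature) {
  stopifnot(inherits(parent, "sbol_component"), inherits(feature, "sbol_feature"))
  did <- feature$displayId
  kids <- c(names(parent$features), names(parent$interactions),
            names(parent$constraints))
  if (did %in% kids)
    stop("duplicate child displayId in ", parent$uri, ": ", did, call. = FALSE)
  feature <- .assign_uris(feature, parent$uri)
  parent$features[[did]] <- feature
  parent
}

#' Add an Interaction to a Component
#'
#' @param parent an `sbol_component`.
#' @param displayId identifier for the interaction.
#' @param types non-empty set of SBO interaction-type IRIs (e.g. inhibition,
#'   `SBO:0000169`).
#' @param participations list of `list(roles =, participant =)` pairs, where
#'   `participant` is the URI of a Feature of `parent` and `roles` a
#'   non-empty set of SBO participant-role IRIs. May be empty (flagged by the
#'   validator as a warning, not an error).
#' @return the modified Component.
#' @export
add_interaction <- function(parent, displayId, types, participations = list()) {
  stopifnot(inherits(parent, "sbol_component"))
  types <- .check_term_set(types, "Interaction types")
  feature_uris <- vapply(parent$features, `[[`, character(1), "uri")
  ia <- .new_identified("sbol_interaction", displayId = displayId)
  ia$types <- types
  ia$participations <- list()
  for (i in seq_along(participations)) {
    p <- participations[[i]]
    roles <- .check_term_set(p$roles, "Participation roles")
    if (!(p$participant %in% feature_uris))
      stop("participant is not a feature of ", parent$uri, ": ", p$participant,
           call. = FALSE)
    part <- .new_identified("sbol_participation",
                            displayId = p$displayId %||% paste0(displayId, "_p", i))
    part$roles <- roles
    part$participant <- p$participant
    ia$participations[[part$displayId]] <- part
  }
  if (displayId %in% c(names(parent$features), names(parent$interactions),
                       names(parent$constraints)))
    stop("duplicate child displayId in ", parent$uri, ": ", displayId, call. = FALSE)
  ia <- .assign_uris(ia, parent$uri)
  parent$interactions[[displayId]] <- ia
  parent
}

#' Add a Constraint to a Component
#'
#' @param parent an `sbol_component`.
#' @param displayId identifier.
#' @param restriction IRI from [restriction_vocabulary()] (or one of its
#'   unqualified names, e.g. `"verifyIdentical"`, `"precedes"`).
#' @param subject,object URIs of two distinct Features of `parent`.
#' @return the modified Component.
#' @export
add_constraint <- function(parent, displayId, restriction, subject, object) {
  stopifnot(inherits(parent, "sbol_component"))
  restriction <- .resolve_restriction(restriction)
  feature_uris <- vapply(parent$features, `[[`, character(1), "uri")
  if (!(subject %in% feature_uris) || !(object %in% feature_uris))
    stop("constraint subject and object must be features of ", parent$uri,
         call. = FALSE)
  if (identical(subject, object))
    stop("constraint subject and object must differ", call. = FALSE)
  cn <- .new_identified("sbol_constraint", displayId = displayId)
  cn$restriction <- restriction
  cn$subject <- subject
  cn$object <- object
  if (displayId %in% c(names(parent$features), names(parent$interactions),
                       names(parent$constraints)))
    stop("duplicate child displayId in ", parent$uri, ": ", displayId, call. = FALSE)
  cn <- .assign_uris(cn, parent$uri)
  parent$constraints[[displayId]] <- cn
  parent
}

.resolve_restriction <- function(restriction) {
  if (.is_absolute_iri(restriction)) {
    if (!(restriction %in% .all_restrictions()))
      stop("restriction IRI outside the closed vocabulary: ", restriction,
           call. = FALSE)
    return(restriction)
  }
  for (fam in restriction_vocabulary()) {
    if (restriction %in% names(fam)) return(unname(fam[restriction]))
  }
  stop("unknown restriction: ", restriction, call. = FALSE)
}

#' Set the Interface of a Component
#'
#' Declares the Component's recommended interface as sets of its own
#' Features: inputs, outputs and non-directional features. A feature may be
#' both input and output (bidirectional), but a non-directional feature may
#' not also be directional. An entirely empty Interface is allowed; the
#' Interface itself is optional.
#'
#' @param parent an `sbol_component`.
#' @param inputs,outputs,nondirectionals character vectors of feature URIs of
#'   `parent`.
#' @return the modified Component, with `parent$interface` replaced.
#' @export
set_interface <- function(parent, inputs = character(0), outputs = character(0),
                          nondirectionals = character(0)) {
  stopifnot(inherits(parent, "sbol_component"))
  feature_uris <- vapply(parent$features, `[[`, character(1), "uri")
  refs <- c(inputs, outputs, nondirectionals)
  bad <- setdiff(refs, feature_uris)
  if (length(bad))
    stop("Interface references must be features of ", parent$uri, ": ",
         bad[1], call. = FALSE)
  if (length(intersect(nondirectionals, union(inputs, outputs))))
    stop("a feature may not be both non-directional and directional", call. = FALSE)
  ifc <- .new_identified("sbol_interface", displayId = "interface")
  ifc$inputs <- unique(as.character(inputs))
  ifc$outputs <- unique(as.character(outputs))
  ifc$nondirectionals <- unique(as.character(nondirectionals))
  ifc <- .assign_uris(ifc, parent$uri)
  parent$interface <- ifc
  parent
}

#' Attach an annotation in a foreign namespace
#'
#' Annotations are (property IRI, value) pairs in non-SBOL namespaces,
#' preserved verbatim through all operations and serializations.
#'
#' @param obj any SBOL object.
#' @param predicate absolute property IRI outside the SBOL namespace.
#' @param value the value.
#' @param type `"literal"` or `"iri"`.
#' @return the modified object.
#' @export
add_annotation <- function(obj, predicate, value, type = c("literal", "iri")) {
  type <- match.arg(type)
  if (!.is_absolute_iri(predicate) || startsWith(predicate, SBOL3_NS))
    stop("annotation predicates must be absolute IRIs outside the SBOL namespace",
         call. = FALSE)
  obj$annotations[[length(obj$annotations) + 1L]] <-
    list(predicate = predicate, value = as.character(value), type = type)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- Document ------------------------------------------------------------

#' Create a Document
#'
#' An in-memory set of top-level objects with URI-keyed lookup and a graph
#' view (see [to_graph()]).
#'
#' @param ... top-level objects to add.
#' @param prefixes named character vector of extra prefix -> namespace IRI
#'   entries for the serializers.
#' @return an object of class `sbol_document`.
#' @export
sbol_document <- function(..., prefixes = character(0)) {
  doc <- structure(list(top_levels = list(),
                        prefixes = c(sbol_prefixes(), prefixes),
                        extensions = list()),
                   class = "sbol_document")
  for (tl in list(...)) doc <- doc_add(doc, tl)
  doc
}

#' Add a top-level object to a Document
#'
#' @param doc an `sbol_document`.
#' @param top_level a TopLevel object.
#' @return the modified document.
#' @export
doc_add <- function(doc, top_level) {
  stopifnot(inherits(doc, "sbol_document"))
  if (!inherits(top_level, "sbol_top_level"))
    stop("only TopLevel objects can be added to a document", call. = FALSE)
  if (top_level$uri %in% names(doc$top_levels))
    stop("URI already present in document: ", top_level$uri, call. = FALSE)
  desc_uris <- vapply(sbol_descendants(top_level), `[[`, character(1), "uri")
  existing <- unlist(lapply(doc$top_levels, function(tl)
    c(tl$uri, vapply(sbol_descendants(tl), `[[`, character(1), "uri"))))
  dup <- intersect(c(top_level$uri, desc_uris), existing)
  if (length(dup))
    stop("URI already present in document: ", dup[1], call. = FALSE)
  doc$top_levels[[top_level$uri]] <- top_level
  doc
}

#' Look up any object in a Document by URI
#'
#' Searches top-level objects and all owned descendants.
#'
#' @param doc an `sbol_document`.
#' @param uri the URI to find.
#' @return the object, or NULL when absent.
#' @export
document_lookup <- function(doc, uri) {
  stopifnot(inherits(doc, "sbol_document"))
  tl <- doc$top_levels[[uri]]
  if (!is.null(tl)) return(tl)
  # children extend their owner's URI, so only matching-prefix top-levels
  # need traversal
  for (tl in doc$top_levels) {
    if (!startsWith(uri, paste0(tl$uri, "/"))) next
    for (d in sbol_descendants(tl)) if (identical(d$uri, uri)) return(d)
  }
  NULL
}

# every object in the document, URIs as names
document_objects <- function(doc) {
  out <- list()
  for (tl in doc$top_levels) out <- c(out, list(tl), sbol_descendants(tl))
  stats::setNames(out, vapply(out, `[[`, character(1), "uri"))
}

#' Resolve a ComponentReference to its ultimate concrete Feature
#'
#' Follows `inChildOf`/`refersTo` chains across any number of layers. The
#' chain may pass through further ComponentReferences; cycles and dangling
#' links are errors.
#'
#' @param doc an `sbol_document`.
#' @param ref an `sbol_component_reference` or its URI.
#' @return the concrete Feature object the chain ends at.
#' @export
resolve_reference <- function(doc, ref) {
  if (is.character(ref)) ref <- document_lookup(doc, ref)
  if (!inherits(ref, "sbol_component_reference"))
    stop("not a ComponentReference", call. = FALSE)
  seen <- character(0)
  while (inherits(ref, "sbol_component_reference")) {
    if (ref$uri %in% seen)
      stop("cycle in ComponentReference chain at ", ref$uri, call. = FALSE)
    seen <- c(seen, ref$uri)
    target <- document_lookup(doc, ref$refersTo)
    if (is.null(target))
      stop("dangling ComponentReference: ", ref$refersTo, " not found",
           call. = FALSE)
    ref <- target
  }
  if (!inherits(ref, "sbol_feature"))
    stop("ComponentReference chain did not end at a Feature", call. = FALSE)
  ref
}

# definition IRI a feature ultimately stands for (for identity constraints)
.feature_definition <- function(doc, feature) {
  if (inherits(feature, "sbol_component_reference"))
    feature <- resolve_reference(doc, feature)
  if (inherits(feature, "sbol_sub_component")) return(feature$instanceOf)
  if (inherits(feature, "sbol_externally_defined")) return(feature$definition)
  NA_character_
}

#' @export
print.sbol_document <- function(x, ...) {
  counts <- table(vapply(x$top_levels, function(tl) class(tl)[1], character(1)))
  cat("SBOL3 document:", length(x$top_levels), "top-level object(s)\n")
  for (nm in names(counts)) cat("  ", nm, ": ", counts[[nm]], "\n", sep = "")
  invisible(x)
}

#' @export
print.sbol_identified <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$uri, "\n", sep = "")
  if (!is.null(x$displayId)) cat("  displayId: ", x$displayId, "\n", sep = "")
  if (inherits(x, "sbol_component"))
    cat("  features: ", length(x$features),
        "  interactions: ", length(x$interactions),
        "  constraints: ", length(x$constraints), "\n", sep = "")
  invisible(x)
}

#' Count objects per class in a document
#'
#' @param doc an `sbol_document`.
#' @return data.frame with columns `class` and `count`, including descendants.
#' @export
document_stats <- function(doc) {
  objs <- document_objects(doc)
  cls <- vapply(objs, function(o) class(o)[1], character(1))
  all_classes <- c(.top_level_registry$class,
                   "sbol_sub_component", "sbol_sequence_feature",
                   "sbol_local_sub_component", "sbol_externally_defined",
                   "sbol_component_reference", "sbol_range", "sbol_cut",
                   "sbol_entire_sequence", "sbol_interaction",
                   "sbol_participation", "sbol_constraint", "sbol_interface",
                   "sbol_variable_feature", "sbol_usage")
  counts <- vapply(all_classes, function(k) sum(cls == k), integer(1))
  data.frame(class = all_classes, count = unname(counts),
             stringsAsFactors = FALSE)
}
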