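# Bidirectional mapping between the object model and an RDF triple set.
#
# Triples are held in a data.frame with columns subject / predicate / object /
# kind ("iri" or "literal") / dtype (datatype IRI or NA). Every SBOL object is
# IRI-named, so no blank nodes occur and graph isomorphism reduces to triple
# set equality.

.empty_triples <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), kind = character(0),
             dtype = character(0), stringsAsFactors = FALSE)
}

.triple <- function(s, p, o, kind = "iri", dtype = NA_character_) {
  data.frame(subject = s, predicate = p, object = o, kind = kind,
             dtype = dtype, stringsAsFactors = FALSE)
}

.rbind_triples <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(.empty_triples())
  do.call(rbind, lst)
}

XSD_INT <- paste0(XSD_NS, "integer")

.obj_triples <- function(obj) {
  cls <- class(obj)[1]
  schema <- .sbol_schema[[cls]]
  if (is.null(schema)) stop("no serialization schema for class ", cls, call. = FALSE)
  out <- list(.triple(obj$uri, RDF_TYPE, schema$type_iri))
  for (fname in names(schema$fields)) {
    fs <- schema$fields[[fname]]
    val <- obj[[fname]]
    if (is.null(val) || (is.character(val) && length(val) == 0)) next
    if (fs$kind == "child") {
      kids <- if (identical(fname, "interface")) list(val) else unname(val)
      for (k in kids) {
        out <- c(out, list(.triple(obj$uri, fs$pred, k$uri)), list(.obj_triples(k)))
      }
    } else if (fs$kind == "iri") {
      out <- c(out, list(.triple(obj$uri, fs$pred, as.character(val))))
      # ordered multi-valued reference lists keep their order via an
      # extension annotation when order is meaningful (length > 1)
      if (fname == "sequences" && length(val) > 1) {
        out <- c(out, list(.triple(obj$uri, PRED_ORDER,
                                   paste(val, collapse = " "),
                                   kind = "literal")))
      }
    } else if (fs$kind == "int") {
      out <- c(out, list(.triple(obj$uri, fs$pred, as.character(val),
                                 kind = "literal", dtype = XSD_INT)))
    } else {
      out <- c(out, list(.triple(obj$uri, fs$pred, as.character(val),
                                 kind = "literal")))
    }
  }
  for (ann in obj$annotations) {
    out <- c(out, list(.triple(obj$uri, ann$predicate, ann$value,
                               kind = if (identical(ann$type, "iri")) "iri" else "literal")))
  }
  .rbind_triples(out)
}

#' Map a Document to its RDF graph
#'
#' Emits one `rdf:type` triple per object, one triple per field value using
#' the property vocabulary (SBOL-owned ownership predicates are of the
#' `has...` form; external ontology terms such as `prov:wasDerivedFrom` keep
#' their own IRIs), and annotations verbatim.
#'
#' @param doc an `sbol_document`.
#' @return a triple data.frame with columns subject, predicate, object, kind,
#'   dtype.
#' @export
to_graph <- function(doc) {
  stopifnot(inherits(doc, "sbol_document"))
  out <- lapply(doc$top_levels, .obj_triples)
  # opaque extension objects (unknown top-level types) re-emit their triples
  out <- c(out, unname(doc$extensions))
  tr <- .rbind_triples(out)
  unique(tr)
}

#' Test two triple sets (or documents) for graph equality
#'
#' SBOL3 graphs contain no blank nodes, so RDF graph isomorphism reduces to
#' equality of the triple sets.
#'
#' @param a,b triple data.frames from [to_graph()], or `sbol_document`s.
#' @return TRUE/FALSE.
#' @export
graph_isomorphic <- function(a, b) {
  if (inherits(a, "sbol_document")) a <- to_graph(a)
  if (inherits(b, "sbol_document")) b <- to_graph(b)
  key <- function(t) {
    dt <- ifelse(is.na(t$dtype), "", t$dtype)
    sort(paste(t$subject, t$predicate, t$object, t$kind, dt, sep = "\r"))
  }
  identical(key(unique(a)), key(unique(b)))
}

## ---- Graph -> objects ----------------------------------------------------

.OWNERSHIP_PREDS <- c(sbol("hasFeature"), sbol("hasInteraction"),
                      sbol("hasConstraint"), sbol("hasInterface"),
                      sbol("hasLocation"), sbol("hasParticipation"),
                      sbol("hasVariableFeature"), prov("qualifiedUsage"))

# schema field name holding children arriving via a given ownership predicate,
# resolved per child class
.child_field_for <- function(child_cls) {
  switch(child_cls,
    sbol_sub_component = , sbol_sequence_feature = ,
    sbol_local_sub_component = , sbol_externally_defined = ,
    sbol_component_reference = "features",
    sbol_interaction = "interactions",
    sbol_constraint = "constraints",
    sbol_interface = "interface",
    sbol_range = , sbol_cut = , sbol_entire_sequence = "locations",
    sbol_participation = "participations",
    sbol_variable_feature = "variableFeatures",
    sbol_usage = "usages",
    stop("unexpected owned child class: ", child_cls, call. = FALSE))
}

.build_object <- function(uri, triples, by_subject, building = character(0)) {
  if (uri %in% building)
    stop("ownership cycle detected at ", uri, call. = FALSE)
  building <- c(building, uri)
  tr <- by_subject[[uri]]
  if (is.null(tr)) stop("no triples for subject ", uri, call. = FALSE)
  types <- tr$object[tr$predicate == RDF_TYPE & tr$kind == "iri"]
  cls <- .type_to_class[types]
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) stop("subject has no known rdf:type: ", uri, call. = FALSE)
  cls <- cls[1]
  schema <- .sbol_schema[[cls]]
  obj <- list(uri = uri, derivedFrom = character(0),
              generatedBy = character(0), annotations = list())
  class(obj) <- c(cls, .class_parents(cls))
  # initialise container fields so downstream code can rely on them
  for (fname in names(schema$fields)) {
    fs <- schema$fields[[fname]]
    if (fs$kind == "child" && fs$many) obj[[fname]] <- list()
    else if (fs$kind == "iri" && fs$many) obj[[fname]] <- character(0)
  }
  if (cls == "sbol_component") {
    obj$types <- character(0); obj$roles <- character(0)
    obj$sequences <- character(0); obj$models <- character(0)
  }
  known_preds <- vapply(schema$fields, `[[`, character(1), "pred")
  handled <- rep(FALSE, nrow(tr))
  handled[tr$predicate == RDF_TYPE] <- TRUE
  for (fname in names(schema$fields)) {
    fs <- schema$fields[[fname]]
    # sbol:type / sbol:role etc. can map to one field only; first match wins
    idx <- which(tr$predicate == fs$pred & !handled)
    if (length(idx) == 0) next
    handled[idx] <- TRUE
    vals <- tr$object[idx]
    if (fs$kind == "child") {
      kids <- lapply(vals, .build_object, triples = triples,
                     by_subject = by_subject, building = building)
      if (identical(fname, "interface")) {
        obj[[fname]] <- kids[[1]]
      } else {
        dids <- vapply(kids, function(k) k$displayId %||% k$uri, character(1))
        ord <- order(vapply(kids, `[[`, character(1), "uri"))
        obj[[fname]] <- stats::setNames(kids[ord], dids[ord])
      }
    } else if (fs$kind == "int") {
      v <- as.integer(vals)
      obj[[fname]] <- if (fs$many) v else v[1]
    } else {
      v <- as.character(vals)
      if (!fs$many) v <- v[1]
      obj[[fname]] <- v
    }
  }
  # restore order of ordered reference lists
  oidx <- which(tr$predicate == PRED_ORDER & !handled)
  if (length(oidx)) {
    handled[oidx] <- TRUE
    ord <- strsplit(tr$object[oidx[1]], " ", fixed = TRUE)[[1]]
    if (setequal(ord, obj$sequences)) obj$sequences <- ord
  }
  # anything left on a known subject is preserved as an annotation
  for (i in which(!handled)) {
    obj$annotations[[length(obj$annotations) + 1L]] <-
      list(predicate = tr$predicate[i], value = tr$object[i],
           type = if (tr$kind[i] == "iri") "iri" else "literal")
  }
  obj
}

#' Reconstruct a Document from an RDF graph
#'
#' Inverse of [to_graph()]. Subjects with a known top-level `rdf:type` become
#' objects; triples with unknown predicates on known subjects are preserved
#' as annotations; subjects with unknown `rdf:type` IRIs are kept as opaque
#' extension triple sets and re-emitted on the next [to_graph()] call.
#' Ownership cycles are an error.
#'
#' @param triples a triple data.frame.
#' @param prefixes optional named prefix map to record on the document.
#' @return an `sbol_document`.
#' @export
from_graph <- function(triples, prefixes = character(0)) {
  doc <- sbol_document(prefixes = prefixes)
  if (nrow(triples) == 0) return(doc)
  triples <- unique(triples)
  by_subject <- split(triples, triples$subject)
  subjects <- names(by_subject)
  # subjects owned by someone are not top-level
  owned <- unique(triples$object[triples$predicate %in% .OWNERSHIP_PREDS &
                                 triples$kind == "iri"])
  type_rows <- triples[triples$predicate == RDF_TYPE & triples$kind == "iri", ]
  tl_classes <- .top_level_registry$type_iri
  reached <- character(0)
  for (s in subjects) {
    if (s %in% owned) next
    stypes <- type_rows$object[type_rows$subject == s]
    if (length(stypes) == 0)
      stop("subject with no rdf:type: ", s, call. = FALSE)
    if (any(stypes %in% tl_classes)) {
      obj <- .build_object(s, triples, by_subject)
      doc$top_levels[[obj$uri]] <- obj
      reached <- c(reached, obj$uri,
                   vapply(sbol_descendants(obj), `[[`, character(1), "uri"))
    } else if (any(stypes %in% names(.type_to_class))) {
      stop("owned-class subject not reachable from a top level: ", s, call. = FALSE)
    } else {
      # unknown top-level type: opaque extension object
      doc$extensions[[s]] <- by_subject[[s]]
      reached <- c(reached, s)
    }
  }
  # known-class subjects that were never reached from a top level indicate an
  # ownership cycle among owned objects
  known <- subjects[vapply(subjects, function(s)
    any(type_rows$object[type_rows$subject == s] %in% names(.type_to_class)),
    logical(1))]
  lost <- setdiff(known, reached)
  if (length(lost))
    stop("ownership cycle or orphaned owned object(s): ",
         paste(lost, collapse = ", "), call. = FALSE)
  doc
}
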