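# Rule engine for the standard's structural and vocabulary rules. Problems
# are findings, never exceptions; all rules always run; output order is
# deterministic (subject URI, then rule id).

.finding <- function(subject, message) {
  data.frame(subject = subject, message = message, stringsAsFactors = FALSE)
}

.no_findings <- function() .finding(character(0), character(0))

# helper: iterate (owner, object) pairs over the whole document
.doc_objects_with_owner <- function(doc) {
  out <- list()
  walk <- function(obj, owner) {
    out[[length(out) + 1L]] <<- list(obj = obj, owner = owner)
    for (k in sbol_children(obj)) walk(k, obj)
  }
  for (tl in doc$top_levels) walk(tl, NULL)
  out
}

.doc_namespaces <- function(doc) {
  unique(unlist(lapply(doc$top_levels, function(tl) tl$namespace)))
}

.rule_registry <- function() {
  so_sbo_go <- function(iri) .is_term_of(iri, "SO") || .is_term_of(iri, "SBO") ||
    .is_term_of(iri, "GO")
  list(
    list(id = "SBOL3-URI-001", severity = "error",
         description = paste("TopLevel URI structure: every top-level object's",
           "URI must be an absolute IRI, its namespace must be a prefix of the",
           "URI, and the URI must end with '/<displayId>' when a displayId is",
           "present (the required <prefix>/<displayId> form)."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!.is_absolute_iri(tl$uri))
               out <- c(out, list(.finding(tl$uri, "URI is not an absolute IRI")))
             else if (is.null(tl$namespace) || !startsWith(tl$uri, tl$namespace))
               out <- c(out, list(.finding(tl$uri, "namespace is not a prefix of the URI")))
             else if (!is.null(tl$displayId) &&
                      !endsWith(tl$uri, paste0("/", tl$displayId)))
               out <- c(out, list(.finding(tl$uri, "URI does not end with '/<displayId>'")))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-URI-002", severity = "error",
         description = paste("Child URI closure: every owned child object's",
           "URI must equal its owner's URI followed by '/<displayId>'."),
         check = function(doc) {
           out <- list()
           for (pair in .doc_objects_with_owner(doc)) {
             if (is.null(pair$owner)) next
             expect <- paste0(pair$owner$uri, "/", pair$obj$displayId)
             if (!identical(pair$obj$uri, expect))
               out <- c(out, list(.finding(pair$obj$uri,
                 paste0("owned object URI should be ", expect))))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-ID-001", severity = "error",
         description = paste("displayId syntax: a displayId must match",
           "[A-Za-z_][A-Za-z0-9_]* (letters, digits, underscore; no leading",
           "digit)."),
         check = function(doc) {
           out <- list()
           for (pair in .doc_objects_with_owner(doc)) {
             d <- pair$obj$displayId
             if (!is.null(d) && !validate_display_id(d))
               out <- c(out, list(.finding(pair$obj$uri,
                 paste0("invalid displayId '", d, "'"))))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-TYPE-001", severity = "error",
         description = "A Component must carry at least one ontology type term.",
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels)
             if (inherits(tl, "sbol_component") && length(tl$types) == 0)
               out <- c(out, list(.finding(tl$uri, "Component has empty types")))
           .rbind_findings(out)
         }),
    list(id = "SBOL3-TYPE-002", severity = "error",
         description = paste("LocalSubComponent and ExternallyDefined features",
           "must carry at least one ontology type term."),
         check = function(doc) {
           out <- list()
           for (pair in .doc_objects_with_owner(doc)) {
             o <- pair$obj
             if ((inherits(o, "sbol_local_sub_component") ||
                  inherits(o, "sbol_externally_defined")) && length(o$types) == 0)
               out <- c(out, list(.finding(o$uri, "feature has empty types")))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-LOC-001", severity = "error",
         description = "A SequenceFeature must be associated with at least one location.",
         check = function(doc) {
           out <- list()
           for (pair in .doc_objects_with_owner(doc)) {
             o <- pair$obj
             if (inherits(o, "sbol_sequence_feature") && length(o$locations) == 0)
               out <- c(out, list(.finding(o$uri, "SequenceFeature without a location")))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-LOC-002", severity = "error",
         description = paste("Range coordinates: 1 <= start <= end, and end",
           "must not exceed the length of the referenced Sequence's elements",
           "when present (1-based, inclusive)."),
         check = function(doc) {
           out <- list()
           for (pair in .doc_objects_with_owner(doc)) {
             o <- pair$obj
             if (!inherits(o, "sbol_range")) next
             if (is.na(o$start) || is.na(o$end) || o$start < 1L || o$start > o$end) {
               out <- c(out, list(.finding(o$uri,
                 paste0("invalid Range ", o$start, "..", o$end))))
               next
             }
             seq_obj <- document_lookup(doc, o$sequence)
             if (!is.null(seq_obj) && !is.null(seq_obj$elements) &&
                 o$end > nchar(seq_obj$elements))
               out <- c(out, list(.finding(o$uri,
                 paste0("Range end ", o$end, " exceeds sequence length ",
                        nchar(seq_obj$elements)))))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-SEQ-001", severity = "error",
         description = paste("A Sequence with elements must declare an encoding,",
           "and its elements may contain only characters legal under that",
           "encoding."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!inherits(tl, "sbol_sequence") || is.null(tl$elements)) next
             if (is.null(tl$encoding)) {
               out <- c(out, list(.finding(tl$uri, "elements present but no encoding")))
               next
             }
             ok <- tryCatch({ .check_elements(tl$elements, tl$encoding); TRUE },
                            error = function(e) FALSE)
             if (!ok)
               out <- c(out, list(.finding(tl$uri,
                 "elements contain characters illegal under the encoding")))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-RESTR-001", severity = "error",
         description = paste("Constraint restrictions are a closed vocabulary:",
           "the restriction IRI must belong to the identity, sequential or",
           "topological family."),
         check = function(doc) {
           out <- list()
           vocab <- .all_restrictions()
           for (pair in .doc_objects_with_owner(doc)) {
             o <- pair$obj
             if (inherits(o, "sbol_constraint") && !(o$restriction %in% vocab))
               out <- c(out, list(.finding(o$uri,
                 paste0("unknown restriction ", o$restriction))))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-CONS-001", severity = "error",
         description = paste("A Constraint's subject and object must be two",
           "distinct Features of the Component that owns the Constraint."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!inherits(tl, "sbol_component")) next
             furis <- vapply(tl$features, `[[`, character(1), "uri")
             for (cn in tl$constraints) {
               if (identical(cn$subject, cn$object))
                 out <- c(out, list(.finding(cn$uri, "subject equals object")))
               else if (!(cn$subject %in% furis) || !(cn$object %in% furis))
                 out <- c(out, list(.finding(cn$uri,
                   "subject/object is not a feature of the owning Component")))
             }
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-PART-001", severity = "error",
         description = paste("A Participation must reference a Feature of the",
           "Component owning the Interaction, and carry at least one",
           "participant role."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!inherits(tl, "sbol_component")) next
             furis <- vapply(tl$features, `[[`, character(1), "uri")
             for (ia in tl$interactions) for (p in ia$participations) {
               if (length(p$roles) == 0)
                 out <- c(out, list(.finding(p$uri, "participation without roles")))
               if (is.null(p$participant) || !(p$participant %in% furis))
                 out <- c(out, list(.finding(p$uri,
                   "participant is not a feature of the owning Component")))
             }
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-INT-001", severity = "warning",
         description = paste("An Interaction without Participations carries no",
           "functional information (permitted, but flagged)."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!inherits(tl, "sbol_component")) next
             for (ia in tl$interactions)
               if (length(ia$participations) == 0)
                 out <- c(out, list(.finding(ia$uri, "Interaction has no participations")))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-IFACE-001", severity = "error",
         description = paste("Interface locality: input, output and",
           "non-directional references must be Features of the Component that",
           "owns the Interface, and no feature may be both non-directional and",
           "directional."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!inherits(tl, "sbol_component") || is.null(tl$interface)) next
             ifc <- tl$interface
             furis <- vapply(tl$features, `[[`, character(1), "uri")
             bad <- setdiff(c(ifc$inputs, ifc$outputs, ifc$nondirectionals), furis)
             for (b in bad)
               out <- c(out, list(.finding(ifc$uri,
                 paste0("interface references non-local feature ", b))))
             both <- intersect(ifc$nondirectionals, union(ifc$inputs, ifc$outputs))
             for (b in both)
               out <- c(out, list(.finding(ifc$uri,
                 paste0("feature is both non-directional and directional: ", b))))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-CREF-001", severity = "error",
         description = paste("A ComponentReference's inChildOf must be a",
           "SubComponent of the owning Component, and refersTo must resolve",
           "within (the document representation of) that SubComponent's",
           "definition."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!inherits(tl, "sbol_component")) next
             furis <- vapply(tl$features, `[[`, character(1), "uri")
             for (f in tl$features) {
               if (!inherits(f, "sbol_component_reference")) next
               sc <- document_lookup(doc, f$inChildOf)
               if (!(f$inChildOf %in% furis) || !inherits(sc, "sbol_sub_component")) {
                 out <- c(out, list(.finding(f$uri,
                   "inChildOf is not a SubComponent of the owning Component")))
                 next
               }
               defn <- document_lookup(doc, sc$instanceOf)
               if (is.null(defn)) next  # external definition: not checkable
               def_furis <- vapply(defn$features, `[[`, character(1), "uri")
               if (!(f$refersTo %in% def_furis))
                 out <- c(out, list(.finding(f$uri,
                   "refersTo does not resolve within the definition of inChildOf")))
             }
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-REF-001", severity = "error",
         description = paste("Reference closure: references into the document's",
           "own namespaces (instanceOf, sequence, participant, template,",
           "variable, members, ...) must resolve to an object in the document;",
           "references into foreign namespaces are treated as external."),
         check = function(doc) {
           out <- list()
           nss <- .doc_namespaces(doc)
           internal <- function(u) any(vapply(nss, function(ns)
             startsWith(u, paste0(ns, "/")), logical(1)))
           ref_fields <- c("instanceOf", "sequence", "sequences", "participant",
                           "subject", "object", "template", "variable",
                           "variants", "members", "built", "models",
                           "inChildOf", "refersTo")
           for (pair in .doc_objects_with_owner(doc)) {
             o <- pair$obj
             for (f in intersect(names(o), ref_fields)) {
               for (u in o[[f]]) {
                 if (is.null(u) || is.na(u) || !internal(u)) next
                 if (is.null(document_lookup(doc, u)))
                   out <- c(out, list(.finding(o$uri,
                     paste0("dangling internal reference (", f, "): ", u))))
               }
             }
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-CD-001", severity = "error",
         description = paste("A VariableFeature's variable must resolve to a",
           "Feature of the derivation's template Component, and at least one",
           "of variants / variantCollections / variantDerivations must be",
           "non-empty."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!inherits(tl, "sbol_combinatorial_derivation")) next
             template <- document_lookup(doc, tl$template)
             for (vf in tl$variableFeatures) {
               if (length(vf$variants) + length(vf$variantCollections) +
                   length(vf$variantDerivations) == 0)
                 out <- c(out, list(.finding(vf$uri, "VariableFeature has no variants")))
               if (!is.null(template)) {
                 furis <- vapply(template$features, `[[`, character(1), "uri")
                 if (!(vf$variable %in% furis))
                   out <- c(out, list(.finding(vf$uri,
                     "variable is not a feature of the template")))
               }
             }
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-NS-001", severity = "error",
         description = "A Namespace object's URI must not end with '/'.",
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels)
             if (inherits(tl, "sbol_namespace") && endsWith(tl$uri, "/"))
               out <- c(out, list(.finding(tl$uri, "Namespace URI ends with '/'")))
           .rbind_findings(out)
         }),
    list(id = "SBOL3-DOC-001", severity = "error",
         description = "All URIs in a document must be unique.",
         check = function(doc) {
           uris <- vapply(.doc_objects_with_owner(doc), function(p) p$obj$uri,
                          character(1))
           dup <- unique(uris[duplicated(uris)])
           .rbind_findings(lapply(dup, function(u)
             .finding(u, "URI occurs more than once in the document")))
         }),
    list(id = "SBOL3-VOCAB-001", severity = "warning",
         description = paste("Component types are recommended to be drawn from",
           "the Systems Biology Ontology (molecular species) or the Gene",
           "Ontology (cells, cellular components)."),
         check = function(doc) {
           out <- list()
           for (tl in doc$top_levels) {
             if (!inherits(tl, "sbol_component")) next
             for (t in tl$types)
               if (!so_sbo_go(t))
                 out <- c(out, list(.finding(tl$uri,
                   paste0("Component type outside SBO/GO: ", t))))
           }
           .rbind_findings(out)
         }),
    list(id = "SBOL3-VOCAB-002", severity = "warning",
         description = paste("Roles are recommended to be drawn from the",
           "Sequence Ontology, Systems Biology Ontology or Gene Ontology."),
         check = function(doc) {
           out <- list()
           for (pair in .doc_objects_with_owner(doc)) {
             o <- pair$obj
             if (!inherits(o, "sbol_component") && !inherits(o, "sbol_feature")) next
             for (r in o$roles %||% character(0))
               if (!so_sbo_go(r))
                 out <- c(out, list(.finding(o$uri,
                   paste0("role outside SO/SBO/GO: ", r))))
           }
           .rbind_findings(out)
         })
  )
}

.rbind_findings <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(.no_findings())
  do.call(rbind, lst)
}

#' The validation rule registry
#'
#' @return data.frame with columns `ruleId`, `severity`, `description`.
#' @export
sbol_rules <- function() {
  reg <- .rule_registry()
  data.frame(ruleId = vapply(reg, `[[`, character(1), "id"),
             severity = vapply(reg, `[[`, character(1), "severity"),
             description = vapply(reg, `[[`, character(1), "description"),
             stringsAsFactors = FALSE)
}

#' Validate a Document against the structural and vocabulary rules
#'
#' Runs every registered rule; problems are returned as findings, never
#' raised. In `lenient` mode (default) vocabulary-recommendation rules
#' produce warnings; `strict` mode escalates them to errors.
#'
#' @param doc an `sbol_document`.
#' @param strictness `"lenient"` or `"strict"`.
#' @return data.frame of class `sbol_findings` with columns `ruleId`,
#'   `severity`, `subject`, `message`, ordered by subject then rule id; zero
#'   rows iff the document is fully conformant at the given strictness.
#' @export
validate_document <- function(doc, strictness = c("lenient", "strict")) {
  strictness <- match.arg(strictness)
  stopifnot(inherits(doc, "sbol_document"))
  out <- list()
  for (rule in .rule_registry()) {
    f <- rule$check(doc)
    if (nrow(f) == 0) next
    sev <- rule$severity
    if (strictness == "strict" && sev == "warning" &&
        startsWith(rule$id, "SBOL3-VOCAB")) sev <- "error"
    out[[length(out) + 1L]] <- data.frame(
      ruleId = rule$id, severity = sev, subject = f$subject,
      message = f$message, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(ruleId = character(0), severity = character(0),
                         subject = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  res <- res[order(res$subject, res$ruleId, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("sbol_findings", "data.frame")
  res
}

#' Explain a validation rule
#'
#' @param ruleId a registered rule id, e.g. `"SBOL3-URI-001"`.
#' @return the rule's description text.
#' @export
explain_rule <- function(ruleId) {
  reg <- sbol_rules()
  i <- match(ruleId, reg$ruleId)
  if (is.na(i)) stop("unknown rule id: ", ruleId, call. = FALSE)
  paste0(ruleId, " [", reg$severity[i], "]: ", reg$description[i])
}

#' Render findings as text lines or JSON records
#'
#' @param findings an `sbol_findings` data.frame.
#' @param format `"text"` (one line per finding) or `"json"`.
#' @return character scalar.
#' @export
format_findings <- function(findings, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json")
    return(as.character(jsonlite::toJSON(as.data.frame(findings), auto_unbox = FALSE)))
  if (nrow(findings) == 0) return("no findings")
  paste(sprintf("%s %s %s: %s", toupper(findings$severity), findings$ruleId,
                findings$subject, findings$message), collapse = "\n")
}

#' @export
print.sbol_findings <- function(x, ...) {
  cat(nrow(x), "finding(s)\n")
  if (nrow(x)) cat(format_findings(x), "\n")
  invisible(x)
}
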