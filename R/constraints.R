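# Constraint evaluation: the Allen interval relations over integer sequence
# ranges, identity-constraint checking, and document-wide constraint sweeps.
#
# Discrete-interval convention: ranges are 1-based and inclusive at both
# ends, so two ranges have no shared boundary *point*; adjacency ("meets")
# is defined as a.end + 1 == b.start. `precedes` (the non-strict SBOL2
# relation) is read as the union strictlyPrecedes ∪ meets.

#' The Allen relation between two integer Ranges
#'
#' Classifies an ordered pair of ranges into exactly one of twelve mutually
#' exclusive, jointly exhaustive relation names covering the thirteen Allen
#' base relations: `strictlyPrecedes`, `meets`, `overlaps`, `starts`,
#' `finishes`, `equals`, `contains`, `strictlyContains`, plus the four
#' inverse names `precededBy`, `metBy`, `overlappedBy` and `during`.
#' `contains` covers the two base relations in which the subject contains the
#' object while sharing exactly one boundary (Allen's startedBy/finishedBy);
#' their converses are `starts` and `finishes` respectively.
#'
#' @param a,b `sbol_range` objects (or `list(start=, end=)`), on the same
#'   Sequence when sequence URIs are present.
#' @return a single relation name.
#' @export
#' @examples
#' allen_relation(loc_range("http://ex/s", 1, 5), loc_range("http://ex/s", 6, 10))
allen_relation <- function(a, b) {
  if (!is.null(a$sequence) && !is.null(b$sequence) &&
      !identical(a$sequence, b$sequence))
    stop("ranges lie on different sequences", call. = FALSE)
  s1 <- as.integer(a$start); e1 <- as.integer(a$end)
  s2 <- as.integer(b$start); e2 <- as.integer(b$end)
  if (any(is.na(c(s1, e1, s2, e2))) || s1 > e1 || s2 > e2)
    stop("malformed range", call. = FALSE)
  if (s1 == s2 && e1 == e2) return("equals")
  if (e1 + 1L < s2) return("strictlyPrecedes")
  if (e1 + 1L == s2) return("meets")
  if (s1 > e2 + 1L) return("precededBy")
  if (s1 == e2 + 1L) return("metBy")
  if (s1 == s2) return(if (e1 < e2) "starts" else "contains")
  if (e1 == e2) return(if (s1 > s2) "finishes" else "contains")
  if (s1 < s2 && e1 > e2) return("strictlyContains")
  if (s1 > s2 && e1 < e2) return("during")
  if (s1 < s2) "overlaps" else "overlappedBy"
}

# acceptance sets: which observed relation names satisfy each sequential
# restriction (equality of boundaries is NOT containment here; documented)
.SEQ_ACCEPT <- list(
  precedes         = c("strictlyPrecedes", "meets"),
  strictlyPrecedes = "strictlyPrecedes",
  meets            = "meets",
  overlaps         = "overlaps",
  starts           = "starts",
  finishes         = "finishes",
  equals           = "equals",
  contains         = c("contains", "strictlyContains"),
  strictlyContains = "strictlyContains"
)

.eval_result <- function(status, detail) list(status = status, detail = detail)

# the single Range a feature carries, or NULL
.feature_range <- function(doc, feature) {
  if (inherits(feature, "sbol_component_reference"))
    feature <- tryCatch(resolve_reference(doc, feature), error = function(e) NULL)
  if (is.null(feature)) return(NULL)
  locs <- feature$locations
  if (is.null(locs) || length(locs) == 0) return(NULL)
  ranges <- Filter(function(l) inherits(l, "sbol_range"), locs)
  if (length(ranges) != 1) return(NULL)
  ranges[[1]]
}

#' Evaluate a single Constraint where its ground data permits
#'
#' Sequential restrictions are decided by [allen_relation()] on the subject
#' and object features' Ranges (`notEvaluable` when either lacks a single
#' Range); orientation restrictions compare `Feature$orientation` when both
#' are set; `verifyIdentical` holds iff both features resolve to the same
#' definition IRI (and, when both resolved definitions carry sequence
#' elements, those match); `differentFrom` is its negation. `replaces` (an
#' instruction for derivation) and the whole topological family (no geometry
#' exists to compute) are representable and vocabulary-checked but
#' `notEvaluable`.
#'
#' @param doc an `sbol_document`.
#' @param constraint an `sbol_constraint` or its URI.
#' @return list with `status` (`"holds"`, `"violated"`, `"notEvaluable"`) and
#'   `detail` text.
#' @export
evaluate_constraint <- function(doc, constraint) {
  if (is.character(constraint)) constraint <- document_lookup(doc, constraint)
  stopifnot(inherits(constraint, "sbol_constraint"))
  r <- constraint$restriction
  vocab <- restriction_vocabulary()
  if (!(r %in% .all_restrictions()))
    stop("restriction IRI outside the closed vocabulary: ", r, call. = FALSE)
  subj <- document_lookup(doc, constraint$subject)
  obj <- document_lookup(doc, constraint$object)
  if (is.null(subj) || is.null(obj))
    return(.eval_result("notEvaluable", "subject or object does not resolve"))

  if (r %in% vocab$topological)
    return(.eval_result("notEvaluable", paste0(
      "topological restriction <", r, "> describes physical space; ",
      "no geometry is available to compute it")))
  if (identical(r, vocab$identity[["replaces"]]))
    return(.eval_result("notEvaluable",
      "replaces is an instruction for derivation, not a testable state"))

  if (r %in% vocab$identity[c("verifyIdentical", "differentFrom")]) {
    d1 <- .feature_definition(doc, subj)
    d2 <- .feature_definition(doc, obj)
    if (is.na(d1) || is.na(d2))
      return(.eval_result("notEvaluable",
        "subject or object has no resolvable definition"))
    same <- identical(d1, d2)
    if (same) {
      c1 <- document_lookup(doc, d1); c2 <- document_lookup(doc, d2)
      if (!is.null(c1) && !is.null(c2) &&
          inherits(c1, "sbol_component") && inherits(c2, "sbol_component")) {
        e1 <- .component_elements(doc, c1); e2 <- .component_elements(doc, c2)
        if (!is.null(e1) && !is.null(e2)) same <- identical(e1, e2)
      }
    }
    detail <- paste0("definitions ", d1, if (same) " == " else " != ", d2)
    if (identical(r, vocab$identity[["verifyIdentical"]]))
      return(.eval_result(if (same) "holds" else "violated", detail))
    return(.eval_result(if (same) "violated" else "holds", detail))
  }

  # orientation restrictions
  ori <- vocab$sequential[c("sameOrientationAs", "oppositeOrientationAs")]
  if (r %in% ori) {
    o1 <- subj$orientation; o2 <- obj$orientation
    if (is.null(o1) || is.null(o2))
      return(.eval_result("notEvaluable", "orientation not set on both features"))
    same <- identical(o1, o2)
    want_same <- identical(r, ori[["sameOrientationAs"]])
    return(.eval_result(if (same == want_same) "holds" else "violated",
                        paste0("orientations ", o1, " vs ", o2)))
  }

  # sequential (Allen) restrictions
  nm <- names(vocab$sequential)[match(r, vocab$sequential)]
  ra <- .feature_range(doc, subj)
  rb <- .feature_range(doc, obj)
  if (is.null(ra) || is.null(rb))
    return(.eval_result("notEvaluable",
      "subject or object lacks a single Range location"))
  if (!is.null(ra$sequence) && !is.null(rb$sequence) &&
      !identical(ra$sequence, rb$sequence))
    return(.eval_result("notEvaluable", "ranges lie on different sequences"))
  seq_obj <- if (!is.null(ra$sequence)) document_lookup(doc, ra$sequence) else NULL
  if (!is.null(seq_obj) && isTRUE(seq_obj$circular))
    return(.eval_result("notEvaluable", "circular sequences are not supported"))
  rel <- allen_relation(ra, rb)
  ok <- rel %in% .SEQ_ACCEPT[[nm]]
  .eval_result(if (ok) "holds" else "violated",
               paste0("observed relation: ", rel))
}

.component_elements <- function(doc, component) {
  if (length(component$sequences) == 0) return(NULL)
  s <- document_lookup(doc, component$sequences[1])
  if (is.null(s)) NULL else s$elements
}

#' Evaluate every Constraint in a document
#'
#' @param doc an `sbol_document`.
#' @return data.frame with one row per Constraint (columns `constraint`,
#'   `restriction`, `status`, `detail`), in deterministic URI order.
#' @export
check_all <- function(doc) {
  stopifnot(inherits(doc, "sbol_document"))
  rows <- list()
  for (tl in doc$top_levels) {
    if (!inherits(tl, "sbol_component")) next
    for (cn in tl$constraints) {
      res <- tryCatch(evaluate_constraint(doc, cn),
                      error = function(e) .eval_result("notEvaluable",
                                                       conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        constraint = cn$uri, restriction = cn$restriction,
        status = res$status, detail = res$detail, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(constraint = character(0), restriction = character(0),
                      status = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$constraint, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
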