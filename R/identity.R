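# URI construction, displayId validation, namespace membership and rewriting.
#
# Every SBOL3 object is named by an absolute URI of the form
# <namespace>[/<local path>]/<displayId>; child objects extend their owner's
# URI by one "/<displayId>" segment. Versioning is deliberately not modelled:
# version segments embedded in prefixes or displayIds pass through untouched.

.DISPLAY_ID_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

#' Validate a displayId
#'
#' A displayId must start with a letter or underscore and contain only
#' letters, digits and underscores.
#'
#' @param candidate character vector of candidate identifiers.
#' @return logical vector.
#' @export
#' @examples
#' validate_display_id(c("lacI_1", "1lacI", "pTet-prom"))
validate_display_id <- function(candidate) {
  if (length(candidate) == 0) return(logical(0))
  !is.na(candidate) & grepl(.DISPLAY_ID_RE, candidate)
}

.is_absolute_iri <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)
}

.assert_ascii <- function(x, what = "IRI") {
  bad <- vapply(x, function(s) any(utf8ToInt(s) > 127L), logical(1))
  if (any(bad))
    stop(what, " contains non-ASCII characters (internationalized IRIs are not supported): ",
         x[bad][1], call. = FALSE)
  invisible(x)
}

#' Compose an SBOL3 URI from a namespace prefix and a displayId
#'
#' @param prefix absolute IRI without trailing slash.
#' @param displayId valid identifier.
#' @return the IRI `<prefix>/<displayId>`.
#' @export
#' @examples
#' compose_uri("http://example.com/toggleswitch", "lacI_1")
compose_uri <- function(prefix, displayId) {
  if (!.is_absolute_iri(prefix))
    stop("namespace prefix must be an absolute IRI: ", prefix, call. = FALSE)
  .assert_ascii(prefix, "namespace prefix")
  if (endsWith(prefix, "/"))
    stop("namespace prefix must not end with '/': ", prefix, call. = FALSE)
  if (!validate_display_id(displayId))
    stop("invalid displayId: ", displayId, call. = FALSE)
  paste0(prefix, "/", displayId)
}

#' Decompose a URI against a set of registered namespaces
#'
#' The longest registered namespace that is a prefix of `uri` wins; the
#' remainder is split on "/" into a (possibly empty) local path and the final
#' displayId segment.
#'
#' @param uri the IRI to decompose.
#' @param namespaces character vector of namespace IRIs.
#' @return list with `namespace`, `localPath` (character vector), `displayId`.
#' @export
decompose_uri <- function(uri, namespaces) {
  stopifnot(length(uri) == 1)
  hits <- namespaces[vapply(namespaces, function(ns)
    startsWith(uri, paste0(ns, "/")), logical(1))]
  if (length(hits) == 0)
    stop("no registered namespace is a prefix of ", uri, call. = FALSE)
  ns <- hits[which.max(nchar(hits))]
  rest <- substring(uri, nchar(ns) + 2L)
  segs <- strsplit(rest, "/", fixed = TRUE)[[1]]
  if (length(segs) == 0 || any(!nzchar(segs)))
    stop("malformed URI remainder after namespace ", ns, ": ", uri, call. = FALSE)
  list(namespace = ns,
       localPath = if (length(segs) > 1) segs[-length(segs)] else character(0),
       displayId = segs[length(segs)])
}

# replace prefix oldNs by newNs on every URI-valued string in x where the
# match is at a segment boundary (exact, or followed by "/" or "#")
.rewrite_str <- function(x, oldNs, newNs) {
  if (!is.character(x) || length(x) == 0) return(x)
  hit <- !is.na(x) & (x == oldNs | startsWith(x, paste0(oldNs, "/")))
  x[hit] <- paste0(newNs, substring(x[hit], nchar(oldNs) + 1L))
  x
}

.URI_FIELDS <- c("uri", "namespace", "sequences", "models", "instanceOf",
                 "definition", "inChildOf", "refersTo", "sequence",
                 "participant", "subject", "object", "inputs", "outputs",
                 "nondirectionals", "template", "variable", "variants",
                 "variantCollections", "variantDerivations", "built",
                 "members", "attachments", "derivedFrom", "generatedBy",
                 "entity")

.rewrite_obj <- function(obj, oldNs, newNs) {
  for (f in intersect(names(obj), .URI_FIELDS))
    obj[[f]] <- .rewrite_str(obj[[f]], oldNs, newNs)
  for (f in .CHILD_FIELDS) {
    if (is.null(obj[[f]])) next
    if (f == "interface") obj[[f]] <- .rewrite_obj(obj[[f]], oldNs, newNs)
    else obj[[f]] <- lapply(obj[[f]], .rewrite_obj, oldNs = oldNs, newNs = newNs)
  }
  obj
}

#' Rewrite a namespace across a whole document
#'
#' Replaces the prefix `oldNs` by `newNs` on the URI of every object and on
#' every internal reference, retaining local paths and displayIds, so the
#' rewritten document is reference-closed whenever the input was. URIs in
#' other namespaces are untouched. The operation is invertible.
#'
#' @param doc an `sbol_document`.
#' @param oldNs namespace IRI currently used in the document.
#' @param newNs replacement namespace IRI (absolute, no trailing slash).
#' @return the rewritten `sbol_document`.
#' @export
rewrite_namespace <- function(doc, oldNs, newNs) {
  stopifnot(inherits(doc, "sbol_document"))
  if (!.is_absolute_iri(newNs) || endsWith(newNs, "/"))
    stop("newNs must be an absolute IRI without trailing '/': ", newNs, call. = FALSE)
  .assert_ascii(newNs, "namespace")
  old_uris <- names(doc$top_levels)
  new_tls <- lapply(doc$top_levels, .rewrite_obj, oldNs = oldNs, newNs = newNs)
  names(new_tls) <- vapply(new_tls, function(x) x$uri, character(1))
  # collision check: a rewritten URI may not land on an existing, unrewritten one
  moved <- names(new_tls) != old_uris
  if (any(names(new_tls)[moved] %in% old_uris[!moved]) ||
      anyDuplicated(names(new_tls)))
    stop("namespace rewrite would collide with existing URIs in ", newNs, call. = FALSE)
  doc$top_levels <- new_tls
  doc
}
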