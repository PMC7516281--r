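# GenBank flat-file import/export and FASTA import.
#
# A GenBank record is held as list(locus, length, definition, sequence,
# features), each feature a list(key, location, qualifiers). Supported
# location dialects: `a..b`, a single base `a`, `complement(...)`,
# `join(...)`; fuzzy `<a`/`>b` coordinates are clamped with a warning.
# Coordinates are 1-based and inclusive at both ends and are preserved
# exactly, which makes the GenBank -> SBOL3 -> GenBank round trip
# feature-table-identical.

#' Parse a GenBank flat file
#'
#' @param text character scalar (or vector of lines) with the record.
#' @return a `genbank_record` list with `locus`, `length`, `definition`,
#'   `sequence` (uppercase) and `features` (list of
#'   `list(key, location, qualifiers)`).
#' @export
parse_genbank <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line) == 0) stop("no LOCUS line", call. = FALSE)
  locus_fields <- strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]]
  locus <- locus_fields[1]
  def_line <- grep("^DEFINITION", lines, value = TRUE)
  definition <- if (length(def_line)) trimws(sub("^DEFINITION", "", def_line[1])) else ""

  features <- list()
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(fstart)) {
    fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
    i <- fstart[1] + 1L
    cur <- NULL
    in_qualifiers <- FALSE
    while (i <= fend) {
      ln <- lines[i]
      if (grepl("^ {5}\\S", ln)) {            # new feature: key at column 6
        if (!is.null(cur)) features[[length(features) + 1L]] <- cur
        key <- trimws(substr(ln, 1, 20))
        locstr <- trimws(substring(ln, 21))
        cur <- list(key = key, location = locstr, qualifiers = character(0))
        in_qualifiers <- FALSE
      } else if (grepl("^ {21}", ln) && !is.null(cur)) {
        cont <- trimws(ln)
        if (startsWith(cont, "/")) {
          in_qualifiers <- TRUE
          q <- sub("^/", "", cont)
          eq <- regexpr("=", q, fixed = TRUE)
          if (eq > 0) {
            qname <- substr(q, 1, eq - 1L)
            qval <- gsub("^\"|\"$", "", substring(q, eq + 1L))
          } else { qname <- q; qval <- "" }
          cur$qualifiers[qname] <- qval
        } else if (!in_qualifiers) {
          cur$location <- paste0(cur$location, cont)   # continued location
        }
      }
      i <- i + 1L
    }
    if (!is.null(cur)) features[[length(features) + 1L]] <- cur
  }

  sequence <- ""
  if (length(ostart)) {
    send <- grep("^//", lines)
    send <- if (length(send)) send[1] - 1L else length(lines)
    seq_lines <- lines[(ostart[1] + 1L):send]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  structure(list(locus = locus, length = nchar(sequence),
                 definition = definition, sequence = sequence,
                 features = features),
            class = "genbank_record")
}

#' @export
#' @rdname parse_genbank
#' @param path path to a GenBank flat file.
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_genbank(readLines(path, warn = FALSE))
}

# parse a GenBank location string into list(ranges = list(c(start, end)),
# complement = logical); fuzzy coordinates are clamped with a warning
.parse_gb_location <- function(locstr, seqlen = NA_integer_) {
  s <- gsub("\\s", "", locstr)
  complement <- FALSE
  if (grepl("^complement\\(", s)) {
    complement <- TRUE
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) {
    s <- sub("^join\\((.*)\\)$", "\\1", s)
  } else if (grepl("[()]", s)) {
    stop("unsupported GenBank location: ", locstr, call. = FALSE)
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  ranges <- lapply(parts, function(p) {
    fuzzy <- grepl("[<>]", p)
    if (fuzzy) {
      warning("fuzzy GenBank coordinates clamped: ", p, call. = FALSE)
      p <- gsub("[<>]", "", p)
    }
    if (grepl("^[0-9]+$", p)) {
      a <- as.integer(p); b <- a
    } else {
      m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
      if (length(m) == 0) stop("unparseable GenBank location part: ", p, call. = FALSE)
      a <- as.integer(m[2]); b <- as.integer(m[3])
    }
    if (!is.na(seqlen)) { a <- max(1L, a); b <- min(seqlen, b) }
    c(start = a, end = b)
  })
  list(ranges = ranges, complement = complement)
}

.gb_location_string <- function(ranges, complement) {
  parts <- vapply(ranges, function(r)
    if (r[["start"]] == r[["end"]]) as.character(r[["start"]])
    else paste0(r[["start"]], "..", r[["end"]]), character(1),
    USE.NAMES = FALSE)
  s <- if (length(parts) > 1) paste0("join(", paste(parts, collapse = ","), ")")
       else parts
  if (complement) paste0("complement(", s, ")") else s
}

#' Import a GenBank record as an SBOL3 Component and Sequence
#'
#' Produces one DNA-typed Component (`SBO:0000251`), one Sequence holding the
#' record's residues under the IUPAC DNA encoding, and one SequenceFeature
#' per GenBank feature: Range coordinates mirror the location string exactly
#' (1-based inclusive), `complement(...)` becomes reverse-complement
#' orientation, and the feature key is mapped to a Sequence Ontology role via
#' a shipped key table (unmapped keys get the generic `sequence_feature` role
#' with a warning).
#'
#' @param record a `genbank_record` from [parse_genbank()].
#' @param namespace namespace IRI for the new objects.
#' @param displayId optional displayId; defaults to the LOCUS name.
#' @return list with elements `component`, `sequence` (detached top-levels)
#'   — add both to a document with [doc_add()].
#' @export
genbank_to_component <- function(record, namespace, displayId = NULL) {
  stopifnot(inherits(record, "genbank_record"))
  if (!nzchar(record$sequence)) stop("GenBank record has no sequence", call. = FALSE)
  displayId <- displayId %||% gsub("[^A-Za-z0-9_]", "_", record$locus)
  if (grepl("^[0-9]", displayId)) displayId <- paste0("x", displayId)
  seq_obj <- sbol_sequence(namespace, paste0(displayId, "_seq"),
                           elements = record$sequence,
                           encoding = ENCODING_IUPAC_DNA)
  sbo <- ontology_terms()$SBO
  cmp <- sbol_component(namespace, displayId, types = sbo[["dna"]],
                        sequences = seq_obj$uri,
                        description = if (nzchar(record$definition))
                          record$definition else NULL)
  used <- character(0)
  for (i in seq_along(record$features)) {
    ft <- record$features[[i]]
    if (identical(ft$key, "source")) next  # whole-record metadata, not a feature
    loc <- .parse_gb_location(ft$location, seqlen = nchar(record$sequence))
    role <- genbank_key_to_role(ft$key)
    if (is.na(role)) {
      warning("unmapped GenBank feature key '", ft$key,
              "'; using generic sequence_feature role", call. = FALSE)
      role <- ontology_terms()$SO[["sequence_feature"]]
    }
    q <- function(n) if (n %in% names(ft$qualifiers)) ft$qualifiers[[n]] else NULL
    base <- q("label") %||% q("gene") %||% paste0(ft$key, "_", i)
    did <- gsub("[^A-Za-z0-9_]", "_", base)
    if (grepl("^[0-9]", did)) did <- paste0("f_", did)
    while (did %in% used) did <- paste0(did, "_", i)
    used <- c(used, did)
    locs <- lapply(loc$ranges, function(r)
      loc_range(seq_obj$uri, r[["start"]], r[["end"]]))
    f <- sequence_feature(did, locations = locs, roles = role,
                          orientation = if (loc$complement) "reverseComplement"
                                        else NULL)
    # retain the original key for lossless export
    f <- add_annotation(f, paste0(SBOL3R_EXT_NS, "genbankKey"), ft$key)
    cmp <- add_feature(cmp, f)
  }
  list(component = cmp, sequence = seq_obj)
}

#' Export a Component as a GenBank record
#'
#' The inverse flattening of [genbank_to_component()]: located features
#' (SequenceFeatures and located SubComponents) become feature-table rows;
#' SubComponents without locations are omitted with a warning. Only
#' nucleotide Components can be exported.
#'
#' @param component an `sbol_component` typed as DNA.
#' @param doc the `sbol_document` containing the Component's Sequence.
#' @return a `genbank_record`.
#' @export
component_to_genbank <- function(component, doc) {
  stopifnot(inherits(component, "sbol_component"))
  sbo <- ontology_terms()$SBO
  if (sbo[["protein"]] %in% component$types || sbo[["rna"]] %in% component$types)
    stop("GenBank export supports nucleotide (DNA) Components only", call. = FALSE)
  if (length(component$sequences) == 0)
    stop("Component has no Sequence", call. = FALSE)
  seq_obj <- document_lookup(doc, component$sequences[1])
  if (is.null(seq_obj) || is.null(seq_obj$elements))
    stop("Component's Sequence has no elements", call. = FALSE)
  features <- list()
  for (f in component$features) {
    if (inherits(f, "sbol_component_reference")) next
    locs <- Filter(function(l) inherits(l, "sbol_range"), f$locations %||% list())
    if (length(locs) == 0) {
      if (inherits(f, "sbol_sub_component"))
        warning("SubComponent without a Range omitted from GenBank export: ",
                f$uri, call. = FALSE)
      next
    }
    ranges <- lapply(locs, function(l) c(start = l$start, end = l$end))
    complement <- identical(f$orientation, ORIENTATION_REVCOMP)
    key <- NULL
    for (ann in f$annotations)
      if (identical(ann$predicate, paste0(SBOL3R_EXT_NS, "genbankKey")))
        key <- ann$value
    if (is.null(key))
      key <- role_to_genbank_key(if (length(f$roles)) f$roles[1] else "")
    features[[length(features) + 1L]] <-
      list(key = key, location = .gb_location_string(ranges, complement),
           qualifiers = c(label = f$displayId))
  }
  structure(list(locus = component$displayId, length = nchar(seq_obj$elements),
                 definition = component$description %||% "",
                 sequence = seq_obj$elements, features = features),
            class = "genbank_record")
}

#' Write a GenBank record to a flat file
#'
#' @param record a `genbank_record`.
#' @param path output path (omit to return the text invisibly).
#' @return invisibly, the lines written.
#' @export
write_genbank <- function(record, path = NULL) {
  stopifnot(inherits(record, "genbank_record"))
  out <- c(sprintf("LOCUS       %-17s %d bp    DNA     linear   UNA",
                   record$locus, nchar(record$sequence)))
  if (nzchar(record$definition))
    out <- c(out, paste0("DEFINITION  ", record$definition))
  out <- c(out, "FEATURES             Location/Qualifiers")
  for (ft in record$features) {
    out <- c(out, sprintf("     %-16s%s", ft$key, ft$location))
    for (qn in names(ft$qualifiers))
      out <- c(out, sprintf("                     /%s=\"%s\"", qn,
                            ft$qualifiers[[qn]]))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substring(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

## ---- FASTA ---------------------------------------------------------------

#' Import a FASTA record as an SBOL3 Sequence
#'
#' Residues are case-normalized to upper case; the encoding is inferred from
#' the alphabet (IUPAC DNA vs protein) unless overridden. Ambiguous alphabets
#' without an override are an error.
#'
#' @param record list with `id` and `residues`, as produced by [read_fasta()].
#' @param namespace namespace IRI for the new Sequence.
#' @param displayId optional; defaults to a sanitized record id.
#' @param encoding optional explicit encoding IRI.
#' @return an `sbol_sequence`.
#' @export
fasta_to_sequence <- function(record, namespace, displayId = NULL,
                              encoding = NULL) {
  if (is.null(record$residues) || !nzchar(record$residues))
    stop("empty FASTA record", call. = FALSE)
  displayId <- displayId %||% gsub("[^A-Za-z0-9_]", "_", record$id)
  if (grepl("^[0-9]", displayId)) displayId <- paste0("x", displayId)
  sbol_sequence(namespace, displayId, elements = toupper(record$residues),
                encoding = encoding)
}

#' Read FASTA records
#'
#' Reads via Biostrings and returns plain records for [fasta_to_sequence()].
#'
#' @param path path to a FASTA file.
#' @return list of `list(id, residues)`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i)
    list(id = strsplit(names(set)[i], "\\s+")[[1]][1],
         residues = as.character(set[[i]])))
}
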