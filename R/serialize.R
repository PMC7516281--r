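# Serialization and parsing of the RDF graph in four concrete syntaxes:
# Turtle (.ttl), N-Triples (.nt), JSON-LD (.jsonld) and RDF/XML (.rdf).
# Canonical (lexicographically sorted) N-Triples is the normative form for
# diffing. All output is UTF-8.

SBOL_FORMATS <- c("turtle", "ntriples", "jsonld", "rdfxml")

.format_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         ttl = "turtle", turtle = "turtle",
         nt = "ntriples", ntriples = "ntriples",
         jsonld = "jsonld", json = "jsonld",
         rdf = "rdfxml", xml = "rdfxml", rdfxml = "rdfxml",
         stop("cannot infer RDF format from extension: ", path, call. = FALSE))
}

.check_format <- function(format) {
  if (!format %in% SBOL_FORMATS)
    stop("unknown format '", format, "'; use one of ",
         paste(SBOL_FORMATS, collapse = ", "), call. = FALSE)
  format
}

#' Serialize a Document
#'
#' @param doc an `sbol_document`.
#' @param format one of `"turtle"`, `"ntriples"`, `"jsonld"`, `"rdfxml"`.
#' @return a single character scalar holding the serialized document.
#' @export
serialize_sbol <- function(doc, format = "turtle") {
  .check_format(format)
  tr <- to_graph(doc)
  switch(format,
         ntriples = .write_ntriples(tr),
         turtle   = .write_turtle(tr, doc$prefixes),
         jsonld   = .write_jsonld(tr, doc$prefixes),
         rdfxml   = .write_rdfxml(tr, doc$prefixes))
}

#' Parse a serialized Document
#'
#' @param text character scalar with the serialized content.
#' @param format one of the four supported syntaxes.
#' @return an `sbol_document`.
#' @export
parse_sbol <- function(text, format) {
  .check_format(format)
  tr <- switch(format,
               ntriples = .parse_ntriples(text),
               turtle   = .parse_turtle(text),
               jsonld   = .parse_jsonld(text),
               rdfxml   = .parse_rdfxml(text))
  from_graph(tr)
}

#' Write a Document to a file
#'
#' @param doc an `sbol_document`.
#' @param path output path; the format is inferred from the extension
#'   (.ttl, .nt, .jsonld, .rdf/.xml) unless given.
#' @param format optional explicit format.
#' @return invisibly, the path.
#' @export
write_sbol <- function(doc, path, format = NULL) {
  format <- format %||% .format_from_path(path)
  writeLines(serialize_sbol(doc, format), path, useBytes = TRUE)
  invisible(path)
}

#' Read a Document from a file
#'
#' @param path input path.
#' @param format optional explicit format; inferred from the extension
#'   otherwise.
#' @return an `sbol_document`.
#' @export
read_sbol <- function(path, format = NULL) {
  format <- format %||% .format_from_path(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_sbol(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                   collapse = "\n"), format)
}

## ---- N-Triples -----------------------------------------------------------

.nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.nt_unescape <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

.nt_object <- function(tr) {
  ifelse(tr$kind == "iri",
         paste0("<", tr$object, ">"),
         ifelse(is.na(tr$dtype),
                paste0("\"", .nt_escape(tr$object), "\""),
                paste0("\"", .nt_escape(tr$object), "\"^^<", tr$dtype, ">")))
}

.write_ntriples <- function(tr) {
  if (nrow(tr) == 0) return("")
  lines <- paste0("<", tr$subject, "> <", tr$predicate, "> ",
                  .nt_object(tr), " .")
  paste(sort(unique(lines), method = "radix"), collapse = "\n")
}

#' Canonical N-Triples form of a document
#'
#' Lexicographically sorted N-Triples, the stable form for diffing under
#' version control.
#'
#' @param doc an `sbol_document`.
#' @return character scalar.
#' @export
canonical_ntriples <- function(doc) serialize_sbol(doc, "ntriples")

.parse_ntriples <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(.empty_triples())
  re <- paste0("^<([^>]*)>\\s+<([^>]*)>\\s+",
               "(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"",
               "(?:\\^\\^<([^>]*)>)?)\\s*\\.\\s*$")
  m <- regmatches(lines, regexec(re, lines))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad))
    stop("N-Triples syntax error at line ", bad[1], ": ", lines[bad[1]],
         call. = FALSE)
  rows <- lapply(m, function(g) {
    if (nzchar(g[4]) || !nzchar(g[5]) && !nzchar(g[6]) && grepl('"', g[1], fixed = TRUE)) {
    }
    if (nzchar(g[4])) {
      .triple(g[2], g[3], g[4], "iri")
    } else {
      dt <- if (nzchar(g[6])) g[6] else NA_character_
      .triple(g[2], g[3], .nt_unescape(g[5]), "literal", dt)
    }
  })
  unique(.rbind_triples(rows))
}

## ---- Turtle --------------------------------------------------------------

.qname <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", local)) return(paste0(p, ":", local))
    }
  }
  NULL
}

.ttl_term <- function(iri, prefixes) {
  q <- .qname(iri, prefixes)
  if (is.null(q)) paste0("<", iri, ">") else q
}

.write_turtle <- function(tr, prefixes) {
  header <- paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> .")
  if (nrow(tr) == 0) return(paste(header, collapse = "\n"))
  out <- character(0)
  for (s in sort(unique(tr$subject), method = "radix")) {
    st <- tr[tr$subject == s, , drop = FALSE]
    # rdf:type first, then predicates alphabetically
    st <- st[order(st$predicate != RDF_TYPE, st$predicate, st$object,
                   method = "radix"), , drop = FALSE]
    preds <- unique(st$predicate)
    plines <- vapply(preds, function(p) {
      pt <- st[st$predicate == p, , drop = FALSE]
      objs <- vapply(seq_len(nrow(pt)), function(i) {
        if (pt$kind[i] == "iri") .ttl_term(pt$object[i], prefixes)
        else if (!is.na(pt$dtype[i]))
          paste0("\"", .nt_escape(pt$object[i]), "\"^^",
                 .ttl_term(pt$dtype[i], prefixes))
        else paste0("\"", .nt_escape(pt$object[i]), "\"")
      }, character(1))
      pname <- if (p == RDF_TYPE) "a" else .ttl_term(p, prefixes)
      paste0("    ", pname, " ", paste(objs, collapse = ", "))
    }, character(1))
    out <- c(out, paste0("<", s, ">\n", paste(plines, collapse = " ;\n"), " ."))
  }
  paste(c(header, "", out), collapse = "\n")
}

# a small Turtle reader covering the subset this package emits plus common
# hand-written variants: @prefix, qnames, <iri>, quoted literals with escapes
# and ^^ datatypes, bare integers, ';' ',' '.' punctuation and '#' comments.
.parse_turtle <- function(text) {
  toks <- .ttl_tokenize(text)
  prefixes <- character(0)
  triples <- list()
  i <- 1L
  n <- length(toks)
  resolve <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    m <- regmatches(tok, regexec("^([A-Za-z_][A-Za-z0-9_-]*)?:(.*)$", tok))[[1]]
    if (length(m) == 0) stop("Turtle: expected IRI or qname, got '", tok, "'",
                             call. = FALSE)
    p <- m[2]
    if (!p %in% names(prefixes))
      stop("Turtle: undeclared prefix '", p, ":'", call. = FALSE)
    paste0(prefixes[[p]], m[3])
  }
  while (i <= n) {
    tok <- toks[i]
    if (tok %in% c("@prefix", "PREFIX")) {
      p <- sub(":$", "", toks[i + 1L])
      prefixes[[p]] <- substr(toks[i + 2L], 2L, nchar(toks[i + 2L]) - 1L)
      i <- i + 3L
      if (i <= n && toks[i] == ".") i <- i + 1L
      next
    }
    subj <- resolve(tok)
    i <- i + 1L
    repeat {
      ptok <- toks[i]
      pred <- if (ptok == "a") RDF_TYPE else resolve(ptok)
      i <- i + 1L
      repeat {
        otok <- toks[i]
        if (startsWith(otok, "\"")) {
          lit <- .nt_unescape(substr(otok, 2L, nchar(otok) - 1L))
          dt <- NA_character_
          if (i + 1L <= n && toks[i + 1L] == "^^") {
            dt <- resolve(toks[i + 2L]); i <- i + 2L
          }
          triples[[length(triples) + 1L]] <- .triple(subj, pred, lit, "literal", dt)
        } else if (grepl("^-?[0-9]+$", otok)) {
          triples[[length(triples) + 1L]] <-
            .triple(subj, pred, otok, "literal", XSD_INT)
        } else {
          triples[[length(triples) + 1L]] <- .triple(subj, pred, resolve(otok), "iri")
        }
        i <- i + 1L
        if (i > n || toks[i] != ",") break
        i <- i + 1L
      }
      if (i > n || toks[i] != ";") break
      i <- i + 1L
      if (i <= n && toks[i] == ".") break  # trailing ';' before '.'
    }
    if (i > n || toks[i] != ".")
      stop("Turtle: expected '.' to end statement about <", subj, ">",
           call. = FALSE)
    i <- i + 1L
  }
  unique(.rbind_triples(triples))
}

.ttl_tokenize <- function(text) {
  # strip comments outside quotes, line by line
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- vapply(lines, function(l) {
    inq <- FALSE; esc <- FALSE; iniri <- FALSE
    chars <- strsplit(l, "")[[1]]
    for (idx in seq_along(chars)) {
      ch <- chars[idx]
      if (inq) {
        if (esc) esc <- FALSE
        else if (ch == "\\") esc <- TRUE
        else if (ch == "\"") inq <- FALSE
      } else if (iniri) {
        if (ch == ">") iniri <- FALSE
      } else {
        if (ch == "\"") inq <- TRUE
        else if (ch == "<") iniri <- TRUE
        else if (ch == "#") return(paste(chars[seq_len(idx - 1L)], collapse = ""))
      }
    }
    l
  }, character(1), USE.NAMES = FALSE)
  text <- paste(lines, collapse = "\n")
  pattern <- paste0(
    "<[^>]*>",                                   # IRI
    "|\"(?:[^\"\\\\]|\\\\.)*\"",                 # quoted literal
    "|\\^\\^",                                   # datatype marker
    "|@prefix|PREFIX",
    "|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*", # qname
    "|[A-Za-z_][A-Za-z0-9_.-]*:",                # prefix declaration name
    "|:[A-Za-z0-9_.%-]*",                        # default-prefix qname
    "|-?[0-9]+",
    "|\\ba\\b",
    "|[.;,]"
  )
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, list(m))[[1]]
}

## ---- JSON-LD -------------------------------------------------------------

.jsonld_compact_iri <- function(iri, prefixes) {
  q <- .qname(iri, prefixes)
  if (is.null(q)) iri else q
}

.write_jsonld <- function(tr, prefixes) {
  ctx <- as.list(prefixes)
  nodes <- list()
  for (s in sort(unique(tr$subject), method = "radix")) {
    st <- tr[tr$subject == s, , drop = FALSE]
    node <- list(`@id` = s)
    types <- st$object[st$predicate == RDF_TYPE & st$kind == "iri"]
    if (length(types))
      node$`@type` <- as.list(vapply(sort(types), .jsonld_compact_iri,
                                     character(1), prefixes = prefixes,
                                     USE.NAMES = FALSE))
    rest <- st[st$predicate != RDF_TYPE, , drop = FALSE]
    for (p in sort(unique(rest$predicate), method = "radix")) {
      pt <- rest[rest$predicate == p, , drop = FALSE]
      vals <- lapply(seq_len(nrow(pt)), function(i) {
        if (pt$kind[i] == "iri") list(`@id` = pt$object[i])
        else if (!is.na(pt$dtype[i]))
          list(`@value` = pt$object[i],
               `@type` = .jsonld_compact_iri(pt$dtype[i], prefixes))
        else pt$object[i]
      })
      node[[.jsonld_compact_iri(p, prefixes)]] <- vals
    }
    nodes[[length(nodes) + 1L]] <- node
  }
  jsonlite::toJSON(list(`@context` = ctx, `@graph` = nodes),
                   auto_unbox = TRUE, pretty = TRUE)
}

.jsonld_expand_iri <- function(x, ctx) {
  m <- regmatches(x, regexec("^([A-Za-z_][A-Za-z0-9_.-]*):(.*)$", x))[[1]]
  if (length(m) && m[2] %in% names(ctx)) return(paste0(ctx[[m[2]]], m[3]))
  x
}

.parse_jsonld <- function(text) {
  j <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  ctx <- j$`@context` %||% list()
  graph <- j$`@graph` %||% list()
  triples <- list()
  for (node in graph) {
    s <- node$`@id`
    if (is.null(s)) stop("JSON-LD node without @id", call. = FALSE)
    for (key in names(node)) {
      if (key == "@id") next
      if (key == "@type") {
        tys <- node[[key]]
        if (!is.list(tys)) tys <- as.list(tys)
        for (t in tys)
          triples[[length(triples) + 1L]] <-
            .triple(s, RDF_TYPE, .jsonld_expand_iri(t, ctx), "iri")
        next
      }
      pred <- .jsonld_expand_iri(key, ctx)
      vals <- node[[key]]
      if (!is.list(vals) || !is.null(names(vals))) vals <- list(vals)
      for (v in vals) {
        if (is.list(v) && !is.null(v$`@id`)) {
          triples[[length(triples) + 1L]] <-
            .triple(s, pred, .jsonld_expand_iri(v$`@id`, ctx), "iri")
        } else if (is.list(v) && !is.null(v$`@value`)) {
          dt <- if (is.null(v$`@type`)) NA_character_
                else .jsonld_expand_iri(v$`@type`, ctx)
          triples[[length(triples) + 1L]] <-
            .triple(s, pred, as.character(v$`@value`), "literal", dt)
        } else {
          triples[[length(triples) + 1L]] <-
            .triple(s, pred, as.character(v), "literal")
        }
      }
    }
  }
  unique(.rbind_triples(triples))
}

## ---- RDF/XML -------------------------------------------------------------

.split_iri <- function(iri) {
  # split into namespace + NCName local part (longest valid local suffix)
  m <- regmatches(iri, regexec("^(.*?)([A-Za-z_][A-Za-z0-9_.-]*)$", iri))[[1]]
  if (length(m) == 0 || !nzchar(m[2]))
    stop("cannot split IRI into namespace and local name: ", iri, call. = FALSE)
  c(ns = m[2], local = m[3])
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.write_rdfxml <- function(tr, prefixes) {
  # collect namespaces for every predicate
  pred_ns <- unique(vapply(unique(c(tr$predicate, RDF_TYPE)),
                           function(p) .split_iri(p)[["ns"]], character(1)))
  nsmap <- prefixes
  extra <- setdiff(pred_ns, unname(nsmap))
  if (length(extra))
    nsmap <- c(nsmap, stats::setNames(extra, paste0("ns", seq_along(extra))))
  prefix_of <- function(ns) names(nsmap)[match(ns, unname(nsmap))]
  decls <- paste0("xmlns:", names(nsmap), "=\"", .xml_escape(unname(nsmap)), "\"")
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<rdf:RDF ", paste(decls, collapse = " "), ">"))
  for (s in sort(unique(tr$subject), method = "radix")) {
    st <- tr[tr$subject == s, , drop = FALSE]
    st <- st[order(st$predicate, st$object, method = "radix"), , drop = FALSE]
    out <- c(out, paste0("  <rdf:Description rdf:about=\"", .xml_escape(s), "\">"))
    for (i in seq_len(nrow(st))) {
      parts <- .split_iri(st$predicate[i])
      qn <- paste0(prefix_of(parts[["ns"]]), ":", parts[["local"]])
      if (st$kind[i] == "iri") {
        out <- c(out, paste0("    <", qn, " rdf:resource=\"",
                             .xml_escape(st$object[i]), "\"/>"))
      } else if (!is.na(st$dtype[i])) {
        out <- c(out, paste0("    <", qn, " rdf:datatype=\"",
                             .xml_escape(st$dtype[i]), "\">",
                             .xml_escape(st$object[i]), "</", qn, ">"))
      } else {
        out <- c(out, paste0("    <", qn, ">", .xml_escape(st$object[i]),
                             "</", qn, ">"))
      }
    }
    out <- c(out, "  </rdf:Description>")
  }
  out <- c(out, "</rdf:RDF>")
  paste(out, collapse = "\n")
}

.parse_rdfxml <- function(text) {
  docx <- xml2::read_xml(text)
  triples <- list()
  for (subj_node in xml2::xml_children(docx)) {
    about <- xml2::xml_attr(subj_node, "about")
    if (is.na(about)) stop("RDF/XML subject without rdf:about", call. = FALSE)
    sname <- .xml_full_name(subj_node)
    if (!identical(sname, paste0(RDF_NS, "Description"))) {
      # typed node element
      triples[[length(triples) + 1L]] <- .triple(about, RDF_TYPE, sname, "iri")
    }
    for (pnode in xml2::xml_children(subj_node)) {
      pred <- .xml_full_name(pnode)
      res <- xml2::xml_attr(pnode, "resource")
      if (!is.na(res)) {
        triples[[length(triples) + 1L]] <- .triple(about, pred, res, "iri")
      } else {
        dt <- xml2::xml_attr(pnode, "datatype")
        triples[[length(triples) + 1L]] <-
          .triple(about, pred, xml2::xml_text(pnode), "literal", dt)
      }
    }
  }
  unique(.rbind_triples(triples))
}

.xml_full_name <- function(node) {
  # resolve the element name against the document namespace map
  nsmap <- xml2::xml_ns(xml2::xml_root(node))
  qn <- xml2::xml_name(node, ns = nsmap)
  pieces <- strsplit(qn, ":", fixed = TRUE)[[1]]
  if (length(pieces) != 2) return(qn)
  full_ns <- unname(as.character(nsmap[pieces[1]]))
  if (is.na(full_ns)) qn else paste0(full_ns, pieces[2])
}
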