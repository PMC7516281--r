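FORMATS <- c("turtle", "ntriples", "jsonld", "rdfxml")

test_that("an empty document maps to an empty graph and back", {
  doc <- sbol_document()
  expect_equal(nrow(to_graph(doc)), 0)
  expect_equal(serialize_sbol(doc, "ntriples"), "")
  expect_length(parse_sbol("", "ntriples")$top_levels, 0)
})

test_that("a minimal component emits exactly the enumerated triples", {
  cmp <- sbol_component("http://ex.org", "c", "https://identifiers.org/SBO:0000251")
  g <- to_graph(sbol_document(cmp))
  # rdf:type + hasNamespace + type, plus the one optional field set
  # (displayId) = 4 triples
  expect_equal(nrow(g), 4)
  key <- paste(g$subject, g$predicate, g$object)
  expect_setequal(key, c(
    "http://ex.org/c http://www.w3.org/1999/02/22-rdf-syntax-ns#type http://sbols.org/v3#Component",
    "http://ex.org/c http://sbols.org/v3#hasNamespace http://ex.org",
    "http://ex.org/c http://sbols.org/v3#type https://identifiers.org/SBO:0000251",
    "http://ex.org/c http://sbols.org/v3#displayId c"))
})

test_that("external ontology predicates are emitted unchanged", {
  cmp <- sbol_component("http://ex.org", "c", "https://identifiers.org/SBO:0000251")
  cmp$derivedFrom <- "http://ex.org/older/c"
  g <- to_graph(sbol_document(cmp))
  row <- g[g$predicate == "http://www.w3.org/ns/prov#wasDerivedFrom", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$object, "http://ex.org/older/c")
})

test_that("every fixture round-trips through every format", {
  for (doc in sbol_fixtures()) {
    ref <- to_graph(doc)
    for (f in FORMATS) {
      back <- parse_sbol(serialize_sbol(doc, f), f)
      expect_true(graph_isomorphic(to_graph(back), ref),
                  info = paste("format", f))
    }
  }
})

test_that("the same document gives identical triples via any two formats", {
  doc <- build_toggle_switch()
  graphs <- lapply(FORMATS, function(f)
    to_graph(parse_sbol(serialize_sbol(doc, f), f)))
  for (i in 2:length(graphs))
    expect_true(graph_isomorphic(graphs[[1]], graphs[[i]]))
})

test_that("foreign-namespace annotations survive all four serializations", {
  doc <- build_nor_gate()
  gate <- doc$top_levels[["http://example.com/norgate/nor_gate"]]
  gate <- add_annotation(gate, "http://purl.org/dc/terms/creator", "lab-42")
  gate <- add_annotation(gate, "http://example.org/myapp#linksTo",
                         "http://example.org/db/123", type = "iri")
  doc$top_levels[["http://example.com/norgate/nor_gate"]] <- gate
  for (f in FORMATS) {
    back <- parse_sbol(serialize_sbol(doc, f), f)
    g <- document_lookup(back, "http://example.com/norgate/nor_gate")
    preds <- vapply(g$annotations, `[[`, character(1), "predicate")
    expect_true("http://purl.org/dc/terms/creator" %in% preds, info = f)
    expect_true("http://example.org/myapp#linksTo" %in% preds, info = f)
    expect_true(graph_isomorphic(back, doc), info = f)
  }
})

test_that("unknown top-level types are preserved as opaque extension objects", {
  doc <- build_autoregulatory_device()
  nt <- serialize_sbol(doc, "ntriples")
  extra <- paste0("<http://example.org/widget1> ",
                  "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type> ",
                  "<http://example.org/schema#Widget> .\n",
                  "<http://example.org/widget1> ",
                  "<http://example.org/schema#knob> \"7\" .")
  back <- parse_sbol(paste(nt, extra, sep = "\n"), "ntriples")
  expect_length(back$extensions, 1)
  re <- serialize_sbol(back, "ntriples")
  expect_true(grepl("widget1", re))
  expect_true(graph_isomorphic(parse_sbol(re, "ntriples"), back))
})

test_that("an ownership cycle in the graph is rejected", {
  t <- function(s, p, o) sprintf("<%s> <%s> <%s> .", s, p, o)
  RT <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  S <- "http://sbols.org/v3#"
  lines <- c(
    t("http://ex/a", RT, paste0(S, "Component")),
    t("http://ex/a", paste0(S, "type"), "https://identifiers.org/SBO:0000251"),
    t("http://ex/a", paste0(S, "hasNamespace"), "http://ex"),
    t("http://ex/a", paste0(S, "hasFeature"), "http://ex/a/b"),
    t("http://ex/a/b", RT, paste0(S, "SubComponent")),
    t("http://ex/a/b", paste0(S, "hasLocation"), "http://ex/a"))
  expect_error(parse_sbol(paste(lines, collapse = "\n"), "ntriples"),
               "cycle")
})

test_that("a subject without rdf:type is rejected", {
  expect_error(parse_sbol('<http://ex/a> <http://ex/p> "v" .', "ntriples"),
               "rdf:type")
})

test_that("property vocabulary follows the naming conventions", {
  approved_lowercase <- c("displayId", "name", "description", "type", "role",
                          "orientation", "instanceOf", "definition",
                          "inChildOf", "refersTo", "start", "end", "at",
                          "participant", "restriction", "subject", "object",
                          "input", "output", "nondirectional", "elements",
                          "encoding", "template", "strategy", "variable",
                          "cardinality", "variant", "variantCollection",
                          "variantDerivation", "built", "member", "source",
                          "language", "framework", "format", "size", "hash",
                          "hashAlgorithm")
  for (cls in names(sbol3:::.sbol_schema)) {
    schema <- sbol3:::.sbol_schema[[cls]]
    # entity IRIs begin with an uppercase letter
    local_type <- sub(".*[#/]", "", schema$type_iri)
    expect_match(local_type, "^[A-Z]")
    for (fs in schema$fields) {
      if (!startsWith(fs$pred, "http://sbols.org/v3#")) next
      local <- sub(".*#", "", fs$pred)
      expect_true(grepl("^has[A-Z]", local) || local %in% approved_lowercase,
                  info = local)
    }
  }
})

test_that("canonical N-Triples output is lexicographically sorted", {
  nt <- canonical_ntriples(build_toggle_switch())
  lines <- strsplit(nt, "\n", fixed = TRUE)[[1]]
  expect_identical(lines, sort(lines, method = "radix"))
  # stable across rebuilds
  expect_identical(nt, canonical_ntriples(build_toggle_switch()))
})

test_that("serializations parse as RDF in an independent tool chain", {
  doc <- build_multicellular_system()
  td <- withr::local_tempdir()
  files <- c(turtle = "d.ttl", rdfxml = "d.rdf", jsonld = "d.jsonld",
             ntriples = "d.nt")
  for (f in names(files)) write_sbol(doc, file.path(td, files[[f]]), f)
  script <- file.path(td, "check.py")
  writeLines(c(
    "import sys, rdflib",
    "from rdflib.compare import isomorphic",
    "base = sys.argv[1]",
    "ref = rdflib.Graph().parse(base + '/d.nt', format='nt')",
    "ok = True",
    "for fn, fmt in [('d.ttl','turtle'), ('d.rdf','xml'), ('d.jsonld','json-ld')]:",
    "    g = rdflib.Graph().parse(base + '/' + fn, format=fmt)",
    "    ok = ok and isomorphic(g, ref)",
    "print('OK' if ok else 'MISMATCH')"), script)
  out <- system2("python", c(script, td), stdout = TRUE, stderr = TRUE)
  expect_equal(tail(out, 1), "OK")
})

test_that("syntax errors carry position information and unknown formats fail", {
  expect_error(parse_sbol("<a> <b> .", "ntriples"), "line")
  expect_error(serialize_sbol(sbol_document(), "pdf"), "unknown format")
  expect_error(parse_sbol("", "pdf"), "unknown format")
})
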