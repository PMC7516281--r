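gb_fixture_path <- function() {
  system.file("extdata", "synthetic_expression_unit.gb", package = "sbol3")
}

mk_gb_text <- function(features, seq_letters) {
  lines <- c(sprintf("LOCUS       TEST1 %d bp DNA linear", nchar(seq_letters)),
             "FEATURES             Location/Qualifiers",
             features, "ORIGIN")
  s <- tolower(seq_letters)
  for (p in seq(1, nchar(s), by = 60))
    lines <- c(lines, sprintf("%9d %s", p, substring(s, p, min(p + 59, nchar(s)))))
  paste(c(lines, "//"), collapse = "\n")
}

test_that("a GenBank CDS feature becomes a located SequenceFeature with the SO role", {
  txt <- mk_gb_text("     CDS             10..30", strrep("ACGTG", 10))
  rec <- parse_genbank(txt)
  expect_equal(nchar(rec$sequence), 50)
  imp <- genbank_to_component(rec, "http://example.com/import")
  expect_length(imp$component$features, 1)
  f <- imp$component$features[[1]]
  expect_s3_class(f, "sbol_sequence_feature")
  expect_equal(f$locations[[1]]$start, 10L)
  expect_equal(f$locations[[1]]$end, 30L)
  expect_equal(f$roles, ontology_terms()$SO[["CDS"]])
  expect_equal(imp$component$types, ontology_terms()$SBO[["dna"]])
  expect_equal(imp$sequence$elements, rec$sequence)
})

test_that("complement, join and fuzzy GenBank locations are handled", {
  txt <- mk_gb_text(c("     promoter        complement(5..8)",
                      "     misc_feature    join(2..4,10..12)"),
                    strrep("ACGT", 10))
  imp <- genbank_to_component(parse_genbank(txt), "http://example.com/import")
  f1 <- imp$component$features[[1]]
  expect_equal(f1$orientation, "http://sbols.org/v3#reverseComplement")
  expect_equal(c(f1$locations[[1]]$start, f1$locations[[1]]$end), c(5L, 8L))
  f2 <- imp$component$features[[2]]
  expect_length(f2$locations, 2)

  fuzzy <- mk_gb_text("     CDS             <3..9", strrep("ACGT", 5))
  expect_warning(imp2 <- genbank_to_component(parse_genbank(fuzzy),
                                              "http://example.com/import"),
                 "clamped")
  expect_equal(imp2$component$features[[1]]$locations[[1]]$start, 3L)
})

test_that("a record with zero features still yields component plus sequence", {
  txt <- mk_gb_text(character(0), "ACGTACGTAC")
  imp <- genbank_to_component(parse_genbank(txt), "http://example.com/import")
  expect_length(imp$component$features, 0)
  expect_equal(imp$sequence$elements, "ACGTACGTAC")
  doc <- sbol_document(imp$sequence, imp$component)
  expect_equal(sum(validate_document(doc)$severity == "error"), 0)
})

test_that("genbank -> sbol3 -> genbank is feature-table identical on the shipped fixture", {
  rec <- read_genbank(gb_fixture_path())
  imp <- genbank_to_component(rec, "http://example.com/import")
  doc <- sbol_document(imp$sequence, imp$component)
  back <- component_to_genbank(imp$component, doc)
  orig <- Filter(function(f) f$key != "source", rec$features)
  expect_equal(lapply(back$features, function(f) f[c("key", "location")]),
               lapply(orig, function(f) f[c("key", "location")]))
  expect_equal(back$sequence, rec$sequence)
  # and the flat file itself re-parses to the same record
  reparsed <- parse_genbank(write_genbank(back))
  expect_equal(lapply(reparsed$features, function(f) f[c("key", "location")]),
               lapply(orig, function(f) f[c("key", "location")]))
})

test_that("unlocated SubComponents are omitted and protein export is refused", {
  terms <- ontology_terms()
  s <- sbol_sequence("http://ex.org", "s", elements = "ACGTACGTAC")
  cmp <- sbol_component("http://ex.org", "dev", terms$SBO[["dna"]],
                        sequences = s$uri)
  cmp <- add_feature(cmp, sub_component("floating", instanceOf = "http://ex.org/p"))
  doc <- sbol_document(s, cmp)
  expect_warning(rec <- component_to_genbank(cmp, doc), "omitted")
  expect_length(rec$features, 0)

  prot <- sbol_component("http://ex.org", "prot", terms$SBO[["protein"]])
  expect_error(component_to_genbank(prot, doc), "nucleotide")
})

test_that("FASTA records become Sequences with inferred encodings", {
  s <- fasta_to_sequence(list(id = "x", residues = "acgt"), "http://ex.org")
  expect_equal(s$elements, "ACGT")
  expect_match(s$encoding, "format_1207")
  p <- fasta_to_sequence(list(id = "p", residues = "MKV"), "http://ex.org")
  expect_match(p$encoding, "format_1208")
  expect_error(fasta_to_sequence(list(id = "e", residues = ""), "http://ex.org"),
               "empty")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rec1 a dna record", "acgtacgt", ">rec2", "MKVL"), fa)
  recs <- read_fasta(fa)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "rec1")
  expect_equal(fasta_to_sequence(recs[[2]], "http://ex.org")$encoding,
               "https://identifiers.org/edam:format_1208")
})

test_that("migrating the SBOL2 toggle yields no identity mappings", {
  snap <- build_sbol2_toggle_switch()
  res <- sbol2_to_sbol3(snap)
  st <- document_stats(res$document)
  expect_equal(st$count[st$class == "sbol_component_reference"], 0)
  expect_length(res$report$collapsed_maps_tos, 4)
  # MapsTo accounting: input count = collapsed + emitted references
  expect_equal(unname(res$report$counts["MapsTo"]),
               length(res$report$collapsed_maps_tos) +
                 length(res$report$component_references))

  # every promoter/CDS element appears exactly once across the document
  feats <- unlist(lapply(res$document$top_levels,
                         function(tl) names(tl$features)))
  for (el in c("pTet", "pLac", "lacI", "tetR"))
    expect_equal(sum(feats == el), 1, info = el)

  # element conservation: distinct leaf definitions referenced are unchanged
  leaf_before <- unique(unlist(lapply(snap$component_definitions, function(cd)
    vapply(cd$components, `[[`, character(1), "definition"))))
  subs <- unlist(lapply(res$document$top_levels, function(tl)
    lapply(tl$features, function(f)
      if (inherits(f, "sbol_sub_component")) f$instanceOf)), use.names = FALSE)
  leaf_defs_after <- unique(subs[vapply(subs, function(u) {
    d <- document_lookup(res$document, u)
    !is.null(d) && length(d$features) == 0
  }, logical(1))])
  expect_length(leaf_defs_after, length(leaf_before))

  expect_equal(sum(validate_document(res$document)$severity == "error"), 0)
})

test_that("a lone ComponentDefinition with an unlinked annotation migrates to a SequenceFeature", {
  u <- "http://example.com/sbol2b"
  snap <- sbol2_snapshot(
    sequences = list(sbol2_sequence(paste0(u, "/s/1"), "s",
                                    elements = strrep("ACGT", 10))),
    component_definitions = list(sbol2_component_definition(
      uri = paste0(u, "/cd/1"), displayId = "cd",
      types = "http://www.biopax.org/release/biopax-level3.owl#DnaRegion",
      sequence = paste0(u, "/s/1"),
      sequence_annotations = list(list(
        uri = paste0(u, "/cd/1/anno"), displayId = "anno", component = NULL,
        ranges = list(list(start = 3, end = 12, orientation = NULL)),
        roles = ontology_terms()$SO[["promoter"]])))))
  res <- sbol2_to_sbol3(snap)
  cmp <- res$document$top_levels[[paste0(u, "/1/cd")]]
  expect_s3_class(cmp, "sbol_component")
  expect_length(cmp$features, 1)
  expect_s3_class(cmp$features[[1]], "sbol_sequence_feature")
  expect_equal(cmp$features[[1]]$locations[[1]]$start, 3L)
  # version segment folded into the prefix
  expect_equal(cmp$namespace, paste0(u, "/1"))
})

test_that("FunctionalComponent directions populate the Interface", {
  u <- "http://example.com/sbol2c"
  cd <- sbol2_component_definition(
    uri = paste0(u, "/part/1"), displayId = "part",
    types = "http://www.biopax.org/release/biopax-level3.owl#DnaRegion")
  md <- sbol2_module_definition(
    uri = paste0(u, "/mod/1"), displayId = "mod",
    functional_components = list(
      list(uri = paste0(u, "/mod/1/fin"), displayId = "fin",
           definition = paste0(u, "/part/1"), direction = "in",
           access = "public", maps_tos = list()),
      list(uri = paste0(u, "/mod/1/fio"), displayId = "fio",
           definition = paste0(u, "/part/1"), direction = "inout",
           access = "private", maps_tos = list())))
  res <- sbol2_to_sbol3(sbol2_snapshot(component_definitions = list(cd),
                                       module_definitions = list(md)))
  mod <- res$document$top_levels[[paste0(u, "/1/mod")]]
  expect_equal(mod$types, ontology_terms()$SBO[["functional_entity"]])
  ifc <- mod$interface
  expect_setequal(ifc$inputs, c(mod$features[["fin"]]$uri,
                                mod$features[["fio"]]$uri))
  expect_equal(ifc$outputs, mod$features[["fio"]]$uri)
  # dropped access fields are reported
  expect_true(any(grepl("access", res$report$dropped)))
})

test_that("the SBOL2 RDF/XML reader reconstructs the snapshot surface", {
  path <- system.file("extdata", "sbol2_expression_unit.xml", package = "sbol3")
  snap <- read_sbol2(path)
  expect_length(snap$component_definitions, 1)
  expect_length(snap$module_definitions, 1)
  expect_length(snap$sequences, 1)
  cd <- snap$component_definitions[[1]]
  expect_equal(cd$displayId, "unit")
  expect_length(cd$sequence_annotations, 1)
  expect_equal(cd$sequence_annotations[[1]]$ranges[[1]]$end, 35L)
  fc <- snap$module_definitions[[1]]$functional_components[[1]]
  expect_equal(fc$direction, "in")

  res <- sbol2_to_sbol3(snap)
  expect_equal(sum(validate_document(res$document)$severity == "error"), 0)
  cmp <- res$document$top_levels[["http://example.com/sbol2file/1/unit"]]
  expect_length(cmp$features, 1)
  expect_equal(cmp$features[[1]]$roles, ontology_terms()$SO[["promoter"]])
})

test_that("dangling snapshot references are an error", {
  u <- "http://example.com/sbol2d"
  cd <- sbol2_component_definition(
    uri = paste0(u, "/cd/1"), displayId = "cd",
    types = "http://www.biopax.org/release/biopax-level3.owl#DnaRegion",
    components = list(list(uri = paste0(u, "/cd/1/x"), displayId = "x",
                           definition = paste0(u, "/nothere/1"),
                           access = NULL)))
  expect_error(sbol2_to_sbol3(sbol2_snapshot(component_definitions = list(cd))),
               "dangling")
})
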