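dna <- function() ontology_terms()$SBO[["dna"]]

test_that("component creation follows the <prefix>/<displayId> rule", {
  cmp <- sbol_component("http://example.com/toggleswitch", "lacI",
                        "https://identifiers.org/SBO:0000251")
  expect_equal(cmp$uri, "http://example.com/toggleswitch/lacI")
  expect_equal(cmp$namespace, "http://example.com/toggleswitch")
  expect_length(cmp$features, 0)
  expect_length(cmp$interactions, 0)
  expect_length(cmp$constraints, 0)
  expect_error(sbol_component("http://example.com", "x", character(0)),
               "non-empty")
  expect_error(sbol_component("http://example.com", "1abc", dna()),
               "displayId")
})

test_that("adding features assigns owner-prefixed URIs and enforces uniqueness", {
  cmp <- sbol_component("http://ex.org", "tu", dna())
  cmp <- add_feature(cmp, sub_component("pTet", instanceOf = "http://ex.org/pTet"))
  expect_equal(cmp$features[["pTet"]]$uri, "http://ex.org/tu/pTet")
  expect_error(sequence_feature("sf", locations = list()), "location")
  cmp <- add_feature(cmp, local_sub_component("f1", types = dna()))
  expect_error(add_feature(cmp, local_sub_component("f1", types = dna())),
               "duplicate")
})

test_that("interactions require locally owned participants", {
  sbo <- ontology_terms()$SBO
  cmp <- sbol_component("http://ex.org", "tu", dna())
  cmp <- add_feature(cmp, local_sub_component("cds", types = dna()))
  cmp <- add_feature(cmp, local_sub_component("prom", types = dna()))
  cmp <- add_interaction(cmp, "rep", sbo[["inhibition"]], list(
    list(roles = sbo[["inhibitor"]], participant = cmp$features[["cds"]]$uri),
    list(roles = sbo[["inhibited"]], participant = cmp$features[["prom"]]$uri)))
  expect_length(cmp$interactions[["rep"]]$participations, 2)

  other <- sbol_component("http://ex.org", "other", dna())
  other <- add_feature(other, local_sub_component("x", types = dna()))
  expect_error(add_interaction(cmp, "bad", sbo[["inhibition"]], list(
    list(roles = sbo[["inhibitor"]], participant = other$features[["x"]]$uri))),
    "not a feature")

  # an empty interaction is allowed, but the validator flags it
  cmp <- add_interaction(cmp, "empty", sbo[["inhibition"]], list())
  f <- validate_document(sbol_document(cmp))
  expect_true("SBOL3-INT-001" %in% f$ruleId)
  expect_false("error" %in% f$severity[f$ruleId == "SBOL3-INT-001"])
})

test_that("interfaces reference local features and may be empty", {
  cmp <- sbol_component("http://ex.org", "gate", dna())
  for (id in c("in1", "in2", "out1"))
    cmp <- add_feature(cmp, local_sub_component(id, types = dna()))
  furi <- function(id) cmp$features[[id]]$uri
  cmp <- set_interface(cmp, inputs = c(furi("in1"), furi("in2")),
                       outputs = furi("out1"))
  expect_length(cmp$interface$inputs, 2)
  expect_length(cmp$interface$outputs, 1)

  expect_error(set_interface(cmp, inputs = "http://ex.org/other/deep/f"),
               "features of")
  expect_error(set_interface(cmp, inputs = furi("in1"),
                             nondirectionals = furi("in1")),
               "non-directional")
  cmp2 <- set_interface(cmp)  # entirely empty interface is valid
  f <- validate_document(sbol_document(cmp2))
  expect_false("error" %in% f$severity)
})

test_that("component references resolve through one or many layers", {
  doc <- build_multicellular_system()
  ref <- document_lookup(doc,
    "http://example.com/multicellular/multicellular_system/AHL_from_sender")
  target <- resolve_reference(doc, ref)
  expect_s3_class(target, "sbol_externally_defined")
  expect_equal(target$uri, "http://example.com/multicellular/sender_system/AHL")

  # a second layer: reference to a reference
  sys <- document_lookup(doc,
    "http://example.com/multicellular/multicellular_system")
  sys <- add_feature(sys, component_reference(
    "AHL_hop", inChildOf = sys$features[["sender"]]$uri,
    refersTo = sys$features[["AHL_from_sender"]]$uri))
  doc2 <- sbol_document(
    document_lookup(doc, "http://example.com/multicellular/sender_system"),
    document_lookup(doc, "http://example.com/multicellular/receiver_system"),
    sys)
  hop <- resolve_reference(doc2, sys$features[["AHL_hop"]]$uri)
  expect_equal(hop$uri, target$uri)

  # a self-referential chain is a cycle error
  sys$features[["AHL_hop"]]$refersTo <- sys$features[["AHL_hop"]]$uri
  doc3 <- sbol_document(
    document_lookup(doc, "http://example.com/multicellular/sender_system"),
    document_lookup(doc, "http://example.com/multicellular/receiver_system"),
    sys)
  expect_error(resolve_reference(doc3, sys$features[["AHL_hop"]]$uri), "cycle")
})

test_that("document lookup finds top levels and descendants, NULL otherwise", {
  doc <- build_autoregulatory_device()
  cmp <- document_lookup(doc, "http://example.com/autoreg/autoreg_device")
  expect_s3_class(cmp, "sbol_component")
  feat <- document_lookup(doc, "http://example.com/autoreg/autoreg_device/pReg")
  expect_s3_class(feat, "sbol_sub_component")
  expect_null(document_lookup(doc, "http://example.com/autoreg/nope"))
})

test_that("child-URI closure holds for every object built via the public API", {
  for (doc in sbol_fixtures()) {
    check <- function(obj) {
      for (k in sbol3:::sbol_children(obj)) {
        expect_equal(k$uri, paste0(obj$uri, "/", k$displayId))
        check(k)
      }
    }
    for (tl in doc$top_levels) check(tl)
  }
})

test_that("every internal reference of each fixture resolves", {
  ref_fields <- c("instanceOf", "sequence", "sequences", "participant",
                  "subject", "object", "template", "variable", "variants",
                  "inChildOf", "refersTo")
  for (doc in sbol_fixtures()) {
    for (pair in sbol3:::.doc_objects_with_owner(doc)) {
      for (f in intersect(names(pair$obj), ref_fields)) {
        for (u in pair$obj[[f]]) {
          if (startsWith(u, "http://example.com/"))
            expect_false(is.null(document_lookup(doc, u)),
                         info = paste(pair$obj$uri, f, u))
        }
      }
    }
  }
})

test_that("in the toggle switch every element appears exactly once", {
  doc <- build_toggle_switch()
  st <- document_stats(doc)
  expect_equal(st$count[st$class == "sbol_component_reference"], 0)
  sw <- document_lookup(doc, "http://example.com/toggleswitch/toggle_switch")
  part_ids <- c("pTet", "rbs_lacI", "lacI", "term_lacI",
                "pLac", "rbs_tetR", "tetR", "term_tetR")
  # each design element occurs once as a definition and once as a feature
  expect_setequal(names(sw$features), part_ids)
  defs <- vapply(sw$features, `[[`, character(1), "instanceOf")
  expect_equal(anyDuplicated(defs), 0L)
  all_feats <- unlist(lapply(doc$top_levels, function(tl) names(tl$features)))
  expect_equal(anyDuplicated(all_feats), 0L)
})

test_that("type totality: components carry types, sequence features carry locations", {
  for (doc in sbol_fixtures()) {
    for (pair in sbol3:::.doc_objects_with_owner(doc)) {
      o <- pair$obj
      if (inherits(o, "sbol_component")) expect_gt(length(o$types), 0)
      if (inherits(o, "sbol_sequence_feature")) expect_gt(length(o$locations), 0)
    }
  }
})

test_that("locations enforce their coordinate conventions", {
  expect_error(loc_range("http://ex/s", 0, 5), "start")
  expect_error(loc_range("http://ex/s", 6, 5), "start")
  expect_error(loc_cut("http://ex/s", -1), ">= 0")
  r <- loc_range("http://ex/s", 3, 3)
  expect_equal(c(r$start, r$end), c(3L, 3L))
  expect_s3_class(loc_entire_sequence("http://ex/s"), "sbol_entire_sequence")
})

test_that("sequences validate their alphabet against the encoding", {
  s <- sbol_sequence("http://ex.org", "s", elements = "acgtacgt")
  expect_equal(s$elements, "ACGTACGT")
  expect_match(s$encoding, "format_1207")
  p <- sbol_sequence("http://ex.org", "p", elements = "MKVLT")
  expect_match(p$encoding, "format_1208")
  expect_error(sbol_sequence("http://ex.org", "bad", elements = "ACGT!!"),
               "infer|illegal")
})
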