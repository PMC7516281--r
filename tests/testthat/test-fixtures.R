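test_that("the auto-regulatory device has four parts and one interaction", {
  doc <- build_autoregulatory_device()
  dev <- document_lookup(doc, "http://example.com/autoreg/autoreg_device")
  expect_length(dev$features, 4)
  expect_true(all(vapply(dev$features, inherits, logical(1),
                         "sbol_sub_component")))
  expect_length(dev$interactions, 1)
  ia <- dev$interactions[[1]]
  expect_equal(ia$types, ontology_terms()$SBO[["inhibition"]])
  expect_length(ia$participations, 2)
  # the CDS feature is the inhibitor, the promoter the inhibited
  roles <- lapply(ia$participations, `[[`, "roles")
  parts <- vapply(ia$participations, `[[`, character(1), "participant")
  expect_equal(parts[[1]], dev$features[["repR"]]$uri)
  expect_equal(parts[[2]], dev$features[["pReg"]]$uri)
  expect_equal(sum(validate_document(doc)$severity == "error"), 0)
})

test_that("the toggle switch co-locates structure and function in one parent", {
  doc <- build_toggle_switch()
  st <- document_stats(doc)
  expect_equal(st$count[st$class == "sbol_component_reference"], 0)
  sw <- document_lookup(doc, "http://example.com/toggleswitch/toggle_switch")
  expect_length(sw$interactions, 2)
  expect_length(sw$features, 8)
  # interactions reference features of the same parent directly
  for (ia in sw$interactions)
    for (p in ia$participations)
      expect_true(p$participant %in%
                    vapply(sw$features, `[[`, character(1), "uri"))
})

test_that("the multicellular system carries compartment roles, cell typing and shared identity", {
  doc <- build_multicellular_system()
  terms <- ontology_terms()
  for (id in c("sender_system", "receiver_system")) {
    sys <- document_lookup(doc, paste0("http://example.com/multicellular/", id))
    expect_true(terms$SBO[["functional_compartment"]] %in% sys$roles, info = id)
    cell <- sys$features[["cell"]]
    expect_true(terms$GO[["cell"]] %in% cell$types)
    expect_true(terms$SBO[["physical_compartment"]] %in% cell$roles)
  }
  res <- check_all(doc)
  identity_row <- res[grepl("shared_AHL", res$constraint), ]
  expect_equal(identity_row$status, "holds")
  expect_equal(sum(validate_document(doc)$severity == "error"), 0)
})

test_that("the NOR gate exposes two inputs and one output over four parts", {
  doc <- build_nor_gate()
  gate <- document_lookup(doc, "http://example.com/norgate/nor_gate")
  subs <- Filter(function(f) inherits(f, "sbol_sub_component"), gate$features)
  expect_length(subs, 4)
  expect_length(gate$interface$inputs, 2)
  expect_length(gate$interface$outputs, 1)
  dna_def <- document_lookup(doc, gate$features[["dna_region"]]$instanceOf)
  expect_length(dna_def$features, 4)  # two binding sites, promoter, gRNA CDS
  expect_equal(sum(validate_document(doc)$severity == "error"), 0)
})

test_that("the combinatorial template enumerates variant x slot designs", {
  doc <- build_combinatorial_template()
  template <- document_lookup(doc, "http://example.com/library/tu_template")
  lscs <- Filter(function(f) inherits(f, "sbol_local_sub_component"),
                 template$features)
  expect_length(lscs, 1)
  cd <- document_lookup(doc, "http://example.com/library/promoter_library")
  vf <- cd$variableFeatures[[1]]
  slot <- document_lookup(doc, vf$variable)
  expect_s3_class(slot, "sbol_local_sub_component")
  # enumeration oracle: the number of derived designs is the product of the
  # variant-set sizes (one variable with 3 variants, cardinality one)
  expected_n <- prod(vapply(cd$variableFeatures, function(v)
    length(v$variants), integer(1)))
  derived <- enumerate_derivation(doc, cd)
  expect_length(derived, expected_n)
  for (d in derived) {
    expect_false(any(vapply(d$features, inherits, logical(1),
                            "sbol_local_sub_component")))
    expect_true(d$features[["promoter_slot"]]$instanceOf %in% vf$variants)
  }
})

test_that("fixtures are deterministic builds", {
  a <- sbol_fixtures()
  b <- sbol_fixtures()
  for (nm in names(a)) expect_true(graph_isomorphic(a[[nm]], b[[nm]]), info = nm)
})

test_that("the fixture corpus can be exported to disk", {
  td <- withr::local_tempdir()
  paths <- export_fixtures(td, format = "turtle")
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))
  back <- read_sbol(paths[[1]])
  expect_true(graph_isomorphic(back, sbol_fixtures()[[1]]))
})
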