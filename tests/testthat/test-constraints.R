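rng <- function(s, e, seq = "http://ex/s") loc_range(seq, s, e)

test_that("allen_relation classifies the canonical cases", {
  expect_equal(allen_relation(rng(1, 10), rng(1, 10)), "equals")
  expect_equal(allen_relation(rng(1, 5), rng(6, 10)), "meets")
  expect_equal(allen_relation(rng(1, 10), rng(3, 5)), "strictlyContains")
  expect_equal(allen_relation(rng(1, 4), rng(8, 9)), "strictlyPrecedes")
  expect_equal(allen_relation(rng(1, 5), rng(3, 9)), "overlaps")
  expect_equal(allen_relation(rng(1, 3), rng(1, 9)), "starts")
  expect_equal(allen_relation(rng(7, 9), rng(1, 9)), "finishes")
  expect_equal(allen_relation(rng(1, 9), rng(1, 3)), "contains")
  expect_equal(allen_relation(rng(3, 5), rng(1, 9)), "during")
  expect_error(allen_relation(rng(1, 2), rng(1, 2, seq = "http://ex/other")),
               "different sequences")
})

test_that("exactly one relation holds per pair, matching the set oracle", {
  ranges <- all_test_ranges(1L, 8L)
  for (a in ranges) for (b in ranges) {
    got <- allen_relation(list(start = a[["s"]], end = a[["e"]]),
                          list(start = b[["s"]], end = b[["e"]]))
    want <- allen_oracle(a[["s"]], a[["e"]], b[["s"]], b[["e"]])
    expect_identical(got, want,
                     info = sprintf("(%d..%d, %d..%d)", a[["s"]], a[["e"]],
                                    b[["s"]], b[["e"]]))
  }
})

test_that("swapping arguments yields the converse relation", {
  ranges <- all_test_ranges(1L, 8L)
  for (a in ranges) for (b in ranges) {
    fwd <- allen_relation(list(start = a[["s"]], end = a[["e"]]),
                          list(start = b[["s"]], end = b[["e"]]))
    rev <- allen_relation(list(start = b[["s"]], end = b[["e"]]),
                          list(start = a[["s"]], end = a[["e"]]))
    if (fwd %in% names(allen_converse)) {
      expect_identical(rev, unname(allen_converse[fwd]))
    } else if (fwd == "contains") {
      expect_true(rev %in% c("starts", "finishes"))
    } else {  # starts / finishes are the converses of contains
      expect_identical(rev, "contains")
    }
  }
})

test_that("identity constraints are evaluated from resolved definitions", {
  doc <- build_multicellular_system()
  res <- evaluate_constraint(doc,
    "http://example.com/multicellular/multicellular_system/shared_AHL")
  expect_equal(res$status, "holds")

  # differentFrom between two SubComponents instantiating the same Component
  dna <- ontology_terms()$SBO[["dna"]]
  def <- sbol_component("http://ex.org", "part", dna)
  cmp <- sbol_component("http://ex.org", "dev", dna)
  cmp <- add_feature(cmp, sub_component("a", instanceOf = def$uri))
  cmp <- add_feature(cmp, sub_component("b", instanceOf = def$uri))
  cmp <- add_constraint(cmp, "k", "differentFrom", cmp$features[["a"]]$uri,
                        cmp$features[["b"]]$uri)
  doc2 <- sbol_document(def, cmp)
  expect_equal(evaluate_constraint(doc2, cmp$constraints[["k"]])$status,
               "violated")
})

test_that("topological and replaces restrictions are representable, not computed", {
  doc <- build_multicellular_system()
  res <- evaluate_constraint(doc,
    "http://example.com/multicellular/sender_system/cell_contains_AHL")
  expect_equal(res$status, "notEvaluable")
  expect_match(res$detail, "space|geometry")

  dna <- ontology_terms()$SBO[["dna"]]
  cmp <- sbol_component("http://ex.org", "dev", dna)
  cmp <- add_feature(cmp, local_sub_component("a", types = dna))
  cmp <- add_feature(cmp, local_sub_component("b", types = dna))
  cmp <- add_constraint(cmp, "k", "replaces", cmp$features[["a"]]$uri,
                        cmp$features[["b"]]$uri)
  expect_equal(evaluate_constraint(sbol_document(cmp),
                                   cmp$constraints[["k"]])$status,
               "notEvaluable")
})

test_that("sequential constraints are decided from feature ranges", {
  dna <- ontology_terms()$SBO[["dna"]]
  s <- sbol_sequence("http://ex.org", "s",
                     elements = strrep("ACGT", 5))
  mk <- function(sub_start, sub_end, obj_start, obj_end, restriction) {
    cmp <- sbol_component("http://ex.org", "dev", dna, sequences = s$uri)
    cmp <- add_feature(cmp, sequence_feature("a", rng(sub_start, sub_end, s$uri),
                                             roles = ontology_terms()$SO[["promoter"]]))
    cmp <- add_feature(cmp, sequence_feature("b", rng(obj_start, obj_end, s$uri),
                                             roles = ontology_terms()$SO[["CDS"]]))
    cmp <- add_constraint(cmp, "k", restriction, cmp$features[["a"]]$uri,
                          cmp$features[["b"]]$uri)
    sbol_document(s, cmp)
  }
  # subject 1..5, object 3..9: the oracle gives overlaps, so strictlyPrecedes
  # is violated
  expect_equal(allen_oracle(1, 5, 3, 9), "overlaps")
  expect_equal(check_all(mk(1, 5, 3, 9, "strictlyPrecedes"))$status, "violated")
  expect_equal(check_all(mk(1, 5, 6, 9, "strictlyPrecedes"))$status, "violated")
  expect_equal(check_all(mk(1, 4, 6, 9, "strictlyPrecedes"))$status, "holds")
  # precedes is the union strictlyPrecedes U meets
  expect_equal(check_all(mk(1, 5, 6, 9, "precedes"))$status, "holds")
  expect_equal(check_all(mk(1, 4, 6, 9, "precedes"))$status, "holds")
  expect_equal(check_all(mk(1, 9, 3, 5, "contains"))$status, "holds")
  expect_equal(check_all(mk(1, 9, 1, 5, "contains"))$status, "holds")
})

test_that("orientation constraints use Feature orientation when both are set", {
  dna <- ontology_terms()$SBO[["dna"]]
  cmp <- sbol_component("http://ex.org", "dev", dna)
  cmp <- add_feature(cmp, local_sub_component("a", types = dna,
                                              orientation = "inline"))
  cmp <- add_feature(cmp, local_sub_component("b", types = dna,
                                              orientation = "reverseComplement"))
  cmp <- add_feature(cmp, local_sub_component("c", types = dna))
  f <- function(id) cmp$features[[id]]$uri
  cmp <- add_constraint(cmp, "same", "sameOrientationAs", f("a"), f("b"))
  cmp <- add_constraint(cmp, "opp", "oppositeOrientationAs", f("a"), f("b"))
  cmp <- add_constraint(cmp, "unset", "sameOrientationAs", f("a"), f("c"))
  res <- check_all(sbol_document(cmp))
  st <- stats::setNames(res$status, sub(".*/", "", res$constraint))
  expect_equal(unname(st["same"]), "violated")
  expect_equal(unname(st["opp"]), "holds")
  expect_equal(unname(st["unset"]), "notEvaluable")
})

test_that("constraints without ground data are notEvaluable, and bad IRIs raise", {
  dna <- ontology_terms()$SBO[["dna"]]
  cmp <- sbol_component("http://ex.org", "dev", dna)
  cmp <- add_feature(cmp, local_sub_component("a", types = dna))
  cmp <- add_feature(cmp, local_sub_component("b", types = dna))
  cmp <- add_constraint(cmp, "k", "meets", cmp$features[["a"]]$uri,
                        cmp$features[["b"]]$uri)
  expect_equal(evaluate_constraint(sbol_document(cmp),
                                   cmp$constraints[["k"]])$status,
               "notEvaluable")
  cmp$constraints[["k"]]$restriction <- "http://ex/frobnicates"
  expect_error(evaluate_constraint(sbol_document(cmp), cmp$constraints[["k"]]),
               "closed vocabulary")
})

test_that("check_all reports every constraint without aborting", {
  expect_equal(nrow(check_all(build_toggle_switch())), 0)
  res <- check_all(build_multicellular_system())
  expect_equal(nrow(res), 3)
  expect_false(is.unsorted(res$constraint))
  expect_true("holds" %in% res$status)
  expect_true("notEvaluable" %in% res$status)
})

test_that("the restriction families are closed and share no IRIs", {
  v <- restriction_vocabulary()
  expect_length(v$identity, 3)
  expect_length(v$sequential, 11)
  expect_length(v$topological, 6)
  all_iris <- unlist(v, use.names = FALSE)
  expect_equal(anyDuplicated(all_iris), 0L)
  # names shared across families are distinct IRIs
  for (nm in c("contains", "strictlyContains", "meets", "overlaps"))
    expect_false(v$sequential[[nm]] == v$topological[[nm]])
})
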