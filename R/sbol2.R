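# SBOL2 -> SBOL3 migration.
#
# SBOL2 input is consumed through a minimal snapshot representation carrying
# exactly the class surface the migration table needs (ComponentDefinition,
# ModuleDefinition, Sequence, component/functional-component instances,
# SequenceAnnotation, MapsTo, Interaction), either built in code or read
# from SBOL2 RDF/XML by read_sbol2(). Mapping summary:
#   ComponentDefinition -> Component
#   ModuleDefinition    -> Component (functional entity, SBO:0000241)
#   Component/Module/FunctionalComponent instances -> SubComponent
#   SequenceAnnotation  -> locations on the linked SubComponent, or a
#                          SequenceFeature when unlinked
#   MapsTo              -> collapsed when the SBOL2 "explode" pattern makes
#                          local and remote the same element (the exposed
#                          part is lifted into the merged Component), else a
#                          ComponentReference
#   FunctionalComponent direction in/out/inout -> Interface membership
#   access              -> dropped, with a report entry
#   <prefix>/<displayId>/<version> URIs -> version folded into the prefix

SBOL2_NS <- "http://sbols.org/v2#"

.BIOPAX_TO_SBO <- c(
  "http://www.biopax.org/release/biopax-level3.owl#DnaRegion" = "dna",
  "http://www.biopax.org/release/biopax-level3.owl#Dna" = "dna",
  "http://www.biopax.org/release/biopax-level3.owl#RnaRegion" = "rna",
  "http://www.biopax.org/release/biopax-level3.owl#Rna" = "rna",
  "http://www.biopax.org/release/biopax-level3.owl#Protein" = "protein",
  "http://www.biopax.org/release/biopax-level3.owl#SmallMolecule" = "simple_chemical",
  "http://www.biopax.org/release/biopax-level3.owl#Complex" = "noncovalent_complex"
)

.sbol2_map_type <- function(type_iri) {
  sbo <- ontology_terms()$SBO
  nm <- .BIOPAX_TO_SBO[type_iri]
  if (!is.na(nm)) unname(sbo[[nm]]) else type_iri
}

#' Assemble an SBOL2-style snapshot
#'
#' @param component_definitions,module_definitions,sequences lists of record
#'   forms (see the constructors below).
#' @return an `sbol2_snapshot`.
#' @export
sbol2_snapshot <- function(component_definitions = list(),
                           module_definitions = list(),
                           sequences = list()) {
  structure(list(component_definitions = component_definitions,
                 module_definitions = module_definitions,
                 sequences = sequences),
            class = "sbol2_snapshot")
}

#' SBOL2 snapshot record constructors
#'
#' Minimal record forms for the SBOL2 classes the migrator consumes.
#' `components` of a ComponentDefinition are part instances
#' (`list(uri, displayId, definition, access)`); `sequence_annotations` are
#' `list(uri, displayId, component, ranges, roles)` where `component` links
#' the annotation to a part instance (or is NULL) and `ranges` is a list of
#' `list(start, end, orientation)`. A ModuleDefinition's
#' `functional_components` are `list(uri, displayId, definition, direction,
#' access, maps_tos)`; each MapsTo is `list(uri, local, remote)` with `local`
#' a functional component of the same module and `remote` a part instance
#' inside this functional component's definition. `interactions` are
#' `list(uri, displayId, types, participations)` with participations
#' `list(uri, roles, participant)` referencing functional components.
#'
#' @param uri,displayId,types,roles,sequence,components,sequence_annotations,functional_components,interactions,elements,encoding record fields.
#' @name sbol2_records
NULL

#' @export
#' @rdname sbol2_records
sbol2_component_definition <- function(uri, displayId, types = character(0),
                                       roles = character(0), sequence = NULL,
                                       components = list(),
                                       sequence_annotations = list()) {
  list(uri = uri, displayId = displayId, types = types, roles = roles,
       sequence = sequence, components = components,
       sequence_annotations = sequence_annotations)
}

#' @export
#' @rdname sbol2_records
sbol2_module_definition <- function(uri, displayId,
                                    functional_components = list(),
                                    interactions = list()) {
  list(uri = uri, displayId = displayId,
       functional_components = functional_components,
       interactions = interactions)
}

#' @export
#' @rdname sbol2_records
sbol2_sequence <- function(uri, displayId, elements, encoding = NULL) {
  list(uri = uri, displayId = displayId, elements = elements,
       encoding = encoding)
}

# derive (namespace, displayId) from an SBOL2 URI, folding a trailing
# version segment into the prefix: <p>/<id>/<ver> -> namespace <p>/<ver>
.sbol2_identity <- function(uri, displayId) {
  if (endsWith(uri, paste0("/", displayId))) {
    return(list(namespace = substr(uri, 1, nchar(uri) - nchar(displayId) - 1L),
                displayId = displayId))
  }
  segs <- strsplit(uri, "/", fixed = TRUE)[[1]]
  n <- length(segs)
  if (n >= 2 && identical(segs[n - 1L], displayId) &&
      grepl("^[0-9][A-Za-z0-9_.]*$", segs[n])) {
    prefix <- paste(segs[seq_len(n - 2L)], collapse = "/")
    return(list(namespace = paste0(prefix, "/", segs[n]), displayId = displayId))
  }
  stop("SBOL2 URI does not follow <prefix>/<displayId>[/<version>]: ", uri,
       call. = FALSE)
}

.mk_report <- function() {
  list(counts = c(ComponentDefinition = 0L, ModuleDefinition = 0L,
                  Sequence = 0L, ComponentInstance = 0L,
                  SequenceAnnotation = 0L, FunctionalComponent = 0L,
                  MapsTo = 0L, Interaction = 0L),
       collapsed_maps_tos = character(0),
       component_references = character(0),
       unconvertible = character(0),
       dropped = character(0))
}

#' Migrate an SBOL2-style snapshot to an SBOL3 Document
#'
#' Implements the class mapping listed above. The SBOL2 "explode" pattern —
#' a ModuleDefinition instantiating ComponentDefinitions and re-exposing
#' their inner parts as FunctionalComponents linked by MapsTo — is collapsed:
#' the exposed part becomes a single direct SubComponent of the migrated
#' module Component (and is removed from the migrated definition Component so
#' that every element appears exactly once), which is why no
#' ComponentReference objects are needed for that pattern. MapsTo links whose
#' remote end is not instantiated in the same module become
#' ComponentReferences instead.
#'
#' @param snapshot an `sbol2_snapshot`.
#' @return list with `document` (an `sbol_document`) and `report` (a
#'   `MigrationReport`: per-class counts, collapsed MapsTo URIs, emitted
#'   ComponentReference URIs, unconvertible items, dropped fields).
#' @export
sbol2_to_sbol3 <- function(snapshot) {
  stopifnot(inherits(snapshot, "sbol2_snapshot"))
  report <- .mk_report()
  sbo <- ontology_terms()$SBO
  doc <- sbol_document()

  uri_map <- character(0)   # sbol2 uri -> sbol3 uri

  # --- sequences
  seq_objs <- list()
  for (sq in snapshot$sequences) {
    idn <- .sbol2_identity(sq$uri, sq$displayId)
    s3 <- sbol_sequence(idn$namespace, idn$displayId, elements = sq$elements,
                        encoding = sq$encoding)
    uri_map[sq$uri] <- s3$uri
    seq_objs[[s3$uri]] <- s3
    report$counts["Sequence"] <- report$counts["Sequence"] + 1L
  }

  # --- pass 1: ComponentDefinitions -> Components (parts may be removed
  # later by the collapse, so keep them mutable)
  cd_objs <- list()     # sbol2 cd uri -> sbol_component
  inst_index <- list()  # sbol2 instance uri -> list(cd = , displayId = , definition = )
  for (cd in snapshot$component_definitions) {
    idn <- .sbol2_identity(cd$uri, cd$displayId)
    types <- vapply(cd$types, .sbol2_map_type, character(1))
    if (length(types) == 0) types <- sbo[["dna"]]
    seqs <- character(0)
    if (!is.null(cd$sequence)) {
      s3uri <- uri_map[cd$sequence]
      if (is.na(s3uri)) stop("dangling sequence reference: ", cd$sequence,
                             call. = FALSE)
      seqs <- unname(s3uri)
    }
    cmp <- sbol_component(idn$namespace, idn$displayId, types = types,
                          roles = cd$roles, sequences = seqs)
    uri_map[cd$uri] <- cmp$uri
    cd_objs[[cd$uri]] <- cmp
    report$counts["ComponentDefinition"] <- report$counts["ComponentDefinition"] + 1L
    for (inst in cd$components)
      inst_index[[inst$uri]] <- list(cd = cd$uri, displayId = inst$displayId,
                                     definition = inst$definition)
  }

  # attach part instances and sequence annotations
  for (cd in snapshot$component_definitions) {
    cmp <- cd_objs[[cd$uri]]
    for (inst in cd$components) {
      def3 <- uri_map[inst$definition]
      if (is.na(def3)) stop("dangling definition reference: ", inst$definition,
                            call. = FALSE)
      sc <- sub_component(inst$displayId, instanceOf = unname(def3))
      cmp <- add_feature(cmp, sc)
      uri_map[inst$uri] <- cmp$features[[inst$displayId]]$uri
      report$counts["ComponentInstance"] <- report$counts["ComponentInstance"] + 1L
      if (!is.null(inst$access))
        report$dropped <- c(report$dropped,
                            paste0(inst$uri, ": access=", inst$access))
    }
    seq3 <- if (length(cmp$sequences)) cmp$sequences[1] else NA_character_
    for (sa in cd$sequence_annotations) {
      report$counts["SequenceAnnotation"] <- report$counts["SequenceAnnotation"] + 1L
      locs <- lapply(sa$ranges, function(r) loc_range(seq3, r$start, r$end))
      ori <- NULL
      for (r in sa$ranges)
        if (identical(r$orientation, "reverseComplement")) ori <- "reverseComplement"
      if (!is.null(sa$component)) {
        # location information for an existing part instance
        target_did <- inst_index[[sa$component]]$displayId
        f <- cmp$features[[target_did]]
        f$locations <- .name_locations(locs)
        if (!is.null(ori)) f$orientation <- ORIENTATION_REVCOMP
        f <- .assign_uris(f, cmp$uri)
        cmp$features[[target_did]] <- f
      } else {
        cmp <- add_feature(cmp, sequence_feature(
          sa$displayId, locations = locs, roles = sa$roles %||% character(0),
          orientation = ori))
        uri_map[sa$uri] <- cmp$features[[sa$displayId]]$uri
      }
    }
    cd_objs[[cd$uri]] <- cmp
  }

  # --- pass 2: ModuleDefinitions
  md_objs <- list()
  for (md in snapshot$module_definitions) {
    idn <- .sbol2_identity(md$uri, md$displayId)
    mcmp <- sbol_component(idn$namespace, idn$displayId,
                           types = sbo[["functional_entity"]])
    fc_defs <- vapply(md$functional_components, function(fc)
      fc$definition %||% NA_character_, character(1))
    names(fc_defs) <- vapply(md$functional_components, `[[`, character(1), "uri")

    # identify collapsible FCs: an FC is redundant when some MapsTo names it
    # as `local` and its `remote` is a part instance in a CD that another FC
    # of this module instantiates
    collapse_of <- character(0)  # local fc uri -> remote instance uri
    for (fc in md$functional_components) for (mt in fc$maps_tos %||% list()) {
      report$counts["MapsTo"] <- report$counts["MapsTo"] + 1L
      remote_cd <- inst_index[[mt$remote]]$cd
      if (!is.null(remote_cd) && remote_cd %in% fc_defs &&
          identical(remote_cd, fc$definition)) {
        collapse_of[mt$local] <- mt$remote
        report$collapsed_maps_tos <- c(report$collapsed_maps_tos, mt$uri)
      } else {
        # not the explode pattern: keep a reference through the instantiating
        # SubComponent
        collapse_of[mt$local] <- NA_character_
      }
    }

    dirs <- list(inputs = character(0), outputs = character(0))
    pending_refs <- list()
    for (fc in md$functional_components) {
      report$counts["FunctionalComponent"] <- report$counts["FunctionalComponent"] + 1L
      if (!is.null(fc$access))
        report$dropped <- c(report$dropped, paste0(fc$uri, ": access=", fc$access))
      if (fc$uri %in% names(collapse_of)) {
        remote <- collapse_of[[fc$uri]]
        if (!is.na(remote)) {
          # lift the exposed part: direct SubComponent of the module
          # Component, named after the part itself (not the redundant
          # module-level copy)
          ri <- inst_index[[remote]]
          did <- if (ri$displayId %in% names(mcmp$features)) fc$displayId
                 else ri$displayId
          sc <- sub_component(did, instanceOf = unname(uri_map[ri$definition]))
          mcmp <- add_feature(mcmp, sc)
          uri_map[fc$uri] <- mcmp$features[[did]]$uri
          # remove the now-duplicated instance from the migrated CD
          donor <- cd_objs[[ri$cd]]
          donor$features[[ri$displayId]] <- NULL
          cd_objs[[ri$cd]] <- donor
          uri_map[remote] <- mcmp$features[[did]]$uri
        } else {
          # MapsTo into a definition not instantiated here: ComponentReference
          mt <- NULL
          for (ofc in md$functional_components) for (m2 in ofc$maps_tos %||% list())
            if (identical(m2$local, fc$uri)) mt <- list(owner = ofc, m = m2)
          pending_refs[[length(pending_refs) + 1L]] <- c(list(fc = fc), mt)
        }
      } else {
        sc <- sub_component(fc$displayId, instanceOf = unname(uri_map[fc$definition]))
        mcmp <- add_feature(mcmp, sc)
        uri_map[fc$uri] <- mcmp$features[[fc$displayId]]$uri
      }
      if (identical(fc$direction, "in"))
        dirs$inputs <- c(dirs$inputs, fc$uri)
      else if (identical(fc$direction, "out"))
        dirs$outputs <- c(dirs$outputs, fc$uri)
      else if (identical(fc$direction, "inout")) {
        dirs$inputs <- c(dirs$inputs, fc$uri)
        dirs$outputs <- c(dirs$outputs, fc$uri)
      }
    }
    for (pr in pending_refs) {
      owner_sc_uri <- uri_map[pr$owner$uri]
      cref <- component_reference(pr$fc$displayId,
                                  inChildOf = unname(owner_sc_uri),
                                  refersTo = unname(uri_map[pr$m$remote]))
      mcmp <- add_feature(mcmp, cref)
      uri_map[pr$fc$uri] <- mcmp$features[[pr$fc$displayId]]$uri
      report$component_references <- c(report$component_references,
                                       mcmp$features[[pr$fc$displayId]]$uri)
    }
    for (ia in md$interactions) {
      report$counts["Interaction"] <- report$counts["Interaction"] + 1L
      parts <- lapply(ia$participations, function(p)
        list(roles = p$roles, participant = unname(uri_map[p$participant]),
             displayId = p$displayId))
      mcmp <- add_interaction(mcmp, ia$displayId, types = ia$types,
                              participations = parts)
    }
    if (length(dirs$inputs) || length(dirs$outputs))
      mcmp <- set_interface(mcmp,
                            inputs = unname(uri_map[unique(dirs$inputs)]),
                            outputs = unname(uri_map[unique(dirs$outputs)]))
    md_objs[[md$uri]] <- mcmp
    report$counts["ModuleDefinition"] <- report$counts["ModuleDefinition"] + 1L
  }

  for (s in seq_objs) doc <- doc_add(doc, s)
  for (cobj in cd_objs) doc <- doc_add(doc, cobj)
  for (mobj in md_objs) doc <- doc_add(doc, mobj)

  total <- sum(report$counts)
  converted <- total - length(report$unconvertible)
  report$total <- total
  report$converted <- converted
  class(report) <- "sbol2_migration_report"
  list(document = doc, report = report)
}

#' @export
print.sbol2_migration_report <- function(x, ...) {
  cat("SBOL2 -> SBOL3 migration report\n")
  for (nm in names(x$counts)) cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  cat("  collapsed MapsTo:", length(x$collapsed_maps_tos), "\n")
  cat("  ComponentReferences emitted:", length(x$component_references), "\n")
  cat("  unconvertible:", length(x$unconvertible), "\n")
  if (length(x$dropped)) cat("  dropped fields:", length(x$dropped), "\n")
  invisible(x)
}

## ---- minimal SBOL2 RDF/XML reader ---------------------------------------

.x2 <- function(local) paste0(SBOL2_NS, local)

# read nested SBOL2 RDF/XML into (subject, predicate, object) form where
# owned children appear as nested typed nodes
.sbol2_node_tree <- function(node) {
  out <- list(type = .xml_full_name(node),
              uri = xml2::xml_attr(node, "about"),
              props = list())
  for (pnode in xml2::xml_children(node)) {
    pred <- .xml_full_name(pnode)
    res <- xml2::xml_attr(pnode, "resource")
    kids <- xml2::xml_children(pnode)
    val <- if (!is.na(res)) list(kind = "iri", value = res)
           else if (length(kids) > 0) list(kind = "node",
                                           value = .sbol2_node_tree(kids[[1]]))
           else list(kind = "literal", value = xml2::xml_text(pnode))
    out$props[[length(out$props) + 1L]] <- c(list(pred = pred), val)
  }
  out
}

.p_lit <- function(tree, pred) {
  for (p in tree$props) if (identical(p$pred, pred) && p$kind == "literal")
    return(p$value)
  NULL
}
.p_iris <- function(tree, pred) {
  out <- character(0)
  for (p in tree$props) if (identical(p$pred, pred) && p$kind == "iri")
    out <- c(out, p$value)
  out
}
.p_nodes <- function(tree, pred) {
  out <- list()
  for (p in tree$props) if (identical(p$pred, pred) && p$kind == "node")
    out <- c(out, list(p$value))
  out
}

#' Read an SBOL2 RDF/XML file into a snapshot
#'
#' A minimal reader covering the class surface [sbol2_to_sbol3()] consumes;
#' it is not a general SBOL2 library.
#'
#' @param path path to an SBOL2 RDF/XML file.
#' @return an `sbol2_snapshot`.
#' @export
read_sbol2 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  docx <- xml2::read_xml(path)
  cds <- list(); mds <- list(); sqs <- list()
  for (node in xml2::xml_children(docx)) {
    tree <- .sbol2_node_tree(node)
    if (identical(tree$type, .x2("ComponentDefinition"))) {
      comps <- lapply(.p_nodes(tree, .x2("component")), function(cn)
        list(uri = cn$uri, displayId = .p_lit(cn, .x2("displayId")),
             definition = .p_iris(cn, .x2("definition"))[1],
             access = NULL))
      sas <- lapply(.p_nodes(tree, .x2("sequenceAnnotation")), function(an) {
        ranges <- lapply(.p_nodes(an, .x2("location")), function(ln)
          list(start = as.integer(.p_lit(ln, .x2("start"))),
               end = as.integer(.p_lit(ln, .x2("end"))),
               orientation = if (identical(.p_iris(ln, .x2("orientation"))[1],
                                           .x2("reverseComplement")))
                 "reverseComplement" else NULL))
        comp_link <- .p_iris(an, .x2("component"))
        list(uri = an$uri, displayId = .p_lit(an, .x2("displayId")),
             component = if (length(comp_link)) comp_link[1] else NULL,
             ranges = ranges, roles = .p_iris(an, .x2("role")))
      })
      cds[[length(cds) + 1L]] <- sbol2_component_definition(
        uri = tree$uri, displayId = .p_lit(tree, .x2("displayId")),
        types = .p_iris(tree, .x2("type")), roles = .p_iris(tree, .x2("role")),
        sequence = { s <- .p_iris(tree, .x2("sequence"))
                     if (length(s)) s[1] else NULL },
        components = comps, sequence_annotations = sas)
    } else if (identical(tree$type, .x2("ModuleDefinition"))) {
      fcs <- lapply(.p_nodes(tree, .x2("functionalComponent")), function(fn) {
        mts <- lapply(.p_nodes(fn, .x2("mapsTo")), function(mn)
          list(uri = mn$uri, local = .p_iris(mn, .x2("local"))[1],
               remote = .p_iris(mn, .x2("remote"))[1]))
        dir <- .p_iris(fn, .x2("direction"))
        list(uri = fn$uri, displayId = .p_lit(fn, .x2("displayId")),
             definition = .p_iris(fn, .x2("definition"))[1],
             direction = if (length(dir)) sub(SBOL2_NS, "", dir[1], fixed = TRUE)
                         else NULL,
             access = { a <- .p_iris(fn, .x2("access"))
                        if (length(a)) sub(SBOL2_NS, "", a[1], fixed = TRUE)
                        else NULL },
             maps_tos = mts)
      })
      ias <- lapply(.p_nodes(tree, .x2("interaction")), function(inode) {
        parts <- lapply(.p_nodes(inode, .x2("participation")), function(pn)
          list(uri = pn$uri, roles = .p_iris(pn, .x2("role")),
               participant = .p_iris(pn, .x2("participant"))[1]))
        list(uri = inode$uri, displayId = .p_lit(inode, .x2("displayId")),
             types = .p_iris(inode, .x2("type")), participations = parts)
      })
      mds[[length(mds) + 1L]] <- sbol2_module_definition(
        uri = tree$uri, displayId = .p_lit(tree, .x2("displayId")),
        functional_components = fcs, interactions = ias)
    } else if (identical(tree$type, .x2("Sequence"))) {
      sqs[[length(sqs) + 1L]] <- sbol2_sequence(
        uri = tree$uri, displayId = .p_lit(tree, .x2("displayId")),
        elements = .p_lit(tree, .x2("elements")))
    }
  }
  sbol2_snapshot(component_definitions = cds, module_definitions = mds,
                 sequences = sqs)
}

#' SBOL2 toggle-switch snapshot fixture
#'
#' The SBOL2 "explode" representation of the genetic toggle switch: one
#' ModuleDefinition instantiating two transcription-unit
#' ComponentDefinitions as FunctionalComponents, re-exposing the two
#' promoters and two repressor CDSs at module level through
#' FunctionalComponents linked by four MapsTo identity relations so that the
#' mutual-repression Interactions can reference them. Migrating this
#' snapshot with [sbol2_to_sbol3()] collapses all four MapsTo links and
#' yields a document with zero ComponentReference objects.
#'
#' @return an `sbol2_snapshot`.
#' @export
build_sbol2_toggle_switch <- function() {
  ns2 <- "http://example.com/sbol2"
  terms <- ontology_terms()
  u <- function(...) paste0(ns2, "/", paste(..., sep = "/"))
  biopax_dna <- "http://www.biopax.org/release/biopax-level3.owl#DnaRegion"
  part_cd <- function(id, role_name) sbol2_component_definition(
    uri = u(id, "1"), displayId = id, types = biopax_dna,
    roles = terms$SO[[role_name]])
  parts <- list(part_cd("pTet", "promoter"),
                part_cd("rbs_lacI", "ribosome_entry_site"),
                part_cd("lacI", "CDS"),
                part_cd("term_lacI", "terminator"),
                part_cd("pLac", "promoter"),
                part_cd("rbs_tetR", "ribosome_entry_site"),
                part_cd("tetR", "CDS"),
                part_cd("term_tetR", "terminator"))
  tu <- function(id, members) sbol2_component_definition(
    uri = u(id, "1"), displayId = id, types = biopax_dna,
    components = lapply(members, function(m)
      list(uri = u(id, "1", m), displayId = m, definition = u(m, "1"),
           access = "public")))
  lacI_unit <- tu("lacI_unit", c("pTet", "rbs_lacI", "lacI", "term_lacI"))
  tetR_unit <- tu("tetR_unit", c("pLac", "rbs_tetR", "tetR", "term_tetR"))
  fc <- function(id, def, mts = list()) list(
    uri = u("toggle_md", "1", id), displayId = id, definition = def,
    direction = NULL, access = "public", maps_tos = mts)
  mt <- function(id, local, remote) list(uri = u("toggle_md", "1", id),
                                         local = local, remote = remote)
  inhib <- function(id, inhibitor, inhibited) list(
    uri = u("toggle_md", "1", id), displayId = id,
    types = terms$SBO[["inhibition"]],
    participations = list(
      list(uri = u("toggle_md", "1", id, "p1"),
           roles = terms$SBO[["inhibitor"]],
           participant = u("toggle_md", "1", inhibitor)),
      list(uri = u("toggle_md", "1", id, "p2"),
           roles = terms$SBO[["inhibited"]],
           participant = u("toggle_md", "1", inhibited))))
  md <- sbol2_module_definition(
    uri = u("toggle_md", "1"), displayId = "toggle_md",
    functional_components = list(
      fc("lacI_unit", u("lacI_unit", "1"), mts = list(
        mt("map_pTet", u("toggle_md", "1", "fc_pTet"), u("lacI_unit", "1", "pTet")),
        mt("map_lacI", u("toggle_md", "1", "fc_lacI"), u("lacI_unit", "1", "lacI")))),
      fc("tetR_unit", u("tetR_unit", "1"), mts = list(
        mt("map_pLac", u("toggle_md", "1", "fc_pLac"), u("tetR_unit", "1", "pLac")),
        mt("map_tetR", u("toggle_md", "1", "fc_tetR"), u("tetR_unit", "1", "tetR")))),
      fc("fc_pTet", u("pTet", "1")),
      fc("fc_lacI", u("lacI", "1")),
      fc("fc_pLac", u("pLac", "1")),
      fc("fc_tetR", u("tetR", "1"))),
    interactions = list(inhib("lacI_represses_pLac", "fc_lacI", "fc_pLac"),
                        inhib("tetR_represses_pTet", "fc_tetR", "fc_pTet")))
  sbol2_snapshot(component_definitions = c(parts, list(lacI_unit, tetR_unit)),
                 module_definitions = list(md))
}
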