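test_that("the clopidogrel fixture builds valid PK and PD documents matching its manifest", {
  fx <- clopidogrelFixture()
  expect_identical(nrow(validatePathway(fx$pk_doc)), 0L)
  expect_identical(nrow(validatePathway(fx$pd_doc)), 0L)
  m <- fx$manifest
  nd <- pathwayNodes(fx$pk_doc)
  expect_identical(nrow(nd), m$pk$n_nodes)
  expect_identical(nrow(pathwayEdges(fx$pk_doc)), m$pk$n_edges)
  expect_identical(nrow(pathwayCompartments(fx$pk_doc)),
                   m$pk$n_compartments)
  expect_identical(sum(nd$node_type == "metabolite" & nd$active,
                       na.rm = TRUE),
                   m$pk$n_active_metabolites)
  expect_identical(nrow(pathwayNodes(fx$pd_doc)), m$pd$n_nodes)
  expect_identical(nrow(pathwayEdges(fx$pd_doc)), m$pd$n_edges)
})

test_that("prodrug activation topology: major enzymes emit active metabolites, non-major inactive", {
  fx <- clopidogrelFixture()
  nd <- pathwayNodes(fx$pk_doc)
  ed <- pathwayEdges(fx$pk_doc)
  mets <- nd[nd$node_type == "metabolite", ]
  producer <- vapply(mets$id, function(m)
    ed$source[ed$target == m & ed$interaction_type == "metabolism"],
    character(1))
  major_by_id <- setNames(nd$major, nd$id)
  expect_identical(unname(mets$active), unname(major_by_id[producer]))
  expect_true(mets$active[producer == "gene:CYP2C19"])
  expect_false(mets$active[producer == "gene:CYP2C9"])
})

test_that("a single active-drug enzyme record builds the minimal 3-node document", {
  rec <- drugGeneRecord("HMDB0000011", "drugX", "CYP3A4", role = "enzyme",
                        interaction_type = "metabolism",
                        action_type = "substrate")
  doc <- buildPKPathway(rec)
  nd <- pathwayNodes(doc)
  expect_identical(nrow(nd), 3L)
  expect_setequal(nd$node_type, c("drug", "gene", "metabolite"))
  ed <- pathwayEdges(doc)
  expect_identical(sum(ed$interaction_type == "metabolism"), 2L)
  expect_false(nd$active[nd$node_type == "metabolite"])
  expect_identical(nrow(validatePathway(doc)), 0L)
})

test_that("excretion edges terminate at the configured transport compartment", {
  fx <- clopidogrelFixture()
  ed <- pathwayEdges(fx$pk_doc)
  exc <- ed[ed$interaction_type == "excretion", ]
  ## both metabolites are hepatic, so both route to the bile duct
  expect_identical(unique(exc$target), "bile_duct")
  rec <- drugGeneRecord("HMDB0000011", "drugX", "CYP3A4", role = "enzyme",
                        interaction_type = "metabolism",
                        action_type = "substrate")
  doc <- buildPKPathway(rec, placement = c(CYP3A4 = "kidney"))
  exc2 <- pathwayEdges(doc)
  expect_identical(
    exc2$target[exc2$interaction_type == "excretion"], "urinary_tract")
  doc3 <- buildPKPathway(rec, config = list(excretion = list(
    CYP3A4 = "gut_lumen")))
  exc3 <- pathwayEdges(doc3)
  expect_identical(exc3$target[exc3$interaction_type == "excretion"],
                   "gut_lumen")
})

test_that("degenerate and inconsistent inputs raise classed errors", {
  fx <- clopidogrelFixture()
  empty <- fx$records[0, ]
  expect_error(buildPKPathway(empty), class = "pgpath_empty_input_error")
  mixed <- fx$records
  mixed$drug_id[2] <- "HMDB0000099"
  expect_error(buildPKPathway(mixed, drugKind = "prodrug"),
               class = "pgpath_mixed_drug_error")
  expect_error(
    buildPKPathway(fx$records, placement = c(CYP2C19 = "liver")),
    class = "pgpath_unplaced_gene_error")
  no_target <- fx$records[fx$records$role != "target", ]
  expect_error(buildPDPathway(no_target, description = "x"),
               class = "pgpath_no_target_error")
  expect_error(buildPDPathway(fx$records[0, ], description = "x"),
               class = "pgpath_empty_input_error")
})

test_that("PD documents accept the full action vocabulary that PK rejects", {
  rec <- drugGeneRecord("HMDB0000012", "drugY", "ADRB2", role = "target",
                        action_type = "agonist")
  pd <- buildPDPathway(rec, description = "receptor agonism")
  expect_identical(nrow(validatePathway(pd)), 0L)
  expect_identical(pathwayEdges(pd)$action_type, "agonist")
  ## the same action seeded into a PK document is a taxonomy violation
  fx <- clopidogrelFixture()
  d <- fx$pk_doc
  d@edges$action_type[1] <- "agonist"
  v <- validatePathway(d)
  expect_identical(v$code, "pk_action_invalid")
})

test_that("the validator flags each seeded taxonomy mutation", {
  for (m in taxonomy_mutations()) {
    v <- validatePathway(m$doc)
    expect_true(m$code %in% v$code,
                info = paste("expected violation", m$code))
  }
})

test_that("compartment vocabulary extensions warn at build time and pass validation", {
  rec <- drugGeneRecord("HMDB0000013", "drugZ", "CYP1A2", role = "enzyme",
                        interaction_type = "metabolism",
                        action_type = "substrate")
  cfg <- list(compartments = data.frame(
    id = "gill", name = "gill", level = "anatomical",
    stringsAsFactors = FALSE))
  expect_warning(
    doc <- buildPKPathway(rec, placement = c(CYP1A2 = "gill"),
                          config = cfg),
    class = "pgpath_vocabulary_warning")
  expect_identical(nrow(validatePathway(doc)), 0L)
})

test_that("built documents are one-drug-centered with closed edge taxonomy (random inputs)", {
  for (seed in 1:25) {
    kind <- if (seed %% 2) "PK" else "PD"
    doc <- makeRandomPathway(1L + seed %% 7L, kind, seed = seed)
    expect_identical(nrow(validatePathway(doc)), 0L)
    expect_identical(nrow(principalDrug(doc)), 1L)
    ed <- pathwayEdges(doc)
    allowed <- actionTypes(kind)
    expect_true(all(is.na(ed$action_type) | ed$action_type %in% allowed))
    expect_true(all(is.na(ed$interaction_type) |
                      ed$interaction_type %in% interactionTypes()))
  }
})

test_that("drug-gene record tables round-trip through TSV and JSON", {
  fx <- clopidogrelFixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDrugGeneRecords(fx$records, tsv)
  back <- readDrugGeneRecords(tsv)
  expect_equal(back, fx$records, ignore_attr = TRUE)
  js <- withr::local_tempfile(fileext = ".json")
  writeDrugGeneRecords(fx$records, js)
  back2 <- readDrugGeneRecords(js)
  expect_equal(back2$gene_symbol, fx$records$gene_symbol)
  expect_equal(back2$major, fx$records$major)
  ## a six-column legacy table still classifies roles
  legacy <- fx$records[, setdiff(names(fx$records), "role")]
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(legacy, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  back3 <- readDrugGeneRecords(tsv2)
  expect_identical(back3$role,
                   c("enzyme", "enzyme", "transporter", "target"))
})
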