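test_that("gvbToColor maps endpoints exactly and interpolates channel-wise", {
  expect_identical(gvbToColor(1), "#FFFFFF")
  expect_identical(gvbToColor(0.001), "#D7191C")
  ## midpoint: arithmetic interpolation per RGB channel
  t <- (1 - 0.5) / (1 - 0.001)
  n <- grDevices::col2rgb("#FFFFFF")[, 1]
  a <- grDevices::col2rgb("#D7191C")[, 1]
  expected <- sprintf("#%02X%02X%02X", round(n[1] + t * (a[1] - n[1])),
                      round(n[2] + t * (a[2] - n[2])),
                      round(n[3] + t * (a[3] - n[3])))
  expect_identical(gvbToColor(0.5), expected)
  expect_error(gvbToColor(0), class = "pgpath_score_range_error")
  expect_error(gvbToColor(1.01), class = "pgpath_score_range_error")
})

test_that("the colour map is monotone: lower scores sit channel-wise closer to the alert endpoint", {
  alert <- grDevices::col2rgb("#D7191C")[, 1]
  scores <- seq(0.001, 1, length.out = 100)
  cols <- t(vapply(scores, function(s) grDevices::col2rgb(
    gvbToColor(s))[, 1], numeric(3)))
  dist_to_alert <- rowSums(abs(sweep(cols, 2, alert)))
  expect_true(all(diff(dist_to_alert) >= 0))
  expect_gt(dist_to_alert[100], dist_to_alert[1])
})

test_that("personalization assigns exactly the gradient colours renderSVG applies", {
  fx <- clopidogrelFixture()
  gvb <- scoreGenes(
    data.frame(gene_symbol = "CYP2C9", sift = 0.05, variant_id = "v",
               genotype = "het", stringsAsFactors = FALSE),
    geneSymbols(fx$pk_doc))
  p <- personalizePathway(fx$pk_doc, gvb)
  cols <- nodeColors(p)
  expect_setequal(names(cols), geneSymbols(fx$pk_doc))
  expect_identical(cols[["CYP2C9"]], gvbToColor(0.05))
  expect_identical(cols[["CYP2C19"]], gvbToColor(1))
  svg <- renderSVG(fx$pk_doc, gvb = p@gvb)@svg
  for (sym in names(cols))
    expect_true(grepl(sprintf('data-pg-node="gene:%s" fill="%s"', sym,
                              cols[[sym]]), svg, fixed = TRUE))
  ## a table missing a pathway gene defaults it to neutral with a message
  partial <- gvbTable("CYP2C9", 0.05, 1L)
  expect_message(p2 <- personalizePathway(fx$pk_doc, partial), "ABCB1")
  expect_identical(nodeColors(p2)[["ABCB1"]], gvbToColor(1))
})

test_that("the concentration-shift rule table is exhaustive over drug kind, enzyme class and threshold", {
  build_doc <- function(drug_kind) {
    recs <- rbind(
      drugGeneRecord("HMDB0000031", "drugT", "ENZMAJ", role = "enzyme",
                     interaction_type = "metabolism",
                     action_type = "substrate", major = TRUE),
      drugGeneRecord("HMDB0000031", "drugT", "ENZMIN", role = "enzyme",
                     interaction_type = "metabolism",
                     action_type = "substrate", major = FALSE))
    suppressWarnings(buildPKPathway(recs, drugKind = drug_kind))
  }
  run <- function(drug_kind, scores, threshold = 0.3) {
    doc <- build_doc(drug_kind)
    gvb <- gvbTable(names(scores), unname(scores),
                    ifelse(scores < 1, 1L, 0L))
    predictConcentrationShift(personalizePathway(doc, gvb),
                              impairedThreshold = threshold)
  }
  cases <- list(
    ## major impaired decides the direction by drug kind
    list("prodrug", c(ENZMAJ = 0.05, ENZMIN = 1),
         "decreased_active_ingredient", "ENZMAJ"),
    list("active_drug", c(ENZMAJ = 0.05, ENZMIN = 1),
         "increased_active_ingredient", "ENZMAJ"),
    ## non-major impairment alone does not flip direction while a major
    ## enzyme exists; it is reported in the mechanism text
    list("prodrug", c(ENZMAJ = 1, ENZMIN = 0.05), "unchanged", NULL),
    list("active_drug", c(ENZMAJ = 1, ENZMIN = 0.05), "unchanged", NULL),
    ## nothing impaired
    list("prodrug", c(ENZMAJ = 1, ENZMIN = 1), "unchanged", NULL),
    list("active_drug", c(ENZMAJ = 1, ENZMIN = 1), "unchanged", NULL),
    ## threshold not crossed
    list("prodrug", c(ENZMAJ = 0.35, ENZMIN = 1), "unchanged", NULL),
    ## both impaired: direction from the major, non-major rides along
    list("prodrug", c(ENZMAJ = 0.05, ENZMIN = 0.05),
         "decreased_active_ingredient", c("ENZMAJ", "ENZMIN")))
  for (cs in cases) {
    pred <- run(cs[[1]], cs[[2]])
    expect_identical(pred$direction, cs[[3]],
                     info = paste(cs[[1]], paste(cs[[2]], collapse = "/")))
    imp <- pred$implicated[[1]]
    if (is.null(cs[[4]])) expect_identical(nrow(imp), 0L)
    else expect_setequal(imp$gene, cs[[4]])
    ## invariant: unchanged iff nothing implicated
    expect_identical(pred$direction == "unchanged", nrow(imp) == 0L)
  }
  ## non-major impairment text survives in the mechanism
  pred <- run("prodrug", c(ENZMAJ = 1, ENZMIN = 0.05))
  expect_match(pred$mechanism, "ENZMIN")
})

test_that("without any major enzyme, impaired non-major enzymes decide the direction", {
  rec <- drugGeneRecord("HMDB0000032", "drugU", "ENZ1", role = "enzyme",
                        interaction_type = "metabolism",
                        action_type = "substrate", major = FALSE)
  doc <- buildPKPathway(rec, drugKind = "prodrug")
  p <- personalizePathway(doc, gvbTable("ENZ1", 0.05, 1L))
  pred <- predictConcentrationShift(p)
  expect_identical(pred$direction, "decreased_active_ingredient")
  expect_identical(pred$implicated[[1]]$gene, "ENZ1")
})

test_that("impaired transporters are flagged indeterminate, never direction-deciding", {
  recs <- rbind(
    drugGeneRecord("HMDB0000033", "drugV", "ENZMAJ", role = "enzyme",
                   interaction_type = "metabolism",
                   action_type = "substrate", major = TRUE),
    drugGeneRecord("HMDB0000033", "drugV", "TRSP", role = "transporter",
                   interaction_type = "transportation",
                   action_type = "substrate"))
  doc <- buildPKPathway(recs, drugKind = "active_drug")
  p <- personalizePathway(doc, gvbTable(c("ENZMAJ", "TRSP"), c(1, 0.05),
                                        c(0L, 1L)))
  pred <- predictConcentrationShift(p)
  expect_identical(pred$direction, "unchanged")
  expect_match(pred$mechanism, "indeterminate")
  expect_match(pred$mechanism, "TRSP")
  expect_identical(nrow(pred$implicated[[1]]), 0L)
})

test_that("concentration-shift prediction refuses PD pathways", {
  fx <- clopidogrelFixture()
  gvb <- gvbTable(geneSymbols(fx$pd_doc),
                  rep(1, length(geneSymbols(fx$pd_doc))))
  p <- personalizePathway(fx$pd_doc, gvb)
  expect_error(predictConcentrationShift(p), class = "pgpath_kind_error")
})

make_pk <- function(drug_id, drug_name, gene, action) {
  buildPKPathway(drugGeneRecord(drug_id, drug_name, gene, role = "enzyme",
                                interaction_type = "metabolism",
                                action_type = action))
}

test_that("the drug-gene-drug rule matrix produces exactly the documented predictions", {
  subB <- make_pk("HMDB0000002", "drugB", "CYP3A4", "substrate")
  cases <- list(
    list("inhibitor", "inhibition", "victim_metabolism_slowed"),
    list("inducer", "induction", "victim_metabolism_accelerated"))
  for (cs in cases) {
    perpA <- make_pk("HMDB0000001", "drugA", "CYP3A4", cs[[1]])
    ddi <- inferDDI(perpA, subB)
    expect_identical(nrow(ddi), 1L)
    expect_identical(ddi$perpetrator_drug, "HMDB0000001")
    expect_identical(ddi$victim_drug, "HMDB0000002")
    expect_identical(ddi$gene, "CYP3A4")
    expect_identical(ddi$mechanism, cs[[2]])
    expect_identical(ddi$expected_effect, cs[[3]])
    ## label symmetry: argument order never changes the prediction set
    expect_identical(inferDDI(subB, perpA), ddi)
  }
  ## a perpetrator without a substrate victim predicts nothing
  perpA <- make_pk("HMDB0000001", "drugA", "CYP3A4", "inhibitor")
  otherB <- make_pk("HMDB0000002", "drugB", "CYP3A4", "inhibitor")
  expect_identical(nrow(inferDDI(perpA, otherB)), 0L)
  ## disjoint gene sets predict nothing
  faraway <- make_pk("HMDB0000002", "drugB", "UGT1A1", "substrate")
  expect_identical(nrow(inferDDI(perpA, faraway)), 0L)
})

test_that("DDI inference rejects PD documents and identical drugs", {
  fx <- clopidogrelFixture()
  a <- make_pk("HMDB0000001", "drugA", "CYP3A4", "inhibitor")
  expect_error(inferDDI(a, fx$pd_doc), class = "pgpath_kind_error")
  expect_error(inferDDI(fx$pk_doc, fx$pk_doc),
               class = "pgpath_same_drug_error")
})
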