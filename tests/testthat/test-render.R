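count_matches <- function(pattern, text, fixed = FALSE) {
  sum(lengths(regmatches(text, gregexpr(pattern, text, fixed = fixed))))
}

test_that("the SVG contains one addressable shape group per pathway node", {
  fx <- clopidogrelFixture()
  d <- renderSVG(fx$pk_doc)
  nd <- pathwayNodes(fx$pk_doc)
  expect_identical(count_matches('class="pg-node"', d@svg, fixed = TRUE),
                   nrow(nd))
  expect_setequal(names(d@anchorIndex), nd$id)
  for (id in nd$id)
    expect_true(grepl(sprintf('id="%s"', id), d@svg, fixed = TRUE))
})

test_that("prodrug and active metabolite share geometry class but differ from the inactive metabolite only in fill", {
  fx <- clopidogrelFixture()
  theme <- defaultTheme()
  d <- renderSVG(fx$pk_doc, theme = theme)
  svg <- d@svg
  grab_fill <- function(id) {
    m <- regmatches(svg, regexpr(sprintf(
      'id="%s" class="pg-node" data-pg-node="[^"]*" fill="(#[0-9A-F]{6})"',
      id), svg))
    sub('.*fill="(#[0-9A-F]{6})".*', "\\1", m)
  }
  nd <- pathwayNodes(fx$pk_doc)
  drug_id <- nd$id[nd$node_type == "drug"]
  active_met <- nd$id[nd$node_type == "metabolite" & nd$active]
  inactive_met <- nd$id[nd$node_type == "metabolite" & !nd$active]
  expect_identical(grab_fill(drug_id), unname(theme$fill[["prodrug"]]))
  expect_identical(grab_fill(active_met),
                   unname(theme$fill[["active_metabolite"]]))
  expect_identical(grab_fill(inactive_met),
                   unname(theme$fill[["inactive_metabolite"]]))
  expect_false(grab_fill(active_met) == grab_fill(inactive_met))
  ## drugs and metabolites share the rect shape; enzymes are rounded
  expect_true(count_matches('rx="10"', svg, fixed = TRUE) >= 2L)
  ## major and active badges render as adjacent glyphs
  expect_true(count_matches('class="pg-badge"', svg, fixed = TRUE) >= 2L)
})

test_that("a GVB table overrides gene fills through the gradient map, leaving others", {
  fx <- clopidogrelFixture()
  theme <- defaultTheme()
  gvb <- gvbTable(c("CYP2C9"), c(0.05), c(1L))
  d <- renderSVG(fx$pk_doc, gvb = gvb, theme = theme)
  expect_true(grepl(sprintf('data-pg-node="gene:CYP2C9" fill="%s"',
                            gvbToColor(0.05)), d@svg, fixed = TRUE))
  ## genes without an entry keep their role colour
  expect_true(grepl(sprintf('data-pg-node="gene:CYP2C19" fill="%s"',
                            theme$fill[["enzyme"]]), d@svg, fixed = TRUE))
  ## an all-ones table paints every gene the neutral endpoint
  all1 <- gvbTable(geneSymbols(fx$pk_doc),
                   rep(1, length(geneSymbols(fx$pk_doc))))
  d1 <- renderSVG(fx$pk_doc, gvb = all1, theme = theme)
  for (sym in geneSymbols(fx$pk_doc))
    expect_true(grepl(sprintf('data-pg-node="gene:%s" fill="%s"', sym,
                              theme$gvb_neutral), d1@svg, fixed = TRUE))
  expect_error(renderSVG(fx$pk_doc, gvb = c(CYP2C9 = 1.5)),
               class = "pgpath_score_range_error")
})

test_that("rendering embeds a PNG background or the built-in vector frame", {
  fx <- clopidogrelFixture()
  plain <- renderSVG(fx$pk_doc)
  expect_true(grepl('id="background" class="pg-frame"', plain@svg,
                    fixed = TRUE))
  expect_false(plain@hasBackground)
  withbg <- renderSVG(fx$pk_doc, background = tiny_png())
  expect_true(withbg@hasBackground)
  expect_identical(count_matches("data:image/png;base64,", withbg@svg,
                                 fixed = TRUE), 1L)
  expect_identical(renderSVG(fx$pk_doc)@svg, plain@svg)  # deterministic
})

test_that("merging produces one self-contained HTML with the full node set and popup hooks", {
  fx <- clopidogrelFixture()
  d <- renderSVG(fx$pk_doc)
  html <- mergeWithBackground(d, tiny_png())
  expect_identical(count_matches("<img ", html, fixed = TRUE), 1L)
  expect_identical(count_matches('class="pg-node"', html, fixed = TRUE),
                   nrow(pathwayNodes(fx$pk_doc)))
  expect_true(grepl("data-pg-node", html, fixed = TRUE))
  expect_true(grepl("<script>", html, fixed = TRUE))
  ## info windows for the drug and every gene, none for metabolites
  expect_identical(count_matches('class="pg-info"', html, fixed = TRUE),
                   1L + length(geneSymbols(fx$pk_doc)))
  expect_error(mergeWithBackground(d, as.raw(c(1, 2, 3))),
               class = "pgpath_image_decode_error")
  ## PD diagrams additionally expose the description window hook
  pd <- renderSVG(fx$pd_doc)
  html_pd <- mergeWithBackground(pd, tiny_png())
  expect_true(grepl('id="info-description"', html_pd, fixed = TRUE))
  expect_true(grepl("pg-show-description", html_pd, fixed = TRUE))
})

test_that("info windows carry clinical fields, identifiers and database links", {
  fx <- clopidogrelFixture()
  drug_id <- principalDrug(fx$pk_doc)$id
  w <- makeInfoWindow(fx$pk_doc, drug_id)
  expect_true(grepl("B01AC04", w, fixed = TRUE))
  expect_true(grepl("hmdb.ca/metabolites", w, fixed = TRUE))
  g <- makeInfoWindow(fx$pk_doc, "gene:CYP2C19")
  expect_true(grepl("CYP2C19", g, fixed = TRUE))
  expect_true(grepl("genenames.org", g, fixed = TRUE))
  expect_true(grepl("metabolism", g, fixed = TRUE))
  ## empty fields render as an em dash, not blank
  rec <- drugGeneRecord("HMDB0000020", "plaindrug", "CYP3A4",
                        role = "enzyme", interaction_type = "metabolism",
                        action_type = "substrate")
  doc <- buildPKPathway(rec)
  w2 <- makeInfoWindow(doc, "HMDB0000020")
  expect_true(grepl("—", w2))
  met_id <- pathwayNodes(fx$pk_doc)$id[
    pathwayNodes(fx$pk_doc)$node_type == "metabolite"][1]
  expect_error(makeInfoWindow(fx$pk_doc, met_id),
               class = "pgpath_type_mismatch_error")
})
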