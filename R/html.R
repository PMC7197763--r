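## HTML info windows and the self-contained SVG+HTML merge.

.HGNC_URL <- "https://www.genenames.org/data/gene-symbol-report/#!/symbol/%s"
.HMDB_URL <- "https://hmdb.ca/metabolites/%s"

.dl <- function(labels, values) {
  values <- vapply(values, function(v) {
    if (is.null(v) || length(v) == 0L || is.na(v) || !nzchar(v)) "—"
    else .xmlEscape(as.character(v))
  }, character(1))
  paste0("<dl>", paste0("<dt>", .xmlEscape(labels), "</dt><dd>", values,
                        "</dd>", collapse = ""), "</dl>")
}

#' Build the pop-up info window for a drug or gene node
#'
#' Drug windows list the clinical free-text fields (drug name, ATC class,
#' indications, adverse drug effects, drug interactions, pharmacokinetic
#' notes; empty fields render as an em dash) and link to the drug's HMDB
#' page. Gene windows list the gene symbol, gene name, interaction type and
#' action type (taken from the document's edges), chromosomal location,
#' expression tissue and description, and link to the gene's HGNC
#' symbol report. Metabolite nodes have no window.
#'
#' @param doc a \linkS4class{PathwayDocument}.
#' @param nodeId id of a drug or gene node of \code{doc}.
#' @return an HTML fragment (one \code{<div class="pg-info">}).
#' @export
makeInfoWindow <- function(doc, nodeId) {
  nodes <- doc@nodes
  nd <- nodes[nodes$id == nodeId, , drop = FALSE]
  if (nrow(nd) != 1L)
    .pgError("pgpath_type_mismatch_error",
             sprintf("node '%s' not found in document", nodeId))
  nd <- nd[1, ]
  if (nd$node_type == "metabolite")
    .pgError("pgpath_type_mismatch_error",
             "metabolite nodes carry no info window")
  if (nd$node_type == "drug") {
    info <- doc@drugInfo
    body <- .dl(
      c("Drug name", "ATC class", "Indications", "Adverse drug effects",
        "Drug interactions", "Pharmacokinetics"),
      list(nd$name, info$atc_class, info$indications, info$adverse_effects,
           info$interactions, info$pk_notes))
    link <- sprintf("<a href=\"%s\" target=\"_blank\">HMDB: %s</a>",
                    sprintf(.HMDB_URL, .xmlEscape(nd$id)), .xmlEscape(nd$id))
  } else {
    edges <- doc@edges
    mine <- edges[edges$source == nodeId | edges$target == nodeId, ,
                  drop = FALSE]
    itypes <- unique(mine$interaction_type[!is.na(mine$interaction_type)])
    atypes <- unique(mine$action_type[!is.na(mine$action_type)])
    body <- .dl(
      c("Gene symbol", "Gene name", "Interaction type", "Action type",
        "Chromosomal location", "Expression tissue", "Description"),
      list(nd$symbol, nd$gene_name,
           if (length(itypes)) paste(itypes, collapse = ", ") else NA,
           if (length(atypes)) paste(atypes, collapse = ", ") else NA,
           nd$location, nd$tissue, nd$description))
    link <- sprintf("<a href=\"%s\" target=\"_blank\">HGNC: %s</a>",
                    sprintf(.HGNC_URL, .xmlEscape(nd$symbol)),
                    .xmlEscape(nd$symbol))
  }
  sprintf(
    "<div class=\"pg-info\" id=\"info-%s\"><h3>%s</h3>%s<p>%s</p></div>",
    .xmlEscape(nodeId), .xmlEscape(nd$name), body, link)
}

.descriptionWindow <- function(doc) {
  sprintf(
    "<div class=\"pg-info pg-description\" id=\"info-description\"><h3>Mechanism of action</h3><p>%s</p></div>",
    .xmlEscape(doc@description))
}

.POPUP_SCRIPT <- paste(
  "document.querySelectorAll('[data-pg-node]').forEach(function (el) {",
  "  el.addEventListener('click', function () {",
  "    var w = document.getElementById('info-' + el.getAttribute('data-pg-node'));",
  "    document.querySelectorAll('.pg-info').forEach(function (d) { d.style.display = 'none'; });",
  "    if (w) { w.style.display = 'block'; }",
  "  });",
  "});",
  "var d = document.getElementById('pg-show-description');",
  "if (d) { d.addEventListener('click', function () {",
  "  var w = document.getElementById('info-description');",
  "  if (w) { w.style.display = w.style.display === 'block' ? 'none' : 'block'; }",
  "}); }",
  sep = "\n")

#' Merge a rendered diagram with a raster background into one HTML page
#'
#' Produces a single self-contained HTML document: the PNG embedded
#' (base64) as the bottom layer, the SVG diagram overlaid on top, the
#' per-node info windows, the PD description window when present, and a
#' small script wiring node clicks to their pop-ups.
#'
#' @param diagram a \linkS4class{RenderedDiagram}.
#' @param png raw vector of PNG bytes (must decode as PNG).
#' @return the HTML document as a single string.
#' @export
mergeWithBackground <- function(diagram, png) {
  stopifnot(is(diagram, "RenderedDiagram"))
  tryCatch(png::readPNG(png),
           error = function(e)
             .pgError("pgpath_image_decode_error",
                      paste("background bytes do not decode as PNG:",
                            conditionMessage(e))))
  b64 <- jsonlite::base64_enc(png)
  desc_button <- if (!is.na(diagram@descriptionWindow))
    "<button id=\"pg-show-description\">Pathway description</button>" else ""
  desc_window <- if (!is.na(diagram@descriptionWindow))
    diagram@descriptionWindow else ""
  paste(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/><title>pgpath pathway</title>",
    "<style>",
    "#pg-stage { position: relative; }",
    "#pg-stage > img { position: absolute; top: 0; left: 0; z-index: 0; }",
    "#pg-stage > svg { position: relative; z-index: 1; }",
    ".pg-info { display: none; border: 1px solid #999; background: #fff;",
    "  padding: 8px 12px; max-width: 420px; }",
    ".pg-node { cursor: pointer; }",
    "</style></head><body>",
    "<div id=\"pg-stage\">",
    sprintf("<img alt=\"background\" src=\"data:image/png;base64,%s\"/>",
            b64),
    diagram@svg,
    "</div>",
    desc_button,
    paste(unname(diagram@infoWindows), collapse = "\n"),
    desc_window,
    sprintf("<script>\n%s\n</script>", .POPUP_SCRIPT),
    "</body></html>",
    sep = "\n")
}
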