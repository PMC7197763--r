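## SVG rendering of pathway documents. Output is assembled with a stable
## element order and 6-decimal coordinates so identical inputs render
## byte-identically.

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.SVG_MARKER_BY_ARROWHEAD <- c(
  "mim-conversion"    = "m-arrow",
  "mim-translocation" = "m-open",
  "mim-binding"       = "m-dot",
  "Arrow"             = "m-arrow",
  "mim-inhibition"    = "m-tee",
  "mim-stimulation"   = "m-open"
)

.svgMarkers <- function(stroke) {
  paste0(
    "<defs>",
    sprintf("<marker id=\"m-arrow\" viewBox=\"0 0 10 10\" refX=\"9\" refY=\"5\" markerWidth=\"8\" markerHeight=\"8\" orient=\"auto-start-reverse\"><path d=\"M 0 0 L 10 5 L 0 10 z\" fill=\"%s\"/></marker>", stroke),
    sprintf("<marker id=\"m-open\" viewBox=\"0 0 10 10\" refX=\"9\" refY=\"5\" markerWidth=\"9\" markerHeight=\"9\" orient=\"auto-start-reverse\"><path d=\"M 0 0 L 10 5 L 0 10\" fill=\"none\" stroke=\"%s\"/></marker>", stroke),
    sprintf("<marker id=\"m-tee\" viewBox=\"0 0 10 10\" refX=\"5\" refY=\"5\" markerWidth=\"8\" markerHeight=\"8\" orient=\"auto-start-reverse\"><path d=\"M 5 0 L 5 10\" stroke=\"%s\" stroke-width=\"2\"/></marker>", stroke),
    sprintf("<marker id=\"m-dot\" viewBox=\"0 0 10 10\" refX=\"5\" refY=\"5\" markerWidth=\"7\" markerHeight=\"7\" orient=\"auto\"><circle cx=\"5\" cy=\"5\" r=\"3.5\" fill=\"%s\"/></marker>", stroke),
    "</defs>")
}

.nodeFill <- function(nd, theme, gvb_colors) {
  switch(nd$node_type,
    drug = unname(theme$fill[[nd$drug_kind]]),
    metabolite = unname(theme$fill[[if (isTRUE(nd$active))
      "active_metabolite" else "inactive_metabolite"]]),
    gene = {
      if (!is.null(gvb_colors) && nd$symbol %in% names(gvb_colors))
        unname(gvb_colors[[nd$symbol]])
      else unname(theme$fill[[nd$role]])
    })
}

.nodeShapeSVG <- function(nd, x, y, theme) {
  w <- theme$node_width; h <- theme$node_height
  shape_kind <- if (nd$node_type == "gene") theme$shape[[nd$role]] else
    theme$shape[[nd$node_type]]
  switch(shape_kind,
    rect = sprintf("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\"/>",
                   .fmt6(x - w / 2), .fmt6(y - h / 2), .fmt6(w), .fmt6(h)),
    roundrect = sprintf(
      "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" rx=\"10\"/>",
      .fmt6(x - w / 2), .fmt6(y - h / 2), .fmt6(w), .fmt6(h)),
    ellipse = sprintf("<ellipse cx=\"%s\" cy=\"%s\" rx=\"%s\" ry=\"%s\"/>",
                      .fmt6(x), .fmt6(y), .fmt6(w / 2), .fmt6(h / 2)))
}

.vectorFrame <- function(comps, theme) {
  boxes <- .compartmentBoxes(comps)
  out <- c("<g id=\"background\" class=\"pg-frame\">")
  for (i in seq_len(nrow(boxes))) {
    out <- c(out, sprintf(
      "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"#F7F7F2\" stroke=\"#C9C9C0\" rx=\"14\"/>",
      .fmt6(boxes$x[i]), .fmt6(boxes$y[i]), .fmt6(boxes$w[i]),
      .fmt6(boxes$h[i])))
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" font-size=\"13\" fill=\"#8A8A80\" font-family=\"%s\">%s</text>",
      .fmt6(boxes$x[i] + 10), .fmt6(boxes$y[i] + 18), theme$font_family,
      .xmlEscape(comps$name[i])))
  }
  c(out, "</g>")
}

#' Render a pathway document as SVG
#'
#' Draws one addressable shape per pathway node at its layout position,
#' following the symbol standard: prodrug and active drug share a shape and
#' differ in fill, as do inactive and active metabolites; gene roles differ
#' in shape and fill. The 'major' and 'active' markers render as adjacent
#' badge glyphs. When a GVB table is supplied, gene fills are overridden by
#' \code{\link{gvbToColor}} of each gene's score. The background is either
#' an embedded PNG (when \code{background} raw bytes are given) or the
#' built-in schematic vector frame drawn from the document's compartments.
#'
#' @param doc a valid \linkS4class{PathwayDocument}.
#' @param background optional raw vector of PNG bytes to embed beneath the
#'   diagram.
#' @param gvb optional \linkS4class{GvbTable} (or named numeric of scores in
#'   (0, 1]) used to colour gene nodes.
#' @param theme a theme list, see \code{\link{defaultTheme}}.
#' @return a \linkS4class{RenderedDiagram}.
#' @export
renderSVG <- function(doc, background = NULL, gvb = NULL,
                      theme = defaultTheme()) {
  viol <- validatePathway(doc)
  if (nrow(viol))
    .pgError("pgpath_validation_error",
             paste("cannot render an invalid document:",
                   paste(unique(viol$code), collapse = ", ")))
  gvb_colors <- NULL
  if (!is.null(gvb)) {
    scores <- if (is(gvb, "GvbTable")) gvbScores(gvb) else gvb
    if (any(scores <= 0 | scores > 1))
      .pgError("pgpath_score_range_error", "GVB scores must lie in (0, 1]")
    gvb_colors <- vapply(scores, gvbToColor, character(1),
                         neutral = theme$gvb_neutral,
                         alert = theme$gvb_alert)
  }
  nodes <- doc@nodes
  layout <- doc@layout
  pos <- setNames(lapply(seq_len(nrow(layout)),
                         function(i) c(layout$x[i], layout$y[i])),
                  layout$id)
  boxes <- .compartmentBoxes(doc@compartments)
  for (i in seq_len(nrow(boxes)))
    pos[[paste0("comp:", boxes$id[i])]] <-
      c(boxes$x[i] + boxes$w[i] / 2, boxes$y[i] + boxes$h[i] / 2)

  W <- theme$canvas_width; H <- theme$canvas_height
  out <- c(sprintf(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" xmlns:xlink=\"http://www.w3.org/1999/xlink\" width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">",
    W, H, W, H),
    .svgMarkers(theme$stroke),
    sprintf("<rect width=\"%d\" height=\"%d\" fill=\"#FFFFFF\"/>", W, H))

  if (!is.null(background)) {
    out <- c(out, sprintf(
      "<image id=\"background\" x=\"0\" y=\"0\" width=\"%d\" height=\"%d\" preserveAspectRatio=\"none\" href=\"data:image/png;base64,%s\"/>",
      W, H, jsonlite::base64_enc(background)))
  } else {
    out <- c(out, .vectorFrame(doc@compartments, theme))
  }

  out <- c(out, "<g id=\"edges\">")
  for (i in seq_len(nrow(doc@edges))) {
    e <- doc@edges[i, ]
    sp <- pos[[e$source]] %||% pos[[paste0("comp:", e$source)]]
    tp <- pos[[e$target]] %||% pos[[paste0("comp:", e$target)]]
    ah <- .edgeArrowhead(e$interaction_type, e$action_type)
    out <- c(out, sprintf(
      "<line class=\"pg-edge %s\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"1.5\" marker-end=\"url(#%s)\"/>",
      ah, .fmt6(sp[1]), .fmt6(sp[2]), .fmt6(tp[1]), .fmt6(tp[2]),
      theme$stroke, .SVG_MARKER_BY_ARROWHEAD[[ah]]))
  }
  out <- c(out, "</g>", "<g id=\"nodes\">")

  anchors <- character()
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    p <- pos[[nd$id]]
    fill <- .nodeFill(nd, theme, gvb_colors)
    eid <- .xmlEscape(nd$id)
    out <- c(out, sprintf(
      "<g id=\"%s\" class=\"pg-node\" data-pg-node=\"%s\" fill=\"%s\" stroke=\"%s\">",
      eid, eid, fill, theme$stroke))
    out <- c(out, .nodeShapeSVG(nd, p[1], p[2], theme))
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-size=\"12\" font-family=\"%s\" fill=\"#111111\" stroke=\"none\">%s</text>",
      .fmt6(p[1]), .fmt6(p[2] + 4), theme$font_family, .xmlEscape(nd$name)))
    badge <- NULL
    if (isTRUE(nd$major)) badge <- "M"
    if (isTRUE(nd$active)) badge <- "A"
    if (!is.null(badge)) {
      bx <- p[1] + theme$node_width / 2 + 8
      out <- c(out, sprintf(
        "<circle class=\"pg-badge\" cx=\"%s\" cy=\"%s\" r=\"8\" fill=\"#FFD54F\" stroke=\"%s\"/>",
        .fmt6(bx), .fmt6(p[2] - theme$node_height / 2), theme$stroke),
        sprintf(
        "<text class=\"pg-badge-label\" x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-size=\"10\" font-family=\"%s\" fill=\"#111111\" stroke=\"none\">%s</text>",
        .fmt6(bx), .fmt6(p[2] - theme$node_height / 2 + 3.5),
        theme$font_family, badge))
    }
    out <- c(out, "</g>")
    anchors[[nd$id]] <- nd$id
  }
  out <- c(out, "</g>", "</svg>")

  windows <- character()
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    if (nd$node_type %in% c("drug", "gene"))
      windows[[nd$id]] <- makeInfoWindow(doc, nd$id)
  }
  desc <- if (doc@pathwayKind == "PD")
    .descriptionWindow(doc) else NA_character_

  new("RenderedDiagram", svg = paste(out, collapse = "\n"),
      anchorIndex = anchors, hasBackground = !is.null(background),
      infoWindows = windows, descriptionWindow = desc)
}
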