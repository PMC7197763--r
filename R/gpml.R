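## GPML serialization (2013a dialect, the schema PathVisio 3.x writes).
## Package-specific semantics that GPML has no native slot for (node kinds,
## drug kind, roles, markers, compartment levels, edge typing) travel in
## PathVisio dynamic properties (<Attribute Key="pgpath.*">), so documents
## round-trip losslessly while remaining openable in PathVisio.

.GPML_NS <- "http://pathvisio.org/GPML/2013a"

.fmt6 <- function(x) sprintf("%.6f", x)

.compartmentBoxes <- function(comps) {
  ncol_grid <- 3L
  box_w <- 320; box_h <- 170; x0 <- 20; y0 <- 20
  i <- seq_len(nrow(comps))
  data.frame(id = comps$id,
             x = x0 + ((i - 1L) %% ncol_grid) * box_w,
             y = y0 + ((i - 1L) %/% ncol_grid) * box_h,
             w = box_w - 20, h = box_h - 20,
             stringsAsFactors = FALSE)
}

.addAttr <- function(parent, key, value) {
  xml2::xml_add_child(parent, "Attribute", Key = key, Value = value)
}

.nodeXref <- function(nd) {
  if (nd$node_type == "gene") c("HGNC", nd$symbol) else c("HMDB", nd$id)
}

#' Write a pathway document as GPML
#'
#' Serializes a valid \linkS4class{PathwayDocument} to GPML (2013a dialect).
#' Every node becomes a DataNode carrying exactly one external identifier
#' (HGNC symbol for genes, HMDB-style id for drugs and metabolites); every
#' edge becomes an Interaction whose arrowhead encodes its type in MIM style
#' (metabolism: mim-conversion, transportation: mim-translocation, binding:
#' mim-binding, excretion: plain arrow, inhibitor: mim-inhibition, inducer:
#' mim-stimulation); compartments become labelled Shapes. Output is
#' deterministic: stable element ordering and 6-decimal coordinates, so
#' identical documents serialize byte-identically.
#'
#' @param doc a valid \linkS4class{PathwayDocument}.
#' @param path optional file to write to.
#' @return the GPML document as a single string (invisibly when \code{path}
#'   is given).
#' @export
writeGPML <- function(doc, path = NULL) {
  viol <- validatePathway(doc)
  if (nrow(viol))
    .pgError("pgpath_validation_error",
             paste("cannot serialize an invalid document:",
                   paste(unique(viol$code), collapse = ", ")))
  nodes <- doc@nodes
  comps <- doc@compartments
  drug <- nodes[nodes$node_type == "drug", ]
  layout <- doc@layout
  pos <- setNames(lapply(seq_len(nrow(layout)),
                         function(i) c(layout$x[i], layout$y[i])),
                  layout$id)
  boxes <- .compartmentBoxes(comps)
  for (i in seq_len(nrow(boxes)))
    pos[[paste0("comp:", boxes$id[i])]] <-
      c(boxes$x[i] + boxes$w / 2, boxes$y[i] + boxes$h / 2)

  root <- xml2::xml_new_root("Pathway", xmlns = .GPML_NS,
                             Name = sprintf("%s %s pathway", drug$name,
                                            doc@pathwayKind),
                             Organism = "Homo sapiens")
  .addAttr(root, "pgpath.kind", doc@pathwayKind)
  if (!is.na(doc@administrationRoute))
    .addAttr(root, "pgpath.route", doc@administrationRoute)
  if (!is.na(doc@description))
    .addAttr(root, "pgpath.description", doc@description)
  if (length(doc@drugInfo))
    .addAttr(root, "pgpath.druginfo",
             as.character(jsonlite::toJSON(doc@drugInfo, auto_unbox = TRUE)))
  xml2::xml_add_child(root, "Graphics",
                      BoardWidth = .fmt6(max(layout$x, boxes$x + boxes$w) + 60),
                      BoardHeight = .fmt6(max(layout$y, boxes$y + boxes$h) + 60))

  graph_id <- setNames(sprintf("n%d", seq_len(nrow(nodes))), nodes$id)
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    dn <- xml2::xml_add_child(root, "DataNode", TextLabel = nd$name,
                              GraphId = graph_id[[nd$id]],
                              Type = if (nd$node_type == "gene")
                                "GeneProduct" else "Metabolite")
    for (col in .NODE_COLUMNS) {
      val <- nd[[col]]
      if (!is.na(val)) .addAttr(dn, paste0("pgpath.", col), as.character(val))
    }
    p <- pos[[nd$id]]
    xml2::xml_add_child(dn, "Graphics", CenterX = .fmt6(p[1]),
                        CenterY = .fmt6(p[2]), Width = .fmt6(110),
                        Height = .fmt6(32))
    xr <- .nodeXref(nd)
    xml2::xml_add_child(dn, "Xref", Database = xr[1], ID = xr[2])
  }

  for (i in seq_len(nrow(doc@edges))) {
    e <- doc@edges[i, ]
    ix <- xml2::xml_add_child(root, "Interaction")
    if (!is.na(e$interaction_type))
      .addAttr(ix, "pgpath.interaction_type", e$interaction_type)
    if (!is.na(e$action_type))
      .addAttr(ix, "pgpath.action_type", e$action_type)
    .addAttr(ix, "pgpath.source", e$source)
    .addAttr(ix, "pgpath.target", e$target)
    g <- xml2::xml_add_child(ix, "Graphics")
    src_ref <- if (e$source %in% names(graph_id)) graph_id[[e$source]] else
      paste0("c_", e$source)
    tgt_ref <- if (e$target %in% names(graph_id)) graph_id[[e$target]] else
      paste0("c_", e$target)
    sp <- pos[[e$source]] %||% pos[[paste0("comp:", e$source)]]
    tp <- pos[[e$target]] %||% pos[[paste0("comp:", e$target)]]
    xml2::xml_add_child(g, "Point", X = .fmt6(sp[1]), Y = .fmt6(sp[2]),
                        GraphRef = src_ref)
    xml2::xml_add_child(g, "Point", X = .fmt6(tp[1]), Y = .fmt6(tp[2]),
                        GraphRef = tgt_ref,
                        ArrowHead = .edgeArrowhead(e$interaction_type,
                                                   e$action_type))
  }

  is_ext <- if ("extension" %in% names(comps)) comps$extension else
    rep(FALSE, nrow(comps))
  for (i in seq_len(nrow(comps))) {
    sh <- xml2::xml_add_child(root, "Shape", TextLabel = comps$name[i],
                              GraphId = paste0("c_", comps$id[i]))
    .addAttr(sh, "pgpath.compartment", comps$id[i])
    .addAttr(sh, "pgpath.level", comps$level[i])
    if (isTRUE(is_ext[i])) .addAttr(sh, "pgpath.extension", "TRUE")
    xml2::xml_add_child(sh, "Graphics",
                        CenterX = .fmt6(boxes$x[i] + boxes$w[i] / 2),
                        CenterY = .fmt6(boxes$y[i] + boxes$h[i] / 2),
                        Width = .fmt6(boxes$w[i]), Height = .fmt6(boxes$h[i]),
                        ShapeType = "Rectangle")
  }
  xml2::xml_add_child(root, "InfoBox", CenterX = "0.0", CenterY = "0.0")

  text <- as.character(root)
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.xmlAttrs <- function(node) {
  kids <- xml2::xml_find_all(node, "./Attribute")
  setNames(xml2::xml_attr(kids, "Value"), xml2::xml_attr(kids, "Key"))
}

.REVERSE_ARROWHEAD <- list(
  "mim-conversion"    = c("metabolism", NA),
  "mim-translocation" = c("transportation", NA),
  "mim-binding"       = c("binding", NA),
  "Arrow"             = c("excretion", NA),
  "mim-inhibition"    = c(NA, "inhibitor"),
  "mim-stimulation"   = c(NA, "inducer")
)

#' Read a GPML pathway document
#'
#' Inverse of \code{\link{writeGPML}}: documents written by this package
#' round-trip exactly (layout coordinates to 1e-6). Files authored elsewhere
#' (e.g. in PathVisio) are read on a best-effort basis: node and edge typing
#' is recovered from the MIM arrowhead classes; an unmapped arrowhead raises
#' an \code{UnknownArrowheadWarning} and the edge is kept with null types.
#'
#' @param x GPML text, or the path of a GPML file.
#' @return a \linkS4class{PathwayDocument}.
#' @export
readGPML <- function(x) {
  input <- if (length(x) == 1L && !grepl("<", x, fixed = TRUE) &&
               file.exists(x)) x else paste(x, collapse = "\n")
  xml <- tryCatch(xml2::read_xml(input),
                  error = function(e)
                    .pgError("pgpath_parse_error",
                             paste("unparseable GPML:",
                                   conditionMessage(e))))
  xml2::xml_ns_strip(xml)
  if (xml2::xml_name(xml) != "Pathway")
    .pgError("pgpath_parse_error", "root element is not <Pathway>")
  root_attrs <- .xmlAttrs(xml)

  dn <- xml2::xml_find_all(xml, "./DataNode")
  nodes <- .emptyNodes()
  layout <- .emptyLayout()
  id_by_graphid <- character()
  for (i in seq_along(dn)) {
    a <- .xmlAttrs(dn[[i]])
    xref <- xml2::xml_find_first(dn[[i]], "./Xref")
    row <- .emptyNodes()[0, ]; row[1, ] <- NA
    if (any(startsWith(names(a), "pgpath."))) {
      for (col in .NODE_COLUMNS) {
        key <- paste0("pgpath.", col)
        if (key %in% names(a)) row[[col]][1] <- a[[key]]
      }
    } else {
      ## foreign GPML: classify from DataNode Type and Xref
      type <- xml2::xml_attr(dn[[i]], "Type")
      sym <- xml2::xml_attr(xref, "ID")
      if (identical(type, "GeneProduct")) {
        row$node_type[1] <- "gene"; row$symbol[1] <- sym
        row$role[1] <- "enzyme"; row$major[1] <- "FALSE"
        row$id[1] <- paste0("gene:", sym)
      } else {
        row$node_type[1] <- "drug"; row$drug_kind[1] <- "active_drug"
        row$id[1] <- sym
      }
      row$name[1] <- xml2::xml_attr(dn[[i]], "TextLabel")
    }
    row$active <- as.logical(row$active)
    row$major <- as.logical(row$major)
    nodes <- rbind(nodes, row)
    g <- xml2::xml_find_first(dn[[i]], "./Graphics")
    layout[nrow(layout) + 1L, ] <-
      list(row$id[1], as.numeric(xml2::xml_attr(g, "CenterX")),
           as.numeric(xml2::xml_attr(g, "CenterY")))
    id_by_graphid[[xml2::xml_attr(dn[[i]], "GraphId")]] <- row$id[1]
  }

  shapes <- xml2::xml_find_all(xml, "./Shape")
  comps <- data.frame(id = character(), name = character(),
                      level = character(), extension = logical(),
                      stringsAsFactors = FALSE)
  for (s in shapes) {
    a <- .xmlAttrs(s)
    if (!"pgpath.compartment" %in% names(a)) next
    comps[nrow(comps) + 1L, ] <-
      list(a[["pgpath.compartment"]], xml2::xml_attr(s, "TextLabel"),
           a[["pgpath.level"]] %||% "anatomical",
           identical(a["pgpath.extension"][[1]], "TRUE"))
    gid <- xml2::xml_attr(s, "GraphId")
    if (!is.na(gid)) id_by_graphid[[gid]] <- a[["pgpath.compartment"]]
  }

  ixs <- xml2::xml_find_all(xml, "./Interaction")
  edges <- .emptyEdges()
  for (ix in ixs) {
    a <- .xmlAttrs(ix)
    pts <- xml2::xml_find_all(ix, "./Graphics/Point")
    src <- a["pgpath.source"][[1]]
    tgt <- a["pgpath.target"][[1]]
    if (is.na(src) && length(pts))
      src <- id_by_graphid[xml2::xml_attr(pts[[1]], "GraphRef")][[1]]
    if (is.na(tgt) && length(pts))
      tgt <- id_by_graphid[xml2::xml_attr(pts[[length(pts)]],
                                          "GraphRef")][[1]]
    itype <- a["pgpath.interaction_type"][[1]]
    atype <- a["pgpath.action_type"][[1]]
    if (is.na(itype) && is.na(atype)) {
      ah <- if (length(pts))
        xml2::xml_attr(pts[[length(pts)]], "ArrowHead") else NA_character_
      if (!is.na(ah) && ah %in% names(.REVERSE_ARROWHEAD)) {
        itype <- .REVERSE_ARROWHEAD[[ah]][1]
        atype <- .REVERSE_ARROWHEAD[[ah]][2]
      } else {
        .pgWarning("pgpath_unknown_arrowhead_warning",
                   sprintf("unmapped arrowhead '%s'; edge kept with null types",
                           if (is.na(ah)) "<none>" else ah))
      }
    }
    edges[nrow(edges) + 1L, ] <- list(src, tgt, itype, atype)
  }

  drug_info <- if ("pgpath.druginfo" %in% names(root_attrs))
    jsonlite::fromJSON(root_attrs[["pgpath.druginfo"]],
                       simplifyVector = FALSE) else list()
  new("PathwayDocument",
      pathwayKind = root_attrs["pgpath.kind"][[1]] %||NA% "PK",
      nodes = nodes, edges = edges, compartments = comps, layout = layout,
      administrationRoute = root_attrs["pgpath.route"][[1]],
      description = root_attrs["pgpath.description"][[1]],
      drugInfo = drug_info)
}

`%||NA%` <- function(a, b) if (is.na(a)) b else a
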