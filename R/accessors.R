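#' Accessors for pathway documents and GVB tables
#'
#' Slot access goes through these accessors rather than \code{@}.
#'
#' @param x a \linkS4class{PathwayDocument}, \linkS4class{GvbTable} or
#'   \linkS4class{PersonalizedPathway}.
#' @return \code{pathwayKind}: \code{"PK"} or \code{"PD"};
#'   \code{pathwayNodes}, \code{pathwayEdges}, \code{pathwayCompartments},
#'   \code{pathwayLayout}: the respective data.frames; \code{principalDrug}:
#'   the one-row drug node; \code{geneSymbols}: the document's HGNC symbols;
#'   \code{gvbScores}: a named numeric of per-gene scores;
#'   \code{gvbCounts}: a named integer of contributing variant counts;
#'   \code{nodeColors}: the gradient colour map of a personalized pathway.
#' @name pathway-accessors
NULL

#' @rdname pathway-accessors
#' @export
setGeneric("pathwayKind", function(x) standardGeneric("pathwayKind"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathwayNodes", function(x) standardGeneric("pathwayNodes"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathwayEdges", function(x) standardGeneric("pathwayEdges"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathwayCompartments",
           function(x) standardGeneric("pathwayCompartments"))
#' @rdname pathway-accessors
#' @export
setGeneric("pathwayLayout", function(x) standardGeneric("pathwayLayout"))
#' @rdname pathway-accessors
#' @export
setGeneric("principalDrug", function(x) standardGeneric("principalDrug"))
#' @rdname pathway-accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname pathway-accessors
#' @export
setGeneric("gvbScores", function(x) standardGeneric("gvbScores"))
#' @rdname pathway-accessors
#' @export
setGeneric("gvbCounts", function(x) standardGeneric("gvbCounts"))
#' @rdname pathway-accessors
#' @export
setGeneric("nodeColors", function(x) standardGeneric("nodeColors"))

#' @rdname pathway-accessors
setMethod("pathwayKind", "PathwayDocument", function(x) x@pathwayKind)
#' @rdname pathway-accessors
setMethod("pathwayNodes", "PathwayDocument", function(x) x@nodes)
#' @rdname pathway-accessors
setMethod("pathwayEdges", "PathwayDocument", function(x) x@edges)
#' @rdname pathway-accessors
setMethod("pathwayCompartments", "PathwayDocument",
          function(x) x@compartments)
#' @rdname pathway-accessors
setMethod("pathwayLayout", "PathwayDocument", function(x) x@layout)
#' @rdname pathway-accessors
setMethod("principalDrug", "PathwayDocument", function(x) {
  x@nodes[x@nodes$node_type == "drug", , drop = FALSE]
})
#' @rdname pathway-accessors
setMethod("geneSymbols", "PathwayDocument", function(x) {
  x@nodes$symbol[x@nodes$node_type == "gene"]
})
#' @rdname pathway-accessors
setMethod("gvbScores", "GvbTable",
          function(x) setNames(x@score, x@gene))
#' @rdname pathway-accessors
setMethod("gvbCounts", "GvbTable",
          function(x) setNames(x@nVariants, x@gene))
#' @rdname pathway-accessors
setMethod("pathwayKind", "PersonalizedPathway",
          function(x) pathwayKind(x@base))
#' @rdname pathway-accessors
setMethod("nodeColors", "PersonalizedPathway", function(x) x@colors)
#' @rdname pathway-accessors
setMethod("gvbScores", "PersonalizedPathway", function(x) gvbScores(x@gvb))

setMethod("show", "PathwayDocument", function(object) {
  nd <- object@nodes
  cat(sprintf("PathwayDocument (%s) for %s\n", object@pathwayKind,
              paste(nd$name[nd$node_type == "drug"], collapse = ", ")))
  cat(sprintf("  nodes: %d (%d drug, %d metabolite, %d gene)\n",
              nrow(nd), sum(nd$node_type == "drug"),
              sum(nd$node_type == "metabolite"),
              sum(nd$node_type == "gene")))
  cat(sprintf("  edges: %d | compartments: %d\n", nrow(object@edges),
              nrow(object@compartments)))
  if (object@pathwayKind == "PK")
    cat(sprintf("  administration route: %s\n", object@administrationRoute))
  invisible(NULL)
})

setMethod("show", "GvbTable", function(object) {
  cat(sprintf("GvbTable: %d genes (floor %g)\n", length(object@gene),
              object@floor))
  if (length(object@gene)) {
    ord <- order(object@score)
    k <- head(ord, 5L)
    cat(sprintf("  %s: %.6f (%d variants)\n", object@gene[k],
                object@score[k], object@nVariants[k]), sep = "")
    if (length(ord) > 5L) cat(sprintf("  ... and %d more\n",
                                      length(ord) - 5L))
  }
  invisible(NULL)
})

setMethod("show", "PersonalizedPathway", function(object) {
  cat(sprintf("PersonalizedPathway (%s), %d gene colours\n",
              pathwayKind(object@base), length(object@colors)))
  invisible(NULL)
})

setMethod("show", "RenderedDiagram", function(object) {
  cat(sprintf("RenderedDiagram: %d node anchors, %d characters of SVG%s\n",
              length(object@anchorIndex), nchar(object@svg),
              if (object@hasBackground) ", raster background" else ""))
  invisible(NULL)
})
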