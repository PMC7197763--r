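## Central S4 classes. Nodes, edges, compartments and layout are kept as
## data.frames with fixed schemas inside a PathwayDocument; per-node-kind
## constructors build schema-conformant rows.

.NODE_COLUMNS <- c("id", "name", "node_type", "drug_kind", "active",
                   "parent_drug", "symbol", "gene_name", "role", "major",
                   "compartment", "location", "tissue", "description")

.EDGE_COLUMNS <- c("source", "target", "interaction_type", "action_type")

.emptyNodes <- function() {
  df <- data.frame(id = character(), name = character(),
                   node_type = character(), drug_kind = character(),
                   active = logical(), parent_drug = character(),
                   symbol = character(), gene_name = character(),
                   role = character(), major = logical(),
                   compartment = character(), location = character(),
                   tissue = character(), description = character(),
                   stringsAsFactors = FALSE)
  df
}

.emptyEdges <- function() {
  data.frame(source = character(), target = character(),
             interaction_type = character(), action_type = character(),
             stringsAsFactors = FALSE)
}

.emptyLayout <- function() {
  data.frame(id = character(), x = numeric(), y = numeric(),
             stringsAsFactors = FALSE)
}

.nodeRow <- function(...) {
  args <- list(...)
  row <- .emptyNodes()[0, ]
  row[1, ] <- NA
  for (nm in names(args)) row[[nm]][1] <- args[[nm]]
  row
}

#' Node row constructors
#'
#' Build single rows of the pathway node table. \code{drugNode} describes the
#' administered drug (prodrug or active drug), \code{metaboliteNode} an
#' enzymatic product (active or inactive) of a parent drug, and
#' \code{geneNode} a gene product acting as enzyme, transporter, carrier or
#' target in a body (or cellular) compartment.
#'
#' @param id node identifier (HMDB-style for drugs/metabolites).
#' @param name display name.
#' @param drug_kind \code{"prodrug"} or \code{"active_drug"}.
#' @param active logical; for metabolites, whether the product is the active
#'   ingredient.
#' @param parent_drug id of the drug the metabolite derives from.
#' @param symbol HGNC gene symbol.
#' @param gene_name full gene name.
#' @param role one of \code{geneRoles()}.
#' @param major logical; marks enzymes playing a significant role in the
#'   drug's metabolism (only meaningful for \code{role = "enzyme"}).
#' @param compartment compartment id the gene product is placed in.
#' @param location chromosomal location (display only).
#' @param tissue main expression tissue (display only).
#' @param description free-text description.
#' @return a one-row data.frame with the node table schema.
#' @export
drugNode <- function(id, name, drug_kind = c("active_drug", "prodrug"),
                     description = NA_character_) {
  drug_kind <- match.arg(drug_kind)
  .nodeRow(id = id, name = name, node_type = "drug", drug_kind = drug_kind,
           description = description)
}

#' @rdname drugNode
#' @export
metaboliteNode <- function(id, name, active, parent_drug) {
  .nodeRow(id = id, name = name, node_type = "metabolite", active = active,
           parent_drug = parent_drug)
}

#' @rdname drugNode
#' @export
geneNode <- function(symbol, gene_name = symbol,
                     role = c("enzyme", "transporter", "carrier", "target"),
                     major = FALSE, compartment = NA_character_,
                     location = NA_character_, tissue = NA_character_,
                     description = NA_character_) {
  role <- match.arg(role)
  .nodeRow(id = paste0("gene:", symbol), name = symbol, node_type = "gene",
           symbol = symbol, gene_name = gene_name, role = role, major = major,
           compartment = compartment, location = location, tissue = tissue,
           description = description)
}

#' PathwayDocument: a standardized single-drug PK or PD pathway
#'
#' One drug-centered pathway: a principal drug node, its metabolites and
#' interacting gene products (typed nodes), typed edges among them,
#' body/cellular compartments, and a 2-D layout in abstract canvas units
#' (origin top-left, y increasing downward). PK documents carry an
#' administration route; PD documents carry a mechanism description.
#'
#' @slot pathwayKind \code{"PK"} or \code{"PD"}.
#' @slot nodes data.frame of typed nodes (see \code{\link{drugNode}}).
#' @slot edges data.frame with columns source, target, interaction_type,
#'   action_type.
#' @slot compartments data.frame with columns id, name, level.
#' @slot layout data.frame with columns id, x, y.
#' @slot administrationRoute compartment id of the administration route
#'   (PK only; \code{NA} for PD).
#' @slot description mechanism-of-action text (PD only; \code{NA} for PK).
#' @slot drugInfo named list of free-text clinical fields for the principal
#'   drug (atc_class, indications, adverse_effects, interactions, pk_notes).
#' @export
setClass("PathwayDocument",
  representation(pathwayKind = "character", nodes = "data.frame",
                 edges = "data.frame", compartments = "data.frame",
                 layout = "data.frame", administrationRoute = "character",
                 description = "character", drugInfo = "list"),
  prototype(pathwayKind = "PK", nodes = .emptyNodes(), edges = .emptyEdges(),
            compartments = data.frame(id = character(), name = character(),
                                      level = character(),
                                      stringsAsFactors = FALSE),
            layout = .emptyLayout(), administrationRoute = NA_character_,
            description = NA_character_, drugInfo = list()))

setValidity("PathwayDocument", function(object) {
  msgs <- character()
  if (!length(object@pathwayKind) == 1L ||
      !object@pathwayKind %in% c("PK", "PD"))
    msgs <- c(msgs, "pathwayKind must be 'PK' or 'PD'")
  if (!all(.NODE_COLUMNS %in% names(object@nodes)))
    msgs <- c(msgs, "nodes is missing schema columns")
  if (!all(.EDGE_COLUMNS %in% names(object@edges)))
    msgs <- c(msgs, "edges is missing schema columns")
  if (!all(c("id", "name", "level") %in% names(object@compartments)))
    msgs <- c(msgs, "compartments is missing schema columns")
  if (!all(c("id", "x", "y") %in% names(object@layout)))
    msgs <- c(msgs, "layout is missing schema columns")
  if (length(msgs)) msgs else TRUE
})

#' GvbTable: per-gene variant burden scores
#'
#' One row per gene of a scoring universe. The score is the geometric mean of
#' the SIFT scores of the gene's qualifying coding variants (zero scores
#' floored at \code{floor} before the log); genes with no qualifying variant
#' score exactly 1. Lower scores indicate greater predicted functional
#' burden.
#'
#' @slot gene HGNC symbols.
#' @slot score GVB scores in (0, 1].
#' @slot nVariants number of contributing variants per gene.
#' @slot variantIds list of contributing variant identifiers per gene.
#' @slot floor the zero-SIFT floor applied before averaging.
#' @export
setClass("GvbTable",
  representation(gene = "character", score = "numeric",
                 nVariants = "integer", variantIds = "list",
                 floor = "numeric"),
  prototype(gene = character(), score = numeric(), nVariants = integer(),
            variantIds = list(), floor = 1e-3))

setValidity("GvbTable", function(object) {
  msgs <- character()
  n <- length(object@gene)
  if (length(object@score) != n || length(object@nVariants) != n ||
      length(object@variantIds) != n)
    msgs <- c(msgs, "gene, score, nVariants and variantIds lengths differ")
  if (anyDuplicated(object@gene))
    msgs <- c(msgs, "duplicated gene symbols")
  if (any(object@score <= 0 | object@score > 1))
    msgs <- c(msgs, "scores must lie in (0, 1]")
  if (any(object@nVariants == 0L & object@score != 1))
    msgs <- c(msgs, "genes without variants must score exactly 1")
  if (length(msgs)) msgs else TRUE
})

#' PersonalizedPathway: a pathway annotated with GVB gradient colours
#'
#' @slot base the underlying \linkS4class{PathwayDocument}.
#' @slot gvb the \linkS4class{GvbTable} used for annotation.
#' @slot colors named character; one gradient colour per gene node of
#'   \code{base}, equal to \code{gvbToColor} of its score.
#' @export
setClass("PersonalizedPathway",
  representation(base = "PathwayDocument", gvb = "GvbTable",
                 colors = "character"))

setValidity("PersonalizedPathway", function(object) {
  genes <- object@base@nodes$symbol[object@base@nodes$node_type == "gene"]
  if (!setequal(names(object@colors), genes) ||
      length(object@colors) != length(genes))
    return("colors must be named by exactly the base document's gene symbols")
  TRUE
})

#' RenderedDiagram: an SVG rendering of a pathway
#'
#' @slot svg the SVG document as a single string.
#' @slot anchorIndex named character mapping node ids to SVG element ids.
#' @slot hasBackground whether a raster background is embedded.
#' @slot infoWindows named character; per-node HTML info-window fragments
#'   (drug and gene nodes only), keyed by node id.
#' @slot descriptionWindow HTML fragment for the PD mechanism description
#'   window (\code{NA} for PK diagrams).
#' @export
setClass("RenderedDiagram",
  representation(svg = "character", anchorIndex = "character",
                 hasBackground = "logical", infoWindows = "character",
                 descriptionWindow = "character"),
  prototype(svg = "", anchorIndex = character(), hasBackground = FALSE,
            infoWindows = character(), descriptionWindow = NA_character_))
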