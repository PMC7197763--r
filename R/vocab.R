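## Closed vocabularies for the standardized PK/PD pathway schema.

#' Compartment vocabulary
#'
#' The closed compartment vocabulary of the standardized pathway frame:
#' anatomical organs, transport structures, administration routes (PK level)
#' and cellular components (PD level). The vocabulary can be extended at
#' build time via the \code{config} argument of the builders; extensions are
#' accepted with a warning.
#'
#' @param level optional character vector restricting the result to one or
#'   more of \code{"anatomical"}, \code{"transport"}, \code{"administration"},
#'   \code{"cellular"}.
#' @return a data.frame with columns \code{id}, \code{name}, \code{level}.
#' @export
#' @examples
#' head(compartmentVocabulary("anatomical"))
compartmentVocabulary <- function(level = NULL) {
  vocab <- .COMPARTMENT_VOCAB
  if (!is.null(level)) {
    level <- match.arg(level, unique(vocab$level), several.ok = TRUE)
    vocab <- vocab[vocab$level %in% level, , drop = FALSE]
  }
  rownames(vocab) <- NULL
  vocab
}

.compartmentId <- function(name) gsub("[^a-z0-9]+", "_", tolower(name))

.makeVocab <- function(names, level) {
  data.frame(id = .compartmentId(names), name = names, level = level,
             stringsAsFactors = FALSE)
}

.COMPARTMENT_VOCAB <- rbind(
  .makeVocab(c("eye", "nose", "mouth", "brain", "blood-brain-barrier",
               "lung", "heart", "muscle", "skin", "kidney", "liver",
               "adrenal gland", "testis", "intestines", "placenta"),
             "anatomical"),
  .makeVocab(c("artery", "vein", "bile duct", "urinary tract", "gut lumen"),
             "transport"),
  .makeVocab(c("eye drop", "inhalation", "sublingual/buccal", "oral",
               "intravenous", "intramuscular", "percutaneous"),
             "administration"),
  .makeVocab(c("nucleus", "endoplasmic reticulum", "mitochondria",
               "Golgi apparatus", "lysosome", "peroxisome", "vesicle",
               "cell membrane", "ribosome"),
             "cellular")
)

.INTERACTION_TYPES <- c("metabolism", "transportation", "binding", "excretion")

.PK_ACTION_TYPES <- c("inhibitor", "inducer", "substrate")

.PD_ACTION_TYPES <- c("inhibitor", "inducer", "substrate", "agonist",
                      "antagonist", "activator", "modulator", "competitor",
                      "cofactor", "ligand", "stimulator", "antibody",
                      "binder", "potentiator", "neutralizer")

.GENE_ROLES <- c("enzyme", "transporter", "carrier", "target")

.DRUG_KINDS <- c("active_drug", "prodrug")

#' Interaction and action vocabularies
#'
#' @return a character vector of allowed values.
#' @param kind for \code{actionTypes}, the pathway kind: the PK vocabulary is
#'   restricted to inhibitor/inducer/substrate; PD admits the full action set.
#' @export
#' @examples
#' interactionTypes()
#' actionTypes("PK")
interactionTypes <- function() .INTERACTION_TYPES

#' @rdname interactionTypes
#' @export
actionTypes <- function(kind = c("PD", "PK")) {
  kind <- match.arg(kind)
  if (kind == "PK") .PK_ACTION_TYPES else .PD_ACTION_TYPES
}

#' @rdname interactionTypes
#' @export
geneRoles <- function() .GENE_ROLES

## Default compartment placement by gene role (the standard ADME narrative:
## hepatic metabolism, intestinal transport, plasma carriage, membrane targets).
.DEFAULT_PLACEMENT <- c(enzyme = "liver", transporter = "intestines",
                        carrier = "artery", target = "cell_membrane")

## Arrowhead classes used in GPML output (MIM-style), one per interaction or
## drug-on-gene action type. Reverse-mapped on read; unknown classes degrade
## to typeless edges with a warning.
.ARROWHEAD_BY_TYPE <- c(
  metabolism     = "mim-conversion",
  transportation = "mim-translocation",
  binding        = "mim-binding",
  excretion      = "Arrow",
  inhibitor      = "mim-inhibition",
  inducer        = "mim-stimulation",
  antagonist     = "mim-inhibition",
  agonist        = "mim-stimulation",
  activator      = "mim-stimulation",
  stimulator     = "mim-stimulation",
  substrate      = "mim-conversion"
)

.edgeArrowhead <- function(interaction, action) {
  ## drug-on-gene modulation dominates the glyph; otherwise the interaction
  if (!is.na(action) && action %in% c("inhibitor", "inducer"))
    return(.ARROWHEAD_BY_TYPE[[action]])
  if (!is.na(interaction)) return(.ARROWHEAD_BY_TYPE[[interaction]])
  ah <- .ARROWHEAD_BY_TYPE[action]
  if (is.na(ah)) "Arrow" else unname(ah)
}

#' Default rendering theme
#'
#' Node shape and fill standard: prodrug and active drug share a shape and
#' differ in colour, as do inactive and active metabolites; gene roles differ
#' in both shape and colour. All values may be overridden by passing a
#' modified copy to \code{\link{renderSVG}}.
#'
#' @return a named list of colours, shapes and canvas dimensions.
#' @export
defaultTheme <- function() {
  list(
    fill = c(prodrug = "#F2A93B", active_drug = "#2E6FB7",
             inactive_metabolite = "#B8B8B8", active_metabolite = "#2E6FB7",
             enzyme = "#4CAF50", transporter = "#8E44AD",
             carrier = "#16A085", target = "#C0392B"),
    shape = c(drug = "rect", metabolite = "rect", enzyme = "roundrect",
              transporter = "ellipse", carrier = "ellipse", target = "rect"),
    stroke = "#333333",
    node_width = 110, node_height = 32,
    canvas_width = 1000, canvas_height = 760,
    font_family = "Helvetica, Arial, sans-serif",
    gvb_neutral = "#FFFFFF", gvb_alert = "#D7191C"
  )
}
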