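#' Map a GVB score to a gradient colour
#'
#' Deterministic, monotone colour scale for pathway annotation: a score of 1
#' (no burden) maps to the neutral endpoint, the zero-SIFT floor maps to the
#' alert endpoint, and scores in between interpolate linearly per RGB
#' channel. Lower scores land closer to the alert endpoint.
#'
#' @param score a GVB score in (0, 1].
#' @param neutral,alert 6-hex-digit endpoint colours.
#' @param floor the score mapped to the full alert colour (the zero-SIFT
#'   floor of the scoring step).
#' @return a 6-hex-digit colour string.
#' @export
#' @examples
#' gvbToColor(1)     # "#FFFFFF"
#' gvbToColor(0.001) # "#D7191C"
gvbToColor <- function(score, neutral = "#FFFFFF", alert = "#D7191C",
                       floor = 1e-3) {
  if (length(score) != 1L || is.na(score) || score <= 0 || score > 1)
    .pgError("pgpath_score_range_error", "score must lie in (0, 1]")
  t <- (1 - score) / (1 - floor)
  t <- min(max(t, 0), 1)
  n <- grDevices::col2rgb(neutral)[, 1]
  a <- grDevices::col2rgb(alert)[, 1]
  mix <- round(n + t * (a - n))
  sprintf("#%02X%02X%02X", mix[1], mix[2], mix[3])
}

#' Personalize a pathway with GVB scores
#'
#' Assigns every gene node of the document the gradient colour of its GVB
#' score. Genes missing from the table default to a score of 1 (neutral)
#' and are reported via \code{message}. The resulting colour map is exactly
#' what \code{\link{renderSVG}} applies when given the same table.
#'
#' @param doc a valid \linkS4class{PathwayDocument}.
#' @param gvb a \linkS4class{GvbTable}.
#' @param theme theme list providing the gradient endpoints.
#' @return a \linkS4class{PersonalizedPathway}.
#' @export
personalizePathway <- function(doc, gvb, theme = defaultTheme()) {
  stopifnot(is(doc, "PathwayDocument"), is(gvb, "GvbTable"))
  genes <- geneSymbols(doc)
  scores <- gvbScores(gvb)
  missing <- setdiff(genes, names(scores))
  if (length(missing)) {
    message("genes without a GVB entry default to 1.0: ",
            paste(missing, collapse = ", "))
    gvb <- gvbTable(c(gvb@gene, missing),
                    c(gvb@score, rep(1, length(missing))),
                    c(gvb@nVariants, rep(0L, length(missing))),
                    c(gvb@variantIds,
                      rep(list(character()), length(missing))),
                    floor = gvb@floor)
    scores <- gvbScores(gvb)
  }
  colors <- vapply(genes, function(g)
    gvbToColor(scores[[g]], neutral = theme$gvb_neutral,
               alert = theme$gvb_alert, floor = gvb@floor), character(1))
  new("PersonalizedPathway", base = doc, gvb = gvb, colors = colors)
}

.drugGeneActions <- function(doc) {
  nodes <- doc@nodes
  drug_id <- nodes$id[nodes$node_type == "drug"]
  sym_by_id <- setNames(nodes$symbol, nodes$id)
  e <- doc@edges
  incident <- (e$source %in% drug_id & e$target %in% names(sym_by_id)) |
    (e$target %in% drug_id & e$source %in% names(sym_by_id))
  e <- e[incident & !is.na(e$action_type), , drop = FALSE]
  gene <- ifelse(e$source %in% drug_id, sym_by_id[e$target],
                 sym_by_id[e$source])
  data.frame(gene = unname(gene), action = e$action_type,
             stringsAsFactors = FALSE)
}

#' Predict the direction of the plasma active-ingredient concentration shift
#'
#' Qualitative rule engine over a personalized PK pathway. A gene is
#' \emph{impaired} when its GVB score falls below \code{impairedThreshold}.
#' The direction is decided by impaired metabolizing enzymes:
#' \itemize{
#'   \item prodrug with an impaired major (activating) enzyme: reduced
#'     bioactivation, so \code{decreased_active_ingredient};
#'   \item active drug with an impaired major metabolizing enzyme: reduced
#'     clearance, so \code{increased_active_ingredient};
#'   \item impaired non-major enzymes do not decide the direction on their
#'     own unless the pathway has no major enzyme at all; they are reported
#'     alongside (in \code{implicated} once a direction is set, otherwise in
#'     the mechanism text);
#'   \item impaired transporters/carriers have no directionality rule and
#'     are flagged indeterminate in the mechanism text;
#'   \item no impaired gene: \code{unchanged}, with empty \code{implicated}.
#' }
#' Predictions are strictly qualitative - a direction with a rationale,
#' never a concentration.
#'
#' @param p a \linkS4class{PersonalizedPathway} over a PK document.
#' @param impairedThreshold GVB cutoff below which a gene counts as
#'   impaired. The default 0.3 is a deliberately arbitrary screening value;
#'   no validated cutoff exists and it should be tuned per use.
#' @return a one-row data.frame with columns \code{drug_id},
#'   \code{direction} (\code{decreased_active_ingredient},
#'   \code{increased_active_ingredient} or \code{unchanged}),
#'   \code{mechanism}, and a list-column \code{implicated} holding a
#'   data.frame (gene, role, gvb) of the deciding genes.
#' @export
predictConcentrationShift <- function(p, impairedThreshold = 0.3) {
  stopifnot(is(p, "PersonalizedPathway"))
  doc <- p@base
  if (pathwayKind(doc) != "PK")
    .pgError("pgpath_kind_error",
             "concentration-shift prediction applies to PK pathways")
  nodes <- doc@nodes
  drug <- nodes[nodes$node_type == "drug", ]
  genes <- nodes[nodes$node_type == "gene", , drop = FALSE]
  scores <- gvbScores(p@gvb)
  gvb <- scores[genes$symbol]
  impaired <- !is.na(gvb) & gvb < impairedThreshold

  is_enzyme <- genes$role == "enzyme"
  has_major <- any(is_enzyme & genes$major)
  deciding <- impaired & is_enzyme & (if (has_major) genes$major else TRUE)
  secondary_enz <- impaired & is_enzyme & !deciding
  transporterish <- impaired & genes$role %in% c("transporter", "carrier")

  prodrug <- identical(drug$drug_kind, "prodrug")
  notes <- character()
  if (any(deciding)) {
    direction <- if (prodrug) "decreased_active_ingredient" else
      "increased_active_ingredient"
    mech <- if (prodrug)
      sprintf("reduced bioactivation: impaired %s enzyme(s) %s lower active-metabolite formation",
              if (has_major) "major activating" else "activating",
              paste(genes$symbol[deciding], collapse = ", "))
    else
      sprintf("reduced clearance: impaired major metabolizing enzyme(s) %s slow elimination of the active drug",
              paste(genes$symbol[deciding], collapse = ", "))
    keep <- deciding | secondary_enz
  } else {
    direction <- "unchanged"
    mech <- "no impaired deciding enzyme"
    keep <- rep(FALSE, nrow(genes))
    if (any(secondary_enz))
      notes <- c(notes, sprintf(
        "non-major enzyme(s) %s impaired but not direction-deciding while major enzymes are unimpaired",
        paste(genes$symbol[secondary_enz], collapse = ", ")))
  }
  if (any(secondary_enz) && any(deciding))
    notes <- c(notes, sprintf("non-major enzyme(s) %s also impaired",
                              paste(genes$symbol[secondary_enz],
                                    collapse = ", ")))
  if (any(transporterish))
    notes <- c(notes, sprintf(
      "transporter/carrier impairment (%s): direction indeterminate",
      paste(genes$symbol[transporterish], collapse = ", ")))
  if (length(notes)) mech <- paste(c(mech, notes), collapse = "; ")

  implicated <- data.frame(gene = genes$symbol[keep],
                           role = genes$role[keep],
                           gvb = unname(gvb[keep]),
                           stringsAsFactors = FALSE)
  out <- data.frame(drug_id = drug$id, direction = direction,
                    mechanism = mech, stringsAsFactors = FALSE)
  out$implicated <- list(implicated)
  out
}

#' Infer drug-gene-drug interactions between two PK pathways
#'
#' Scans the genes shared by two single-drug PK pathways: when one drug
#' inhibits a gene of which the other drug is a substrate, the victim's
#' metabolism is predicted to slow down (inhibition); when the perpetrator
#' induces the gene, the victim's metabolism is predicted to accelerate
#' (induction). The scan is symmetric - both drugs are considered as
#' perpetrator - and results are ordered by gene symbol, then perpetrator.
#'
#' @param docA,docB valid PK \linkS4class{PathwayDocument}s of two distinct
#'   drugs.
#' @return a data.frame with columns \code{perpetrator_drug},
#'   \code{victim_drug}, \code{gene}, \code{mechanism} (\code{inhibition}
#'   or \code{induction}) and \code{expected_effect}
#'   (\code{victim_metabolism_slowed} or
#'   \code{victim_metabolism_accelerated}); zero rows when no shared gene
#'   qualifies.
#' @export
inferDDI <- function(docA, docB) {
  stopifnot(is(docA, "PathwayDocument"), is(docB, "PathwayDocument"))
  if (pathwayKind(docA) != "PK" || pathwayKind(docB) != "PK")
    .pgError("pgpath_kind_error", "DDI inference requires two PK pathways")
  drugA <- principalDrug(docA)$id
  drugB <- principalDrug(docB)$id
  if (identical(drugA, drugB))
    .pgError("pgpath_same_drug_error",
             "DDI inference requires two distinct drugs")
  actsA <- .drugGeneActions(docA)
  actsB <- .drugGeneActions(docB)
  effect <- c(inhibitor = "victim_metabolism_slowed",
              inducer = "victim_metabolism_accelerated")
  mech <- c(inhibitor = "inhibition", inducer = "induction")
  out <- data.frame(perpetrator_drug = character(),
                    victim_drug = character(), gene = character(),
                    mechanism = character(), expected_effect = character(),
                    stringsAsFactors = FALSE)
  scan <- function(perp_acts, vict_acts, perp_id, vict_id) {
    for (g in sort(intersect(perp_acts$gene, vict_acts$gene))) {
      pa <- perp_acts$action[perp_acts$gene == g]
      va <- vict_acts$action[vict_acts$gene == g]
      if (!"substrate" %in% va) next
      for (mod in intersect(c("inhibitor", "inducer"), pa)) {
        out[nrow(out) + 1L, ] <<- list(perp_id, vict_id, g, mech[[mod]],
                                       effect[[mod]])
      }
    }
  }
  scan(actsA, actsB, drugA, drugB)
  scan(actsB, actsA, drugB, drugA)
  out <- out[order(out$gene, out$perpetrator_drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
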