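## Builders: drug-gene interaction records -> validated pathway documents.

.resolveCompartments <- function(ids, config = list()) {
  ext <- config$compartments
  out <- lapply(unique(ids), function(id) {
    hit <- .COMPARTMENT_VOCAB[.COMPARTMENT_VOCAB$id == id, , drop = FALSE]
    if (nrow(hit) == 1L) {
      hit$extension <- FALSE
      return(hit)
    }
    if (!is.null(ext) && id %in% ext$id) {
      row <- ext[ext$id == id, c("id", "name", "level"), drop = FALSE][1L, ]
      row$extension <- TRUE
      .pgWarning("pgpath_vocabulary_warning",
                 sprintf("compartment '%s' added outside the closed vocabulary",
                         row$name))
      return(row)
    }
    .pgWarning("pgpath_vocabulary_warning",
               sprintf("unknown compartment id '%s'; added as an %s extension",
                       id, "anatomical"))
    data.frame(id = id, name = id, level = "anatomical", extension = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.effectivePlacement <- function(records, placement) {
  genes <- records$gene_symbol
  if (is.null(placement)) {
    placement <- setNames(unname(.DEFAULT_PLACEMENT[records$role]), genes)
  } else {
    missing <- setdiff(genes, names(placement))
    if (length(missing))
      .pgError("pgpath_unplaced_gene_error",
               paste("placement does not cover gene(s):",
                     paste(missing, collapse = ", ")))
    placement <- placement[genes]
  }
  placement
}

.checkOneDrug <- function(records) {
  if (nrow(records) == 0L)
    .pgError("pgpath_empty_input_error", "no interaction records supplied")
  drugs <- unique(records$drug_id)
  if (length(drugs) > 1L)
    .pgError("pgpath_mixed_drug_error",
             paste("records name more than one drug:",
                   paste(drugs, collapse = ", ")))
  invisible(drugs)
}

## Deterministic grid layout: compartments tile a 3-column grid; nodes fill
## slots inside their compartment box in document order. Abstract canvas
## units, origin top-left, y increasing downward.
.layoutDocument <- function(nodes, comps, node_compartment) {
  boxes <- .compartmentBoxes(comps)
  comp_pos <- list()
  for (i in seq_len(nrow(boxes)))
    comp_pos[[boxes$id[i]]] <- c(x = boxes$x[i], y = boxes$y[i])
  slot_count <- setNames(rep(0L, nrow(comps)), comps$id)
  free_count <- 0L
  xs <- ys <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    cid <- node_compartment[[nodes$id[i]]]
    if (!is.null(cid) && !is.na(cid) && cid %in% names(comp_pos)) {
      k <- slot_count[[cid]]
      slot_count[[cid]] <- k + 1L
      p <- comp_pos[[cid]]
      xs[i] <- p[["x"]] + 80 + (k %% 2L) * 150
      ys[i] <- p[["y"]] + 60 + (k %/% 2L) * 45
    } else {
      xs[i] <- 80 + free_count * 160
      ys[i] <- 40
      free_count <- free_count + 1L
    }
  }
  data.frame(id = nodes$id, x = xs, y = ys, stringsAsFactors = FALSE)
}

.assertBuilt <- function(doc) {
  viol <- validatePathway(doc)
  if (nrow(viol))
    .pgError("pgpath_validation_error",
             paste("built document fails validation:",
                   paste(viol$code, collapse = ", ")))
  doc
}

#' Build a pharmacokinetic pathway from interaction records
#'
#' Constructs the standardized one-drug-centered PK document. Enzymes yield
#' metabolism edges drug -> enzyme -> metabolite, each enzyme producing its
#' own metabolite node; on a prodrug, major (activating) enzymes emit
#' \emph{active} metabolites and non-major enzymes inactive ones, while on an
#' active drug all metabolites are inactive. Transporters yield
#' transportation edges and carriers binding edges (gene -> drug). Each
#' metabolite gains an excretion edge terminating at the bile duct when it is
#' produced in the liver and at the urinary tract otherwise (overridable per
#' gene via \code{config$excretion}).
#'
#' @param records a drug-gene record data.frame (rows with role
#'   \code{"target"} are ignored here; they belong to the PD document).
#' @param drugKind \code{"active_drug"} or \code{"prodrug"}.
#' @param placement named character mapping gene symbols to compartment ids.
#'   \code{NULL} uses the role defaults (enzyme: liver, transporter:
#'   intestines, carrier: artery); a supplied map must cover every gene.
#' @param route administration-route compartment id (default \code{"oral"}).
#' @param drugInfo optional named list of clinical free-text fields
#'   (atc_class, indications, adverse_effects, interactions, pk_notes).
#' @param config optional list: \code{$compartments} (data.frame id, name,
#'   level) extends the closed compartment vocabulary with a warning;
#'   \code{$excretion} (named character, gene symbol -> transport compartment
#'   id) overrides excretion routing.
#' @return a validated \linkS4class{PathwayDocument} of kind PK.
#' @export
#' @examples
#' fx <- clopidogrelFixture()
#' doc <- buildPKPathway(fx$records, drugKind = "prodrug")
#' doc
buildPKPathway <- function(records, drugKind = c("active_drug", "prodrug"),
                           placement = NULL, route = "oral",
                           drugInfo = list(), config = list()) {
  drugKind <- match.arg(drugKind)
  .checkRecords(records)
  if (nrow(records) == 0L)
    .pgError("pgpath_empty_input_error", "no interaction records supplied")
  .checkOneDrug(records)
  pk <- records[records$role != "target", , drop = FALSE]
  if (nrow(pk) == 0L)
    .pgError("pgpath_empty_input_error",
             "no enzyme/transporter/carrier records for a PK pathway")
  drug_id <- pk$drug_id[1L]
  drug_name <- pk$drug_name[1L]
  placement <- .effectivePlacement(pk, placement)

  nodes <- drugNode(drug_id, drug_name, drugKind)
  edges <- .emptyEdges()
  addEdge <- function(source, target, interaction, action) {
    edges[nrow(edges) + 1L, ] <<- list(source, target, interaction, action)
  }

  for (i in seq_len(nrow(pk))) {
    r <- pk[i, ]
    gnode <- geneNode(r$gene_symbol, role = r$role, major = isTRUE(r$major),
                      compartment = placement[[r$gene_symbol]])
    nodes <- rbind(nodes, gnode)
    if (r$role == "enzyme") {
      active <- drugKind == "prodrug" && isTRUE(r$major)
      met <- metaboliteNode(
        id = sprintf("met:%s:%s", drug_id, r$gene_symbol),
        name = sprintf("%s metabolite (%s)", drug_name, r$gene_symbol),
        active = active, parent_drug = drug_id)
      nodes <- rbind(nodes, met)
      addEdge(drug_id, gnode$id, "metabolism", r$action_type)
      addEdge(gnode$id, met$id, "metabolism", NA_character_)
    } else if (r$role == "transporter") {
      addEdge(gnode$id, drug_id, "transportation", r$action_type)
    } else {
      addEdge(gnode$id, drug_id, "binding", r$action_type)
    }
  }

  ## excretion: hepatic metabolites to bile duct, others to urinary tract
  mets <- nodes[nodes$node_type == "metabolite", , drop = FALSE]
  excretion_targets <- character(0)
  for (i in seq_len(nrow(mets))) {
    sym <- sub("^met:[^:]*:", "", mets$id[i])
    target <- config$excretion[[sym]]
    if (is.null(target))
      target <- if (identical(unname(placement[sym]), "liver"))
        "bile_duct" else "urinary_tract"
    addEdge(mets$id[i], target, "excretion", NA_character_)
    excretion_targets <- c(excretion_targets, target)
  }

  comp_ids <- unique(c(route, unname(placement), excretion_targets))
  comps <- .resolveCompartments(comp_ids, config)

  node_compartment <- setNames(nodes$compartment, nodes$id)
  ## metabolites sit with their producing enzyme; the drug at its route
  for (i in seq_len(nrow(mets))) {
    sym <- sub("^met:[^:]*:", "", mets$id[i])
    node_compartment[[mets$id[i]]] <- unname(placement[sym])
  }
  node_compartment[[drug_id]] <- route

  doc <- new("PathwayDocument", pathwayKind = "PK", nodes = nodes,
             edges = edges, compartments = comps,
             layout = .layoutDocument(nodes, comps, node_compartment),
             administrationRoute = route, description = NA_character_,
             drugInfo = drugInfo)
  .assertBuilt(doc)
}

#' Build a pharmacodynamic pathway from interaction records
#'
#' Constructs the cellular-level PD document: the administered drug, the
#' active ingredient (the drug itself for an active drug; a bioactivated
#' metabolite for a prodrug) and one edge per target gene carrying the
#' record's action type (the full PD action vocabulary is allowed). Targets
#' default to the cell membrane compartment.
#'
#' @inheritParams buildPKPathway
#' @param description mechanism-of-action text attached to the document
#'   (required).
#' @param placement named character mapping target gene symbols to cellular
#'   compartment ids; \code{NULL} places all targets at the cell membrane.
#' @return a validated \linkS4class{PathwayDocument} of kind PD.
#' @export
buildPDPathway <- function(records, description,
                           drugKind = c("active_drug", "prodrug"),
                           placement = NULL, drugInfo = list(),
                           config = list()) {
  drugKind <- match.arg(drugKind)
  .checkRecords(records)
  if (nrow(records) == 0L)
    .pgError("pgpath_empty_input_error", "no interaction records supplied")
  .checkOneDrug(records)
  targets <- records[records$role == "target", , drop = FALSE]
  if (nrow(targets) == 0L)
    .pgError("pgpath_no_target_error",
             "a PD pathway requires at least one target record")
  if (missing(description) || is.na(description) || !nzchar(description))
    .pgError("pgpath_format_error", "PD documents require a description")
  if (any(is.na(targets$action_type)))
    .pgError("pgpath_format_error", "target records require an action_type")
  drug_id <- targets$drug_id[1L]
  drug_name <- targets$drug_name[1L]
  placement <- .effectivePlacement(targets, placement)
  placement[is.na(placement)] <- "cell_membrane"

  nodes <- drugNode(drug_id, drug_name, drugKind)
  actor_id <- drug_id
  if (drugKind == "prodrug") {
    met <- metaboliteNode(id = sprintf("met:%s:active", drug_id),
                          name = sprintf("%s active metabolite", drug_name),
                          active = TRUE, parent_drug = drug_id)
    nodes <- rbind(nodes, met)
    actor_id <- met$id
  }
  edges <- .emptyEdges()
  for (i in seq_len(nrow(targets))) {
    r <- targets[i, ]
    gnode <- geneNode(r$gene_symbol, role = "target",
                      compartment = placement[[r$gene_symbol]])
    nodes <- rbind(nodes, gnode)
    edges[nrow(edges) + 1L, ] <- list(actor_id, gnode$id,
                                      r$interaction_type, r$action_type)
  }
  comps <- .resolveCompartments(unique(unname(placement)), config)
  node_compartment <- setNames(nodes$compartment, nodes$id)
  doc <- new("PathwayDocument", pathwayKind = "PD", nodes = nodes,
             edges = edges, compartments = comps,
             layout = .layoutDocument(nodes, comps, node_compartment),
             administrationRoute = NA_character_, description = description,
             drugInfo = drugInfo)
  .assertBuilt(doc)
}
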