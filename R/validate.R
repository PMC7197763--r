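#' Validate a pathway document against the standardized taxonomy
#'
#' Checks every structural invariant of the PK/PD pathway schema: node typing
#' (drug kind, metabolite parentage, gene roles, the major marker restricted
#' to enzymes), compartment vocabulary membership, edge typing (the PK action
#' vocabulary is restricted to inhibitor/inducer/substrate; metabolism edges
#' must connect an enzyme with a drug or metabolite; transportation edges
#' must involve a transporter or carrier), one-drug-centeredness, and the
#' kind-specific requirements (administration route for PK, description for
#' PD). Excretion edges may terminate at a transport-level compartment (bile
#' duct, urinary tract, gut lumen) instead of a node.
#'
#' Violations are returned, never raised, and are deterministically ordered:
#' node violations by node index, then compartment, then edge violations by
#' edge index, then document-level violations.
#'
#' @param doc a \linkS4class{PathwayDocument}.
#' @return a data.frame with columns \code{code}, \code{where} (node/edge id
#'   or index) and \code{message}; zero rows iff the document is valid.
#' @export
#' @examples
#' fx <- clopidogrelFixture()
#' nrow(validatePathway(fx$pk_doc))  # 0
validatePathway <- function(doc) {
  stopifnot(is(doc, "PathwayDocument"))
  v <- list()
  add <- function(code, where, message) {
    v[[length(v) + 1L]] <<- data.frame(code = code, where = where,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  nodes <- doc@nodes
  edges <- doc@edges
  comps <- doc@compartments
  kind <- doc@pathwayKind

  node_ids <- nodes$id
  drug_ids <- nodes$id[nodes$node_type == "drug"]
  comp_ids <- comps$id
  transport_ids <- comps$id[comps$level == "transport"]

  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    if (is.na(nd$id) || !nzchar(nd$id))
      add("node_id_empty", as.character(i), "node has an empty id")
    switch(nd$node_type,
      drug = {
        if (is.na(nd$drug_kind) || !nd$drug_kind %in% .DRUG_KINDS)
          add("drug_kind_invalid", nd$id,
              "drug_kind must be 'prodrug' or 'active_drug'")
      },
      metabolite = {
        if (is.na(nd$parent_drug) || !nd$parent_drug %in% drug_ids)
          add("parent_drug_unresolved", nd$id,
              "metabolite parent_drug does not name a drug node")
        if (is.na(nd$active))
          add("metabolite_active_missing", nd$id,
              "metabolite must carry an active/inactive marker")
      },
      gene = {
        if (is.na(nd$role) || !nd$role %in% .GENE_ROLES)
          add("gene_role_invalid", nd$id,
              "gene role must be enzyme, transporter, carrier or target")
        if (isTRUE(nd$major) && !identical(nd$role, "enzyme"))
          add("major_non_enzyme", nd$id,
              "the 'major' marker is restricted to enzymes")
        if (is.na(nd$compartment) || !nd$compartment %in% comp_ids)
          add("gene_compartment_unresolved", nd$id,
              "gene compartment does not resolve")
        if (is.na(nd$symbol) || !nzchar(nd$symbol))
          add("gene_symbol_empty", nd$id, "gene symbol must be non-empty")
      },
      add("node_type_invalid", nd$id, "unknown node type")
    )
  }

  if (anyDuplicated(comp_ids))
    add("compartment_id_duplicate",
        comps$id[duplicated(comps$id)][1L],
        "compartment ids must be unique within a pathway")
  is_ext <- if ("extension" %in% names(comps)) comps$extension else
    rep(FALSE, nrow(comps))
  for (i in seq_len(nrow(comps))) {
    cp <- comps[i, ]
    if (!cp$level %in% unique(.COMPARTMENT_VOCAB$level)) {
      add("compartment_level_invalid", cp$id, "unknown compartment level")
    } else if (!isTRUE(is_ext[i])) {
      known <- .COMPARTMENT_VOCAB$name[.COMPARTMENT_VOCAB$level == cp$level]
      if (!cp$name %in% known)
        add("compartment_name_unknown", cp$id,
            sprintf("'%s' is not in the %s vocabulary (mark as extension)",
                    cp$name, cp$level))
    }
  }

  allowed_actions <- if (kind == "PK") .PK_ACTION_TYPES else .PD_ACTION_TYPES
  gene_role <- setNames(nodes$role, nodes$id)
  node_type <- setNames(nodes$node_type, nodes$id)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    ref <- sprintf("edge %d (%s -> %s)", i, e$source, e$target)
    if (!e$source %in% node_ids)
      add("edge_endpoint_unresolved", ref, "source does not name a node")
    target_ok <- e$target %in% node_ids ||
      (identical(e$interaction_type, "excretion") &&
         e$target %in% transport_ids)
    if (!target_ok)
      add("edge_endpoint_unresolved", ref,
          "target does not name a node (or transport compartment for excretion)")
    if (is.na(e$interaction_type) && is.na(e$action_type))
      add("edge_untyped", ref,
          "at least one of interaction_type/action_type is required")
    if (!is.na(e$interaction_type) &&
        !e$interaction_type %in% .INTERACTION_TYPES)
      add("edge_type_invalid", ref, "unknown interaction_type")
    if (!is.na(e$action_type) && !e$action_type %in% .PD_ACTION_TYPES)
      add("edge_type_invalid", ref, "unknown action_type")
    else if (!is.na(e$action_type) && !e$action_type %in% allowed_actions)
      add("pk_action_invalid", ref,
          "PK pathways restrict action_type to inhibitor/inducer/substrate")
    if (identical(e$interaction_type, "metabolism") &&
        e$source %in% node_ids && e$target %in% node_ids) {
      st <- node_type[[e$source]]; tt <- node_type[[e$target]]
      enzyme_end <- (st == "gene" && identical(gene_role[[e$source]], "enzyme")) ||
        (tt == "gene" && identical(gene_role[[e$target]], "enzyme"))
      chem_end <- st %in% c("drug", "metabolite") ||
        tt %in% c("drug", "metabolite")
      if (!enzyme_end || !chem_end)
        add("metabolism_edge_invalid", ref,
            "metabolism edges connect an enzyme and a drug/metabolite")
    }
    if (identical(e$interaction_type, "transportation")) {
      ends <- c(e$source, e$target)
      roles <- gene_role[ends[ends %in% node_ids]]
      if (!any(roles %in% c("transporter", "carrier"), na.rm = TRUE))
        add("transportation_edge_invalid", ref,
            "transportation edges must involve a transporter or carrier")
    }
  }

  if (length(drug_ids) != 1L)
    add("principal_drug_count", "document",
        sprintf("expected exactly one principal drug node, found %d",
                length(drug_ids)))
  if (kind == "PK") {
    route <- doc@administrationRoute
    admin_ids <- comps$id[comps$level == "administration"]
    if (is.na(route) || !route %in% admin_ids)
      add("missing_route", "document",
          "PK documents require an administration_route compartment")
  } else {
    if (is.na(doc@description) || !nzchar(doc@description))
      add("missing_description", "document",
          "PD documents require a mechanism description")
  }
  missing_layout <- setdiff(node_ids, doc@layout$id)
  if (length(missing_layout))
    add("layout_missing", missing_layout[1L],
        "every node needs a layout position")

  if (length(v)) do.call(rbind, v) else
    data.frame(code = character(), where = character(),
               message = character(), stringsAsFactors = FALSE)
}
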