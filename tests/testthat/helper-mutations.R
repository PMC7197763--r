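## Mutation suite for the taxonomy validator: each entry perturbs one
## invariant of a valid document and names the violation code the validator
## must raise. Shared by the unit tests and the acceptance checks.
taxonomy_mutations <- function() {
  fx <- clopidogrelFixture()
  pk <- fx$pk_doc
  pd <- fx$pd_doc
  mutate <- function(doc, fun) { fun(doc); }
  list(
    drug_kind_invalid = list(code = "drug_kind_invalid", doc = {
      d <- pk; d@nodes$drug_kind[d@nodes$node_type == "drug"] <- "elixir"; d
    }),
    parent_drug_unresolved = list(code = "parent_drug_unresolved", doc = {
      d <- pk
      i <- which(d@nodes$node_type == "metabolite")[1]
      d@nodes$parent_drug[i] <- "HMDB9999999"; d
    }),
    gene_role_invalid = list(code = "gene_role_invalid", doc = {
      d <- pk
      i <- which(d@nodes$node_type == "gene")[1]
      d@nodes$role[i] <- "chaperone"; d
    }),
    major_non_enzyme = list(code = "major_non_enzyme", doc = {
      d <- pk
      i <- which(d@nodes$role == "transporter")[1]
      d@nodes$major[i] <- TRUE; d
    }),
    gene_compartment_unresolved = list(
      code = "gene_compartment_unresolved", doc = {
        d <- pk
        i <- which(d@nodes$node_type == "gene")[1]
        d@nodes$compartment[i] <- "spleen"; d
      }),
    gene_symbol_empty = list(code = "gene_symbol_empty", doc = {
      d <- pk
      i <- which(d@nodes$node_type == "gene")[1]
      d@nodes$symbol[i] <- ""; d
    }),
    compartment_id_duplicate = list(code = "compartment_id_duplicate",
                                    doc = {
      d <- pk; d@compartments <- rbind(d@compartments, d@compartments[1, ])
      d
    }),
    compartment_name_unknown = list(code = "compartment_name_unknown",
                                    doc = {
      d <- pk; d@compartments$name[1] <- "gizzard"
      d@compartments$extension[1] <- FALSE; d
    }),
    compartment_level_invalid = list(code = "compartment_level_invalid",
                                     doc = {
      d <- pk; d@compartments$level[1] <- "astral"; d
    }),
    edge_endpoint_unresolved = list(code = "edge_endpoint_unresolved",
                                    doc = {
      d <- pk; d@edges$target[1] <- "gene:NOPE"; d
    }),
    edge_untyped = list(code = "edge_untyped", doc = {
      d <- pk
      d@edges$interaction_type[1] <- NA_character_
      d@edges$action_type[1] <- NA_character_; d
    }),
    edge_type_invalid = list(code = "edge_type_invalid", doc = {
      d <- pk; d@edges$interaction_type[1] <- "osmosis"; d
    }),
    pk_action_invalid = list(code = "pk_action_invalid", doc = {
      d <- pk; d@edges$action_type[1] <- "agonist"; d
    }),
    metabolism_edge_invalid = list(code = "metabolism_edge_invalid", doc = {
      d <- pk
      ## metabolism edge rerouted between the transporter and the drug
      i <- which(d@edges$interaction_type == "metabolism")[1]
      d@edges$source[i] <- "gene:ABCB1"
      d@edges$target[i] <- d@nodes$id[d@nodes$node_type == "drug"]
      d@nodes$role[d@nodes$symbol == "ABCB1"] <- "transporter"; d
    }),
    transportation_edge_invalid = list(
      code = "transportation_edge_invalid", doc = {
        d <- pk
        i <- which(d@edges$interaction_type == "transportation")[1]
        d@edges$source[i] <- "gene:CYP2C19"; d
      }),
    principal_drug_count = list(code = "principal_drug_count", doc = {
      d <- pk
      extra <- drugNode("HMDB0000042", "second drug", "active_drug")
      d@nodes <- rbind(d@nodes, extra)
      d@layout <- rbind(d@layout,
                        data.frame(id = extra$id, x = 1, y = 1)); d
    }),
    missing_route = list(code = "missing_route", doc = {
      d <- pk; d@administrationRoute <- NA_character_; d
    }),
    missing_description = list(code = "missing_description", doc = {
      d <- pd; d@description <- NA_character_; d
    }),
    layout_missing = list(code = "layout_missing", doc = {
      d <- pk; d@layout <- d@layout[-1, ]; d
    })
  )
}
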