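#' Drug-gene interaction records
#'
#' The ingestion boundary of the package: one row per drug-gene interaction
#' with the drug identifier and name, HGNC gene symbol, the gene's role in
#' the reaction (\code{interaction_type}: metabolism, transportation,
#' binding, excretion, or \code{"target"} marking PD target rows), how the
#' drug and protein act on each other (\code{action_type}), and whether the
#' gene is a major enzyme for the drug's metabolism.
#'
#' @param drug_id,drug_name drug identifier (HMDB-style) and display name.
#' @param gene_symbol HGNC symbol.
#' @param role gene role, one of \code{geneRoles()}.
#' @param interaction_type one of \code{interactionTypes()} or \code{NA}.
#' @param action_type an action type or \code{NA}.
#' @param major logical major-enzyme flag.
#' @return a one-row data.frame in the record schema.
#' @seealso \code{\link{readDrugGeneRecords}}
#' @export
drugGeneRecord <- function(drug_id, drug_name, gene_symbol,
                           role = c("enzyme", "transporter", "carrier",
                                    "target"),
                           interaction_type = NA_character_,
                           action_type = NA_character_, major = FALSE) {
  role <- match.arg(role)
  rec <- data.frame(drug_id = drug_id, drug_name = drug_name,
                    gene_symbol = gene_symbol, role = role,
                    interaction_type = interaction_type,
                    action_type = action_type, major = major,
                    stringsAsFactors = FALSE)
  .checkRecords(rec)
  rec
}

.RECORD_COLUMNS <- c("drug_id", "drug_name", "gene_symbol", "role",
                     "interaction_type", "action_type", "major")

.checkRecords <- function(records) {
  if (!is.data.frame(records) || !all(.RECORD_COLUMNS %in% names(records)))
    .pgError("pgpath_format_error",
             paste("records must contain columns:",
                   paste(.RECORD_COLUMNS, collapse = ", ")))
  if (any(!records$role %in% .GENE_ROLES))
    .pgError("pgpath_format_error", "invalid gene role in records")
  bad_int <- !is.na(records$interaction_type) &
    !records$interaction_type %in% .INTERACTION_TYPES
  if (any(bad_int))
    .pgError("pgpath_format_error", "invalid interaction_type in records")
  bad_act <- !is.na(records$action_type) &
    !records$action_type %in% .PD_ACTION_TYPES
  if (any(bad_act))
    .pgError("pgpath_format_error", "invalid action_type in records")
  if (any(is.na(records$gene_symbol) | !nzchar(records$gene_symbol)))
    .pgError("pgpath_format_error", "gene_symbol must be non-empty")
  if (!is.logical(records$major))
    .pgError("pgpath_format_error", "major must be logical")
  invisible(records)
}

#' Read and write drug-gene interaction tables
#'
#' Tab-separated with a header (columns \code{drug_id}, \code{drug_name},
#' \code{gene_symbol}, \code{role}, \code{interaction_type},
#' \code{action_type}, \code{major}), or an equivalent JSON array of
#' objects; the format is chosen by file extension.
#'
#' @param path file to read or write.
#' @param records a record data.frame (see \code{\link{drugGeneRecord}}).
#' @return \code{readDrugGeneRecords}: a validated record data.frame.
#' @export
readDrugGeneRecords <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    records <- jsonlite::fromJSON(path)
  } else {
    records <- read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  }
  if (is.null(records$role)) {
    ## legacy 6-column tables: derive the protein role from the interaction
    ## type; PD-vocabulary actions without an interaction type mark targets
    map <- c(metabolism = "enzyme", transportation = "transporter",
             binding = "carrier", excretion = "transporter")
    records$role <- unname(map[records$interaction_type])
    records$role[is.na(records$role)] <- "target"
  }
  if (is.character(records$major))
    records$major <- tolower(records$major) %in% c("true", "t", "1", "yes")
  records$major <- as.logical(records$major)
  .checkRecords(records)
  records[, .RECORD_COLUMNS]
}

#' @rdname readDrugGeneRecords
#' @export
writeDrugGeneRecords <- function(records, path) {
  .checkRecords(records)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(records, path, dataframe = "rows", na = "null",
                         pretty = TRUE)
  } else {
    out <- records[, .RECORD_COLUMNS]
    out$major <- ifelse(out$major, "true", "false")
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
  }
  invisible(path)
}
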