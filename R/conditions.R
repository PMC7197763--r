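## Classed conditions so callers can test for specific failure modes.

.pgError <- function(class, message, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "pgpath_error"),
                      call = call))
}

.pgWarning <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "pgpath_warning")))
}

## error classes used across the package:
##   pgpath_mixed_drug_error     records name more than one drug
##   pgpath_empty_input_error    degenerate empty input
##   pgpath_unplaced_gene_error  placement map does not cover all genes
##   pgpath_no_target_error      PD build without target records
##   pgpath_validation_error     operation requires a valid document
##   pgpath_parse_error          unparseable GPML/VCF/TSV
##   pgpath_format_error         structurally invalid input file
##   pgpath_missing_source_error configured SIFT source absent from header
##   pgpath_score_range_error    SIFT/GVB value outside its domain
##   pgpath_image_decode_error   PNG bytes do not decode
##   pgpath_type_mismatch_error  node kind unsupported by the operation
##   pgpath_kind_error           PK-only operation given a PD document (or v.v.)
##   pgpath_same_drug_error      DDI scan given two pathways of one drug
##   pgpath_spec_error           invalid synthetic-data specification
## warning classes:
##   pgpath_unknown_arrowhead_warning  unmapped arrowhead on GPML read
##   pgpath_vocabulary_warning         compartment outside the closed vocabulary
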