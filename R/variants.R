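## VCF parsing: SIFT-annotated coding variants in, one row per
## (record, alt allele, gene) triple out. Built on VariantAnnotation;
## multi-allelic records are decomposed with expand().

.CODING_CONSEQUENCES <- c(
  "missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
  "start_lost", "start_gained", "coding_sequence_variant",
  "frameshift_variant", "inframe_insertion", "inframe_deletion",
  "protein_altering_variant", "missense", "nonsense", "coding")

#' SIFT source configurations for \code{parseVariants}
#'
#' Three ways of locating SIFT scores: \code{siftInfoSource} reads a plain
#' numeric INFO key (per alternate allele) plus a gene-symbol key and an
#' optional consequence key; \code{siftCsqSource} reads a VEP-style
#' pipe-delimited INFO field with named subfields; \code{siftSidecarSource}
#' joins a tab-separated lookup (columns \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{gene}, \code{sift}, optional
#' \code{consequence}) onto the VCF records.
#'
#' @param key the INFO key holding the score (or the annotation blob).
#' @param geneKey INFO key holding the gene symbol.
#' @param consequenceKey optional INFO key holding the consequence term;
#'   when \code{NULL} every SIFT-scored variant is treated as coding.
#' @param siftField,geneField,alleleField,consequenceField subfield names
#'   inside the pipe-delimited annotation (as declared in its header
#'   \code{Format:} description).
#' @param path path of the sidecar TSV.
#' @return a configuration list for \code{\link{parseVariants}}.
#' @export
siftInfoSource <- function(key = "SIFT", geneKey = "GENE",
                           consequenceKey = NULL) {
  list(type = "info", key = key, gene_key = geneKey,
       consequence_key = consequenceKey)
}

#' @rdname siftInfoSource
#' @export
siftCsqSource <- function(key = "CSQ", siftField = "SIFT",
                          geneField = "SYMBOL", alleleField = "Allele",
                          consequenceField = "Consequence") {
  list(type = "csq", key = key, sift_field = siftField,
       gene_field = geneField, allele_field = alleleField,
       consequence_field = consequenceField)
}

#' @rdname siftInfoSource
#' @export
siftSidecarSource <- function(path) list(type = "sidecar", path = path)

.genotypeClass <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  alleles <- alleles[alleles != "."]
  if (length(alleles) == 0L || all(alleles == "0")) return(NA_character_)
  if (length(unique(alleles)) == 1L) "hom_alt" else "het"
}

.isCoding <- function(conseq) {
  if (is.na(conseq)) return(FALSE)
  any(vapply(.CODING_CONSEQUENCES, grepl, logical(1), x = conseq,
             fixed = TRUE))
}

.siftNumber <- function(x) {
  ## accepts "0.05" as well as VEP's "deleterious(0.05)"
  if (is.na(x)) return(NA_real_)
  m <- regmatches(x, regexpr("[0-9]*\\.?[0-9]+", x))
  if (length(m)) as.numeric(m) else NA_real_
}

#' Parse SIFT-annotated coding variants from a VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped), decomposes multi-allelic
#' records, and returns one variant row per (record, alternate allele, gene)
#' triple that has a SIFT score and a coding consequence. Records without a
#' SIFT score or with a non-coding consequence are dropped and counted in
#' the parse report, as are records whose genotype carries no alternate
#' allele (when the file has a sample column).
#'
#' @param vcf path of the VCF file.
#' @param siftSource a configuration from \code{\link{siftInfoSource}},
#'   \code{\link{siftCsqSource}} or \code{\link{siftSidecarSource}}.
#' @return a list with elements \code{variants} (data.frame with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene_symbol},
#'   \code{sift}, \code{coding}, \code{genotype}, \code{variant_id}) and
#'   \code{report} (drop counts).
#' @export
parseVariants <- function(vcf, siftSource = siftInfoSource()) {
  v <- tryCatch(suppressWarnings(VariantAnnotation::readVcf(vcf)),
                error = function(e)
                  .pgError("pgpath_format_error",
                           paste("unparseable VCF:", conditionMessage(e))))
  hdr <- VariantAnnotation::header(v)
  info_keys <- rownames(VariantAnnotation::info(hdr))
  if (siftSource$type %in% c("info", "csq") &&
      !siftSource$key %in% info_keys)
    .pgError("pgpath_missing_source_error",
             sprintf("INFO key '%s' is not declared in the VCF header",
                     siftSource$key))
  if (identical(siftSource$type, "info") &&
      !siftSource$gene_key %in% info_keys)
    .pgError("pgpath_missing_source_error",
             sprintf("INFO key '%s' is not declared in the VCF header",
                     siftSource$gene_key))

  e <- VariantAnnotation::expand(v)
  n <- length(e)
  chrom <- as.character(GenomeInfoDb::seqnames(e))
  pos <- BiocGenerics::start(e)
  ref <- as.character(VariantAnnotation::ref(e))
  alt <- as.character(VariantAnnotation::alt(e))
  gt <- if (ncol(VariantAnnotation::geno(e)$GT %||% matrix(nrow = 0,
                                                           ncol = 0)) >= 1L)
    VariantAnnotation::geno(e)$GT[, 1L] else rep(NA_character_, n)
  genotype <- vapply(gt, .genotypeClass, character(1), USE.NAMES = FALSE)
  carried <- if (all(is.na(gt))) rep(TRUE, n) else !is.na(genotype)
  genotype[is.na(genotype)] <- "het"

  .asChr1 <- function(x) {
    if (is.null(x)) return(rep(NA_character_, n))
    if (is.list(x) || inherits(x, "List"))
      return(vapply(as.list(x), function(el)
        if (length(el)) paste(as.character(el), collapse = ",")
        else NA_character_, character(1)))
    as.character(x)
  }

  rows <- list()
  report <- list(n_records = length(v), n_expanded = n,
                 dropped_no_sift = 0L, dropped_noncoding = 0L,
                 dropped_not_carried = 0L)
  addRow <- function(i, gene, sift, conseq) {
    coding <- if (is.null(conseq)) TRUE else .isCoding(conseq)
    if (is.na(gene)) {
      report$dropped_no_sift <<- report$dropped_no_sift + 1L
    } else if (is.na(sift)) {
      report$dropped_no_sift <<- report$dropped_no_sift + 1L
    } else if (!coding) {
      report$dropped_noncoding <<- report$dropped_noncoding + 1L
    } else if (!carried[i]) {
      report$dropped_not_carried <<- report$dropped_not_carried + 1L
    } else {
      for (g in strsplit(gene, ",")[[1]]) {
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
          gene_symbol = g, sift = sift, coding = TRUE,
          genotype = genotype[i],
          variant_id = sprintf("%s:%d:%s>%s", chrom[i], pos[i], ref[i],
                               alt[i]),
          stringsAsFactors = FALSE)
      }
    }
  }

  if (siftSource$type == "info") {
    sift <- suppressWarnings(as.numeric(
      .asChr1(VariantAnnotation::info(e)[[siftSource$key]])))
    gene <- .asChr1(VariantAnnotation::info(e)[[siftSource$gene_key]])
    conseq <- if (!is.null(siftSource$consequence_key))
      .asChr1(VariantAnnotation::info(e)[[siftSource$consequence_key]]) else
      NULL
    for (i in seq_len(n)) {
      if (is.na(gene[i])) {
        report$dropped_no_sift <- report$dropped_no_sift + 1L
        next
      }
      addRow(i, gene[i], sift[i], if (is.null(conseq)) NULL else conseq[i])
    }
  } else if (siftSource$type == "csq") {
    fmt <- VariantAnnotation::info(hdr)[siftSource$key, "Description"]
    fmt <- sub(".*Format: *", "", fmt)
    fields <- strsplit(gsub("[\"']", "", fmt), "|", fixed = TRUE)[[1]]
    need <- c(siftSource$allele_field, siftSource$gene_field,
              siftSource$sift_field, siftSource$consequence_field)
    if (!all(need %in% fields))
      .pgError("pgpath_missing_source_error",
               sprintf("annotation format lacks subfield(s): %s",
                       paste(setdiff(need, fields), collapse = ", ")))
    csq <- VariantAnnotation::info(e)[[siftSource$key]]
    for (i in seq_len(n)) {
      entries <- as.character(csq[[i]])
      matched <- FALSE
      for (entry in entries) {
        parts <- strsplit(entry, "|", fixed = TRUE)[[1]]
        length(parts) <- length(fields)
        val <- setNames(as.list(parts), fields)
        if (!identical(val[[siftSource$allele_field]], alt[i])) next
        matched <- TRUE
        addRow(i, val[[siftSource$gene_field]] %||NA2% NA_character_,
               .siftNumber(val[[siftSource$sift_field]] %||NA2%
                             NA_character_),
               val[[siftSource$consequence_field]] %||NA2% NA_character_)
      }
      if (!matched) report$dropped_no_sift <- report$dropped_no_sift + 1L
    }
  } else if (siftSource$type == "sidecar") {
    side <- read.delim(siftSource$path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "gene", "sift")
    if (!all(need %in% names(side)))
      .pgError("pgpath_missing_source_error",
               paste("sidecar TSV requires columns:",
                     paste(need, collapse = ", ")))
    key <- sprintf("%s:%d:%s>%s", side$chrom, side$pos, side$ref, side$alt)
    for (i in seq_len(n)) {
      k <- sprintf("%s:%d:%s>%s", chrom[i], pos[i], ref[i], alt[i])
      hit <- which(key == k)
      if (!length(hit)) {
        report$dropped_no_sift <- report$dropped_no_sift + 1L
        next
      }
      for (j in hit)
        addRow(i, side$gene[j], side$sift[j],
               if ("consequence" %in% names(side)) side$consequence[j] else
                 NULL)
    }
  } else {
    .pgError("pgpath_format_error", "unknown siftSource type")
  }

  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene_symbol = character(),
               sift = numeric(), coding = logical(), genotype = character(),
               variant_id = character(), stringsAsFactors = FALSE)
  bad <- !is.na(variants$sift) & (variants$sift < 0 | variants$sift > 1)
  if (any(bad))
    .pgError("pgpath_score_range_error",
             "SIFT scores in the VCF must lie in [0, 1]")
  list(variants = variants, report = report)
}

`%||NA2%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
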