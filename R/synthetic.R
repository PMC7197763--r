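## Synthetic inputs: SIFT-annotated VCFs with an independently computed
## truth table, random valid pathways for property testing, and the
## clopidogrel worked example. All generators are pure functions of their
## specification and seed.

#' Specification for a synthetic SIFT-annotated VCF
#'
#' @param genes character vector of gene symbols to simulate variants in.
#' @param variantsPerGene a single count, or a length-2 range sampled
#'   uniformly per gene.
#' @param siftDistribution a list: \code{list(kind = "uniform", lo, hi)},
#'   \code{list(kind = "point_mass", value)}, or \code{list(kind =
#'   "mixture", components = list(...), weights)} over those two.
#' @param fractionNoncoding fraction of records annotated with a non-coding
#'   consequence (excluded from the truth table).
#' @param fractionMissingSift fraction of records written without a SIFT
#'   key (excluded from the truth table).
#' @param seed mandatory integer seed; generation is fully reproducible.
#' @param floor zero-SIFT floor used by the truth-table oracle.
#' @return a validated specification list for \code{\link{makeSyntheticVCF}}.
#' @export
synthSpec <- function(genes, variantsPerGene = 3L,
                      siftDistribution = list(kind = "uniform", lo = 0.01,
                                              hi = 1),
                      fractionNoncoding = 0, fractionMissingSift = 0,
                      seed, floor = 1e-3) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    .pgError("pgpath_spec_error", "a scalar seed is mandatory")
  if (length(genes) == 0L)
    .pgError("pgpath_spec_error", "at least one gene is required")
  if (!length(variantsPerGene) %in% 1:2 || any(variantsPerGene < 0))
    .pgError("pgpath_spec_error",
             "variantsPerGene must be a count or a range")
  for (f in c(fractionNoncoding, fractionMissingSift))
    if (is.na(f) || f < 0 || f > 1)
      .pgError("pgpath_spec_error", "fractions must lie in [0, 1]")
  kinds <- c("uniform", "point_mass", "mixture")
  if (!is.list(siftDistribution) || !siftDistribution$kind %in% kinds)
    .pgError("pgpath_spec_error",
             "siftDistribution kind must be uniform, point_mass or mixture")
  list(genes = as.character(genes),
       variants_per_gene = as.integer(variantsPerGene),
       sift_distribution = siftDistribution,
       fraction_noncoding = fractionNoncoding,
       fraction_missing_sift = fractionMissingSift,
       seed = as.integer(seed), floor = floor)
}

.drawSift <- function(dist, n) {
  switch(dist$kind,
    uniform = runif(n, dist$lo, dist$hi),
    point_mass = rep(dist$value, n),
    mixture = {
      w <- dist$weights / sum(dist$weights)
      comp <- sample.int(length(dist$components), n, replace = TRUE,
                         prob = w)
      vapply(comp, function(k) .drawSift(dist$components[[k]], 1L),
             numeric(1))
    })
}

#' Generate a synthetic SIFT-annotated VCF with a truth table
#'
#' Writes a well-formed VCF 4.2 (GRCh38-style contig names; positions are
#' arbitrary) with INFO keys \code{GENE}, \code{SIFT} (per alternate
#' allele) and \code{CONSEQ}, plus one sample with genotypes. The returned
#' truth table holds each gene's expected GVB computed by an independent
#' plain product-and-root oracle over exactly the coding, SIFT-bearing
#' records as written (scores rounded to the 6 decimals serialized), so it
#' can stand as a test oracle for the scoring path.
#'
#' @param spec a specification from \code{\link{synthSpec}}.
#' @param path optional file to write the VCF to.
#' @return a list: \code{vcf} (the VCF text), \code{truth} (data.frame
#'   gene, gvb, n_variants), \code{path} (when written).
#' @export
makeSyntheticVCF <- function(spec, path = NULL) {
  if (is.null(spec$seed))
    .pgError("pgpath_spec_error", "spec must come from synthSpec()")
  withr::with_seed(spec$seed, {
    genes <- spec$genes
    recs <- list()
    bases <- c("A", "C", "G", "T")
    for (gi in seq_along(genes)) {
      n <- if (length(spec$variants_per_gene) == 2L)
        sample(spec$variants_per_gene[1]:spec$variants_per_gene[2], 1L)
      else spec$variants_per_gene
      if (n == 0L) next
      sift <- round(.drawSift(spec$sift_distribution, n), 6)
      pos <- sort(sample.int(1e6, n)) + 1e4
      for (k in seq_len(n)) {
        ref <- sample(bases, 1L)
        alt <- sample(setdiff(bases, ref), 1L)
        noncoding <- runif(1) < spec$fraction_noncoding
        missing_sift <- runif(1) < spec$fraction_missing_sift
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = sprintf("chr%d", ((gi - 1L) %% 22L) + 1L),
          pos = pos[k], ref = ref, alt = alt, gene = genes[gi],
          sift = if (missing_sift) NA_real_ else sift[k],
          conseq = if (noncoding) "intron_variant" else "missense_variant",
          gt = sample(c("0/1", "1/1"), 1L, prob = c(0.7, 0.3)),
          stringsAsFactors = FALSE)
      }
    }
    df <- if (length(recs)) do.call(rbind, recs) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), gene = character(), sift = numeric(),
                 conseq = character(), gt = character(),
                 stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]

    ## truth table: independent oracle - plain product then n-th root over
    ## the coding, SIFT-bearing records as serialized
    truth <- data.frame(gene = genes, gvb = 1, n_variants = 0L,
                        stringsAsFactors = FALSE)
    for (gi in seq_along(genes)) {
      s <- df$sift[df$gene == genes[gi] & !is.na(df$sift) &
                     df$conseq != "intron_variant"]
      if (length(s)) {
        s <- pmax(s, spec$floor)
        truth$gvb[gi] <- prod(s)^(1 / length(s))
        truth$n_variants[gi] <- length(s)
      }
    }

    header <- c(
      "##fileformat=VCFv4.2",
      "##source=pgpath-synthetic",
      sprintf("##contig=<ID=%s>", unique(df$chrom)),
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=SIFT,Number=A,Type=Float,Description=\"SIFT deleteriousness score\">",
      "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Variant consequence\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSYNTH")
    info <- ifelse(is.na(df$sift),
                   sprintf("GENE=%s;CONSEQ=%s", df$gene, df$conseq),
                   sprintf("GENE=%s;SIFT=%.6f;CONSEQ=%s", df$gene, df$sift,
                           df$conseq))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                    df$chrom, df$pos, df$ref, df$alt, info, df$gt)
    vcf <- paste(c(header, body), collapse = "\n")
    if (!is.null(path)) writeLines(vcf, path)
    list(vcf = vcf, truth = truth, path = path)
  })
}

#' Generate a random valid pathway document
#'
#' Samples roles, actions and major flags from the standardized
#' vocabularies and builds the document with the regular builders, so the
#' result is valid by construction. Deterministic per seed.
#'
#' @param nGenes number of gene records (>= 1).
#' @param kind \code{"PK"} or \code{"PD"}.
#' @param seed integer seed.
#' @return a valid \linkS4class{PathwayDocument}.
#' @export
makeRandomPathway <- function(nGenes, kind = c("PK", "PD"), seed) {
  kind <- match.arg(kind)
  stopifnot(nGenes >= 1L)
  withr::with_seed(seed, {
    drug_id <- sprintf("HMDB%07d", sample.int(9999999L, 1L))
    drug_name <- sprintf("drug%d", sample.int(999L, 1L))
    drug_kind <- sample(c("active_drug", "prodrug"), 1L)
    syms <- sprintf("G%dX%d", seq_len(nGenes), sample.int(99L, nGenes,
                                                          replace = TRUE))
    if (kind == "PK") {
      roles <- sample(c("enzyme", "transporter", "carrier"), nGenes,
                      replace = TRUE, prob = c(0.6, 0.25, 0.15))
      recs <- do.call(rbind, lapply(seq_len(nGenes), function(i) {
        drugGeneRecord(drug_id, drug_name, syms[i], role = roles[i],
                       interaction_type = switch(roles[i],
                         enzyme = "metabolism",
                         transporter = "transportation",
                         carrier = "binding"),
                       action_type = if (roles[i] == "enzyme")
                         sample(.PK_ACTION_TYPES, 1L) else "substrate",
                       major = roles[i] == "enzyme" && runif(1) < 0.4)
      }))
      route <- sample(.COMPARTMENT_VOCAB$id[
        .COMPARTMENT_VOCAB$level == "administration"], 1L)
      buildPKPathway(recs, drugKind = drug_kind, route = route)
    } else {
      recs <- do.call(rbind, lapply(seq_len(nGenes), function(i) {
        drugGeneRecord(drug_id, drug_name, syms[i], role = "target",
                       action_type = sample(.PD_ACTION_TYPES, 1L))
      }))
      placement <- setNames(sample(.COMPARTMENT_VOCAB$id[
        .COMPARTMENT_VOCAB$level == "cellular"], nGenes, replace = TRUE),
        syms)
      buildPDPathway(recs, description = sprintf(
        "Synthetic mechanism description for %s.", drug_name),
        drugKind = drug_kind, placement = placement)
    }
  })
}

#' The clopidogrel worked example
#'
#' A curated, versioned fixture mirroring the canonical prodrug case:
#' clopidogrel requires hepatic CYP-mediated bioactivation (CYP2C19 as the
#' major activating enzyme, CYP2C9 as a non-major enzyme), is effluxed by
#' the intestinal transporter ABCB1, and its active metabolite irreversibly
#' antagonizes the platelet ADP receptor P2RY12. Identifiers and clinical
#' text are illustrative placeholders, not database extracts; the manifest
#' records exact node/edge counts for assertions and is marked accordingly.
#'
#' @return a list: \code{records} (drug-gene record data.frame),
#'   \code{pk_doc} and \code{pd_doc} (valid
#'   \linkS4class{PathwayDocument}s), \code{manifest} (expected counts and
#'   provenance flags).
#' @export
#' @examples
#' fx <- clopidogrelFixture()
#' fx$pk_doc
clopidogrelFixture <- function() {
  drug_id <- "HMDB0014457"  # illustrative HMDB-style id
  records <- rbind(
    drugGeneRecord(drug_id, "clopidogrel", "CYP2C19", role = "enzyme",
                   interaction_type = "metabolism",
                   action_type = "substrate", major = TRUE),
    drugGeneRecord(drug_id, "clopidogrel", "CYP2C9", role = "enzyme",
                   interaction_type = "metabolism",
                   action_type = "substrate", major = FALSE),
    drugGeneRecord(drug_id, "clopidogrel", "ABCB1", role = "transporter",
                   interaction_type = "transportation",
                   action_type = "substrate", major = FALSE),
    drugGeneRecord(drug_id, "clopidogrel", "P2RY12", role = "target",
                   action_type = "antagonist", major = FALSE))
  drug_info <- list(
    atc_class = "B01AC04",
    indications = "Prevention of atherothrombotic events (illustrative summary).",
    adverse_effects = "Bleeding, dyspepsia (illustrative summary).",
    interactions = "Reduced activation with strong CYP2C19 inhibitors (illustrative summary).",
    pk_notes = "Oral prodrug; hepatic CYP-mediated bioactivation; biliary excretion of metabolites (illustrative summary).")
  gene_meta <- list(
    CYP2C19 = c("cytochrome P450 family 2 subfamily C member 19",
                "10q23.33", "liver"),
    CYP2C9 = c("cytochrome P450 family 2 subfamily C member 9",
               "10q23.33", "liver"),
    ABCB1 = c("ATP binding cassette subfamily B member 1", "7q21.12",
              "intestines"),
    P2RY12 = c("purinergic receptor P2Y12", "3q25.1", "platelet"))
  decorate <- function(doc) {
    for (sym in names(gene_meta)) {
      i <- which(doc@nodes$symbol == sym)
      if (length(i)) {
        doc@nodes$gene_name[i] <- gene_meta[[sym]][1]
        doc@nodes$location[i] <- gene_meta[[sym]][2]
        doc@nodes$tissue[i] <- gene_meta[[sym]][3]
      }
    }
    doc
  }
  pk_doc <- decorate(buildPKPathway(records, drugKind = "prodrug",
                                    route = "oral", drugInfo = drug_info))
  pd_doc <- decorate(buildPDPathway(
    records, drugKind = "prodrug", drugInfo = drug_info,
    description = paste(
      "The active thiol metabolite of clopidogrel binds irreversibly to",
      "the platelet ADP receptor P2RY12, blocking ADP-mediated platelet",
      "activation and aggregation (illustrative description).")))
  manifest <- list(
    drug = "clopidogrel", drug_id = drug_id, illustrative = TRUE,
    n_records = nrow(records),
    pk = list(n_nodes = 6L, n_edges = 7L, n_compartments = 4L,
              n_active_metabolites = 1L, major_enzymes = "CYP2C19"),
    pd = list(n_nodes = 3L, n_edges = 1L, n_compartments = 1L,
              targets = "P2RY12"))
  list(records = records, pk_doc = pk_doc, pd_doc = pd_doc,
       manifest = manifest)
}
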