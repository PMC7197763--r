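#' Gene-wise variant burden: geometric mean of SIFT scores
#'
#' The GVB score of a gene is the geometric mean of the SIFT deleteriousness
#' scores of its qualifying coding variants, computed in log space:
#' \code{exp(mean(log(pmax(s, floor))))}. SIFT scores of exactly zero are
#' floored at \code{floor} before the log, otherwise a single fully
#' deleterious variant would annihilate the mean to 0 and leave the (0, 1]
#' range. A gene with no qualifying variants scores exactly 1; lower scores
#' indicate greater predicted functional burden.
#'
#' @param sift numeric vector of SIFT scores in [0, 1] (may be empty).
#' @param floor the zero-score floor (default 1e-3).
#' @return a single score in (0, 1].
#' @export
#' @examples
#' computeGVB(c(0.2, 0.8))  # 0.4
#' computeGVB(numeric(0))   # 1
computeGVB <- function(sift, floor = 1e-3) {
  if (length(sift) == 0L) return(1)
  if (anyNA(sift) || any(sift < 0 | sift > 1))
    .pgError("pgpath_score_range_error", "SIFT scores must lie in [0, 1]")
  exp(mean(log(pmax(sift, floor))))
}

#' GvbTable constructor
#'
#' @param gene character vector of gene symbols.
#' @param score numeric GVB scores in (0, 1].
#' @param nVariants integer counts of contributing variants.
#' @param variantIds list of contributing variant identifiers (optional).
#' @param floor the zero-SIFT floor the scores were computed with.
#' @return a \linkS4class{GvbTable}.
#' @export
gvbTable <- function(gene, score, nVariants = rep(0L, length(gene)),
                     variantIds = rep(list(character()), length(gene)),
                     floor = 1e-3) {
  new("GvbTable", gene = as.character(gene), score = as.numeric(score),
      nVariants = as.integer(nVariants), variantIds = variantIds,
      floor = floor)
}

#' Score the genes of a pathway from parsed variants
#'
#' Computes one GVB score per gene of a scoring universe (typically the
#' gene nodes of a pathway document). Genes with no qualifying variant score
#' exactly 1. Each qualifying variant contributes once regardless of
#' zygosity unless \code{homCountsTwice}; variants annotated to several
#' genes contribute to each independently (they arrive as separate rows from
#' \code{\link{parseVariants}}).
#'
#' @param variants a variant data.frame from \code{\link{parseVariants}}
#'   (columns \code{gene_symbol}, \code{sift}, \code{variant_id},
#'   \code{genotype}).
#' @param geneUniverse character vector of gene symbols to score (required,
#'   non-empty).
#' @param floor zero-SIFT floor passed to \code{\link{computeGVB}}.
#' @param siftThreshold optional cutoff: when given, only variants with
#'   \code{sift < siftThreshold} contribute. The default (\code{NULL}) lets
#'   every coding SIFT-scored variant contribute.
#' @param homCountsTwice when \code{TRUE}, homozygous-alternate variants
#'   contribute their score twice. Off by default: the burden definition
#'   aggregates the \emph{set} of coding variants.
#' @return a \linkS4class{GvbTable} with one entry per universe gene.
#' @export
scoreGenes <- function(variants, geneUniverse, floor = 1e-3,
                       siftThreshold = NULL, homCountsTwice = FALSE) {
  if (length(geneUniverse) == 0L)
    .pgError("pgpath_empty_input_error", "geneUniverse must be non-empty")
  geneUniverse <- unique(as.character(geneUniverse))
  if (is.null(variants) || nrow(variants) == 0L)
    return(gvbTable(geneUniverse, rep(1, length(geneUniverse)),
                    floor = floor))
  if (!all(c("gene_symbol", "sift") %in% names(variants)))
    .pgError("pgpath_format_error",
             "variants must have gene_symbol and sift columns")
  if (!is.null(siftThreshold))
    variants <- variants[variants$sift < siftThreshold, , drop = FALSE]
  score <- numeric(length(geneUniverse))
  nvar <- integer(length(geneUniverse))
  vids <- vector("list", length(geneUniverse))
  for (i in seq_along(geneUniverse)) {
    hits <- variants[variants$gene_symbol == geneUniverse[i], ,
                     drop = FALSE]
    s <- hits$sift
    if (homCountsTwice && nrow(hits) && "genotype" %in% names(hits))
      s <- c(s, hits$sift[hits$genotype == "hom_alt"])
    score[i] <- computeGVB(s, floor = floor)
    nvar[i] <- nrow(hits)
    vids[[i]] <- if ("variant_id" %in% names(hits))
      hits$variant_id else character()
  }
  gvbTable(geneUniverse, score, nvar, vids, floor = floor)
}

#' Read and write GVB tables as TSV
#'
#' Tab-separated with a header and columns \code{gene}, \code{gvb} (6
#' decimals) and \code{n_variants}.
#'
#' @param gvb a \linkS4class{GvbTable}.
#' @param path file to read or write.
#' @return \code{readGvbTable}: a \linkS4class{GvbTable};
#'   \code{writeGvbTable}: the path, invisibly.
#' @export
writeGvbTable <- function(gvb, path) {
  stopifnot(is(gvb, "GvbTable"))
  df <- data.frame(gene = gvb@gene, gvb = sprintf("%.6f", gvb@score),
                   n_variants = gvb@nVariants, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGvbTable
#' @export
readGvbTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("gene", "gvb") %in% names(df)))
    .pgError("pgpath_format_error", "GVB TSV requires gene and gvb columns")
  n <- if ("n_variants" %in% names(df)) df$n_variants else
    rep(0L, nrow(df))
  ## a 6-decimal serialization may round a no-variant score away from 1
  score <- as.numeric(df$gvb)
  score[n == 0L] <- 1
  gvbTable(df$gene, score, n)
}
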