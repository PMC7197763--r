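vcf_header <- function(extra = character()) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr10>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=SIFT,Number=A,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Consequence\">",
    extra,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
}

test_that("coding SIFT-annotated SNVs parse one variant per record with an empty drop report", {
  path <- write_vcf(c(vcf_header(), sprintf(
    "chr10\t%d\t.\tA\tG\t.\tPASS\tGENE=CYP2C9;SIFT=0.%d;CONSEQ=missense_variant\tGT\t0/1",
    c(100L, 200L, 300L), c(1L, 2L, 3L))))
  res <- parseVariants(path, siftInfoSource(consequenceKey = "CONSEQ"))
  expect_identical(nrow(res$variants), 3L)
  expect_identical(res$report$dropped_no_sift, 0L)
  expect_identical(res$report$dropped_noncoding, 0L)
  expect_identical(res$variants$gene_symbol, rep("CYP2C9", 3))
  expect_equal(res$variants$sift, c(0.1, 0.2, 0.3))
  expect_identical(res$variants$genotype, rep("het", 3))
  expect_identical(res$variants$variant_id[1], "chr10:100:A>G")
})

test_that("records lacking SIFT, non-coding records and uncarried genotypes are dropped and counted", {
  path <- write_vcf(c(vcf_header(), c(
    "chr10\t100\t.\tA\tG\t.\tPASS\tGENE=CYP2C9;SIFT=0.2;CONSEQ=missense_variant\tGT\t0/1",
    "chr10\t200\t.\tC\tT\t.\tPASS\tGENE=CYP2C9;CONSEQ=missense_variant\tGT\t0/1",
    "chr10\t300\t.\tG\tA\t.\tPASS\tGENE=CYP2C9;SIFT=0.3;CONSEQ=intron_variant\tGT\t0/1",
    "chr10\t400\t.\tT\tC\t.\tPASS\tGENE=CYP2C9;SIFT=0.4;CONSEQ=missense_variant\tGT\t0/0")))
  res <- parseVariants(path, siftInfoSource(consequenceKey = "CONSEQ"))
  expect_identical(nrow(res$variants), 1L)
  expect_identical(res$report$dropped_no_sift, 1L)
  expect_identical(res$report$dropped_noncoding, 1L)
  expect_identical(res$report$dropped_not_carried, 1L)
})

test_that("multi-allelic records decompose into one variant per annotated alternate allele", {
  path <- write_vcf(c(vcf_header(),
    "chr10\t100\t.\tC\tT,G\t.\tPASS\tGENE=CYP2C9;SIFT=0.2,0.8;CONSEQ=missense_variant\tGT\t1/2"))
  res <- parseVariants(path, siftInfoSource(consequenceKey = "CONSEQ"))
  expect_identical(nrow(res$variants), 2L)
  expect_identical(res$variants$alt, c("T", "G"))
  expect_equal(res$variants$sift, c(0.2, 0.8))
  expect_identical(res$variants$genotype, c("het", "het"))
})

test_that("homozygous alternate genotypes classify as hom_alt and multi-gene annotations fan out", {
  hdr <- sub("GENE,Number=1", "GENE,Number=.", vcf_header(), fixed = TRUE)
  path <- write_vcf(c(hdr,
    "chr10\t100\t.\tA\tG\t.\tPASS\tGENE=CYP2C8,CYP2C9;SIFT=0.5;CONSEQ=missense_variant\tGT\t1/1"))
  res <- parseVariants(path, siftInfoSource(consequenceKey = "CONSEQ"))
  expect_identical(nrow(res$variants), 2L)
  expect_setequal(res$variants$gene_symbol, c("CYP2C8", "CYP2C9"))
  expect_identical(unique(res$variants$genotype), "hom_alt")
})

test_that("a missing configured INFO key raises MissingSourceError; junk raises FormatError", {
  path <- write_vcf(c(vcf_header(),
    "chr10\t100\t.\tA\tG\t.\tPASS\tGENE=CYP2C9;SIFT=0.2;CONSEQ=missense_variant\tGT\t0/1"))
  expect_error(parseVariants(path, siftInfoSource(key = "CADD")),
               class = "pgpath_missing_source_error")
  expect_error(parseVariants(path, siftInfoSource(geneKey = "SYMBOL")),
               class = "pgpath_missing_source_error")
  junk <- withr::local_tempfile(fileext = ".vcf")
  writeLines("this is not a vcf", junk)
  expect_error(parseVariants(junk, siftInfoSource()),
               class = "pgpath_format_error")
})

test_that("VEP-style pipe-delimited annotations parse via the declared Format fields", {
  csq_hdr <- "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations. Format: Allele|Consequence|SYMBOL|SIFT\">"
  path <- write_vcf(c(vcf_header(csq_hdr), c(
    "chr10\t100\t.\tA\tG\t.\tPASS\tCSQ=G|missense_variant|CYP2C9|deleterious(0.03)\tGT\t0/1",
    "chr10\t200\t.\tC\tT\t.\tPASS\tCSQ=T|intron_variant|CYP2C9|\tGT\t0/1")))
  res <- parseVariants(path, siftCsqSource())
  expect_identical(nrow(res$variants), 1L)
  expect_equal(res$variants$sift, 0.03)
  expect_identical(res$variants$gene_symbol, "CYP2C9")
  expect_identical(res$report$dropped_no_sift +
                     res$report$dropped_noncoding, 1L)
})

test_that("a sidecar TSV supplies scores joined on chrom/pos/ref/alt", {
  path <- write_vcf(c(vcf_header(), c(
    "chr10\t100\t.\tA\tG\t.\tPASS\tGENE=CYP2C9;CONSEQ=missense_variant\tGT\t0/1",
    "chr10\t200\t.\tC\tT\t.\tPASS\tGENE=CYP2C9;CONSEQ=missense_variant\tGT\t0/1")))
  side <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgene\tsift",
               "chr10\t100\tA\tG\tCYP2C9\t0.07"), side)
  res <- parseVariants(path, siftSidecarSource(side))
  expect_identical(nrow(res$variants), 1L)
  expect_equal(res$variants$sift, 0.07)
  expect_identical(res$report$dropped_no_sift, 1L)
})

test_that("out-of-range SIFT values in the VCF are rejected", {
  path <- write_vcf(c(vcf_header(),
    "chr10\t100\t.\tA\tG\t.\tPASS\tGENE=CYP2C9;SIFT=1.7;CONSEQ=missense_variant\tGT\t0/1"))
  expect_error(parseVariants(path, siftInfoSource(consequenceKey = "CONSEQ")),
               class = "pgpath_score_range_error")
})
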