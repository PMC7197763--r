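## Independent burden oracle: plain product then n-th root, sharing no code
## with computeGVB (which works in log space).
gvb_oracle <- function(s, floor = 1e-3) {
  if (length(s) == 0L) return(1)
  s <- pmax(s, floor)
  prod(s)^(1 / length(s))
}

## Slot-wise document comparison, tolerant of row names and of layout
## rounding introduced by serialization.
expect_doc_equal <- function(a, b, layout_tol = 1e-6) {
  for (sl in c("nodes", "edges", "compartments")) {
    x <- slot(a, sl); y <- slot(b, sl)
    rownames(x) <- rownames(y) <- NULL
    expect_equal(x, y, info = paste("slot", sl))
  }
  expect_identical(a@pathwayKind, b@pathwayKind)
  expect_identical(a@administrationRoute, b@administrationRoute)
  expect_identical(a@description, b@description)
  expect_equal(a@drugInfo, b@drugInfo)
  expect_identical(a@layout$id, b@layout$id)
  expect_lt(max(c(0, abs(a@layout$x - b@layout$x),
                  abs(a@layout$y - b@layout$y))), layout_tol * 1.0001)
}

## A tiny valid PNG (white 2x2) for background-merging tests.
tiny_png <- function() png::writePNG(array(1, dim = c(2, 2, 3)))

## Write VCF text to a temp file and return the path.
write_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
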