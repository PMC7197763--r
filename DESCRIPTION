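Package: pgpath
Title: Standardized Pharmacogenomic Pathway Modeling and Personalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds standardized single-drug pharmacokinetic (PK) and
    pharmacodynamic (PD) pathway documents from drug-gene interaction
    tables, writes and reads them as GPML, and renders them as SVG/HTML
    diagrams over an anatomical background frame. Personalizes pathways
    from an individual's SIFT-annotated variants (VCF) by computing
    gene-wise variant burden (GVB) scores - the geometric mean of SIFT
    deleteriousness scores over a gene's coding variants - colouring
    pathway genes on a gradient, and applying qualitative rules to
    predict the direction of plasma active-ingredient concentration
    change and drug-gene-drug interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    xml2,
    jsonlite,
    yaml,
    png,
    withr,
    VariantAnnotation,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Pharmacogenomics, Pathways, Visualization
RoxygenNote: 7.3.3
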