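# pgpath

Standardized pharmacogenomic pathway modeling and personalization in R.

## What problem this solves

How a drug moves through a body — absorption, distribution, metabolism,
excretion (ADME) — and what it does at its target depends on the gene
products it meets on the way: metabolizing enzymes, transporters, carriers
and receptors. Clinically relevant variation in those genes changes the
plasma concentration of the *active ingredient*, and with it efficacy and
toxicity. pgpath gives pharmacogenomics researchers and clinical
bioinformaticians a standardized, machine-readable representation of a
single drug's pharmacokinetic (PK) and pharmacodynamic (PD) pathway, plus a
personalization engine that overlays an individual's variant burden onto
the diagram and derives qualitative predictions.

The package covers four layers:

1. **Core model** — a one-drug-centered pathway schema: typed nodes
   (prodrug/active drug, active/inactive metabolites, genes in the roles
   enzyme/transporter/carrier/target), typed edges (metabolism,
   transportation, binding, excretion; drug actions such as inhibitor,
   inducer, substrate, agonist, antagonist, ...), and a closed compartment
   vocabulary (anatomical organs, transport structures, administration
   routes, cellular components). `buildPKPathway()` / `buildPDPathway()`
   construct validated documents from drug–gene interaction tables;
   `validatePathway()` enforces the taxonomy.
2. **IO and rendering** — lossless GPML (2013a dialect) serialization with
   MIM-style arrowheads and HGNC/HMDB cross-references (`writeGPML()`,
   `readGPML()`), deterministic SVG rendering with a built-in schematic
   body frame or an embedded PNG background (`renderSVG()`,
   `mergeWithBackground()`), and HTML pop-up info windows for drugs and
   genes (`makeInfoWindow()`).
3. **Variant burden scoring** — `parseVariants()` reads SIFT-annotated
   coding variants from a VCF (plain INFO keys, VEP-style pipe-delimited
   annotations, or a sidecar TSV) and `scoreGenes()` computes the per-gene
   **GVB (gene-wise variant burden)** score

   $$\mathrm{GVB}(g) \;=\; \Bigl(\prod_{i=1}^{n_g} \max(s_i, \epsilon)\Bigr)^{1/n_g}
     \;=\; \exp\!\Bigl(\tfrac{1}{n_g}\sum_{i=1}^{n_g}\log \max(s_i,\epsilon)\Bigr),$$

   the geometric mean of the SIFT scores $s_i \in [0,1]$ of the gene's
   coding variants (zero scores floored at $\epsilon = 10^{-3}$; genes
   with no qualifying variant score exactly 1). Lower GVB means greater
   predicted functional impairment.
4. **Personalization** — `personalizePathway()` colours each gene on a
   monotone white-to-red gradient of its GVB score;
   `predictConcentrationShift()` applies a qualitative rule engine (a
   prodrug with an impaired major activating enzyme yields
   *decreased* active ingredient; an active drug with an impaired major
   metabolizing enzyme yields *increased* active ingredient);
   `inferDDI()` scans two pathways for drug–gene–drug interactions
   (perpetrator inhibits/induces an enzyme whose substrate the victim is).

A synthetic-data layer (`makeSyntheticVCF()`, `makeRandomPathway()`,
`clopidogrelFixture()`) makes the whole package testable and demonstrable
without any external download.

## Worked example: clopidogrel

Clopidogrel is the canonical prodrug case: it is inactive as administered
and requires hepatic CYP-mediated bioactivation (CYP2C19 is the major
activating enzyme) before its active metabolite can antagonize the
platelet ADP receptor P2RY12. A genome with strongly deleterious CYP2C19
variants therefore activates less drug.

```r
library(pgpath)

fx <- clopidogrelFixture()
fx$pk_doc
#> PathwayDocument (PK) for clopidogrel
#>   nodes: 6 (1 drug, 2 metabolite, 3 gene)
#>   edges: 7 | compartments: 4
#>   administration route: oral

## a synthetic genome carrying three SIFT = 0.05 coding variants in CYP2C19
spec <- synthSpec("CYP2C19", variantsPerGene = 3L,
                  siftDistribution = list(kind = "point_mass", value = 0.05),
                  seed = 101L)
vcf <- tempfile(fileext = ".vcf")
makeSyntheticVCF(spec, path = vcf)

parsed <- parseVariants(vcf, siftInfoSource(consequenceKey = "CONSEQ"))
gvb <- scoreGenes(parsed$variants, geneSymbols(fx$pk_doc))
gvb
#> GvbTable: 3 genes (floor 0.001)
#>   CYP2C19: 0.050000 (3 variants)
#>   CYP2C9: 1.000000 (0 variants)
#>   ABCB1: 1.000000 (0 variants)

pred <- predictConcentrationShift(personalizePathway(fx$pk_doc, gvb))
pred[, c("direction", "mechanism")]
#>                     direction
#> 1 decreased_active_ingredient
#>                                                                                              mechanism
#> 1 reduced bioactivation: impaired major activating enzyme(s) CYP2C19 lower active-metabolite formation
pred$implicated[[1]]
#>      gene   role  gvb
#> 1 CYP2C19 enzyme 0.05
```

The GVB of 0.05 is the geometric mean of the three identical SIFT scores;
because it falls below the (deliberately arbitrary, overridable) impairment
threshold of 0.3 and CYP2C19 is the prodrug's major activating enzyme, the
engine predicts a decreased plasma concentration of active ingredient —
i.e. the drug may not reach its full therapeutic effect. With an
unimpaired table (all scores 1) the same call returns `unchanged`.
`renderSVG(fx$pk_doc, gvb = gvb)` draws the personalized diagram with
CYP2C19 shifted toward the alert colour.

A command-line front end wrapping these functions is installed at
`inst/scripts/pgpath.R` (subcommands `build`, `render`, `score`,
`personalize`, `ddi`, `synth`, `pipeline`).

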