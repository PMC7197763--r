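---
title: "Methods: standardized PK/PD pathway modeling and GVB-based personalization"
author: "pgpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized PK/PD pathway modeling and GVB-based personalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgpath)
```

# The pathway model

pgpath represents one drug at a time. A **PK document** describes ADME at
the systemic level: the administered drug (an *active drug* or a
*prodrug*), the gene products acting on it (enzymes, transporters,
carriers), the metabolites those enzymes produce, and the body
compartments everything sits in. A **PD document** describes the
mechanism of action at the cellular level: the active ingredient (the
drug itself, or the bioactivated metabolite of a prodrug) acting on
target gene products. This one-drug-centered scope is deliberate:
personalized prescribing reasons about an administered drug, not about a
whole metabolic network, and it is what makes the drug–gene–drug
interaction scan between two such documents well defined.

The schema is closed. Gene roles are `enzyme`, `transporter`, `carrier`,
`target`; interaction types are `metabolism`, `transportation`,
`binding`, `excretion`; PK documents restrict drug-action types to
`inhibitor`/`inducer`/`substrate` while PD documents admit the full
receptor-pharmacology vocabulary (agonist, antagonist, activator,
modulator, competitor, cofactor, ligand, stimulator, antibody, binder,
potentiator, neutralizer). Compartments come from fixed vocabularies per
level — anatomical organs, transport structures (vessels, bile duct,
urinary tract, gut lumen), administration routes, and cellular
components. The vocabulary is extensible through the builder `config`
argument, but every extension is surfaced as a warning and tracked, so
silent schema drift is impossible. `validatePathway()` checks every
invariant and *returns* an ordered violation table instead of raising,
so documents from external sources can be triaged.

Two markers carry the pharmacological semantics the prediction rules
need: `major` flags enzymes that dominate the drug's metabolism (legal
only on enzymes), and `active` flags metabolites that are themselves the
therapeutic agent.

## Construction rules

`buildPKPathway()` turns an interaction table into a document with a
fixed, documented topology:

* each enzyme record yields `drug → enzyme → metabolite` metabolism
  edges, with the record's action type (typically `substrate`) on the
  drug–enzyme edge;
* on a prodrug, **major enzymes emit active metabolites** and non-major
  enzymes inactive ones; on an active drug all metabolites are inactive.
  This is the minimal rule that reproduces the canonical prodrug picture
  (bioactivation by the major enzyme) while keeping the `major` and
  `active` markers independent inputs;
* transporters yield `transportation` edges and carriers `binding`
  edges, oriented gene → drug (the protein acts on the drug);
* every metabolite gains an excretion edge: to the **bile duct** when it
  is produced in the liver, to the **urinary tract** otherwise,
  overridable per gene. Excretion edges are the one place an edge may
  terminate at a compartment rather than a node — excretion is a flow
  out of the system, and inventing a pseudo-node for "bile" would
  pollute the node taxonomy. The validator special-cases exactly this:
  excretion targets may be transport-level compartments.

Default placement, used when no placement map is supplied, follows the
standard ADME narrative: enzymes in the liver (first-pass metabolism),
transporters in the intestines (absorption), carriers in the arterial
plasma, targets at the cell membrane. Real tissue expression varies, and
a supplied placement map always wins; the defaults exist so that a bare
interaction table yields a sensible diagram. When a placement map *is*
supplied it must cover every gene — partial maps raise rather than
silently mixing explicit and default placements.

Layout is deterministic: compartments tile a three-column grid of fixed
boxes and nodes fill slots inside their compartment box in document
order. Coordinates are abstract canvas units with the SVG convention
(origin top-left, y increasing downward), chosen once to remove any
coordinate-system ambiguity from the file formats.

# Serialization and rendering

Documents serialize to GPML (the 2013a dialect, which PathVisio 3.x
writes), so they open in standard pathway editors. GPML has no native
slots for the package's semantics (drug kind, roles, markers,
compartment levels, edge typing), so those travel as PathVisio *dynamic
properties* (`<Attribute Key="pgpath.*">`) on the corresponding
elements; a PathVisio user sees a normal pathway, and `readGPML()`
recovers the full document. Edge types map to MIM-style arrowheads
(metabolism `mim-conversion`, transportation `mim-translocation`,
binding `mim-binding`, excretion plain arrow, inhibitor
`mim-inhibition`, inducer `mim-stimulation`); on reading a foreign file
the map is inverted, and an unknown arrowhead degrades to a typeless
edge with a classed warning rather than an error. Serialization is
deterministic — stable element order, 6-decimal coordinates — so equal
documents produce byte-identical files, and write→read→write is a
fixed point. The round-trip tolerance for layout is 1e-6 canvas units,
the precision of the fixed-point float format.

`renderSVG()` follows a symbol standard in which *shape encodes role and
fill encodes state*: prodrug and active drug share the drug rectangle
with different fills, as do inactive and active metabolites; enzymes are
rounded rectangles, transporters and carriers ellipses, targets
rectangles, each with a role colour; `major`/`active` render as badge
glyphs next to the node. All colours live in a theme list and are
overridable. The background is either an embedded raster image or, by
default, a schematic vector frame drawn from the document's own
compartments, so a fully self-contained diagram needs no artwork.
`mergeWithBackground()` produces one self-contained HTML file (base64
PNG under the SVG, pop-up info windows for the drug and each gene wired
to node clicks, plus the PD description window). Gene info windows link
to HGNC symbol reports and drug windows to HMDB pages as static URL
templates — no live service is queried.

# GVB scoring

The gene-wise variant burden of gene $g$ with coding variant SIFT scores
$s_1,\dots,s_{n_g}$ is

$$\mathrm{GVB}(g) = \exp\Bigl(\frac{1}{n_g}\sum_i \log\max(s_i,\epsilon)\Bigr),$$

computed in log space for numerical stability. Choices worth making
explicit:

* **Zero floor** $\epsilon = 10^{-3}$ (configurable). SIFT emits exact
  zeros; without a floor a single zero annihilates the geometric mean
  and the score leaves its $(0,1]$ range. The floor also defines the
  alert endpoint of the colour gradient.
* **No-variant convention**: a gene with no qualifying variant scores
  exactly 1, which maps to the neutral colour and can never trigger a
  prediction.
* **Zygosity**: each qualifying variant contributes once regardless of
  het/hom genotype, because the definition aggregates the *set* of
  coding variants; `homCountsTwice = TRUE` double-counts homozygous
  alternates for users who prefer a dosage-weighted variant.
* **No deleteriousness cutoff by default**: all coding SIFT-scored
  variants contribute, which is the literal reading of the definition.
  Much of the burden-score literature restricts to predicted-damaging
  variants; `siftThreshold` (e.g. 0.7) provides that, and it is a
  documented opt-in rather than a silent default.
* Variants annotated to several genes contribute to each independently.

`parseVariants()` consumes VCF 4.x through Bioconductor's
VariantAnnotation, decomposing multi-allelic records so that scoring
sees one (record, alternate allele, gene) triple at a time. Variants
without a SIFT score or without a coding consequence are dropped and
counted in a parse report, as are records whose genotype carries no
alternate allele; coding status is taken from the annotation source
(consequence terms or sidecar column) — no re-annotation is attempted.

# Personalization rules

`gvbToColor()` interpolates linearly per RGB channel between a neutral
endpoint (score 1, default white) and an alert endpoint (score at the
floor, default `#D7191C`), giving a monotone map: lower score, closer to
alert in every channel.

`predictConcentrationShift()` is a qualitative rule engine, not a PK
model. With impairment defined as GVB below `impairedThreshold`:

| drug kind | impaired deciding enzyme | direction |
|---|---|---|
| prodrug | yes | `decreased_active_ingredient` (reduced bioactivation) |
| active drug | yes | `increased_active_ingredient` (reduced clearance) |
| either | no | `unchanged` |

"Deciding" enzymes are the major ones when the pathway has any, and all
enzymes otherwise — an impaired non-major enzyme never flips the
direction while unimpaired major enzymes exist, but it is reported: in
the `implicated` table when a direction is set, and in the mechanism
text when the direction stays `unchanged`. This keeps the output
invariant — `unchanged` exactly when nothing is implicated — while still
surfacing secondary findings. Impaired transporters and carriers are
flagged *indeterminate* in the mechanism text: impaired transport can
raise or lower plasma exposure depending on which membrane and direction
the transporter serves, and no defensible general rule exists, so the
engine refuses to guess. Reabsorption is likewise outside the rule set.

The default `impairedThreshold = 0.3` is **arbitrary**: no validated
cutoff for "functionally impaired" GVB exists. It is a screening default,
prominently exposed on the function and the command line.

`inferDDI()` implements the drug–gene–drug pattern: for every gene
shared by two PK documents, a perpetrator with an `inhibitor` action and
a victim with a `substrate` action on that gene predicts
`victim_metabolism_slowed` (mechanism `inhibition`); an `inducer`
predicts `victim_metabolism_accelerated` (`induction`). The scan runs in
both directions and orders output by gene symbol, so it is symmetric up
to perpetrator/victim labelling.

# Synthetic data: what it does and does not emulate

The generators exist so every claim in the package is testable offline.

`makeSyntheticVCF()` emulates a SIFT-annotated germline VCF: per-gene
variant counts, a configurable SIFT distribution (uniform, point mass,
or mixture), controllable fractions of non-coding and SIFT-less records,
genotypes drawn 70/30 het/hom. It returns a truth table computed by a
*separately implemented* oracle — plain product and $n$-th root over
exactly the records as serialized (scores rounded to the 6 decimals
written) — sharing no code with `computeGVB`, so the chain
parse → score can be tested against an independent expectation.
What it does **not** emulate: linkage, allele frequencies, realistic
positions or consequence spectra, multi-sample files. Passing tests
demonstrate correctness of parsing and aggregation, not calibration on
real genomes.

`makeRandomPathway()` samples roles, actions, routes and placements from
the closed vocabularies and builds through the regular builders, so
every generated document is valid by construction — which is precisely
the property the round-trip and validator tests need. It does not
emulate realistic pathway topology sizes or biology.

`clopidogrelFixture()` encodes the worked example: clopidogrel as a
prodrug with CYP2C19 (major) and CYP2C9 (non-major) hepatic enzymes, the
intestinal efflux transporter ABCB1, and P2RY12 antagonism by the active
metabolite in the PD document. Identifiers and clinical text are
illustrative placeholders (the fixture's manifest says so), not database
extracts; the structure, not the prose, is what the tests assert. The
published description of this example reports no numeric GVB values, so
the end-to-end check uses a synthetic point-mass construction (three
SIFT = 0.05 variants giving CYP2C19 GVB = 0.05) and asserts the
qualitative outcome — one decreased-active-ingredient call implicating
CYP2C19.

# Numerical and engineering choices

* Geometric means in log space; oracle comparisons at 1e-12 absolute.
* All file outputs (GPML, SVG, HTML, TSV, JSON) are deterministic for
  fixed inputs; randomness enters only through explicit seeds, and every
  generator is a pure function of spec + seed.
* GVB TSV serializes scores at 6 decimals; a re-read table therefore
  agrees with the in-memory one to 1e-6, and no-variant genes are
  restored to exactly 1.
* Degenerate inputs raise classed conditions (`pgpath_*_error`) rather
  than generic errors, so callers and tests can discriminate failure
  modes; taxonomy problems in *documents* are returned as violation
  tables, not raised.
* A gene interacting in two roles (say enzyme and transporter) becomes
  two role-specific nodes, one per record — roles carry different edge
  semantics and different placements, and merging them would force
  multi-role nodes through every rule. This is an interpretation, and
  the fixture documents it.
* Problem sizes in the test-suite property checks (1,000 random SIFT
  sets, 200 random documents, 100-point colour sweeps) were chosen as
  the point where additional cases stopped changing the observed
  behaviour of the properties; they run in seconds on one CPU.

# Known limitations

* Predictions are qualitative directions with rationales — there is no
  compartment ODE model, no dose, no time course, and no guideline
  (CPIC/PharmGKB) lookup.
* Only SIFT feeds the burden score; other deleteriousness predictors
  would need mapping onto $[0,1]$ with the same orientation.
* Tissue placement is configuration, not expression data.
* The GPML reader recovers full semantics only for files this package
  wrote; foreign files get a best-effort structural import.
* The impairment threshold, the gradient endpoints and the zero floor
  are conventions, not estimates; conclusions sensitive to them should
  be checked across a range.
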