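---
title: "Marker-driven classification of developing spinal cord single-cell data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-driven classification of developing spinal cord single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

During the first weeks of vertebrate development the neural tube is
partitioned along its dorsoventral (DV) axis into 11 molecularly distinct
progenitor domains (dp1--dp6, p0--p2, pMN, p3) flanked by the roof plate
(RP) and floor plate (FP).  Each domain produces a characteristic neuronal
class (dI1--dI6, V0--V3, motor neurons), while neural-crest derivatives in
the dorsal root ganglia progress from SOX10^+^ progenitors through
NEUROG/NEUROD^+^ sensory precursors to ELAVL3^+^ postmitotic sensory
neurons.  Unsupervised clustering of single-cell RNA-seq from this tissue
fails to recover the DV domains: identities are combinatorial, with most
marker genes shared between neighbouring domains.  The productive
alternative is supervised, marker-driven classification against a
**knowledge matrix** -- an inventory stating, for every cell type, which
markers are *required*, which are *forbidden* and which are *irrelevant*.

`spinalatlas` implements this analysis end to end: droplet QC, gene-module
scoring, two-step knowledge-matrix classification (broad tissue, then CNS
DV subtype or PNS lineage stage), cross-species correlation over 1:1
orthologs, in vivo/in vitro staging correlation, composition and
neurogenesis-rate dynamics, and the gating and characterisation of
OLIG2^+^/NKX2-2^+^ double-positive progenitors.  A ground-truthed
negative-binomial simulator generates data whose statistical structure
matches what the analysis assumes, so every stage is testable against known
truth.

# The knowledge matrix

The shipped default (`default_knowledge_matrix()`) has 13 progenitor rows
(RP, dp1--dp6, p0--p2, pMN, p3, FP, ordered dorsal to ventral by
`dv_rank`), 12 neuronal rows, six PNS rows, an oligodendrocyte-precursor
row and three contaminant tissues.  Its logic uses the canonical vertebrate
DV code: SOX2 is required by every progenitor, ELAVL3 by every neuron; pMN
requires OLIG2 and forbids NKX2-2 while p3 does the converse; PAX3/PAX7
mark dorsal progenitors, NKX6-1 ventral ones, NKX6-2 p1; the human FP row
additionally requires PAX7, a primate feature absent in mouse.  Because the
11 neuronal DV classes leave one row short of the twelve the classifier
distinguishes, the twelfth row is the visceral motor neuron class `MNV`
(PHOX2B/ISL1/TBX2/TBX3, with little TBX20 in human); it is an ordinary
named row that users may rename or delete.  TUBB3 is deliberately absent
from the neuronal pan-module: STMN2 and MAP2 stand in for it, since TUBB3
is lowly expressed in human embryonic spinal cord.

The matrix ships as a TSV (`type`, `class`, `dv_rank`, one column per gene
with values 1/-1/0) rather than code, so a curated inventory can be
substituted verbatim with `read_knowledge_matrix()`.

# Classification model

**Step 1 (broad tissue).**  Counts are normalised as
`log1p(count * target_depth / cell_total)` with `target_depth` defaulting
to the median cell total, and each tissue programme (neural, mesoderm,
blood, skin) is scored.  The broad call is the argmax of the *unsubtracted*
mean module expression.  This is a deliberate deviation from
control-matched module scores: control matching centres any programme that
is active in most cells at zero, which turns the argmax into a coin flip on
homogeneous datasets (e.g. a pure-neural dissection).  Absolute programme
activity is the quantity the tissue call needs.  Ties or a winning score
below `min_score` give `"other"`.

**Step 2 (subtype).**  Marker expression of the neural cells is binarised
per gene and each cell is matched against the knowledge matrix:
`mismatches = (# required markers absent) + (# forbidden markers present)`.
The cell takes the unique row with minimal mismatches if that minimum is at
most `max_mismatch` (default 0 -- the inventory is presence/absence by
construction); equidistant ties are left `Unassigned` by default, because
silently preferring one row would bias compositions (an opt-in
`tie_break = "dv_rank"` resolves ties dorsally instead).  SOX2/ELAVL3
gating prunes candidates: SOX2^+^/ELAVL3^-^ cells compete only against
progenitor (and glia) rows, ELAVL3^+^/SOX2^-^ cells only against neuronal
rows, and cells positive for both or neither -- transition states are not
resolved by the data -- compete across all rows.  Cells binarised
SIX1^+^, or SOX10^+^ without OLIG2 (OLIG2 excludes oligodendrocyte
precursors), are routed to the PNS branch, which applies the three-stage
rule (precursor markers NEUROG1/NEUROG2/NEUROD1, then postmitotic ELAVL3,
then progenitor SOX10) before refining postmitotic cells into sensory
subtypes by the same mismatch rule.

## Binarisation

No binarisation method is prescribed by the source analysis, so the package
uses Otsu's criterion per gene (parameter-free, reproducible) with three
documented guards:

* genes expressed in fewer than `min_pos_frac` (1%) of cells are all-zero;
* genes expressed in more than `ubiquitous_frac` (99%) of cells are
  thresholded at detection (`> 0`) -- Otsu would otherwise split a unimodal
  positive population, de-calling half of a pan-marker such as SOX2 in a
  progenitor-only dataset;
* the positive class must average at least `min_on_mean` (default
  `log1p(2)`, roughly two transcripts in a typical cell under median-depth
  scaling).  Otsu always finds a split; without this guard a marker with no
  genuinely expressing population calls every cell with a single stray
  transcript positive (~5% per gene at an ambient mean of 0.05), which both
  misroutes cells to the PNS branch and poisons forbidden-marker checks.

Binarisation is computed on the combined neural dataset by default
(`binarize_scope = "per_sample"` is available); whether the original
analysis thresholded per sample is not stated.

# Module scores

`module_score()` follows the standard bin-matched control design: genes are
ranked by dataset-wide mean expression (ties broken by gene name, making
the score invariant to gene ordering), cut into `n_bins = 24` equal-size
bins, and each module gene draws `n_ctrl = 100` controls with replacement
from its bin under a fixed seed; the score is the mean module expression
minus the mean control expression, per cell.  A request of at least the
whole bin is served exhaustively, which makes the score deterministic and
exactly equal to a mean-difference oracle -- the configuration used by the
test suite.  These constants are conventions of the scoring function this
field uses, not values taken from any publication.  Raw normalised values
enter the score without any detection threshold.

Cell-cycle scoring applies the canonical human S and G2M lists; the phase
is G1 when both scores are non-positive, otherwise the larger score's
phase, ties resolved to G2M (deterministic and documented).  The
`S − G2M` difference is exposed as a covariate for the optional
mean-preserving OLS residualisation (`regress_covariate()`), the
dependency-light replacement for the variance-stabilising integration
workflow that the original study used: the downstream statistics
(binarisation, correlations, proportions) require a monotone normalisation,
not integration.  The gliogenic score is a module score over the fixed
11-gene list (FABP7, SOX9, SOX10, PDGFRA, CSPG4, FGFR3, FGFBP3, DBI,
SLC1A3, HOPX, ALDH1L1).

# Cross-species and staging comparisons

Orthology is strict 1:1: any gene occurring more than once on either side
of the raw pair list is discarded (`map_orthologs()`).  Per-type mean
profiles (`mean_profiles()`, `min_cells = 10` for stability, exclusions
logged) are correlated with Pearson's coefficient over a
transcription-factor panel; undefined coefficients from constant profiles
are reported as missing, never zero.  Profiles are computed on normalised
expression (whether the original used raw or normalised means is not
stated; this is configurable).

Staging correlation min-max scales each time point to [0, 1] over the
comparison gene subset and computes Spearman's coefficient for every
(in vivo stage, in vitro day) pair.  The scaling is monotone and therefore
does not change Spearman -- it is kept for comparability of stored
profiles.  The comparison subset should contain the genes that actually
vary along the progenitor-to-neuron trajectory (the published comparison
used a curated subset of 1448 highly expressed, dynamically varying genes,
which is user input here); the synthetic bulk generator exports its varying
genes as `attr(bulk, "varying_genes")`.  Because single-cell pseudo-bulk is
averaged in log space while the bulk course mixes linearly, mid-course
argmaxes are biased slightly toward earlier days; the alignment test
therefore asserts that the best-day mixing weight tracks the designed
neuron fraction within 0.2 and increases strictly, rather than an exact
nearest-day match.

# Double-positive analysis

Within binarised SOX2^+^ progenitors, cells are gated into
OLIG2^+^/NKX2-2^+^ (`dp`), OLIG2^+^-only (`pmn_like`) and NKX2-2^+^-only
(`p3_like`); the dp ratio is `|dp| / (|dp| + |pmn_like| + |p3_like|)`.
The similarity of dp cells to pMN and p3 reference populations is computed
per stage between mean profiles.  The source text says only that a
"distance" was calculated with values near 1 meaning similar; the package
defines `similarity = (Pearson r + 1) / 2` over the knowledge-matrix
marker genes plus the gliogenic list -- bounded in [0, 1], scale-free, and
exactly 1 for identical profiles -- with `1 / (1 + Euclidean distance)`
and an all-genes gene space available by configuration.

# The synthetic world

`simulate_counts()` draws `NB(mu * depth, size = dispersion)` counts:
`mu_on` for a type's required markers and class programmes, `mu_off`
elsewhere, a log-normal unit-mean depth multiplier, always-on housekeeping
genes, a 10-gene `MT-` block calibrated so the expected mitochondrial
fraction equals `mito_frac_mean`, and SRY expressed only in samples
declared male.  Defaults -- `mu_on = 20`, `mu_off = 0.05`,
`dispersion = 10` (NB size; UMI data are mildly overdispersed),
`depth_sdlog = 0.35`, `mito_frac_mean = 0.05` -- were chosen once as
representative of a good 10x marker gene (a well-expressed transcription
factor at median depth ~3000 detected genes) and are not tuned to any test
outcome.  `noise_free_params()` gives the Poisson limit with `mu_off = 0`
and no depth spread, in which the classifier must recover every label.

The four-stage presets state the developmental world the dynamics analyses
expect: the progenitor share falls from 0.85 (CS12) to 0.40 (CS19); within
progenitors the ventral pMN+p3 share falls 22% to 11% to 3%, with pD+pI
at 55% at CS12, matching the reported territory proportions; neurons shift
from ventral- to dorsal-biased; CS12 and CS17 are male.  The `"full"`
preset adds the PNS lineage (no sensory neurons at CS12, terminal subtypes
appearing from CS14), rare OLPs (~0.5%), and early-enriched mesoderm plus
blood and skin contaminants.

What a green test does and does not establish: the generator reproduces the
marker logic, overdispersion, library-size spread, mitochondrial load and
composition trends that the pipeline's statistics consume, so green tests
establish the *correctness of the computations* against known truth.  It
does not emulate ambient-RNA profiles beyond uniform background, doublets,
batch effects, spliced/unspliced layers, or continuous differentiation
states, so green tests do not certify performance on real droplet data;
thresholds (QC bounds in particular) must still be chosen per replicate by
inspection.

# Numerical choices and degenerate inputs

* All-zero cells: QC reports `mito_frac = 0` with a warning; normalisation
  leaves them at zero.
* Constant covariate in regression: input returned unchanged, with a
  warning.
* Constant profiles in any correlation: missing value, never 0.
* Equidistant knowledge-matrix ties: `Unassigned` (opt-in dorsal
  tie-break).
* Otsu degenerate (constant values): midpoint of min/max.
* Zero progenitors in a neurogenesis ratio: `Inf` if neurons present,
  missing if both are zero.
* Every seeded routine restores the caller's RNG state; the pipeline fans a
  single global seed into per-stage sub-seeds by a fixed derivation, so
  stages are reproducible in isolation and end-to-end reruns are
  byte-identical (only `run.log` carries timings).

# Known limitations

The default QC bounds (`min_genes = 500`, `max_genes = 9000`,
`max_mito_frac = 0.1`) are package defaults for typical 10x libraries --
the thresholds used in the original study are in its supplementary table
and were chosen per replicate by manual inspection, so real analyses should
do the same.  The knowledge matrix shipped here is authored from markers
named in the literature and completed with the canonical DV code; it is a
faithful stand-in, not a copy of the original supplementary inventory.
Embeddings, RNA-velocity/trajectory modelling and probabilistic label
transfer are intentionally out of scope.
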