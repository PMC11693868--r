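---
title: "Methods: translatome/transcriptome co-profiling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translatome/transcriptome co-profiling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosel)
```

## The design this package analyses

Polysome/ribosome-fraction profiling experiments sequence, for each
biological condition, two RNA populations: cytosolic RNA (the
transcriptome) and ribosome-associated RNA (the translatome). With two
conditions — call them A and B, e.g. an embryonic stage versus a derived
cell line — this yields four libraries: {A, B} x {cytosolic, ribosome}.
`ribosel` takes transcript-level quantifications of these four libraries
(estimated counts and FPKM, as produced by a StringTie-style assembler)
plus the transcript models as GTF, and asks four questions:

1. Which genes differ between conditions in the transcriptome (DEGs) and in
   the translatome (DTGs)?
2. Which genes are translated with different efficiency in the two
   conditions (differential TE)?
3. Within each condition, which genes' isoforms are selectively recruited
   by ribosomes, which isoforms carry that selection, and do the extreme
   isoforms differ in 5'UTR, 3'UTR or CDS structure?
4. Does the dominant isoform of a gene change between the cytosolic and
   ribosome fractions?

A gene-set over-representation stage and a ground-truthed simulator
complete the pipeline.

## Differential expression and translation

The design has one library per condition x fraction: no biological
replicates. The only defensible replicate-free count test is an exact test
of the 2x2 table (gene count, library total − gene count) across the two
libraries, i.e. a two-sided Fisher exact test conditioning on the margins.
`fisher_gene_p()` computes it directly from the hypergeometric point
probabilities over the whole support, which keeps genome-scale margins fast;
the suite verifies it against both `stats::fisher.test` and a brute-force
tail enumeration.

A gene is called when all three hold:

* |log2 fold change| ≥ 1, computed on gene FPKM with a pseudocount
  (default 0.25 FPKM) that enters *only* the fold change, never the test;
* FPKM ≥ 1 in at least one condition — this filter is applied *before*
  multiple-testing adjustment, so the Benjamini–Hochberg family is exactly
  the set of tested genes;
* BH-adjusted p ≤ 0.001.

All three thresholds are configurable (`call_differential()`); the defaults
are the printed criteria of the study design this pipeline targets.

**Assumption and known limitation.** The exact test models sampling noise
only. Counts that are overdispersed relative to Poisson (biological
replicates collapsed into one library, or highly expressed genes under even
mild extra-Poisson technical noise) make it anti-conservative, most visibly
at the top of the expression range. This is an inherent property of
replicate-free designs, not of this implementation; the strict 0.001
adjusted-p threshold plus the fold-change gate is what keeps calls
conservative in practice.

## Translational efficiency

TE is the gene-level ratio of ribosome-associated to cytosolic FPKM,
defined where the cytosolic denominator is expressed (FPKM ≥ 1, per
condition). The two conditions' eligible sets are intersected to a
common-gene table before comparison.

TE ratios are heavy-tailed, so "normalize to [0, 1]" is ambiguous. The
default is the empirical quantile (`rank`): `(rank − 1)/(n − 1)` with
average ranks for ties. It is invariant to monotone transforms (so whether
TE is logged is irrelevant), idempotent, and — unlike min–max — not
degenerate under a single outlier, which would otherwise compress every
other gene below any fixed separation threshold. Min–max normalization is
retained as an option (`normalize_te(..., "minmax")`) for fidelity with
analyses that used it; with all-identical input it maps everything to 0.5
with a warning.

A gene is differentially translated when the normalized difference exceeds
0.5 in absolute value (strict inequality; `delta = te_norm_A − te_norm_B`,
flag `up_A` when `delta > 0.5`). Flags are antisymmetric under condition
swap by construction.

## Ribosome-selective isoform usage

Within one condition, each gene's isoform composition is summarised per
fraction by composition proportions (CP): isoform i's share of the gene
total among isoforms passing the per-transcript expression filter
(FPKM ≥ 1 in that fraction), renormalized after filtering. CP is computed
from estimated counts by default: a within-gene proportion cancels
transcript length only when isoform lengths are equal, and they generally
are not; `units = "fpkm"` gives length-normalized (molar) proportions for
sensitivity analysis.

Selective usage is tested per gene on the 2-by-k table of cytosolic and
ribosome counts over the union of expressed isoforms, with a Pearson
chi-square statistic and two small-sample modifications:

* a pseudocount (default 0.5) added to every cell, stabilising genes with
  an isoform absent from one fraction;
* isoforms whose expected cell count falls below 5 are merged — smallest
  share first — into a single "other" bin until every expectation passes
  or only two bins remain; df = bins − 1.

Both knobs are configurable and `min_expected = 0, pseudocount = 0` gives
the textbook Pearson test (the form the oracle tests exercise). The exact
parameterisation used is recorded in the analysis metadata so outputs are
self-describing. The multiple-testing family is the testable genes (≥ 2
expressed isoforms) of one condition; selection means BH q ≤ 0.05, a
conventional default since no threshold is printed for this stage in the
study design.

Per isoform, the selection score is `Diff_CP = CP_ribo − CP_cyto`
(absent = 0; scores of one gene sum to 0). The extreme pair is the argmax
and argmin of Diff_CP, with ties broken by higher cytosolic CP and then
lexicographic transcript id so outputs are reproducible. For that pair,
`compare_structural_elements()` reports which of {5'UTR, 3'UTR, CDS}
differ as genomic interval *sets* (after merging adjacent intervals);
comparing a coding against a CDS-less transcript is undefined element-wise,
so every element present in either is reported and such transcripts are
identifiable by their empty CDS.

## Dominant transcripts

"Expressed at a considerably higher level than the other isoforms" is
operationalised as: the top isoform's CP is at least 0.5 *and* at least
twice the runner-up's (both constants configurable; single-isoform genes
are dominant by definition). A gene's dominant status between fractions is
`unchanged`, `switched`, or `undefined` (one or both fractions have no
dominant isoform). The two constants are a concrete stand-in for a verbal
rule; sensitivity to them can be explored directly through
`call_dominant_transcript()`.

## Gene-set enrichment

`hypergeometric_enrichment()` is a one-sided over-representation test
(upper hypergeometric tail) of a query against a user-supplied GMT
collection, with the universe restricted to the expressed genes of the
relevant comparison rather than the whole genome — the correct background
when the query itself was derived from the tested genes. Note that with
k, n, K fixed, *shrinking* the universe makes the same overlap less
surprising and the p-value grows; the suite asserts this direction.

## The simulator

`simulate_experiment()` provides the stand-in for real sequencing data and
the ground truth for every downstream stage. What it emulates:

* a multi-isoform catalog (default isoform-count weights give ~1.9
  isoforms/gene, matching an assembled insect transcriptome) on one
  pseudo-chromosome, alternating strands; isoforms of a gene share a CDS
  core and differ in exactly one recorded element — 5'UTR end, 3'UTR end,
  or an internal coding exon — so structural attribution has known
  answers;
* log-normal gene expression (log2 sd 1.5) and a log-normal per-gene
  intrinsic TE (log2 sd 1) shared between conditions. The intrinsic TE
  term matters: without it the two conditions' TE ranks are independent
  noise under the null and |ΔTE| > 0.5 would fire for ~25% of genes at
  any depth, whereas real genes have strongly condition-conserved
  translational efficiency;
* planted effects by independent Bernoulli draws (overlap allowed and
  recorded): DE genes scaled by 2^±2 in condition B; TE-shifted genes'
  condition-B ribosome fraction scaled by 2^±3; selected genes' ribosome
  CP shifted by moving 0.3 of composition onto one isoform
  (`plant_cp_shift()`, e.g. (0.5, 0.5) → (0.8, 0.2)); planted dominant
  switches swap the top two ribosome-fraction proportions;
* negative-binomial counts around depth-scaled expectations, and FPKM
  derived from counts, lengths and depth.

The default dispersion is 1e-4, deliberately near-Poisson: the emulated
design has no biological replicates, so the noise the replicate-free tests
can claim to model is technical, and technical RNA-seq noise is close to
Poisson. The NB form is kept so users can study biological overdispersion
by raising `nb_dispersion` — doing so degrades the error control of the
exact tests, which is precisely the point of such a study.

What the simulator does **not** emulate: positional ribosome occupancy,
sequence content (uORFs, structure, codon usage), correlated effect
layers, isoform-level quantification uncertainty from read assignment, and
batch effects. Passing tests therefore demonstrate correctness of the
statistics and bookkeeping under a clean generative model, not robustness
to real-data artefacts.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen once: null calibration at
1000 genes x 20 replicates and depth 1e6 (about 1000 counts/gene/library);
planted-effect recovery at 500 genes and depth 3e5, which puts the mean
around 600 counts/gene/library — comfortably above the ≥ 200/gene regime
the recovery properties are stated for; the bundled end-to-end example at
200 genes. Tolerances: oracle agreement at 1e-9 (chi-square) and 1e-12
(Fisher, hypergeometric); simplex/conservation identities at 1e-9; results
tables render floats at 6 significant digits, so round-trips through disk
agree to ~1e-6 relative.

Degenerate inputs are handled explicitly rather than by accident: empty
GTFs parse to empty catalogs; genes with one expressed isoform are marked
not-testable and excluded from the BH family; an all-zero Diff_CP vector is
flagged `no_selection`; minmax normalization of a constant vector warns and
returns 0.5; the pipeline writes a MANIFEST naming completed stages when a
stage fails, keeping partial outputs auditable.

## Reproducibility

Every stochastic component flows from a single integer seed
(`simulation_params(seed = )`), and the pipeline serializes its full
configuration next to its outputs. Identical (inputs, config, seed)
produce byte-identical output tables; the suite asserts this end-to-end.
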