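---
title: "Methods: mapping a sex-determination region from segregation, depth, divergence and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a sex-determination region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The inference problem

A dioecious species with homomorphic sex chromosomes carries a
sex-determination region (SDR): a usually small interval where X and Y (or Z
and W) have stopped recombining and diverged. `sexscan` infers, from an F1
cross and male/female whole-genome sequencing, (i) which sex is
heterogametic, (ii) where the X- and Y-specific intervals lie on each
haplotype assembly, (iii) how long ago the gametologs inside them diverged
(synonymous divergence), and (iv) which Y-region genes behave like sex
determinants in expression data. Each stage is an independent line of
evidence; the package's orchestration composes them, and the synthetic-data
generator produces inputs with exactly the statistical structure each stage
assumes, so the full chain can be validated by parameter recovery.

All genomic coordinates are 1-based inclusive internally (matching the
boundary convention of depth-scan outputs); BED export converts to 0-based
half-open.

## Pseudo-testcross segregation and the association scan

In a cross between two outbred parents, a marker heterozygous in exactly one
parent and homozygous in the other segregates 1:1 among F1 progeny — a
testcross configuration per parent ("pseudo-testcross"). `classify_markers()`
assigns each SNP row (`AB x AA` -> female-parent-het, `AA x AB` ->
male-parent-het) and each presence/absence (PA) row (present in one parent,
absent in the other) to a category; markers heterozygous in both parents,
or fixed-different (`AA x BB`), carry no 1:1 segregation signal and are
uninformative. PA states are called from read counts: `>= min_present`
(default 3) reads is present, zero is absent, in between is missing — too
few reads to distinguish a true absence from sampling. The threshold is a
config knob; three reads is the smallest count for which a false "present"
from index hopping or contamination is unlikely at RAD-level coverage.

A segregation filter (`filter_segregation()`) screens markers against 1:1 by
a chi-squared goodness-of-fit at alpha = 0.01 over non-missing flowering
progeny. Markers with fewer than 20 informative calls are flagged `low_n`
rather than failed, since the test has no power there. Note that
SDR-linked markers in an unbalanced family (38 F / 89 M here) legitimately
distort toward the sex ratio — the filter is a data-quality screen to apply
to autosomal linkage work, not a precondition of the association scan.

The scan itself builds one carrier-by-sex 2x2 table per informative marker
over flowering progeny (non-flowering individuals have phenotype `U` and are
excluded; missing genotypes are dropped per marker; carriers are progeny
with the het parent's variant: `AB` or `P`). `fisher_exact_2x2()` computes
the exact two-sided p by the point-probability rule — the sum of
hypergeometric probabilities of all tables with the observed margins whose
point probability does not exceed the observed one — evaluated in log space
so large margins cannot underflow, with a 1e-7 relative tie tolerance.
Zero-margin tables return p = 1 by convention. Benjamini-Hochberg control at
FDR 0.05 is applied *within* each parent category by default (the two marker
sets are tested as separate families, the way per-panel Manhattan thresholds
are drawn); `fdr_scope = "global"` pools them, and `pool_types = FALSE`
additionally separates SNP from PA markers — both scopes are provided
because either family definition is defensible. A `balanced = TRUE`
replicate subsamples the majority sex to the minority count without
replacement under a seed, removing any imbalance artifact.

The verdict rule is deliberately strict: significant male-het markers with
*no* significant female-het markers give XY; the mirror gives ZW; both give
`ambiguous`; neither `none`. The peak interval is the span of significant
markers on the modal chromosome.

## Depth-based region mapping

Hemizygosity leaves an unambiguous copy-number signature in short-read
depth. With tracks from one male and one female aligned to a haplotype
assembly, each track is normalized by its own genome-wide mean (so calls are
invariant to sequencing effort), averaged in sliding windows (default
150 kb window, 10 kb step; the terminal partial window is kept and flagged),
and labeled:

| label | male | female | reading |
|---|---|---|---|
| `X_like` | 0.5 ± 0.15 | 1 ± 0.15 | male hemizygous, female diploid |
| `Y_like` | 0.5 ± 0.15 | < 0.15 | male hemizygous, female lacks the region |
| `balanced` | 1 ± 0.15 | 1 ± 0.15 | ordinary diploid window |

Threshold comparisons are closed intervals with a 1e-9 epsilon so exact
boundary values (e.g. a noiseless window mean of exactly 0.65) are not lost
to floating-point rounding. Under a ZW system the pipeline swaps the roles
of the two samples — the contrast is heterogametic (hemizygous) vs
homogametic carrier, whatever the sexes are called.

Runs of same-label windows separated by at most `max_gap_bp` (default one
coarse window, 150 kb) merge into candidate regions. Boundaries are then
refined at 20 kb / 1 kb resolution. A refinement subtlety: a window
overlapping a copy-number step edge passes the thresholds as soon as a
*fraction* f0 of it lies inside the region (for the male 0.5-band with
flanking level ~1, f0 ≈ 0.7; for the female absence rule, ≈ 0.85), so
"first passing window start" over-extends each boundary by (1 − f0) x
window. `call_regions()` inverts this window response: it estimates the
flanking and interior plateau levels from the track itself (normalization
shifts them slightly away from the nominal 1 / 0.5 / 0, because the
hemizygous region contributes to the sample's grand mean), derives f0 from
the thresholds and those levels, and corrects the first/last passing window
start by (1 − f0) x window. The estimate is exact in the noiseless limit
and unbiased to within the refine step under noise; on 10 Mb simulations at
30x and dispersion 0.2 the recovered boundaries sit well within ±2 kb (the
acceptance suite measures ≈0.8 kb worst-case).

`feature_density()` supplies the genome-context track (percent bp covered by
merged features per 500 kb / 100 kb window, non-N denominators; all-N
windows are NA), and `annotate_regions()` reports spans and the genes
overlapping a region by at least half their length (a containment rule the
user can change; printed gene counts from any particular annotation depend
on that annotation, so the rule is a declared choice).

## Gametolog divergence (NG86 with Jukes-Cantor correction)

Candidate gametologs are paired by reciprocal best hit of translated CDS
under local protein alignment (BLOSUM62, gap open 10 / extend 0.5), keeping
hits with at least 60% identity over at least 100 aligned residues, up to 2
targets per query. This identity/length criterion replaces a database
E-value model: there is no database size here to calibrate an E-value
against, and for intraspecific gametologs (expected identity far above any
twilight zone) the two filters select the same pairs.

Each pair is aligned in codon frame by threading a global protein alignment
back onto the nucleotides, so gaps come in multiples of 3; codon columns
containing gaps or ambiguity codes are excluded from counting, terminal
stops and partial codons are trimmed, and an internal stop in the counted
region is an error (such gene models are annotation artifacts and must be
filtered upstream). NG86 counting then proceeds classically: per-codon
synonymous site fractions are the per-position fraction of the three
possible changes that preserve the amino acid, averaged over the two
sequences, with changes to stop codons counted as nonsynonymous — this
keeps S + N = 3 x counted codons exactly. Multi-difference codons average
their synonymous/nonsynonymous step counts over all mutational pathways
with equal weights (pathway steps through stop codons count as
nonsynonymous steps rather than excluding the pathway; for the
low-divergence pairs this method targets, multi-hit codons are rare and the
convention is immaterial). The Jukes-Cantor correction
d = −(3/4) ln(1 − (4/3) p) maps proportions to divergences and is undefined
at p >= 3/4 (flagged, not fabricated). Note pS = Sd/S may exceed 1 for
low-opportunity codons; the undefined flag handles this correctly.

Summaries exclude pairs with dS > 1 (likely paralogs, not gametologs),
report the median over the remainder, and emit a position-sorted strata
table under the stricter dS < 0.5 filter. Strata detection is deliberately
descriptive — a table to inspect, not a changepoint statistic — because with
the handful of pairs a single SDR yields, any segmentation statistic would
be badly underpowered; discrete divergence bands, if present, are visible
directly.

## The expression cascade

`de_summary()` is a compact negative-binomial differential-expression test
with the standard ingredients: median-of-ratios size factors (over genes
with all-positive counts), baseMean as the mean of normalized counts,
log2FC as the log2 ratio of group means with a +0.5 pseudo-count (kept
finite and unshrunken — a deliberate divergence from shrinkage estimators,
documented so its output is comparable to a plain ratio of means), and a
Wald test of the log ratio with per-gene method-of-moments NB dispersion
floored at 0.01. The Wald statistic is referenced against a t distribution
with nA + nB − 2 degrees of freedom rather than the normal: with three
replicates per group and a moment dispersion estimate, the normal reference
is anticonservative, and the t reference brings the null type-I rate into
the nominal range (verified by simulation in the test suite). BH adjustment
is per contrast; genes with baseMean < 1 are not tested (padj missing).
The cascade consumes any table with the required columns, so output from an
external DE package can be dropped in unchanged — the thresholds, not the
test, are the contract.

The cascade itself: among Y-specific genes, stage 1 keeps padj1 < 0.05
(contrast 1: male vs female early flowers), stage 2 adds log2FC1 > 2, and
the final stage requires padj2 < 0.05 and log2FC2 > 2 in contrast 2 (male
flowers vs non-reproductive organs). Stage 1 applies no sign constraint:
it is a significance screen whose printed reference membership includes
down-regulated genes; direction is enforced by the fold-change stages.
Missing padj never passes. Significance is evaluated on *adjusted* p-values
(the table columns the reference counts reproduce exactly — 35 Y-specific
genes -> 14 -> 10 -> 2 on the shipped table), not raw p.

Y-specificity of a Y-region gene is decided by two rules in order: a
reciprocal-best X partner makes it an XY gametolog; otherwise mean female
normalized depth over the gene body below 0.15 (no female reads — the
hemizygosity signature at gene resolution) makes it Y-specific; genes
failing both are `unresolved` rather than forced into either class.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 186 F1 progeny
(38 female, 89 male, 59 non-flowering, so 127 flowering individuals carry
phenotype information), a male-heterogametic system, a 4 Mb SDR
mid-chromosome, 30x coverage, negative-binomial depth with dispersion 0.2
(the noise model is a declared choice — the depth data themselves carry no
stated model; 0.2 reproduces the overdispersion typical of short-read
coverage), 22 gametolog pairs at target dS 0.02 (near the observed median
divergence of such systems' young strata), 56 Y-region genes (22 gametolog
+ 34 Y-specific) vs 54 X-region genes, PA markers enriched inside the SDR
(80% vs 30% outside, mirroring repeat-driven PA enrichment), and two planted
candidate genes at log2FC 5 in both contrasts. Recombination is fully
suppressed inside the SDR in the heterogametic parent and one obligate
crossover per chromosome occurs outside it (SDRs suppress recombination
while the flanking pseudoautosomal regions keep recombining); the
homogametic parent recombines freely. Exact phenotype counts are achieved
by conditioning the transmitted sex haplotype on each progeny's class, which
preserves the crossover distribution. Sex-limited expression effects follow
the heterogametic sex, so ZW runs are exact mirrors.

The CDS generator draws a stop-free ancestral sequence and applies a
Poisson(dS x S) number of synonymous-only single-base substitutions, each
chosen uniformly among the currently available synonymous changes — the
equal-rate model underlying the JC correction restricted to synonymous
moves, with multiple hits possible. Realized dN is exactly zero, which
keeps the dS oracle clean (any estimated dN > 0 is an estimator artifact,
not simulation noise).

Deliberately not emulated: read-level artifacts (the generator produces
depths and genotypes, not FASTQ), alignment and assembly error, mapping
bias between diverged haplotypes, repeat-induced multi-mapping, genotyping
error and missingness (the marker module handles missing data, but the
generator emits complete calls), linked selection, and nonuniform
recombination maps. Passing recovery tests therefore demonstrates that the
*inference chain* is correct under its stated model, not that real libraries
are free of upstream artifacts.

## Numerical choices and problem sizes

- Fisher ties: point probabilities within 1e-7 relative tolerance count as
  "as extreme"; computation is in log space.
- Depth thresholds are closed intervals with a 1e-9 epsilon.
- The refinement edge inversion clamps f0 to [0.5, 1] and falls back to the
  nominal-threshold value when a region is too narrow to estimate plateau
  levels.
- Seeds: every generator derives independent stream seeds from the base
  seed and a stage label via a polynomial rolling hash, so stages are
  reproducible independently and in any order; identical config + seed give
  byte-identical output files.
- Pipeline caching hashes the stage configuration (JSON-serialized, md5);
  unchanged stages are reused on reruns, and the run report is itself
  deterministic.
- Test problem sizes are the package's validation choices: exhaustive
  Fisher enumeration to table total 40; 1,000 random BH vectors; 400
  random short codon alignments against the pathway-enumeration oracle;
  dS recovery at targets {0.01, 0.02, 0.05, 0.1} with 200 replicates of
  500 codons; SDR recovery on ten seeded 10 Mb simulations (4 Mb SDR, 30x,
  dispersion 0.2) plus a ZW mirror; cascade recovery over twenty seeded
  expression simulations. Unit tests run the same machinery on 1 Mb
  chromosomes, where every stage completes in seconds.

## Interfaces and orchestration

Every stage reads and writes plain-text formats (genotype TSV dialect with
parent header lines, three-column depth TSV, GFF3, FASTA, counts TSV,
regions BED/TSV, JSON reports); `read_genotypes_vcf()` accepts VCF GT
fields, skipping multiallelic records, since the pseudo-testcross needs
biallelic configurations. `run_pipeline()` orchestrates the simulated study
end to end; with real data the stage functions compose directly from the
file readers, as the numbered `analysis/` drivers demonstrate stage by
stage. The package deliberately ships no shell wrapper: the drivers and
functions are the interface.

## Known limitations

- The association scan tests marginal association per marker; it does not
  build a linkage map or run interval mapping, so the "peak interval" is a
  span of significant markers, not a QTL support interval.
- Reciprocal-best-hit pairing can be confounded by recent segmental
  duplications inside the SDR; the dS > 1 exclusion catches old paralogs
  but not young ones.
- The DE stand-in is a screening test. For publication-grade expression
  inference, run a dedicated DE package and feed its table to
  `filter_cascade()` — the cascade is the contract, not the test.
- Depth-based classification assumes a single copy-number step per
  boundary; nested insertions inside the SDR produce `other` windows that
  merge across gaps up to `max_gap_bp` but are not modeled explicitly.
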