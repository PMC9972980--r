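---
title: "Models and methods behind lumenstrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lumenstrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumenstrain)
```

# The analysis in one paragraph

`lumenstrain` studies one bacterial species sampled at several intestinal
sites of one person. All inference runs against a reference genome with gene
coordinates, from two per-sample inputs: a *pileup table* (per-position
depth and A/C/G/T counts) and a *read summary* (per-read interval and
mismatch count). From these the package infers strain structure (SNP
distances, within-genome heterogeneity, minor co-resident lineages, ANI),
gene gain/loss, the selection regime (dN/dS, fixed mutations, divergence
time, quinolone-resistance genotype) and in situ replication. A simulator
generates the same inputs from a known ground truth, so every estimator is
testable by parameter recovery.

# Variant model and thresholds

Variant calling is deliberately simple: no genotype likelihoods, no
base-quality model. A position is callable at depth ≥ `min_depth` (default
8 reads); the most frequent non-reference allele is reported when its
fraction reaches `min_vaf` (default 0.20). Both thresholds are inclusive.
At multi-allelic positions only the top alternative is kept, ties broken
lexicographically — a fixed, documented tie-break rather than caller-version
luck. Malformed rows (counts not summing to depth) are an input error that
names the row.

Two different 80% rules co-exist on purpose:

* a call is **dominant** (near-fixed) when its variant allele frequency is
  **≥ 0.80** (inclusive);
* a callable position is **polymorphic** for the heterogeneity score when
  the dominant allele overall is **≤ 0.80**, i.e. nonpolymorphic strictly
  above 80%.

The heterogeneity rate is `1000 × polymorphic / callable` SNPs per kb, and
more than 5/kb flags a probable strain mixture; with zero callable bases the
rate is `NA` and the flag stays `FALSE`. Effect annotation translates the
reference and variant codon in the gene's sense frame (reverse-complemented
for minus-strand genes) under the standard genetic code, which is identical
to bacterial table 11 for every codon — the tables differ only in start
codons, irrelevant for substitution effects. A change to a stop codon is
`nonsense`; stop-loss is classified as nonsynonymous.

# Minor-lineage detection

A minor lineage is evidenced by SNPs at intermediate frequency shared
identically across sites mapped to one common reference. Per site, calls
with VAF in `[0.20, 0.50]` are retained — strictly above 50% the variant is
attributed to the major lineage and dropped; exactly 0.50 is retained. The
shared set is the exact intersection on (contig, position, variant allele)
across *all* sites, and ≥ 20 shared SNPs indicate presence. Pileups that
disagree on reference bases at common positions are rejected as having been
mapped to different references.

# ANI

Genome A is cut into 1-kb fragments (per contig, short tails dropped); each
fragment is aligned to its best-matching region of B. The fast path aligns
against the colinear window (same coordinates ± a margin) with a global-local
pairwise alignment, which suffices for genomes sharing contig structure; if
that identity falls below the 0.8 counting floor, an exact 18-mer
seed-and-extend search over all contigs of B locates the window instead,
accommodating renamed or shuffled contigs. Identity is matches over fragment
length, and the ANI is the mean over fragments reaching the floor. Identical
genomes give exactly 100; the tests assert calibration at 1% simulated
substitutions to 99.0 ± 0.1.

# Gene flux and gene-content dissimilarity

Reads are counted per gene with any-overlap semantics (≥ 1 shared base, once
per gene). A gene is *missing* in a target sample when it attracts fewer
than 3 reads there but ≥ 10 in the reference sample; both bounds are
reported as they stand, with no depth normalisation — the simulator shows
the rule is exact at 20× depth. Gene-content dissimilarity is the Jaccard
distance on presence/absence; a sample with no present genes makes its pairs
undefined (`NA`) rather than silently 1.

PERMANOVA is implemented from scratch as a permutation test on the
distance-based pseudo-F: `SS_total = Σ d²/n` over all pairs,
`SS_within` summed per group, `R² = SS_between/SS_total`, and
`p = (1 + #{F_perm ≥ F_obs}) / (1 + permutations)` under label permutation
with a caller-supplied seed. The +1 correction keeps p-values in (0, 1]; at
α = 0.05 with 199 permutations the test is exact under exchangeability,
which the acceptance suite verifies empirically (type-I error 0.05 ± 0.03
over 200 structure-free replicates). `vegan::adonis2` is used in the test
suite only as an independent cross-check of R² and F. PCoA is classical
scaling (`stats::cmdscale`) with a fixed eigen-sign convention — each axis's
largest-magnitude loading is positive — so ordinations are reproducible;
axes beyond the configuration's rank are zero-padded.

# Selection

Filtered coding SNPs (depth ≥ 10, VAF ≥ 0.50) are concatenated, in genome
order, into a *quasi-coding sequence*: per SNP one reference codon and one
variant codon differing only at the SNP's within-codon offset. dN/dS is
estimated by Nei–Gojobori counting:

* **Expected sites** are computed on the reference codons only. Each codon
  position contributes `f_syn` synonymous and `1 − f_syn` nonsynonymous
  sites, where `f_syn` is the synonymous fraction among the three possible
  changes after excluding changes that create a stop. Averaging expected
  sites with the variant sequence would change nothing material because
  each codon pair differs by at most one base.
* **Observed differences** translate each codon pair; pairs differing at
  more than one position (possible only for user-supplied sequences, not
  SNP-derived ones) are averaged over mutational paths with equal weight,
  dropping paths through stops.
* `ω = (Nd/N)/(Sd/S)`; ω < 1 reads as purifying, ω > 1 as positive
  selection. When `Sd = 0` the ratio is undefined and reported as `NA` — no
  pseudocount is injected, because a fabricated denominator would
  misrepresent sparse data.

This counting estimator replaces site-specific maximum-likelihood machinery
deliberately: SNP-derived codon pairs differ at single positions, so
multiple-hit corrections have nothing to correct, and the estimator's known
bias at extreme ω is acknowledged in the recovery tolerances (± 50% relative
at ω = 0.2) rather than hidden.

Fixed and near-fixed mutations are calls at VAF ≥ 0.80, coding and
intergenic alike. Divergence time is the arithmetic `years = m/(μG)` with
μ = 7×10⁻⁷ mutations · base⁻¹ · year⁻¹ by default — at the typical 5-Mb
genome that is 3.5 mutations per genome per year. Resistance genotyping
translates gyrA and parC and compares the QRDR residues (GyrA Ser83, Asp87;
ParC Ser80, *E. coli* numbering) to wild type; the wild-type residues are
defaults, overridable for other species or numbering schemes. Three
non-wild-type residues are scored resistant, zero sensitive, otherwise
partial.

# Replication index

The estimator assumes bidirectional replication from a single origin:
expected coverage decays log2-linearly from origin to terminus. Sliding
windows (5 kb, 100-b slide, over the per-position coverage concatenated
across contigs in genome order) are averaged, **sorted ascending**, and the
extreme 5% at each end trimmed as outliers. A least-squares line is fit to
log2(coverage) against the window's *original* rank scaled to [0, 1] — the
trimmed points are removed from the fit but the axis is not re-scaled, so
trimming rejects outliers without shrinking the fitted range — and the index
is `2^(fit(1) − fit(0))`. Sorting before fitting is the key simplification:
it removes any dependence on knowing where the origin lies. Perfectly flat
coverage yields index 1 and, by convention, `fit_r2 = 1` (a zero-variance
fit is a perfect fit, and the convention keeps the field total). Fewer than
20 windows, or any retained window with zero coverage, yields an `NA` index
with a reason. The fit r² is reported but never used as a hard filter, and
no GC-bias correction is applied — both stated limitations.

Relative abundance keeps mapped reads with fewer than 2 mismatches (reads
with ≥ 2 likely come from closely related strains) and divides by the
sample's total read count.

# What the simulator emulates — and what it does not

The generator encodes the study conditions: a single founder genome
(default 100 kb, one contig, 85% coding, 900-b genes as complete ORFs on
random strands) diversifies independently at TI, cecum, DC and feces with
site-private substitutions plus pre-split shared ones. Candidate changes
never create premature stops, and nonsynonymous candidates are accepted with
probability `omega_true` (synonymous thinned by `1/omega_true` when
ω > 1), so the realised nonsynonymous/synonymous ratio targets the requested
dN/dS. An optional minor lineage carries the shared (pre-split)
substitutions plus its own SNP set — placed only at positions untouched by
the major lineage — so the cross-site shared-SNP intersection equals the
minor set exactly. Depth is Poisson around the log2-linear origin→terminus
gradient (origin at position 1, terminus at the genome midpoint, circular
symmetric), scaled so the genome-wide mean equals `mean_depth`; allele
counts mix major lineage, minor lineage and uniform base-call error; reads
are uniform-start with mismatch counts from strain-vs-reference differences
plus binomial errors.

Defaults were chosen once to be realistic for a healthy-adult gut
commensal: tens of substitutions per site (a few years of within-site
divergence at the default mutation rate), ω = 0.2 (strong purifying
selection, the regime typical of gut commensals), PTR 1.5 (the *E. coli*
scale of in situ replication), 50× depth, 0.1% base-call error, and a minor
lineage disabled unless requested. The within-site polymorphism spectrum of
the major lineage is *not* asserted — real populations carry low-frequency
variation whose spectrum this study design cannot constrain — so it is
exposed through `minor_lineage_freq`/`minor_lineage_snps` rather than
defaulted.

Not emulated: read-level FASTQ (no alignment or assembly is simulated),
indels, recombination or chimeric strains, GC-dependent coverage bias,
contamination, and multi-origin replication. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
generative model, not robustness to artifacts the model excludes.

# Coordinates and formats

Internally everything is Bioconductor-idiomatic: 1-based closed intervals in
`GRanges`, sequences in `DNAStringSet`. On disk the package follows each
format's own convention — GFF3 and VCF 1-based, BED 0-based, and the pileup
TSV dialect (`contig pos ref depth A C G T`) 0-based — with conversion at
I/O only. Read summaries carry `read_id contig start end mismatches`; the
interval columns serve gene counting, the mismatch column abundance
filtering. VCF output is a minimal hand-written VCF 4.2 (substitution
records with `DP`/`VAF` INFO keys), which is all these calls need.

# Orchestration

`runIndividual()` executes stages in dependency order and isolates failures:
a site without a pileup loses its own heterogeneity/growth sections with a
recorded reason while every other section completes — partially analyzable
individuals are the norm in this design, so stage isolation beats fail-fast.
Reports serialise to JSON losslessly and deterministically (timings go to
log lines, never into the report). Thresholds live in one flat key=value
config (`lumenThresholds()` / `readRunConfig()`), one named key per
documented default. The package's surface is its R functions; there is no
shell entry point, and `runBenchmark()` is the scenario-grid driver used by
the acceptance checks.

# Problem sizes in the tests

The test and acceptance suites run on scaled scenarios chosen to make each
estimator's signal unambiguous while keeping the whole suite quick on one
CPU: 100-kb genomes (20 kb for ANI calibration, 40–60 kb for unit tests),
depth 20–100 as each check requires, 1 200 implanted substitutions for the
purifying dN/dS recovery, 200 structure-free replicates at 199 permutations
for the PERMANOVA type-I check. These sizes are the package's own choices;
the estimators contain no dependence on them.

# Known limitations

* The variant caller has no error model beyond thresholds; very deep or
  very error-prone data deserve a likelihood-based caller upstream, with
  this package consuming the resulting table.
* The Nei–Gojobori estimator is biased toward 1 at extreme ω and ignores
  codon-usage and transition/transversion asymmetries.
* The replication index assumes a single bidirectional origin and clean
  coverage; plasmids, prophage induction and GC bias violate it.
* ANI counts only fragments above the 0.8 identity floor, so highly
  diverged genome pairs are summarised over their alignable fraction only,
  as fragment-based ANI conventionally does.
* Frameshifts are accepted as pre-computed annotations if provided, never
  inferred; indels are out of variant-calling scope.
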