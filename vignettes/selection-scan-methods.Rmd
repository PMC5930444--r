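---
title: "Detecting recent selection in divergently selected lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent selection in divergently selected lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long-running divergent selection experiments — one control line kept
under stabilizing selection, one or more lines selected for a trait —
leave detectable footprints in the genome: favorable alleles and their
linked neighbourhoods rise in frequency in the selected lines but not
in the control. `sweepscan` implements a complete scan for such
footprints from SNP-array genotypes: quality control, population
structure, a windowed FST outlier test, haplotype-based iHS and XP-EHH
scans, and a cross-test consensus. Because a real experimental herd's
genotypes are rarely shareable, the package also contains a
forward-in-time Wright–Fisher simulator of the whole experimental
design, used as the test bed for every stage.

# Data model

Genotypes are held as a samples × SNPs dosage matrix
(`GenotypeData`, values 0/1/2/`NA` counting copies of the B allele),
phased haplotypes as a (2·samples) × SNPs binary matrix
(`HaplotypeData`, no missing values), both aligned to a sorted
`SnpMap` (1-based bp positions). Window and region intervals are
half-open `[start, end)` in bp; BED output is 0-based half-open.
The counted allele of PLINK text input is the observed minor allele
(ties broken to the lexicographically larger label), which makes the
coding deterministic and independent of sample order; phased VCF input
counts ALT.

# Quality control

Filters run in a fixed order: samples with call rate strictly below
0.90; then SNPs with call rate strictly below 0.95, SNPs off the
configured autosome set, SNPs sharing a (chromosome, position) pair
(all copies removed, since there is no principled way to pick one),
and SNPs monomorphic in *every* line simultaneously. Each stage is
idempotent.

The misplaced-SNP detector exploits the decay of linkage
disequilibrium with physical distance: a SNP whose strongest r²
partners lie tens of megabases away is almost certainly mapped to the
wrong place. Per iteration, every SNP under scrutiny records its ten
highest-r² same-chromosome partners (genotype-based Pearson r², since
this step runs before phasing; undefined r² ranks as 0; ties break by
smaller distance, then map order) and earns one flag per partner
farther than 10 Mb. On each chromosome, all SNPs attaining the
chromosome's maximum flag count (if ≥ 1) are removed; SNPs flagged but
not removed are re-examined in the next iteration, until none remain.
Removing *all* tied SNPs per iteration guarantees termination and
avoids an arbitrary choice among ties. A truly misplaced SNP that left
a strong-LD block collects ~`topK` flags, while each abandoned block
mate collects only one, so the guilty SNP is removed first and its
block mates are exonerated in the following iteration.

# Population structure

The genomic distance between two individuals is 1 − (proportion of
alleles identical by state), computed per pair over the SNPs called in
both. Classical multidimensional scaling (principal coordinates)
double-centres the squared distance matrix, eigendecomposes it, and
scales eigenvectors by the square roots of their eigenvalues.
Axis signs are fixed (first nonzero loading positive) for
reproducibility; explained-variance fractions divide by the sum of
*positive* eigenvalues only, so fractions remain interpretable for
slightly non-Euclidean IBS distances. Separation of the control line
along PCo1 is quantified by a one-dimensional silhouette width.

# FST outlier scan

Per-SNP differentiation between two lines uses the Weir & Cockerham
(1984) θ estimator, which corrects for unequal sample sizes, in its
allele-frequency form (the within-population heterozygosity term taken
from Hardy–Weinberg expected frequencies). Nei & Chesser's corrected
GST is available behind `fstScanConfig(estimator = "nei")` as a
sensitivity check. θ and the pair heterozygosity 2p̄(1 − p̄) (p̄ the
unweighted mean frequency, the convention of FST–heterozygosity
outlier methods) are averaged in 100-kb windows overlapping by 75 kb —
a grid anchored at 0 bp, advancing 25 kb, per chromosome up to the
last SNP. Windows need more than five scored SNPs to be eligible.

Because the null distribution of FST depends on allele frequency, a
window is a candidate only if, in *both* control-vs-selected
comparisons, it is (a) strictly above the empirical top-1% of window
mean FST and (b) strictly above the upper 97.5% empirical quantile of
FST within its heterozygosity bin (20 equal-count bins). Only the
upper tail flags candidates: low-FST outliers are reported but a
divergence scan has no use for them. Empirical quantiles use R's
default type-7 interpolation, recorded in the configuration.

# Haplotype scans

EHH at a flanking SNP is the probability that two haplotypes drawn
from a carrier set are identical over the interval from the core
(exclusive) to that SNP (inclusive); it is 1 at the core and
non-increasing outward. The implementation refines identity classes
outward (a compiled kernel; exact duplicate haplotypes are collapsed
with multiplicities, and classes reduced to a single pattern retire
from refinement — both exact optimizations). iHH integrates EHH
against physical distance by trapezoids, truncating at the first point
below 0.05. A core is dropped (not partially integrated) when its
curve never reaches the cutoff before a chromosome end or spans an
inter-SNP gap over 200 kb — partial integrals would inflate boundary
scores. The 0.05 cutoff and 200-kb gap rule are the conventional
defaults of haplotype-scan software, made explicit and configurable;
physical distance is used because array data rarely come with a
per-interval genetic map.

iHS runs inside the pooled selected lines on cores with MAF ≥ 0.01
(near-fixed cores are uninformative within a population). One allele
per SNP is assigned as "reference" uniformly at random under a seed —
with no reliable ancestral-allele resource, |iHS| of the randomly
polarized score is the robust choice. Raw ln(iHH_ref/iHH_other)
scores are standardized to mean 0, sd 1 within 20 equal-count
reference-frequency bins (equal-count rather than equal-width so every
bin is estimable; undersized bins merge with a neighbour), and the
absolute standardized score is the window statistic.

XP-EHH compares each selected line against the control line:
population-level EHH (all haplotypes, no allele conditioning) is
integrated for both populations with a shared truncation point — where
the EHH of the two populations combined drops below the cutoff — and
the raw score is ln(iHH_selected/iHH_control), standardized
genome-wide. Windows (same grid) are flagged when the mean |iHS|
exceeds 2.58, or when the mean XP-EHH exceeds +2.58 in *both*
control-vs-selected comparisons with at least six scored SNPs each.
Strongly negative XP-EHH windows — long homozygosity in the control
line — are never flagged: a small control line drifts into long
haplotypes without any selection.

# Regions and consensus

Flagged windows that overlap or exactly abut merge into per-test
regions (the 25-kb grid makes flagged runs overlap; including abutting
windows covers grid-edge cases). The consensus is the set of maximal
intervals covered by regions of at least two distinct tests, reported
as the intersection footprint — conservative coordinates, each listing
all supporting tests. Annotation against user feature intervals (BED)
is a pure half-open interval-overlap join.

# The simulator

`simulateLines()` models the experiment: founder haplotypes drawn per
SNP from a truncated Beta(0.5, 0.5) frequency distribution (a
U-shaped folded site-frequency spectrum), 100 generations of random
mating in a population of 100 diploids to build LD by drift, a split
into one control and two selected lines, then eight discrete
generations in which selected lines retain the top 20% by trait value
(an additive trait: QTL effects times favored-allele dosage plus
N(0, 1) noise) and the control line retains a *random* 20% — the
experimental control herd is also culled, so its effective size also
scales with census. Mating is hermaphroditic random pairing of the
retained parents; gametes recombine as a Poisson crossover process.
Generations are non-overlapping; the pedigree niceties of a real herd
(sire rotation, performance-test timing) affect effective size, not
the correctness of the statistics, and are not modelled.

Two scaling choices keep desk-scale runs faithful where it matters:

* **Genetic length is preserved, not physical length.** Haplotype
  statistics are governed by the genetic scale. The default
  chromosomes are 12 Mb at 4.8 cM/Mb — the ~0.5 Morgan arm of a real
  ~50 Mb autosome compressed 4-fold — with ~1 SNP per 4 kb, a density
  comparable to a high-density array. On a genetically short
  chromosome, EHH plateaus above its cutoff (recent within-line
  coancestry spans the whole chromosome) and most cores become
  invalid; preserving Morgans avoids that artifact.
* **Line censuses of 150/300/300 under 20% retention** give per-line
  effective sizes of roughly 30/60/60 — the control line smallest, in
  the proportions of a real divergent-selection herd — without the
  cost of simulating hundreds of animals per line. The control line's
  smaller Ne is what makes control-vs-selected mean FST exceed
  selected-vs-selected mean FST, the ordering the scan relies on.

QTL are snapped to the nearest simulated SNP whose post-burn-in MAF
lies in [0.01, 0.03], and the favored allele is the minor allele at
the split. A rare allele in a small population is typically young and
rests on a narrow haplotype background, so its rise under selection
leaves the hard-sweep footprint (long shared haplotypes) that iHS and
XP-EHH target; a common standing variant would sweep "softly" across
many backgrounds and leave little EHH signal — a genuine limitation of
haplotype scans, not of the implementation. Monomorphic or
out-of-range QTL are recorded as warnings in the returned truth.

Artifact injection (`injectMissingness()`, `relocateSnps()`) provides
ground truth for the QC stages.

# What the simulations do and do not show

The simulator reproduces drift-generated LD, line structure, truncation
response and missingness/misplacement artifacts. It does not model
genotyping error, array ascertainment bias of SNP frequencies,
mutation after burn-in, sex chromosomes, overlapping generations or
the real herd's pedigree structure. Passing tests therefore
demonstrate the statistical machinery and its calibration under a
faithful generative null and sweep alternative — not performance on
any particular real array.

# Numerical and design choices

* Undefined values (θ at pooled-monomorphic SNPs, r² against a
  monomorphic partner) are excluded, never imputed; windows count only
  scored SNPs.
* Strict inequalities implement every "lower than"/"higher than" rule,
  so threshold-equal cases keep the paper-style semantics (a sample
  with call rate exactly 0.90 is kept; identical window FSTs flag
  nothing).
* All randomness (simulator, reference-allele draws, missingness) is
  governed by explicit integer seeds; a pipeline rerun with the same
  configuration is byte-identical, including `summary.json`.
* Problem sizes used by the test suite and the acceptance script —
  the 6,000-SNP replicate genomes, the 18,000-SNP calibration genome,
  ten replicates per Monte-Carlo check, five planar MDS
  configurations — were chosen once as the smallest sizes at which the
  Monte-Carlo criteria are stable.

# Known limitations

* The FST estimator behind the scan is Weir & Cockerham's θ; if a
  different unequal-sample-size correction is preferred, only the
  `estimator` switch is provided.
* iHS is blind to completed sweeps (cores near fixation are MAF-
  filtered) and gains little from soft sweeps; the consensus rule
  (two of three tests) is the intended safeguard.
* The misplaced-SNP algorithm's "remove the most-flagged SNPs"
  step is ambiguous in the field's descriptions; this implementation
  removes all SNPs tied at the per-chromosome maximum each iteration,
  which is deterministic and terminates, and treats flagged-but-kept
  SNPs as the next iteration's scrutiny list.
* XP-EHH standardization is genome-wide; with very short genomes the
  sweep itself inflates the standard deviation and deflates its own
  score, so simulated genomes should not shrink much below the
  defaults.
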