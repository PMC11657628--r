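---
title: "Models and methods behind divomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind divomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`divomics` compares two populations that diverged under opposite
selection pressure at three molecular levels — SNPs, copy number and DNA
methylation — and integrates the calls over genomic intervals. This
vignette explains the statistical models, the defaults and why they were
chosen, what the synthetic world does and does not emulate, and the
numerical corner cases.

## Coordinates and containers

Internally everything lives in Bioconductor containers: genomes are
`DNAStringSet`, intervals are `GRanges` (1-based, closed), genotypes are a
samples × loci dosage matrix inside a `genotype_table`. BED input/output
(0-based half-open) and VCF (1-based) are converted at the boundary only,
so round trips are exact and half-open boundary semantics are preserved:
abutting BED intervals do not overlap after conversion. Half-missing
diploid calls (`0/.`) are treated as fully missing — the simplest
consistent reading of heterozygous-haploid cleanup — and multi-allelic
VCF records are skipped with a logged count rather than coerced.

## Genotype filters and association

Filters run in a fixed order: samples below the 20% call-rate floor are
dropped first, then loci below 70% call rate or below 2% minor allele
frequency. All thresholds are inclusive ("at least"). The association
statistic is the allelic Pearson chi-squared on the 2×2 table of
alt/ref counts by line, one degree of freedom, **no** continuity
correction — matching the default behaviour of the standard `--assoc`
style allele test. A locus monomorphic after filtering is defined to have
chi-squared 0 and p 1 rather than erroring. Permutation p-values permute
line labels jointly across loci and use the add-one estimator
`(1 + #{chi2_perm >= chi2_obs}) / (1 + n_perm)`; note that they converge
to the *exact conditional* p, which differs from the continuous
chi-squared p by up to half the probability mass at the observed
statistic (the test suite measures this explicitly). The BH step-up is
implemented directly (sorted cumulative minimum) and cross-checked
against an independent reference implementation. LD r² is the squared
Pearson correlation of dosages, i.e. composite LD, because phase is
unknown at these designs.

## Fst, Tajima's D and the selection classes

Per-locus Fst is the Weir–Cockerham (1984) two-population estimator from
the variance components *a*, *b*, *c*; the global value is the
ratio-of-sums Σa/Σ(a+b+c). The estimator may be negative at
low-divergence loci; raw values are reported, and clamping to 0 happens
only inside the classifier. Loci with fewer than two called individuals
in either line get no Fst. Tajima's D is computed per non-overlapping
window (default 10 kb, configurable, since the upstream choice is not
documented) treating genotypes as 2n chromosomes: per-locus allele
frequencies use the available calls, loci with fewer than two called
samples are skipped, and the sample-size constants use the median called
count per window. With complete data the π term is algebraically
identical to the mean pairwise difference over all chromosome pairs,
which is how the tests verify it by brute-force enumeration.

The ten classes are evaluated in their listed order with first match
winning — the categories overlap (Fst = 1 also satisfies Fst > 0.25), and
listing order is the only ordering evidence available — with |D| < 1e-9
treated as exactly 0, and negative Fst clamped to 0 for classification
only.

## CpG gain and loss

A CpG loss (CpG-SNP) requires the reference base to be the C of a
reference CpG with a non-C alternate, or, by strand complement, the G of
a CpG with a non-G alternate; both sides are counted and the strand is
recorded, because reported missense examples include substitutions in the G
position. A novel CpG requires the alternate allele to be C, a reference
G immediately 3′, and a non-C reference base; G-side gains are *not*
counted, since the definition names only C-containing SNPs. The two calls
are mutually exclusive by construction. Enrichment uses the 1/16
uniform-dinucleotide expectancy per category — deliberately
composition-blind, as in the reference analysis — with a 1-df
goodness-of-fit chi-squared on observed vs expected CpG and non-CpG
counts. Fixed-allele detection requires every non-missing call
homozygous (per-line frequency exactly 0 or 1), not a threshold. The
most-frequent-allele-per-line map uses dosage-weighted frequencies with
ties broken toward the reference allele.

## Copy number

The best-window formula inverts the Geary–Hinkley power calculation: a
true ratio r = 2^±0.6 must reach p < 0.001 under the Gaussian
approximation of the Poisson count ratio, evaluated in both directions
and both library orientations, and the largest minimum window is
multiplied by the customary 1.5 enlargement factor. At a 1.05-Gb genome
with 64.9 M vs 60.9 M reads this returns 3,410 bp. Per window, the
statistic is t = (λ_b z − λ_a)/√(λ_b z² + λ_a) with z the raw count
ratio and λ the expected counts under no copy difference, two-sided
normal p-values, zero counts floored at 0.5 and flagged. Significance is
Bonferroni (α/number of windows); adjacent same-direction significant
windows merge. Two deliberate choices in the call-level fold: the
*median* member-window log2 ratio is used (partial windows at segment
boundaries dilute the mean systematically), and it is measured relative
to the genome-wide median log2 ratio. The centering matters because copy
gains add reads to one library only, so library-size normalization
shifts *every* window by the genome-wide copy imbalance (≈ 5% in the
synthetic world); median-centering restores the neutral baseline, and a
planted 8× segment is then labelled a top CNV as intended.

## Differential methylation

The stacked-read filter estimates λ as total reads over genome length
(per sample) and caps identical-start stacks at the largest k with
P(X ≥ k) ≥ 0.001 under Poisson(λ) — equivalently `qpois(0.999, λ)`, floor
1. Reads shorter than 100 bp are extended 3′-ward and clipped at contig
ends. A read increments every 300-bp window it overlaps. The coupling
factor CF is the count of CG dinucleotides fully inside a window; the
normalization divides each sample's counts-per-million by the expected
CPM at that CF, estimated as the pooled mean per integer CF level and
smoothed monotone by isotonic regression (the coverage–CpG-density
dependency the normalization assumes is monotone; missing CF levels are
interpolated). Windows with total raw count below 10 are dropped; the
per-window test is Welch's t on log2(rms + 0.1) — the upstream software's
exact statistic is version-dependent and unstated, so a fully specified
test was preferred; an edgeR-style negative-binomial exact test is a
possible future option, not the default. Significance is raw p ≤ 0.05,
mirroring the reference analysis, with no FDR by default; consequently, with ~3,300 windows
and 30 planted DMRs, most flagged windows are expected false positives
(a false-discovery proportion near 85%). That is an inherent property of
the raw-p rule, not a defect of the test — the null p-values are
verifiably uniform — and it is why the one stated recovery criterion is
about *power* (≥ 60% of planted DMRs recovered), not precision.
Same-direction significant windows merge across gaps of at most 1 bp,
and the CpG count is recomputed on the merged span. Both a density-ratio
(relH-like) and an observed/expected (GoGe-like) CpG enrichment score
are reported because the baseline score formula used upstream is ambiguous.

## The synthetic world

The generator is a stated world, not a tuning knob. Defaults follow the
reference study design where stated: 10 + 7 individuals, background Fst
0.045 (via the Balding–Nichols model, the one-parameter divergence model
matching the reported global Fst), high-Fst loci at F = 0.30, 300-bp
methylation windows, 3-kb promoter flanks, planted copy ratios including
the 8× top-CNV threshold, 30 DMRs at a total log2 fold change of 1.0,
negative-binomial dispersion 0.2 and mean window depth 30 (a realistic
MeDIP depth at which the stated power floor is attainable), 5% missing
genotypes, and a desk-scale 1-Mb genome so absolute window/flank sizes
transfer unchanged. Promoters receive planted CG dinucleotides to at
least twice the background CpG density, with an equal number of other
C/G bases in the same promoter demoted to A/T so the global GC fraction
stays at its configured 0.42. Reads are fixed 50-bp intervals; the
100-bp extension rule therefore still exercises real logic.

What the world does **not** emulate, and what a green test therefore
does not establish: sequencing error and mapping bias (reads are
intervals, not sequences); linkage between loci (sites are independent,
so LD summaries only probe the near-independence scale); and a neutral
coalescent site-frequency spectrum — ancestral frequencies are uniform
and the two lines are structured, so pooled Tajima's D on the default
world is strongly positive (≈ +1.7). The D estimator is instead verified
against exhaustive pairwise-difference enumeration, and its calibration
near zero is checked on input constructed with an exact neutral 1/i
spectrum.

## Integration

Overlap counting is any-overlap (≥ 1 bp) of the smaller set against the
other; the hypergeometric p is the upper tail
P(X ≥ k | N, n_a, n_b). The universe N is not documented for this kind of
test, so by default it is derived as genome length divided by the mean
feature width of the union of both sets and always echoed in the result —
p-values are reproducible only conditional on that choice. Venn cells
assign each feature once, to the cell of its full overlap profile, so
cell counts sum to the number of participating features. DMRs
intersecting any CNV call are flagged as possibly confounded by copy
number. Repeat profiles report, per repeat class, the fraction of
queries overlapping that class, with fold enrichment against caller-
supplied backgrounds (whole-genome tiles and, where available, the
assayed fraction).

## Determinism and numerical corner cases

Every stochastic step derives its stream from the configuration seed
(offset per stage), so identical config + seed gives byte-identical
output files. Degenerate inputs are defined, not errors: monomorphic
loci (chi-squared 0), windows with S = 0 (D undefined), zero-variance
methylation windows (p = 1 when means agree, the numeric floor
otherwise), zero CNV counts (floored at 0.5, flagged, excluded from
top-CNV labelling), empty gene models (everything Distal Intergenic with
a warning), and intervals past a contig end (clipped with a warning).
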