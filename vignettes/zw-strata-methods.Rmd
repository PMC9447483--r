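---
title: "ZWstrata methods: models, generators and numerical conventions"
author: "ZWstrata authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ZWstrata methods: models, generators and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ZWstrata)
```

# Overview

ZWstrata implements the statistical core of a W-chromosome degeneration
study in a ZW system: sex-linkage inference from read depth, strata
dating from gametolog synonymous divergence, repeat refugium and
composition analyses, and W gene-content accounting. Each analysis has a
matching simulation generator with recorded truth, so every estimator in
the package is validated end-to-end in the test suite. This vignette
documents the models, the generator design, the numerical conventions,
and the package's resolutions of points the underlying methods leave
open.

# Sex-linkage from read depth

## Model

Window depths for a female (ZW) and a male (ZZ) sample are normalized by
each sex's autosomal median depth. The statistic is

$$\mathrm{log_2FM} = \log_2\left(\frac{F_\mathrm{norm}}{M_\mathrm{norm}}\right),$$

with expectation 0 for autosomes and pseudoautosomal regions, −1 for the
Z (one female copy vs two male copies), and a large positive value for
the W, bounded in practice by background male mapping to W-like repeat
sequence. `classifyLog2FM()` calls W at `log2FM >= 1`, Z within
`[-1.5, -0.5]`, autosomal within `[-0.25, 0.25]`, else ambiguous.

`classifyIQR()` implements the alternative outlier-fence rule: windows
whose *proportion of female read depth*,
$F_\mathrm{norm}/(F_\mathrm{norm}+M_\mathrm{norm})$, exceeds
Q3 + 1.5×IQR are called W. The proportion (autosomal expectation 0.5, W
expectation near 1) is used rather than the raw female normalized depth,
whose autosomal and W expectations coincide at 1 and which therefore
carries no discriminating signal for this fence.

## Generator

`simulateDepthProfiles()` draws per-window depths from a negative
binomial with mean `meanDepth` times the copy-number multiplier of the
window's class (female: 1, ½, ½ for autosome, Z, W; male: 1, 1,
`maleWBackground`) and dispersion `size = dispersion`.
`maleWBackground = 0.125` by default, so the W expectation is
log2FM = 2, matching the conservative threshold's headroom.
`dispersion = Inf` gives the noise-free limit, used for exact
calibration checks (power 1, false-positive rate 0 for both methods).

The generator is deliberately idealized: it models sampling
overdispersion but not mappability artifacts, collapsed repeats, or
copy-number-variable regions, which in real data inflate the tails of
the autosomal depth distribution. One consequence, verified by
simulation in the test suite, is that under this model the IQR fence is
*more* specific than the log2FM threshold at realistic dispersion,
whereas on real data the published ordering is the reverse: artifact
tails push autosomal windows past the fixed threshold far more often
than past the adaptive fence. The calibration machinery reports both so
the trade-off can be examined on any data set.

# Gametolog divergence and strata dating

## NG86

`ng86Pair()` implements Nei–Gojobori (1986) from first principles.
Synonymous site counts per codon are the sum over positions of the
fraction of possible single-nucleotide changes that preserve the amino
acid; mutations to stop codons count as nonsynonymous possibilities.
For codon pairs differing at $k$ positions, the $k!$ substitution
orderings are enumerated; orderings passing through a stop codon are
excluded and the synonymous/nonsynonymous difference counts are averaged
with equal weight over the surviving orderings (if none survive, all
orderings are used and the pair is flagged). Proportions are corrected
with Jukes–Cantor, $d = -\tfrac34\ln(1-\tfrac43 p)$, undefined
(saturated) at $p \ge 0.75$. The test suite verifies the implementation
against an independent recursive pathway-enumeration oracle to 1e-12 on
1,000 random 200-codon pairs.

Pairs are filtered to `0.001 <= dS <= 2` (`filterPairs()`) **before**
stratum assignment and clustering: near-zero values are dominated by
alignment artifacts and saturating values by correction error, and
either would distort k-means centers and stratum means. This ordering —
filter first, then assign — is the package's resolution of an ambiguity
in the method description.

## Strata assignment and dating

`assignStrata()` bins genes by Z anchor position, either at explicit
breakpoints (fully reproducible, the recommended path) or by 1-D k-means
with 100 restarts and a fixed seed. Stratum labels are positional;
attribute `age_rank` gives the age ordering by mean dS.

The sex-specific rate model (`RateModel`) combines a Z component
`muA * zRatio` and a female-limited W component `muA * femaleFraction`:

* `muA = 2.8e-9`: median ortholog dS (0.94) over twice the
  colubrid–viperid split time (167 Ma) — divergence accrues on both
  branches, hence the factor 2.
* `zRatio = 1.1`: modest male mutation bias on the Z.
* `femaleFraction = 0.25`: the W spends all its history in females,
  which contribute ~¼ of the per-generation mutation input.

`rounding = 2` (default) rounds each component to 2 significant figures
before summing, reproducing the printed arithmetic
3.1e-9 + 0.7e-9 = 3.8e-9; `rounding = NA` returns the exact sum, which
for the squamate 4-fold-degenerate rate 2.4e-9 gives
2.64e-9 + 0.6e-9 = 3.24e-9. Both conventions are exposed because both
appear in practice; results must state which was used. With
`dsToTime()`, dS 0.33 dates to 87 Ma and 102 Ma respectively.

## Gametolog generator

`simulateGametologPairs()` evolves the W copy of a random stop-free
codon sequence by uniform single-nucleotide proposals, accepting
synonymous changes always and nonsynonymous changes with probability
`omega`, discarding stop-creating proposals. The pair's NG86 dS is
tracked incrementally and evolution stops when it reaches `targetDS`,
so realized dS sits at the target up to one substitution's granularity;
pairs that saturate first are flagged, never silently truncated. The
generator is coalescent-free (no within-stratum rate variation, no
indels, no alignment error), which is sufficient for validating the
estimator chain but understates real variance in stratum dS.

# Composition and repeat landscape

`gcContent()` uses unambiguous bases as the denominator; `cpgContent()`
divides CpG dinucleotide counts by the total dinucleotide count of the
sequence (its length minus one, for a gap-free sequence). This
whole-sequence denominator — rather than, say, CG-permissive positions
only — is the package's fixed convention; it is stated here because CpG
"content" has no single standard definition.

`k2pDistance()` implements Kimura's two-parameter distance
$d = -\tfrac12\ln\left[(1-2P-Q)\sqrt{1-2Q}\right]$ from transition (P)
and transversion (Q) proportions against a consensus. With
`cpgCorrect = TRUE`, sites within consensus CpG dinucleotides are
excluded from both numerator and denominator before computing P and Q,
removing the hypermutable-site bias from repeat-age estimates.

`simulateRepeatAnnotation()` places non-overlapping elements per family
and chromosome until class-specific target densities
(`density × enrichment`) are met; `buildGenomeWithRepeats()` splices
family-GC element sequences into an i.i.d. background of specified GC.
`windowComposition()` then recovers per-window GC, CpG and per-family
repeat fractions (same-family overlaps merged; short terminal windows
retained and flagged). `repeatGcAssociation()` reports the Spearman
correlation of family fraction with window GC plus a partial Spearman
controlling CpG and other-repeat content, computed from the inverse of
the rank-correlation matrix; perfectly collinear ranks make the partial
correlation undefined and return `NA` rather than a fabricated value.

# Refugium and gene content

`refugiumIndex()` compares observed repeat counts per chromosome class
to length-proportional expectations,
$RI_c = (\mathrm{obs}_c - \mathrm{exp}_c)/\mathrm{exp}_c$, with a
Pearson chi-square uniformity test (df = classes − 1; small expected
counts trigger a warning, not an error). `toxicityIndex()` contrasts
the heterogametic (2A + Z + W) and homogametic (2A + 2Z) diploid element
loads. `flLtrSummary()` combines counts, percentage shares and RI per
class.

`copyNumber()` estimates per-gene copies as
`2 × depth / autosomal_median` (the factor 2 undoes the haploid-W
normalization in females); `decayRate()` converts Z/W gene deficits to
genes lost per year and is additive over concatenated strata;
`stratumEnrichment()` is a two-sided Fisher exact test;
`expressionFlags()` applies raw-count detection rules per sex with
optional TPM normalization.

# Simulation defaults as study conditions

Generator defaults (`meanDepth = 30`, `dispersion = 10`,
`maleWBackground = 0.125`, `geneLength = 1000`, problem sizes used in
the tests) were fixed from the modeled sequencing design before the
validation suite was run, and are not tuned to test outcomes. Where a
validation result disagrees with published real-data behavior (the
classifier FPR ordering above), the discrepancy is reported as a model
limitation rather than resolved by parameter adjustment.

# Known limitations

* The depth model omits mappability and assembly artifacts; classifier
  error rates from simulation are optimistic and their method ordering
  can differ from real data (see above).
* The codon generator has no indels, no alignment uncertainty and no
  among-site rate variation; recovered stratum variances understate
  reality.
* The NG86 implementation targets the standard genetic code only.
* Repeat simulation draws element sequences i.i.d.; no phylogenetic
  structure within families, so K2P landscapes on simulated data are
  degenerate.
* Real-data summaries from the motivating system (assembly-scale repeat
  content, observed copy-number tables, real dN/dS contrasts) require
  the original assemblies and reads and are outside the desk-scale
  scope; the test suite validates the estimators on generated data
  instead.
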