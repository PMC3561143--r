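---
title: "Shared genomic segment analysis in extended pedigrees: models and methods"
author: "pedSGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared genomic segment analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedSGS)
```

# The problem

Extended high-risk pedigrees — families with significantly more cases of a
disease than population rates predict — are a classical design for mapping
rare, relatively penetrant susceptibility variants.  Cases in such a family
who carry the same risk variant also carry, around it, a chromosomal
segment inherited identically by descent (IBD) from the common ancestor.
With dense SNP genotypes, IBD cannot be observed directly, but it leaves a
footprint: an excessively *long* run of consecutive SNPs at which the cases
share alleles identically by state (IBS).  Shared genomic segment (SGS)
methods scan the genome for such runs and assess them against a
gene-dropping Monte Carlo null.

The central difficulty in common, heterogeneous diseases is
*intra-familial heterogeneity*: even at a true risk locus, several distinct
risk alleles (or sporadic cases) may segregate in one family, so only a
subset of cases share any one risk haplotype.  The all-case SGS statistic
collapses as soon as one case fails to share.  The weighted pairwise
statistic (pSGS) implemented here is designed to stay informative in that
regime.

# Statistics

Genotypes at a biallelic SNP are coded 11, 12, 22.  Two individuals can
share an allele IBS unless they are opposite homozygotes (11 vs 22).
Missing genotypes are treated as heterozygotes — the permissive choice that
never breaks a run — inside the sharing rules only, never in QC.

For the \(N\) genotyped cases of one pedigree:

* **Sharing count** \(S_i = N - \min(N_{11,i}, N_{22,i})\), the number of
  cases sharing at least one allele IBS at SNP \(i\);
  \(\lceil N/2\rceil \le S_i \le N\).
* **Run length** \(R_i(t)\): the number of consecutive SNPs (including
  SNP \(i\)) at which at least \(t\) cases share.  The **SGS statistic**
  is \(R_i(N)\).
* **Pairwise run length** \(R_i^{jk}(2)\): the run length for the case
  pair \((j,k)\).
* **pSGS statistic**: with \(d_{jk}\) the number of meioses separating
  cases \(j\) and \(k\) (siblings 2, first cousins 4),
  \[
    \mathrm{pSGS}_i \;=\;
      \frac{\sum_{j<k} d_{jk}\, R_i^{jk}(2)}{\sum_{j<k} d_{jk}} .
  \]
  Sharing across many meioses is rarer under the null, so distant pairs
  carry more weight.  The statistic is invariant to rescaling the weights,
  and any constant prefactor cancels in the empirical p-values, so this
  weighted-mean normalization is the one the package uses throughout.
* **Two-pedigree statistic**: for cases pooled from pedigrees with no
  known genealogical links there is no meiosis count to weight by, so the
  plain mean of \(R_i^{jk}(2)\) over *all* pairs of the combined case set
  is used.

Run lengths are counted in SNPs, as the empirical null is computed on the
same marker map; regions are additionally reported in Mb.  Runs never span
chromosome boundaries.

# The gene-dropping null

Significance is assessed empirically under a null that preserves the two
structures that inflate IBS runs in the absence of a risk locus: linkage
disequilibrium (LD) between markers, and transmission through the observed
pedigree.

1. **Founder haplotypes** are sampled from an order-\(k\) Markov chain over
   alleles (default \(k = 1\)), estimated from unrelated controls by
   windowed haplotype-frequency EM (for \(k = 1\), classical two-locus EM
   resolving the double-heterozygote phase ambiguity), with a pseudocount
   of 0.5 per haplotype class so no transition is exactly 0 or 1 unless
   the data are monomorphic.  EM starts from linkage-equilibrium
   frequencies and stops when the largest frequency change falls below
   \(10^{-6}\) (at most 500 iterations).  A serial Markov chain is a
   deliberate simplification of a general graphical LD model: it captures
   the dominant adjacent-marker association that drives null run lengths,
   it is fully specifiable from the package's own code, and it can be
   sampled exactly.  Longer-range LD structure is not represented; this is
   the major modelling approximation of the package, and p-values on real
   data inherit it.
2. **Transmission**: each founder receives two sampled haplotypes; each
   non-founder receives one recombinant gamete from each parent.
   Crossovers follow a homogeneous Poisson process at rate 1 per Morgan on
   the sex-averaged cM axis (Haldane model, no interference), chromosomes
   segregate independently, and founders are unrelated (random mating).
3. Genotypes are retained for the cases only, and the chosen statistic is
   recorded at every locus, giving each locus its own null distribution.
   When observed data carry missingness, the observed missingness pattern
   is copied onto each null replicate before the statistic is computed
   (flag `maskFrom`, on by default in the pipeline), so observed and null
   tracks are treated identically under the missing-as-heterozygote rule.

Under this null the classical segment-length laws hold and are verified by
simulation in the test suite: for a pair separated by \(d\) meioses,
maximal IBD segments are approximately Exponential with mean \(1/d\)
Morgans (25 cM for first cousins), and the segment containing a locus at
which the pair is *conditioned* to share is length-biased, approximately
Gamma with mean \(2/d\) Morgans (50 cM for first cousins).  Segment
boundaries on a finite marker grid are attributed to the midpoints between
the last shared marker and its neighbour (chromosome ends when a run
touches them), which makes interior segment lengths unbiased for the
underlying crossover interval.

# Empirical significance

* **Per-locus p-value**: \(p_i = (1 + \#\{\text{null} \ge
  \text{observed}\}) / (1 + n)\).  The add-one correction keeps p-values
  strictly positive; with \(n\) replicates the smallest attainable p is
  \(1/(n+1)\), which sets how deep a scan can resolve.
* **Regions**: maximal runs of consecutive loci with \(p \le \alpha\)
  (nominal \(\alpha = 0.05\)).  Bounds are the bp positions of the first
  and last nominal locus — not midpoints to the flanking loci — and the
  reported length is \((\text{end} - \text{start})/10^6\) rounded to one
  decimal.
* **Genomewide thresholds**: simulate \(G\) null genomes; for each, run
  the full scan against an inner null store, call regions, and record each
  region's p-value (its minimum per-locus p).  Pool and rank the segment
  p-values across genomes: the value at rank \(\mathrm{round}(0.05\,G)\)
  is the genomewide *significant* threshold (0.05 expected findings per
  genome) and rank \(\mathrm{round}(1.0\,G)\) the *suggestive* threshold
  (1 per genome).  By default the same inner store serves all \(G\)
  genomes; full re-simulation per genome is available (`freshInner`) at
  roughly \(G\)-fold cost.
* **\(\mu\) rate**: for an observed region p-value,
  \(\mu = \#\{\text{pooled null segment } p \le p_{\text{obs}}\}/G\) — the
  expected number of equally extreme findings per genome under the null.

Design choices worth stating: the null store is per-locus (each locus is
compared with its own null distribution, since local LD and map density
affect run lengths); the segment p-value used for ranking is the minimum
per-locus p within the segment; ties at the ranking position are resolved
by taking the value at that position of the ascending sort.

# SNP quality control

Four filters, each computed on the unfiltered input (so the retained set
is independent of filter order): differential case/control missingness
(two-sided Fisher exact test, remove at \(p < 10^{-5}\)); overall missing
rate above 5%; minor allele frequency below 1%; and Hardy–Weinberg
disequilibrium (exact conditional test, remove at \(p < 10^{-4}\); a
chi-square variant is available).  MAF and HWE are computed on the
controls only, because pedigree cases are related and would violate the
independence assumptions of both statistics.

# The synthetic-data generator

The generator produces complete, seeded study inputs: a known-parameter
order-1 LD model (per-SNP allele frequencies uniform on [0.1, 0.9];
transitions interpolating between the next SNP's marginal at LD strength 0
and deterministic copying at 1), an evenly spaced genetic/physical map, an
unrelated control panel, and case genotypes with an embedded risk
haplotype.  Defaults emulate a dense-array pedigree study at reduced
scale: 20 chromosomes of 100 SNPs spanning 1.5 Morgans and 100 Mb each,
moderate LD (0.5), 224 controls, and low missingness (0.002) and genotype
error (0.001, symmetric hom/het code flips).

The risk haplotype is a designated founder gamete.  Carrier cases are
forced to inherit it at the risk locus by *conditional transmission
sampling*: each transmission on a carrier's descent path draws its
crossover process unconditionally and flips the whole origin vector when
it fails to deliver the gamete at the locus.  Flipping exchanges the two
conditionings and preserves the crossover law, so this is exactly
equivalent to rejection sampling of transmissions — but remains feasible
for carriers many meioses deep, where plain rejection would need
\(2^{\,\text{depth}}\)-scale retries per carrier.  Drops in which a
non-carrier also inherits the gamete are rejected (a rare event for deep
pedigrees).  Because recombination structure is preserved, the shared
segment around the locus follows its proper length-biased conditioned
distribution, which the test suite verifies against the \(2/d\) law.

What the generator does *not* emulate: long-range and block-structured LD,
population structure and admixture, allele-frequency spectra of real
arrays, phenotype liability models, and sex-specific recombination maps.
Passing tests on synthetic data therefore demonstrate correctness of the
machinery and the statistical behaviour of the method under its own
assumptions — not performance guarantees on any particular real dataset.

## Power-scenario design

The heterogeneity robustness test embeds a risk haplotype carried by 3 of
5 cases and asks the pSGS scan to localize it.  Its settings are chosen
for testability and are worth explaining, because segment methods only
have localization power in a particular regime:

* the conditioned shared segment (mean \(2/d\) Morgans) must be several
  times shorter than the chromosome, or there is nothing to localize;
* background IBS runs (whose genetic length is marker spacing divided by
  the per-SNP probability of an opposite-homozygote break) must be much
  shorter than the conditioned segment, which requires dense markers;
* null IBD sharing per pair (coverage \(\approx 2^{2-d}\) per ancestor
  couple) must be rare, which requires *distant* relatives.

The scenario therefore uses five cases on disjoint depth-5 descent lines
from one founder couple (every pair separated by \(d = 10\) meioses,
within the meiotic range typical of extended high-risk pedigrees), one
2,000-SNP chromosome at 0.1 cM spacing (2 Morgans — array-like density at
reduced scale), LD strength 0.3, and a 999-replicate inner null.  Under
these conditions the weighted pairwise scan's best region covers the
embedded locus in well over 80% of seeded runs while the all-share SGS
scan essentially never does — the heterogeneity robustness that motivates
the pairwise statistic.  At close relationships (first cousins) or sparse
maps the same embedded effect is *not* localizable by either statistic;
that negative result is a property of segment sharing, not of the
implementation.

# Problem sizes

The test suite and the reproduction script run at desk scale, with sizes
chosen so every stochastic check has clear resolution: 2,000 replicates
for the segment-length laws (on 10–20-Morgan chromosomes so end
truncation is negligible), 500 null-as-observed replicates against a
199-replicate inner store for p-value calibration on the default
20-chromosome synthetic genome, 100 random instances for the brute-force
oracle equivalence suite, and 50 seeded runs for the power comparisons.
Threshold machinery is exercised at \(G = 25\) genomes in the unit tests;
the rank rule itself is exact and is checked against constructed pooled
lists, including the \(G = 1{,}000\) ranks (50th and 1,000th) used at
study scale.

# Known limitations

* The Markov LD model understates long-range LD; empirical p-values on
  real data are anti-conservative to the extent that real null IBS runs
  outlast the fitted chain's.  Fitting with a larger `order` is supported
  but costs \(2^k\) in state space and needs correspondingly more
  controls.
* Meiotic distances use the single shortest path; marriage loops and
  inbreeding (multiple connecting paths) are collapsed to the minimum,
  and founder inbreeding is not modelled.
* The X chromosome, sex-specific maps and crossover interference are out
  of scope; all maps are sex-averaged and Haldane.
* Pedigrees with untyped cases or case statuses beyond case/unknown are
  not represented.
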