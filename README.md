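# pedSGS — weighted pairwise shared genomic segment analysis in extended pedigrees

`pedSGS` localizes disease susceptibility loci in extended high-risk
pedigrees from dense SNP genotypes.  Cases who inherit the same risk
variant from a common ancestor also share, around it, a chromosomal
segment identical by descent (IBD); on a dense array that segment shows up
as an excessively long run of consecutive SNPs at which the cases share
alleles identically by state (IBS).  The package scans for such runs,
assesses them against a gene-dropping Monte Carlo null that accounts for
marker linkage disequilibrium (LD) and pedigree transmission, and reports
nominal regions, per-genome false-positive (μ) rates and empirical
genomewide thresholds.

It is aimed at statistical geneticists working with extended pedigrees
(many meioses, a handful of genotyped cases) where genomewide association
has no power for rare variants and classical multipoint linkage struggles
with dense, LD-correlated markers.

## Statistics

With genotypes coded 11/12/22, two cases share an allele IBS unless they
are opposite homozygotes; missing genotypes count as heterozygotes.  For
the N cases of a pedigree, at SNP i:

- sharing count `S_i = N − min(N11_i, N22_i)`;
- all-case **SGS** statistic `R_i(N)`: the run length of consecutive SNPs
  at which all N cases share;
- weighted pairwise **pSGS** statistic, with `d_jk` the meioses separating
  cases j and k and `R_i^jk(2)` the pair's run length:

      pSGS_i = Σ_{j<k} d_jk · R_i^jk(2) / Σ_{j<k} d_jk

  Sharing across more meioses is rarer under the null, so distant pairs
  weigh more.  Because it pools evidence over pairs, pSGS keeps power when
  only a subset of cases carry any one risk haplotype (intra-familial
  heterogeneity), where the all-share SGS statistic collapses.

Null configurations are produced by gene dropping: founder haplotypes
sampled from a Markov LD model fitted to unrelated controls, segregated
through the pedigree with Poisson (Haldane) recombination on a genetic
map.  Per-locus empirical p-values use the add-one rule
`p = (1 + #{null ≥ obs}) / (1 + n)`; regions are maximal runs of loci with
p ≤ 0.05; genomewide suggestive/significant thresholds are the p-values
crossed at rates 1.0/0.05 per genome, read off as rank `round(rate·G)` of
the pooled segment p-values from G null genomes.

See `vignette("pedSGS-methods")` for the full model, the design decisions
and their rationale, and known limitations.

## Worked example

A fully synthetic study: five cases on deep descent lines (all pairs 10
meioses apart), one 2,000-SNP chromosome at 0.1 cM spacing, and a risk
haplotype carried by 3 of the 5 cases.

```r
library(pedSGS)

ped <- linesPedigree(5, 5)       # all case pairs d = 10
cfg <- syntheticConfig(pedigree = ped, nChrom = 1, snpsPerChrom = 2000,
                       mapLengthMorgans = 2, ldStrength = 0.3,
                       carrierFraction = 0.6, seed = 42)
tm       <- generateTruthModel(cfg)
controls <- generateControlPanel(tm$model, tm$map, n = 224, seed = 43)
sim      <- generateCaseGenotypes(ped, tm$model, tm$map, cfg)
sim$truth$riskBp
#> [1] 50251256

model <- fitMarkovLD(controls)        # LD model from the 224 controls
prof  <- sharingProfile(sim$genotypes, ped)
prof
#> SharingProfile: 2000 SNPs, 5 cases, 10 pairs
#>   S range 3-5; max pSGS 93.9; max SGS 15

store   <- simulateNullStatistics(ped, model, tm$map, n = 999,
                                  statistic = "psgs", seed = 44,
                                  maskFrom = genoCodes(sim$genotypes))
p       <- locusPValues(prof, store)
regions <- callRegions(p, tm$map, alpha = 0.05, S = sharingCounts(prof))
best    <- regions[which.max(mcols(regions)$nSnps *
                             (mcols(regions)$bestP ==
                              min(mcols(regions)$bestP)))]
best
#> GRanges object with 1 range and 8 metadata columns:
#>       seqnames            ranges strand |     nSnps  lengthMb     bestP
#>   [1]     chr1 40520760-57260130      * |       339      16.7     0.001
#>        startIdx    endIdx meanSharing minSharing maxSharing
#>   [1]       799      1137     4.67257          3          5
```

The best region (minimum empirical p = 0.001, the floor of a
999-replicate null; 339 SNPs, 16.7 Mb) covers the embedded risk locus at
50.25 Mb.  The sharing summary shows the heterogeneity: on average 4.7 of
5 cases share across the region, but sharing dips to the minimum possible
(3) — exactly the situation in which the all-share SGS scan loses the
locus while the pairwise scan retains it.  `genomewideThresholds()` turns
the same machinery on G null genomes to calibrate suggestive/significant
levels, and `muRate()` converts a region's p-value into expected findings
per genome.  File-based end-to-end runs (QC → LD fit → scan → null →
regions → thresholds → manifest) go through `runConfig()` /
`runFullScan()`, and cross-pedigree overlap analyses through
`runTwoPedigree()`.

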