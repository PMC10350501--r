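---
title: "Methods: SNP-index bulked segregant analysis in bsascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-index bulked segregant analysis in bsascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

# The method

Bulked segregant analysis contrasts pooled allele frequencies between two
phenotypic extreme bulks of a segregating population. `bsascan` implements
the SNP-index formulation for a BC₂F₂ design: a donor parent is crossed to a
recurrent parent, the F1 is backcrossed to the recurrent parent twice, and
one BC₂F₂ selfing generation is phenotyped. At each site where the parents
are opposite homozygotes, the bulk's SNP-index is the donor-allele read
fraction `DepM / (DepM + DepW)` and the ΔSNP-index is the resistant-bulk
index minus the susceptible-bulk index. Under no linkage both indices
estimate the same population allele frequency and Δ is centred at zero;
directional selection on a linked trait locus pushes Δ towards ±1.

Three statistical layers sit on top of the per-site index:

1. **Windowing.** Indices are arithmetically averaged in 1-Mb windows
   advanced in 5-kb steps. Windows are half-open on a 1-based grid
   (`[start, start + window)`), so `end - start` equals the window size and
   merged region coordinates land on the step grid; partial chromosome-end
   windows are kept and flagged. Windows with fewer than `min_sites = 5`
   sites are masked: they are reported but never seed a region, so a single
   noisy marker cannot call a locus. The window mean is computed from
   cumulative sums over the position-sorted sites and is tested against a
   brute-force per-window recomputation.

2. **Null thresholds.** The significance machinery is a Monte-Carlo null
   conditioned on depth, in the style of the standard QTL-seq procedure: a
   segregating site descends from a self of a heterozygous BC₂F₁, so the
   `n = 30` members of a bulk draw donor dosages 1:2:1 (equivalently, the
   bulk's allele count is Binomial(2n, ½)); each bulk's donor read count is
   then Binomial(depth, frequency). The two-sided |Δ| quantiles at the 95,
   99 and 99.9% levels are taken from 10,000 replicates per observed
   (rounded) depth pair. Because the true threshold can only tighten with
   depth, the Monte-Carlo estimates are projected onto a non-increasing
   function of total depth with isotonic regression, removing simulation
   jitter without biasing the level. At depth pair (10, 10) the 95% and 99%
   thresholds agree with exhaustive enumeration of the null to within 0.01.

3. **Region calling.** Unmasked windows whose |mean Δ| exceeds the threshold
   at the requested level are merged when overlapping or within one step of
   each other; a region runs from its first window's start to its last
   window's end, reports the peak Δ, the highest level attained by any
   member window, and its length in Mb rounded **half-up** to two decimals —
   base R's round-half-to-even would turn a 1,055,000-bp region into 1.05 Mb
   instead of the conventional 1.06. HIGH/MODERATE-impact sites inside the
   bounds are attached as the region's effective variants; impact classes
   are consumed from the VCF annotation (SnpEff-style `ANN` or an `IMPACT`
   INFO key), never computed.

A deliberate orientation convention: "M" is always the donor-parent allele,
so an index of 1 means a pure donor signal and Δ > 0 means donor enrichment
in the resistant bulk. Alleles are re-oriented per site from the parental
genotypes, so it does not matter which parent matched the VCF reference.
Both bulks are scored against a single coordinate system; a two-reference
design (each bulk aligned to its own parent's assembly) is not recoverable
from one VCF and is out of scope.

# Read quality control

The cleaning procedure applies seven steps in a fixed order to each read:
(1) 3′ adapter removal; (2) 5′ trimming of bases below Q20 or `N`; (3) 3′
trimming of bases below Q3 or `N`; (4) truncation at the first 4-base window
with mean quality below Q20, scanning 5′→3′; (5) drop if the `N` fraction is
≥ 10%; (6) drop if more than 40% of bases are below Q15; (7) drop if fewer
than 30 bp remain. Phred+33 is assumed throughout.

Where the procedure's prose left room, the package fixes the simplest
reproducible rule and documents it:

* **Adapter matching** is an exact search for the leftmost position at which
  the read's remainder matches a prefix of the adapter (full adapter with
  read-through bases after it, or a 3′ suffix with at least 5 bases of
  overlap). The trim is iterated to a fixpoint so that cleaning a cleaned
  read changes nothing.
* **The 40%-below-Q15 rule** is read as a whole-read drop criterion
  (fraction strictly greater than 0.40), and the N-rate rule drops at
  fraction ≥ 0.10; both are evaluated on the read as it stands after
  trimming, per the step order.
* **Window trimming** truncates at the first failing window rather than
  searching for a best cut point, keeping the step order semantics exact.

The per-cycle report gives base-composition fractions (A/C/G/T/N, summing to
one per cycle) and the mean error rate `10^(-Q/10)` per cycle of the clean
reads. Equivalence with an independently written step-by-step oracle is
asserted on 1,000 fuzzed reads covering mixed quality regimes, planted
adapters and `N` runs.

# Phenotypes and bulk construction

Replicates are averaged per line before any analysis. Trait summaries use
the sample (n−1) SD, the adjusted Fisher–Pearson skewness and the
bias-adjusted excess kurtosis — the conventions of mainstream statistical
packages, matched against an independent implementation to 1e-10. Pearson
correlations on line means carry one-tailed p-values via the t transform
with stars at 0.05 and 0.01; a zero-variance trait renders its pairs
undefined rather than erroring the whole table.

Bulk selection must turn "highest mean values on three traits" into a
deterministic rule. The package ranks lines by the mean of per-trait
z-scores over the selection traits (default shoot fresh weight, shoot dry
weight, root fresh weight), takes the top and bottom `n = 30`, breaks ties
at either cut by line ID, and reports each bulk's realized per-trait ranges
so interval-style reporting of bulk composition is reproducible. The
composite is invariant under any uniform positive affine rescaling of the
traits, and on small instances it provably coincides with exhaustive
subset enumeration (the composite is linear, so the top-n set maximizes
every monotone aggregate).

# What the generator emulates — and what it does not

The synthetic module defines the study conditions the tests run under:

* **Population.** 200 BC₂F₂ lines by default (2,000 for locus-recovery
  experiments), each line descending through its own independently sampled
  pedigree. Gametes follow Haldane's model: Poisson crossover counts with
  mean equal to the map length (1 cM/Mb by default — a typical plant
  genome-wide average; the source design gives no rate) and uniform
  breakpoints. The single-locus BC₂F₂ dosage distribution
  (0.8125, 0.125, 0.0625) and the donor-allele frequency of (1/2)³ = 0.125
  are checked against exact pedigree enumeration.
* **Genome.** Three 2-Mb chromosomes with 400 markers each — big enough for
  hundreds of overlapping windows per chromosome, small enough that the full
  pipeline runs in seconds. Optionally a fraction of markers become indels
  with a planted signed-length spectrum, and markers carry impact classes
  with realistic modifier-heavy proportions.
* **Traits.** Seven seedling traits under salt stress with the observed
  means, SDs and pairwise correlations of the cotton BC₂F₂ study population
  (e.g. shoot fresh weight 7.35 ± 3.67 g, shoot–root dry weight correlation
  0.81); the correlation matrix is positive definite as given (smallest
  eigenvalue 0.066), so it is used unmodified. The planted QTL adds one
  phenotypic SD per donor-allele copy to the three bulking traits — a large
  single locus, as a BSA mapping design presumes. Negative draws of weights
  and lengths are truncated at zero; chlorophyll content is not truncated.
  Replicates add 10% measurement noise around the line value, so line means
  preserve the target moments.
* **Sequencing.** Poisson total depth at 40× per bulk (negative binomial
  optionally), binomial donor-allele counts at the bulk frequency, and a
  symmetric error model: an error flips a read to the other parental
  allele, so the observed frequency is `f(1-e) + (1-f)e` with e = 0.001.
  Parents are emitted as fixed homozygotes.
* **Reads.** Defective FASTQ reads carry at most one planted defect each
  (adapter read-through, central N runs, sub-Q3 3′ tails, half-the-bases
  low quality), so every read's fate under the cleaning procedure is known
  by construction and recorded in a sidecar truth table.

What it deliberately does not emulate: read-level alignment (no SAM/BAM),
homoeologous mapping artifacts of an allotetraploid genome, the
two-reference alignment design, linkage disequilibrium structure beyond the
simulated pedigree, genotyping error in parents, or multi-QTL genetic
architectures. Passing tests therefore demonstrate the statistical
machinery is correct under the stated model, not that real tetraploid
cotton data would behave as cleanly.

# Test and simulation sizes

The suite pins its stochastic checks to fixed seeds and sizes chosen to
keep the full run around a minute: 10,000 lines for the allele-frequency
law; 20 seeds × 2,000 lines, 30-line bulks and 40× depth for locus recovery
(the called 99%-level region must contain the planted QTL in ≥ 90% of
seeds); 20 seeds × 200 lines for null calibration (on average ≤ 5% + 3pp of
unmasked windows exceed the 95% threshold when no QTL exists — in practice
far fewer, because window means pool sites and the per-site null is
conservative for them); 1,000 fuzzed reads for QC equivalence; 10,000
Monte-Carlo replicates per depth pair for thresholds.

# Known limitations

* Thresholds assume every informative site segregates 1:2:1 within bulks
  (heterozygous-BC₂F₁ descent). Sites fixed earlier in the pedigree have
  smaller variance, making the thresholds conservative; this is the
  standard trade-off in QTL-seq-style nulls and the calibration test
  reflects it.
* Window means treat sites as exchangeable; no LOESS smoothing, G-statistic
  or ED⁴ alternatives are provided.
* Multiallelic VCF records are decomposed per alternate allele; a genotype
  involving a third allele becomes missing within a decomposed record
  rather than being phased.
* The adapter trimmer is exact-match only — no mismatches, no paired-end
  overlap rescue — which is adequate for the simulated defects it is
  specified against, not a replacement for a production trimmer.
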