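# bsascan

Bulked segregant analysis (BSA) from pooled short-read sequencing, for
mapping quantitative trait loci in backcross populations — the design used
to localize seedling salt-tolerance loci in cotton introgression lines, but
applicable to any biparental cross where two phenotypic extreme pools and
the two parents have been sequenced.

In BSA, DNA from the most resistant and most susceptible lines of a
segregating population (here BC₂F₂: two backcrosses to the recurrent parent,
then one selfing) is pooled into two bulks. At every site where the parents
carry different alleles, the **SNP-index** of a bulk is the fraction of its
reads carrying the donor-parent allele,

    SNP-index = DepM / (DepM + DepW)

and the **ΔSNP-index** is the difference between the resistant and
susceptible bulks. Away from any trait locus both bulks are random samples
of the population and Δ ≈ 0; near a selected locus the donor allele is
enriched in one bulk and Δ deviates towards ±1. The scan averages the
indices in 1-Mb windows advanced in 5-kb steps, attaches per-depth
significance thresholds simulated from the null (1:2:1 segregation within
each bulk of 30, binomial read sampling at the observed depth), and merges
significant windows into candidate regions reported with their length in Mb
and their HIGH/MODERATE-impact "effective" variants.

The package covers the full desk-side pipeline:

* **simulate** — a BC₂F₂ generator (Haldane recombination model, correlated
  seven-trait seedling phenotypes with a planted QTL, pooled read depths,
  defective FASTQ reads with a truth table) so everything downstream is
  testable without external data;
* **readqc** — the seven-step raw-read cleaning procedure (adapter removal,
  5′/3′ end trimming at Q20/Q3, 4-base Q20 sliding window, N-rate ≥ 10% and
  \>40%-below-Q15 drops, 30-bp length filter) with per-cycle diagnostics;
* **phenotype** — trait summaries (SD, skewness, kurtosis in the SPSS
  conventions), one-tailed Pearson correlation tables, and deterministic
  z-score bulk selection on shoot fresh weight, shoot dry weight and root
  fresh weight;
* **variants** — per-sample summaries from a VCF: transition/transversion
  counts and Ti/Tv, zygosity, signed indel length spectra, impact-class
  tallies;
* **scan** — SNP-index / ΔSNP-index records, window aggregation,
  simulation-based thresholds, candidate-region calling with BED output.

## Worked example

Simulate a 2,000-line BC₂F₂ population with a salt-tolerance QTL on
chromosome 2 (one phenotypic SD per donor-allele copy on the three bulking
traits), select 30-line bulks, draw 40× pooled depths, and scan:

```r
library(bsascan)

gm     <- genome_model(seed = 1)                      # 3 x 2 Mb, 400 markers/chr
pop    <- simulate_cross(gm, n_offspring = 2000, seed = 2)
qtl    <- default_qtl(gm)                             # chr2:1004669
traits <- simulate_traits(pop, qtl, seed = 3)
bulks  <- select_bulks(traits)                        # SFW/SDW/RFW z-score composite

sites  <- simulate_bulk_depths(pop, bulks$resistant, bulks$susceptible,
                               depth_model(mean_depth = 40), qtl = qtl, seed = 4)
rec    <- filter_informative_sites(sites, min_depth = 10)
win    <- sliding_windows(rec, setNames(gm$chromosomes$length, gm$chromosomes$name))
win    <- attach_thresholds(win, null_model(n_bulk = 30, reps = 10000), seed = 5)
call_candidate_regions(win, level = 0.99, sites = rec)
```

Output:

```
bsa_population: 2000 BC2F2 lines, 1200 markers; mean donor-allele frequency 0.124
bulk_selection: 30 lines per bulk on SFW/SDW/RFW
  bulk        trait   min     max
1 resistant   SFW   16.1  23.9
2 susceptible SFW    0     1.20
...
  chrom start     end length_mb peak_delta level_attained n_effective
1  chr2     1 2000001         2  0.825          0.999               0
```

The population's mean donor-allele frequency sits at the BC₂F₂ expectation
(1/2)³ = 0.125; the bulks' trait ranges separate cleanly; and the scan calls
one region at the 99.9% level on the QTL chromosome with a peak ΔSNP-index
of 0.83 — on this toy genome linkage extends across the whole 2-Mb
chromosome, so the region spans it. `length_mb` is the region size in Mb
rounded half-up to two decimals, the same arithmetic that turns the interval
60,120,000–61,980,000 into 1.86 Mb.

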