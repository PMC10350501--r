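# small programmatic fixtures shared across test files

# wrap a dosage matrix as a population without running the cross simulator
make_pop <- function(dosage, genome) {
  structure(list(dosage = dosage, generation = "BC2F2", genome = genome),
            class = "bsa_population")
}

# a long-format variant table from per-site sample specs;
# spec entries: list(gt =, ad_ref =, ad_alt =) keyed by sample name
make_sites <- function(chrom, pos, ref, alt, samples,
                       impact = NA_character_, consequence = NA_character_) {
  cls <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
                ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  dplyr::bind_rows(lapply(names(samples), function(sm) {
    sp <- samples[[sm]]
    tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   class = cls, impact = impact, consequence = consequence,
                   sample = sm, gt = sp$gt,
                   ad_ref = as.integer(sp$ad_ref),
                   ad_alt = as.integer(sp$ad_alt),
                   dp = as.integer(sp$ad_ref + sp$ad_alt))
  }))
}

# windows table with thresholds attached by hand, for region-calling tests;
# ends are the half-open upper bounds, matching sliding_windows()
make_windows <- function(chrom, starts, ends, delta, thr95 = 0.3, thr99 = 0.4,
                         thr999 = 0.5, masked = FALSE) {
  tibble::tibble(chrom = chrom, start = starts, end = ends,
                 n_sites = 10L, index_res = NA_real_, index_sus = NA_real_,
                 delta = delta, dp_res = 40, dp_sus = 40,
                 masked = masked, partial = FALSE,
                 thr_95 = thr95, thr_99 = thr99, thr_99.9 = thr999)
}
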