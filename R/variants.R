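#' Classify a single-base substitution
#'
#' Purine-purine (`A<->G`) and pyrimidine-pyrimidine (`C<->T`) changes are
#' transitions; all purine-pyrimidine changes are transversions. Transitions
#' occur roughly twice as often as transversions in most resequencing data,
#' even though only 4 of the 12 possible substitutions are transitions.
#'
#' @param ref,alt Single bases in `A,C,G,T`, `ref != alt` (vectorized).
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G") # transition
#' classify_substitution("A", "T") # transversion
#' @export
classify_substitution <- function(ref, alt) {
  ok <- c("A", "C", "G", "T")
  bad <- !(ref %in% ok) | !(alt %in% ok)
  if (any(bad)) {
    stop("substitution alleles must be single bases in A,C,G,T; got ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Transition/transversion ratio
#'
#' Ti/Tv rounded half-up to two decimals, the convention used in per-sample
#' variant summary tables.
#'
#' @param transitions,transversions Counts.
#' @return Ratio with two decimals; `NA` when there are no transversions.
#' @examples
#' titv_ratio(1509021, 699275) # 2.16
#' @export
titv_ratio <- function(transitions, transversions) {
  ifelse(transversions > 0,
         round_half_up(transitions / transversions, 2), NA_real_)
}

# rows of the long table carried by a sample (genotype contains the alt allele)
carried <- function(sites, sample) {
  if (!sample %in% sites$sample) {
    if (nrow(sites) == 0) { # empty table: every tally is zero
      s <- sites
      s$het <- logical(0)
      return(s)
    }
    stop("unknown sample: ", sample)
  }
  s <- sites[sites$sample == sample, ]
  al <- strsplit(gsub("\\|", "/", s$gt), "/", fixed = TRUE)
  has_alt <- vapply(al, function(a) any(a == "1"), logical(1))
  genotyped <- !is.na(s$gt) & !(s$gt %in% c("./.", ".", ".|."))
  s$het <- vapply(al, function(a) length(unique(a)) > 1, logical(1))
  s[genotyped & has_alt, ]
}

#' Per-sample variant summary
#'
#' Counts the variants a sample carries (genotype heterozygous or homozygous
#' for the alternate allele): SNP/insertion/deletion counts, the
#' transition/transversion breakdown with its Ti/Tv ratio, and zygosity.
#' Heterozygous plus homozygous always equals the total carried count;
#' transitions plus transversions equals the biallelic SNP count.
#'
#' @param sites Long variant table ([read_variant_vcf()] shape).
#' @param sample Sample name.
#' @return One-row tibble: `sample`, `n_variants`, `n_snp`, `n_ins`, `n_del`,
#'   `transition`, `transversion`, `titv`, `het`, `hom`.
#' @export
sample_summary <- function(sites, sample) {
  s <- carried(sites, sample)
  snp <- s[s$class == "SNP", ]
  cls <- if (nrow(snp) > 0) classify_substitution(snp$ref, snp$alt) else character(0)
  ti <- sum(cls == "transition")
  tv <- sum(cls == "transversion")
  tibble::tibble(sample = sample,
                 n_variants = nrow(s),
                 n_snp = nrow(snp),
                 n_ins = sum(s$class == "INS"),
                 n_del = sum(s$class == "DEL"),
                 transition = ti, transversion = tv,
                 titv = titv_ratio(ti, tv),
                 het = sum(s$het), hom = sum(!s$het))
}

#' Indel length spectrum for one sample
#'
#' Signed length is `nchar(alt) - nchar(ref)`: positive for insertions,
#' negative for deletions. Only indels the sample carries are counted.
#'
#' @param sites Long variant table.
#' @param sample Sample name.
#' @return Tibble `length`/`n`, sorted by signed length, with insertion and
#'   deletion totals in `attr(, "totals")`.
#' @export
indel_length_spectrum <- function(sites, sample) {
  s <- carried(sites, sample)
  s <- s[s$class %in% c("INS", "DEL"), ]
  len <- nchar(s$alt) - nchar(s$ref)
  tab <- table(factor(len, levels = sort(unique(len))))
  out <- tibble::tibble(length = as.integer(names(tab)), n = as.integer(tab))
  attr(out, "totals") <- c(insertions = sum(len > 0), deletions = sum(len < 0))
  out
}

#' Impact-class tally for one sample
#'
#' Counts of carried sites per SnpEff-style impact severity class. Impact is
#' consumed from the annotation, never computed. Sites without an annotation
#' are reported separately as unannotated.
#'
#' @param sites Long variant table with an `impact` column.
#' @param sample Sample name.
#' @return Named integer vector over `HIGH`, `MODERATE`, `LOW`, `MODIFIER`,
#'   with the unannotated count in `attr(, "unannotated")`.
#' @export
impact_tally <- function(sites, sample) {
  s <- carried(sites, sample)
  lv <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  lab <- s$impact[!is.na(s$impact)]
  unknown <- setdiff(unique(lab), lv)
  if (length(unknown) > 0) {
    stop("unrecognized impact label: ", paste(unknown, collapse = ", "))
  }
  out <- vapply(lv, function(x) sum(lab == x, na.rm = TRUE), integer(1))
  attr(out, "unannotated") <- sum(is.na(s$impact))
  out
}

#' Variant summary table for all samples
#'
#' @param sites Long variant table.
#' @return Tibble with one [sample_summary()] row per sample.
#' @export
variant_summary_table <- function(sites) {
  dplyr::bind_rows(lapply(unique(sites$sample), function(sm) {
    sample_summary(sites, sm)
  }))
}
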