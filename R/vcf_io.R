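#' Read a multi-sample VCF into the long variant table
#'
#' Wraps vcfR. Multiallelic records are decomposed into one biallelic record
#' per alternate allele (genotypes involving a third allele become missing
#' for that split record; allelic depths take the ref and that alt's
#' entries). The per-record impact annotation is taken from an `IMPACT=` INFO
#' key or, failing that, from the impact field of a SnpEff `ANN=` string;
#' a `CSQ=` key (or the ANN annotation term) supplies the consequence label.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @return Long tibble: `chrom`, `pos`, `ref`, `alt`, `class`, `impact`,
#'   `consequence`, `sample`, `gt`, `ad_ref`, `ad_alt`, `dp`.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- v@fix[, "INFO"]
  gt_m <- vcfR::extract.gt(v, element = "GT")
  ad_m <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt_m)

  grab <- function(info, key) {
    pat <- paste0("(?:^|;)", key, "=([^;]*)")
    hit <- grepl(pat, info, perl = TRUE)
    out <- rep(NA_character_, length(info))
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(info, regexpr(pat, info, perl = TRUE)))
    out
  }
  impact <- grab(info, "IMPACT")
  csq <- grab(info, "CSQ")
  ann <- grab(info, "ANN")
  use_ann <- is.na(impact) & !is.na(ann)
  if (any(use_ann)) {
    first_ann <- sub(",.*$", "", ann[use_ann])
    parts <- strsplit(first_ann, "|", fixed = TRUE)
    impact[use_ann] <- vapply(parts, function(p) {
      if (length(p) >= 3) p[3] else NA_character_
    }, character(1))
    csq[use_ann] <- vapply(parts, function(p) {
      if (length(p) >= 2) p[2] else NA_character_
    }, character(1))
  }

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    dplyr::bind_rows(lapply(seq_along(alts), function(k) {
      ads <- strsplit(ad_m[i, ], ",", fixed = TRUE)
      ad_ref <- vapply(ads, function(a) {
        if (length(a) >= 1 && !is.na(a[1]) && a[1] != ".") as.integer(a[1]) else NA_integer_
      }, integer(1))
      ad_alt <- vapply(ads, function(a) {
        if (length(a) >= k + 1 && !is.na(a[k + 1]) && a[k + 1] != ".") {
          as.integer(a[k + 1])
        } else NA_integer_
      }, integer(1))
      gt <- remap_gt(gt_m[i, ], k)
      ref <- fix[i, "REF"]
      alt <- alts[k]
      tibble::tibble(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                     ref = ref, alt = alt,
                     class = variant_class(ref, alt),
                     impact = impact[i], consequence = csq[i],
                     sample = samples, gt = unname(gt),
                     ad_ref = unname(ad_ref), ad_alt = unname(ad_alt),
                     dp = unname(ad_ref + ad_alt))
    }))
  })
  dplyr::bind_rows(rows)
}

# genotype of the k-th alt in a decomposed record: alleles equal to k become
# 1, ref stays 0, any other alt allele makes the genotype missing
remap_gt <- function(gt, k) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c("./.", ".", ".|.")) return("./.")
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]]
    if (any(!al %in% c("0", as.character(k), "."))) return("./.")
    paste(ifelse(al == as.character(k), "1", ifelse(al == "0", "0", ".")),
          collapse = "/")
  }, character(1))
}

variant_class <- function(ref, alt) {
  dplyr::case_when(nchar(ref) == 1 & nchar(alt) == 1 ~ "SNP",
                   nchar(alt) > nchar(ref) ~ "INS",
                   nchar(ref) > nchar(alt) ~ "DEL",
                   TRUE ~ "MNP")
}

#' Write the long variant table as a four-sample VCF
#'
#' Emits a VCFv4.2 file with `GT:AD:DP` genotype fields and `IMPACT`/`CSQ`
#' INFO keys for annotated records. One alternate allele per record.
#'
#' @param sites Long variant table ([simulate_bulk_depths()] shape).
#' @param path Output path; written gzip-compressed (use a `.vcf.gz` suffix).
#' @return Invisibly, `path`.
#' @export
write_variant_vcf <- function(sites, path) {
  samples <- unique(sites$sample)
  wide <- sites |>
    dplyr::mutate(field = paste0(.data$gt, ":", .data$ad_ref, ",", .data$ad_alt,
                                 ":", .data$dp)) |>
    tidyr::pivot_wider(id_cols = c("chrom", "pos", "ref", "alt", "impact",
                                   "consequence"),
                       names_from = "sample", values_from = "field") |>
    dplyr::arrange(.data$chrom, .data$pos)
  info <- ifelse(is.na(wide$impact), ".",
                 paste0("IMPACT=", wide$impact,
                        ifelse(is.na(wide$consequence), "",
                               paste0(";CSQ=", wide$consequence))))
  fix <- cbind(CHROM = wide$chrom, POS = as.character(wide$pos), ID = ".",
               REF = wide$ref, ALT = wide$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)
  gt <- cbind(FORMAT = "GT:AD:DP",
              as.matrix(wide[, samples, drop = FALSE]))
  meta <- c("##fileformat=VCFv4.2",
            "##source=bsascan",
            "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Annotation impact class\">",
            "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence label\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
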