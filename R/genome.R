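#' Toy genome model for simulation
#'
#' A lightweight stand-in for a reference genome: a set of chromosomes with
#' biallelic markers at fixed positions. Markers are sites where the donor and
#' recurrent parent carry different alleles; the alt allele is, by convention,
#' the donor allele. Optionally a fraction of markers are made indels (with a
#' planted signed-length spectrum) and each marker can carry a SnpEff-style
#' impact class so downstream summaries have ground truth to recover.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp (recycled across chromosomes).
#' @param markers_per_chrom Markers per chromosome, placed at random distinct
#'   positions (sorted).
#' @param indel_fraction Fraction of markers emitted as insertions/deletions
#'   instead of SNPs.
#' @param indel_lengths Signed lengths (alt minus ref length) to sample indel
#'   markers from; positive = insertion, negative = deletion.
#' @param impact_probs Named probabilities over
#'   `c("HIGH","MODERATE","LOW","MODIFIER")` used to annotate markers, or
#'   `NULL` for no annotation.
#' @param seed Integer seed; marker placement and allele draws are
#'   reproducible.
#' @return An object of class `genome_model`: list with `chromosomes`
#'   (tibble name/length) and `markers` (tibble chrom/pos/ref/alt/class/
#'   impact/consequence).
#' @examples
#' gm <- genome_model(n_chrom = 2, chrom_length = 1e6, markers_per_chrom = 50, seed = 1)
#' head(gm$markers)
#' @export
genome_model <- function(n_chrom = 3, chrom_length = 2e6, markers_per_chrom = 400,
                         indel_fraction = 0, indel_lengths = c(-3:-1, 1:3),
                         impact_probs = NULL, seed = 1) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 1, all(chrom_length >= markers_per_chrom))
  stopifnot(indel_fraction >= 0, indel_fraction <= 1)
  set_sim_seed(seed)
  lens <- rep_len(as.integer(chrom_length), n_chrom)
  chroms <- tibble::tibble(name = paste0("chr", seq_len(n_chrom)), length = lens)
  bases <- c("A", "C", "G", "T")
  markers <- dplyr::bind_rows(lapply(seq_len(n_chrom), function(i) {
    pos <- sort(sample.int(lens[i], markers_per_chrom))
    ref <- sample(bases, markers_per_chrom, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    tibble::tibble(chrom = chroms$name[i], pos = pos, ref = unname(ref), alt = unname(alt))
  }))
  markers$class <- "SNP"
  if (indel_fraction > 0) {
    n_ind <- round(indel_fraction * nrow(markers))
    idx <- sample.int(nrow(markers), n_ind)
    lens_i <- sample(indel_lengths, n_ind, replace = TRUE)
    for (k in seq_along(idx)) {
      j <- idx[k]; L <- lens_i[k]
      anchor <- markers$ref[j]
      pad <- paste(sample(bases, abs(L), replace = TRUE), collapse = "")
      if (L > 0) { # insertion: alt longer than ref
        markers$ref[j] <- anchor
        markers$alt[j] <- paste0(anchor, pad)
        markers$class[j] <- "INS"
      } else {
        markers$ref[j] <- paste0(anchor, pad)
        markers$alt[j] <- anchor
        markers$class[j] <- "DEL"
      }
    }
  }
  if (!is.null(impact_probs)) {
    lv <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
    stopifnot(all(names(impact_probs) %in% lv))
    p <- stats::setNames(rep(0, 4), lv)
    p[names(impact_probs)] <- impact_probs
    markers$impact <- sample(lv, nrow(markers), replace = TRUE, prob = p)
    markers$consequence <- dplyr::case_when(
      markers$impact == "HIGH" ~ "stop_gained",
      markers$impact == "MODERATE" ~ "missense_variant",
      markers$impact == "LOW" ~ "synonymous_variant",
      TRUE ~ "intergenic_region"
    )
  } else {
    markers$impact <- NA_character_
    markers$consequence <- NA_character_
  }
  out <- list(chromosomes = chroms, markers = markers)
  class(out) <- "genome_model"
  out
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,", nrow(x$markers), "markers\n")
  invisible(x)
}

#' Planted QTL specification
#'
#' Describes a single quantitative trait locus: its marker position and the
#' additive shift (per donor-allele copy) it adds to each affected trait.
#'
#' @param chrom Chromosome name.
#' @param pos Marker position in bp; must be a marker of the genome it is used
#'   with.
#' @param effects Named numeric vector of additive effects, names drawn from
#'   the seven seedling traits (`SL`, `RL`, `SFW`, `RFW`, `SDW`, `RDW`,
#'   `CHL`); units are trait units per donor-allele copy.
#' @return An object of class `qtl_spec`.
#' @examples
#' qtl_spec("chr2", 1e6, c(SFW = 3.7, SDW = 0.46, RFW = 1.7))
#' @export
qtl_spec <- function(chrom, pos, effects) {
  stopifnot(is.character(chrom), length(chrom) == 1, length(pos) == 1, pos >= 1)
  stopifnot(length(effects) >= 1, all(names(effects) %in% trait_names()))
  if (all(effects == 0)) stop("qtl_spec: at least one effect must be nonzero")
  structure(list(chrom = chrom, pos = as.integer(pos), effects = effects),
            class = "qtl_spec")
}

#' The seven seedling traits
#'
#' Shoot/root length (cm), shoot/root fresh and dry weight (g), and chlorophyll
#' content (SPAD units), in their conventional order.
#' @return Character vector of the seven trait names.
#' @export
trait_names <- function() c("SL", "RL", "SFW", "RFW", "SDW", "RDW", "CHL")

set_sim_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  invisible(NULL)
}
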