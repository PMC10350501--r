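#' Simulate a BC2F2 backcross population
#'
#' Walks the fixed crossing scheme P1 x P2 -> F1, F1 x P1 -> BC1F1,
#' BC1F1 x P1 -> BC2F1, BC2F1 selfed -> BC2F2, where P1 is the recurrent
#' parent (contributes allele 0 everywhere) and P2 the donor parent (allele 1).
#' Each offspring line descends through its own independently sampled pedigree.
#' Gametes are formed under Haldane's no-interference model: the crossover
#' count per chromosome is Poisson with mean `length_bp * rate_cM_per_Mb / 100
#' / 1e6` (i.e. the map length in Morgans) and breakpoints are uniform along
#' the chromosome.
#'
#' The expected donor-allele frequency at any locus in BC2F2 is
#' (1/2)^3 = 0.125: one halving per backcross gamete plus the F1 gamete;
#' selfing leaves the expectation unchanged.
#'
#' @param genome A [genome_model()].
#' @param n_offspring Number of BC2F2 lines to produce.
#' @param rate_cM_per_Mb Recombination rate; default 1 cM/Mb.
#' @param generation Final generation to return: `"BC2F2"` (default),
#'   `"BC2F1"` or `"BC1F1"` (useful for checking segregation ratios).
#' @param seed Integer seed; the population is reproducible bit-for-bit.
#' @return An object of class `bsa_population`: list with `dosage` (integer
#'   matrix, lines x markers, entries 0/1/2 counting donor-allele copies),
#'   `generation`, and `genome`.
#' @examples
#' gm <- genome_model(n_chrom = 1, chrom_length = 1e6, markers_per_chrom = 20, seed = 1)
#' pop <- simulate_cross(gm, n_offspring = 100, seed = 2)
#' mean(pop$dosage) / 2 # close to 0.125
#' @export
simulate_cross <- function(genome, n_offspring, rate_cM_per_Mb = 1,
                           generation = c("BC2F2", "BC2F1", "BC1F1"), seed = 1) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  generation <- match.arg(generation)
  set_sim_seed(seed)

  mk <- genome$markers
  chroms <- genome$chromosomes
  n <- as.integer(n_offspring)

  # haplotypes are stored per chromosome as n x m 0/1 matrices (donor allele = 1)
  per_chrom <- lapply(seq_len(nrow(chroms)), function(ci) {
    pos <- mk$pos[mk$chrom == chroms$name[ci]]
    m <- length(pos)
    L <- chroms$length[ci]
    zero <- matrix(0L, n, m)
    one <- matrix(1L, n, m)
    # F1: haplotypes (donor, recurrent); gamete -> BC1F1 donor haplotype
    g1 <- meiose(one, zero, pos, L, rate_cM_per_Mb)
    # BC1F1 = (g1, 0); gamete -> BC2F1 donor haplotype
    g2 <- meiose(g1, zero, pos, L, rate_cM_per_Mb)
    if (generation == "BC1F1") return(g1)
    if (generation == "BC2F1") return(g2)
    # selfing: two independent gametes from the same BC2F1 individual
    ga <- meiose(g2, zero, pos, L, rate_cM_per_Mb)
    gb <- meiose(g2, zero, pos, L, rate_cM_per_Mb)
    ga + gb
  })
  dosage <- do.call(cbind, per_chrom)
  rownames(dosage) <- sprintf("L%04d", seq_len(n))
  colnames(dosage) <- paste0(mk$chrom, ":", mk$pos)
  structure(list(dosage = dosage, generation = generation, genome = genome),
            class = "bsa_population")
}

#' @export
print.bsa_population <- function(x, ...) {
  cat("bsa_population:", nrow(x$dosage), x$generation, "lines,",
      ncol(x$dosage), "markers; mean donor-allele frequency",
      signif(mean(x$dosage) / 2, 3), "\n")
  invisible(x)
}

# one meiosis per row: hapA/hapB are n x m 0/1 matrices (the two homologs of
# each of n independent individuals); returns the n x m gamete matrix.
meiose <- function(hapA, hapB, pos, chrom_length, rate_cM_per_Mb) {
  n <- nrow(hapA)
  m <- ncol(hapA)
  morgans <- chrom_length / 1e6 * rate_cM_per_Mb / 100
  nco <- stats::rpois(n, morgans)
  start <- sample.int(2L, n, replace = TRUE) # which homolog leads at the 5' end
  out <- matrix(0L, n, m)
  plain <- nco == 0L
  if (any(plain)) {
    a <- plain & start == 1L
    b <- plain & start == 2L
    out[a, ] <- hapA[a, , drop = FALSE]
    out[b, ] <- hapB[b, , drop = FALSE]
  }
  for (i in which(!plain)) {
    bp <- sort(stats::runif(nco[i], 0, chrom_length))
    seg <- findInterval(pos, bp) # 0-based segment index per marker
    use_a <- ((seg + start[i]) %% 2L) == 0L
    out[i, ] <- ifelse(use_a, hapA[i, ], hapB[i, ])
  }
  out
}

#' Default trait distribution for the seedling phenotypes
#'
#' Means, standard deviations and pairwise Pearson correlations of the seven
#' seedling traits under salt stress, the study conditions the generator
#' emulates: shoot/root length in cm, shoot/root fresh and dry weight in g,
#' chlorophyll content in SPAD units. The implied covariance matrix is
#' positive definite.
#'
#' @return List with `means` (named vector), `sds` (named vector), `corr` and
#'   `cov` (7 x 7 matrices).
#' @export
default_trait_model <- function() {
  tr <- trait_names()
  means <- c(SL = 21.31, RL = 26.94, SFW = 7.35, RFW = 3.42,
             SDW = 0.88, RDW = 0.25, CHL = 36.75)
  sds <- c(SL = 3.46, RL = 4.03, SFW = 3.67, RFW = 1.71,
           SDW = 0.46, RDW = 0.12, CHL = 6.28)
  R <- diag(7)
  dimnames(R) <- list(tr, tr)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("SL", "RL", 0.09); set2("SL", "SFW", 0.641); set2("SL", "RFW", 0.598)
  set2("SL", "SDW", 0.681); set2("SL", "RDW", 0.544); set2("SL", "CHL", 0.052)
  set2("RL", "SFW", 0.272); set2("RL", "RFW", 0.259); set2("RL", "SDW", 0.244)
  set2("RL", "RDW", 0.370); set2("RL", "CHL", 0.183)
  set2("SFW", "RFW", 0.723); set2("SFW", "SDW", 0.929); set2("SFW", "RDW", 0.793)
  set2("SFW", "CHL", 0.165)
  set2("RFW", "SDW", 0.765); set2("RFW", "RDW", 0.867); set2("RFW", "CHL", 0.161)
  set2("SDW", "RDW", 0.812); set2("SDW", "CHL", 0.122)
  set2("RDW", "CHL", 0.230)
  cov <- diag(sds) %*% R %*% diag(sds)
  dimnames(cov) <- list(tr, tr)
  list(means = means, sds = sds, corr = R, cov = cov)
}

#' Default planted QTL
#'
#' A salt-tolerance locus in the middle of chromosome 2 of a genome, with an
#' additive effect of one phenotypic standard deviation per donor-allele copy
#' on the three bulking traits (SFW, SDW, RFW).
#'
#' @param genome A [genome_model()].
#' @return A [qtl_spec()] whose position is the marker closest to the midpoint
#'   of the genome's second chromosome (first if only one).
#' @export
default_qtl <- function(genome) {
  sds <- default_trait_model()$sds
  ci <- min(2, nrow(genome$chromosomes))
  cn <- genome$chromosomes$name[ci]
  mid <- genome$chromosomes$length[ci] / 2
  pos_all <- genome$markers$pos[genome$markers$chrom == cn]
  pos <- pos_all[which.min(abs(pos_all - mid))]
  qtl_spec(cn, pos, c(SFW = sds[["SFW"]], SDW = sds[["SDW"]], RFW = sds[["RFW"]]))
}

#' Simulate correlated seedling traits with a planted QTL
#'
#' Each line's genetic value is `base_means + dosage(qtl) * effects`; a single
#' multivariate-normal draw with covariance `cov` is added per line
#' (line-level biological noise), and each replicate observation adds
#' independent measurement noise with standard deviation
#' `rep_noise_frac * sd(trait)`. Weight and length traits are truncated at 0
#' (they cannot be negative); chlorophyll content is left untruncated.
#'
#' @param pop A [simulate_cross()] population.
#' @param qtl A [qtl_spec()] or `NULL` for no QTL.
#' @param base_means Named per-trait means; default [default_trait_model()].
#' @param cov 7 x 7 trait covariance (symmetric positive semi-definite).
#' @param n_rep Replicates per line (default 3).
#' @param rep_noise_frac Measurement-noise SD as a fraction of each trait's SD
#'   (default 0.1).
#' @param seed Integer seed.
#' @return Tibble with columns `line`, `replicate`, and the seven traits.
#' @export
simulate_traits <- function(pop, qtl = NULL, base_means = NULL, cov = NULL,
                            n_rep = 3, rep_noise_frac = 0.1, seed = 1) {
  stopifnot(inherits(pop, "bsa_population"))
  tm <- default_trait_model()
  base_means <- base_means %||% tm$means
  cov <- cov %||% tm$cov
  tr <- trait_names()
  stopifnot(setequal(names(base_means), tr), all(dim(cov) == c(7, 7)))
  if (is.null(dimnames(cov))) dimnames(cov) <- list(tr, tr)
  if (max(abs(cov - t(cov))) > 1e-8) stop("trait covariance must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("trait covariance must be positive semi-definite")
  set_sim_seed(seed)

  n <- nrow(pop$dosage)
  base <- matrix(base_means[tr], n, 7, byrow = TRUE, dimnames = list(NULL, tr))
  if (!is.null(qtl)) {
    key <- paste0(qtl$chrom, ":", qtl$pos)
    if (!key %in% colnames(pop$dosage)) {
      stop("QTL position ", key, " is not a marker of this population's genome")
    }
    d <- pop$dosage[, key]
    eff <- stats::setNames(rep(0, 7), tr)
    eff[names(qtl$effects)] <- qtl$effects
    base <- base + outer(d, eff)
  }
  noise <- MASS::mvrnorm(n, mu = rep(0, 7), Sigma = cov[tr, tr])
  line_vals <- base + noise

  rep_sd <- rep_noise_frac * sqrt(diag(cov[tr, tr]))
  dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
    obs <- line_vals + matrix(stats::rnorm(n * 7, sd = rep(rep_sd, each = n)), n, 7)
    trunc_tr <- setdiff(tr, "CHL")
    obs[, trunc_tr] <- pmax(obs[, trunc_tr], 0)
    dplyr::bind_cols(
      tibble::tibble(line = rownames(pop$dosage), replicate = r),
      tibble::as_tibble(obs)
    )
  }))
}

#' Read-depth model for pooled sequencing
#'
#' @param mean_depth Mean reads per site per bulk (default 40).
#' @param error_rate Per-base sequencing error rate; an error flips a read's
#'   allele to the other parental allele, so the observed donor frequency is
#'   `f * (1 - e) + (1 - f) * e`.
#' @param overdispersed If `TRUE`, depths are negative-binomial instead of
#'   Poisson.
#' @param dispersion Negative-binomial size parameter when overdispersed.
#' @return An object of class `depth_model`.
#' @export
depth_model <- function(mean_depth = 40, error_rate = 0.001,
                        overdispersed = FALSE, dispersion = 5) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 overdispersed = overdispersed, dispersion = dispersion),
            class = "depth_model")
}

#' Simulate pooled read depths for two bulks and the parents
#'
#' For each marker the bulk's true donor-allele frequency is the mean donor
#' dosage over its members divided by two. Total depth is Poisson (or
#' negative-binomial) around the model's mean depth; the donor-allele read
#' count is binomial at the error-adjusted frequency. The two parents are
#' emitted as fixed homozygotes (recurrent `0/0`, donor `1/1`) with their own
#' simulated depths. The result is a four-sample variant table in long format
#' (samples `P1`, `P2`, `bulk_res`, `bulk_sus`), the same shape
#' [read_variant_vcf()] produces.
#'
#' @param pop A [simulate_cross()] population.
#' @param res_ids,sus_ids Line IDs of the resistant and susceptible bulks;
#'   disjoint, nonempty, all present in `pop`.
#' @param dm A [depth_model()].
#' @param qtl Optional [qtl_spec()], used only to flag the QTL marker in the
#'   truth table.
#' @param seed Integer seed.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `impact`, `consequence`, `sample`, `gt`, `ad_ref`, `ad_alt`, `dp`. The
#'   per-marker ground truth (true donor frequency per bulk, QTL flag) is
#'   attached as `attr(, "truth")`.
#' @export
simulate_bulk_depths <- function(pop, res_ids, sus_ids, dm = depth_model(),
                                 qtl = NULL, seed = 1) {
  stopifnot(inherits(pop, "bsa_population"), inherits(dm, "depth_model"))
  if (length(res_ids) == 0 || length(sus_ids) == 0) stop("bulks must be nonempty")
  if (length(intersect(res_ids, sus_ids)) > 0) stop("bulks must be disjoint")
  missing_ids <- setdiff(c(res_ids, sus_ids), rownames(pop$dosage))
  if (length(missing_ids) > 0) {
    stop("bulk members absent from population: ", paste(missing_ids, collapse = ", "))
  }
  set_sim_seed(seed)

  mk <- pop$genome$markers
  m <- nrow(mk)
  f_res <- colMeans(pop$dosage[res_ids, , drop = FALSE]) / 2
  f_sus <- colMeans(pop$dosage[sus_ids, , drop = FALSE]) / 2
  e <- dm$error_rate

  draw_depth <- function(m) {
    if (dm$overdispersed) {
      stats::rnbinom(m, size = dm$dispersion, mu = dm$mean_depth)
    } else {
      stats::rpois(m, dm$mean_depth)
    }
  }
  one_sample <- function(sample, f_true, fixed_gt = NULL) {
    dp <- draw_depth(m)
    f_obs <- f_true * (1 - e) + (1 - f_true) * e
    ad_alt <- stats::rbinom(m, dp, f_obs)
    ad_ref <- dp - ad_alt
    gt <- if (!is.null(fixed_gt)) rep(fixed_gt, m) else {
      frac <- ifelse(dp > 0, ad_alt / dp, NA_real_)
      dplyr::case_when(is.na(frac) ~ "./.",
                       frac <= 0.1 ~ "0/0",
                       frac >= 0.9 ~ "1/1",
                       TRUE ~ "0/1")
    }
    dplyr::bind_cols(
      tibble::as_tibble(mk[, c("chrom", "pos", "ref", "alt", "class", "impact", "consequence")]),
      tibble::tibble(sample = sample, gt = gt,
                     ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt),
                     dp = as.integer(dp))
    )
  }

  out <- dplyr::bind_rows(
    one_sample("P1", rep(0, m), fixed_gt = "0/0"),
    one_sample("P2", rep(1, m), fixed_gt = "1/1"),
    one_sample("bulk_res", f_res),
    one_sample("bulk_sus", f_sus)
  )
  truth <- tibble::tibble(chrom = mk$chrom, pos = mk$pos,
                          f_res = unname(f_res), f_sus = unname(f_sus),
                          is_qtl = FALSE)
  if (!is.null(qtl)) {
    truth$is_qtl <- truth$chrom == qtl$chrom & truth$pos == qtl$pos
  }
  attr(out, "truth") <- truth
  out
}
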