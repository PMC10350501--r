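# "thr_95", "thr_99", "thr_99.9" for levels 0.95, 0.99, 0.999
thr_col_name <- function(levels) {
  paste0("thr_", vapply(levels * 100, function(x) format(x, trim = TRUE),
                        character(1)))
}

#' SNP-index of a bulk at one site
#'
#' Fraction of reads carrying the donor (mutant-parent) allele:
#' `DepM / (DepM + DepW)`. An index of 1 means every read in the pool carries
#' the donor allele, 0 means none does, and 0.5 means both parental alleles
#' contributed equally.
#'
#' @param dep_m Reads carrying the donor allele (vectorized).
#' @param dep_w Reads carrying the recurrent (wild) allele.
#' @return Numeric index in `[0, 1]`; `NA` where total depth is zero (such
#'   sites are skipped by the scan).
#' @examples
#' snp_index(20, 20) # 0.5
#' snp_index(7, 0) # 1
#' @export
snp_index <- function(dep_m, dep_w) {
  if (any(dep_m < 0 | dep_w < 0, na.rm = TRUE)) stop("depths must be non-negative")
  tot <- dep_m + dep_w
  ifelse(tot > 0, dep_m / tot, NA_real_)
}

#' Delta SNP-index
#'
#' Difference of the SNP-indices of the resistant and susceptible bulks at a
#' site or window. Under the null (no linked locus) it is centered at 0; near
#' a trait locus it deviates towards +1 (donor allele enriched in the
#' resistant bulk) or -1.
#'
#' @param index_res,index_sus SNP-indices in `[0, 1]`.
#' @return `index_res - index_sus`, in `[-1, 1]`.
#' @examples
#' delta_snp_index(1, 0) # 1
#' @export
delta_snp_index <- function(index_res, index_sus) {
  if (any(index_res < 0 | index_res > 1 | index_sus < 0 | index_sus > 1,
          na.rm = TRUE)) {
    stop("SNP-indices must lie in [0, 1]")
  }
  index_res - index_sus
}

#' Filter to informative sites and compute per-site indices
#'
#' Keeps sites where the two parents are opposite homozygotes (the only sites
#' at which bulk allele frequencies are informative about parental origin)
#' and where both bulks reach the minimum total depth. Alleles are oriented
#' so that "M" is the donor parent's allele regardless of which of ref/alt it
#' is in the VCF.
#'
#' @param sites Long variant table ([read_variant_vcf()] /
#'   [simulate_bulk_depths()] shape).
#' @param min_depth Minimum per-bulk total depth (default 10).
#' @param donor,recurrent,res_bulk,sus_bulk Sample names.
#' @return Tibble of SNP-index records: `chrom`, `pos`, `ref`, `alt`,
#'   `class`, `impact`, `consequence`, donor/wild depths per bulk
#'   (`dep_m_res`, `dep_w_res`, `dep_m_sus`, `dep_w_sus`), `dp_res`,
#'   `dp_sus`, `index_res`, `index_sus`, `delta`. Drop reasons are tallied in
#'   `attr(, "dropped")`.
#' @export
filter_informative_sites <- function(sites, min_depth = 10,
                                     donor = "P2", recurrent = "P1",
                                     res_bulk = "bulk_res", sus_bulk = "bulk_sus") {
  need <- c(donor, recurrent, res_bulk, sus_bulk)
  have <- unique(sites$sample)
  if (!all(need %in% have)) {
    stop("samples missing from variant table: ",
         paste(setdiff(need, have), collapse = ", "))
  }
  wide <- sites |>
    dplyr::filter(.data$sample %in% need) |>
    tidyr::pivot_wider(id_cols = c("chrom", "pos", "ref", "alt", "class",
                                   "impact", "consequence"),
                       names_from = "sample",
                       values_from = c("gt", "ad_ref", "ad_alt"))
  g_d <- wide[[paste0("gt_", donor)]]
  g_r <- wide[[paste0("gt_", recurrent)]]
  hom <- function(g) !is.na(g) & g %in% c("0/0", "1/1", "0|0", "1|1")
  missing_parent <- is.na(g_d) | is.na(g_r) | g_d %in% c("./.", ".") |
    g_r %in% c("./.", ".")
  informative <- !missing_parent & hom(g_d) & hom(g_r) &
    substr(g_d, 1, 1) != substr(g_r, 1, 1)

  donor_is_alt <- substr(g_d, 1, 1) == "1"
  ad_alt_res <- wide[[paste0("ad_alt_", res_bulk)]]
  ad_ref_res <- wide[[paste0("ad_ref_", res_bulk)]]
  ad_alt_sus <- wide[[paste0("ad_alt_", sus_bulk)]]
  ad_ref_sus <- wide[[paste0("ad_ref_", sus_bulk)]]
  dep_m_res <- ifelse(donor_is_alt, ad_alt_res, ad_ref_res)
  dep_w_res <- ifelse(donor_is_alt, ad_ref_res, ad_alt_res)
  dep_m_sus <- ifelse(donor_is_alt, ad_alt_sus, ad_ref_sus)
  dep_w_sus <- ifelse(donor_is_alt, ad_ref_sus, ad_alt_sus)
  dp_res <- dep_m_res + dep_w_res
  dp_sus <- dep_m_sus + dep_w_sus
  deep <- !is.na(dp_res) & !is.na(dp_sus) & dp_res >= min_depth & dp_sus >= min_depth

  keep <- informative & deep
  dropped <- tibble::tibble(
    reason = c("missing_parent", "non_informative", "depth"),
    n = c(sum(missing_parent),
          sum(!missing_parent & !informative),
          sum(informative & !deep))
  )
  idx_res <- snp_index(dep_m_res[keep], dep_w_res[keep])
  idx_sus <- snp_index(dep_m_sus[keep], dep_w_sus[keep])
  out <- tibble::tibble(
    chrom = wide$chrom[keep], pos = wide$pos[keep],
    ref = wide$ref[keep], alt = wide$alt[keep], class = wide$class[keep],
    impact = wide$impact[keep], consequence = wide$consequence[keep],
    dep_m_res = dep_m_res[keep], dep_w_res = dep_w_res[keep],
    dep_m_sus = dep_m_sus[keep], dep_w_sus = dep_w_sus[keep],
    dp_res = dp_res[keep], dp_sus = dp_sus[keep],
    index_res = idx_res, index_sus = idx_sus
  )
  out$delta <- delta_snp_index(out$index_res, out$index_sus)
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "dropped") <- dropped
  out
}

#' Sliding-window aggregation of SNP-index records
#'
#' Windows of `window` bp advanced by `step` bp along each chromosome,
#' half-open: a window starting at `start` (1, 1+step, ...) covers positions
#' `start` to `end - 1`, so `end - start` equals the window size and region
#' coordinates land on the step grid. Per window the arithmetic mean of the
#' two indices, of delta and of the bulk depths is taken over contained
#' sites. Windows with fewer than `min_sites` sites are kept but masked
#' (excluded from region calling); chromosome-end partial windows (truncated
#' at the chromosome boundary) are retained and flagged.
#'
#' @param records [filter_informative_sites()] output.
#' @param chrom_lengths Named vector of chromosome lengths in bp; inferred
#'   from the largest position per chromosome when `NULL`.
#' @param window Window size in bp (default 1 Mb).
#' @param step Step size in bp (default 5 kb); must not exceed `window`.
#' @param min_sites Minimum sites per unmasked window (default 5).
#' @return Tibble: `chrom`, `start`, `end`, `n_sites`, `index_res`,
#'   `index_sus`, `delta`, `dp_res`, `dp_sus`, `masked`, `partial`.
#' @export
sliding_windows <- function(records, chrom_lengths = NULL,
                            window = 1e6, step = 5000, min_sites = 5) {
  if (window < step) stop("window must be >= step")
  chroms <- unique(records$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cn) {
      max(records$pos[records$chrom == cn])
    }, numeric(1))
  }
  dplyr::bind_rows(lapply(chroms, function(cn) {
    r <- records[records$chrom == cn, ]
    r <- r[order(r$pos), ]
    L <- chrom_lengths[[cn]]
    starts <- seq(1, L, by = step)
    ends <- pmin(starts + window, L + 1) # exclusive upper bounds
    # cumulative sums over sorted sites make each window O(log n)
    cs <- function(v) cumsum(c(0, v))
    S_res <- cs(r$index_res); S_sus <- cs(r$index_sus); S_d <- cs(r$delta)
    S_dpr <- cs(r$dp_res); S_dps <- cs(r$dp_sus)
    lo <- findInterval(starts - 1, r$pos)
    hi <- findInterval(ends - 1, r$pos)
    n <- hi - lo
    avg <- function(S) ifelse(n > 0, (S[hi + 1] - S[lo + 1]) / n, NA_real_)
    tibble::tibble(chrom = cn, start = as.integer(starts), end = as.integer(ends),
                   n_sites = n,
                   index_res = avg(S_res), index_sus = avg(S_sus),
                   delta = avg(S_d), dp_res = avg(S_dpr), dp_sus = avg(S_dps),
                   masked = n < min_sites,
                   partial = starts + window > L + 1)
  }))
}

#' Null model for significance thresholds
#'
#' The bulk-sequencing null for a BC2F2 population: every segregating site
#' descends from a self of a heterozygous BC2F1, so the `n` individuals of a
#' bulk carry donor dosages drawn 1:2:1; the bulk allele frequency is the mean
#' dosage over the bulk divided by two, and each bulk's donor read count is
#' binomial at that frequency given the observed depth. Both bulks are drawn
#' from the same null (no selection), so delta is centered at zero.
#'
#' @param n_bulk Individuals per bulk (default 30).
#' @param reps Monte-Carlo replicates (>= 1000; default 10000).
#' @param levels Significance levels (default 95%, 99%, 99.9%).
#' @return An object of class `null_model`.
#' @export
null_model <- function(n_bulk = 30, reps = 10000, levels = c(0.95, 0.99, 0.999)) {
  stopifnot(n_bulk >= 1, reps >= 1000, all(levels > 0 & levels < 1))
  structure(list(n_bulk = n_bulk, reps = reps, levels = sort(levels)),
            class = "null_model")
}

#' Simulation-based |delta| thresholds per depth pair
#'
#' For each observed (resistant depth, susceptible depth) pair, simulates the
#' null distribution of delta and takes the two-sided `|delta|` quantile at
#' each significance level. Thresholds are then made monotone non-increasing
#' in total depth by isotonic smoothing (deeper windows can only have tighter
#' nulls; Monte-Carlo jitter is projected out).
#'
#' @param nm A [null_model()].
#' @param depth_pairs Tibble/data.frame with columns `dp_res`, `dp_sus`
#'   (rounded to integers internally).
#' @param seed Integer seed.
#' @return Tibble: `dp_res`, `dp_sus`, one `thr_<level>` column per level
#'   (e.g. `thr_95`, `thr_99`, `thr_99.9`). Zero-depth pairs get `NA`
#'   thresholds.
#' @export
null_thresholds <- function(nm, depth_pairs, seed = 1) {
  stopifnot(inherits(nm, "null_model"))
  set_sim_seed(seed)
  pairs <- tibble::tibble(dp_res = round(depth_pairs$dp_res),
                          dp_sus = round(depth_pairs$dp_sus)) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$dp_res + .data$dp_sus, .data$dp_res)
  thr_names <- thr_col_name(nm$levels)
  qs <- matrix(NA_real_, nrow(pairs), length(nm$levels),
               dimnames = list(NULL, thr_names))
  two_n <- 2 * nm$n_bulk
  for (i in seq_len(nrow(pairs))) {
    d1 <- pairs$dp_res[i]; d2 <- pairs$dp_sus[i]
    if (is.na(d1) || is.na(d2) || d1 <= 0 || d2 <= 0) next
    f1 <- stats::rbinom(nm$reps, two_n, 0.5) / two_n
    f2 <- stats::rbinom(nm$reps, two_n, 0.5) / two_n
    idx1 <- stats::rbinom(nm$reps, d1, f1) / d1
    idx2 <- stats::rbinom(nm$reps, d2, f2) / d2
    qs[i, ] <- stats::quantile(abs(idx1 - idx2), probs = nm$levels, names = FALSE)
  }
  # isotonic projection: thresholds non-increasing in total depth
  tot <- pairs$dp_res + pairs$dp_sus
  ok <- !is.na(qs[, 1]) & !is.na(tot)
  if (sum(ok) > 1) {
    o <- order(tot[ok])
    for (j in seq_along(nm$levels)) {
      v <- qs[ok, j]
      v[o] <- -stats::isoreg(seq_along(o), -v[o])$yf
      qs[ok, j] <- v
    }
  }
  dplyr::bind_cols(pairs, tibble::as_tibble(qs))
}

#' Attach null thresholds to scan windows
#'
#' Convenience wrapper: computes [null_thresholds()] at the windows' rounded
#' mean depth pairs and joins them on.
#'
#' @param windows [sliding_windows()] output.
#' @param nm A [null_model()].
#' @param seed Integer seed.
#' @return `windows` with one `thr_<level>` column per level.
#' @export
attach_thresholds <- function(windows, nm = null_model(), seed = 1) {
  thr <- null_thresholds(nm, windows[, c("dp_res", "dp_sus")], seed = seed)
  windows$dp_res_r <- round(windows$dp_res)
  windows$dp_sus_r <- round(windows$dp_sus)
  out <- dplyr::left_join(windows, thr,
                          by = c(dp_res_r = "dp_res", dp_sus_r = "dp_sus"))
  out$dp_res_r <- NULL
  out$dp_sus_r <- NULL
  out
}

#' Call candidate regions from significant windows
#'
#' A window is significant at the requested level when it is unmasked and
#' `|delta|` exceeds its null threshold. Significant windows on the same
#' chromosome are merged when overlapping or within one step of each other;
#' the region runs from the first merged window's start to the last one's
#' end. Region length is reported in Mb (half-up, two decimals). When a site
#' table is supplied, HIGH/MODERATE-impact sites inside each region are
#' attached as its effective variants.
#'
#' @param windows [attach_thresholds()] output.
#' @param level Significance level to call at (must be one of the threshold
#'   levels; default 0.99).
#' @param sites Optional site table with `chrom`, `pos`, `impact` (and
#'   `consequence`) columns, e.g. [filter_informative_sites()] output.
#' @param step Step size used to build the windows (default 5000).
#' @return Tibble of regions: `chrom`, `start`, `end`, `length_mb`,
#'   `n_windows`, `peak_delta`, `level_attained`, `n_effective`, and
#'   `effective` (list-column of effective-variant tibbles). Empty when
#'   nothing is significant.
#' @export
call_candidate_regions <- function(windows, level = 0.99, sites = NULL,
                                   step = 5000) {
  thr_col <- thr_col_name(level)
  if (!thr_col %in% names(windows)) {
    stop("no thresholds at level ", level, " (looked for column ", thr_col, ")")
  }
  lev_cols <- grep("^thr_", names(windows), value = TRUE)
  lev_vals <- as.numeric(sub("thr_", "", lev_cols)) / 100
  w <- windows
  w$sig <- !w$masked & !is.na(w[[thr_col]]) & abs(w$delta) > w[[thr_col]]

  empty <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), length_mb = numeric(0),
                          n_windows = integer(0), peak_delta = numeric(0),
                          level_attained = numeric(0), n_effective = integer(0),
                          effective = list())
  sw <- w[w$sig, ]
  if (nrow(sw) == 0) return(empty)

  out <- dplyr::bind_rows(lapply(unique(sw$chrom), function(cn) {
    s <- sw[sw$chrom == cn, ]
    s <- s[order(s$start), ]
    grp <- cumsum(c(1, as.integer(s$start[-1] > utils::head(s$end, -1) + step)))
    dplyr::bind_rows(lapply(split(s, grp), function(g) {
      attained <- 0
      for (j in order(lev_vals)) {
        pass <- any(!is.na(g[[lev_cols[j]]]) & abs(g$delta) > g[[lev_cols[j]]])
        if (pass) attained <- lev_vals[j]
      }
      tibble::tibble(chrom = cn,
                     start = min(g$start), end = max(g$end),
                     length_mb = region_length_mb(min(g$start), max(g$end)),
                     n_windows = nrow(g),
                     peak_delta = g$delta[which.max(abs(g$delta))],
                     level_attained = attained)
    }))
  }))
  out$n_effective <- 0L
  out$effective <- vector("list", nrow(out))
  if (!is.null(sites) && "impact" %in% names(sites)) {
    for (i in seq_len(nrow(out))) {
      eff <- sites[sites$chrom == out$chrom[i] &
                     sites$pos >= out$start[i] & sites$pos <= out$end[i] &
                     !is.na(sites$impact) &
                     sites$impact %in% c("HIGH", "MODERATE"), , drop = FALSE]
      keep_cols <- intersect(c("chrom", "pos", "ref", "alt", "class",
                               "impact", "consequence", "delta"), names(eff))
      out$effective[[i]] <- tibble::as_tibble(eff[, keep_cols])
      out$n_effective[i] <- nrow(eff)
    }
  }
  out
}

#' Write candidate regions as BED
#'
#' Region coordinates are 1-based half-open, so BED's 0-based half-open
#' interval is `[start - 1, end - 1)`.
#'
#' @param regions [call_candidate_regions()] output.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end - 1L,
                    name = sprintf("region_%d_%.2fMb", seq_len(nrow(regions)),
                                   regions$length_mb),
                    score = round(1000 * abs(regions$peak_delta)),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plot the delta SNP-index scan
#'
#' One panel per chromosome: window mean delta with the null threshold band
#' and called regions shaded. Requires ggplot2.
#'
#' @param windows [attach_thresholds()] output.
#' @param regions Optional [call_candidate_regions()] output.
#' @param level Level whose threshold to draw (default 0.99).
#' @return A ggplot object.
#' @export
plot_scan <- function(windows, regions = NULL, level = 0.99) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_scan needs ggplot2")
  }
  thr_col <- thr_col_name(level)
  w <- windows[!windows$masked, ]
  p <- ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                       y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data[[thr_col]]),
                       colour = "firebrick", linetype = 2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = -.data[[thr_col]]),
                       colour = "firebrick", linetype = 2, na.rm = TRUE) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta ~ "SNP-index")) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -1, ymax = 1, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}
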