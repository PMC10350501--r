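#' Summary statistics for one trait
#'
#' Mean, minimum, maximum, sample SD, skewness and excess kurtosis. Skewness
#' is the adjusted Fisher-Pearson coefficient and kurtosis the bias-adjusted
#' excess estimator, i.e. the conventions mainstream statistics packages
#' (SPSS, SAS, Excel) report:
#' \deqn{g_1 \frac{\sqrt{n(n-1)}}{n-2}, \qquad
#'   \frac{n(n+1)}{(n-1)(n-2)(n-3)} \sum z_i^4 - \frac{3(n-1)^2}{(n-2)(n-3)}}
#' Skewness needs n >= 3 and kurtosis n >= 4 (and nonzero SD); otherwise the
#' statistic is `NA`.
#'
#' @param values Numeric vector (replicate or line means of one trait).
#' @return Tibble with one row: `n`, `mean`, `minimum`, `maximum`, `sd`,
#'   `skewness`, `kurtosis`.
#' @examples
#' summarize_trait(c(1, 2, 3))
#' @export
summarize_trait <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n == 0) stop("summarize_trait: no non-missing values")
  m <- mean(x)
  s <- if (n >= 2) stats::sd(x) else NA_real_
  skew <- kurt <- NA_real_
  if (!is.na(s) && s > 0) {
    z <- (x - m) / s
    if (n >= 3) {
      b1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
      skew <- b1 * sqrt(n * (n - 1)) / (n - 2)
    }
    if (n >= 4) {
      kurt <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
        3 * (n - 1)^2 / ((n - 2) * (n - 3))
    }
  }
  tibble::tibble(n = n, mean = m, minimum = min(x), maximum = max(x),
                 sd = s, skewness = skew, kurtosis = kurt)
}

#' Table of trait summaries
#'
#' [summarize_trait()] applied to the per-line means of every trait in a
#' phenotype table.
#'
#' @param tm Phenotype tibble with columns `line`, `replicate`, and trait
#'   columns.
#' @return Tibble with one row per trait.
#' @export
trait_stats_table <- function(tm) {
  lm <- line_means(tm)
  dplyr::bind_rows(lapply(intersect(trait_names(), names(lm)), function(tr) {
    dplyr::bind_cols(tibble::tibble(trait = tr), summarize_trait(lm[[tr]]))
  }))
}

# replicate -> line aggregation: arithmetic mean over available replicates
line_means <- function(tm) {
  stopifnot(all(c("line") %in% names(tm)))
  trs <- intersect(trait_names(), names(tm))
  if (length(trs) == 0) stop("phenotype table has no recognized trait columns")
  tm |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(trs), ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Pairwise trait correlations with one-tailed p-values
#'
#' Pearson correlations on per-line trait means (replicates are averaged
#' first). P-values are one-tailed via the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, testing association in the direction
#' of the observed sign; stars mark the 0.05 and 0.01 levels.
#'
#' @param tm Phenotype tibble (`line`, `replicate`, trait columns).
#' @return A list of class `trait_correlations`: `r` and `p` (7 x 7
#'   matrices), `stars` (character matrix: `""`, `"*"`, `"**"`), `n` (lines
#'   used).
#' @export
correlation_matrix <- function(tm) {
  lm <- line_means(tm)
  trs <- intersect(trait_names(), names(lm))
  X <- as.matrix(lm[, trs])
  n <- nrow(X)
  if (n < 3) stop("need at least 3 lines for correlation analysis")
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    degenerate <- which(sds == 0)
    r[degenerate, ] <- NA
    r[, degenerate] <- NA
    diag(r)[] <- 1
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 3, ...) {
  cat("Pearson correlations on", x$n, "line means (one-tailed stars: * 0.05, ** 0.01)\n")
  out <- matrix(paste0(format(round(x$r, digits)), x$stars),
                nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}

#' Select phenotypic extreme bulks
#'
#' Ranks lines by the mean of per-trait z-scores over the selection traits
#' (computed on line means) and takes the top `n` as the resistant bulk and
#' the bottom `n` as the susceptible bulk. Ties at either cut are broken by
#' line ID order, so selection is deterministic. The realized per-trait value
#' ranges of each bulk are reported alongside the memberships.
#'
#' @param tm Phenotype tibble (`line`, `replicate`, trait columns).
#' @param traits Selection traits; default the three bulking traits
#'   `SFW`, `SDW`, `RFW`.
#' @param n Bulk size (default 30).
#' @return A list of class `bulk_selection`: `resistant` and `susceptible`
#'   (line IDs), `ranges` (tibble bulk/trait/min/max), `score` (named
#'   composite score per line).
#' @export
select_bulks <- function(tm, traits = c("SFW", "SDW", "RFW"), n = 30) {
  stopifnot(length(traits) >= 1, all(traits %in% trait_names()))
  lm <- line_means(tm)
  if (!all(traits %in% names(lm))) stop("selection traits missing from table")
  if (nrow(lm) < 2 * n) {
    stop("need at least ", 2 * n, " lines to select two bulks of ", n)
  }
  Z <- scale(as.matrix(lm[, traits]))
  if (any(attr(Z, "scaled:scale") == 0)) {
    stop("selection trait with zero variance: ",
         paste(traits[attr(Z, "scaled:scale") == 0], collapse = ", "))
  }
  score <- stats::setNames(rowMeans(Z), lm$line)
  # ties at either cut broken by line ID order
  resistant <- lm$line[order(-score, lm$line)][seq_len(n)]
  susceptible <- lm$line[order(score, lm$line)][seq_len(n)]

  ranges <- dplyr::bind_rows(lapply(traits, function(tr) {
    tibble::tibble(
      bulk = c("resistant", "susceptible"),
      trait = tr,
      min = c(min(lm[[tr]][lm$line %in% resistant]),
              min(lm[[tr]][lm$line %in% susceptible])),
      max = c(max(lm[[tr]][lm$line %in% resistant]),
              max(lm[[tr]][lm$line %in% susceptible]))
    )
  }))
  structure(list(resistant = resistant, susceptible = susceptible,
                 ranges = ranges, score = score, traits = traits, n = n),
            class = "bulk_selection")
}

#' @export
print.bulk_selection <- function(x, ...) {
  cat("bulk_selection:", x$n, "lines per bulk on",
      paste(x$traits, collapse = "/"), "\n")
  print(x$ranges)
  invisible(x)
}

#' Read a phenotype table
#'
#' @param path TSV with columns `line`, `replicate`, and trait columns.
#' @return Tibble.
#' @export
read_phenotypes <- function(path) {
  tm <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("line", "replicate") %in% names(tm))) {
    stop("phenotype table must have 'line' and 'replicate' columns")
  }
  tibble::as_tibble(tm)
}
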