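#' Round half-up
#'
#' Commercial ("half away from zero") rounding, as used for reported ratios and
#' region lengths. Base R's `round()` rounds half to even, which disagrees with
#' printed two-decimal values exactly at the .x5 boundary.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(1.055, 2) # 1.06
#' round_half_up(2.1584, 2) # 2.16
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by an epsilon scaled to the value so that numbers whose decimal
  # representation is exactly .5 but whose binary double sits a hair below
  # (e.g. 1.055 * 100 = 105.49999...) still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps) * abs(x) * scale) / scale
}

#' Region length in megabases
#'
#' Length of a genomic interval in Mb, rounded half-up to two decimals. Kept in
#' integer arithmetic when coordinates are whole numbers so boundary cases
#' (e.g. 1,055,000 bp = 1.06 Mb) round the way the printed values do.
#'
#' @param start,end Interval bounds in bp, `start < end`.
#' @return Length in Mb with two decimals.
#' @examples
#' region_length_mb(60120000, 61980000) # 1.86
#' region_length_mb(57795000, 58850000) # 1.06
#' @export
region_length_mb <- function(start, end) {
  stopifnot(all(end > start))
  len <- end - start
  if (all(len == floor(len))) {
    # hundredths of a Mb via integer division: len bp + half-ulp of 0.01 Mb
    (len + 5000) %/% 10000 / 100
  } else {
    round_half_up(len / 1e6, 2)
  }
}

# derive a reproducible child seed from a base seed and a stage label,
# kept below 2^31
derive_seed <- function(seed, label) {
  h <- as.numeric(utils::head(utf8ToInt(paste0(label, ":")), 20))
  s <- (sum(h * seq_along(h)) * 2654435 + as.numeric(seed)) %% 2147483647
  as.integer(abs(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
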