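#' Quality-control thresholds for read cleaning
#'
#' Defaults are the standard seven-step resequencing QC parameterization:
#' 5' bases below Q20 (or `N`) are cut, 3' bases below Q3 (or `N`) are cut,
#' a 4-base sliding window is cut when its mean quality falls under Q20, reads
#' with an `N` rate of 10% or more are dropped, reads with more than 40% of
#' bases under Q15 are dropped, and reads shorter than 30 bp after pruning are
#' dropped.
#'
#' @param q5 5'-end per-base quality cutoff (step 2).
#' @param q3 3'-end per-base quality cutoff (step 3).
#' @param window Sliding-window width in bases (step 4).
#' @param window_q Minimum mean window quality (step 4).
#' @param n_rate Maximum tolerated `N` fraction; a read is dropped when its
#'   `N` fraction is at or above this (step 5).
#' @param q_low Low-quality base threshold for the whole-read rule (step 6).
#' @param low_frac Maximum tolerated fraction of bases below `q_low`; a read
#'   is dropped when the fraction strictly exceeds this (step 6).
#' @param min_len Minimum surviving read length in bp (step 7).
#' @param adapter_min_overlap Minimum 3'-end overlap with the adapter prefix
#'   for adapter trimming (step 1).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(q5 = 20, q3 = 3, window = 4, window_q = 20,
                      n_rate = 0.10, q_low = 15, low_frac = 0.40,
                      min_len = 30, adapter_min_overlap = 5) {
  stopifnot(q5 >= 0, q3 >= 0, window >= 1, n_rate > 0, low_frac > 0, min_len >= 1)
  structure(list(q5 = q5, q3 = q3, window = window, window_q = window_q,
                 n_rate = n_rate, q_low = q_low, low_frac = low_frac,
                 min_len = min_len, adapter_min_overlap = adapter_min_overlap),
            class = "qc_params")
}

# leftmost position j at which the read's 3' remainder matches the adapter:
# either the full adapter occurs at j (read-through with trailing bases), or
# the read's suffix starting at j equals a prefix of the adapter with at least
# min_overlap bases. Returns NA when there is no match.
adapter_match_pos <- function(s, a, min_overlap = 5) {
  n <- length(s)
  la <- length(a)
  if (n < min_overlap) return(NA_integer_)
  for (j in seq_len(n - min_overlap + 1)) {
    k <- n - j + 1
    if (k >= la) {
      if (all(s[j:(j + la - 1)] == a)) return(j)
    } else {
      if (all(s[j:n] == a[seq_len(k)])) return(j)
    }
  }
  NA_integer_
}

#' Clean one read with the seven-step procedure
#'
#' Applies, in order: (1) adapter removal at the 3' end (exact prefix match,
#' iterated until no match remains); (2) 5'-end trimming of bases below Q20 or
#' `N`; (3) 3'-end trimming of bases below Q3 or `N`; (4) truncation at the
#' first 4-base window whose mean quality is below Q20, scanning 5' to 3';
#' (5) drop when the `N` fraction is >= 10%; (6) drop when more than 40% of
#' bases are below Q15; (7) drop when fewer than 30 bp remain.
#'
#' @param seq Read sequence (single string over `A,C,G,T,N`).
#' @param qual Integer vector of per-base Phred qualities, same length as
#'   `seq`.
#' @param adapter Adapter sequence, or `NULL` to skip step 1.
#' @param params A [qc_params()].
#' @return A list: `status` (`"kept"` or `"dropped"`), `seq`, `qual` (trimmed;
#'   empty when dropped), `drop_step` (5, 6 or 7, `NA` when kept), and
#'   `trimmed`, the bases removed by each trimming step
#'   (`adapter`, `five_prime`, `three_prime`, `window`).
#' @examples
#' clean_read("ACGTACGTAC", rep(40L, 10), params = qc_params(min_len = 5))
#' @export
clean_read <- function(seq, qual, adapter = NULL, params = qc_params()) {
  if (nchar(seq) != length(qual)) {
    stop("malformed read: sequence length ", nchar(seq),
         " != quality length ", length(qual))
  }
  s <- strsplit(seq, "")[[1]]
  q <- as.integer(qual)
  trimmed <- c(adapter = 0L, five_prime = 0L, three_prime = 0L, window = 0L)

  # step 1: adapter removal, iterated to a fixpoint so cleaning is idempotent
  if (!is.null(adapter) && nzchar(adapter)) {
    a <- strsplit(adapter, "")[[1]]
    repeat {
      j <- adapter_match_pos(s, a, params$adapter_min_overlap)
      if (is.na(j)) break
      trimmed["adapter"] <- trimmed["adapter"] + (length(s) - j + 1L)
      keep <- seq_len(j - 1)
      s <- s[keep]; q <- q[keep]
    }
  }
  # step 2: 5' cut below q5 or N
  i <- 1L
  while (i <= length(s) && (q[i] < params$q5 || s[i] == "N")) i <- i + 1L
  if (i > 1L) {
    trimmed["five_prime"] <- i - 1L
    s <- s[-seq_len(i - 1L)]; q <- q[-seq_len(i - 1L)]
  }
  # step 3: 3' cut below q3 or N
  e <- length(s)
  while (e >= 1L && (q[e] < params$q3 || s[e] == "N")) e <- e - 1L
  if (e < length(s)) {
    trimmed["three_prime"] <- length(s) - e
    s <- s[seq_len(e)]; q <- q[seq_len(e)]
  }
  # step 4: truncate at the first failing mean-quality window (5' -> 3')
  w <- params$window
  if (length(q) >= w) {
    cs <- cumsum(c(0, q))
    wmeans <- (cs[(w + 1):length(cs)] - cs[seq_len(length(cs) - w)]) / w
    bad <- which(wmeans < params$window_q)
    if (length(bad) > 0) {
      cut_at <- bad[1] # window starts here; keep bases before it
      trimmed["window"] <- length(s) - cut_at + 1L
      keep <- seq_len(cut_at - 1L)
      s <- s[keep]; q <- q[keep]
    }
  }

  drop <- NA_integer_
  if (length(s) > 0 && mean(s == "N") >= params$n_rate) drop <- 5L
  if (is.na(drop) && length(q) > 0 && mean(q < params$q_low) > params$low_frac) drop <- 6L
  if (is.na(drop) && length(s) < params$min_len) drop <- 7L

  if (!is.na(drop)) {
    list(status = "dropped", seq = "", qual = integer(0),
         drop_step = drop, trimmed = trimmed)
  } else {
    list(status = "kept", seq = paste(s, collapse = ""), qual = q,
         drop_step = NA_integer_, trimmed = trimmed)
  }
}

#' Stream a FASTQ file through read cleaning
#'
#' Applies [clean_read()] to every record, writes surviving reads, and
#' accumulates a QC report: read and base counts, per-step drop/trim tallies,
#' and per-cycle diagnostics of the clean reads (base composition fractions
#' and mean error rate `10^(-Q/10)` per cycle).
#'
#' @param input Path to a FASTQ file (Phred+33; `.gz` allowed).
#' @param output Optional path for the cleaned FASTQ (`.gz` compresses);
#'   `NULL` skips writing.
#' @param adapter Adapter sequence or `NULL`.
#' @param params A [qc_params()].
#' @return An object of class `qc_report`: list with `reads_in`, `reads_out`,
#'   `bases_in`, `bases_out`, `dropped` (per drop step), `bases_trimmed` (per
#'   trimming step), and `per_cycle` (tibble: cycle, A/C/G/T/N fractions,
#'   mean_error).
#' @export
qc_stream <- function(input, output = NULL, adapter = NULL, params = qc_params()) {
  reads <- read_fastq(input)
  n <- nrow(reads)
  dropped <- c(step5 = 0L, step6 = 0L, step7 = 0L)
  bases_trimmed <- c(adapter = 0L, five_prime = 0L, three_prime = 0L, window = 0L)
  keep <- logical(n)
  out_seq <- character(n)
  out_qual <- character(n)
  bases_in <- 0L
  bases_out <- 0L

  for (i in seq_len(n)) {
    q <- phred_to_int(reads$qual[i])
    bases_in <- bases_in + length(q)
    res <- clean_read(reads$seq[i], q, adapter = adapter, params = params)
    bases_trimmed <- bases_trimmed + res$trimmed
    if (res$status == "kept") {
      keep[i] <- TRUE
      out_seq[i] <- res$seq
      out_qual[i] <- int_to_phred(res$qual)
      bases_out <- bases_out + length(res$qual)
    } else {
      dropped[paste0("step", res$drop_step)] <-
        dropped[paste0("step", res$drop_step)] + 1L
    }
  }

  clean <- tibble::tibble(id = reads$id[keep], seq = out_seq[keep],
                          qual = out_qual[keep])
  if (!is.null(output)) write_fastq(clean, output)

  structure(list(reads_in = n, reads_out = nrow(clean),
                 bases_in = bases_in, bases_out = bases_out,
                 dropped = dropped, bases_trimmed = bases_trimmed,
                 per_cycle = per_cycle_stats(clean)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$reads_in, "reads in,", x$reads_out, "kept (",
      x$bases_out, "of", x$bases_in, "bases )\n")
  cat("  dropped:", paste(names(x$dropped), x$dropped, collapse = ", "), "\n")
  cat("  bases trimmed:", paste(names(x$bases_trimmed), x$bases_trimmed,
                                collapse = ", "), "\n")
  invisible(x)
}

# per-cycle base composition and mean error rate over a set of clean reads
per_cycle_stats <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble::tibble(cycle = integer(0), A = numeric(0), C = numeric(0),
                          G = numeric(0), T = numeric(0), N = numeric(0),
                          mean_error = numeric(0)))
  }
  lens <- nchar(reads$seq)
  max_len <- max(lens)
  ch <- matrix(NA_character_, nrow(reads), max_len)
  er <- matrix(NA_real_, nrow(reads), max_len)
  for (i in seq_len(nrow(reads))) {
    ch[i, seq_len(lens[i])] <- strsplit(reads$seq[i], "")[[1]]
    er[i, seq_len(lens[i])] <- 10^(-phred_to_int(reads$qual[i]) / 10)
  }
  comp <- sapply(c("A", "C", "G", "T", "N"), function(b) {
    colMeans(ch == b, na.rm = TRUE)
  })
  comp <- matrix(comp, ncol = 5, dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  tibble::tibble(cycle = seq_len(max_len),
                 A = comp[, "A"], C = comp[, "C"], G = comp[, "G"],
                 T = comp[, "T"], N = comp[, "N"],
                 mean_error = colMeans(er, na.rm = TRUE))
}

#' Write a QC report as TSV
#'
#' A summary block of `#`-prefixed key/value lines followed by the per-cycle
#' table (one row per cycle).
#'
#' @param report A [qc_stream()] report.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  con <- file(path, "w")
  on.exit(close(con))
  kv <- c(reads_in = report$reads_in, reads_out = report$reads_out,
          bases_in = report$bases_in, bases_out = report$bases_out,
          stats::setNames(report$dropped, paste0("dropped_", names(report$dropped))),
          stats::setNames(report$bases_trimmed,
                          paste0("trimmed_", names(report$bases_trimmed))))
  writeLines(sprintf("#%s\t%s", names(kv), kv), con)
  utils::write.table(report$per_cycle, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

phred_to_int <- function(qual_str) as.integer(charToRaw(qual_str)) - 33L

int_to_phred <- function(q) rawToChar(as.raw(as.integer(q) + 33L))

#' Read a FASTQ file
#'
#' Thin wrapper over Biostrings' quality-aware FASTQ reader (Phred+33), with a
#' structural pre-check that reports the index of a truncated record.
#'
#' @param path FASTQ path (`.gz` allowed).
#' @return Tibble with columns `id`, `seq`, `qual` (quality as a Phred+33
#'   string).
#' @export
read_fastq <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4 != 0) {
    stop("truncated FASTQ record at read ", n_lines %/% 4 + 1, " in ", path)
  }
  if (n_lines == 0) {
    return(tibble::tibble(id = character(0), seq = character(0),
                          qual = character(0)))
  }
  # the quality-aware reader warns about dropped metadata columns; harmless
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  )
  tibble::tibble(id = names(x),
                 seq = as.character(x),
                 qual = as.character(Biostrings::quality(x)))
}

#' Write a FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (Phred+33 string).
#' @param path Output path; a `.gz` suffix gzip-compresses.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    close(con)
    return(invisible(path))
  }
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual)
  ))
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}
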