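#' Defect specification for synthetic reads
#'
#' Controls what fraction of synthetic reads carries each quality defect. Each
#' read receives at most one defect so the expected fate of every read under
#' the cleaning procedure is unambiguous and can be recorded in a truth table.
#'
#' @param adapter Adapter sequence planted at the 3' end of adapter reads.
#' @param p_adapter Fraction of reads with adapter read-through: the read is a
#'   random insert followed by the adapter (and random bases past it when the
#'   adapter ends before the read does).
#' @param p_n_run Fraction of reads with a central run of `N` bases covering
#'   `n_frac` of the read (at high quality, so only the N-rate rule fires).
#' @param n_frac N fraction planted in N-run reads; at or above the drop
#'   threshold of 0.10 these reads must be discarded.
#' @param p_tail3 Fraction of reads with a 3' tail of `tail3_len` bases below
#'   quality 3; cleaning must shorten these by exactly `tail3_len`.
#' @param tail3_len Length of the planted low-quality 3' tail.
#' @param p_lowq Fraction of reads in which every second base has quality 10,
#'   putting half the bases under Q15 and forcing the low-quality drop rule.
#' @param base_q Quality of non-defective bases (default 40).
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(adapter = "AGATCGGAAGAGC", p_adapter = 0,
                        p_n_run = 0, n_frac = 0.12,
                        p_tail3 = 0, tail3_len = 10,
                        p_lowq = 0, base_q = 40) {
  p <- c(p_adapter, p_n_run, p_tail3, p_lowq)
  stopifnot(all(p >= 0), sum(p) <= 1, n_frac > 0, n_frac < 1, tail3_len >= 1)
  structure(list(adapter = adapter, p_adapter = p_adapter, p_n_run = p_n_run,
                 n_frac = n_frac, p_tail3 = p_tail3, tail3_len = tail3_len,
                 p_lowq = p_lowq, base_q = base_q),
            class = "defect_spec")
}

#' Synthesize a FASTQ file with planted quality defects
#'
#' Generates reads whose behaviour under the seven-step cleaning procedure is
#' known by construction, together with a truth table recording each read's
#' expected fate (surviving length, or the step that should drop it). Used to
#' validate [qc_stream()] end to end.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length in bp (default 150, a common short-read
#'   length).
#' @param defects A [defect_spec()].
#' @param seed Integer seed; output is deterministic.
#' @param path Optional output path; `.gz` suffix compresses. The truth table
#'   is written next to it as `<path>.truth.tsv`.
#' @return Invisibly, a list with `reads` (tibble id/seq/qual-string) and
#'   `truth` (tibble id/defect/survives/drop_step/expected_length).
#' @export
synth_fastq <- function(n_reads, read_len = 150, defects = defect_spec(),
                        seed = 1, path = NULL) {
  if (read_len < 1) stop("read_len must be >= 1")
  stopifnot(inherits(defects, "defect_spec"))
  set_sim_seed(seed)
  bases <- c("A", "C", "G", "T")
  kinds <- c("adapter", "n_run", "tail3", "lowq", "clean")
  probs <- c(defects$p_adapter, defects$p_n_run, defects$p_tail3, defects$p_lowq)
  probs <- c(probs, 1 - sum(probs))
  kind <- sample(kinds, n_reads, replace = TRUE, prob = probs)

  la <- nchar(defects$adapter)
  a_chars <- strsplit(defects$adapter, "")[[1]]
  if (defects$p_adapter > 0 && read_len < 36) {
    stop("adapter defects need read_len >= 36 so trimmed reads can survive")
  }
  seqs <- character(n_reads)
  quals <- vector("list", n_reads)
  exp_len <- integer(n_reads)
  drop_step <- rep(NA_integer_, n_reads)

  # mutate bases until no adapter match remains, so a read's fate is exactly
  # the one its planted defect dictates (random sequence can otherwise carry a
  # chance 3'-suffix match to the adapter prefix)
  scrub_adapter <- function(s) {
    repeat {
      j <- adapter_match_pos(s, a_chars, 5)
      if (is.na(j)) return(s)
      s[j] <- sample(setdiff(bases, a_chars[1]), 1)
    }
  }

  for (i in seq_len(n_reads)) {
    s <- sample(bases, read_len, replace = TRUE)
    q <- rep(defects$base_q, read_len)
    el <- read_len
    switch(kind[i],
      adapter = {
        # insert of length >= 30 so the trimmed read survives the length rule;
        # at least 5 bases of adapter fit so the overlap rule can fire
        insert <- sample(30:(read_len - 5), 1)
        tail_len <- min(la, read_len - insert)
        s[seq_len(insert)] <- scrub_adapter(s[seq_len(insert)])
        s[(insert + 1):(insert + tail_len)] <- a_chars[seq_len(tail_len)]
        el <- insert
      },
      n_run = {
        k <- ceiling(defects$n_frac * read_len)
        from <- max(2, (read_len - k) %/% 2)
        s[from:(from + k - 1)] <- "N" # central, high quality: only rule 5 fires
        el <- 0L
        drop_step[i] <- 5L
      },
      tail3 = {
        q[(read_len - defects$tail3_len + 1):read_len] <- 2
        el <- read_len - defects$tail3_len
      },
      lowq = {
        q[seq(2, read_len, by = 2)] <- 10 # half the bases below Q15
        el <- 0L
        drop_step[i] <- 6L
      },
      clean = NULL
    )
    if (kind[i] != "adapter") s <- scrub_adapter(s)
    seqs[i] <- paste(s, collapse = "")
    quals[[i]] <- q
    exp_len[i] <- el
  }

  ids <- sprintf("read%05d", seq_len(n_reads))
  qual_str <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), character(1))
  reads <- tibble::tibble(id = ids, seq = seqs, qual = qual_str)
  truth <- tibble::tibble(id = ids, defect = kind,
                          survives = is.na(drop_step),
                          drop_step = drop_step,
                          expected_length = exp_len)
  if (!is.null(path)) {
    write_fastq(reads, path)
    utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(reads = reads, truth = truth))
}
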