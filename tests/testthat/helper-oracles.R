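# Independent oracle implementations, written naively (plain loops, no shared
# code with the package) so that agreement is evidence, not tautology.

# step-by-step read cleaner: same rules as clean_read, expressed directly
oracle_clean_read <- function(seq, qual, adapter = NULL, p = qc_params()) {
  s <- strsplit(seq, "")[[1]]
  q <- as.integer(qual)

  if (!is.null(adapter) && nzchar(adapter)) {
    a <- strsplit(adapter, "")[[1]]
    repeat {
      hit <- NA
      n <- length(s)
      if (n >= p$adapter_min_overlap) {
        for (j in 1:(n - p$adapter_min_overlap + 1)) {
          len <- min(length(a), n - j + 1)
          if (identical(s[j:(j + len - 1)], a[1:len])) {
            hit <- j
            break
          }
        }
      }
      if (is.na(hit)) break
      s <- s[seq_len(hit - 1)]
      q <- q[seq_len(hit - 1)]
    }
  }
  while (length(s) > 0 && (q[1] < p$q5 || s[1] == "N")) {
    s <- s[-1]
    q <- q[-1]
  }
  while (length(s) > 0 && (q[length(q)] < p$q3 || s[length(s)] == "N")) {
    s <- s[-length(s)]
    q <- q[-length(q)]
  }
  if (length(s) >= p$window) {
    for (i in 1:(length(s) - p$window + 1)) {
      if (mean(q[i:(i + p$window - 1)]) < p$window_q) {
        s <- s[seq_len(i - 1)]
        q <- q[seq_len(i - 1)]
        break
      }
    }
  }
  if (length(s) > 0 && sum(s == "N") / length(s) >= p$n_rate) {
    return(list(kept = FALSE, drop_step = 5L))
  }
  if (length(s) > 0 && sum(q < p$q_low) / length(q) > p$low_frac) {
    return(list(kept = FALSE, drop_step = 6L))
  }
  if (length(s) < p$min_len) {
    return(list(kept = FALSE, drop_step = 7L))
  }
  list(kept = TRUE, seq = paste(s, collapse = ""), qual = q,
       drop_step = NA_integer_)
}

# fuzzed reads with a broad quality mix and occasional planted adapters / Ns
fuzz_reads <- function(n, adapter, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    len <- sample(20:90, 1)
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (stats::runif(1) < 0.15) { # sprinkle Ns
      k <- sample.int(max(1, len %/% 8), 1)
      s[sample.int(len, k)] <- "N"
    }
    # per-read quality regime: high, low, mixed, or ramped
    q <- switch(sample(4, 1),
                rep(40L, len),
                sample(0:18, len, replace = TRUE),
                sample(0:40, len, replace = TRUE),
                as.integer(round(seq(38, 2, length.out = len))))
    if (stats::runif(1) < 0.3) { # plant an adapter suffix
      ov <- sample(5:min(nchar(adapter), len - 1), 1)
      at <- len - ov + 1
      s[at:len] <- strsplit(adapter, "")[[1]][1:ov]
    }
    list(seq = paste(s, collapse = ""), qual = q)
  })
}

# window means recomputed the slow way: one pass over sites per window
oracle_windows <- function(records, chrom_lengths, window, step) {
  out <- NULL
  for (cn in unique(records$chrom)) {
    r <- records[records$chrom == cn, ]
    L <- chrom_lengths[[cn]]
    starts <- seq(1, L, by = step)
    for (st in starts) {
      en <- min(st + window, L + 1) # half-open upper bound
      sel <- r$pos >= st & r$pos < en
      out <- rbind(out, data.frame(
        chrom = cn, start = st, end = en, n_sites = sum(sel),
        delta = if (any(sel)) mean(r$delta[sel]) else NA_real_
      ))
    }
  }
  out
}

# exact single-locus BC2F2 dosage distribution by pedigree enumeration:
# F1 gamete -> BC1F1, BC1F1 gamete -> BC2F1, two BC2F1 gametes -> BC2F2
oracle_bc2f2_probs <- function() {
  p <- c(`0` = 0, `1` = 0, `2` = 0)
  for (g1 in 0:1) {
    p1 <- 0.5 # F1 is heterozygous everywhere
    for (g2 in 0:1) {
      p2 <- if (g2 == 1) g1 / 2 else 1 - g1 / 2
      for (ga in 0:1) {
        pa <- if (ga == 1) g2 / 2 else 1 - g2 / 2
        for (gb in 0:1) {
          pb <- if (gb == 1) g2 / 2 else 1 - g2 / 2
          p[ga + gb + 1] <- p[ga + gb + 1] + p1 * p2 * pa * pb
        }
      }
    }
  }
  p
}

# exact null |delta| quantile at one depth pair by full enumeration of the
# 1:2:1 bulk frequency and both binomial read counts
oracle_null_quantile <- function(n_bulk, depth, probs) {
  fs <- (0:(2 * n_bulk)) / (2 * n_bulk)
  wf <- stats::dbinom(0:(2 * n_bulk), 2 * n_bulk, 0.5)
  pc <- vapply(0:depth, function(cc) {
    sum(wf * stats::dbinom(cc, depth, fs))
  }, numeric(1))
  idx <- (0:depth) / depth
  joint <- outer(pc, pc)
  dv <- round(abs(outer(idx, idx, "-")), 10)
  agg <- tapply(as.vector(joint), factor(dv), sum)
  cdf <- cumsum(agg)
  vapply(probs, function(p) {
    as.numeric(names(cdf))[which(cdf >= p)[1]]
  }, numeric(1))
}

# SPSS/SAS-convention moments via e1071 (type = 2)
oracle_skew <- function(x) e1071::skewness(x, type = 2)
oracle_kurt <- function(x) e1071::kurtosis(x, type = 2)
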