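# Independent oracles used across the test suite. These deliberately
# share no code with the package internals: the aligner oracle is an
# exhaustive all-placement scan, the N50 oracle applies the definition
# literally, and the signature oracle is a brute-force substring walk.

oracle_random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Maximum-sum contiguous segment (Kadane via cumulative sums).
oracle_max_subarray <- function(s) {
  cs <- cumsum(s)
  max(cs - cummin(c(0, cs[-length(cs)])))
}

# Best ungapped local alignment score over every diagonal of every
# orientation; N matches nothing. Returns 0 when no positive segment
# exists.
oracle_best_ungapped_score <- function(read, ref, match = 1, mismatch = -2) {
  best <- 0
  for (q in c(read, oracle_revcomp(read))) {
    qc <- strsplit(q, "")[[1]]
    rc <- strsplit(ref, "")[[1]]
    L <- length(qc); R <- length(rc)
    for (d in (1 - L):(R - 1)) {           # ref index = query index + d
      i_lo <- max(1, 1 - d); i_hi <- min(L, R - d)
      if (i_hi < i_lo) next
      qi <- qc[i_lo:i_hi]; ri <- rc[(i_lo + d):(i_hi + d)]
      mv <- qi == ri & qi != "N" & ri != "N"
      s <- ifelse(mv, match, mismatch)
      best <- max(best, oracle_max_subarray(s))
    }
  }
  as.numeric(best)
}

# All motif occurrences (both strands) by a brute-force substring walk.
oracle_find_motifs <- function(seq, motifs) {
  L <- nchar(seq)
  out <- NULL
  for (m in unique(c(motifs, vapply(motifs, oracle_revcomp, "")))) {
    w <- nchar(m)
    for (st in seq_len(max(0, L - w + 1))) {
      if (substr(seq, st, st + w - 1) == m) {
        out <- rbind(out, data.frame(pattern = m, start = st,
                                     end_distance = L - (st + w - 1)))
      }
    }
  }
  out
}

# N50 by definition: the largest member length L with
# sum(lengths >= L) >= total / 2.
oracle_n50 <- function(lengths) {
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
  }
  stop("unreachable")
}

# Substitute exactly the given 1-based positions of a sequence.
oracle_mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste(ch, collapse = "")
}

# Shared toy simulation for the acceptance checks (built once per run).
toy_simulation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(rng_seed = 20210426)
      cache <<- list(config = cfg, pipeline = pipeline_config(),
                     sim = suppressMessages(simulate_fst_dataset(cfg)))
    }
    cache
  }
})
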