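# Self-contained seed-and-extend local aligner for FST mapping:
# k-mer seeds from a keyed index, ungapped x-drop extension, BLAST-like
# identity, and Karlin-Altschul E-values. FSTs are near-identical to
# their source genome, so ungapped extension under the 90% identity
# filter is the whole model; no gapped extension is provided.

#' Build a k-mer index over a reference genome
#'
#' Every N-free k-mer of every chromosome is stored with its 0-based
#' offset. Reverse-complement hits are found by querying the read's
#' reverse complement, so only the forward strand is indexed.
#'
#' @param genome named character vector of chromosome sequences.
#' @param k seed length (>= 8).
#' @return list of class `tnt1_index` with `k`, `kmers` (keyed
#'   data.table of `kmer`, `chrom`, `offset`), `raw` (per-chromosome
#'   raw byte vectors), `chrom_len`, `total_len`.
#' @export
build_index <- function(genome, k = 15L) {
  stopifnot(is.character(genome), length(genome) > 0, k >= 8L)
  k <- as.integer(k)
  lens <- nchar(genome)
  if (all(lens < k)) {
    stop("k = ", k, " exceeds every chromosome length", call. = FALSE)
  }
  pieces <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    L <- lens[ci]
    if (L < k) next
    n_kmer <- L - k + 1L
    km <- substring(genome[[ci]], seq_len(n_kmer), seq_len(n_kmer) + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    if (!any(ok)) next
    pieces[[ci]] <- data.table::data.table(
      kmer = km[ok], chrom = names(genome)[ci],
      offset = which(ok) - 1L
    )
  }
  kmers <- data.table::rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  data.table::setkey(kmers, kmer)
  structure(list(
    k = k,
    kmers = kmers,
    raw = lapply(genome, charToRaw),
    chrom_len = lens,
    total_len = sum(as.numeric(lens))
  ), class = "tnt1_index")
}

#' Karlin-Altschul parameters for an ungapped match/mismatch system
#'
#' `lambda` solves sum_ij p_i p_j exp(lambda * s_ij) = 1 by bisection;
#' `H` is the relative entropy lambda * E[s exp(lambda s)]; `K` is
#' computed by the lattice-case series over convolutions of the score
#' distribution.
#'
#' @param match,mismatch integer scores (match > 0, mismatch < 0).
#' @param base_freqs background base frequencies (length 4, sums to 1).
#' @param tol bisection tolerance on lambda.
#' @return list with `lambda`, `K`, `H`.
#' @export
karlin_params <- function(match = 1L, mismatch = -2L,
                          base_freqs = rep(0.25, 4), tol = 1e-10) {
  stopifnot(match > 0, mismatch < 0,
            length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-8)
  p_match <- sum(base_freqs^2)
  p_mis <- 1 - p_match
  values <- c(match, mismatch)
  probs <- c(p_match, p_mis)
  expected <- sum(values * probs)
  if (expected >= 0) {
    stop("expected score is non-negative; lambda is undefined ",
         "(make the mismatch penalty stronger)", call. = FALSE)
  }
  # phi(lambda) = E[exp(lambda * s)] - 1; phi(0) = 0, phi'(0) < 0,
  # phi -> Inf: the positive root is lambda.
  phi <- function(lam) sum(probs * exp(lam * values)) - 1
  hi <- 1
  while (phi(hi) < 0) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (phi(mid) < 0) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  H <- lambda * sum(probs * values * exp(lambda * values))

  # K for lattice scores (span g = gcd of score values):
  #   sigma = sum_j (1/j) [ sum_{s<0} P_j(s) e^{lambda s} + P(S_j >= 0) ]
  #   K = g * lambda * exp(-2 sigma) / (H * (1 - e^{-lambda g}))
  g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b),
              abs(values))
  vs <- values %/% g
  lam_g <- lambda * g
  lo_v <- min(vs)
  # P_1 on the scaled lattice, as a vector indexed from lo_v
  width1 <- max(vs) - min(vs) + 1L
  p1 <- numeric(width1)
  p1[vs - lo_v + 1L] <- probs
  sigma <- 0
  dist <- 1 # j = 0 convolution: point mass at 0
  dist_lo <- 0L
  for (j in 1:2000) {
    # convolve dist with p1
    new_lo <- dist_lo + lo_v
    new_len <- length(dist) + width1 - 1L
    nd <- numeric(new_len)
    for (u in seq_along(p1)) {
      if (p1[u] > 0) {
        idx <- seq_along(dist) + (u - 1L)
        nd[idx] <- nd[idx] + dist * p1[u]
      }
    }
    dist <- nd; dist_lo <- new_lo
    s_vals <- seq.int(dist_lo, length.out = length(dist))
    neg <- s_vals < 0
    term <- sum(dist[neg] * exp(lam_g * s_vals[neg])) + sum(dist[!neg])
    sigma <- sigma + term / j
    if (term / j < 1e-12) break
  }
  K <- g * lambda * exp(-2 * sigma) / (H * (1 - exp(-lam_g)))
  list(lambda = lambda, K = K, H = H)
}

#' Karlin-Altschul E-value for an ungapped score
#'
#' E = K * m * n * exp(-lambda * S): strictly decreasing in the score
#' and linear in both the read length m and the genome length n.
#'
#' @param score raw alignment score.
#' @param read_len read length m (bp).
#' @param genome_len total genome length n (bp).
#' @param params output of [karlin_params()].
#' @return numeric E-value.
#' @export
score_to_evalue <- function(score, read_len, genome_len, params) {
  stopifnot(read_len > 0, genome_len > 0,
            all(c("lambda", "K") %in% names(params)))
  params$K * read_len * genome_len * exp(-params$lambda * score)
}

# Ungapped x-drop extension along one diagonal.
# s: per-position score vector over the q-overlap range [i_lo, i_hi]
# (index 1 of s is q position i_lo); seed occupies q positions
# [s0, s0 + k - 1]. Returns c(ql, qr, gain_left, gain_right).
xdrop_extend <- function(s, i_lo, s0, k, x_drop) {
  seed_a <- s0 - i_lo + 1L     # index of seed start within s
  seed_b <- seed_a + k - 1L
  ql <- s0; qr <- s0 + k - 1L
  gain_r <- 0; gain_l <- 0
  if (seed_b < length(s)) {
    right <- s[(seed_b + 1L):length(s)]
    cum <- cumsum(right)
    run_max <- cummax(cum)
    stop_at <- which(run_max - cum > x_drop)[1L]
    n_scan <- if (is.na(stop_at)) length(cum) else stop_at
    best <- which.max(cum[seq_len(n_scan)])
    if (cum[best] > 0) { gain_r <- cum[best]; qr <- qr + best }
  }
  if (seed_a > 1L) {
    left <- s[(seed_a - 1L):1L]   # walk leftwards from the seed
    cum <- cumsum(left)
    run_max <- cummax(cum)
    stop_at <- which(run_max - cum > x_drop)[1L]
    n_scan <- if (is.na(stop_at)) length(cum) else stop_at
    best <- which.max(cum[seq_len(n_scan)])
    if (cum[best] > 0) { gain_l <- cum[best]; ql <- ql - best }
  }
  c(ql = ql, qr = qr, gain_l = gain_l, gain_r = gain_r)
}

empty_hits <- function() {
  data.frame(fst_id = character(), chrom = character(),
             ref_start = integer(), ref_end = integer(),
             read_start = integer(), read_end = integer(),
             read_len = integer(), strand = character(),
             matches = integer(), aln_len = integer(),
             identity = numeric(), score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Align one read against an indexed reference
#'
#' Seed-and-extend: k-mer seed matches are collected for the read and
#' its reverse complement, merged per (chromosome, diagonal), extended
#' ungapped in both directions under an x-drop rule, scored with the
#' configured match/mismatch scores, and reported when they meet the
#' identity and E-value thresholds. Hits are deduplicated by
#' (chromosome, reference interval, strand), keeping the maximum score.
#' N never matches any base.
#'
#' @param read a single nucleotide string (or a one-row record with
#'   `fst_id` and `sequence`).
#' @param index a [build_index()] result.
#' @param config a [pipeline_config()].
#' @param params Karlin-Altschul parameters; computed from `config`
#'   when NULL.
#' @return data.frame of hits: `fst_id`, `chrom`, `ref_start`,
#'   `ref_end` (1-based inclusive), `read_start`, `read_end` (1-based
#'   on the original read), `read_len`, `strand`, `matches`,
#'   `aln_len`, `identity`, `score`, `evalue`.
#' @export
align_read <- function(read, index, config = pipeline_config(),
                       params = NULL) {
  stopifnot(inherits(index, "tnt1_index"), inherits(config, "tnt1_config"))
  if (is.list(read) || is.data.frame(read)) {
    fst_id <- read$fst_id[[1L]]; seq <- toupper(read$sequence[[1L]])
  } else {
    fst_id <- NA_character_; seq <- toupper(read[[1L]])
  }
  k <- index$k
  L <- nchar(seq)
  if (L < k) stop("read shorter than seed length k = ", k, call. = FALSE)
  if (is.null(params)) {
    params <- karlin_params(config$match, config$mismatch)
  }
  n_raw <- charToRaw("N")
  queries <- list(`+` = seq, `-` = revcomp(seq))
  rows <- list()
  for (strand in c("+", "-")) {
    q <- queries[[strand]]
    qraw <- charToRaw(q)
    n_kmer <- L - k + 1L
    km <- substring(q, seq_len(n_kmer), seq_len(n_kmer) + k - 1L)
    ok <- which(!grepl("N", km, fixed = TRUE))
    if (length(ok) == 0L) next
    qdt <- data.table::data.table(kmer = km[ok], qpos = ok)
    seeds <- index$kmers[qdt, on = "kmer", nomatch = NULL,
                         allow.cartesian = TRUE]
    if (nrow(seeds) == 0L) next
    seeds[, diag := offset - (qpos - 1L)]
    # one seed (smallest qpos) per (chrom, diagonal)
    seeds <- seeds[order(chrom, diag, qpos)]
    seeds <- seeds[!duplicated(paste(chrom, diag))]
    for (si in seq_len(nrow(seeds))) {
      chrom <- seeds$chrom[si]; d <- seeds$diag[si]; s0 <- seeds$qpos[si]
      rraw <- index$raw[[chrom]]
      i_lo <- max(1L, 1L - d)
      i_hi <- min(L, length(rraw) - d)
      qs <- qraw[i_lo:i_hi]
      rs <- rraw[(d + i_lo):(d + i_hi)]
      mv <- qs == rs & qs != n_raw
      s <- ifelse(mv, config$match, config$mismatch)
      ext <- xdrop_extend(s, i_lo, s0, k, config$x_drop)
      ql <- as.integer(ext[["ql"]]); qr <- as.integer(ext[["qr"]])
      score <- as.numeric(k * config$match + ext[["gain_l"]] + ext[["gain_r"]])
      aln_len <- qr - ql + 1L
      matches <- as.integer(sum(mv[(ql - i_lo + 1L):(qr - i_lo + 1L)]))
      identity <- matches / aln_len
      ev <- score_to_evalue(score, L, index$total_len, params)
      id_ok <- if (config$identity_strictly_greater)
        identity > config$min_identity else identity >= config$min_identity
      if (!id_ok || ev > config$max_evalue) next
      if (strand == "+") {
        read_start <- ql; read_end <- qr
      } else {
        read_start <- L - qr + 1L; read_end <- L - ql + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fst_id = fst_id, chrom = chrom,
        ref_start = d + ql, ref_end = d + qr,
        read_start = read_start, read_end = read_end, read_len = L,
        strand = strand, matches = matches, aln_len = aln_len,
        identity = identity, score = score, evalue = ev,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  # dedupe identical intervals, keep max score
  key <- paste(hits$chrom, hits$ref_start, hits$ref_end, hits$strand)
  hits <- hits[order(key, -hits$score), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$chrom, hits$ref_start,
                                 hits$ref_end, hits$strand)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Select the best alignment hit
#'
#' Maximum score; ties broken by lower E-value, then longer alignment,
#' then lexicographically smaller chromosome, then smaller reference
#' start. NULL for an empty hit set (such FSTs count as unmapped).
#'
#' @param hits data.frame of hits from [align_read()].
#' @return one-row data.frame, or NULL.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  ord <- order(-hits$score, hits$evalue, -hits$aln_len, hits$chrom,
               hits$ref_start)
  out <- hits[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the insertion coordinate from a best hit
#'
#' The insertion site is the genome coordinate of the transposon/genome
#' junction: the read base immediately flanking the signature motif,
#' projected through the hit's diagonal onto the reference (and
#' extrapolated along it when that base fell just outside the aligned
#' segment, e.g. when a sequencing error trimmed the alignment edge).
#'
#' @param hit one-row data.frame from [best_hit()].
#' @param qc_outcome the matching row of `filter_batch()$outcomes`
#'   (carries `which_end`, `start_offset`, `end_distance`, `motif`).
#' @param genome optional reference genome; when supplied the call is
#'   clamped to chromosome bounds.
#' @return one-row data.frame: `fst_id`, `chrom`, `position` (1-based),
#'   `strand`, plus the supporting hit columns `score`, `evalue`,
#'   `identity`.
#' @export
call_insertion_site <- function(hit, qc_outcome, genome = NULL) {
  stopifnot(nrow(hit) == 1L)
  if (!is.na(hit$fst_id) && !is.na(qc_outcome$fst_id[[1L]]) &&
      hit$fst_id != qc_outcome$fst_id[[1L]]) {
    stop("hit fst_id '", hit$fst_id, "' does not match QC outcome '",
         qc_outcome$fst_id[[1L]], "'", call. = FALSE)
  }
  m_len <- nchar(qc_outcome$motif[[1L]])
  L <- hit$read_len
  which_end <- qc_outcome$which_end[[1L]]
  if (!which_end %in% c("head", "tail")) {
    stop("QC outcome has no end-proximal signature", call. = FALSE)
  }
  j <- if (which_end == "head") {
    qc_outcome$start_offset[[1L]] + m_len + 1L   # first base after motif
  } else {
    L - qc_outcome$end_distance[[1L]] - m_len    # last base before motif
  }
  pos <- if (hit$strand == "+") hit$ref_start + (j - hit$read_start)
         else hit$ref_end - (j - hit$read_start)
  if (!is.null(genome)) {
    pos <- max(1L, min(pos, nchar(genome[[hit$chrom]])))
  }
  data.frame(fst_id = hit$fst_id, chrom = hit$chrom,
             position = as.integer(pos), strand = hit$strand,
             score = hit$score, evalue = hit$evalue,
             identity = hit$identity, stringsAsFactors = FALSE)
}

#' Map a batch of high-confidence FSTs and call insertion sites
#'
#' @param pass_records records that passed [filter_batch()] (`fst_id`,
#'   `line_id`, `sequence`).
#' @param genome named character vector of chromosome sequences.
#' @param config a [pipeline_config()].
#' @param outcomes the `outcomes` data.frame from [filter_batch()].
#' @param index optional prebuilt [build_index()]; built from `genome`
#'   when NULL.
#' @param verbose log mapping counts.
#' @return list with `sites` (data.frame `fst_id`, `line_id`, `chrom`,
#'   `position`, `strand`, `score`, `evalue`, `identity`),
#'   `sites_dedup` (unique line_id x chrom x position), and `summary`
#'   (list: `input`, `mapped`, `unmapped`, `percent_mapped` as a
#'   round-half-up integer, `per_chromosome` named counts).
#' @export
map_batch <- function(pass_records, genome, config = pipeline_config(),
                      outcomes = NULL, index = NULL, verbose = TRUE) {
  stopifnot(is.data.frame(pass_records))
  n <- nrow(pass_records)
  if (n == 0L) {
    warning("no input reads; mapped percent reported as 0", call. = FALSE)
    return(list(
      sites = data.frame(fst_id = character(), line_id = character(),
                         chrom = character(), position = integer(),
                         strand = character(), score = numeric(),
                         evalue = numeric(), identity = numeric(),
                         stringsAsFactors = FALSE),
      sites_dedup = data.frame(line_id = character(), chrom = character(),
                               position = integer(), strand = character(),
                               n_fsts = integer(), stringsAsFactors = FALSE),
      summary = list(input = 0L, mapped = 0L, unmapped = 0L,
                     percent_mapped = 0, per_chromosome = integer(0))
    ))
  }
  if (is.null(index)) index <- build_index(genome, config$seed_k)
  if (is.null(outcomes)) {
    outcomes <- filter_batch(pass_records, config, verbose = FALSE)$outcomes
  }
  params <- karlin_params(config$match, config$mismatch)
  oc <- outcomes[match(pass_records$fst_id, outcomes$fst_id), , drop = FALSE]
  site_rows <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- align_read(pass_records[i, ], index, config, params)
    bh <- best_hit(hits)
    if (is.null(bh)) next
    site_rows[[i]] <- call_insertion_site(bh, oc[i, ], genome)
  }
  got <- !vapply(site_rows, is.null, logical(1))
  sites <- if (any(got)) do.call(rbind, site_rows[got]) else
    empty_hits()[, c("fst_id", "chrom"), drop = FALSE]
  if (any(got)) {
    sites$line_id <- pass_records$line_id[got]
    sites <- sites[, c("fst_id", "line_id", "chrom", "position", "strand",
                       "score", "evalue", "identity")]
    rownames(sites) <- NULL
  } else {
    sites <- data.frame(fst_id = character(), line_id = character(),
                        chrom = character(), position = integer(),
                        strand = character(), score = numeric(),
                        evalue = numeric(), identity = numeric(),
                        stringsAsFactors = FALSE)
  }
  mapped <- nrow(sites)
  dedup <- if (mapped > 0) {
    agg <- stats::aggregate(list(n_fsts = sites$fst_id),
                            by = list(line_id = sites$line_id,
                                      chrom = sites$chrom,
                                      position = sites$position,
                                      strand = sites$strand),
                            FUN = length)
    agg[order(agg$chrom, agg$position, agg$line_id), , drop = FALSE]
  } else {
    data.frame(line_id = character(), chrom = character(),
               position = integer(), strand = character(),
               n_fsts = integer(), stringsAsFactors = FALSE)
  }
  rownames(dedup) <- NULL
  per_chrom <- if (mapped > 0) {
    tab <- table(factor(sites$chrom, levels = names(genome)))
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(length(genome)), names(genome))
  summary <- list(
    input = n, mapped = mapped, unmapped = n - mapped,
    percent_mapped = as.integer(round_half_up(mapped / n * 100, 0)),
    per_chromosome = per_chrom
  )
  if (verbose) {
    message("FST mapping: ", n, " in, ", mapped, " mapped (",
            summary$percent_mapped, "%), ", n - mapped, " unmapped")
  }
  list(sites = sites, sites_dedup = dedup, summary = summary)
}
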