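# Synthetic TAIL-PCR FST data: toy genome, gene models, planted Tnt1
# insertions, and reads of four classes (SIGNATURE, NO_SIGNATURE,
# TOO_SHORT, INTERNAL_SIGNATURE) with per-read ground truth.

FST_CLASSES <- c("SIGNATURE", "NO_SIGNATURE", "TOO_SHORT", "INTERNAL_SIGNATURE")

# sample() with prob on a character set, returning a single string
random_seq <- function(n, gc_content) {
  if (n <= 0L) return("")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a random reference genome
#'
#' Bases are i.i.d. with P(G) + P(C) = `gc_content`, split evenly
#' between G and C (and between A and T). Deterministic for a fixed
#' `rng_seed`.
#'
#' @param config a [simulation_config()].
#' @return named character vector of chromosome sequences
#'   (`chr1`, `chr2`, ...).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "tnt1_simconfig"))
  if (config$gc_content < 0 || config$gc_content > 1) {
    stop("gc_content must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  seqs <- vapply(seq_len(config$n_chroms), function(i) {
    random_seq(config$chrom_length[i], config$gc_content)
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chroms))
  seqs
}

#' Generate non-overlapping gene models on a genome
#'
#' Genes are distributed across chromosomes proportionally to length,
#' with uniform lengths in `config$gene_length` and uniform strands.
#' Within a chromosome genes never overlap.
#'
#' @param genome named character vector of chromosome sequences.
#' @param config a [simulation_config()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
generate_genes <- function(genome, config) {
  stopifnot(inherits(config, "tnt1_simconfig"), length(genome) > 0)
  n <- config$n_genes
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  lens <- nchar(genome)
  n_per <- as.vector(stats::rmultinom(1, n, prob = lens / sum(lens)))
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    k <- n_per[ci]
    if (k == 0L) next
    L <- lens[ci]
    accepted_start <- integer(0)
    accepted_end <- integer(0)
    tries <- 0L
    while (length(accepted_start) < k) {
      tries <- tries + 1L
      if (tries > 200L * k) {
        stop("could not place ", k, " non-overlapping genes on ",
             names(genome)[ci], call. = FALSE)
      }
      gl <- sample(seq(config$gene_length[1], config$gene_length[2]), 1L)
      if (gl > L) next
      st <- sample.int(L - gl + 1L, 1L)
      en <- st + gl - 1L
      if (any(st <= accepted_end & en >= accepted_start)) next
      accepted_start <- c(accepted_start, st)
      accepted_end <- c(accepted_end, en)
    }
    ord <- order(accepted_start)
    out[[ci]] <- data.frame(
      chrom = names(genome)[ci],
      start = accepted_start[ord],
      end = accepted_end[ord],
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes <- cbind(gene_id = sprintf("gene%04d", seq_len(nrow(genes))), genes,
                 stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  genes
}

#' Plant Tnt1 insertions uniformly over a genome
#'
#' Insertion positions are drawn uniformly over the genome
#' (per-chromosome probability proportional to length), strands are
#' uniform, and no two insertions of the same line share a coordinate.
#'
#' @param genome named character vector of chromosome sequences.
#' @param config a [simulation_config()].
#' @return data.frame with `line_id`, `insertion_id`, `chrom`,
#'   `position` (1-based), `strand`.
#' @export
plant_insertions <- function(genome, config) {
  stopifnot(inherits(config, "tnt1_simconfig"), length(genome) > 0)
  lens <- nchar(genome)
  total_pos <- sum(as.numeric(lens))
  n_ins_range <- config$insertions_per_line
  rows <- vector("list", config$n_lines)
  for (li in seq_len(config$n_lines)) {
    n_ins <- if (n_ins_range[1] == n_ins_range[2]) n_ins_range[1] else
      sample(seq(n_ins_range[1], n_ins_range[2]), 1L)
    if (n_ins > total_pos) {
      stop("more insertions requested than distinct genomic positions",
           call. = FALSE)
    }
    # flat 1..total coordinate, deduplicated within the line
    flat <- unique(ceiling(runif(n_ins) * total_pos))
    while (length(flat) < n_ins) {
      flat <- unique(c(flat, ceiling(runif(n_ins - length(flat)) * total_pos)))
    }
    cum <- cumsum(as.numeric(lens))
    ci <- findInterval(flat - 1, cum) + 1L
    pos <- as.integer(flat - c(0, cum)[ci])
    rows[[li]] <- data.frame(
      line_id = sprintf("L%04d", li),
      chrom = names(genome)[ci],
      position = pos,
      strand = sample(c("+", "-"), n_ins, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth)) {
    return(data.frame(line_id = character(), insertion_id = character(),
                      chrom = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  truth <- cbind(insertion_id = sprintf("ins%05d", seq_len(nrow(truth))),
                 truth, stringsAsFactors = FALSE)
  truth[, c("line_id", "insertion_id", "chrom", "position", "strand")]
}

# apply i.i.d. substitutions to a sequence, leaving positions in
# `exempt` (logical vector) untouched; substituted bases always change
apply_substitutions <- function(seq, rate, exempt = NULL) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(ch)) < rate
  if (!is.null(exempt)) hit <- hit & !exempt
  hit <- hit & ch %in% c("A", "C", "G", "T")
  if (!any(hit)) return(seq)
  for (i in which(hit)) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# does seq contain any motif (or its revcomp, when enabled)?
has_any_motif <- function(seq, motifs, search_rc = TRUE) {
  pats <- if (search_rc) unique(c(motifs, revcomp(motifs))) else motifs
  any(vapply(pats, function(m) grepl(m, seq, fixed = TRUE), logical(1)))
}

# are all motif occurrences internal (outside both end windows)?
all_motifs_internal <- function(seq, motifs, end_window, search_rc = TRUE) {
  pats <- if (search_rc) unique(c(motifs, revcomp(motifs))) else motifs
  L <- nchar(seq)
  for (m in pats) {
    st <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1L]]
    if (st[1L] == -1L) next
    start_off <- st - 1L                       # 0-based
    end_dist <- L - (st + nchar(m) - 1L)       # bp after motif's last base
    if (any(start_off <= end_window - 1L | end_dist <= end_window - 1L)) {
      return(FALSE)
    }
  }
  TRUE
}

# Draw one read length (bp), Normal(mean, sd) clipped below at min_len.
draw_length <- function(config, min_len) {
  max(min_len, round(rnorm(1, config$fst_length_mean, config$fst_length_sd)))
}

#' Emit TAIL-PCR-like FST reads with ground truth
#'
#' Each emitted read is assigned a class i.i.d. from the configured
#' fractions. A SIGNATURE read carries one of the Tnt1 end motifs
#' (chosen uniformly) starting within `motif_jitter` bases of the read
#' start, followed by the genomic flank beginning at the insertion
#' position in the strand's direction (truncated at chromosome ends);
#' per-base substitutions are applied (motif bases exempt) and a
#' configured fraction of reads is emitted reverse-complemented.
#' SIGNATURE reads sample a planted insertion with replacement, so one
#' insertion can support several FSTs, as in real TAIL-PCR data.
#'
#' Class labels are guaranteed on the emitted sequence: NO_SIGNATURE
#' reads contain no motif on either strand, TOO_SHORT reads are shorter
#' than `pipeline$min_fst_length`, and INTERNAL_SIGNATURE reads contain
#' motifs only outside both end windows (contaminant reads are
#' rejection-sampled after noise is applied).
#'
#' @param genome named character vector of chromosome sequences.
#' @param truth insertion table from [plant_insertions()].
#' @param config a [simulation_config()].
#' @param pipeline a [pipeline_config()] supplying the motif set,
#'   `end_window` and `min_fst_length` the labels are defined against.
#' @param n_fsts total reads to emit; default
#'   `round(nrow(truth) / (1 - sum(contaminant fractions)))`, so the
#'   expected SIGNATURE count matches the number of planted insertions.
#' @return list with `records` (data.frame `fst_id`, `line_id`,
#'   `sequence`) and `truth` (per-FST data.frame `line_id`, `fst_id`,
#'   `chrom`, `position`, `strand`, `fst_class`; position/strand are NA
#'   for contaminant classes).
#' @export
emit_fsts <- function(genome, truth, config, pipeline = pipeline_config(),
                      n_fsts = NULL) {
  stopifnot(inherits(config, "tnt1_simconfig"),
            inherits(pipeline, "tnt1_config"))
  frac_sig <- 1 - config$frac_no_signature - config$frac_too_short -
    config$frac_internal_signature
  if (frac_sig <= 0 && nrow(truth) > 0) {
    stop("contaminant fractions leave no room for SIGNATURE reads",
         call. = FALSE)
  }
  if (is.null(n_fsts)) {
    n_fsts <- if (nrow(truth) == 0) 0L else round(nrow(truth) / frac_sig)
  }
  n_fsts <- as.integer(n_fsts)
  if (n_fsts == 0L) {
    return(list(
      records = data.frame(fst_id = character(), line_id = character(),
                           sequence = character(), stringsAsFactors = FALSE),
      truth = data.frame(line_id = character(), fst_id = character(),
                         chrom = character(), position = integer(),
                         strand = character(), fst_class = character(),
                         stringsAsFactors = FALSE),
      n_skipped = 0L
    ))
  }
  motifs <- pipeline$signature_motifs
  end_window <- pipeline$end_window
  min_len <- pipeline$min_fst_length
  probs <- c(frac_sig, config$frac_no_signature, config$frac_too_short,
             config$frac_internal_signature)
  classes <- sample(FST_CLASSES, n_fsts, replace = TRUE, prob = probs)
  if (any(classes == "SIGNATURE") && nrow(truth) == 0) {
    stop("SIGNATURE reads requested but no planted insertions supplied",
         call. = FALSE)
  }

  rec_id <- character(n_fsts); rec_line <- character(n_fsts)
  rec_seq <- character(n_fsts)
  tr_chrom <- rep(NA_character_, n_fsts); tr_pos <- rep(NA_integer_, n_fsts)
  tr_strand <- rep(NA_character_, n_fsts)
  keep <- rep(TRUE, n_fsts)
  n_skipped <- 0L

  # random genomic fragment (no motif constraints applied here)
  genomic_fragment <- function(len) {
    lens <- nchar(genome)
    ok <- which(lens >= len)
    if (length(ok) == 0L) return(random_seq(len, config$gc_content))
    ci <- if (length(ok) == 1L) ok else
      sample(ok, 1L, prob = lens[ok] / sum(lens[ok]))
    st <- sample.int(lens[ci] - len + 1L, 1L)
    substr(genome[[ci]], st, st + len - 1L)
  }

  for (i in seq_len(n_fsts)) {
    cls <- classes[i]
    if (cls == "SIGNATURE") {
      ti <- sample.int(nrow(truth), 1L)
      chrom <- truth$chrom[ti]; pos <- truth$position[ti]
      strand <- truth$strand[ti]
      motif <- sample(motifs, 1L)
      jit <- if (config$motif_jitter > 0L)
        sample.int(min(config$motif_jitter, end_window - 1L) + 1L, 1L) - 1L
      else 0L
      total_len <- draw_length(config, min_len)
      flank_len <- total_len - nchar(motif) - jit
      chrom_len <- nchar(genome[[chrom]])
      if (strand == "+") {
        flank_len <- min(flank_len, chrom_len - pos + 1L)
        flank <- if (flank_len >= 1L)
          substr(genome[[chrom]], pos, pos + flank_len - 1L) else ""
      } else {
        flank_len <- min(flank_len, pos)
        flank <- if (flank_len >= 1L)
          revcomp(substr(genome[[chrom]], pos - flank_len + 1L, pos)) else ""
      }
      if (flank_len < 1L ||
          jit + nchar(motif) + flank_len < min_len) {
        # terminal insertion: flank empty or read unavoidably short
        keep[i] <- FALSE; n_skipped <- n_skipped + 1L
        next
      }
      lead <- random_seq(jit, config$gc_content)
      flank <- apply_substitutions(flank, config$substitution_rate)
      seq <- paste0(lead, motif, flank)
      if (runif(1) < config$frac_revcomp) seq <- revcomp(seq)
      rec_seq[i] <- seq
      tr_chrom[i] <- chrom; tr_pos[i] <- pos; tr_strand[i] <- strand
      rec_line[i] <- truth$line_id[ti]
    } else if (cls == "NO_SIGNATURE") {
      repeat {
        seq <- apply_substitutions(genomic_fragment(draw_length(config, min_len)),
                                   config$substitution_rate)
        if (!has_any_motif(seq, motifs)) break
      }
      rec_seq[i] <- seq
      rec_line[i] <- sprintf("L%04d", sample.int(max(config$n_lines, 1L), 1L))
    } else if (cls == "TOO_SHORT") {
      len <- sample(seq(20L, min_len - 1L), 1L)
      motif <- sample(motifs, 1L)
      body <- if (len > nchar(motif))
        paste0(motif, genomic_fragment(len - nchar(motif)))
      else genomic_fragment(len)
      rec_seq[i] <- apply_substitutions(body, config$substitution_rate)
      rec_line[i] <- sprintf("L%04d", sample.int(max(config$n_lines, 1L), 1L))
    } else { # INTERNAL_SIGNATURE
      repeat {
        len <- max(draw_length(config, min_len), 2L * end_window + 30L)
        motif <- sample(motifs, 1L)
        # motif start st (1-based) with start_offset > end_window - 1
        # and end_distance > end_window - 1
        lo <- end_window + 1L
        hi <- len - nchar(motif) + 1L - end_window
        if (hi < lo) next
        st <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
        left <- genomic_fragment(st - 1L)
        right <- genomic_fragment(len - (st - 1L) - nchar(motif))
        seq <- paste0(apply_substitutions(left, config$substitution_rate),
                      motif,
                      apply_substitutions(right, config$substitution_rate))
        if (all_motifs_internal(seq, motifs, end_window) &&
            has_any_motif(seq, motifs)) break
      }
      rec_seq[i] <- seq
      rec_line[i] <- sprintf("L%04d", sample.int(max(config$n_lines, 1L), 1L))
    }
  }

  idx <- which(keep)
  rec_id <- sprintf("%s|fst%05d", rec_line, seq_len(n_fsts))
  if (n_skipped > 0L) {
    message(n_skipped, " SIGNATURE read(s) skipped (terminal insertion, ",
            "flank empty or unavoidably short)")
  }
  list(
    records = data.frame(fst_id = rec_id[idx], line_id = rec_line[idx],
                         sequence = rec_seq[idx], stringsAsFactors = FALSE),
    truth = data.frame(line_id = rec_line[idx], fst_id = rec_id[idx],
                       chrom = tr_chrom[idx], position = tr_pos[idx],
                       strand = tr_strand[idx], fst_class = classes[idx],
                       stringsAsFactors = FALSE),
    n_skipped = n_skipped
  )
}

#' Simulate a complete toy FST dataset
#'
#' Convenience wrapper chaining [generate_genome()], [generate_genes()],
#' [plant_insertions()] and [emit_fsts()] under one seed.
#'
#' @param config a [simulation_config()].
#' @param pipeline a [pipeline_config()].
#' @param n_fsts passed to [emit_fsts()].
#' @return list with `genome`, `genes`, `insertions`, `records`,
#'   `truth`, `n_skipped`.
#' @export
simulate_fst_dataset <- function(config = simulation_config(),
                                 pipeline = pipeline_config(),
                                 n_fsts = NULL) {
  genome <- generate_genome(config)   # seeds the RNG
  genes <- generate_genes(genome, config)
  insertions <- plant_insertions(genome, config)
  em <- emit_fsts(genome, insertions, config, pipeline, n_fsts = n_fsts)
  list(genome = genome, genes = genes, insertions = insertions,
       records = em$records, truth = em$truth, n_skipped = em$n_skipped)
}
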