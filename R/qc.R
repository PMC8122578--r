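# Signature-based FST quality control: an FST is kept only when it is
# at least min_fst_length bp long and carries a Tnt1 end motif within
# end_window bp of one of its ends.

QC_REASONS <- c("PASS", "TOO_SHORT", "NO_SIGNATURE", "SIGNATURE_INTERNAL")

#' Find Tnt1 signature motifs in a read
#'
#' Reports every exact occurrence of each motif (and, when enabled, of
#' its reverse complement) with 0-based start offsets, the distance
#' from the motif's last base to the read's last base, and the end
#' classification: `head` when the motif starts within the first
#' `end_window` bases, `tail` when it ends within the last
#' `end_window` bases, `internal` otherwise (head wins when both
#' hold). N never matches any motif base.
#'
#' @param sequence a single nucleotide string.
#' @param motifs character vector of motifs over \{A,C,G,T\}.
#' @param search_reverse_complement also search reverse complements.
#' @param end_window end-proximity window in bp.
#' @return data.frame with columns `motif`, `strand_of_motif`
#'   (`forward`/`revcomp`), `start_offset` (0-based), `end_distance`,
#'   `which_end`, sorted by `start_offset`. Zero rows when nothing
#'   matches.
#' @export
find_signature <- function(sequence, motifs,
                           search_reverse_complement = TRUE,
                           end_window = 28L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  check_alphabet(motifs, allow_n = FALSE, what = "signature motif")
  L <- nchar(sequence)
  pats <- data.frame(motif = motifs, pattern = motifs,
                     strand_of_motif = "forward", stringsAsFactors = FALSE)
  if (isTRUE(search_reverse_complement)) {
    rc <- data.frame(motif = motifs, pattern = revcomp(motifs),
                     strand_of_motif = "revcomp", stringsAsFactors = FALSE)
    # drop revcomp patterns identical to a forward pattern (palindromes)
    rc <- rc[!rc$pattern %in% pats$pattern, , drop = FALSE]
    pats <- rbind(pats, rc)
  }
  hits <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    # zero-width lookahead: report overlapping occurrences too
    # (tandem motif repeats otherwise hide the end-proximal copy)
    pat <- paste0("(?=", pats$pattern[i], ")")
    st <- gregexpr(pat, sequence, perl = TRUE)[[1L]]
    if (st[1L] == -1L) next
    m_len <- nchar(pats$pattern[i])
    hits[[i]] <- data.frame(
      motif = pats$motif[i],
      strand_of_motif = pats$strand_of_motif[i],
      start_offset = as.integer(st) - 1L,
      end_distance = L - (as.integer(st) + m_len - 1L),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(motif = character(), strand_of_motif = character(),
                      start_offset = integer(), end_distance = integer(),
                      which_end = character(), stringsAsFactors = FALSE))
  }
  out$which_end <- ifelse(out$start_offset <= end_window - 1L, "head",
                          ifelse(out$end_distance <= end_window - 1L,
                                 "tail", "internal"))
  out <- out[order(out$start_offset, out$strand_of_motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one FST read
#'
#' Rules are applied in fixed precedence: (1) length below
#' `min_fst_length` gives `TOO_SHORT`; (2) no motif occurrence at all
#' gives `NO_SIGNATURE`; (3) occurrences exist but none is
#' end-proximal gives `SIGNATURE_INTERNAL`; otherwise `PASS`, with
#' `best_match` the end-proximal occurrence closest to its own read
#' end (head matches measured by start offset, tail matches by tail
#' distance; ties prefer head).
#'
#' @param record a one-row data.frame (or list) with `fst_id` and
#'   `sequence`.
#' @param config a [pipeline_config()].
#' @return list of class `tnt1_qc` with `fst_id`, `passed`, `reason`,
#'   `best_match` (one-row data.frame or NULL).
#' @export
classify_fst <- function(record, config = pipeline_config()) {
  stopifnot(inherits(config, "tnt1_config"))
  seq <- toupper(record$sequence[[1L]])
  if (is.na(seq) || nchar(seq) == 0L) {
    stop("empty sequence for FST '", record$fst_id[[1L]], "'", call. = FALSE)
  }
  out <- list(fst_id = record$fst_id[[1L]], passed = FALSE,
              reason = NA_character_, best_match = NULL)
  class(out) <- "tnt1_qc"
  if (nchar(seq) < config$min_fst_length) {
    out$reason <- "TOO_SHORT"
    return(out)
  }
  m <- find_signature(seq, config$signature_motifs,
                      config$search_reverse_complement, config$end_window)
  if (nrow(m) == 0L) {
    out$reason <- "NO_SIGNATURE"
    return(out)
  }
  endward <- m[m$which_end %in% c("head", "tail"), , drop = FALSE]
  if (nrow(endward) == 0L) {
    out$reason <- "SIGNATURE_INTERNAL"
    return(out)
  }
  prox <- ifelse(endward$which_end == "head",
                 endward$start_offset, endward$end_distance)
  # smallest distance to its own end; ties prefer head, then the longer
  # motif (one motif's reverse complement nests inside another), then
  # smaller offset
  ord <- order(prox, endward$which_end != "head", -nchar(endward$motif),
               endward$start_offset)
  out$passed <- TRUE
  out$reason <- "PASS"
  out$best_match <- endward[ord[1L], , drop = FALSE]
  rownames(out$best_match) <- NULL
  out
}

#' Filter a batch of FSTs through the QC funnel
#'
#' @param records data.frame with `fst_id`, `line_id`, `sequence`.
#' @param config a [pipeline_config()].
#' @param verbose log the funnel (input, pass, reject-reason histogram).
#' @return list with `pass` (records subset), `fail` (records subset
#'   plus `reason`), `outcomes` (per-read data.frame `fst_id`,
#'   `passed`, `reason`, and best-match columns for passing reads),
#'   and `summary` (a funnel summary, see [funnel_counts()]).
#' @export
filter_batch <- function(records, config = pipeline_config(),
                         verbose = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("fst_id", "sequence") %in% names(records)))
  if (anyDuplicated(records$fst_id)) {
    stop("duplicate fst_id(s): ",
         paste(head(unique(records$fst_id[duplicated(records$fst_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  reason <- character(n)
  bm_motif <- rep(NA_character_, n); bm_strand <- rep(NA_character_, n)
  bm_off <- rep(NA_integer_, n); bm_dist <- rep(NA_integer_, n)
  bm_end <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    qc <- classify_fst(records[i, ], config)
    reason[i] <- qc$reason
    if (qc$passed) {
      bm_motif[i] <- qc$best_match$motif
      bm_strand[i] <- qc$best_match$strand_of_motif
      bm_off[i] <- qc$best_match$start_offset
      bm_dist[i] <- qc$best_match$end_distance
      bm_end[i] <- qc$best_match$which_end
    }
  }
  outcomes <- data.frame(
    fst_id = records$fst_id, passed = reason == "PASS", reason = reason,
    motif = bm_motif, strand_of_motif = bm_strand, start_offset = bm_off,
    end_distance = bm_dist, which_end = bm_end, stringsAsFactors = FALSE
  )
  pass <- records[outcomes$passed, , drop = FALSE]
  fail <- records[!outcomes$passed, , drop = FALSE]
  fail$reason <- reason[!outcomes$passed]
  rownames(pass) <- rownames(fail) <- NULL
  reject_reasons <- table(factor(reason[reason != "PASS"],
                                 levels = setdiff(QC_REASONS, "PASS")))
  summary <- funnel_counts(total = n, pass = nrow(pass),
                           reasons = setNames(as.integer(reject_reasons),
                                              names(reject_reasons)))
  if (verbose) {
    message("FST QC funnel: ", n, " in, ", nrow(pass), " pass, ",
            summary$rejected, " rejected [",
            paste(sprintf("%s=%d", names(summary$reasons), summary$reasons),
                  collapse = ", "), "]")
  }
  list(pass = pass, fail = fail, outcomes = outcomes, summary = summary)
}

#' Funnel summary arithmetic
#'
#' Builds the QC funnel bookkeeping from counts: `rejected` is always
#' `total - pass`, and when a reject-reason histogram is supplied it
#' must sum to `rejected` (the published funnel reads
#' 392,396 in, 221,275 pass, 171,121 rejected).
#'
#' @param total reads in.
#' @param pass reads passing.
#' @param reasons optional named integer vector of reject-reason counts.
#' @return list of class `tnt1_funnel` with `total`, `pass`,
#'   `rejected`, `reasons`.
#' @export
#' @examples
#' funnel_counts(392396, 221275)$rejected
funnel_counts <- function(total, pass, reasons = NULL) {
  stopifnot(total >= 0, pass >= 0, pass <= total)
  rejected <- total - pass
  if (!is.null(reasons)) {
    stopifnot(!is.null(names(reasons)), all(reasons >= 0))
    if (sum(reasons) != rejected) {
      stop("reject-reason counts (", sum(reasons),
           ") do not sum to total - pass (", rejected, ")", call. = FALSE)
    }
  }
  structure(list(total = total, pass = pass, rejected = rejected,
                 reasons = reasons),
            class = "tnt1_funnel")
}
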