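# Assembly partition statistics: N50, contig splitting at N-gaps, and
# per-partition base-pair/count summaries.

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L cover at
#' least half of the total length.
#'
#' @param lengths numeric vector of positive lengths.
#' @return the N50 length (one of `lengths`).
#' @export
#' @examples
#' compute_n50(c(5, 4, 3, 2, 1)) # 4
compute_n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  stopifnot(all(lengths > 0))
  srt <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(as.numeric(srt))
  srt[which(csum >= sum(as.numeric(srt)) / 2)[1L]]
}

#' Split scaffolds into contigs at N-gaps
#'
#' A gap is a run of at least `min_n_run` consecutive N; contigs are
#' the gap-free fragments (zero-length fragments discarded). Fragment
#' plus gap lengths always sum to the scaffold length.
#'
#' @param genome named character vector of scaffold sequences.
#' @param min_n_run minimum N-run length treated as a gap.
#' @param verbose log all-N scaffolds.
#' @return named list of integer vectors of per-scaffold contig
#'   lengths (an all-N scaffold yields an empty vector).
#' @export
contigs_from_scaffolds <- function(genome, min_n_run = 10L, verbose = TRUE) {
  stopifnot(min_n_run >= 1)
  pat <- sprintf("N{%d,}", as.integer(min_n_run))
  out <- lapply(seq_along(genome), function(ci) {
    pieces <- strsplit(gsub(pat, "\n", genome[[ci]]), "\n", fixed = TRUE)[[1L]]
    lens <- nchar(pieces)
    lens <- lens[lens > 0L]
    if (length(lens) == 0L && verbose) {
      message("scaffold ", names(genome)[ci], " is all gap (no contigs)")
    }
    lens
  })
  names(out) <- names(genome)
  out
}

#' Partition statistics for a scaffolded assembly
#'
#' Computes, per named partition and as a grand total: summed base
#' pairs, scaffold count, scaffold N50, and (when sequences are
#' supplied) contig count and contig N50. Scaffolds below the
#' minimum-size cutoff are excluded first, matching the published
#' convention of dropping scaffolds under 1 kb.
#'
#' @param records data.frame with `name`, `length`, `partition_label`
#'   (length may be omitted when `genome` is given).
#' @param genome optional named character vector of scaffold sequences
#'   (enables contig statistics).
#' @param min_scaffold_length exclusion cutoff in bp.
#' @param min_n_run gap definition passed to
#'   [contigs_from_scaffolds()].
#' @return data.frame with one row per partition plus a `total` row:
#'   `partition_label`, `n_scaffolds`, `total_bp`, `scaffold_n50`,
#'   `n_contigs`, `contig_n50` (contig columns NA without `genome`).
#' @export
partition_summary <- function(records, genome = NULL,
                              min_scaffold_length = 1000L,
                              min_n_run = 10L) {
  stopifnot(is.data.frame(records),
            all(c("name", "partition_label") %in% names(records)))
  if (!"length" %in% names(records)) {
    stopifnot(!is.null(genome))
    records$length <- nchar(genome[records$name])
  }
  unlabeled <- is.na(records$partition_label) | records$partition_label == ""
  if (any(unlabeled)) {
    stop("unlabeled scaffold(s): ",
         paste(head(records$name[unlabeled], 10), collapse = ", "),
         call. = FALSE)
  }
  records <- records[records$length >= min_scaffold_length, , drop = FALSE]
  if (nrow(records) == 0L) stop("no scaffolds pass the size cutoff",
                                call. = FALSE)
  contigs <- if (!is.null(genome)) {
    contigs_from_scaffolds(genome[records$name], min_n_run, verbose = FALSE)
  } else NULL
  one <- function(idx, label) {
    lens <- records$length[idx]
    clens <- if (!is.null(contigs)) unlist(contigs[records$name[idx]],
                                           use.names = FALSE) else NULL
    data.frame(
      partition_label = label,
      n_scaffolds = length(lens),
      total_bp = sum(as.numeric(lens)),
      scaffold_n50 = compute_n50(lens),
      n_contigs = if (is.null(clens)) NA_integer_ else length(clens),
      contig_n50 = if (is.null(clens) || length(clens) == 0L) NA_real_
                   else compute_n50(clens),
      stringsAsFactors = FALSE
    )
  }
  labels <- unique(records$partition_label)
  rows <- lapply(labels, function(lb)
    one(which(records$partition_label == lb), lb))
  rows[[length(rows) + 1L]] <- one(seq_len(nrow(records)), "total")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grand-total row from pre-aggregated partition statistics
#'
#' Sums base pairs and scaffold/contig counts over partition rows —
#' the arithmetic check that published partition rows add up to the
#' published assembly totals.
#'
#' @param stats data.frame with `total_bp` and `n_scaffolds` (and
#'   optionally `n_contigs`) columns, one row per partition.
#' @return list with `total_bp`, `n_scaffolds`, `n_contigs`.
#' @export
partition_grand_total <- function(stats) {
  stopifnot(all(c("total_bp", "n_scaffolds") %in% names(stats)))
  list(
    total_bp = sum(as.numeric(stats$total_bp)),
    n_scaffolds = sum(stats$n_scaffolds),
    n_contigs = if ("n_contigs" %in% names(stats))
      sum(stats$n_contigs) else NA_integer_
  )
}
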