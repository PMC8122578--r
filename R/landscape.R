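# Insertion-landscape statistics: per-gene tallies, per-chromosome
# distribution tables, frequency classes, frequent-gene selection,
# fixed-width genomic bins with GC content, and synteny-block tallies.

#' Assign insertion sites to genes
#'
#' A site is assigned to every gene whose full span (1-based,
#' inclusive at both ends; introns/UTRs included) contains its
#' position. Overlapping genes each receive the insertion.
#'
#' @param sites data.frame with `chrom`, `position`, `fst_id`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param verbose log multi-gene assignments.
#' @return list with `tallies` (data.frame `gene_id`,
#'   `insertion_count`, `fst_ids` — comma-joined supporting ids) and
#'   `zero_genes` (character vector of genes with no insertion).
#' @export
assign_to_genes <- function(sites, genes, verbose = FALSE) {
  stopifnot(all(c("chrom", "position", "fst_id") %in% names(sites)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (nrow(genes) == 0L) {
    return(list(tallies = data.frame(gene_id = character(),
                                     insertion_count = integer(),
                                     fst_ids = character(),
                                     stringsAsFactors = FALSE),
                zero_genes = character()))
  }
  if (nrow(sites) == 0L) {
    return(list(tallies = data.frame(gene_id = character(),
                                     insertion_count = integer(),
                                     fst_ids = character(),
                                     stringsAsFactors = FALSE),
                zero_genes = sort(genes$gene_id)))
  }
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end)
  )
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position, width = 1L)
  )
  ov <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  if (verbose && length(si) > 0L) {
    multi <- sum(table(si) > 1L)
    if (multi > 0L) {
      message(multi, " site(s) fell in more than one (overlapping) gene")
    }
  }
  if (length(gi) == 0L) {
    return(list(tallies = data.frame(gene_id = character(),
                                     insertion_count = integer(),
                                     fst_ids = character(),
                                     stringsAsFactors = FALSE),
                zero_genes = sort(genes$gene_id)))
  }
  by_gene <- split(sites$fst_id[si], genes$gene_id[gi])
  tallies <- data.frame(
    gene_id = names(by_gene),
    insertion_count = lengths(by_gene),
    fst_ids = vapply(by_gene, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  tallies <- tallies[order(-tallies$insertion_count, tallies$gene_id), ,
                     drop = FALSE]
  rownames(tallies) <- NULL
  list(tallies = tallies,
       zero_genes = sort(setdiff(genes$gene_id, tallies$gene_id)))
}

#' Per-chromosome insertion distribution table
#'
#' One row per chromosome with the FST count and its percentage of the
#' high-confidence FST total (round-half-up at `digits` decimals),
#' plus rows for the total mapped to chromosomes, the total mapped to
#' unanchored scaffolds, and the mean insertions per chromosome
#' (round-half-up integer).
#'
#' @param sites data.frame with a `chrom` column, or NULL when
#'   `counts` is given.
#' @param n_highconf_total the high-confidence FST total used as the
#'   percentage denominator.
#' @param chromosomes character vector of chromosome names; sites on
#'   any other sequence count as unanchored. Defaults to all
#'   chromosomes seen in `sites`/`counts`.
#' @param counts optional named integer vector of per-sequence counts,
#'   used instead of `sites` (arithmetic-level reproduction from
#'   printed counts).
#' @param digits decimal places for the percent column.
#' @return data.frame with `chrom`, `fst_count`, `percent_of_total`;
#'   the summary rows are labelled `total_chromosomes`, `unanchored`,
#'   `mean_per_chromosome`.
#' @export
chromosome_table <- function(sites = NULL, n_highconf_total,
                             chromosomes = NULL, counts = NULL,
                             digits = 2) {
  stopifnot(n_highconf_total > 0)
  if (is.null(counts)) {
    stopifnot(!is.null(sites), "chrom" %in% names(sites))
    counts <- table(sites$chrom)
    counts <- setNames(as.integer(counts), names(counts))
  }
  if (is.null(chromosomes)) chromosomes <- names(counts)
  unknown <- setdiff(names(counts), chromosomes)
  if (length(unknown) > 0L && !is.null(sites)) {
    warning(sum(counts[unknown]), " site(s) on unanchored scaffold(s)",
            call. = FALSE)
  }
  chrom_counts <- setNames(integer(length(chromosomes)), chromosomes)
  present <- intersect(chromosomes, names(counts))
  chrom_counts[present] <- counts[present]
  unanchored <- sum(counts[unknown])
  rows <- data.frame(
    chrom = c(chromosomes, "total_chromosomes", "unanchored",
              "mean_per_chromosome"),
    fst_count = c(unname(chrom_counts), sum(chrom_counts), unanchored,
                  as.integer(round_half_up(mean(chrom_counts), 0))),
    stringsAsFactors = FALSE
  )
  rows$percent_of_total <- c(
    percent_of(chrom_counts, n_highconf_total, digits),
    percent_of(sum(chrom_counts), n_highconf_total, digits),
    percent_of(unanchored, n_highconf_total, digits),
    NA_real_
  )
  rows
}

#' Gene frequency-class summary
#'
#' Counts genes with >= 1, > 1 and >= 4 insertions, their percentages
#' of the annotated gene total (round-half-up at the per-class printed
#' precision), and the mean insertions per gene under both candidate
#' denominators (genes with at least one insertion, and all annotated
#' genes).
#'
#' @param tallies tallies data.frame from [assign_to_genes()].
#' @param n_annotated_genes annotated gene total (the percentage
#'   denominator).
#' @param digits named numeric vector of decimal places per class.
#' @return list with `n_genes_ge1`, `n_genes_gt1`, `n_genes_ge4`,
#'   `pct_ge1`, `pct_gt1`, `pct_ge4`, `mean_per_inserted_gene`,
#'   `mean_per_annotated_gene`, `n_genic_insertions`.
#' @export
frequency_classes <- function(tallies, n_annotated_genes,
                              digits = c(ge1 = 2, gt1 = 1, ge4 = 2)) {
  stopifnot(n_annotated_genes >= nrow(tallies))
  cnt <- tallies$insertion_count
  n_ge1 <- sum(cnt >= 1L); n_gt1 <- sum(cnt > 1L); n_ge4 <- sum(cnt >= 4L)
  total_ins <- sum(cnt)
  list(
    n_genes_ge1 = n_ge1,
    n_genes_gt1 = n_gt1,
    n_genes_ge4 = n_ge4,
    pct_ge1 = percent_of(n_ge1, n_annotated_genes, digits[["ge1"]]),
    pct_gt1 = percent_of(n_gt1, n_annotated_genes, digits[["gt1"]]),
    pct_ge4 = percent_of(n_ge4, n_annotated_genes, digits[["ge4"]]),
    mean_per_inserted_gene = if (n_ge1 > 0) total_ins / n_ge1 else 0,
    mean_per_annotated_gene = if (n_annotated_genes > 0)
      total_ins / n_annotated_genes else 0,
    n_genic_insertions = total_ins
  )
}

#' Select frequently inserted genes
#'
#' Genes whose insertion count is strictly greater than the threshold
#' (by default the mean insertions per inserted gene), sorted by count
#' descending then gene id — the selection rule feeding GO-enrichment
#' of frequently disrupted genes.
#'
#' @param tallies tallies data.frame from [assign_to_genes()].
#' @param mean_threshold numeric threshold; default computes the mean
#'   insertions per gene with >= 1 insertion from `tallies`.
#' @return data.frame subset of `tallies`, re-sorted.
#' @export
select_frequent_genes <- function(tallies, mean_threshold = NULL) {
  if (is.null(mean_threshold)) {
    mean_threshold <- if (nrow(tallies) > 0)
      sum(tallies$insertion_count) / nrow(tallies) else 0
  }
  stopifnot(mean_threshold >= 0)
  out <- tallies[tallies$insertion_count > mean_threshold, , drop = FALSE]
  out <- out[order(-out$insertion_count, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fixed-width genomic bins with insertion counts and GC content
#'
#' Each chromosome is tiled with bins `[1..w]`, `[w+1..2w]`, ... (the
#' terminal bin truncated at the chromosome end). Sites are counted by
#' containment; the GC fraction is (G+C)/(A+C+G+T) per bin, 0 with
#' `all_n = TRUE` for bins containing no called base.
#'
#' @param sites data.frame with `chrom`, `position`.
#' @param genome named character vector of chromosome sequences.
#' @param bin_width bin width in bp (the published landscape uses
#'   500 kb).
#' @return data.frame with `chrom`, `bin_start`, `bin_end`,
#'   `insertion_count`, `gc_fraction`, `all_n`.
#' @export
bin_landscape <- function(sites, genome, bin_width = 500000L) {
  stopifnot(bin_width > 0, length(genome) > 0)
  bin_width <- as.integer(bin_width)
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    L <- nchar(genome[[ci]])
    n_bins <- ceiling(L / bin_width)
    bin_start <- (seq_len(n_bins) - 1L) * bin_width + 1L
    bin_end <- pmin(seq_len(n_bins) * bin_width, L)
    pos <- sites$position[sites$chrom == chrom]
    cnt <- if (length(pos) > 0) {
      tabulate(((pos - 1L) %/% bin_width) + 1L, nbins = n_bins)
    } else integer(n_bins)
    views <- Biostrings::Views(Biostrings::DNAString(genome[[ci]]),
                               start = bin_start, end = bin_end)
    freq <- Biostrings::letterFrequency(views, c("A", "C", "G", "T"))
    called <- rowSums(freq)
    gc <- ifelse(called > 0, (freq[, "C"] + freq[, "G"]) / called, 0)
    out[[ci]] <- data.frame(
      chrom = chrom, bin_start = bin_start, bin_end = bin_end,
      insertion_count = cnt, gc_fraction = gc, all_n = called == 0,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-synteny-block insertion tallies
#'
#' For each block: the number of member genes, the number with at
#' least one insertion, and the summed insertions; sorted by
#' genes-with-insertions descending. Genes appearing in several blocks
#' are counted in each (logged).
#'
#' @param tallies tallies data.frame from [assign_to_genes()].
#' @param blocks data.frame with `block_id`, `gene_id`.
#' @param annotation optional character vector of annotated gene ids;
#'   block members missing from it are logged and kept out of the
#'   gene counts.
#' @param verbose log overlaps and unresolved genes.
#' @return data.frame with `block_id`, `n_genes`,
#'   `n_genes_with_insertion`, `n_insertions`.
#' @export
synteny_tally <- function(tallies, blocks, annotation = NULL,
                          verbose = TRUE) {
  stopifnot(is.data.frame(blocks))
  if (nrow(blocks) == 0L) stop("empty synteny block table", call. = FALSE)
  stopifnot(all(c("block_id", "gene_id") %in% names(blocks)))
  if (!is.null(annotation)) {
    unresolved <- !blocks$gene_id %in% annotation
    if (any(unresolved) && verbose) {
      message(sum(unresolved), " block member gene(s) not in the annotation")
    }
    blocks <- blocks[!unresolved, , drop = FALSE]
  }
  n_multi <- sum(table(unique(blocks)[, "gene_id"]) > 1L)
  if (n_multi > 0L && verbose) {
    message(n_multi, " gene(s) belong to more than one block")
  }
  cnt <- setNames(tallies$insertion_count, tallies$gene_id)
  per_block <- split(blocks$gene_id, blocks$block_id)
  res <- data.frame(
    block_id = names(per_block),
    n_genes = unname(lengths(per_block)),
    n_genes_with_insertion = unname(vapply(per_block, function(g)
      sum(g %in% names(cnt)), integer(1))),
    n_insertions = unname(vapply(per_block, function(g)
      sum(cnt[g[g %in% names(cnt)]]), numeric(1))),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$n_genes_with_insertion, res$block_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
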