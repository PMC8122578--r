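#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the \{A,C,G,T,N\}
#' alphabet; duplicate sequence names and empty files are rejected.
#' Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences (a
#'   "reference genome"); names are the FASTA identifiers (first word
#'   of each header).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name(s) in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(dss))
  names(seqs) <- nm
  check_alphabet(seqs, allow_n = TRUE, what = paste0("FASTA '", path, "'"))
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence in '", path, "'", call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, filepath = path, width = width)
  invisible(path)
}

#' Read FST reads from FASTA
#'
#' The line identifier is parsed from the read id prefix before the
#' first `|` when one is present (ids of the form `LINE|fst00001`);
#' otherwise the line id equals the read id.
#'
#' @param path path to a FASTA file of FST reads.
#' @return data.frame with columns `fst_id`, `line_id`, `sequence`.
#' @export
read_fst_fasta <- function(path) {
  seqs <- read_genome_fasta(path)
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate FST id(s) in '", path, "'", call. = FALSE)
  data.frame(
    fst_id = ids,
    line_id = ifelse(grepl("|", ids, fixed = TRUE), sub("\\|.*$", "", ids), ids),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}

#' Write FST records to FASTA
#'
#' @param records data.frame with `fst_id` and `sequence` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fst_fasta <- function(records, path) {
  stopifnot(all(c("fst_id", "sequence") %in% names(records)))
  write_fasta(setNames(records$sequence, records$fst_id), path)
}

#' Read gene models from GFF3
#'
#' Keeps only records of the requested feature type. Coordinates are
#' 1-based inclusive, as in GFF3. When a genome is supplied, records on
#' unknown chromosomes are dropped with a warning and coordinates are
#' validated against chromosome lengths.
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature type to keep (default `"gene"`).
#' @param genome optional named character vector (reference genome) for
#'   coordinate validation.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3_genes <- function(path, feature_type = "gene", genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NULL
  if (is.null(ids) || anyNA(ids)) {
    alt <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
    ids <- ifelse(is.na(ids), alt, ids)
    ids[is.na(ids)] <- paste0(feature_type, "_", which(is.na(ids)))
  }
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id(s) in '", path, "'", call. = FALSE)
  }
  if (!is.null(genome)) {
    unknown <- !genes$chrom %in% names(genome)
    if (any(unknown)) {
      warning(sum(unknown), " gene record(s) on unknown chromosome(s) skipped",
              call. = FALSE)
      genes <- genes[!unknown, , drop = FALSE]
    }
    too_far <- genes$end > nchar(genome[genes$chrom])
    if (any(too_far)) {
      stop("gene(s) extend beyond chromosome end: ",
           paste(head(genes$gene_id[too_far], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  rownames(genes) <- NULL
  genes
}

#' Write gene models to GFF3
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param path output path.
#' @param feature_type feature type to write.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path, feature_type = "gene",
                             source = "tnt1fst") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    type = feature_type,
    source = source,
    ID = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write insertion sites to BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based
#' half-open, so a site at position p is written as
#' `chromStart = p - 1`, `chromEnd = p`. The name column carries the
#' FST id, the score column is unused (0), and the strand column comes
#' from the site.
#'
#' @param sites data.frame with `chrom`, `position`, `fst_id`, `strand`.
#' @param path output path.
#' @param genome optional reference genome for bounds checking.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path, genome = NULL) {
  stopifnot(all(c("chrom", "position", "fst_id", "strand") %in% names(sites)))
  if (nrow(sites) > 0) {
    if (any(sites$position < 1)) stop("site position < 1", call. = FALSE)
    if (!is.null(genome)) {
      bad <- sites$position > nchar(genome[sites$chrom])
      if (anyNA(bad) || any(bad)) {
        stop("site position outside chromosome bounds", call. = FALSE)
      }
    }
  }
  bed <- data.frame(
    chrom = sites$chrom,
    chromStart = sites$position - 1L,
    chromEnd = sites$position,
    name = sites$fst_id,
    score = rep(0L, nrow(sites)),
    strand = sites$strand,
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read insertion sites from BED
#'
#' Inverse of [write_bed()]: converts 0-based half-open intervals of
#' width 1 back to 1-based positions.
#'
#' @param path path to a BED file written by [write_bed()].
#' @return data.frame with `chrom`, `position`, `fst_id`, `strand`.
#' @export
read_bed_sites <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), position = integer(),
                      fst_id = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("expected 6 BED columns in '", path, "'", call. = FALSE)
  if (any(bed[[3]] - bed[[2]] != 1L)) {
    stop("BED intervals must have width 1 (single insertion positions)",
         call. = FALSE)
  }
  data.frame(chrom = as.character(bed[[1]]), position = bed[[2]] + 1L,
             fst_id = as.character(bed[[4]]), strand = as.character(bed[[6]]),
             stringsAsFactors = FALSE)
}

#' Read a synteny block table
#'
#' A TSV with columns `block_id` and `gene_id`, one member gene per
#' row (the format emitted by collinearity tools once anchors are
#' exploded to genes).
#'
#' @param path path to the TSV.
#' @return data.frame with `block_id`, `gene_id`.
#' @export
read_synteny_blocks <- function(path) {
  if (!file.exists(path)) stop("block table not found: ", path, call. = FALSE)
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("block_id", "gene_id") %in% names(tb))) {
    stop("block table must have columns block_id, gene_id", call. = FALSE)
  }
  tb
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
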