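#' Pipeline configuration
#'
#' Bundles every tunable of the FST QC and mapping stages. Defaults
#' follow the published filtering and mapping thresholds for the R108
#' Tnt1 FST dataset: reads shorter than 50 bp are discarded, the Tnt1
#' end signature must sit within 28 bp of a read end, mapping requires
#' at least 90% identity and an E-value of at most 1e-5, and landscape
#' bins are 500 kb wide.
#'
#' @param min_fst_length minimum read length in bp (reads below are
#'   rejected as `TOO_SHORT`).
#' @param end_window signature window in bp: a motif counts as
#'   end-proximal when it starts within the first `end_window` bases
#'   (head) or ends within the last `end_window` bases (tail).
#' @param signature_motifs character vector of Tnt1 end motifs over
#'   \{A,C,G,T\}.
#' @param search_reverse_complement also search each motif's reverse
#'   complement (TAIL-PCR read orientation is not guaranteed).
#' @param min_identity minimum alignment identity (matches / alignment
#'   columns), as a fraction.
#' @param max_evalue maximum Karlin-Altschul E-value for a reported hit.
#' @param bin_width landscape bin width in bp.
#' @param seed_k k-mer seed length for the reference index.
#' @param match,mismatch alignment scores (match > 0, mismatch < 0).
#' @param x_drop ungapped extension stops once the running score drops
#'   more than `x_drop` below its maximum.
#' @param identity_strictly_greater require identity strictly greater
#'   than `min_identity` instead of at-least (the published methods use
#'   both phrasings; at-least is the default).
#' @param rng_seed integer seed for any randomized step.
#' @return a list of class `tnt1_config`.
#' @export
pipeline_config <- function(min_fst_length = 50L,
                            end_window = 28L,
                            signature_motifs = c("CCCAACA", "CATCATCA", "TGATGATGTCC"),
                            search_reverse_complement = TRUE,
                            min_identity = 0.90,
                            max_evalue = 1e-5,
                            bin_width = 500000L,
                            seed_k = 15L,
                            match = 1L,
                            mismatch = -2L,
                            x_drop = 20L,
                            identity_strictly_greater = FALSE,
                            rng_seed = NULL) {
  stopifnot(min_fst_length > 0, end_window > 0,
            length(signature_motifs) > 0,
            min_identity > 0, min_identity <= 1,
            max_evalue > 0, bin_width > 0,
            seed_k >= 8, match > 0, mismatch < 0, x_drop > 0)
  check_alphabet(signature_motifs, allow_n = FALSE, what = "signature motif")
  cfg <- list(
    min_fst_length = as.integer(min_fst_length),
    end_window = as.integer(end_window),
    signature_motifs = toupper(signature_motifs),
    search_reverse_complement = isTRUE(search_reverse_complement),
    min_identity = min_identity,
    max_evalue = max_evalue,
    bin_width = as.integer(bin_width),
    seed_k = as.integer(seed_k),
    match = as.integer(match),
    mismatch = as.integer(mismatch),
    x_drop = as.integer(x_drop),
    identity_strictly_greater = isTRUE(identity_strictly_greater),
    rng_seed = rng_seed
  )
  class(cfg) <- "tnt1_config"
  cfg
}

#' Simulation configuration
#'
#' Study conditions for the synthetic TAIL-PCR FST generator. The
#' defaults emulate the structure of the real dataset at desk scale:
#' a 1-Mb two-chromosome genome, 200 mutant lines with 10 insertions
#' each (2,000 planted insertions), reads of mean length 363 bp, a
#' signature-bearing class making up roughly the 56% high-confidence
#' fraction observed in the real funnel, an AD-primer contaminant class
#' lacking the signature, a too-short class, an internal-signature
#' class, and a 1% per-base substitution error rate.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp (recycled).
#' @param gc_content genome GC fraction in \[0,1\].
#' @param n_genes number of non-overlapping gene models across the genome.
#' @param gene_length length-2 vector: min/max gene length in bp.
#' @param n_lines number of mutant lines.
#' @param insertions_per_line length-2 vector: min/max insertions per line.
#' @param fst_length_mean,fst_length_sd Normal parameters (bp) for read
#'   length before clipping.
#' @param frac_no_signature,frac_too_short,frac_internal_signature class
#'   fractions of emitted reads; the remainder are signature-bearing.
#' @param frac_revcomp fraction of reads emitted reverse-complemented.
#' @param motif_jitter maximum 0-based start offset of the signature
#'   motif in a signature-class read (0 places the motif at the read
#'   start; values up to `end_window - 1` exercise the head-window rule).
#' @param substitution_rate per-base substitution error rate (motif
#'   bases exempt).
#' @param rng_seed integer seed.
#' @return a list of class `tnt1_simconfig`.
#' @export
simulation_config <- function(n_chroms = 2L,
                              chrom_length = 500000L,
                              gc_content = 0.34,
                              n_genes = 100L,
                              gene_length = c(1000L, 5000L),
                              n_lines = 200L,
                              insertions_per_line = c(10L, 10L),
                              fst_length_mean = 363,
                              fst_length_sd = 80,
                              frac_no_signature = 0.35,
                              frac_too_short = 0.05,
                              frac_internal_signature = 0.05,
                              frac_revcomp = 0.5,
                              motif_jitter = 0L,
                              substitution_rate = 0.01,
                              rng_seed = 1L) {
  fr <- c(frac_no_signature, frac_too_short, frac_internal_signature)
  stopifnot(n_chroms >= 1, all(chrom_length > 0),
            gc_content >= 0, gc_content <= 1,
            n_genes >= 0, length(gene_length) == 2, gene_length[1] <= gene_length[2],
            n_lines >= 0, length(insertions_per_line) == 2,
            insertions_per_line[1] <= insertions_per_line[2],
            fst_length_mean > 0, fst_length_sd >= 0,
            all(fr >= 0), all(fr <= 1), sum(fr) <= 1,
            frac_revcomp >= 0, frac_revcomp <= 1,
            motif_jitter >= 0, substitution_rate >= 0, substitution_rate < 1)
  cfg <- list(
    n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(rep_len(chrom_length, n_chroms)),
    gc_content = gc_content,
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    n_lines = as.integer(n_lines),
    insertions_per_line = as.integer(insertions_per_line),
    fst_length_mean = fst_length_mean,
    fst_length_sd = fst_length_sd,
    frac_no_signature = frac_no_signature,
    frac_too_short = frac_too_short,
    frac_internal_signature = frac_internal_signature,
    frac_revcomp = frac_revcomp,
    motif_jitter = as.integer(motif_jitter),
    substitution_rate = substitution_rate,
    rng_seed = rng_seed
  )
  class(cfg) <- "tnt1_simconfig"
  cfg
}
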