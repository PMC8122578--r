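mk_sites <- function(chrom, position, ids = NULL) {
  data.frame(chrom = chrom, position = as.integer(position),
             fst_id = ids %||% sprintf("f%03d", seq_along(position)),
             strand = rep("+", length(position)), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gene assignment uses inclusive containment on the full span", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "c1",
                      start = c(10L, 200L), end = c(100L, 300L),
                      strand = "+", stringsAsFactors = FALSE)
  got <- assign_to_genes(mk_sites("c1", c(50, 100, 150)), genes)
  expect_identical(got$tallies$gene_id, "A")
  expect_identical(got$tallies$insertion_count, 2L) # 50 and the inclusive 100
  expect_identical(got$zero_genes, "B")

  # boundary starts count too
  got2 <- assign_to_genes(mk_sites("c1", c(10, 9)), genes)
  expect_identical(got2$tallies$insertion_count, 1L)

  # overlapping genes each receive the insertion
  ovl <- data.frame(gene_id = c("A", "B"), chrom = "c1",
                    start = c(10L, 40L), end = c(100L, 120L),
                    strand = "+", stringsAsFactors = FALSE)
  got3 <- assign_to_genes(mk_sites("c1", 50), ovl)
  expect_setequal(got3$tallies$gene_id, c("A", "B"))
})

test_that("gene tallies equal brute-force containment counting", {
  withr::local_seed(61)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:30), chrom = sample(c("c1", "c2"), 30, TRUE),
    start = sample.int(9000, 30), strand = "+", stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(800, 30)
  sites <- mk_sites(sample(c("c1", "c2"), 200, TRUE), sample.int(10000, 200))
  got <- assign_to_genes(sites, genes)
  brute <- setNames(integer(30), genes$gene_id)
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(genes))) {
      if (sites$chrom[i] == genes$chrom[j] &&
          sites$position[i] >= genes$start[j] &&
          sites$position[i] <= genes$end[j]) {
        brute[j] <- brute[j] + 1L
      }
    }
  }
  expect_identical(setNames(got$tallies$insertion_count, got$tallies$gene_id),
                   sort(brute[brute > 0], decreasing = TRUE))
  expect_setequal(got$zero_genes, names(brute)[brute == 0])
  # supporting ids agree with the counts
  expect_identical(lengths(strsplit(got$tallies$fst_ids, ",")),
                   unname(got$tallies$insertion_count))
})

test_that("chromosome table reproduces exact percent arithmetic", {
  tab <- chromosome_table(mk_sites(c("c1", "c1", "c1", "c2"), 1:4),
                          n_highconf_total = 8)
  expect_identical(tab$percent_of_total[tab$chrom == "c1"], 37.50)
  expect_identical(tab$percent_of_total[tab$chrom == "c2"], 12.50)
  expect_identical(tab$fst_count[tab$chrom == "total_chromosomes"], 4L)

  # unanchored sequences split out once chromosomes are named
  expect_warning(
    tab2 <- chromosome_table(mk_sites(c("c1", "scaf9"), c(1, 2)),
                             n_highconf_total = 10,
                             chromosomes = "c1"),
    "unanchored")
  expect_identical(tab2$fst_count[tab2$chrom == "unanchored"], 1L)
})

test_that("percent and mean arithmetic matches the published table", {
  counts <- c(chr1 = 27902L, chr2 = 24559L, chr3 = 27679L, chr4 = 26975L,
              chr5 = 25313L, chr6 = 16433L, chr7 = 25451L, chr8 = 27115L,
              unanchored = 1361L)
  tab <- chromosome_table(counts = counts, n_highconf_total = 221275,
                          chromosomes = paste0("chr", 1:8))
  expect_identical(tab$percent_of_total[tab$chrom == "chr1"], 12.61)
  expect_identical(tab$percent_of_total[tab$chrom == "chr6"], 7.43)
  expect_identical(tab$fst_count[tab$chrom == "total_chromosomes"], 201427L)
  expect_identical(tab$percent_of_total[tab$chrom == "total_chromosomes"],
                   91.03)
  expect_identical(tab$percent_of_total[tab$chrom == "unanchored"], 0.62)
  expect_identical(tab$fst_count[tab$chrom == "mean_per_chromosome"], 25178L)
})

test_that("frequency classes count nested thresholds and both means", {
  tal <- data.frame(gene_id = c("A", "B", "C"),
                    insertion_count = c(1L, 2L, 5L),
                    fst_ids = "", stringsAsFactors = FALSE)
  fc <- frequency_classes(tal, n_annotated_genes = 10)
  expect_identical(fc$n_genes_ge1, 3L)
  expect_identical(fc$n_genes_gt1, 2L)
  expect_identical(fc$n_genes_ge4, 1L)
  expect_equal(fc$mean_per_inserted_gene, 8 / 3)
  expect_equal(fc$mean_per_annotated_gene, 8 / 10)

  fc0 <- frequency_classes(tal[0, ], n_annotated_genes = 10)
  expect_identical(fc0$n_genes_ge1, 0L)
  expect_identical(fc0$mean_per_inserted_gene, 0)

  # published arithmetic: 19,008 of 39,027 annotated genes is 48.7%
  expect_identical(percent_of(19008, 39027, 1), 48.7)
})

test_that("frequent-gene selection is strict and rank-ordered", {
  tal <- data.frame(gene_id = c("A", "B", "C"),
                    insertion_count = c(5L, 4L, 3L),
                    fst_ids = "", stringsAsFactors = FALSE)
  expect_identical(select_frequent_genes(tal, 4.33)$gene_id, "A")
  expect_identical(select_frequent_genes(tal, 0)$gene_id, c("A", "B", "C"))
  # default threshold: the mean over tallied genes (here 4)
  expect_identical(select_frequent_genes(tal)$gene_id, "A")
  # max-count gene always ranks first
  expect_identical(select_frequent_genes(tal, 0)$insertion_count[1], 5L)
})

test_that("bins tile chromosomes exactly and count by containment", {
  withr::local_seed(71)
  genome <- c(c1 = oracle_random_seq(1200), c2 = oracle_random_seq(500))
  sites <- mk_sites(c("c1", "c1", "c1", "c2"), c(500, 501, 1200, 1))
  bins <- bin_landscape(sites, genome, bin_width = 500)
  b1 <- bins[bins$chrom == "c1", ]
  expect_identical(nrow(b1), 3L)
  expect_identical(b1$bin_end - b1$bin_start + 1L, c(500L, 500L, 200L))
  # boundary: 500 in bin 1, 501 in bin 2
  expect_identical(b1$insertion_count, c(1L, 1L, 1L))
  # tiling covers every base exactly once
  for (ch in names(genome)) {
    b <- bins[bins$chrom == ch, ]
    expect_identical(b$bin_start, c(1L, head(b$bin_end, -1) + 1L))
    expect_identical(b$bin_end[nrow(b)], nchar(genome[[ch]]))
  }
  # conservation: per-bin sums equal per-chromosome counts
  expect_identical(sum(bins$insertion_count[bins$chrom == "c1"]), 3L)
  expect_identical(sum(bins$insertion_count[bins$chrom == "c2"]), 1L)
})

test_that("bin GC handles composition extremes and all-N bins", {
  genome <- c(c1 = paste0(strrep("G", 50), strrep("C", 50), strrep("N", 100),
                          strrep("A", 100)))
  bins <- bin_landscape(mk_sites(character(0), integer(0)), genome,
                        bin_width = 100)
  expect_identical(bins$gc_fraction, c(1, 0, 0))
  expect_identical(bins$all_n, c(FALSE, TRUE, FALSE))
})

test_that("synteny tallies count member genes and insertions per block", {
  tal <- data.frame(gene_id = c("A", "D"), insertion_count = c(2L, 7L),
                    fst_ids = "", stringsAsFactors = FALSE)
  blocks <- data.frame(block_id = c("b1", "b1", "b2", "b2"),
                       gene_id = c("A", "B", "C", "D"),
                       stringsAsFactors = FALSE)
  st <- synteny_tally(tal, blocks, verbose = FALSE)
  expect_identical(st$n_genes, c(b2 = 2L, b1 = 2L), ignore_attr = TRUE)
  expect_identical(st$block_id, c("b1", "b2"))
  expect_identical(st$n_genes_with_insertion, c(1L, 1L))
  expect_identical(st$n_insertions, c(2, 7))

  # block with no tallied genes
  b3 <- rbind(blocks, data.frame(block_id = "b3", gene_id = "Z"))
  st3 <- synteny_tally(tal, b3, verbose = FALSE)
  expect_identical(st3$n_genes_with_insertion[st3$block_id == "b3"], 0L)

  # a gene in two blocks is counted in both
  dup <- rbind(blocks, data.frame(block_id = "b3", gene_id = "A"))
  std <- suppressMessages(synteny_tally(tal, dup))
  expect_identical(std$n_insertions[std$block_id == "b3"], 2)

  expect_error(synteny_tally(tal, blocks[0, ]), "empty")

  # unresolved members are dropped from gene counts when an annotation
  # is given
  stn <- suppressMessages(
    synteny_tally(tal, b3, annotation = c("A", "B", "C", "D")))
  expect_false("b3" %in% stn$block_id)
})
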