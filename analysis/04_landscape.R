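#!/usr/bin/env Rscript
# Stage 4 — landscape statistics over the called insertion sites:
# per-chromosome distribution, per-gene tallies with frequency
# classes, frequently inserted genes, 500-kb bins with GC content
# (here 50-kb bins, scaled to the toy genome), and tallies over a
# synthetic synteny-block table built from runs of adjacent genes.

suppressMessages(library(tnt1fst))

out_dir <- "results/landscape"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome_fasta("results/sim/genome.fa")
genes <- read_gff3_genes("results/sim/genes.gff3", genome = genome)
sites <- read.delim("results/mapping/insertion_sites.tsv")
funnel <- read.delim("results/qc/funnel.tsv")
n_highconf <- funnel$count[funnel$stage == "pass"]

tab <- chromosome_table(sites, n_highconf_total = n_highconf,
                        chromosomes = names(genome))
write_tsv(tab, file.path(out_dir, "chromosome_table.tsv"))
message("per-chromosome distribution (percent of ", n_highconf,
        " high-confidence FSTs):")
for (i in seq_len(nrow(tab))) {
  message(sprintf("  %-20s %6d  %s", tab$chrom[i], tab$fst_count[i],
                  ifelse(is.na(tab$percent_of_total[i]), "",
                         paste0(tab$percent_of_total[i], "%"))))
}

ga <- assign_to_genes(sites, genes, verbose = TRUE)
write_tsv(ga$tallies, file.path(out_dir, "gene_tallies.tsv"))
writeLines(ga$zero_genes, file.path(out_dir, "genes_without_insertion.txt"))
fc <- frequency_classes(ga$tallies, nrow(genes))
write_tsv(data.frame(metric = names(unlist(fc)), value = unlist(fc)),
          file.path(out_dir, "frequency_classes.tsv"))
message(sprintf(paste0("genes with insertions: %d/%d (%.2f%%); >1: %d ",
                       "(%s%%); >=4: %d (%s%%); mean %.2f per inserted gene"),
                fc$n_genes_ge1, nrow(genes), fc$pct_ge1, fc$n_genes_gt1,
                fc$pct_gt1, fc$n_genes_ge4, fc$pct_ge4,
                fc$mean_per_inserted_gene))

freq <- select_frequent_genes(ga$tallies)
write_tsv(freq, file.path(out_dir, "frequent_genes.tsv"))
message(nrow(freq), " genes exceed the mean insertion count (threshold ",
        round(fc$mean_per_inserted_gene, 2), "); top gene ",
        freq$gene_id[1], " with ", freq$insertion_count[1], " insertions")

bins <- bin_landscape(sites, genome, bin_width = 50000L)
write_tsv(bins, file.path(out_dir, "bins_50kb.tsv"))
message("bin landscape: ", nrow(bins), " bins of 50 kb; GC ",
        round(min(bins$gc_fraction), 3), "-",
        round(max(bins$gc_fraction), 3), "; max ",
        max(bins$insertion_count), " insertions per bin")

# synthetic synteny blocks: consecutive runs of 10 genes per chromosome
ord <- genes[order(genes$chrom, genes$start), ]
blocks <- do.call(rbind, lapply(split(ord, ord$chrom), function(g) {
  data.frame(block_id = paste0(g$chrom[1], "_b",
                               ceiling(seq_len(nrow(g)) / 10)),
             gene_id = g$gene_id, stringsAsFactors = FALSE)
}))
write_tsv(blocks, file.path(out_dir, "synthetic_blocks.tsv"))
st <- synteny_tally(ga$tallies, blocks, annotation = genes$gene_id)
write_tsv(st, file.path(out_dir, "block_tallies.tsv"))
message("block tallies over ", length(unique(blocks$block_id)),
        " synthetic blocks; busiest block ", st$block_id[1], " has ",
        st$n_genes_with_insertion[1], " inserted genes / ",
        st$n_insertions[1], " insertions")
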