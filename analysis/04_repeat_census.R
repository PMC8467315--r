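#!/usr/bin/env Rscript
# Repeat-motif census and domain segmentation of the synthetic locus written
# by 02: count every catalogue motif, enumerate CpG sites, and segment the
# gene into repetitive domains and amorphous regions.

suppressMessages(library(ceoseq))

genome <- read_genome_fasta("results/locus/genome.fasta")
motifs <- fibh_motifs()

cm <- count_motifs(genome[[1]], motifs, chrom = names(genome))
cat("Motif census of the emitted genome:\n")
print(cm$counts, row.names = FALSE)
write.table(cm$counts, "results/motif_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
stopifnot(identical(cm$counts$count, motifs$copies))
cat("Census equals the generator blueprint (",
    sum(cm$counts$count), "copies )\n")

gene <- read_bed("results/locus/domains.bed")
gene_start <- min(gene$start); gene_end <- max(gene$end)
gi <- cm$instances[cm$instances$start >= gene_start &
                     cm$instances$end <= gene_end, ]
gi$start <- gi$start - gene_start
gi$end <- gi$end - gene_start
seg <- segment_domains(gi, gene_end - gene_start)
cat("\nDensity-window segmentation of the", gene_end - gene_start,
    "bp gene:\n")
print(table(seg$kind))
write.table(seg, "results/domains_segmented.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cg <- find_cg_sites(substring(genome[[1]], gene_start + 1, gene_end))
cat("\nCpG sites within the gene:", length(cg), "\n")
cat("Each of the", nrow(motifs), "catalogue motifs carries",
    "exactly one CpG:", all(vapply(motifs$sequence, function(s)
      length(find_cg_sites(s)) == 1, logical(1))), "\n")
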