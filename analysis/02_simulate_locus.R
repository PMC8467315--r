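#!/usr/bin/env Rscript
# Build the synthetic FibH-like locus (16,845-bp gene, 12 repetitive domains
# with 11 amorphous spacers, 354 planted motif copies, four flanking Cas12a
# guide sites on a 500-kb background) and push it through the in-silico
# protocol: dephosphorylation, Cas12a cleavage, adapter ligation, sequencing.

suppressMessages(library(ceoseq))
seed <- 42

loc <- build_synthetic_locus(locus_spec(), seed = seed)
print(loc)
write_locus(loc, "results/locus")
cat("\nCore GC fraction:",
    round(gc_fraction(loc, loc$core[["start"]], loc$core[["end"]]), 4), "\n")

sim <- simulate_protocol(loc, protocol_params(), seed = seed + 1)
cl <- setNames(nchar(loc$genome), names(loc$genome))
write_simulation(sim, cl, "results/sim")
cat("Simulated", nrow(sim$reads), "reads (",
    sum(sim$reads$mean_q >= 7), "with mean Q >= 7 ) and",
    nrow(sim$calls), "per-read CpG calls\n")
cat("Wrote results/locus/ (FASTA + BED truth) and results/sim/",
    "(FASTQ, truth PAF, methylation TSV)\n")
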