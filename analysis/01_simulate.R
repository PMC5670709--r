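#!/usr/bin/env Rscript
# Simulate the synthetic genus used by every downstream analysis step:
# 5 genomes, 40 core families, a 30-family accessory pool at presence 0.5,
# 5 private families per genome, 20% within-family protein divergence.
# Writes FASTA + ground truth under results/sim/.

suppressMessages(library(lactopan))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

sim <- simulate_pangenome(sim_params(seed = seed))
write_pangenome_sim(sim, "results/sim")

message("Simulated ", length(sim$genomes), " genomes, ",
        nrow(sim$genes), " genes; true pan = ", sim$truth$true_pan_count,
        ", true core = ", sim$truth$true_core_count)
message("Genome sizes (bp): ",
        paste(vapply(sim$genomes, function(g) sum(nchar(g$scaffolds)), 0),
              collapse = ", "))
st <- do.call(rbind, lapply(sim$genomes, genome_stats))
write_genome_stats(st, "results/sim_genome_stats.tsv")
message("GC%: ", paste(st$gc_percent, collapse = ", "),
        " (target 37.00)")
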