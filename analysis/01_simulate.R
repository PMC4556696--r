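#!/usr/bin/env Rscript
# Stage 1: build the synthetic study -- a toy genome with planted mirtron
# loci of all four biogenesis subtypes, canonical miRNA controls, bulk
# introns, small RNA libraries (total RNA, Ago-IP, control-IP, input) and
# tissue expression tables with known ground truth.
suppressPackageStartupMessages(library(mirtrons))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
outdir <- "results/analysis/sim"

cfg <- sim_config(seed = seed)
manifest <- sim_manifest()
tissues <- c("brain", "heart", "kidney", "liver", "lung", "muscle", "spleen")

truth <- build_truth(cfg)
sim <- simulate_reads(truth, manifest, cfg)
expr <- simulate_expression(truth, tissues, cfg)
write_simulation(truth, sim, manifest, outdir, expr)

mir <- truth$planted[truth$planted$class != "canonical", ]
cat("Simulated genome:", length(truth$genome), "chromosomes,",
    sum(nchar(truth$genome)), "bp\n")
cat("Introns:", nrow(truth$introns), "of which planted mirtrons:",
    nrow(mir), "\n")
print(table(truth$planted$class))
cat("Libraries:", nrow(manifest), "| reads per library:",
    paste(vapply(sim$batches, function(b) sum(b$count), 1), collapse = " "),
    "\n")
cat("Ground truth written under", outdir, "\n")
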