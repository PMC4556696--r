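#!/usr/bin/env Rscript
# Stage 2: map the small RNA libraries back onto the genome with the
# iterative 3'-trimming exact mapper, assign placements to introns, and
# call mirtrons under the tiered duplex/Ago-IP evidence criteria.
# Consumes only the files stage 1 wrote.
suppressPackageStartupMessages(library(mirtrons))

simdir <- "results/analysis/sim"
outdir <- "results/analysis"

genome <- read_genome_fasta(file.path(simdir, "genome.fa"))
introns <- read_introns_bed(file.path(simdir, "introns.bed"),
                            genome = genome)
manifest <- read_manifest(file.path(simdir, "manifest.tsv"))
batches <- lapply(setNames(manifest$library_id, manifest$library_id),
                  function(l) read_small_rna(
                    file.path(simdir, "reads", paste0(l, ".fa")), l))

calls <- annotate_mirtrons(genome, introns, batches, manifest)
write_table(calls, file.path(outdir, "calls.tsv"), key = "intron_id")
saveRDS(attr(calls, "stacks"), file.path(outdir, "stacks.rds"))

truth <- read_result_table(file.path(simdir, "truth_loci.tsv"))
mir <- truth[truth$class != "canonical", ]
confident <- calls[calls$tier %in% c("confident_duplex", "confident_agoip",
                                     "rescue_a", "rescue_b"), ]
tp <- intersect(confident$intron_id, mir$locus_id)

cat("Loci with read stacks:", nrow(calls), "\n")
cat("Tier x subtype table:\n")
print(table(calls$subtype, calls$tier))
cat(sprintf("Recovery of %d planted mirtrons: recall %.3f, precision %.3f\n",
            nrow(mir), length(tp) / nrow(mir), length(tp) / nrow(confident)))
acc <- mean(calls$subtype[match(tp, calls$intron_id)] ==
              mir$class[match(tp, mir$locus_id)])
cat(sprintf("Subtype accuracy on true positives: %.3f\n", acc))
cat("Calls written to", file.path(outdir, "calls.tsv"), "\n")
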