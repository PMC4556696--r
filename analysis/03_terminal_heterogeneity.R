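#!/usr/bin/env Rscript
# Stage 3: terminal heterogeneity of the mirtron-derived small RNAs --
# 5'/3' offset profiles per arm, untemplated 3' additions called against
# the splice-acceptor anchor, and 5'-G decapitation ("xU") fractions.
suppressPackageStartupMessages(library(mirtrons))

simdir <- "results/analysis/sim"
outdir <- "results/analysis"
genome <- read_genome_fasta(file.path(simdir, "genome.fa"))
introns <- read_introns_bed(file.path(simdir, "introns.bed"), genome = genome)
calls <- read_result_table(file.path(outdir, "calls.tsv"))
stacks <- readRDS(file.path(outdir, "stacks.rds"))
called <- calls[calls$tier == "confident_duplex", ]

## offset profiles for every called locus, arm and terminus
prof_rows <- list()
for (i in seq_len(nrow(called))) {
  id <- called$intron_id[i]
  intron <- introns[introns$intron_id == id, ]
  for (arm in c("5p", "3p")) for (term in c("5", "3")) {
    pr <- end_offset_profile(stacks[[id]], called[i, ], intron, arm, term)
    if (pr$empty) next
    prof_rows[[length(prof_rows) + 1]] <- data.frame(
      locus = id, arm = arm, terminus = term, provenance = pr$provenance,
      offset = as.integer(names(pr$histogram)),
      fraction = unname(pr$histogram))
  }
}
profiles <- do.call(rbind, prof_rows)
write_table(profiles, file.path(outdir, "end_profiles.tsv"),
            key = c("locus", "arm", "terminus", "offset"))

## splice-anchored untemplated tails, pooled per subtype
tail_rows <- list()
for (id in called$intron_id[called$subtype %in%
                            c("conventional", "fivep_tailed")]) {
  s3 <- stacks[[id]][stacks[[id]]$bucket == "threep", ]
  intron <- introns[introns$intron_id == id, ]
  tc <- call_untemplated_tail(s3, anchored = TRUE,
                              intron_length = intron$end - intron$start)
  tc$subtype <- called$subtype[called$intron_id == id]
  tail_rows[[id]] <- tc
}
tails_all <- do.call(rbind, tail_rows)
tail_tab <- do.call(rbind, lapply(split(tails_all, tails_all$subtype),
  function(d) cbind(subtype = d$subtype[1], summarize_tails(d))))
write_table(tail_tab, file.path(outdir, "tails.tsv"),
            key = c("subtype", "category"))
cat("Untemplated 3' additions (read-weighted, per subtype):\n")
print(tail_tab, row.names = FALSE)

## xU fractions at splice-defined 5p loci
xu_rows <- list()
for (id in called$intron_id[called$subtype %in%
                            c("conventional", "threep_tailed")]) {
  x <- xu_frequency(stacks[[id]], called[called$intron_id == id, ][1, ])
  xu_rows[[id]] <- data.frame(locus = x$locus, n_5p_reads = x$n_5p_reads,
                              frac_GU = x$frac_GU, frac_xU = x$frac_xU,
                              frac_other = x$frac_other,
                              defined = x$defined)
}
xu <- do.call(rbind, xu_rows)
write_table(xu, file.path(outdir, "xu.tsv"), key = "locus")
def <- xu[xu$defined, ]
cat(sprintf("\nxU summary over %d loci with >= 10 5p reads: mean xU %.3f; %d/%d loci >= 10%% xU\n",
            nrow(def), mean(def$frac_xU), sum(def$frac_xU >= 0.1),
            nrow(def)))
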