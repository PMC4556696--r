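#!/usr/bin/env Rscript
# Stage 4: comparative locus features -- host intron length histograms,
# splice-acceptor-anchored nucleotide logos, folding energy against
# length-matched intronic controls, host-gene intron counts, pre-miRNA
# length statistics and seed mimicry against the planted canonical set.
suppressPackageStartupMessages(library(mirtrons))

simdir <- "results/analysis/sim"
outdir <- "results/analysis"
genome <- read_genome_fasta(file.path(simdir, "genome.fa"))
introns <- read_introns_bed(file.path(simdir, "introns.bed"), genome = genome)
truth <- read_result_table(file.path(simdir, "truth_loci.tsv"))
calls <- read_result_table(file.path(outdir, "calls.tsv"))
called <- calls[calls$tier == "confident_duplex", ]

## intron length histogram per class
labels <- setNames(rep("bulk", nrow(introns)), introns$intron_id)
labels[called$intron_id] <- called$subtype
hist_tab <- intron_length_hist(introns, labels[introns$intron_id],
                               pool_above = 15000L)
write_table(hist_tab, file.path(outdir, "intron_lengths.tsv"),
            key = c("class", "bin_start"))
cat("Intron length histogram by class written; class totals:\n")
print(tapply(hist_tab$count, hist_tab$class, sum))

## acceptor-anchored logo: called 5'-tailed hairpins vs bulk introns at -65
f5 <- called[called$subtype == "fivep_tailed", ]
f5_introns <- introns[match(f5$intron_id, introns$intron_id), ]
f5_seq <- genome_fetch(genome, f5_introns$chrom, f5_introns$start,
                       f5_introns$end, f5_introns$strand)
logo_case <- logo_matrix(f5_seq, nchar(f5_seq), window = 40L)
bulk <- introns[labels[introns$intron_id] == "bulk", ]
bulk <- bulk[(bulk$end - bulk$start) >= 50 &
               (bulk$end - bulk$start) <= 3000, ]
bulk_seq <- genome_fetch(genome, bulk$chrom, bulk$start, bulk$end,
                         bulk$strand)
logo_ctrl <- logo_matrix(bulk_seq, nchar(bulk_seq) - 65L, window = 40L)
logo_case$set <- "fivep_tailed_acceptor"
logo_ctrl$set <- "bulk_minus65"
write_table(rbind(logo_case, logo_ctrl), file.path(outdir, "logos.tsv"),
            key = c("set", "offset"))
in_arm <- logo_case$offset >= -21 & logo_case$offset <= -2
cat(sprintf("Mean C frequency across the 3p arm (acceptor-anchored): %.3f vs %.3f in bulk\n",
            mean(logo_case$C[in_arm]), mean(logo_ctrl$C[in_arm])))

## folding energy vs length-matched intronic windows
hp <- genome_fetch(genome, called$chrom, called$hairpin_start,
                   called$hairpin_end, called$strand)
set.seed(401)
pool <- vapply(sample(nrow(bulk), 300, replace = TRUE), function(i) {
  len <- sample(50:150, 1)
  len <- min(len, bulk$end[i] - bulk$start[i])
  s <- bulk$start[i] + sample(0:(bulk$end[i] - bulk$start[i] - len), 1)
  genome_fetch(genome, bulk$chrom[i], s, s + len, bulk$strand[i])
}, "")
cmp <- mfe_comparison(hp, pool, seed = 402)
write_table(data.frame(set = rep(c("mirtron", "control"),
                                 c(length(cmp$case_scores),
                                   length(cmp$control_scores))),
                       energy_per_base = c(cmp$case_scores,
                                           cmp$control_scores)),
            file.path(outdir, "mfe.tsv"), key = c("set", "energy_per_base"))
cat(sprintf("Energy/base: mirtron hairpins %.3f vs matched controls %.3f (t-test p = %.2e, matched = %s)\n",
            mean(cmp$case_scores), mean(cmp$control_scores), cmp$test_p,
            cmp$matched))

## host-gene intron counts
ic <- introns[!duplicated(introns$host_gene),
              c("host_gene", "host_intron_count")]
gt <- data.frame(gene = ic$host_gene, n_introns = ic$host_intron_count,
                 class = ifelse(ic$host_gene %in%
                                  sub("\\|.*", "", called$intron_id),
                                "mirtron_host", "bulk"))
hstats <- host_intron_count_stats(gt)
write_table(hstats$stats, file.path(outdir, "intron_counts.tsv"),
            key = "class")
cat(sprintf("Host-gene intron counts: mirtron hosts %.1f (trimmed) vs bulk %.1f, rank-sum p = %.2e\n",
            hstats$stats$trimmed_mean[hstats$stats$class == "mirtron_host"],
            hstats$stats$trimmed_mean[hstats$stats$class == "bulk"],
            hstats$stats$p_vs_bulk[hstats$stats$class == "mirtron_host"]))

## pre-miRNA lengths per class against the planted canonical hairpins
canon <- truth[truth$class == "canonical", ]
lens <- c(called$premirna_length, canon$hairpin_rel3 - canon$hairpin_rel5)
cls <- c(called$subtype, rep("canonical", nrow(canon)))
pstats <- premirna_length_stats(lens, cls)
write_table(pstats, file.path(outdir, "premirna_lengths.tsv"), key = "class")
cat("Pre-miRNA length statistics (mean +/- sd, test vs canonical):\n")
print(pstats, row.names = FALSE)

## seed mimicry against the canonical planted loci
canon_seq <- genome_fetch(genome, canon$chrom,
                          canon$arm5_rel5, canon$arm5_rel3, "+")
refs <- setNames(substr(canon_seq, 2, 7), canon$locus_id)
mim <- seed_mimics(called, refs)
write_table(mim$matches, file.path(outdir, "seed_mimics.tsv"),
            key = "locus")
cat("Seed mimics of planted canonical miRNAs:", nrow(mim$matches), "\n")
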