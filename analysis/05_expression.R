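#!/usr/bin/env Rscript
# Stage 5: expression analyses -- mirtron/host correlation across tissues
# with a shuffled-label confidence envelope, expression breadth, and
# Ago-IP enrichment of mirtron-derived small RNAs.
suppressPackageStartupMessages(library(mirtrons))

simdir <- "results/analysis/sim"
outdir <- "results/analysis"
read_mat <- function(name) {
  t <- read_result_table(file.path(simdir, paste0(name, ".tsv")))
  m <- as.matrix(t[, -1, drop = FALSE])
  rownames(m) <- t$locus_id
  m
}
mirtron <- read_mat("mirtron_rpmm")
junction <- read_mat("junction_rpm")

env <- shuffle_envelope(mirtron, junction, n_shuffles = 100L, seed = 501L)
write_table(data.frame(grid = env$grid, observed_cdf = env$observed_cdf,
                       env_lo = env$env_lo, env_hi = env$env_hi),
            file.path(outdir, "correlation_cdf.tsv"), key = "grid")
write_table(data.frame(locus = seq_along(env$observed_r),
                       r = env$observed_r),
            file.path(outdir, "correlations.tsv"), key = "locus")
cat(sprintf("Mirtron/host junction correlation over %d loci: median r = %.3f, Wilcoxon median p = %.2e\n",
            length(env$observed_r), median(env$observed_r), env$median_p))
exits <- any(env$observed_cdf < env$env_lo - 1e-12)
cat("Observed CDF exits the alpha = 0.99 shuffle envelope to the right:",
    exits, "\n")

br <- expression_breadth(mirtron, cutoff = 5)
write_table(br, file.path(outdir, "breadth.tsv"), key = "locus")
cat("Expression breadth (samples > 5 RPMM) bins:\n")
print(table(br$bin))

## Ago-IP enrichment from the annotated stacks
manifest <- read_manifest(file.path(simdir, "manifest.tsv"))
stacks <- readRDS(file.path(outdir, "stacks.rds"))
calls <- read_result_table(file.path(outdir, "calls.tsv"))
called <- calls[calls$tier == "confident_duplex", ]
depth <- vapply(manifest$library_id, function(l)
  sum(read_small_rna(file.path(simdir, "reads", paste0(l, ".fa")),
                     l)$count), 1)
rpm <- t(vapply(called$intron_id, function(id) {
  s <- stacks[[id]]
  s <- s[s$bucket %in% c("fivep", "threep"), ]
  vapply(names(depth), function(l)
    sum(s$weight[s$library_id == l]) / depth[[l]] * 1e6, 1)
}, numeric(length(depth))))
enr <- ago_enrichment(rpm, setNames(manifest$lib_class,
                                    manifest$library_id))
write_table(enr$tests, file.path(outdir, "ago_enrichment_tests.tsv"),
            key = c("group1", "group2"))
cat(sprintf("Ago-IP enrichment: %d loci analyzed, %d all-zero excluded\n",
            nrow(enr$transformed), enr$n_excluded_allzero))
print(enr$tests, row.names = FALSE)
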