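test_that("zero planted classes yields a bulk-only genome", {
  cfg <- sim_config(seed = 2, n_genes = 5L,
                    class_counts = c(conventional = 0L, fivep_tailed = 0L,
                                     threep_tailed = 0L, two_tailed = 0L,
                                     canonical = 0L))
  truth <- build_truth(cfg)
  expect_equal(nrow(truth$planted), 0L)
  expect_gt(nrow(truth$introns), 0L)
  expect_true(all(truth$introns$donor == "GT"))
  expect_true(all(truth$introns$acceptor == "AG"))
})

test_that("planted geometry matches the declared biogenesis subtype", {
  cfg <- small_config(seed = 14)
  truth <- build_truth(cfg)
  p <- truth$planted
  ilen <- p$intron_end - p$intron_start
  conv <- p[p$class == "conventional", ]
  # conventional: hairpin == intron, sequence starts GT and ends AG
  expect_true(all(conv$hairpin_rel5 == 0L))
  expect_true(all(conv$hairpin_rel3 == (conv$intron_end - conv$intron_start)))
  seqs <- genome_fetch(truth$genome, conv$chrom, conv$intron_start,
                       conv$intron_end, conv$strand)
  expect_true(all(startsWith(seqs, "GT")))
  expect_true(all(endsWith(seqs, "AG")))
  # 5'-tailed: hairpin 3' end coincides with the acceptor, 5' end is the tail
  f5 <- p[p$class == "fivep_tailed", ]
  expect_true(all(f5$hairpin_rel3 == (f5$intron_end - f5$intron_start)))
  expect_true(all(f5$hairpin_rel5 >= 10L))
  # 3'-tailed: hairpin 5' end at the donor
  f3 <- p[p$class == "threep_tailed", ]
  expect_true(all(f3$hairpin_rel5 == 0L))
  expect_true(all(f3$hairpin_rel3 < (f3$intron_end - f3$intron_start)))
  # two-tailed: both ends >= 5 nt from the splice sites
  tt <- p[p$class == "two_tailed", ]
  expect_true(all(tt$hairpin_rel5 >= 5L))
  expect_true(all((tt$intron_end - tt$intron_start) - tt$hairpin_rel3 >= 5L))
})

test_that("a 5'-tailed locus with a fixed tail has the exact hairpin offset", {
  cfg <- sim_config(seed = 8, n_genes = 0L,
                    class_counts = c(conventional = 0L, fivep_tailed = 1L,
                                     threep_tailed = 0L, two_tailed = 0L,
                                     canonical = 0L),
                    tail5_length_range = c(150L, 150L))
  truth <- build_truth(cfg)
  p <- truth$planted
  expect_equal(p$hairpin_rel5, 150L)
  expect_equal(p$hairpin_rel3, p$intron_end - p$intron_start)
})

test_that("identical configs give byte-identical simulations", {
  cfg <- small_config(seed = 33)
  man <- sim_manifest(tissues = c("brain", "heart", "liver"))
  t1 <- build_truth(cfg); t2 <- build_truth(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_reads(t1, man, cfg); s2 <- simulate_reads(t2, man, cfg)
  expect_identical(s1, s2)
  e1 <- simulate_expression(t1, c("a", "b", "c"), cfg)
  e2 <- simulate_expression(t2, c("a", "b", "c"), cfg)
  expect_identical(e1, e2)
})

test_that("degenerate noise config emits only genome-exact, splice-exact reads", {
  cfg <- small_config(seed = 5, jitter5_distribution = c(`0` = 1),
                      uridylation_prob = 0, adenylation_prob = 0,
                      decapitation_prob = 0, background_rate = 0)
  truth <- build_truth(cfg)
  man <- sim_manifest(tissues = "brain", n_ago = 0, n_control = 0,
                      n_input = 0)
  sim <- simulate_reads(truth, man, cfg)
  expect_true(all(sim$ledger$offset5 == 0L))
  expect_true(all(sim$ledger$tail == ""))
  # every emitted species is an exact genome substring (maps untrimmed)
  al <- map_iterative(sim$batches[[1]], truth$genome)
  expect_equal(nrow(attr(al, "unmapped")), 0L)
  expect_true(all(al$trimmed_suffix == ""))
})

test_that("forced uridylation tails every splice-defined 3p read", {
  cfg <- small_config(seed = 6, uridylation_prob = 1, adenylation_prob = 0)
  truth <- build_truth(cfg)
  man <- sim_manifest(tissues = "brain", n_ago = 0, n_control = 0,
                      n_input = 0)
  sim <- simulate_reads(truth, man, cfg)
  led <- sim$ledger
  splice3 <- truth$planted$locus_id[truth$planted$class %in%
                                      c("conventional", "fivep_tailed")]
  reads3p <- led[led$origin %in% splice3 & led$arm == "3p", ]
  expect_gt(nrow(reads3p), 0L)
  expect_true(all(grepl("^T+$", reads3p$tail)))
  # loci without a splice-defined 3' end are never tailed
  other3p <- led[!led$origin %in% splice3 & led$arm == "3p", ]
  expect_true(all(other3p$tail == ""))
})

test_that("mature:star split follows the configured asymmetry binomially", {
  cfg <- sim_config(seed = 41, n_genes = 0L,
                    class_counts = c(conventional = 1L, fivep_tailed = 0L,
                                     threep_tailed = 0L, two_tailed = 0L,
                                     canonical = 0L),
                    reads_per_locus = 1100L, locus_abundance_sd = 0,
                    star_asymmetry = 10,
                    loop_read_rate = 0, background_rate = 0)
  truth <- build_truth(cfg)
  man <- sim_manifest(tissues = "brain", n_ago = 0, n_control = 0,
                      n_input = 0)
  sim <- simulate_reads(truth, man, cfg)
  led <- sim$ledger
  dom <- truth$planted$dominant_arm[1]
  n_mat <- sum(led$count[led$arm == dom])
  expect_equal(sum(led$count), 1100L)
  expect_gt(binom.test(n_mat, 1100L, 10 / 11)$p.value, 0.001)
})

test_that("loop reads reach total libraries only; control-IP sees background only", {
  cfg <- small_config(seed = 12)
  truth <- build_truth(cfg)
  man <- sim_manifest(tissues = c("brain", "heart"), n_ago = 2,
                      n_control = 1, n_input = 1)
  sim <- simulate_reads(truth, man, cfg)
  led <- sim$ledger
  cls <- setNames(man$lib_class, man$library_id)
  loop <- led[led$arm == "loop", ]
  expect_gt(nrow(loop), 0L)
  expect_true(all(cls[loop$library_id] == "total"))
  ctl <- led[cls[led$library_id] == "control_ip", ]
  expect_gt(nrow(ctl), 0L)
  expect_true(all(ctl$origin == "background"))
  ago <- led[cls[led$library_id] == "ago_ip", ]
  expect_true(all(ago$origin != "background"))
})

test_that("ledger counts reconcile with the emitted batches", {
  cfg <- small_config(seed = 9)
  truth <- build_truth(cfg)
  man <- sim_manifest(tissues = "brain", n_ago = 1, n_control = 1,
                      n_input = 1)
  sim <- simulate_reads(truth, man, cfg)
  for (lib in names(sim$batches)) {
    expect_equal(sum(sim$batches[[lib]]$count),
                 sum(sim$ledger$count[sim$ledger$library_id == lib]))
  }
})

test_that("noise-free correlated expression gives Pearson r of exactly 1", {
  cfg <- small_config(seed = 3, discordant_fraction = 0,
                      expression_noise_sd = 0)
  truth <- build_truth(cfg)
  expr <- simulate_expression(truth, paste0("t", 1:7), cfg)
  r <- host_correlations(expr$mirtron_rpmm, expr$junction_rpm)
  expect_equal(r$r, rep(1, nrow(r)))
})

test_that("discordant loci populate the low tail of the correlation distribution", {
  cfg <- small_config(seed = 26, discordant_fraction = 0.3,
                      expression_noise_sd = 0.1,
                      class_counts = c(conventional = 10L, fivep_tailed = 10L,
                                       threep_tailed = 0L, two_tailed = 0L,
                                       canonical = 0L))
  truth <- build_truth(cfg)
  expr <- simulate_expression(truth, paste0("t", 1:7), cfg)
  r <- host_correlations(expr$mirtron_rpmm, expr$junction_rpm)
  rr <- setNames(r$r, r$locus)
  cor_r <- rr[names(expr$regime)[expr$regime == "correlated"]]
  dis_r <- rr[names(expr$regime)[expr$regime == "discordant"]]
  # correlated loci stay near 1; discordant loci (tissue-restricted and
  # uncoupled from the host) fall in the low tail, though single loci can
  # land anywhere when the kept tissue happens to track the host
  expect_true(all(cor_r > 0.8))
  expect_lt(median(dis_r), 0.5)
  expect_lt(min(dis_r), 0)
})

test_that("expression simulation validates inputs", {
  cfg <- small_config(seed = 2)
  truth <- build_truth(cfg)
  expect_error(simulate_expression(truth, c("a", "b"), cfg), "3 tissues")
  expect_error(simulate_reads(truth, sim_manifest(tissues = character(0),
                                                  n_ago = 0, n_control = 0,
                                                  n_input = 0)[0, ], cfg),
               "zero libraries")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(uridylation_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(uridylation_prob = 0.8, adenylation_prob = 0.5),
               "<= 1")
  expect_error(sim_config(jitter5_distribution = c(`0` = 0.5)), "sum to 1")
})
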