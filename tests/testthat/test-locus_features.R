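test_that("intron length histogram bins by 100 nt and pools above the cap", {
  introns <- rbind(make_intron(0L, 150L, id = "a|1"),
                   make_intron(0L, 199L, id = "b|1"),
                   make_intron(0L, 20000L, id = "c|1"))
  labels <- c("bulk", "bulk", "bulk")
  h <- intron_length_hist(introns, labels, pool_above = 15000L)
  expect_equal(h$count[h$bin_start == 100], 2L)      # 150 and 199 share a bin
  expect_equal(h$count[is.infinite(h$bin_end)], 1L)  # 20 kb pooled
  expect_equal(sum(h$count), 3L)

  # a class with no members still gets an all-zero row set
  h2 <- intron_length_hist(introns, factor(labels,
                                           levels = c("bulk", "mirtron")))
  expect_true("mirtron" %in% h2$class)
  expect_equal(sum(h2$count[h2$class == "mirtron"]), 0L)

  expect_error(intron_length_hist(introns, c("bulk", NA, "bulk")), "label")
})

test_that("logo matrices count anchored nucleotide frequencies", {
  # identical sequences: every covered column is an indicator vector
  m <- logo_matrix(rep("GTACGTACGTAC", 3), rep(1L, 3), window = 10L)
  row0 <- m[m$offset == 0, ]
  expect_equal(row0$G, 1)
  expect_equal(row0$coverage, 3L)

  # "GT..." and "GA..." anchored at position 1
  m2 <- logo_matrix(c("GTCCCCCCCCCC", "GACCCCCCCCCC"), c(1L, 1L),
                    window = 10L)
  expect_equal(m2[m2$offset == 0, "G"], 1)
  expect_equal(m2[m2$offset == 1, "U"], 0.5)
  expect_equal(m2[m2$offset == 1, "A"], 0.5)
  # covered columns sum to 1; uncovered flagged by coverage 0
  covered <- m2$coverage > 0
  expect_equal(unname(rowSums(m2[covered, c("A", "C", "G", "U")])),
               rep(1, sum(covered)))
  expect_true(all(rowSums(m2[!covered, c("A", "C", "G", "U")]) == 0))
  # out-of-range offsets reduce the column denominator, never add NaN
  m3 <- logo_matrix(c("ACGTACGTACG", "ACG"), c(2L, 2L), window = 10L)
  expect_equal(m3$coverage[m3$offset == 3], 1L)
  expect_false(anyNA(m3))
})

test_that("simulated 5p-arm G bias is recovered in the logo", {
  cfg <- small_config(seed = 31, arm5_g_frac = 0.4)
  truth <- build_truth(cfg)
  p <- truth$planted[truth$planted$class == "fivep_tailed", ]
  seqs <- genome_fetch(truth$genome, p$chrom,
                       ifelse(p$strand == "+",
                              p$intron_start + p$arm5_rel5,
                              p$intron_end - p$arm5_rel3),
                       ifelse(p$strand == "+",
                              p$intron_start + p$arm5_rel3,
                              p$intron_end - p$arm5_rel5),
                       p$strand)
  m <- logo_matrix(seqs, rep(1L, length(seqs)), window = 21L)
  arm_cols <- m[m$offset >= 2 & m$offset <= 21, ]   # skip the biased 5' nt
  g_mean <- mean(arm_cols$G)
  n_obs <- 20 * length(seqs)
  ci <- binom.test(round(g_mean * n_obs), n_obs, 0.4,
                   conf.level = 0.999)$conf.int
  expect_true(ci[1] <= 0.4 && 0.4 <= ci[2])
})

test_that("length-matched sampling equalizes per-bin counts", {
  set.seed(3)
  cases <- vapply(c(55, 65, 150, 160, 170), rand_seq, "")
  pool <- vapply(rep(c(60, 80, 140, 155, 180, 190, 520), 3), rand_seq, "")
  cmp <- mfe_comparison(cases, pool, seed = 4)
  expect_true(cmp$matched)
  case_bins <- table(nchar(cases) %/% 100)
  ctrl_bins <- table(nchar(pool[cmp$control_idx]) %/% 100)
  expect_equal(as.integer(ctrl_bins[names(case_bins)]),
               as.integer(case_bins))
  # identical case and control inputs give mean difference 0
  cmp2 <- mfe_comparison(cases, cases, seed = 1)
  expect_equal(mean(cmp2$case_scores), mean(cmp2$control_scores))
  # a pool short of a bin proceeds unmatched with the flag cleared
  cmp3 <- mfe_comparison(cases, pool[1:2], seed = 1)
  expect_false(cmp3$matched)
})

test_that("planted hairpins fold lower per base than their shuffles", {
  cfg <- small_config(seed = 42)
  truth <- build_truth(cfg)
  p <- truth$planted
  seqs <- genome_fetch(truth$genome, p$chrom,
                       ifelse(is.na(p$intron_start), p$hairpin_rel5,
                              ifelse(p$strand == "+",
                                     p$intron_start + p$hairpin_rel5,
                                     p$intron_end - p$hairpin_rel3)),
                       ifelse(is.na(p$intron_start), p$hairpin_rel3,
                              ifelse(p$strand == "+",
                                     p$intron_start + p$hairpin_rel3,
                                     p$intron_end - p$hairpin_rel5)),
                       ifelse(is.na(p$intron_start), "+", p$strand))
  set.seed(7)
  wins <- vapply(seqs, function(s) {
    fold_hairpin(s)$energy_score / nchar(s) <
      fold_hairpin(dinuc_shuffle(s))$energy_score / nchar(s)
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("trimmed means drop the top fraction of genes", {
  gt <- data.frame(gene = paste0("g", 1:100), n_introns = 1:100,
                   class = "bulk")
  st <- host_intron_count_stats(gt)$stats
  expect_equal(st$trimmed_mean, mean(1:98))
  expect_equal(st$mean, mean(1:100))
  expect_lte(st$trimmed_mean, st$mean)

  # identical distributions: rank-sum p near 1
  gt2 <- rbind(gt, transform(gt, class = "mirtron_host"))
  st2 <- host_intron_count_stats(gt2)$stats
  expect_gt(st2$p_vs_bulk[st2$class == "mirtron_host"], 0.9)
  bins <- host_intron_count_stats(gt2)$bins
  expect_equal(sum(bins$count[bins$class == "bulk"]), 100L)

  # small classes are flagged
  gt3 <- rbind(gt, data.frame(gene = "x", n_introns = 50,
                              class = "snoRNA_host"))
  st3 <- host_intron_count_stats(gt3)$stats
  expect_true(st3$low_n[st3$class == "snoRNA_host"])
})

test_that("simulated host genes carry the planted intron-count excess", {
  cfg <- small_config(seed = 19, n_genes = 30L)
  truth <- build_truth(cfg)
  ic <- truth$introns[!duplicated(truth$introns$host_gene),
                      c("host_gene", "host_intron_count")]
  gt <- data.frame(gene = ic$host_gene, n_introns = ic$host_intron_count,
                   class = ifelse(grepl("^HOST", ic$host_gene),
                                  "mirtron_host", "bulk"))
  st <- host_intron_count_stats(gt)$stats
  ratio <- st$trimmed_mean[st$class == "mirtron_host"] /
    st$trimmed_mean[st$class == "bulk"]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 4.2)
  expect_lt(st$p_vs_bulk[st$class == "mirtron_host"], 0.01)
})

test_that("pre-miRNA length statistics handle degenerate classes", {
  st <- premirna_length_stats(c(60, 60, 60, 70), c(rep("canonical", 3),
                                                   "conventional"))
  canon <- st[st$class == "canonical", ]
  expect_equal(canon$mean, 60)
  expect_equal(canon$sd, 0)
  conv <- st[st$class == "conventional", ]
  expect_true(conv$low_n)
  expect_true(is.na(conv$sd))

  # two literally identical classes test as indistinguishable
  x <- rnorm(30, 60, 3)
  st2 <- premirna_length_stats(c(x, x),
                               rep(c("canonical", "conventional"),
                                   each = 30))
  expect_gt(st2$p_vs_reference[st2$class == "conventional"], 0.9)
})

test_that("seed conservation separates sequence from positional matches", {
  calls_a <- data.frame(intron_id = c("ha1", "ha2"),
                        mature_seq = c("TGAGGTAGTAGGTTGTATAGTT",
                                       "TGAGGCAGTAGGTTGTATAGTT"))
  calls_b <- data.frame(intron_id = c("mb1", "mb2"),
                        mature_seq = c("TGAGGTAGTAGGTTGTATAGTT",
                                       "TGAGGCTGTAGGTTGTATAGTT"))
  hom <- data.frame(intron_a = c("ha1", "ha2"), intron_b = c("mb1", "mb2"))
  res <- seed_conservation(calls_a, calls_b, hom)
  expect_equal(res$status, c("conserved", "positional_only"))
  # homology pairs not present in both call sets are dropped
  hom2 <- rbind(hom, data.frame(intron_a = "ha1", intron_b = "zz"))
  expect_equal(nrow(seed_conservation(calls_a, calls_b, hom2)), 2L)
})

test_that("permuted homology maps give chance-level seed conservation", {
  set.seed(15)
  n <- 60
  calls_a <- data.frame(intron_id = paste0("a", 1:n),
                        mature_seq = replicate(n, rand_seq(22)))
  calls_b <- data.frame(intron_id = paste0("b", 1:n),
                        mature_seq = calls_a$mature_seq)
  hom_true <- data.frame(intron_a = paste0("a", 1:n),
                         intron_b = paste0("b", 1:n))
  expect_equal(sum(seed_conservation(calls_a, calls_b,
                                     hom_true)$status == "conserved"), n)
  conserved_perm <- replicate(20, {
    hp <- data.frame(intron_a = paste0("a", 1:n),
                     intron_b = paste0("b", sample(n)))
    sum(seed_conservation(calls_a, calls_b, hp)$status == "conserved")
  })
  # chance rate for a 7-mer match between random 22-mers is ~n/4^7
  expect_lt(mean(conserved_perm), 3)
})

test_that("seed mimicry matches nt 2-7 against reference seeds", {
  calls <- data.frame(intron_id = c("m1", "m2", "m3"),
                      mature_seq = c("UGAGGUAGUAGGUUGUAUAGUU",
                                     "ACCCGTAGATCCGAACTTGTGG",
                                     "TGAGG"))
  refs <- c(`let7` = "GAGGUA", `mir100` = "CCCGUA")
  res <- seed_mimics(calls, refs)
  expect_equal(res$matches$locus, c("m1", "m2"))
  expect_equal(res$matches$reference, c("let7", "mir100"))
  expect_equal(res$skipped, "m3")     # mature < 8 nt skipped with flag
  expect_equal(nrow(seed_mimics(calls, character(0))$matches), 0L)
})

test_that("random reference seeds match at the closed-form chance rate", {
  set.seed(44)
  n_loci <- 300; n_refs <- 40
  calls <- data.frame(intron_id = paste0("m", 1:n_loci),
                      mature_seq = replicate(n_loci, rand_seq(22)))
  refs <- setNames(replicate(n_refs, rand_seq(6)), paste0("r", 1:n_refs))
  n_hit <- length(unique(seed_mimics(calls, refs)$matches$locus))
  p_hit <- 1 - (1 - length(unique(refs)) / 4^6)^1   # per-locus match prob
  expect_gt(binom.test(n_hit, n_loci, p_hit)$p.value, 0.001)
})
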