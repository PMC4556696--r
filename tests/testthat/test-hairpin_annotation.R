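test_that("the proxy fold recovers the documented GC-stem optimum", {
  f <- fold_hairpin("GGGGGGGGGGAAAACCCCCCCCCC")
  expect_equal(f$energy_score, -26)         # 10 G:C pairs (-3) + 1 loop (+4)
  expect_equal(sum(f$pair_table > 0), 20L)  # 10 pairs
  # perfect stack: position i pairs position 25 - i
  stem <- 1:10
  expect_equal(f$pair_table[stem], 25L - stem)
  expect_equal(f$loop_interval, c(11L, 14L))
})

test_that("fold score equals exhaustive enumeration on short sequences", {
  set.seed(101)
  seqs <- c("GGGGGAAAACCCCC", "GCGCGCAAAGCGCG", "ATATATAAAATATAT",
            replicate(8, rand_seq(sample(10:14, 1))))
  for (s in seqs) {
    expect_equal(mirtrons:::.fold_nussinov(s)$energy_score,
                 brute_fold_score(s), info = s)
  }
})

test_that("homopolymers fold to nothing; folding is deterministic", {
  f <- fold_hairpin(strrep("A", 40))
  expect_equal(f$energy_score, 0)
  expect_equal(sum(f$pair_table), 0L)
  expect_null(f$loop_interval)

  set.seed(77)
  s <- rand_seq(120)
  expect_identical(fold_hairpin(s), fold_hairpin(s))
})

test_that("a strong stem scores below its dinucleotide shuffle", {
  set.seed(13)
  arm <- rand_seq(20, alphabet = c("G", "C", "G", "A"))
  hp <- paste0(arm, "AACAA", rc(arm))
  shuf <- dinuc_shuffle(hp)
  expect_lt(fold_hairpin(hp)$energy_score, fold_hairpin(shuf)$energy_score)
})

test_that("planted simulator hairpins refold with most stem pairs recovered", {
  cfg <- small_config(seed = 21)
  truth <- build_truth(cfg)
  p <- truth$planted[truth$planted$class == "conventional", ][1, ]
  hp_seq <- genome_fetch(truth$genome, p$chrom,
                         if (p$strand == "+") p$intron_start else
                           p$intron_start,
                         p$intron_end, p$strand)
  f <- fold_hairpin(hp_seq)
  m <- cfg$arm_len
  planted_pairs <- 0L; recovered <- 0L
  paired_span <- m - cfg$overhang_3p
  L <- nchar(hp_seq)
  for (i in seq_len(paired_span)) {       # planted: i pairs L - 2 - i + 1
    j <- L - cfg$overhang_3p - i + 1L
    planted_pairs <- planted_pairs + 1L
    if (f$pair_table[i] == j) recovered <- recovered + 1L
  }
  expect_gte(recovered / planted_pairs, 0.8)
})

test_that("fold rejects out-of-bounds and invalid sequences", {
  expect_error(fold_hairpin(strrep("A", 10)), "length")
  expect_error(fold_hairpin(strrep("A", 1500)), "length")
  expect_error(fold_hairpin(paste0(strrep("A", 30), "X")), "ACGTN")
})

test_that("hairpin extent snaps dominant ends to splice sites and buckets reads", {
  intron <- make_intron(0L, 80L)
  crit <- annotation_criteria()
  # all 5p reads start at the donor, all 3p reads end at the acceptor
  st <- make_stacks(rel5 = c(0, 0, 0, 58, 58), rel3 = c(22, 22, 22, 80, 80))
  ext <- define_hairpin_extent(intron, st, crit)
  expect_equal(unname(ext$hairpin), c(0L, 80L))     # extent = whole intron
  expect_equal(ext$buckets$bucket, c(rep("fivep", 3), rep("threep", 2)))

  # dominant 5p start 150 nt into a 215-nt intron, 3p ends at acceptor
  intron2 <- make_intron(0L, 215L)
  st2 <- make_stacks(rel5 = c(rep(150, 5), rep(185, 2)),
                     rel3 = c(rep(172, 5), rep(215, 2)))
  ext2 <- define_hairpin_extent(intron2, st2, crit)
  expect_equal(unname(ext2$hairpin), c(150L, 215L))

  # within-tolerance ends snap to the splice sites
  st3 <- make_stacks(rel5 = c(1, 1, 60, 60), rel3 = c(23, 23, 79, 79))
  ext3 <- define_hairpin_extent(intron, st3, crit)
  expect_equal(unname(ext3$hairpin), c(0L, 80L))
})

test_that("ties between equal-weight species break to the lower coordinate", {
  intron <- make_intron(0L, 100L)
  st <- make_stacks(rel5 = c(10, 12, 60, 60), rel3 = c(32, 34, 82, 82))
  ext <- define_hairpin_extent(intron, st, annotation_criteria())
  expect_equal(ext$hairpin[["start"]], 10L)
})

test_that("loci with fewer than two distinct species are skipped", {
  intron <- make_intron(0L, 100L)
  st <- make_stacks(rel5 = c(10, 10), rel3 = c(32, 32))
  expect_null(define_hairpin_extent(intron, st, annotation_criteria()))
})

test_that("subtype classification follows the four splice-offset patterns", {
  crit <- annotation_criteria()
  intron <- make_intron(0L, 300L)
  cls <- function(h5, h3) classify_subtype(intron, c(start = h5, end = h3),
                                           crit)
  expect_equal(cls(0, 300)$subtype, "conventional")
  expect_equal(cls(200, 300)$subtype, "fivep_tailed")
  expect_equal(cls(0, 100)$subtype, "threep_tailed")
  two <- cls(30, 270)
  expect_equal(two$subtype, "two_tailed")
  expect_false(two$ambiguous)
  # 1-nt tolerance at both ends still reads as conventional
  expect_equal(cls(1, 299)$subtype, "conventional")
  # ambiguous band (offset in (1, 5)) snaps to the nearest class, flagged
  amb <- cls(3, 300)
  expect_true(amb$ambiguous)
  expect_equal(amb$subtype, "conventional")
  amb2 <- cls(4, 300)
  expect_true(amb2$ambiguous)
  expect_equal(amb2$subtype, "fivep_tailed")
})

test_that("duplex geometry accepts canonical overhangs and rejects extremes", {
  crit <- annotation_criteria()
  # synthetic pair table for a 60-nt hairpin: arms 0-22 and 38-60,
  # i (1-based, 1..20) pairs 59 - i: a clean stem with 2-nt 3' overhangs
  pt <- integer(60)
  for (i in 1:20) { pt[i] <- 59L - i; pt[59L - i] <- i }
  fold <- list(pair_table = pt)
  arm5 <- c(start = 0L, end = 22L); arm3 <- c(start = 38L, end = 60L)
  d <- assess_duplex(fold, arm5, arm3, crit)
  expect_equal(d$overhang_open_end, 2L)
  expect_equal(d$overhang_dicer_end, 2L)
  expect_true(d$dicing_ok)

  # blunt duplex: i pairs 61 - i, arms flush -> overhangs (0, 0), still ok
  pt2 <- integer(60)
  for (i in 1:20) { pt2[i] <- 61L - i; pt2[61L - i] <- i }
  d2 <- assess_duplex(list(pair_table = pt2), c(start = 0L, end = 20L),
                      c(start = 40L, end = 60L), crit)
  expect_equal(d2$overhang_open_end, 0L)
  expect_equal(d2$overhang_dicer_end, 0L)
  expect_true(d2$dicing_ok)

  # 6-nt 3' overhang at the open end fails the [-1, 4] window
  pt3 <- c(pt2, integer(6))   # same stem inside a 66-nt hairpin
  d3 <- assess_duplex(list(pair_table = pt3), c(start = 0L, end = 20L),
                      c(start = 40L, end = 66L), crit)
  expect_equal(d3$overhang_open_end, 6L)
  expect_false(d3$dicing_ok)

  # arms that never pair each other fail with a reason code
  d4 <- assess_duplex(list(pair_table = integer(60)),
                      arm5, arm3, crit)
  expect_false(d4$dicing_ok)
  expect_equal(d4$reason, "arms_unpaired")
})

test_that("tier assignment follows the documented precedence", {
  crit <- annotation_criteria()
  tier <- function(mature, star, ago = 0, total = mature + star,
                   ok = TRUE)
    apply_criteria(list(mature = mature, star = star, ago_ip = ago,
                        total = total), ok, crit)
  expect_equal(tier(45, 5), "confident_duplex")       # duplex 50, star 5
  expect_equal(tier(100, 1, ago = 20), "confident_agoip")
  expect_equal(tier(45, 4, total = 49), "candidate")  # below all, total >= 10
  expect_equal(tier(30, 2, ago = 20), "rescue_a")
  expect_equal(tier(93, 4, ago = 10, total = 100), "rescue_b")
  expect_equal(tier(4, 1, total = 5), "rejected")
  expect_equal(tier(100, 50, ok = FALSE), "candidate") # dicing gate
  expect_error(tier(-1, 5), "negative")
})

test_that("fractional evidence rounds half-up before threshold comparison", {
  crit <- annotation_criteria()
  expect_equal(apply_criteria(list(mature = 44.5, star = 5, ago_ip = 0,
                                   total = 49.5), TRUE, crit),
               "confident_duplex")
  expect_equal(apply_criteria(list(mature = 44.4, star = 4.4, ago_ip = 0,
                                   total = 48.8), TRUE, crit),
               "candidate")
})

test_that("a depth titrated to 49 duplex reads yields candidate, not confident", {
  set.seed(99)
  genome <- c(chr1 = rand_seq(400))
  intron <- make_intron(100L, 180L, strand = "+")
  arm5 <- substr(genome[["chr1"]], 101, 122)
  arm3 <- substr(genome[["chr1"]], 159, 180)
  batch <- read_batch(c(rep(arm5, 45), rep(arm3, 4)), rep(1L, 49), "lib1")
  man <- data.frame(library_id = "lib1", species = "s", tissue = "t",
                    lib_class = "total", stringsAsFactors = FALSE)
  calls <- annotate_mirtrons(genome, intron, list(lib1 = batch), man)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_total, 49)
  expect_equal(calls$tier, "candidate")
})

test_that("annotation with an empty library set yields no calls", {
  genome <- c(chr1 = rand_seq(300))
  intron <- make_intron(100L, 180L)
  man <- data.frame(library_id = "lib1", species = "s", tissue = "t",
                    lib_class = "total", stringsAsFactors = FALSE)
  empty <- read_batch(character(0), integer(0), "lib1")
  calls <- annotate_mirtrons(genome, intron, list(lib1 = empty), man)
  expect_equal(nrow(calls), 0L)
})

test_that("conventional calls have premirna_length equal to the intron length", {
  cfg <- small_config(seed = 4)
  truth <- build_truth(cfg)
  man <- sim_manifest(tissues = c("brain", "heart"), n_ago = 1,
                      n_control = 0, n_input = 0)
  sim <- simulate_reads(truth, man, cfg)
  calls <- annotate_mirtrons(truth$genome, truth$introns, sim$batches, man)
  conv <- truth$planted[truth$planted$class == "conventional", ]
  idx <- match(conv$locus_id, calls$intron_id)
  expect_false(anyNA(idx))
  ilen <- conv$intron_end - conv$intron_start
  expect_equal(calls$premirna_length[idx], ilen)
})
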