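# Synthetic genomes, planted mirtron loci and small RNA libraries with
# known ground truth.  The generator's defaults encode the study
# conditions the pipeline is characterized under; see the methods vignette
# for the rationale behind each value.

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator with their default study
#' conditions.  Hairpins are built by sampling a 22-nt 5p arm and
#' reverse-complementing it (with `stem_mismatch_rate` substitutions) into
#' the 3p arm, leaving 2-nt 3' overhangs at both duplex ends.  The duplex
#' depth per locus per library is split mature:star binomially with odds
#' `star_asymmetry`:1.
#'
#' @param seed integer master seed; every stage derives its own substream.
#' @param n_genes number of bulk (non-mirtron-host) genes.
#' @param class_counts named integer vector of planted loci per class:
#'   conventional, fivep_tailed, threep_tailed, two_tailed, canonical.
#' @param bulk_intron_mean,host_intron_mean Poisson means (shifted by +1)
#'   for intron counts of bulk genes and of mirtron host genes; the default
#'   host mean is ~2.7x the bulk mean, mirroring the observed excess of
#'   introns in mirtron host genes.
#' @param arm_len mature/star arm length (nt).
#' @param loop_len_conventional,loop_len_tailed mean/sd of the terminal
#'   loop length for conventional loci (longer hairpins) and for all other
#'   classes; loops are never shorter than 18 nt so the phased loop read
#'   survives the 17-nt mapping floor.
#' @param tail5_length_range,tail3_length_range log-uniform sampling range
#'   (nt) for the unstructured 5' and 3' tails.
#' @param two_tailed_tail_range range for both tails of two-tailed loci.
#' @param duplex_gc_bias G+C fraction of the sampled 5p arm.
#' @param arm5_g_frac G fraction of the 5p arm (C gets the remainder of
#'   `duplex_gc_bias`); the C-rich 3p arm follows by complementarity.
#' @param stem_mismatch_rate per-position substitution rate in the interior
#'   of the 3p arm, so folds are realistic but unambiguous.
#' @param overhang_3p 3' overhang (nt) left at each duplex end.
#' @param reads_per_locus duplex (mature + star) reads per planted locus in
#'   each total-RNA library, before the per-locus abundance scalar.
#' @param locus_abundance_sd sdlog of the log-normal per-locus abundance
#'   scalar (median 1) multiplying `reads_per_locus`, so loci are
#'   expressed over a realistic range rather than uniformly; 0 gives
#'   every locus identical depth.
#' @param star_asymmetry mature:star odds of the binomial strand split.
#' @param loop_read_rate loop reads emitted per mature read (total-RNA
#'   libraries only; loop species are rejected from Ago complexes).
#' @param jitter5_distribution named numeric vector mapping signed 5'-end
#'   offsets to probabilities (must sum to 1).  Splice-defined 5' ends are
#'   clipped at offset 0: no read can extend upstream of the donor.
#' @param uridylation_prob,adenylation_prob per-read probability that a
#'   3p read ending at the splice acceptor gains an untemplated U (T) or A
#'   tail; tail lengths follow `tail_length_probs`.
#' @param tail_length_probs named numeric vector, tail length -> probability.
#' @param decapitation_prob probability that a splice-defined 5p read
#'   starting exactly at the donor loses its leading G ("xU" read).
#' @param tail_confound if TRUE the 2 exonic nt downstream of every
#'   acceptor equal "TT", so an untemplated di-U tail also matches the
#'   genome -- the stress test for splice-anchored tail calling.  Default
#'   FALSE writes "CC" there so tails never match.
#' @param background_rate background degradation reads per kb of bulk
#'   intron per library.
#' @param ago_scale,input_scale depth multipliers for ago_ip and input
#'   libraries relative to total-RNA libraries.
#' @param discordant_fraction fraction of mirtron loci whose expression is
#'   restricted to a tissue subset while the host stays broad.
#' @param expression_noise_sd sd of the log-normal multiplicative noise
#'   linking mirtron RPMM to host junction RPM.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 40L,
                       class_counts = c(conventional = 6L, fivep_tailed = 10L,
                                        threep_tailed = 4L, two_tailed = 2L,
                                        canonical = 10L),
                       bulk_intron_mean = 6,
                       host_intron_mean = 18,
                       arm_len = 22L,
                       loop_len_conventional = c(mean = 38, sd = 9),
                       loop_len_tailed = c(mean = 20, sd = 3),
                       tail5_length_range = c(10L, 3000L),
                       tail3_length_range = c(10L, 300L),
                       two_tailed_tail_range = c(10L, 100L),
                       duplex_gc_bias = 0.5,
                       arm5_g_frac = 0.35,
                       stem_mismatch_rate = 0.1,
                       overhang_3p = 2L,
                       reads_per_locus = 550L,
                       locus_abundance_sd = 0.5,
                       star_asymmetry = 10,
                       loop_read_rate = 0.02,
                       jitter5_distribution = c(`0` = 0.8, `1` = 0.1, `-1` = 0.1),
                       uridylation_prob = 0.45,
                       adenylation_prob = 0.10,
                       tail_length_probs = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
                       decapitation_prob = 0.10,
                       tail_confound = FALSE,
                       background_rate = 1,
                       ago_scale = 1,
                       input_scale = 0.5,
                       discordant_fraction = 0.2,
                       expression_noise_sd = 0.2) {
  cfg <- as.list(environment())
  cls <- c("conventional", "fivep_tailed", "threep_tailed", "two_tailed",
           "canonical")
  if (!all(cls %in% names(cfg$class_counts)))
    stop("class_counts must name all of: ", paste(cls, collapse = ", "))
  cfg$class_counts <- cfg$class_counts[cls]
  stopifnot(all(cfg$class_counts >= 0), cfg$overhang_3p >= 0,
            cfg$n_genes >= 0, cfg$arm_len >= 17)
  probs <- c(cfg$uridylation_prob, cfg$adenylation_prob, cfg$decapitation_prob,
             cfg$loop_read_rate, cfg$discordant_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$uridylation_prob + cfg$adenylation_prob > 1)
    stop("uridylation_prob + adenylation_prob must be <= 1")
  if (abs(sum(cfg$jitter5_distribution) - 1) > 1e-9)
    stop("jitter5_distribution must sum to 1")
  if (abs(sum(cfg$tail_length_probs) - 1) > 1e-9)
    stop("tail_length_probs must sum to 1")
  if (is.null(names(cfg$jitter5_distribution)))
    stop("jitter5_distribution must be named by signed offset")
  structure(cfg, class = "sim_config")
}

# seeded RNG scoped to a block; master seed fans out into per-stage
# substreams so changing one stage's sampling does not perturb others
with_substream <- function(seed, offset, code) {
  sub <- (as.integer(seed) + as.integer(offset)) %% 2147480000L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub)
  force(code)
}

sample_nt <- function(n, probs) {
  if (n <= 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

rand_dna <- function(n, gc = 0.4) {
  paste(sample_nt(n, c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                       T = (1 - gc) / 2)), collapse = "")
}

log_uniform_int <- function(n, range) {
  lo <- log(range[1]); hi <- log(max(range[1], range[2]))
  as.integer(round(exp(runif(n, lo, hi))))
}

arm5_probs <- function(cfg) {
  g <- cfg$arm5_g_frac
  c <- max(cfg$duplex_gc_bias - g, 0)
  at <- max(1 - g - c, 0)
  c(A = at / 2, C = c, G = g, T = at / 2)
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Build one hairpin in sense orientation.  Returns the sequence plus arm /
# loop offsets relative to the hairpin start (0-based half-open).
build_hairpin <- function(cfg, splice5, splice3) {
  m <- cfg$arm_len
  loop_par <- if (splice5 && splice3) cfg$loop_len_conventional else
    cfg$loop_len_tailed
  loop_len <- max(18L, as.integer(round(rnorm(1, loop_par["mean"],
                                              loop_par["sd"]))))
  a <- sample_nt(m, arm5_probs(cfg))
  if (splice5) a[1:2] <- c("G", "T") else if (runif(1) < 0.7) a[1] <- "T"
  ov <- cfg$overhang_3p
  paired <- m - ov                      # arm positions in the stem
  b <- rev(COMP[a[seq_len(paired)]])    # revcomp of the paired 5p prefix
  # stem imperfections are planted as G:U wobbles (Watson-Crick partner
  # downgraded to the wobble base), so every planted position still pairs
  # and the planted register stays the unambiguous folding optimum;
  # only G/T partners admit a wobble, interior positions only
  if (paired > 8) {
    inner <- 4:(paired - 4)
    for (i in inner[runif(length(inner)) < cfg$stem_mismatch_rate]) {
      partner <- a[paired - i + 1L]   # b[i] pairs a[paired - i + 1]
      if (partner == "G") b[i] <- "T" else if (partner == "T") b[i] <- "G"
    }
  }
  tail3 <- if (splice3) c("A", "G") else sample_nt(ov, c(A = .25, C = .25,
                                                         G = .25, T = .25))
  b <- c(b, tail3)
  # A/C-only loops cannot pair internally (no A:C, A:A or C:C pairs), so
  # the planted stem register is the unambiguous folding optimum
  loop <- sample_nt(loop_len, c(A = 0.6, C = 0.4))
  seq <- paste(c(a, loop, b), collapse = "")
  L <- nchar(seq)
  list(seq = seq,
       arm5 = c(0L, m),                 # [start, end)
       arm3 = c(L - m, L),
       loop = c(m, L - m),
       length = L)
}

#' Build the ground-truth genome, intron set and planted loci
#'
#' @param config a [sim_config()].
#' @return list of class `truth_set` with elements `genome` (named character
#'   vector), `introns` (data.frame as from [read_introns_bed()], with
#'   splice dinucleotides), `planted` (one row per planted locus: class,
#'   genomic hairpin/arm intervals, intron-relative offsets, dominant arm,
#'   expression regime) and `config`.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, 0L, build_truth_impl(config))
}

build_truth_impl <- function(cfg) {
  cc <- cfg$class_counts
  mirtron_classes <- rep(c("conventional", "fivep_tailed", "threep_tailed",
                           "two_tailed"),
                         times = cc[c("conventional", "fivep_tailed",
                                      "threep_tailed", "two_tailed")])
  n_mirtron <- length(mirtron_classes)
  n_canonical <- cc[["canonical"]]

  exon_pad <- if (cfg$tail_confound) "TT" else "CC"
  genes <- list()

  # mirtron host genes: one planted intron each, remaining introns bulk
  for (i in seq_len(n_mirtron)) {
    cls <- mirtron_classes[i]
    n_int <- 1L + stats::rpois(1, cfg$host_intron_mean)
    planted_idx <- sample.int(n_int, 1)
    genes[[length(genes) + 1]] <- list(
      gene_id = sprintf("HOST%03d", i), n_introns = n_int,
      planted_idx = planted_idx, planted_class = cls)
  }
  for (i in seq_len(cfg$n_genes)) {
    n_int <- 1L + stats::rpois(1, cfg$bulk_intron_mean)
    genes[[length(genes) + 1]] <- list(
      gene_id = sprintf("BULK%03d", i), n_introns = n_int,
      planted_idx = NA_integer_, planted_class = NA_character_)
  }

  bulk_intron_len <- function(n) {
    heavy <- runif(n) < 0.15
    len <- ifelse(heavy, rlnorm(n, log(1500), 0.7), rlnorm(n, log(220), 0.55))
    pmin(pmax(as.integer(round(len)), 80L), 6000L)
  }

  chroms <- c("chrS1", "chrS2", "chrS3")
  chrom_seqs <- setNames(vector("list", length(chroms)), chroms)
  chrom_off <- setNames(rep(0L, length(chroms)), chroms)
  intron_rows <- list()
  planted_rows <- list()

  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    strand <- sample(c("+", "-"), 1)
    chrom <- chroms[(gi - 1L) %% length(chroms) + 1L]
    parts <- list(rand_dna(60L))        # leading exon
    pos <- 60L
    sense_introns <- list()             # per intron: start, end, rel info
    for (ii in seq_len(g$n_introns)) {
      if (!is.na(g$planted_idx) && ii == g$planted_idx) {
        cls <- g$planted_class
        hp <- build_hairpin(cfg, splice5 = cls %in% c("conventional",
                                                      "threep_tailed"),
                            splice3 = cls %in% c("conventional",
                                                 "fivep_tailed"))
        tail5 <- switch(cls,
          conventional = 0L,
          fivep_tailed = log_uniform_int(1, cfg$tail5_length_range),
          threep_tailed = 0L,
          two_tailed = log_uniform_int(1, cfg$two_tailed_tail_range))
        tail3 <- switch(cls,
          conventional = 0L,
          fivep_tailed = 0L,
          threep_tailed = log_uniform_int(1, cfg$tail3_length_range),
          two_tailed = log_uniform_int(1, cfg$two_tailed_tail_range))
        t5 <- if (tail5 > 0)
          paste0("GT", substr(rand_dna(tail5, 0.4), 3, tail5)) else ""
        t3 <- if (tail3 > 0)
          paste0(substr(rand_dna(tail3, 0.4), 1, tail3 - 2), "AG") else ""
        iseq <- paste0(t5, hp$seq, t3)
        ilen <- nchar(iseq)
        sense_introns[[ii]] <- list(
          start = pos, end = pos + ilen, seq = iseq, planted = TRUE,
          class = cls, hairpin_rel = c(tail5, tail5 + hp$length),
          arm5_rel = tail5 + hp$arm5, arm3_rel = tail5 + hp$arm3,
          loop_rel = tail5 + hp$loop)
      } else {
        ilen <- bulk_intron_len(1)
        iseq <- paste0("GT", substr(rand_dna(ilen, 0.4), 3, ilen - 2), "AG")
        sense_introns[[ii]] <- list(start = pos, end = pos + ilen, seq = iseq,
                                    planted = FALSE)
      }
      parts[[length(parts) + 1]] <- sense_introns[[ii]]$seq
      pos <- pos + nchar(sense_introns[[ii]]$seq)
      exon <- rand_dna(40L)
      # pin the 2 nt downstream of every acceptor (tail confound control)
      exon <- paste0(exon_pad, substr(exon, 3, 40))
      parts[[length(parts) + 1]] <- exon
      pos <- pos + 40L
    }
    gene_seq <- paste(parts, collapse = "")
    Lg <- nchar(gene_seq)
    off <- chrom_off[[chrom]]
    chrom_seqs[[chrom]][[length(chrom_seqs[[chrom]]) + 1]] <-
      if (strand == "+") gene_seq else revcomp(gene_seq)
    chrom_seqs[[chrom]][[length(chrom_seqs[[chrom]]) + 1]] <- rand_dna(50L)
    chrom_off[[chrom]] <- off + Lg + 50L

    to_genomic <- function(rel_start, rel_end) {
      if (strand == "+") c(off + rel_start, off + rel_end)
      else c(off + Lg - rel_end, off + Lg - rel_start)
    }
    for (ii in seq_along(sense_introns)) {
      si <- sense_introns[[ii]]
      gcoord <- to_genomic(si$start, si$end)
      intron_rows[[length(intron_rows) + 1]] <- data.frame(
        chrom = chrom, start = gcoord[1], end = gcoord[2], strand = strand,
        host_gene = g$gene_id, intron_index = ii,
        host_intron_count = g$n_introns, stringsAsFactors = FALSE)
      if (isTRUE(si$planted)) {
        planted_rows[[length(planted_rows) + 1]] <- data.frame(
          locus_id = paste0(g$gene_id, "|", ii), class = si$class,
          chrom = chrom, strand = strand,
          intron_start = gcoord[1], intron_end = gcoord[2],
          hairpin_rel5 = si$hairpin_rel[1], hairpin_rel3 = si$hairpin_rel[2],
          arm5_rel5 = si$arm5_rel[1], arm5_rel3 = si$arm5_rel[2],
          arm3_rel5 = si$arm3_rel[1], arm3_rel3 = si$arm3_rel[2],
          loop_rel5 = si$loop_rel[1], loop_rel3 = si$loop_rel[2],
          dominant_arm = sample(c("5p", "3p"), 1),
          stringsAsFactors = FALSE)
      }
    }
  }

  # canonical miRNA loci in intergenic space, plus strand
  for (ci in seq_len(n_canonical)) {
    hp <- build_hairpin(cfg, splice5 = FALSE, splice3 = FALSE)
    chrom <- chroms[(ci - 1L) %% length(chroms) + 1L]
    off <- chrom_off[[chrom]]
    pad5 <- rand_dna(25L); pad3 <- rand_dna(25L)
    chrom_seqs[[chrom]][[length(chrom_seqs[[chrom]]) + 1]] <-
      paste0(pad5, hp$seq, pad3)
    chrom_off[[chrom]] <- off + 50L + hp$length
    hstart <- off + 25L
    planted_rows[[length(planted_rows) + 1]] <- data.frame(
      locus_id = sprintf("CANON%03d", ci), class = "canonical",
      chrom = chrom, strand = "+",
      intron_start = NA_integer_, intron_end = NA_integer_,
      hairpin_rel5 = hstart, hairpin_rel3 = hstart + hp$length,
      arm5_rel5 = hstart + hp$arm5[1], arm5_rel3 = hstart + hp$arm5[2],
      arm3_rel5 = hstart + hp$arm3[1], arm3_rel3 = hstart + hp$arm3[2],
      loop_rel5 = hstart + hp$loop[1], loop_rel3 = hstart + hp$loop[2],
      dominant_arm = sample(c("5p", "3p"), 1),
      stringsAsFactors = FALSE)
  }
  # note: canonical rows store genomic (not intron-relative) coordinates in
  # the *_rel fields, with intron_start NA marking the convention switch

  genome <- vapply(chrom_seqs, function(p) paste(unlist(p), collapse = ""), "")
  genome <- genome[nchar(genome) > 0]

  introns <- do.call(rbind, intron_rows)
  introns <- introns[order(introns$chrom, introns$start), , drop = FALSE]
  rownames(introns) <- NULL
  introns$intron_id <- paste0(introns$host_gene, "|", introns$intron_index)
  introns <- annotate_splice_sites(introns, genome)

  planted <- if (length(planted_rows)) do.call(rbind, planted_rows) else
    data.frame()
  if (nrow(planted)) {
    planted$abundance <- rlnorm(nrow(planted), 0, cfg$locus_abundance_sd)
    mir <- planted$class != "canonical"
    planted$expression_regime <- NA_character_
    if (any(mir)) {
      n_dis <- round(cfg$discordant_fraction * sum(mir))
      regime <- rep("correlated", sum(mir))
      if (n_dis > 0) regime[sample.int(sum(mir), n_dis)] <- "discordant"
      planted$expression_regime[mir] <- regime
    }
    rownames(planted) <- NULL
  }

  structure(list(genome = genome, introns = introns, planted = planted,
                 config = cfg), class = "truth_set")
}

# sense sequence of a locus with 6 nt of flank on each side; origin is
# (anchor - 6) in sense coordinates
locus_region <- function(truth, p) {
  if (!is.na(p$intron_start)) {
    genome_fetch(truth$genome, p$chrom, p$intron_start - 6L,
                 p$intron_end + 6L, p$strand)
  } else {
    genome_fetch(truth$genome, p$chrom, p$hairpin_rel5 - 6L,
                 p$hairpin_rel3 + 6L, "+")
  }
}

# intron-relative [start,end) for mirtrons; genomic for canonical.  The
# region string from locus_region() has the locus anchor at offset 6.
region_substr <- function(region, rel5, rel3, anchor0 = 0L) {
  # substring, not substr: the region is scalar but rel5/rel3 are vectors
  substring(region, rel5 - anchor0 + 6L + 1L, rel3 - anchor0 + 6L)
}

#' Simulate small RNA libraries from a truth set
#'
#' Per library class: `total` libraries receive duplex, loop and background
#' reads; `input` the same at `input_scale` depth; `ago_ip` duplex reads
#' only (loop species are rejected from Ago complexes); `control_ip` only
#' background reads.  Every emitted read is annotated in the returned
#' ledger with its origin locus, arm, 5' offset and untemplated tail.
#'
#' @param truth a [build_truth()] result.
#' @param manifest data.frame of libraries (see [read_manifest()]).
#' @param config the same [sim_config()] lineage used for `truth`.
#' @return list with `batches` (named list of collapsed read batches, one
#'   per library) and `ledger` (data.frame: library_id, sequence, origin,
#'   arm, offset5, tail, count).
#' @export
simulate_reads <- function(truth, manifest, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"))
  validate_manifest(manifest)
  if (nrow(manifest) == 0L) stop("manifest with zero libraries")
  with_substream(config$seed, 1000L, simulate_reads_impl(truth, manifest,
                                                         config))
}

simulate_reads_impl <- function(truth, manifest, cfg) {
  planted <- truth$planted
  bulk <- truth$introns[!truth$introns$intron_id %in% planted$locus_id, ,
                        drop = FALSE]
  jit_off <- as.integer(names(cfg$jitter5_distribution))
  jit_p <- as.numeric(cfg$jitter5_distribution)
  tl_len <- as.integer(names(cfg$tail_length_probs))
  tl_p <- as.numeric(cfg$tail_length_probs)

  regions <- lapply(seq_len(nrow(planted)), function(i)
    locus_region(truth, planted[i, ]))

  emit_locus <- function(p, region, n_duplex, with_loop) {
    # for mirtrons the *_rel coords are intron-relative and the region
    # starts at intron_start - 6; for canonical loci they are genomic and
    # the region starts at hairpin_rel5 - 6
    a0 <- if (!is.na(p$intron_start)) 0L else p$hairpin_rel5
    splice5 <- p$class %in% c("conventional", "threep_tailed")
    splice3 <- p$class %in% c("conventional", "fivep_tailed")
    n_mat <- rbinom(1, n_duplex, cfg$star_asymmetry / (cfg$star_asymmetry + 1))
    n_star <- n_duplex - n_mat
    counts <- if (p$dominant_arm == "5p") c(`5p` = n_mat, `3p` = n_star)
              else c(`5p` = n_star, `3p` = n_mat)
    out <- list()
    for (arm in c("5p", "3p")) {
      n <- counts[[arm]]
      if (n == 0L) next
      r5 <- if (arm == "5p") p$arm5_rel5 else p$arm3_rel5
      r3 <- if (arm == "5p") p$arm5_rel3 else p$arm3_rel3
      off <- jit_off[sample.int(length(jit_off), n, replace = TRUE,
                                prob = jit_p)]
      if (arm == "5p" && splice5) {
        off[off < 0L] <- 0L              # lariat: nothing upstream of donor
        decap <- off == 0L & runif(n) < cfg$decapitation_prob
        off[decap] <- 1L
      }
      starts <- r5 + off
      seqs <- region_substr(region, starts, rep(r3, n), a0)
      tails <- rep("", n)
      if (arm == "3p" && splice3) {
        u <- runif(n)
        cat_u <- u < cfg$uridylation_prob
        cat_a <- !cat_u & u < cfg$uridylation_prob + cfg$adenylation_prob
        nt <- tl_len[sample.int(length(tl_len), n, replace = TRUE,
                                prob = tl_p)]
        tails[cat_u] <- strrep("T", nt[cat_u])
        tails[cat_a] <- strrep("A", nt[cat_a])
      }
      out[[arm]] <- data.frame(sequence = paste0(seqs, tails),
                               origin = p$locus_id, arm = arm,
                               offset5 = off, tail = tails,
                               stringsAsFactors = FALSE)
    }
    if (with_loop) {
      n_loop <- round(cfg$loop_read_rate * n_duplex)
      if (n_loop > 0L) {
        lseq <- region_substr(region, p$loop_rel5, p$loop_rel3, a0)
        out$loop <- data.frame(sequence = rep(lseq, n_loop),
                               origin = p$locus_id, arm = "loop",
                               offset5 = 0L, tail = "",
                               stringsAsFactors = FALSE)
      }
    }
    out
  }

  emit_background <- function(n_bg) {
    if (n_bg <= 0L || nrow(bulk) == 0L) return(NULL)
    lens <- bulk$end - bulk$start
    idx <- sample.int(nrow(bulk), n_bg, replace = TRUE, prob = lens)
    rlen <- sample(18:26, n_bg, replace = TRUE)
    rel <- floor(runif(n_bg) * pmax(lens[idx] - rlen, 1L))
    seqs <- character(n_bg)
    for (k in seq_len(n_bg)) {
      i <- idx[k]
      sense <- genome_fetch(truth$genome, bulk$chrom[i], bulk$start[i],
                            bulk$end[i], bulk$strand[i])
      seqs[k] <- substr(sense, rel[k] + 1L, min(rel[k] + rlen[k],
                                                nchar(sense)))
    }
    data.frame(sequence = seqs, origin = "background", arm = "bg",
               offset5 = NA_integer_, tail = "", stringsAsFactors = FALSE)
  }

  bulk_kb <- sum(bulk$end - bulk$start) / 1000
  batches <- list()
  ledger <- list()
  for (li in seq_len(nrow(manifest))) {
    lib <- manifest[li, ]
    scale <- switch(lib$lib_class, total = 1, input = cfg$input_scale,
                    ago_ip = cfg$ago_scale, control_ip = 0)
    reads <- list()
    if (lib$lib_class != "control_ip") {
      for (i in seq_len(nrow(planted))) {
        n_duplex <- as.integer(round(cfg$reads_per_locus * scale *
                                       planted$abundance[i]))
        reads <- c(reads, emit_locus(planted[i, ], regions[[i]], n_duplex,
                                     with_loop = lib$lib_class == "total"))
      }
    }
    if (lib$lib_class %in% c("total", "input", "control_ip")) {
      bg_scale <- if (lib$lib_class == "control_ip") 1 else scale
      n_bg <- as.integer(round(cfg$background_rate * bulk_kb * bg_scale))
      reads <- c(reads, list(emit_background(n_bg)))
    }
    reads <- do.call(rbind, Filter(Negate(is.null), reads))
    if (is.null(reads))
      reads <- data.frame(sequence = character(), origin = character(),
                          arm = character(), offset5 = integer(),
                          tail = character(), stringsAsFactors = FALSE)
    reads$library_id <- lib$library_id
    batches[[lib$library_id]] <- read_batch(reads$sequence,
                                            rep(1L, nrow(reads)),
                                            lib$library_id)
    if (nrow(reads)) {
      # manual key aggregation: background reads carry NA offsets, which
      # stats::aggregate would silently drop from its grouping columns
      key_cols <- c("library_id", "sequence", "origin", "arm", "offset5",
                    "tail")
      key <- do.call(paste, c(reads[key_cols], sep = "\x01"))
      first <- !duplicated(key)
      agg <- reads[first, key_cols, drop = FALSE]
      agg$count <- as.integer(rowsum(rep(1L, nrow(reads)), key)[key[first], 1])
      ledger[[lib$library_id]] <- agg
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(library_id = character(), sequence = character(),
               origin = character(), arm = character(), offset5 = integer(),
               tail = character(), count = integer())
  rownames(ledger) <- NULL
  list(batches = batches, ledger = ledger)
}

#' Default library manifest for simulations
#'
#' @param species species tag.
#' @param tissues tissues for the total-RNA libraries (one library each).
#' @param n_ago,n_control,n_input numbers of ago_ip / control_ip / input
#'   libraries.
#' @return manifest data.frame.
#' @export
sim_manifest <- function(species = "synthetic",
                         tissues = c("brain", "heart", "liver", "kidney"),
                         n_ago = 2L, n_control = 1L, n_input = 1L) {
  rows <- if (length(tissues)) data.frame(
    library_id = paste0("total_", tissues), species = species,
    tissue = tissues, lib_class = "total", stringsAsFactors = FALSE)
  else NULL
  add <- function(n, class, tag) {
    if (n <= 0) return(NULL)
    data.frame(library_id = paste0(tag, seq_len(n)), species = species,
               tissue = "mixed", lib_class = class, stringsAsFactors = FALSE)
  }
  out <- rbind(rows, add(n_ago, "ago_ip", "ago"),
               add(n_control, "control_ip", "ctl"),
               add(n_input, "input", "input"))
  if (is.null(out))
    out <- data.frame(library_id = character(), species = character(),
                      tissue = character(), lib_class = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate tissue expression tables with planted mirtron-host regimes
#'
#' Host expression is emitted at three levels (gene-level RPKM, flanking
#' exon RPKM, mirtron-spanning junction RPM, mutually consistent by
#' construction).  Loci in the `correlated` regime have mirtron RPMM
#' proportional to host junction RPM up to log-normal multiplicative noise;
#' `discordant` loci are tissue-masked: the mirtron accumulates in a small
#' tissue subset while the host stays broad.
#'
#' @param truth a [build_truth()] result.
#' @param tissues character vector of >= 3 tissue names.
#' @param config the config lineage of `truth`.
#' @return list with matrices `gene_rpkm`, `flank_rpkm`, `junction_rpm`,
#'   `mirtron_rpmm` (loci x tissues) and `regime` (named vector).
#' @export
simulate_expression <- function(truth, tissues, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"))
  if (length(tissues) < 3L) stop("need at least 3 tissues")
  with_substream(config$seed, 2000L,
                 simulate_expression_impl(truth, tissues, config))
}

simulate_expression_impl <- function(truth, tissues, cfg) {
  mir <- truth$planted[truth$planted$class != "canonical", , drop = FALSE]
  n <- nrow(mir); k <- length(tissues)
  if (n == 0L) stop("no mirtron loci in truth set")
  host <- matrix(rlnorm(n * k, meanlog = 3, sdlog = 1), n, k,
                 dimnames = list(mir$locus_id, tissues))
  junction <- host * 0.1               # junction RPM <= scaled exon signal
  gene <- host * exp(matrix(rnorm(n * k, 0, 0.05), n, k))
  noise <- exp(matrix(rnorm(n * k, 0, cfg$expression_noise_sd), n, k))
  mirtron <- junction * 5 * noise
  # discordant loci are uncoupled from the host: expression restricted to a
  # small tissue subset AND drawn independently of the host profile there
  dis <- which(mir$expression_regime == "discordant")
  for (i in dis) {
    keep <- sample.int(k, sample(1:2, 1))
    mirtron[i, ] <- 0
    mirtron[i, keep] <- rlnorm(length(keep), meanlog = 3, sdlog = 1)
  }
  list(gene_rpkm = gene, flank_rpkm = host, junction_rpm = junction,
       mirtron_rpmm = mirtron,
       regime = setNames(mir$expression_regime, mir$locus_id))
}

#' Write a full simulation to disk
#'
#' Emits genome.fa, introns.bed, manifest.tsv, reads/<library>.fa,
#' truth tables and expression tables under `outdir`.
#'
#' @param truth,sim,expr results of [build_truth()], [simulate_reads()],
#'   [simulate_expression()] (`expr` optional).
#' @param manifest the manifest used for `sim`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(truth, sim, manifest, outdir, expr = NULL) {
  dir.create(file.path(outdir, "reads"), recursive = TRUE,
             showWarnings = FALSE)
  write_genome_fasta(truth$genome, file.path(outdir, "genome.fa"))
  introns <- truth$introns
  bed <- data.frame(chrom = introns$chrom, start = introns$start,
                    end = introns$end,
                    name = paste(introns$host_gene, introns$intron_index,
                                 introns$host_intron_count, sep = "|"),
                    score = 0L, strand = introns$strand)
  con <- file(file.path(outdir, "introns.bed"), "w")
  write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  write_table(manifest, file.path(outdir, "manifest.tsv"),
              key = "library_id")
  for (lib in names(sim$batches))
    write_small_rna(sim$batches[[lib]],
                    file.path(outdir, "reads", paste0(lib, ".fa")))
  write_table(truth$planted, file.path(outdir, "truth_loci.tsv"),
              key = "locus_id")
  write_table(sim$ledger, file.path(outdir, "truth_ledger.tsv"),
              key = c("library_id", "origin", "sequence"))
  if (!is.null(expr)) {
    for (nm in c("gene_rpkm", "flank_rpkm", "junction_rpm", "mirtron_rpmm")) {
      tab <- data.frame(locus_id = rownames(expr[[nm]]), expr[[nm]],
                        check.names = FALSE)
      write_table(tab, file.path(outdir, paste0(nm, ".tsv")),
                  key = "locus_id")
    }
  }
  invisible(outdir)
}
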