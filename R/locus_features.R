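# Comparative statistics of mirtron loci: intron-length histograms,
# anchored nucleotide logos, folding-energy comparisons with
# length-matched controls, host-gene intron counts, pre-miRNA length
# statistics, and seed-based conservation/mimicry.

#' Intron length histogram in 100-nt bins with a pooled top bin
#'
#' @param introns intron data.frame.
#' @param class_labels character vector (parallel to `introns`, or named
#'   by intron_id and covering every intron) of class labels; NA or
#'   missing labels are an error.
#' @param bin bin width (nt).
#' @param pool_above lengths above this cap pool into one final bin
#'   (species-dependent in practice; 15 kb for human, 10 kb for mouse).
#' @return data.frame (class, bin_start, bin_end, count); the pooled bin
#'   has `bin_end = Inf`.
#' @export
intron_length_hist <- function(introns, class_labels, bin = 100L,
                               pool_above = 15000L) {
  if (!is.null(names(class_labels)))
    class_labels <- class_labels[introns$intron_id]
  if (length(class_labels) != nrow(introns) || anyNA(class_labels))
    stop("every intron needs a class label")
  classes <- if (is.factor(class_labels)) levels(class_labels) else
    sort(unique(class_labels))
  class_labels <- as.character(class_labels)
  len <- introns$end - introns$start
  lo <- pmin((len %/% bin) * bin, pool_above)
  starts <- sort(unique(c(seq(0L, pool_above, by = bin))))
  out <- expand.grid(class = classes, bin_start = starts,
                     stringsAsFactors = FALSE)
  out$bin_end <- ifelse(out$bin_start >= pool_above, Inf,
                        out$bin_start + bin)
  key <- paste(class_labels, lo)
  tab <- table(key)
  out$count <- as.integer(tab[paste(out$class, out$bin_start)])
  out$count[is.na(out$count)] <- 0L
  out[order(out$class, out$bin_start), , drop = FALSE]
}

#' Anchored position frequency matrix (sequence logo matrix)
#'
#' Aligns sequences at per-sequence anchor positions and tallies
#' nucleotide frequencies at each offset.  Sequences not covering an
#' offset are skipped at that offset, so column denominators vary; a
#' zero-coverage column carries zero frequencies and `coverage = 0` rather
#' than NaN.
#'
#' @param seqs character vector of sequences (DNA or RNA).
#' @param anchors 1-based anchor position within each sequence (the
#'   nucleotide reported at offset 0).
#' @param window offsets -window .. +window are reported.
#' @return data.frame (offset, A, C, G, U, coverage); each covered row's
#'   A+C+G+U sums to 1.
#' @export
logo_matrix <- function(seqs, anchors, window = 25L) {
  stopifnot(length(seqs) == length(anchors), window >= 10L)
  seqs <- gsub("U", "T", toupper(seqs), fixed = TRUE)
  offsets <- (-window):window
  mat <- matrix(0, length(offsets), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  cov <- integer(length(offsets))
  for (i in seq_along(seqs)) {
    pos <- anchors[i] + offsets
    ok <- pos >= 1L & pos <= nchar(seqs[i])
    nt <- substring(seqs[i], pos[ok], pos[ok])
    keep <- nt %in% c("A", "C", "G", "T")
    rows <- which(ok)[keep]
    idx <- cbind(rows, match(nt[keep], colnames(mat)))
    for (r in seq_len(nrow(idx)))
      mat[idx[r, 1], idx[r, 2]] <- mat[idx[r, 1], idx[r, 2]] + 1
    cov[rows] <- cov[rows] + 1L
  }
  freq <- mat
  covered <- cov > 0L
  freq[covered, ] <- mat[covered, , drop = FALSE] / cov[covered]
  out <- data.frame(offset = offsets, A = freq[, "A"], C = freq[, "C"],
                    G = freq[, "G"], U = freq[, "T"], coverage = cov)
  rownames(out) <- NULL
  out
}

#' Folding-energy comparison against length-matched controls
#'
#' Controls are sampled without replacement from the pool to match the
#' case length distribution in 100-nt bins; a bin short of pool takes the
#' whole bin and flags the comparison unmatched.  Scores are
#' energy-per-base from [fold_hairpin()]; significance by two-sample
#' t-test on the per-base means.
#'
#' @param case_seqs,control_pool character vectors (each 30-1000 nt).
#' @param seed RNG seed for the sampler.
#' @param backend fold backend.
#' @return list of class `mfe_comparison`: case_scores, control_scores
#'   (per-base energies), matched, test_p, case_cdf, control_cdf (sorted
#'   score vectors), control_idx (indices sampled from the pool).
#' @export
mfe_comparison <- function(case_seqs, control_pool, seed = 1L,
                           backend = "nussinov") {
  lens_case <- nchar(case_seqs); lens_pool <- nchar(control_pool)
  if (any(lens_case < 30L) || any(lens_pool < 30L))
    stop("all sequences must be >= 30 nt")
  bin_of <- function(l) l %/% 100L
  cb <- bin_of(lens_case); pb <- bin_of(lens_pool)
  picked <- integer(0); matched <- TRUE
  with_substream(seed, 0L, {
    for (b in sort(unique(cb))) {
      need <- sum(cb == b)
      avail <- which(pb == b)
      if (length(avail) < need) {
        matched <- FALSE
        take <- avail
      } else take <- sample(avail, need)
      picked <- c(picked, take)
    }
  })
  per_base <- function(s)
    vapply(s, function(x) fold_hairpin(x, backend)$energy_score / nchar(x),
           1, USE.NAMES = FALSE)
  case_scores <- per_base(case_seqs)
  control_scores <- per_base(control_pool[picked])
  p <- if (length(case_scores) > 1L && length(control_scores) > 1L &&
           (stats::var(case_scores) + stats::var(control_scores)) > 0)
    stats::t.test(case_scores, control_scores)$p.value else NA_real_
  structure(list(case_scores = case_scores, control_scores = control_scores,
                 matched = matched, test_p = p,
                 case_cdf = sort(case_scores),
                 control_cdf = sort(control_scores),
                 control_idx = picked),
            class = "mfe_comparison")
}

#' Host-gene intron count statistics with trimmed means
#'
#' The trimmed mean drops the top `trim_frac` of genes (by intron count)
#' before averaging, removing the outlier genes with extreme intron
#' numbers; significance per class against the `bulk` class by Wilcoxon
#' rank-sum test.
#'
#' @param gene_table data.frame with columns gene, n_introns, class; the
#'   reference class must be named "bulk".
#' @param trim_frac fraction of top genes trimmed (default 0.02).
#' @param breaks bin edges for the per-class intron-count distributions.
#' @return list: `stats` (class, n, mean, trimmed_mean, p_vs_bulk, low_n),
#'   `bins` (class, bin, count).
#' @export
host_intron_count_stats <- function(gene_table, trim_frac = 0.02,
                                    breaks = c(1, 5, 10, 20, 40, Inf)) {
  stopifnot(all(c("gene", "n_introns", "class") %in% names(gene_table)))
  trimmed_mean <- function(x) {
    n_drop <- floor(trim_frac * length(x))
    if (n_drop > 0) x <- sort(x)[seq_len(length(x) - n_drop)]
    mean(x)
  }
  bulk <- gene_table$n_introns[gene_table$class == "bulk"]
  classes <- sort(unique(gene_table$class))
  stats_df <- do.call(rbind, lapply(classes, function(cl) {
    x <- gene_table$n_introns[gene_table$class == cl]
    p <- if (cl == "bulk" || length(bulk) == 0L) NA_real_ else
      suppressWarnings(stats::wilcox.test(x, bulk)$p.value)
    data.frame(class = cl, n = length(x), mean = mean(x),
               trimmed_mean = trimmed_mean(x), p_vs_bulk = p,
               low_n = length(x) < 3L, stringsAsFactors = FALSE)
  }))
  labs <- paste0("[", breaks[-length(breaks)], ",",
                 breaks[-1], ")")
  binned <- do.call(rbind, lapply(classes, function(cl) {
    x <- gene_table$n_introns[gene_table$class == cl]
    cut_x <- cut(x, breaks = breaks, labels = labs, right = FALSE,
                 include.lowest = TRUE)
    data.frame(class = cl, bin = labs, count = as.integer(table(cut_x)),
               stringsAsFactors = FALSE)
  }))
  list(stats = stats_df, bins = binned)
}

#' Pre-miRNA length statistics per class
#'
#' @param lengths numeric vector of hairpin lengths (inclusive of the
#'   mature/star species).
#' @param classes parallel class labels.
#' @param reference_class class each mirtron class is tested against
#'   (rank-based two-sided test).
#' @return data.frame (class, n, mean, sd, p_vs_reference, low_n).
#' @export
premirna_length_stats <- function(lengths, classes,
                                  reference_class = "canonical") {
  stopifnot(length(lengths) == length(classes))
  ref <- lengths[classes == reference_class]
  out <- do.call(rbind, lapply(sort(unique(classes)), function(cl) {
    x <- lengths[classes == cl]
    p <- if (cl == reference_class || length(ref) == 0L) NA_real_ else
      suppressWarnings(stats::wilcox.test(x, ref)$p.value)
    data.frame(class = cl, n = length(x), mean = mean(x),
               sd = if (length(x) >= 2L) sd(x) else NA_real_,
               p_vs_reference = p, low_n = length(x) < 2L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

seed_of <- function(seq, from = 2L, to = 8L) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  substr(seq, from, to)
}

#' Cross-species seed conservation of mirtrons in homologous introns
#'
#' A pair is sequence-conserved iff the introns are homologous AND the
#' 7-mer seeds (nt 2-8 of the dominant mature species) are identical;
#' homologous pairs whose seeds differ are reported as positional-only.
#'
#' @param calls_a,calls_b call tables with `intron_id` and a mature
#'   sequence column `mature_seq` (falls back to the dominant arm's
#'   seq_5p/seq_3p from [annotate_mirtrons()]).
#' @param homology data.frame (intron_a, intron_b).
#' @return data.frame (intron_a, intron_b, seed_a, seed_b, status) with
#'   status in {conserved, positional_only}.
#' @export
seed_conservation <- function(calls_a, calls_b, homology) {
  mat_seq <- function(calls) {
    if ("mature_seq" %in% names(calls)) return(calls$mature_seq)
    ifelse(calls$mature_arm == "5p", calls$seq_5p, calls$seq_3p)
  }
  a <- setNames(mat_seq(calls_a), calls_a$intron_id)
  b <- setNames(mat_seq(calls_b), calls_b$intron_id)
  keep <- homology$intron_a %in% names(a) & homology$intron_b %in% names(b)
  h <- homology[keep, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(intron_a = character(), intron_b = character(),
                      seed_a = character(), seed_b = character(),
                      status = character()))
  h$seed_a <- seed_of(a[h$intron_a])
  h$seed_b <- seed_of(b[h$intron_b])
  h$status <- ifelse(h$seed_a == h$seed_b, "conserved", "positional_only")
  rownames(h) <- NULL
  h
}

#' Seed mimicry of mirtrons against reference miRNA seeds
#'
#' A mirtron matches a reference iff nt 2-7 of its dominant mature species
#' equals the reference 6-mer seed.  Mature species shorter than 8 nt are
#' skipped with a flag.
#'
#' @param calls call table (see [seed_conservation()] for the mature
#'   sequence convention).
#' @param reference_seeds named character vector of 6-mer seeds
#'   (names = reference miRNA ids).
#' @return list: `matches` (locus, reference, seed) and `skipped` (loci
#'   with too-short mature species).
#' @export
seed_mimics <- function(calls, reference_seeds) {
  if (length(reference_seeds) == 0L || nrow(calls) == 0L)
    return(list(matches = data.frame(locus = character(),
                                     reference = character(),
                                     seed = character()),
                skipped = character()))
  mature <- if ("mature_seq" %in% names(calls)) calls$mature_seq else
    ifelse(calls$mature_arm == "5p", calls$seq_5p, calls$seq_3p)
  short <- is.na(mature) | nchar(mature) < 8L
  seeds <- seed_of(mature[!short], 2L, 7L)
  refs <- gsub("U", "T", toupper(reference_seeds), fixed = TRUE)
  hit <- lapply(seq_along(seeds), function(i) {
    m <- which(refs == seeds[i])
    if (length(m) == 0L) return(NULL)
    data.frame(locus = calls$intron_id[!short][i], reference = names(refs)[m],
               seed = seeds[i], stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, Filter(Negate(is.null), hit))
  if (is.null(matches))
    matches <- data.frame(locus = character(), reference = character(),
                          seed = character())
  list(matches = matches, skipped = calls$intron_id[short])
}
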