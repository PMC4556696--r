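# Independent oracles and fixture builders shared across the suite.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

# Brute-force read mapper: scans every (trim, position, strand) triple by
# raw substring comparison.  Independent of map_iterative's search.
brute_map <- function(seq, genome, min_len = 17L, max_iter = 4L) {
  for (trim in 0:max_iter) {
    pre <- substr(seq, 1, nchar(seq) - trim)
    if (nchar(pre) < min_len) break
    hits <- list()
    for (chrom in names(genome)) {
      g <- genome[[chrom]]
      L <- nchar(g); w <- nchar(pre)
      for (s in 0:(L - w)) {
        win <- substr(g, s + 1, s + w)
        if (win == pre)
          hits[[length(hits) + 1]] <- c(chrom, s, s + w, "+")
        if (win == rc(pre))
          hits[[length(hits) + 1]] <- c(chrom, s, s + w, "-")
      }
    }
    if (length(hits))
      return(list(trim = trim,
                  hits = do.call(rbind, hits)[, , drop = FALSE]))
  }
  NULL
}

# Exhaustive enumeration of nested secondary structures (min loop 3) with
# the proxy energy model: sum of pair scores, +4 per hairpin loop, +2 per
# interior loop/bulge, +4 per multiloop; stacks and external bases free.
# Feasible for sequences up to ~14 nt; the independent oracle for the DP.
brute_fold_score <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  pscore <- function(a, b) {
    k <- paste0(a, b)
    if (k %in% c("GC", "CG")) return(-3)
    if (k %in% c("AT", "TA")) return(-2)
    if (k %in% c("GT", "TG")) return(-1)
    NA_real_
  }
  enum <- function(i, j) {
    if (j - i + 1 < 5) return(list(list()))
    out <- enum(i + 1, j)                  # i unpaired
    for (k in (i + 4):j) {
      if (is.na(pscore(s[i], s[k]))) next
      inner <- enum(i + 1, k - 1)
      right <- if (k + 1 <= j) enum(k + 1, j) else list(list())
      for (a in inner) for (b in right)
        out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
    }
    out
  }
  score_struct <- function(pairs) {
    if (length(pairs) == 0) return(0)
    sc <- 0
    for (p in pairs) {
      sc <- sc + pscore(s[p[1]], s[p[2]])
      inside <- Filter(function(q) q[1] > p[1] && q[2] < p[2], pairs)
      # children: pairs directly inside p (not nested in another inner pair)
      children <- Filter(function(q)
        !any(vapply(inside, function(r)
          r[1] < q[1] && q[2] < r[2], TRUE)), inside)
      if (length(children) == 0) sc <- sc + 4          # hairpin loop
      else if (length(children) >= 2) sc <- sc + 4     # multiloop
      else {
        ch <- children[[1]]
        if (!(ch[1] == p[1] + 1 && ch[2] == p[2] - 1))
          sc <- sc + 2                                 # interior loop/bulge
      }
    }
    sc
  }
  min(vapply(enum(1, n), score_struct, 1))
}

# Dinucleotide-unit shuffle: splits the sequence into non-overlapping
# 2-mers and permutes them, preserving mononucleotide counts exactly and
# dinucleotide-unit composition, while destroying long-range
# complementarity.
dinuc_shuffle <- function(seq) {
  n <- nchar(seq)
  cut <- seq(1, n - 1, by = 2)
  units <- substring(seq, cut, pmin(cut + 1, n))
  paste(sample(units), collapse = "")
}

# Stack fixture: per-read rows in the format assign_to_introns() emits
make_stacks <- function(rel5, rel3, weight = 1, sequence = NULL,
                        trimmed_suffix = "", genomic_overhang3 = 0L,
                        lib_class = "total", library_id = "lib1",
                        bucket = NULL) {
  n <- max(length(rel5), length(rel3))
  df <- data.frame(
    rel5 = rep_len(rel5, n), rel3 = rep_len(rel3, n),
    genomic_overhang3 = rep_len(genomic_overhang3, n),
    trimmed_suffix = rep_len(trimmed_suffix, n),
    sequence = if (is.null(sequence)) strrep("A", 20) else
      rep_len(sequence, n),
    weight = rep_len(weight, n), count = rep_len(weight, n),
    library_id = rep_len(library_id, n),
    lib_class = rep_len(lib_class, n), stringsAsFactors = FALSE)
  if (!is.null(bucket)) df$bucket <- rep_len(bucket, n)
  df
}

make_intron <- function(start = 0L, end = 100L, chrom = "chr1",
                        strand = "+", id = "G|1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             host_gene = sub("\\|.*", "", id), intron_index = 1L,
             host_intron_count = 1L, intron_id = id,
             stringsAsFactors = FALSE)
}

run_small_annotation <- function(cfg, manifest = NULL) {
  truth <- build_truth(cfg)
  if (is.null(manifest))
    manifest <- sim_manifest(tissues = "brain", n_ago = 0, n_control = 0,
                             n_input = 0)
  sim <- simulate_reads(truth, manifest, cfg)
  calls <- annotate_mirtrons(truth$genome, truth$introns, sim$batches,
                             manifest)
  list(truth = truth, sim = sim, calls = calls,
       stacks = attr(calls, "stacks"))
}

small_config <- function(...) {
  defaults <- list(n_genes = 8L,
                   class_counts = c(conventional = 2L, fivep_tailed = 2L,
                                    threep_tailed = 2L, two_tailed = 1L,
                                    canonical = 2L),
                   tail5_length_range = c(10L, 200L))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
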