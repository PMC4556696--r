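# Exact-match placement of collapsed reads with iterative 3' trimming,
# and assignment of placements to annotated introns.

#' Mapping configuration
#'
#' Only exact matching is supported; the `mismatches` field exists for
#' forward compatibility and any value other than 0 is rejected.
#'
#' @param min_len minimum prefix length retained while trimming (nt).
#' @param max_iterations maximum number of 1-nt 3' trims attempted.
#' @param mismatches must be 0.
#' @return list of class `mapping_config`.
#' @export
mapping_config <- function(min_len = 17L, max_iterations = 4L,
                           mismatches = 0L) {
  stopifnot(min_len >= 1L, max_iterations >= 0L)
  if (mismatches != 0L)
    stop("only exact matching is supported (mismatches = 0)")
  structure(list(min_len = as.integer(min_len),
                 max_iterations = as.integer(max_iterations),
                 mismatches = 0L),
            class = "mapping_config")
}

# all exact occurrences of `pattern` in `subject`; 0-based starts
find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Map collapsed reads by iterative 3' trimming
#'
#' Each read species is searched for as an exact substring of the genome on
#' both strands.  A read that fails to match is trimmed one 3' nucleotide
#' per iteration (up to `max_iterations` trims, never below `min_len`) and
#' re-searched; it is reported at the first iteration with any hit, with
#' all placements at that iteration retained (`multi = TRUE` when more
#' than one).  The trimmed 3' nucleotides are carried as `trimmed_suffix`
#' -- the substrate of untemplated-tail calling downstream.
#'
#' @param batch read batch from [read_batch()] / [read_small_rna()].
#' @param genome named character vector of chromosome sequences.
#' @param cfg a [mapping_config()].
#' @return data.frame of placements (one row per read species x placement):
#'   sequence, matched_prefix_len, trimmed_suffix, chrom, start, end,
#'   strand, n_placements, multi, weight (count / n_placements), count,
#'   library_id; unmapped species are attached as attribute `unmapped`.
#' @export
map_iterative <- function(batch, genome, cfg = mapping_config()) {
  validate_genome(genome)
  seqs <- batch$sequence
  n <- length(seqs)
  placements <- vector("list", n)
  mapped <- rep(FALSE, n)
  if (n > 0) {
    for (iter in 0:cfg$max_iterations) {
      todo <- which(!mapped & nchar(seqs) - iter >= cfg$min_len)
      if (length(todo) == 0L) break
      prefixes <- substr(seqs[todo], 1L, nchar(seqs[todo]) - iter)
      for (k in seq_along(todo)) {
        i <- todo[k]
        pat <- prefixes[k]
        rc <- revcomp(pat)
        rows <- list()
        for (chrom in names(genome)) {
          fwd <- find_all(pat, genome[[chrom]])
          if (length(fwd))
            rows[[length(rows) + 1]] <- data.frame(
              chrom = chrom, start = fwd, end = fwd + nchar(pat),
              strand = "+", stringsAsFactors = FALSE)
          rev <- find_all(rc, genome[[chrom]])
          if (length(rev))
            rows[[length(rows) + 1]] <- data.frame(
              chrom = chrom, start = rev, end = rev + nchar(pat),
              strand = "-", stringsAsFactors = FALSE)
        }
        if (length(rows)) {
          pl <- do.call(rbind, rows)
          pl$sequence <- seqs[i]
          pl$matched_prefix_len <- nchar(pat)
          pl$trimmed_suffix <- substr(seqs[i], nchar(pat) + 1L,
                                      nchar(seqs[i]))
          pl$n_placements <- nrow(pl)
          placements[[i]] <- pl
          mapped[i] <- TRUE
        }
      }
    }
  }
  out <- do.call(rbind, Filter(Negate(is.null), placements))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      sequence = character(), matched_prefix_len = integer(),
                      trimmed_suffix = character(), n_placements = integer(),
                      stringsAsFactors = FALSE)
  idx <- match(out$sequence, batch$sequence)
  out$count <- batch$count[idx]
  out$library_id <- batch$library_id[idx]
  out$multi <- out$n_placements > 1L
  out$weight <- out$count / out$n_placements
  out <- out[order(out$chrom, out$start, out$strand, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- batch[!mapped, , drop = FALSE]
  out
}

#' Assign read placements to introns (sense strand of the host gene)
#'
#' A placement is assigned to an intron iff it lies inside the intron on
#' the host gene's strand.  Reads whose 3' end overhangs the splice
#' acceptor by at most `acceptor_slack` nt (5' end inside) are kept and
#' their genomic overhang recorded -- these are the candidate templated
#' extensions that splice-anchored tail calling must still classify as
#' tails.  Any other boundary-spanning placement goes to the
#' junction-overlap bin and never counts as mirtron evidence; antisense
#' placements are tallied separately.
#'
#' Output coordinates are sense-relative: `rel5` is the read 5' end
#' measured from the intron's sense 5' end (0 = first intronic nt), `rel3`
#' the position one past the read 3' end.
#'
#' @param aligned placements from [map_iterative()].
#' @param introns intron data.frame (see [read_introns_bed()]).
#' @param lib_classes named vector mapping library_id to lib_class.
#' @param acceptor_slack maximum templated 3' overhang past the acceptor
#'   (nt) still treated as a locus read.
#' @return named list (by intron_id) of per-intron stack data.frames with
#'   columns rel5, rel3, genomic_overhang3, trimmed_suffix, sequence,
#'   weight, count, library_id, lib_class; attributes `antisense` and
#'   `junction_overlap` hold the tallied excluded weights.
#' @export
assign_to_introns <- function(aligned, introns,
                              lib_classes = NULL, acceptor_slack = 6L) {
  stacks <- setNames(vector("list", nrow(introns)), introns$intron_id)
  antisense <- 0; junction <- 0
  if (nrow(aligned) == 0L) {
    out <- Filter(Negate(is.null), stacks)
    attr(out, "antisense") <- 0; attr(out, "junction_overlap") <- 0
    return(out)
  }
  for (ii in seq_len(nrow(introns))) {
    intr <- introns[ii, ]
    on_chrom <- aligned$chrom == intr$chrom &
      aligned$start < intr$end + acceptor_slack &
      aligned$end > intr$start - acceptor_slack
    if (!any(on_chrom)) next
    cand <- aligned[on_chrom, , drop = FALSE]
    sense <- cand$strand == intr$strand
    antisense <- antisense +
      sum(cand$weight[!sense & cand$start >= intr$start &
                        cand$end <= intr$end])
    cand <- cand[sense, , drop = FALSE]
    if (nrow(cand) == 0L) next
    if (intr$strand == "+") {
      rel5 <- cand$start - intr$start
      rel3 <- cand$end - intr$start
    } else {
      rel5 <- intr$end - cand$end
      rel3 <- intr$end - cand$start
    }
    ilen <- intr$end - intr$start
    inside <- rel5 >= 0L & rel3 <= ilen
    over3 <- rel5 >= 0L & rel3 > ilen & rel3 <= ilen + acceptor_slack
    junction <- junction + sum(cand$weight[!(inside | over3)])
    keep <- inside | over3
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    st <- data.frame(
      rel5 = rel5[keep], rel3 = pmin(rel3[keep], ilen),
      genomic_overhang3 = pmax(rel3[keep] - ilen, 0L),
      trimmed_suffix = cand$trimmed_suffix, sequence = cand$sequence,
      weight = cand$weight, count = cand$count,
      library_id = cand$library_id, stringsAsFactors = FALSE)
    st$lib_class <- if (is.null(lib_classes)) "total" else
      unname(lib_classes[st$library_id])
    stacks[[introns$intron_id[ii]]] <-
      rbind(stacks[[introns$intron_id[ii]]], st)
  }
  out <- Filter(function(x) !is.null(x) && nrow(x) > 0, stacks)
  attr(out, "antisense") <- antisense
  attr(out, "junction_overlap") <- junction
  out
}
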