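# Terminal heterogeneity, untemplated 3' additions against splice-anchored
# references, and 5'-G decapitation ("xU") scoring.

SPLICE5_CLASSES <- c("conventional", "threep_tailed")  # 5p end = donor
SPLICE3_CLASSES <- c("conventional", "fivep_tailed")   # 3p end = acceptor

#' Terminal offset profile of an arm
#'
#' Offsets are signed nucleotides relative to the reference terminus
#' (negative = upstream); the reference is the splice site when that
#' terminus is splice-defined for the locus subtype, else the
#' weight-modal read end.  Untemplated suffixes never move a 3' end: the
#' stack coordinates already exclude them.  Mass outside [-window, window]
#' pools into the boundary bins.
#'
#' @param stacks bucketed per-locus stacks (from [define_hairpin_extent()],
#'   i.e. the `stacks` attribute of [annotate_mirtrons()]).
#' @param call the locus's row from [annotate_mirtrons()].
#' @param intron the matching intron row.
#' @param arm "5p" or "3p"; @param terminus "5" or "3".
#' @param window histogram half-width (nt).
#' @return list of class `end_profile`: locus, arm, terminus,
#'   reference (rel position), provenance, histogram (named fractions
#'   summing to 1), n_reads; `empty = TRUE` when the arm has no reads.
#' @export
end_offset_profile <- function(stacks, call, intron, arm = c("5p", "3p"),
                               terminus = c("5", "3"), window = 5L) {
  arm <- match.arg(arm); terminus <- match.arg(terminus)
  bucket <- if (arm == "5p") "fivep" else "threep"
  s <- stacks[stacks$bucket == bucket, , drop = FALSE]
  base <- list(locus = call$intron_id, arm = arm, terminus = terminus)
  if (nrow(s) == 0L)
    return(structure(c(base, list(empty = TRUE)), class = "end_profile"))
  ilen <- intron$end - intron$start
  ends <- if (terminus == "5") s$rel5 else s$rel3
  splice_ref <- (arm == "5p" && terminus == "5" &&
                   call$subtype %in% SPLICE5_CLASSES) ||
                (arm == "3p" && terminus == "3" &&
                   call$subtype %in% SPLICE3_CLASSES)
  if (splice_ref) {
    ref <- if (terminus == "5") 0L else ilen
    prov <- if (terminus == "5") "splice_donor" else "splice_acceptor"
  } else {
    agg <- rowsum(s$weight, ends)
    pos <- as.integer(rownames(agg))
    ref <- pos[order(-agg[, 1], pos)][1]
    prov <- "dominant_read"
  }
  off <- pmin(pmax(ends - ref, -window), window)
  hist <- rowsum(s$weight, off)
  frac <- setNames(as.numeric(hist[, 1]) / sum(s$weight), rownames(hist))
  structure(c(base, list(reference = ref, provenance = prov,
                         histogram = frac, n_reads = sum(s$weight),
                         empty = FALSE)),
            class = "end_profile")
}

tail_category <- function(tails) {
  n <- nchar(tails)
  nT <- nchar(gsub("[^T]", "", tails))
  nA <- nchar(gsub("[^A]", "", tails))
  out <- rep("other", length(tails))
  out[n == 0L] <- "none"
  allT <- n > 0L & nT == n
  out[allT & n == 1L] <- "monoU"
  out[allT & n == 2L] <- "diU"
  out[allT & n >= 3L] <- "multiU"
  allA <- n > 0L & nA == n
  out[allA & n == 1L] <- "monoA"
  out[allA & n == 2L] <- "diA"
  out[n > 0L & !allT & !allA & nT + nA == n] <- "mixed"
  out
}

#' Call untemplated 3' additions on a read stack
#'
#' With `anchored = TRUE` (splice-defined 3p ends) the reference is the
#' splice acceptor's 3' edge and every read nucleotide past it is tail,
#' regardless of whether it matches the genome; with `anchored = FALSE`
#' the reference is the weight-modal templated end and only
#' mapping-trimmed (genome-mismatching) suffixes are tail.  A read ending
#' before the reference never yields a negative tail: its suffix (if any)
#' is still untemplated tail.
#'
#' @param stacks per-locus stacks (any subset, typically the `threep`
#'   bucket).
#' @param reference_end sense-relative reference position; defaults to the
#'   intron length (the acceptor) when anchored, else the modal end.
#' @param anchored logical.
#' @param intron_length required when `anchored` and `reference_end` is
#'   NULL.
#' @return `stacks` with `tail_seq` and `tail_category` columns added.
#' @export
call_untemplated_tail <- function(stacks, anchored, reference_end = NULL,
                                  intron_length = NULL) {
  if (nrow(stacks) == 0L) {
    stacks$tail_seq <- character(0); stacks$tail_category <- character(0)
    return(stacks)
  }
  if (anchored) {
    if (is.null(reference_end)) {
      if (is.null(intron_length))
        stop("anchored tail calling needs reference_end or intron_length")
      reference_end <- intron_length
    }
    # templated nucleotides past the acceptor count as tail too
    matched_len <- nchar(stacks$sequence) - nchar(stacks$trimmed_suffix)
    past <- pmax(stacks$rel3 + stacks$genomic_overhang3 - reference_end, 0L)
    past <- pmin(past, stacks$genomic_overhang3)
    genomic_part <- substr(stacks$sequence, matched_len - past + 1L,
                           matched_len)
    tail <- paste0(genomic_part, stacks$trimmed_suffix)
  } else {
    tail <- stacks$trimmed_suffix
  }
  stacks$tail_seq <- tail
  stacks$tail_category <- tail_category(tail)
  stacks
}

#' Summarize tail categories with the >1% pooling rule
#'
#' Read-weighted fractions per tail category; categories carrying less
#' than `min_category_frac` of the reads are merged into `others`.
#'
#' @param calls data.frame with `tail_category` and `weight` columns
#'   (pooled across whatever grouping the caller wants).
#' @param min_category_frac pooling threshold (default 0.01).
#' @return data.frame (category, fraction), fractions summing to 1;
#'   empty input gives an empty table.
#' @export
summarize_tails <- function(calls, min_category_frac = 0.01) {
  if (nrow(calls) == 0L)
    return(data.frame(category = character(), fraction = numeric()))
  agg <- rowsum(calls$weight, calls$tail_category)
  frac <- as.numeric(agg[, 1]) / sum(agg[, 1])
  cat <- rownames(agg)
  small <- frac < min_category_frac
  if (any(small)) {
    frac <- c(frac[!small], sum(frac[small]))
    cat <- c(cat[!small], "others")
  }
  out <- data.frame(category = cat, fraction = frac,
                    stringsAsFactors = FALSE)
  out[order(-out$fraction, out$category), , drop = FALSE]
}

#' 5'-G decapitation ("xU") frequency of a splice-defined 5p arm
#'
#' Defined only for subtypes whose 5p arm starts at the splice donor
#' (conventional and 3'-tailed).  5p reads starting at the donor with the
#' G present are "GU"; reads starting one nt in (the G lost) are "xU";
#' everything else (>= 2 nt in, or upstream starts) is "other".  Loci with
#' fewer than `min_reads` 5p reads are returned undefined.
#'
#' @param stacks bucketed per-locus stacks.
#' @param call the locus's call row.
#' @param min_reads minimum 5p read count (default 10).
#' @return list of class `xu_summary`: locus, n_5p_reads, frac_GU,
#'   frac_xU, frac_other, defined.
#' @export
xu_frequency <- function(stacks, call, min_reads = 10L) {
  if (!call$subtype %in% SPLICE5_CLASSES)
    stop("xU is defined only for splice-defined 5p arms (conventional, ",
         "threep_tailed); got subtype ", call$subtype)
  s <- stacks[stacks$bucket == "fivep", , drop = FALSE]
  n <- sum(s$weight)
  base <- list(locus = call$intron_id, n_5p_reads = n)
  if (round_half_up(n) < min_reads)
    return(structure(c(base, list(frac_GU = NA_real_, frac_xU = NA_real_,
                                  frac_other = NA_real_, defined = FALSE)),
                     class = "xu_summary"))
  gu <- s$rel5 == 0L & startsWith(s$sequence, "G")
  xu <- s$rel5 == 1L
  structure(c(base, list(frac_GU = sum(s$weight[gu]) / n,
                         frac_xU = sum(s$weight[xu]) / n,
                         frac_other = sum(s$weight[!gu & !xu]) / n,
                         defined = TRUE)),
            class = "xu_summary")
}
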