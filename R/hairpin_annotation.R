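# Hairpin folding, duplex geometry, mirtron subtype classification and the
# tiered read-evidence criteria.

#' Annotation criteria
#'
#' Evidence thresholds for the tiered mirtron calls.  The main tier
#' requires at least `min_duplex_reads` total duplex (mature + star) reads
#' with at least `min_star_reads` star reads; loci failing that can still
#' be called confidently on Ago-IP support (`>= ago_rescue_min_mature`
#' mature reads of which `>= ago_rescue_min_agoip` from Ago-IP), or under
#' two narrow rescue tiers (few star reads but solid Ago-IP recovery).
#' Duplex 3' overhangs outside `[min_overhang, max_overhang]` nt fail the
#' dicing geometry check.  Hairpin ends within `splice_tolerance` nt of a
#' splice site are snapped to it; hairpin ends at least
#' `two_tailed_min_offset` nt from both splice sites define the two-tailed
#' class.
#'
#' @param min_duplex_reads,min_star_reads main duplex tier thresholds.
#' @param ago_rescue_min_mature,ago_rescue_min_agoip Ago-IP confident tier.
#' @param rescue_a_max_star,rescue_a_min_agoip rescue tier A (<= 3 star,
#'   >= 20 Ago-IP reads).
#' @param rescue_b_star_range,rescue_b_min_agoip,rescue_b_min_total rescue
#'   tier B (3-4 star, >= 10 Ago-IP, >= 100 total).
#' @param min_candidate_total floor below which a locus is rejected.
#' @param min_overhang,max_overhang accepted duplex 3'-overhang window
#'   (nt; negative = 5' overhang).  Brackets the canonical 2-nt 3' overhang
#'   while tolerating the occasional 4-nt case.
#' @param min_stem_pairs minimum base pairs linking the two arms.
#' @param splice_tolerance nt, snap-to-splice-site window.
#' @param two_tailed_min_offset nt, minimum offset of both hairpin ends
#'   from the splice sites for the two-tailed class.
#' @return list of class `annotation_criteria`.
#' @export
annotation_criteria <- function(min_duplex_reads = 50L, min_star_reads = 5L,
                                ago_rescue_min_mature = 100L,
                                ago_rescue_min_agoip = 20L,
                                rescue_a_max_star = 3L,
                                rescue_a_min_agoip = 20L,
                                rescue_b_star_range = c(3L, 4L),
                                rescue_b_min_agoip = 10L,
                                rescue_b_min_total = 100L,
                                min_candidate_total = 10L,
                                min_overhang = -1L, max_overhang = 4L,
                                min_stem_pairs = 12L,
                                splice_tolerance = 1L,
                                two_tailed_min_offset = 5L) {
  cfg <- as.list(environment())
  thresholds <- unlist(cfg[c("min_duplex_reads", "min_star_reads",
                             "ago_rescue_min_mature", "ago_rescue_min_agoip",
                             "min_candidate_total")])
  stopifnot(all(thresholds >= 0), cfg$min_overhang <= cfg$max_overhang)
  structure(cfg, class = "annotation_criteria")
}

#' Fold a candidate hairpin
#'
#' Default backend is the package's deterministic base-pair-maximization
#' scorer (G:C = -3, A:U = -2, G:U = -1, +4 per hairpin loop, nested
#' structures only); `backend = "rnafold"` shells out to ViennaRNA's
#' RNAfold when it is on the PATH and returns its thermodynamic MFE.
#' Scores are comparable within a backend only.
#'
#' @param seq DNA or RNA string, 20 to 1000 nt.
#' @param backend "nussinov" (built-in) or "rnafold".
#' @return list of class `hairpin_fold`: sequence, pair_table (1-based
#'   partner index, 0 = unpaired), energy_score (lower = more stable),
#'   loop_interval (1-based [start, end] of the terminal loop of the
#'   deepest stem, NULL if no pairs).
#' @export
fold_hairpin <- function(seq, backend = c("nussinov", "rnafold")) {
  backend <- match.arg(backend)
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  n <- nchar(seq)
  if (n < 20L || n > 1000L)
    stop("fold_hairpin requires 20 <= length <= 1000, got ", n)
  if (grepl("[^ACGTN]", seq)) stop("non-ACGTN characters in hairpin")
  if (backend == "nussinov") {
    res <- .fold_nussinov(seq)
    pt <- res$pair_table
    score <- res$energy_score
  } else {
    rna <- gsub("T", "U", seq, fixed = TRUE)
    out <- system2("RNAfold", c("--noPS"), input = rna, stdout = TRUE)
    line <- out[2]
    db <- sub("\\s.*$", "", line)
    score <- as.numeric(gsub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", line))
    pt <- dotbracket_to_pairs(db)
  }
  structure(list(sequence = seq, pair_table = pt, energy_score = score,
                 loop_interval = terminal_loop(pt)),
            class = "hairpin_fold")
}

dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  pt
}

# terminal loop of the deepest (longest) stem: the innermost pair with no
# pairs inside, chosen to maximize enclosing stack depth
terminal_loop <- function(pt) {
  paired <- which(pt > 0)
  if (length(paired) == 0L) return(NULL)
  opens <- which(pt > seq_along(pt))
  best <- NULL; best_depth <- -1L
  for (i in opens) {
    j <- pt[i]
    if (j - i < 2L) next
    inner <- (i + 1L):(j - 1L)
    if (all(pt[inner] == 0L)) {
      depth <- sum(pt[seq_len(i)] >= j)   # pairs enclosing (i, j)
      if (depth > best_depth) { best_depth <- depth; best <- c(i + 1L, j - 1L) }
    }
  }
  best
}

# weight-dominant read species; ties break to the lower coordinate
dominant_species <- function(stacks) {
  agg <- stats::aggregate(list(weight = stacks$weight),
                          by = stacks[c("rel5", "rel3")], FUN = sum)
  agg[order(-agg$weight, agg$rel5, agg$rel3), , drop = FALSE]
}

#' Define the hairpin extent of a locus and bucket its reads
#'
#' The hairpin 5' end is the weight-dominant read start (snapped to the
#' splice donor if within `splice_tolerance`); the 3' end the dominant
#' read end after untemplated-suffix stripping (snapped to the acceptor
#' likewise).  Reads are then bucketed: `fivep` if their 5' end lies
#' within 3 nt of the hairpin 5' end, `threep` if their 3' end lies within
#' 3 nt of the hairpin 3' end, `loop` if fully between the two dominant
#' arm species, `other` otherwise.
#'
#' @param intron one intron row (with donor/acceptor columns).
#' @param stacks per-intron stack data.frame from [assign_to_introns()].
#' @param criteria an [annotation_criteria()].
#' @return NULL when fewer than two distinct read species exist (no duplex
#'   possible), else list: hairpin (rel [start, end)), arm5, arm3 (dominant
#'   species rel intervals), buckets (stacks plus `bucket` column).
#' @export
define_hairpin_extent <- function(intron, stacks, criteria) {
  dom <- dominant_species(stacks)
  if (nrow(dom) < 2L) return(NULL)
  top <- dom[1, ]
  # partner: heaviest species overlapping the top species by less than
  # half of the shorter read, so mature and star are distinct stacks
  ovl <- pmin(dom$rel3, top$rel3) - pmax(dom$rel5, top$rel5)
  minlen <- pmin(dom$rel3 - dom$rel5, top$rel3 - top$rel5)
  partner_ok <- ovl < minlen / 2
  partner_ok[1] <- FALSE
  if (!any(partner_ok)) return(NULL)
  partner <- dom[which(partner_ok)[1], ]
  if (top$rel5 <= partner$rel5) { a5 <- top; a3 <- partner }
  else { a5 <- partner; a3 <- top }
  ilen <- intron$end - intron$start
  tol <- criteria$splice_tolerance
  h5 <- if (a5$rel5 <= tol) 0L else a5$rel5
  h3 <- if (ilen - a3$rel3 <= tol) ilen else a3$rel3
  bucket <- rep("other", nrow(stacks))
  near5 <- abs(stacks$rel5 - a5$rel5) <= 3L
  near3 <- abs(stacks$rel3 - a3$rel3) <= 3L
  bucket[near3] <- "threep"
  bucket[near5] <- "fivep"    # 5p wins the (rare) double-qualification
  isloop <- !near5 & !near3 & stacks$rel5 >= a5$rel3 & stacks$rel3 <= a3$rel5
  bucket[isloop] <- "loop"
  stacks$bucket <- bucket
  list(hairpin = c(start = h5, end = h3),
       arm5 = c(start = a5$rel5, end = a5$rel3),
       arm3 = c(start = a3$rel5, end = a3$rel3),
       buckets = stacks)
}

#' Classify the biogenesis subtype from hairpin-splice-site offsets
#'
#' Both ends within `splice_tolerance` of the splice sites: conventional.
#' Only the 3' end abutting the acceptor: 5'-tailed.  Only the 5' end
#' abutting the donor: 3'-tailed.  Neither end within
#' `two_tailed_min_offset`: two-tailed.  Offsets in the ambiguous band
#' between the two bounds snap to the nearest class with `ambiguous = TRUE`.
#'
#' @param intron intron row; @param hairpin rel [start, end) from
#'   [define_hairpin_extent()]; @param criteria an [annotation_criteria()].
#' @return list(subtype, ambiguous).
#' @export
classify_subtype <- function(intron, hairpin, criteria) {
  ilen <- intron$end - intron$start
  d5 <- hairpin[["start"]]
  d3 <- ilen - hairpin[["end"]]
  tol <- criteria$splice_tolerance
  off <- criteria$two_tailed_min_offset
  near5 <- d5 <= tol; near3 <- d3 <= tol
  far5 <- d5 >= off; far3 <- d3 >= off
  amb <- FALSE
  if (near5 && near3) subtype <- "conventional"
  else if (near3 && far5) subtype <- "fivep_tailed"
  else if (near5 && far3) subtype <- "threep_tailed"
  else if (far5 && far3) subtype <- "two_tailed"
  else {
    # at least one offset in (tol, off): snap each end to its nearer state
    amb <- TRUE
    close5 <- d5 <= (tol + off) / 2
    close3 <- d3 <= (tol + off) / 2
    subtype <- if (close5 && close3) "conventional"
    else if (close3) "fivep_tailed"
    else if (close5) "threep_tailed"
    else "two_tailed"
  }
  list(subtype = subtype, ambiguous = amb)
}

#' Assess miRNA/star duplex geometry on a folded hairpin
#'
#' Overhangs are signed: positive = 3' overhang.  The open-end overhang is
#' the extension of the 3p 3' end past the pairing partner of the 5p 5'
#' end; the Dicer-end overhang the extension of the 5p 3' end past the
#' partner of the 3p 5' end.  Partners are extrapolated from the duplex
#' register (the median of i + partner(i) over all arm-arm pairs), which
#' is robust to unpaired or locally shifted terminal bases.  `dicing_ok`
#' requires both overhangs inside the accepted window and at least
#' `min_stem_pairs` base pairs linking the two arms.
#'
#' @param fold a [fold_hairpin()] over the hairpin extent.
#' @param arm5,arm3 dominant arm intervals relative to the hairpin start
#'   (0-based half-open, as rel coords minus hairpin start).
#' @param criteria an [annotation_criteria()].
#' @return list: overhang_open_end, overhang_dicer_end, stem_pairs,
#'   dicing_ok, reason.
#' @export
assess_duplex <- function(fold, arm5, arm3, criteria) {
  pt <- fold$pair_table
  n <- length(pt)
  a1 <- arm5[["start"]] + 1L; a2 <- arm5[["end"]]     # 1-based inclusive
  b1 <- arm3[["start"]] + 1L; b2 <- arm3[["end"]]
  a2 <- min(a2, n); b2 <- min(b2, n)
  arm_pos <- (a1:a2)[pt[a1:a2] >= b1 & pt[a1:a2] <= b2]
  stem_pairs <- length(arm_pos)
  if (stem_pairs == 0L)
    return(list(overhang_open_end = NA_integer_,
                overhang_dicer_end = NA_integer_, stem_pairs = 0L,
                dicing_ok = FALSE, reason = "arms_unpaired"))
  register <- stats::median(arm_pos + pt[arm_pos])
  overhang_open <- round_half_up(b2 + a1 - register)
  overhang_dicer <- round_half_up(a2 + b1 - register)
  ok_open <- overhang_open >= criteria$min_overhang &&
    overhang_open <= criteria$max_overhang
  ok_dicer <- overhang_dicer >= criteria$min_overhang &&
    overhang_dicer <= criteria$max_overhang
  ok_stem <- stem_pairs >= criteria$min_stem_pairs
  reason <- if (!ok_stem) "weak_stem"
  else if (!ok_open || !ok_dicer) "overhang_out_of_window" else "ok"
  list(overhang_open_end = as.integer(overhang_open),
       overhang_dicer_end = as.integer(overhang_dicer),
       stem_pairs = stem_pairs,
       dicing_ok = ok_open && ok_dicer && ok_stem, reason = reason)
}

round_half_up <- function(x) floor(x + 0.5)

#' Apply the tiered evidence criteria
#'
#' Tiers are evaluated in order -- confident_duplex, confident_agoip,
#' rescue_a, rescue_b, candidate, rejected -- and the first match wins.
#' Counts are weighted sums (multi-mappers contribute fractionally) and
#' are rounded half-up before threshold comparison.
#'
#' @param counts named list/vector with mature, star, ago_ip, total.
#' @param dicing_ok logical from [assess_duplex()].
#' @param criteria an [annotation_criteria()].
#' @return tier string.
#' @export
apply_criteria <- function(counts, dicing_ok, criteria) {
  counts <- as.list(counts)
  v <- vapply(counts[c("mature", "star", "ago_ip", "total")], as.numeric, 1)
  if (any(v < 0)) stop("negative evidence counts")
  v <- round_half_up(v)
  mature <- v[["mature"]]; star <- v[["star"]]
  ago <- v[["ago_ip"]]; total <- v[["total"]]
  duplex <- mature + star
  if (duplex >= criteria$min_duplex_reads && star >= criteria$min_star_reads &&
      dicing_ok) return("confident_duplex")
  if (mature >= criteria$ago_rescue_min_mature &&
      ago >= criteria$ago_rescue_min_agoip && dicing_ok)
    return("confident_agoip")
  if (star <= criteria$rescue_a_max_star && ago >= criteria$rescue_a_min_agoip &&
      dicing_ok) return("rescue_a")
  if (star >= criteria$rescue_b_star_range[1] &&
      star <= criteria$rescue_b_star_range[2] &&
      ago >= criteria$rescue_b_min_agoip &&
      total >= criteria$rescue_b_min_total && dicing_ok) return("rescue_b")
  if (total >= criteria$min_candidate_total) return("candidate")
  "rejected"
}

#' Annotate mirtrons end to end
#'
#' Maps every library, assigns placements to introns, defines hairpin
#' extents, folds, assesses duplex geometry, classifies subtype and applies
#' the tiered criteria.  A stage failure on one locus never aborts the
#' run: the locus is emitted with tier "errored".
#'
#' @param genome named character vector.
#' @param introns intron data.frame with donor/acceptor annotated.
#' @param batches named list of read batches (one per library).
#' @param manifest library manifest.
#' @param criteria an [annotation_criteria()].
#' @param map_cfg a [mapping_config()].
#' @param fold_backend backend for [fold_hairpin()].
#' @return data.frame of mirtron calls, one row per intron with >= 2 read
#'   stacks, sorted by intron_id; per-locus stacks (with buckets) attached
#'   as attribute `stacks`, placements as attribute `placements`.
#' @export
annotate_mirtrons <- function(genome, introns, batches, manifest,
                              criteria = annotation_criteria(),
                              map_cfg = mapping_config(),
                              fold_backend = "nussinov") {
  validate_manifest(manifest)
  lib_classes <- setNames(manifest$lib_class, manifest$library_id)
  placements <- do.call(rbind, lapply(batches, map_iterative, genome = genome,
                                      cfg = map_cfg))
  if (is.null(placements) || nrow(placements) == 0L)
    return(empty_calls())
  rownames(placements) <- NULL
  stacks_by_intron <- assign_to_introns(placements, introns,
                                        lib_classes = lib_classes)
  calls <- list(); kept_stacks <- list()
  for (iid in names(stacks_by_intron)) {
    intron <- introns[introns$intron_id == iid, ][1, ]
    res <- tryCatch(
      annotate_one(intron, stacks_by_intron[[iid]], criteria, fold_backend,
                   genome),
      error = function(e) list(call = errored_call(intron, conditionMessage(e)),
                               stacks = NULL))
    if (!is.null(res$call)) calls[[iid]] <- res$call
    if (!is.null(res$stacks)) kept_stacks[[iid]] <- res$stacks
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  out <- out[order(out$intron_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stacks") <- kept_stacks
  attr(out, "placements") <- placements
  out
}

annotate_one <- function(intron, stacks, criteria, fold_backend, genome) {
  ext <- define_hairpin_extent(intron, stacks, criteria)
  if (is.null(ext)) return(list(call = NULL, stacks = NULL))
  cls <- classify_subtype(intron, ext$hairpin, criteria)
  h5 <- ext$hairpin[["start"]]; h3 <- ext$hairpin[["end"]]
  if (intron$strand == "+") {
    g5 <- intron$start + h5; g3 <- intron$start + h3
  } else {
    g5 <- intron$end - h3; g3 <- intron$end - h5
  }
  hp_seq <- genome_fetch(genome, intron$chrom, g5, g3, intron$strand)
  b <- ext$buckets
  w5 <- sum(b$weight[b$bucket == "fivep"])
  w3 <- sum(b$weight[b$bucket == "threep"])
  mature_arm <- if (w5 >= w3) "5p" else "3p"
  counts <- list(mature = max(w5, w3), star = min(w5, w3),
                 loop = sum(b$weight[b$bucket == "loop"]),
                 ago_ip = sum(b$weight[b$bucket %in% c("fivep", "threep") &
                                         b$lib_class == "ago_ip"]),
                 total = sum(b$weight))
  # folding decides only the dicing-gated tiers; skip it when read counts
  # alone already confine the locus to candidate/rejected
  duplex <- if (!apply_criteria(counts, TRUE, criteria) %in%
                  c("candidate", "rejected")) {
    if (nchar(hp_seq) >= 20L && nchar(hp_seq) <= 1000L) {
      fold <- fold_hairpin(hp_seq, backend = fold_backend)
      assess_duplex(fold, ext$arm5 - h5, ext$arm3 - h5, criteria)
    } else list(overhang_open_end = NA_integer_,
                overhang_dicer_end = NA_integer_, stem_pairs = 0L,
                dicing_ok = FALSE, reason = "hairpin_length_out_of_bounds")
  } else list(overhang_open_end = NA_integer_,
              overhang_dicer_end = NA_integer_, stem_pairs = NA_integer_,
              dicing_ok = FALSE, reason = "not_assessed")
  tier <- apply_criteria(counts, duplex$dicing_ok, criteria)
  dom_seq <- function(arm) {
    sel <- b$bucket == arm
    if (!any(sel)) return(NA_character_)
    s <- b[sel, , drop = FALSE]
    agg <- stats::aggregate(list(weight = s$weight),
                            by = s["sequence"], FUN = sum)
    agg$sequence[order(-agg$weight, agg$sequence)][1]
  }
  call <- data.frame(
    intron_id = intron$intron_id, chrom = intron$chrom,
    strand = intron$strand, subtype = cls$subtype,
    ambiguous = cls$ambiguous, tier = tier,
    hairpin_start = g5, hairpin_end = g3,
    premirna_length = h3 - h5,
    mature_arm = mature_arm,
    n_mature = round_half_up(counts$mature),
    n_star = round_half_up(counts$star),
    n_loop = round_half_up(counts$loop),
    n_ago_ip = round_half_up(counts$ago_ip),
    n_total = round_half_up(counts$total),
    overhang_open_end = duplex$overhang_open_end,
    overhang_dicer_end = duplex$overhang_dicer_end,
    stem_pairs = duplex$stem_pairs,
    dicing_ok = duplex$dicing_ok, dicing_reason = duplex$reason,
    seq_5p = dom_seq("fivep"), seq_3p = dom_seq("threep"),
    stringsAsFactors = FALSE)
  list(call = call, stacks = ext$buckets)
}

errored_call <- function(intron, msg) {
  data.frame(intron_id = intron$intron_id, chrom = intron$chrom,
             strand = intron$strand, subtype = NA_character_,
             ambiguous = NA, tier = "errored",
             hairpin_start = NA_integer_, hairpin_end = NA_integer_,
             premirna_length = NA_integer_, mature_arm = NA_character_,
             n_mature = NA_real_, n_star = NA_real_, n_loop = NA_real_,
             n_ago_ip = NA_real_, n_total = NA_real_,
             overhang_open_end = NA_integer_,
             overhang_dicer_end = NA_integer_, stem_pairs = NA_integer_,
             dicing_ok = FALSE, dicing_reason = paste0("error: ", msg),
             seq_5p = NA_character_, seq_3p = NA_character_,
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  errored_call(data.frame(intron_id = "x", chrom = "x", strand = "+"),
               "")[0, ]
}
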