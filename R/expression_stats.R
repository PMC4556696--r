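# Expression normalization, mirtron-host correlation with shuffled-label
# confidence envelopes, expression breadth, and Ago-IP enrichment.

#' Normalize raw counts to RPMM / RPKM / RPM
#'
#' RPMM = reads per million mapped miRNA reads; RPM = reads per million
#' mapped reads; RPKM additionally divides by feature length in kb.
#' value = count / denominator * 1e6 (/ length_kb for RPKM).
#'
#' @param counts loci x samples matrix of non-negative counts.
#' @param mode "RPMM", "RPKM" or "RPM".
#' @param denominators per-sample totals (mapped miRNA reads for RPMM,
#'   mapped reads otherwise); a zero denominator yields an all-zero column
#'   with a warning.
#' @param length_kb per-locus feature length in kb (RPKM only).
#' @return matrix with a `unit` attribute.
#' @export
normalize_expression <- function(counts, mode = c("RPMM", "RPKM", "RPM"),
                                 denominators, length_kb = NULL) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (length(denominators) != ncol(counts))
    stop("one denominator per sample required")
  zero <- denominators == 0
  if (any(zero)) {
    warning("zero denominator for sample(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    denominators[zero] <- 1
    counts[, zero] <- 0
  }
  out <- sweep(counts, 2, denominators, "/") * 1e6
  if (mode == "RPKM") {
    if (is.null(length_kb) || length(length_kb) != nrow(counts))
      stop("RPKM requires one length_kb per locus")
    out <- sweep(out, 1, length_kb, "/")
  }
  attr(out, "unit") <- mode
  out
}

#' Per-locus Pearson correlation between mirtron and host expression
#'
#' Matrices must share loci (rows) and tissue columns in matched order.
#' Pairs with zero variance in either vector are dropped with a flag.
#'
#' @param mirtron_expr,host_expr loci x tissues matrices.
#' @return data.frame (locus, r); attribute `n_dropped_zero_variance`.
#' @export
host_correlations <- function(mirtron_expr, host_expr) {
  if (!identical(dim(mirtron_expr), dim(host_expr)))
    stop("matrices must have identical dimensions")
  if (ncol(mirtron_expr) < 3L) stop("need >= 3 shared tissues")
  v1 <- apply(mirtron_expr, 1, stats::var)
  v2 <- apply(host_expr, 1, stats::var)
  flat <- v1 == 0 | v2 == 0
  keep <- which(!flat)
  r <- vapply(keep, function(i)
    stats::cor(mirtron_expr[i, ], host_expr[i, ]), 1)
  out <- data.frame(locus = if (!is.null(rownames(mirtron_expr)))
    rownames(mirtron_expr)[keep] else as.character(keep),
    r = r, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped_zero_variance") <- sum(flat)
  out
}

#' Shuffled-tissue-label confidence envelope for correlation CDFs
#'
#' The host matrix's tissue labels are permuted (one permutation per
#' shuffle, the mirtron matrix untouched, so the mirtron marginal is
#' preserved) and correlations recomputed.  The envelope is simultaneous
#' over the whole CDF curve: each shuffled curve's sup-deviation from the
#' mean shuffled curve is computed, the `alpha` quantile of those
#' deviations sets the half-width, and the band is mean +/- that width
#' (clipped to [0, 1]).  By exchangeability a null curve exits such a band
#' with probability about 1 - `alpha`, which a pointwise band over the
#' same shuffles does not achieve.  The observed correlation median is
#' tested against zero with a two-tailed one-sample Wilcoxon test.
#'
#' @param mirtron_expr,host_expr loci x tissues matrices (>= 3 tissues).
#' @param n_shuffles number of label shuffles (default 100).
#' @param alpha envelope coverage (default 0.99).
#' @param seed RNG seed.
#' @param grid correlation grid the CDFs are evaluated on.
#' @return list of class `correlation_envelope`: observed_r, grid,
#'   observed_cdf, env_lo, env_hi (NULL when `n_shuffles` = 0), median_p,
#'   n_shuffles.
#' @export
shuffle_envelope <- function(mirtron_expr, host_expr, n_shuffles = 100L,
                             alpha = 0.99, seed = 1L,
                             grid = seq(-1, 1, by = 0.02)) {
  obs <- host_correlations(mirtron_expr, host_expr)$r
  k <- ncol(host_expr)
  if (k < 3L) stop("need >= 3 tissues")
  cdf_on <- function(r) vapply(grid, function(g) mean(r <= g), 1)
  env_lo <- env_hi <- NULL
  if (n_shuffles > 0L) {
    shuf <- with_substream(seed, 0L, {
      vapply(seq_len(n_shuffles), function(s) {
        perm <- sample.int(k)
        cdf_on(host_correlations(mirtron_expr,
                                 host_expr[, perm, drop = FALSE])$r)
      }, numeric(length(grid)))
    })
    center <- rowMeans(shuf)
    dev <- apply(abs(shuf - center), 2, max)   # sup-deviation per curve
    width <- stats::quantile(dev, probs = alpha, names = FALSE)
    env_lo <- pmax(center - width, 0)
    env_hi <- pmin(center + width, 1)
  }
  median_p <- suppressWarnings(
    stats::wilcox.test(obs, mu = 0, alternative = "two.sided")$p.value)
  structure(list(observed_r = obs, grid = grid, observed_cdf = cdf_on(obs),
                 env_lo = env_lo, env_hi = env_hi, median_p = median_p,
                 n_shuffles = n_shuffles),
            class = "correlation_envelope")
}

#' Expression breadth: samples above an expression cutoff per locus
#'
#' @param expr loci x samples matrix (RPM or comparable units).
#' @param cutoff a locus counts as expressed in a sample iff its value is
#'   strictly greater than this (5 RPM for mirtrons, 20 RPM for canonical
#'   miRNAs in the reference analysis).
#' @param breaks breadth bin lower edges (the reference bins are 1, 2-5,
#'   6-10, 11-20, 21-99, >= 100; breadth 0 is its own bin).
#' @return data.frame (locus, breadth, bin).
#' @export
expression_breadth <- function(expr, cutoff = 5,
                               breaks = c(1, 2, 6, 11, 21, 100)) {
  breadth <- rowSums(as.matrix(expr) > cutoff)
  edges <- c(0, breaks, Inf)
  labs <- c("0", vapply(seq_along(breaks), function(i) {
    hi <- if (i < length(breaks)) breaks[i + 1] - 1 else Inf
    if (breaks[i] == hi) as.character(breaks[i])
    else if (is.infinite(hi)) paste0(">=", breaks[i])
    else paste0(breaks[i], "-", hi)
  }, ""))
  bin <- cut(breadth, breaks = edges, labels = labs, right = FALSE)
  data.frame(locus = if (!is.null(rownames(expr))) rownames(expr) else
    as.character(seq_len(nrow(expr))),
    breadth = breadth, bin = as.character(bin),
    stringsAsFactors = FALSE)
}

#' Ago-IP enrichment analysis
#'
#' Replicate libraries within a group are combined (mean RPM); loci with
#' zero reads across every group are excluded and counted; values are
#' transformed log2(RPM + offset) so zero-read loci plot on the log scale;
#' all pairwise two-sample t-tests on the transformed values are reported
#' with Holm-adjusted p-values.
#'
#' @param locus_rpm loci x libraries matrix of RPM values.
#' @param group_map named character vector library_id -> group.
#' @param offset pseudo-RPM added before log2 (default 0.1).
#' @return list of class `enrichment_result`: transformed (loci x groups
#'   matrix of log2(RPM + offset)), group_rpm, cdfs (per-group sorted
#'   transformed values), tests (group1, group2, p_raw, p_holm),
#'   n_excluded_allzero.
#' @export
ago_enrichment <- function(locus_rpm, group_map, offset = 0.1) {
  locus_rpm <- as.matrix(locus_rpm)
  if (!all(colnames(locus_rpm) %in% names(group_map)))
    stop("group_map must cover every library")
  groups <- group_map[colnames(locus_rpm)]
  glev <- unique(unname(groups))
  if (any(!glev %in% groups)) stop("group with zero libraries")
  grp <- vapply(glev, function(g)
    rowMeans(locus_rpm[, groups == g, drop = FALSE]), numeric(nrow(locus_rpm)))
  colnames(grp) <- glev
  allzero <- rowSums(grp) == 0
  grp <- grp[!allzero, , drop = FALSE]
  transformed <- log2(grp + offset)
  tests <- NULL
  if (length(glev) >= 2L && nrow(transformed) >= 2L) {
    pairs <- utils::combn(glev, 2)
    # Welch test; a pair where both groups are essentially constant (e.g.
    # every locus at the zero-read offset in a control IP) has no defined
    # statistic and reports NA rather than aborting the comparison set
    p_raw <- apply(pairs, 2, function(pr)
      tryCatch(stats::t.test(transformed[, pr[1]],
                             transformed[, pr[2]])$p.value,
               error = function(e) NA_real_))
    tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        p_raw = p_raw,
                        p_holm = stats::p.adjust(p_raw, method = "holm"),
                        stringsAsFactors = FALSE)
  }
  structure(list(transformed = transformed, group_rpm = grp,
                 cdfs = lapply(setNames(glev, glev),
                               function(g) sort(transformed[, g])),
                 tests = tests,
                 n_excluded_allzero = sum(allzero)),
            class = "enrichment_result")
}
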