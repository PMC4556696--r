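# End-to-end orchestration over simulated or on-disk inputs.

#' Run the full pipeline on a simulated data set
#'
#' simulate -> map/annotate -> terminal analysis -> locus features ->
#' expression statistics, returning a report bundle.  Deterministic under
#' a fixed `sim_config` seed: every stage draws from its own substream of
#' the master seed.
#'
#' @param config a [sim_config()].
#' @param manifest library manifest (default [sim_manifest()]).
#' @param tissues tissues for the expression simulation.
#' @param criteria an [annotation_criteria()].
#' @param outdir optional directory; when given, inputs and all result
#'   tables are written there.
#' @return list of class `pipeline_report`: truth, calls, tier_table
#'   (subtype x tier counts), recovery (planted-vs-called confusion),
#'   tails (pooled tail-category table), xu (per-locus xU table),
#'   length_stats, correlation (envelope object), enrichment, stacks.
#' @export
run_pipeline <- function(config = sim_config(),
                         manifest = sim_manifest(),
                         tissues = c("brain", "heart", "kidney", "liver",
                                     "lung", "muscle", "spleen"),
                         criteria = annotation_criteria(),
                         outdir = NULL) {
  truth <- build_truth(config)
  sim <- simulate_reads(truth, manifest, config)
  expr <- simulate_expression(truth, tissues, config)

  calls <- annotate_mirtrons(truth$genome, truth$introns, sim$batches,
                             manifest, criteria)
  stacks <- attr(calls, "stacks")
  report <- summarize_run(truth, calls, stacks, expr, config)
  report$config <- config
  if (!is.null(outdir)) {
    write_simulation(truth, sim, manifest, outdir, expr)
    write_table(calls, file.path(outdir, "calls.tsv"), key = "intron_id")
    write_table(report$tier_table, file.path(outdir, "report_tiers.tsv"))
    write_table(report$tails, file.path(outdir, "report_tails.tsv"))
    write_table(report$xu, file.path(outdir, "report_xu.tsv"))
    write_table(report$length_stats, file.path(outdir, "report_lengths.tsv"))
  }
  report
}

summarize_run <- function(truth, calls, stacks, expr, config) {
  planted <- truth$planted
  mir <- planted[planted$class != "canonical", , drop = FALSE]
  called <- calls[calls$tier %in% c("confident_duplex", "confident_agoip",
                                    "rescue_a", "rescue_b"), , drop = FALSE]
  tp <- intersect(called$intron_id, mir$locus_id)
  recovery <- data.frame(
    n_planted = nrow(mir), n_called = nrow(called), n_true_positive = length(tp),
    precision = if (nrow(called)) length(tp) / nrow(called) else NA_real_,
    recall = if (nrow(mir)) length(tp) / nrow(mir) else NA_real_,
    subtype_accuracy = if (length(tp)) {
      mean(calls$subtype[match(tp, calls$intron_id)] ==
             mir$class[match(tp, mir$locus_id)])
    } else NA_real_)
  tier_table <- as.data.frame(table(subtype = calls$subtype,
                                    tier = calls$tier),
                              stringsAsFactors = FALSE)
  names(tier_table)[3] <- "count"

  # untemplated tails pooled over splice-defined-3p called loci
  tails <- data.frame(category = character(), fraction = numeric())
  tail_rows <- list()
  for (iid in intersect(names(stacks),
                        calls$intron_id[calls$subtype %in% SPLICE3_CLASSES])) {
    intron <- truth$introns[truth$introns$intron_id == iid, ][1, ]
    s <- stacks[[iid]]
    s <- s[s$bucket == "threep", , drop = FALSE]
    if (nrow(s) == 0L) next
    tail_rows[[iid]] <- call_untemplated_tail(
      s, anchored = TRUE, intron_length = intron$end - intron$start)
  }
  if (length(tail_rows))
    tails <- summarize_tails(do.call(rbind, tail_rows))

  xu_rows <- list()
  for (iid in intersect(names(stacks),
                        calls$intron_id[calls$subtype %in% SPLICE5_CLASSES])) {
    xr <- xu_frequency(stacks[[iid]],
                       calls[calls$intron_id == iid, ][1, ])
    xu_rows[[iid]] <- data.frame(locus = xr$locus,
                                 n_5p_reads = xr$n_5p_reads,
                                 frac_GU = xr$frac_GU, frac_xU = xr$frac_xU,
                                 frac_other = xr$frac_other,
                                 defined = xr$defined,
                                 stringsAsFactors = FALSE)
  }
  xu <- if (length(xu_rows)) do.call(rbind, xu_rows) else
    data.frame(locus = character(), n_5p_reads = numeric(),
               frac_GU = numeric(), frac_xU = numeric(),
               frac_other = numeric(), defined = logical())
  rownames(xu) <- NULL

  length_stats <- premirna_length_stats(
    c(calls$premirna_length,
      planted$hairpin_rel3[planted$class == "canonical"] -
        planted$hairpin_rel5[planted$class == "canonical"]),
    c(calls$subtype, rep("canonical", sum(planted$class == "canonical"))))

  correlation <- shuffle_envelope(expr$mirtron_rpmm, expr$junction_rpm,
                                  n_shuffles = 100L,
                                  seed = config$seed + 77L)
  list(truth = truth, calls = calls, stacks = stacks,
       recovery = recovery, tier_table = tier_table, tails = tails,
       xu = xu, length_stats = length_stats, correlation = correlation)
}
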