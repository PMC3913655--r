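#' End-to-end design evaluation on one synthetic data set
#'
#' Runs the full pipeline (tiling simulation, control-median normalization,
#' windowed-median smoothing, Max400, top-k consensus, peak concordance and
#' TSS profile, expression simulation, quantile normalization, QC,
#' differential expression, set-shift test) against the generator's truth
#' and reports recovery metrics. Intended for power/design analysis of the
#' study layout and used by the package's acceptance checks.
#'
#' @param config a [sim_config()].
#' @param k per-replicate top-k size; the default ties the list size to
#'   twice the number of seeded bound promoters.
#' @param m consensus support threshold.
#' @param top_n size of the down-regulated list used for knockdown recovery.
#' @return list with `recall` and `precision` of the consensus against the
#'   bound truth set, `modal_offset` (centre of the modal TSS-profile bin of
#'   the true-positive calls), `shift_direction` and `shift_p` (set-shift
#'   test of the consensus set on the silencing log-ratios),
#'   `top_down_recovery` (fraction of bound genes in the top `top_n` down
#'   list), and `n_members`.
#' @export
end_to_end_metrics <- function(config, k = 2 * config$n_bound, m = 2,
                               top_n = 200) {
  sim <- simulate_tiling_arrays(config)
  res <- chip_score_pipeline(sim$promoters, sim$probes, sim$replicates,
                             k = k, m = m)
  recall <- mean(sim$bound %in% res$members)
  precision <- mean(res$members %in% sim$bound)

  loc <- peak_locations(res$max_tables)
  tp <- intersect(res$members, sim$bound)
  calls <- concordant_peaks(loc[loc$promoter_id %in% tp, , drop = FALSE],
                            sim$promoters)
  prof <- tss_profile(calls, sim$promoters)
  modal <- prof$offset[which.max(prof$count)]

  ex <- simulate_expression(config, sim$bound)
  em <- quantile_normalize(ex$em)
  qc <- qc_correlations(em)
  keep <- c(qc$kept, names(em$arms)[em$arms == "control"])
  de <- differential_expression(em, samples = keep)
  lr <- setNames(de$log_ratio, de$gene_id)
  shift <- set_shift_test(lr, res$members)
  down <- top_n_lists(de, top_n)$down

  list(recall = recall, precision = precision, modal_offset = modal,
       shift_direction = shift$direction, shift_p = shift$p_value,
       top_down_recovery = mean(sim$bound %in% down),
       n_members = length(res$members))
}
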