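#' Run the full synthetic editome study end to end
#'
#' Simulates the four-genotype study at the default desk-scale conditions
#' (miniature genome, planted truth, per-sample pileups and expression
#' counts), then runs the analysis pipeline: per-sample edit calling with
#' exome-SNP exclusion and strand orientation, per-genotype all-replicates
#' consensus editomes with feature/repeat attribution, the four-set Venn
#' comparison, the DEG/ISG expression summary for the double-het vs WT
#' contrast, and the exact test for ISG enrichment among uniquely edited
#' sites (double het vs WT).
#'
#' @param seed integer seed driving every stage.
#' @param genome an `editome_genome`; defaults to [sim_genome()] at default
#'   scale.
#' @param model an [edit_model()].
#' @param design a [sample_design()].
#' @param coverage a [coverage_model()].
#' @param error_rate per-base sequencing error rate.
#' @param thresholds an [edit_thresholds()].
#' @return list with the simulated inputs (`genome`, `truth`, `design`,
#'   `counts`) and results (`calls`, `comparison`, `expression`,
#'   `isg_fraction`, `proportion_test`).
#' @export
editome_pipeline <- function(seed,
                             genome = sim_genome(seed = seed),
                             model = edit_model(),
                             design = sample_design(),
                             coverage = coverage_model(),
                             error_rate = 0.003,
                             thresholds = edit_thresholds()) {
  truth <- plant_truth(genome, model, seed = seed)
  pileups <- sim_pileups(genome, truth, design, coverage, error_rate,
                         seed = seed)
  counts <- sim_expression(genome, design, truth, seed = seed)
  index <- feature_index(genome)

  calls <- lapply(names(pileups), function(sid) {
    x <- call_edit_sites(pileups[[sid]], genome, thresholds, sample_id = sid)
    x <- exclude_snps(x, truth$snps)
    orient_edits(x, genome)
  })
  names(calls) <- names(pileups)

  comparison <- compare_editomes(calls, design, index)

  isg_genes <- genome$genes$gene_id[genome$genes$is_isg]
  expr <- expression_summary(counts, design, isg_genes)
  isg_fraction <- classify_isg_fraction(expr$gene[expr$is_deg], isg_genes,
                                        universe = expr$gene)
  isg_map <- setNames(genome$genes$is_isg, genome$genes$gene_id)
  prop_test <- isg_proportion_test(
    comparison$unique_sites[["RdRp_Adar_het"]],
    comparison$unique_sites[["WT"]],
    isg_map, labels = c("RdRp_Adar_het", "WT"))

  list(genome = genome, truth = truth, design = design, counts = counts,
       calls = calls, comparison = comparison, expression = expr,
       isg_fraction = isg_fraction, proportion_test = prop_test)
}
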