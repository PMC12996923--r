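#' Run the full analysis pipeline on a simulated design
#'
#' One-command end-to-end run: sample QC -> probe filtering -> quantile
#' normalisation -> variable-probe selection -> reference-based cell-type
#' deconvolution (the estimated neuronal proportion, not the simulation
#' truth, is threaded into the models, so covariate-estimation error
#' propagates as it would on real data) -> pseudo-age scoring -> probe-level
#' differential models with interaction tests -> Bonferroni DMP calls ->
#' gene-level aggregation -> DMR calling and annotation -> gene-set
#' enrichment. Returns all stage outputs plus a recovery report against the
#' planted truth. Deterministic under the design seed.
#'
#' @param design A [simulation_design()] (its `seed` drives every stage).
#' @param n_tests Bonferroni denominator override for DMP calling
#'   (default: number of variable probes tested).
#' @param use_true_proportions Thread the simulation's true neuronal
#'   proportions into the models instead of the deconvolution estimates
#'   (ablation switch, default FALSE).
#' @param reference_n_per_type,reference_within_sd Reference-panel
#'   simulation parameters.
#' @return List of class `methdev_run`; see `$report` for the stage counts
#'   and recovery metrics, and the named elements for each stage's output.
#' @export
run_pipeline <- function(design = simulation_design(), n_tests = NULL,
                         use_true_proportions = FALSE,
                         reference_n_per_type = 25,
                         reference_within_sd = 0.05) {
  sim <- simulate_dataset(design)

  ## sample QC
  sqc <- apply_sample_qc(sim$sample_qc)
  keep_samples <- sqc$sample_id[sqc$pass]
  beta <- beta_matrix(unclass(sim$beta)[, keep_samples, drop = FALSE],
                      rownames(sim$beta), keep_samples)
  samples <- sim$samples[sim$samples$sample_id %in% keep_samples, ]

  ## probe QC + normalisation + variable probes
  fp <- filter_probes(beta, sim$manifest, sim$detection_fail_counts)
  norm <- quantile_normalize(fp$beta)
  vp <- select_variable_probes(norm)
  variable_ids <- vp$probe_id[vp$is_variable]

  ## deconvolution on a simulated reference panel
  truth_ref <- reference_truth(sim$truth$m_neuron, sim$truth$m_glia,
                               probe_ids = sim$manifest$probe_id,
                               n_per_type = reference_n_per_type,
                               within_sd = reference_within_sd)
  ref <- simulate_reference_panel(truth_ref, seed = design$seed + 1000L)
  panel <- train_reference(ref$beta, ref$labels, sim$manifest)
  decon <- project_proportions(norm, panel)
  samples <- dplyr::left_join(samples,
                              dplyr::select(decon, "sample_id",
                                            "neuronal_prop", "error_score"),
                              by = "sample_id")
  if (use_true_proportions) {
    samples$neuronal_prop <- sim$truth$neuronal_prop$neuronal_prop[
      match(samples$sample_id, sim$truth$neuronal_prop$sample_id)]
  }

  ## pseudo-age
  scores <- score_samples(norm, sim$clock)
  samples <- dplyr::left_join(samples, scores, by = "sample_id")
  age_geno <- test_age_genotype_effects(scores, samples)

  ## differential models on variable probes
  vb <- beta_matrix(unclass(norm)[variable_ids, , drop = FALSE],
                    variable_ids, colnames(norm))
  probe_results <- fit_probe_models(vb, samples)
  probe_results <- bonferroni_dmps(probe_results,
                                   n_tests = n_tests %||% nrow(probe_results))

  ## gene aggregation
  gene_results <- aggregate_by_gene(probe_results, vb, sim$manifest)

  ## DMRs
  dmrs <- call_dmrs(probe_results, sim$manifest, vb)
  dmrs <- annotate_dmrs(dmrs, gene_bodies_from_manifest(sim$manifest))

  ## enrichment
  planted_genes <- manifest_gene_map(sim$manifest) |>
    dplyr::filter(.data$probe_id %in% sim$truth$dmps$probe_id) |>
    dplyr::pull("gene") |> unique()
  gene_sets <- simulate_gene_sets(sim$manifest, planted_genes,
                                  seed = design$seed + 2000L)
  universe <- build_gene_universe(gene_results, sim$manifest, variable_ids,
                                  gene_biotypes = sim$gene_table)
  enrichment <- term_enrichment(universe, gene_sets)

  report <- pipeline_report(sim, sqc, fp, vp, probe_results, gene_results,
                            dmrs, enrichment, scores, samples)
  structure(list(
    sim = sim, sample_qc = sqc, probe_status = fp$status, beta = norm,
    variable_probes = vp, panel = panel, deconvolution = decon,
    samples = samples, pseudo_age = scores, age_genotype = age_geno,
    probe_results = probe_results, gene_results = gene_results,
    dmrs = dmrs, gene_sets = gene_sets, universe = universe,
    enrichment = enrichment, report = report
  ), class = "methdev_run")
}

# stage counts and planted-truth recovery metrics
pipeline_report <- function(sim, sqc, fp, vp, probe_results, gene_results,
                            dmrs, enrichment, scores, samples) {
  truth <- sim$truth
  planted <- truth$dmps
  called <- probe_results$probe_id[probe_results$is_dmp]
  iso <- planted$probe_id[planted$isolated]
  tested_iso <- intersect(iso, probe_results$probe_id)
  sens <- if (length(tested_iso)) mean(tested_iso %in% called) else NA_real_
  fdr <- if (length(called)) mean(!(called %in% planted$probe_id)) else 0
  est <- probe_results$beta_genotype[match(planted$probe_id,
                                           probe_results$probe_id)]
  rmse <- sqrt(mean((est - planted$delta)^2, na.rm = TRUE))
  ## per-block best-match probe Jaccard
  jac <- if (nrow(truth$dmr_blocks)) {
    called_sets <- strsplit(dmrs$probe_ids[dmrs$adjusted_p < 0.05], ";")
    vapply(strsplit(truth$dmr_blocks$probe_ids, ";"), function(bp) {
      if (!length(called_sets)) return(0)
      max(vapply(called_sets, function(cs)
        length(intersect(bp, cs)) / length(union(bp, cs)), numeric(1)))
    }, numeric(1))
  } else numeric()
  sig_dmrs <- dmrs[dmrs$adjusted_p < 0.05, ]
  false_dmrs <- if (nrow(sig_dmrs)) {
    sum(!vapply(strsplit(sig_dmrs$probe_ids, ";"), function(cs)
      any(cs %in% planted$probe_id), logical(1)))
  } else 0L
  age_cor <- stats::cor(samples$pseudo_age, samples$age_days)
  tibble::tibble(
    metric = c("n_samples_pass_qc", "n_probes_retained", "n_variable_probes",
               "n_dmps", "n_dmps_hypo", "n_dmps_hyper",
               "n_genes_significant", "n_dmrs_candidate", "n_dmrs_significant",
               "n_terms_enriched", "clip_frac",
               "dmp_sensitivity", "dmp_fdr", "effect_rmse",
               "dmr_block_jaccard", "false_dmrs", "pseudoage_age_cor"),
    value = c(sum(sqc$pass), sum(fp$status$removed_reason == "none"),
              sum(vp$is_variable),
              sum(probe_results$is_dmp),
              sum(probe_results$dmp_direction == "hypo", na.rm = TRUE),
              sum(probe_results$dmp_direction == "hyper", na.rm = TRUE),
              sum(gene_results$adjusted_p < 0.05),
              nrow(dmrs), nrow(sig_dmrs),
              sum(enrichment$p_bonferroni < 0.05),
              truth$clip_frac,
              sens, fdr, rmse,
              if (length(jac)) mean(jac) else NA_real_,
              false_dmrs, age_cor)
  )
}

#' @export
print.methdev_run <- function(x, ...) {
  cat("methdev pipeline run\n")
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-22s %s\n", r$metric[i], format(r$value[i], digits = 4)))
  }
  invisible(x)
}
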