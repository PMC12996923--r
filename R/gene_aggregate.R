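#' Aggregate probe-level P values to gene-level statistics
#'
#' Groups tested probes by their annotated gene(s) (a probe annotated to
#' several genes contributes to each) and combines each gene's raw genotype
#' P values with the Empirical Brown's method, estimating the dependence
#' between probes from their normalised beta rows. Gene-level P values are
#' Bonferroni-adjusted over the number of genes with at least one
#' contributing probe. `mode = "promoter_only"` restricts annotation to
#' probes in promoter regions (secondary analysis).
#'
#' @param probe_results Tibble from [fit_probe_models()] (needs `probe_id`,
#'   `p_genotype`).
#' @param beta The `beta_matrix` the models were fitted on (dependence
#'   source).
#' @param manifest Probe manifest carrying gene annotations.
#' @param mode `"all_sites"` (default) or `"promoter_only"`.
#' @return Tibble `gene`, `n_probes`, `combined_p`, `adjusted_p`,
#'   `annotation_mode`, sorted by `combined_p`.
#' @export
aggregate_by_gene <- function(probe_results, beta, manifest,
                              mode = c("all_sites", "promoter_only")) {
  mode <- match.arg(mode)
  gm <- manifest_gene_map(manifest,
                          feature_filter = if (mode == "promoter_only")
                            "promoter" else NULL)
  d <- dplyr::inner_join(
    dplyr::select(probe_results, "probe_id", "p_genotype"), gm,
    by = "probe_id", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$probe_id %in% rownames(beta))
  if (nrow(d) == 0) {
    return(tibble::tibble(gene = character(), n_probes = integer(),
                          combined_p = numeric(), adjusted_p = numeric(),
                          annotation_mode = character()))
  }
  genes <- split(d, d$gene)
  res <- purrr::map_dfr(genes, function(g) {
    p <- pmax(g$p_genotype, .Machine$double.xmin)
    cp <- brown_combine(p, unclass(beta)[g$probe_id, , drop = FALSE])
    tibble::tibble(gene = g$gene[1], n_probes = nrow(g), combined_p = cp)
  })
  res |>
    dplyr::mutate(adjusted_p = pmin(.data$combined_p * dplyr::n(), 1),
                  annotation_mode = mode) |>
    dplyr::arrange(.data$combined_p)
}
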