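#' Call differentially methylated regions
#'
#' Scans each chromosome in position order over all tested probes. A
#' candidate region is a maximal run of two or more qualifying probes —
#' nominally significant genotype effect (raw P < `nominal_p`) with a
#' common direction — in which every adjacent pair is spaced strictly less
#' than `gap_bp` apart. By default an intervening tested probe that fails
#' to qualify (P >= `nominal_p`, opposite sign, or zero effect) terminates
#' the run; `skip_nonsignificant = TRUE` gives the permissive reading in
#' which such probes are ignored (their positions still count toward the
#' gap). Member P values are combined per region with the Empirical Brown's
#' method and adjusted by Bonferroni over the number of candidate regions
#' found genome-wide.
#'
#' @param probe_results Tibble from [fit_probe_models()] for tested probes.
#' @param manifest Probe manifest (positions; sorted internally if needed).
#' @param beta The `beta_matrix` used for model fitting (Brown dependence).
#' @param gap_bp Maximum inter-probe spacing within a region (strict <).
#' @param nominal_p Qualification threshold for member probes (strict <).
#' @param skip_nonsignificant Permissive run rule (see above).
#' @return Tibble, one row per candidate region: `chrom`, `start`, `end`
#'   (outermost member-probe positions, 1-based inclusive), `n_probes`,
#'   `probe_ids` (";"-joined, position order), `direction` ("hypo"/"hyper"),
#'   `combined_p`, `adjusted_p`.
#' @export
call_dmrs <- function(probe_results, manifest, beta, gap_bp = 1500,
                      nominal_p = 0.05, skip_nonsignificant = FALSE) {
  manifest <- validate_manifest(manifest)
  d <- dplyr::inner_join(
    dplyr::select(probe_results, "probe_id", "p_genotype", "direction"),
    dplyr::select(manifest, "probe_id", "chrom", "pos"),
    by = "probe_id"
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  d$qual <- d$p_genotype < nominal_p & d$direction != 0

  runs <- list()
  for (ch in unique(d$chrom)) {
    x <- d[d$chrom == ch, ]
    cur <- integer()
    flush <- function(cur) if (length(cur) >= 2) runs[[length(runs) + 1]] <<- x[cur, ]
    prev_i <- NA_integer_
    for (i in seq_len(nrow(x))) {
      if (!x$qual[i]) {
        if (!skip_nonsignificant) { flush(cur); cur <- integer(); prev_i <- NA }
        next
      }
      extend <- length(cur) > 0 &&
        x$direction[i] == x$direction[cur[1]] &&
        !is.na(prev_i) && (x$pos[i] - x$pos[prev_i]) < gap_bp
      if (extend) {
        cur <- c(cur, i)
      } else {
        flush(cur)
        cur <- i
      }
      prev_i <- i
    }
    flush(cur)
  }
  if (length(runs) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          probe_ids = character(), direction = character(),
                          combined_p = numeric(), adjusted_p = numeric()))
  }
  res <- purrr::map_dfr(runs, function(r) {
    p <- pmax(r$p_genotype, .Machine$double.xmin)
    cp <- brown_combine(p, unclass(beta)[r$probe_id, , drop = FALSE])
    tibble::tibble(
      chrom = r$chrom[1], start = min(r$pos), end = max(r$pos),
      n_probes = nrow(r),
      probe_ids = paste(r$probe_id, collapse = ";"),
      direction = if (r$direction[1] < 0) "hypo" else "hyper",
      combined_p = cp
    )
  })
  res$adjusted_p <- pmin(res$combined_p * nrow(res), 1)
  dplyr::arrange(res, .data$combined_p)
}

#' Annotate regions to genes by gene-body overlap
#'
#' A region is annotated to every gene whose body, expanded by `flank_bp`
#' (default 1500) on each side, overlaps the region interval
#' (closed-interval overlap on 1-based coordinates). Nested genes (e.g. a
#' snoRNA inside a host gene) each receive the annotation.
#'
#' @param dmrs Region tibble from [call_dmrs()] (`chrom`, `start`, `end`).
#' @param gene_models Tibble of gene bodies: `chrom`, `start`, `end`,
#'   `gene` (1-based closed intervals).
#' @param flank_bp Expansion applied to each gene body.
#' @return `dmrs` with an added `genes` column (";"-joined symbols, `NA`
#'   when none overlap).
#' @export
annotate_dmrs <- function(dmrs, gene_models, flank_bp = 1500) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(gene_models)))
  if (nrow(dmrs) == 0) return(dplyr::mutate(dmrs, genes = character()))
  ann <- vapply(seq_len(nrow(dmrs)), function(i) {
    g <- gene_models[gene_models$chrom == dmrs$chrom[i] &
                       gene_models$start - flank_bp <= dmrs$end[i] &
                       gene_models$end + flank_bp >= dmrs$start[i], ]
    if (nrow(g) == 0) NA_character_ else paste(unique(g$gene), collapse = ";")
  }, character(1))
  dplyr::mutate(dmrs, genes = ann)
}

#' Derive gene-body intervals from a probe manifest
#'
#' Convenience for simulated data: a gene's body spans the outermost
#' positions of the probes annotated to it.
#'
#' @param manifest Probe manifest.
#' @return Tibble `chrom`, `start`, `end`, `gene` (1-based closed).
#' @export
gene_bodies_from_manifest <- function(manifest) {
  manifest <- validate_manifest(manifest)
  manifest_gene_map(manifest) |>
    dplyr::inner_join(dplyr::select(manifest, "probe_id", "chrom", "pos"),
                      by = "probe_id") |>
    dplyr::group_by(.data$gene, .data$chrom) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "gene")
}
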