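#' Sample-level quality control
#'
#' Applies the study's sample gates to precomputed signal summaries: median
#' methylated and unmethylated intensities must both reach
#' `min_median_intensity` (default 2000 a.u.), at most
#' `max_detection_fail_frac` (default 1%) of probes may fail the detection P
#' threshold, and bisulfite conversion must be at least `min_bisulfite_pct`
#' (default 90%, inclusive).
#'
#' @param summaries Tibble with `sample_id`, `median_meth_intensity`,
#'   `median_unmeth_intensity`, `frac_probes_failing_detection`,
#'   `bisulfite_conversion_pct`.
#' @param min_median_intensity,max_detection_fail_frac,min_bisulfite_pct
#'   Thresholds (see above).
#' @return Tibble `sample_id`, `pass`, `failed_criterion` (`NA` when
#'   passing; first failed gate otherwise).
#' @export
apply_sample_qc <- function(summaries,
                            min_median_intensity = 2000,
                            max_detection_fail_frac = 0.01,
                            min_bisulfite_pct = 90) {
  stopifnot(all(c("sample_id", "median_meth_intensity",
                  "median_unmeth_intensity",
                  "frac_probes_failing_detection",
                  "bisulfite_conversion_pct") %in% names(summaries)))
  tibble::as_tibble(summaries) |>
    dplyr::mutate(
      failed_criterion = dplyr::case_when(
        .data$median_meth_intensity < min_median_intensity |
          .data$median_unmeth_intensity < min_median_intensity ~ "intensity",
        .data$frac_probes_failing_detection > max_detection_fail_frac ~
          "detection",
        .data$bisulfite_conversion_pct < min_bisulfite_pct ~ "conversion",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$failed_criterion)
    ) |>
    dplyr::select("sample_id", "pass", "failed_criterion")
}

#' Probe-level filtering
#'
#' Removes probes flagged in the manifest as technically variable, probes
#' with a manufacturer change flag, probes mapped to chromosome "0", and
#' probes failing detection in more than `max_fail_samples` samples
#' (default 1, i.e. a single failing sample is tolerated). Each removed
#' probe gets exactly one removal reason, applied in that priority order.
#'
#' @param beta A `beta_matrix`.
#' @param manifest Probe manifest.
#' @param detection_fail_counts Named integer vector (per probe id) of
#'   samples failing detection; probes absent are treated as 0.
#' @param max_fail_samples Tolerated failing samples per probe.
#' @return List with `beta` (filtered matrix) and `status` (tibble
#'   `probe_id`, `removed_reason` in
#'   flagged_manifest/mfg_change_flagged/chrom0/detection_fail/none).
#' @export
filter_probes <- function(beta, manifest, detection_fail_counts = NULL,
                          max_fail_samples = 1) {
  manifest <- validate_manifest(manifest)
  m <- manifest[match(rownames(beta), manifest$probe_id), ]
  if (anyNA(m$probe_id)) stop("beta contains probes absent from manifest",
                              call. = FALSE)
  fails <- numeric(nrow(beta))
  if (!is.null(detection_fail_counts)) {
    hit <- intersect(names(detection_fail_counts), rownames(beta))
    fails[match(hit, rownames(beta))] <- detection_fail_counts[hit]
  }
  reason <- dplyr::case_when(
    m$flagged ~ "flagged_manifest",
    m$mfg_change_flagged ~ "mfg_change_flagged",
    m$chrom == "0" ~ "chrom0",
    fails > max_fail_samples ~ "detection_fail",
    TRUE ~ "none"
  )
  status <- tibble::tibble(probe_id = rownames(beta), removed_reason = reason)
  keep <- reason == "none"
  list(beta = beta_matrix(unclass(beta)[keep, , drop = FALSE],
                          rownames(beta)[keep], colnames(beta),
                          allow_missing = TRUE),
       status = status)
}

#' Quantile normalisation of a beta matrix
#'
#' Forces every sample onto the common reference distribution given by the
#' across-sample mean of sorted values; ties share the average rank. A
#' single-sample matrix is returned unchanged with a warning. Backed by
#' `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param beta A `beta_matrix` with no missing values.
#' @return Quantile-normalised `beta_matrix`.
#' @export
quantile_normalize <- function(beta) {
  if (anyNA(beta)) stop("quantile normalisation requires complete data",
                        call. = FALSE)
  if (ncol(beta) < 2) {
    warning("single-sample matrix: quantile normalisation is the identity",
            call. = FALSE)
    return(beta)
  }
  out <- limma::normalizeQuantiles(unclass(beta), ties = TRUE)
  beta_matrix(pmin(pmax(out, 0), 1), rownames(beta), colnames(beta))
}

#' Select variable probes
#'
#' A probe is "variable" when its methylation range across the inner 80% of
#' samples exceeds `min_range` (strict), i.e. the linear-interpolation 90th
#' percentile of its sorted betas minus the 10th percentile is > 0.05 by
#' default. Variable probes form the statistical background for the
#' differential and enrichment stages.
#'
#' @param beta A `beta_matrix` (>= 3 samples).
#' @param min_range Strict lower bound on the inner range (beta scale).
#' @param inner_fraction Central mass defining the inner range (0.8 means
#'   quantiles at 0.1 and 0.9).
#' @return Tibble `probe_id`, `inner_range`, `is_variable`.
#' @export
select_variable_probes <- function(beta, min_range = 0.05,
                                   inner_fraction = 0.8) {
  if (ncol(beta) < 3) stop("variable-probe selection needs >= 3 samples",
                           call. = FALSE)
  lo <- (1 - inner_fraction) / 2
  qs <- row_quantiles(unclass(beta), probs = c(lo, 1 - lo))
  rng <- qs[, 2] - qs[, 1]
  tibble::tibble(probe_id = rownames(beta), inner_range = unname(rng),
                 is_variable = unname(rng > min_range))
}

# row-wise type-7 quantiles without extra dependencies
row_quantiles <- function(x, probs) {
  t(apply(x, 1, stats::quantile, probs = probs, type = 7, names = FALSE))
}
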