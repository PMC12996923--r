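#' Fit a methylation age clock
#'
#' For each candidate site, the ordinary least-squares slope of beta on
#' chronological age (in days) is estimated; the slopes are the clock
#' weights used by [score_samples()]. Constant sites get slope 0.
#'
#' @param reference_beta A `beta_matrix` of reference samples.
#' @param ages Numeric vector of ages in days, one per sample (>= 3
#'   distinct values).
#' @param site_ids Candidate sites (default: all rows).
#' @return Tibble `site_id`, `slope` (beta per day).
#' @export
fit_clock <- function(reference_beta, ages, site_ids = rownames(reference_beta)) {
  stopifnot(length(ages) == ncol(reference_beta))
  if (length(unique(ages)) < 3) {
    stop("clock fitting needs >= 3 distinct ages", call. = FALSE)
  }
  x <- unclass(reference_beta)[site_ids, , drop = FALSE]
  a <- ages - mean(ages)
  slopes <- as.numeric(x %*% a) / sum(a^2)
  tibble::tibble(site_id = site_ids, slope = slopes)
}

#' Pseudo-age score per sample
#'
#' The score is the weighted sum over clock sites of slope times beta,
#' score = sum_i s_i * beta_i — a raw weighted sum with no intercept or
#' rescaling, so it is unitless and only its association with age is
#' interpretable. Clock sites absent from the data are dropped with a
#' warning; zero overlapping sites is an error.
#'
#' @param beta A `beta_matrix` of normalised betas.
#' @param clock Tibble `site_id`, `slope` (nominally 105 sites).
#' @return Tibble `sample_id`, `pseudo_age`.
#' @export
score_samples <- function(beta, clock) {
  stopifnot(all(c("site_id", "slope") %in% names(clock)))
  present <- clock$site_id %in% rownames(beta)
  if (!any(present)) stop("no clock sites present in the beta matrix",
                          call. = FALSE)
  if (!all(present)) {
    warning(sprintf("%d clock site(s) absent from data dropped",
                    sum(!present)), call. = FALSE)
  }
  cl <- clock[present, ]
  scores <- as.numeric(crossprod(unclass(beta)[cl$site_id, , drop = FALSE],
                                 cl$slope))
  tibble::tibble(sample_id = colnames(beta), pseudo_age = scores)
}

#' Test age and genotype effects on the pseudo-age score
#'
#' Fits `pseudo_age ~ age_days + genotype` and reports the per-day age
#' slope and the genotype (HET vs WT) effect with two-sided P values.
#'
#' @param scores Tibble `sample_id`, `pseudo_age` from [score_samples()].
#' @param samples Sample sheet with `sample_id`, `genotype`, `age_days`.
#' @return Tibble with one row per term (`age_days`, `genotypeHET`):
#'   `term`, `estimate`, `std_error`, `statistic`, `p_value`.
#' @export
test_age_genotype_effects <- function(scores, samples) {
  samples <- validate_sample_sheet(samples)
  d <- dplyr::inner_join(
    dplyr::select(scores, "sample_id", "pseudo_age"),
    dplyr::select(samples, "sample_id", "genotype", "age_days"),
    by = "sample_id"
  ) |>
    dplyr::mutate(genotype = factor(.data$genotype, levels = c("WT", "HET")))
  if (nrow(d) < 4) stop("insufficient samples for the age/genotype model",
                        call. = FALSE)
  fit <- lm(pseudo_age ~ age_days + genotype, data = d)
  s <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(s)[-1],
    estimate = unname(s[-1, 1]), std_error = unname(s[-1, 2]),
    statistic = unname(s[-1, 3]), p_value = unname(s[-1, 4])
  )
}
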