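#' Probe-level differential methylation models
#'
#' For every probe, fits the ordinary least-squares model
#' `beta ~ genotype + age + chip + neuronal_prop` with genotype coded WT = 0
#' / HET = 1, age categorical with E14.5 as the reference level and chip as
#' a categorical batch covariate, and reports the genotype coefficient
#' (beta-scale shift in HET; negative = hypomethylated in HET), its
#' standard error, two-sided t-test P and direction. A genotype-by-age
#' interaction is tested per probe by a nested-model F test contrasting
#' this additive model with `beta ~ genotype * age + chip + neuronal_prop`
#' (numerator df = number of ages - 1).
#'
#' All probes share one design matrix, so the fits are vectorised through a
#' single QR decomposition. Probes with zero residual variance get P = 1
#' when the genotype coefficient is also zero (no evidence either way), and
#' P ~ 0 when a non-zero effect is fitted exactly.
#'
#' @param beta A `beta_matrix`, typically restricted to variable probes.
#' @param samples Sample sheet with `genotype`, `age_label`, `chip_id` and
#'   `neuronal_prop` for every column of `beta`.
#' @param interaction Also compute the interaction F test (default TRUE).
#' @return Tibble with `probe_id`, `beta_genotype`, `se`, `p_genotype`,
#'   `direction`, and (when requested) `F_interaction`, `p_interaction`,
#'   `df_interaction`.
#' @export
fit_probe_models <- function(beta, samples, interaction = TRUE) {
  samples <- validate_sample_sheet(samples)
  samples <- samples[match(colnames(beta), samples$sample_id), ]
  if (anyNA(samples$sample_id)) {
    stop("every beta column needs a sample-sheet row", call. = FALSE)
  }
  if (!"neuronal_prop" %in% names(samples) || anyNA(samples$neuronal_prop)) {
    stop("samples need a neuronal_prop covariate (run deconvolution first)",
         call. = FALSE)
  }
  d <- dplyr::mutate(samples,
                     genotype = factor(.data$genotype, levels = c("WT", "HET")),
                     age_label = factor(.data$age_label,
                                        levels = names(age_day_map())),
                     chip_id = factor(.data$chip_id))
  d$age_label <- droplevels(d$age_label)
  d$chip_id <- droplevels(d$chip_id)
  X0 <- model.matrix(~ genotype + age_label + chip_id + neuronal_prop, d)
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) {
    aliased <- colnames(X0)[qr0$pivot[(qr0$rank + 1):ncol(X0)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  Y <- t(unclass(beta))                       # samples x probes
  n <- nrow(Y)
  coefs <- qr.coef(qr0, Y)
  res0 <- qr.resid(qr0, Y)
  rss0 <- colSums(res0^2)
  df0 <- n - ncol(X0)
  gi <- which(colnames(X0) == "genotypeHET")
  XtXinv_g <- chol2inv(chol(crossprod(X0)))[gi, gi]
  sigma2 <- rss0 / df0
  se <- sqrt(sigma2 * XtXinv_g)
  b <- coefs[gi, ]
  tiny <- sigma2 < .Machine$double.eps * 100
  tstat <- ifelse(se > 0, b / se, ifelse(abs(b) > 1e-12, Inf, 0))
  p <- 2 * pt(abs(tstat), df0, lower.tail = FALSE)
  p[tiny & abs(b) <= 1e-12] <- 1
  out <- tibble::tibble(
    probe_id = rownames(beta),
    beta_genotype = unname(b), se = unname(se), p_genotype = unname(p),
    direction = ifelse(abs(unname(b)) <= 1e-12, 0, sign(unname(b)))
  )
  if (interaction) {
    X1 <- model.matrix(~ genotype * age_label + chip_id + neuronal_prop, d)
    qr1 <- qr(X1)
    res1 <- qr.resid(qr1, Y)
    rss1 <- colSums(res1^2)
    df1 <- n - qr1$rank
    ddf <- df0 - df1                         # = n_ages - 1
    Fint <- pmax((rss0 - rss1) / ddf, 0) / (rss1 / df1)
    pint <- pf(Fint, ddf, df1, lower.tail = FALSE)
    zero <- rss1 <= .Machine$double.eps * 100 * n
    Fint[zero & (rss0 - rss1) <= 1e-12] <- 0
    pint[Fint == 0] <- 1
    out$F_interaction <- unname(Fint)
    out$p_interaction <- unname(pint)
    out$df_interaction <- ddf
  }
  out
}

#' Genotype-by-age interaction test
#'
#' Convenience wrapper returning only the interaction statistics from
#' [fit_probe_models()].
#'
#' @inheritParams fit_probe_models
#' @return Tibble `probe_id`, `F_interaction`, `p_interaction`,
#'   `df_interaction`.
#' @export
test_interaction <- function(beta, samples) {
  fit_probe_models(beta, samples, interaction = TRUE) |>
    dplyr::select("probe_id", "F_interaction", "p_interaction",
                  "df_interaction")
}

#' Classify differentially methylated positions at a Bonferroni threshold
#'
#' The genome-wide threshold is `alpha / n_tests` and a probe is a DMP iff
#' its genotype P is strictly below it. `n_tests` defaults to the number of
#' probes actually tested; pass the full post-QC site count to reproduce
#' the convention of correcting over all retained sites (e.g. 262,086 sites
#' gives a threshold of 1.91e-7).
#'
#' @param results Probe-result tibble from [fit_probe_models()].
#' @param n_tests Bonferroni denominator (default `nrow(results)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `results` with added `threshold`, `is_dmp` and `dmp_direction`
#'   ("hypo"/"hyper"/NA).
#' @export
bonferroni_dmps <- function(results, n_tests = nrow(results), alpha = 0.05) {
  if (is.na(n_tests) || n_tests < 1) n_tests <- nrow(results)
  thr <- alpha / n_tests
  dplyr::mutate(results,
                threshold = thr,
                is_dmp = .data$p_genotype < thr,
                dmp_direction = dplyr::case_when(
                  .data$is_dmp & .data$direction < 0 ~ "hypo",
                  .data$is_dmp & .data$direction > 0 ~ "hyper",
                  TRUE ~ NA_character_
                ))
}
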