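#' Build the gene universe for enrichment testing
#'
#' The statistical background is the set of genes annotated to at least one
#' variable probe. Each universe gene carries its differential-methylation
#' status, its probe density (number of variable probes annotated, >= 1 by
#' construction) and optionally a biotype.
#'
#' @param gene_results Gene-level tibble from [aggregate_by_gene()].
#' @param manifest Probe manifest.
#' @param variable_probes Character vector of variable probe ids.
#' @param dm_genes Character vector of differentially methylated genes
#'   (default: Bonferroni-significant genes from `gene_results`).
#' @param gene_biotypes Optional tibble `gene`, `biotype`.
#' @param alpha Significance level applied to `adjusted_p` for the default
#'   DM set.
#' @return Tibble `gene`, `is_dm`, `probe_density`, `biotype`.
#' @export
build_gene_universe <- function(gene_results, manifest, variable_probes,
                                dm_genes = NULL, gene_biotypes = NULL,
                                alpha = 0.05) {
  gm <- manifest_gene_map(manifest) |>
    dplyr::filter(.data$probe_id %in% variable_probes)
  uni <- gm |>
    dplyr::count(.data$gene, name = "probe_density")
  if (is.null(dm_genes)) {
    dm_genes <- gene_results$gene[gene_results$adjusted_p < alpha]
  }
  uni <- dplyr::mutate(uni, is_dm = .data$gene %in% dm_genes)
  if (!is.null(gene_biotypes)) {
    uni <- dplyr::left_join(uni, dplyr::select(gene_biotypes, "gene",
                                               "biotype"), by = "gene")
  } else {
    uni$biotype <- NA_character_
  }
  dplyr::select(uni, "gene", "is_dm", "probe_density", "biotype")
}

# logistic fit of is_dm on predictors + log10 probe density over the
# universe; ridge-penalised IRLS refit when separation breaks the MLE
density_adjusted_fit <- function(universe, predictor, covariate_cols = NULL) {
  df <- dplyr::mutate(universe, .log_density = log10(.data$probe_density))
  rhs <- c(predictor, ".log_density", covariate_cols)
  form <- stats::as.formula(paste("is_dm ~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  co <- summary(fit)$coefficients
  row <- rownames(co)[grepl(paste0("^", predictor), rownames(co))][1]
  if (is.na(row) || is.na(coef(fit)[predictor])) {
    ## predictor aliased (e.g. constant over the universe, or perfectly
    ## collinear with a conditioning covariate): no testable effect
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                flagged = TRUE))
  }
  separated <- !fit$converged || is.na(co[row, 2]) || co[row, 2] > 50 ||
    abs(co[row, 1]) > 25
  if (separated) {
    X <- model.matrix(form, df)
    y <- as.numeric(df$is_dm)
    rf <- ridge_logit(X, y, lambda = 1e-3)
    j <- grep(paste0("^", predictor), colnames(X))[1]
    list(estimate = rf$coef[j], se = rf$se[j],
         p = 2 * pnorm(abs(rf$coef[j] / rf$se[j]), lower.tail = FALSE),
         flagged = TRUE)
  } else {
    list(estimate = co[row, 1], se = co[row, 2], p = co[row, 4],
         flagged = FALSE)
  }
}

# small-ridge logistic regression via IRLS (intercept penalised too; the
# penalty only regularises degenerate fits and is documented as such)
ridge_logit <- function(X, y, lambda = 1e-3, maxit = 100) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    g <- crossprod(X, y - mu) - lambda * b
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- as.numeric(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X, X * w) + diag(lambda, ncol(X))
  list(coef = stats::setNames(as.numeric(b), colnames(X)),
       se = sqrt(diag(solve(H))))
}

#' Probe-density-adjusted term enrichment
#'
#' For every gene-set term with at least `min_genes` members in the
#' universe, fits a logistic regression of differential-methylation status
#' on term membership plus log10 probe density over the whole universe and
#' reports the membership coefficient's exponent as the odds ratio with a
#' two-sided Wald P, Bonferroni-adjusted over the tested terms. The raw
#' 2x2-table odds ratio is reported alongside (`unadjusted_or`). Perfect
#' separation triggers a flagged ridge-penalised refit rather than a crash.
#'
#' @param universe Tibble from [build_gene_universe()].
#' @param terms Long gene-set tibble (`term_id`, `term_name`, `gene`).
#' @param min_genes Minimum universe members for a term to be tested.
#' @return Tibble `term_id`, `term_name`, `n_genes`, `odds_ratio`,
#'   `unadjusted_or`, `p`, `p_bonferroni`, `flagged`, sorted by `p`.
#' @export
term_enrichment <- function(universe, terms, min_genes = 10) {
  stopifnot(nrow(universe) > 0)
  terms <- dplyr::filter(terms, .data$gene %in% universe$gene)
  sizes <- dplyr::count(terms, .data$term_id)
  keep <- sizes$term_id[sizes$n >= min_genes]
  terms <- dplyr::filter(terms, .data$term_id %in% keep)
  ids <- unique(terms$term_id)
  res <- purrr::map_dfr(ids, function(tid) {
    members <- terms$gene[terms$term_id == tid]
    u <- dplyr::mutate(universe, in_term = as.numeric(.data$gene %in% members))
    f <- density_adjusted_fit(u, "in_term")
    a <- sum(u$is_dm & u$in_term == 1); b <- sum(u$is_dm & u$in_term == 0)
    cc <- sum(!u$is_dm & u$in_term == 1); dd <- sum(!u$is_dm & u$in_term == 0)
    tibble::tibble(
      term_id = tid,
      term_name = terms$term_name[terms$term_id == tid][1],
      n_genes = length(members),
      odds_ratio = exp(f$estimate),
      unadjusted_or = (a * dd) / (b * cc),
      p = f$p, flagged = f$flagged
    )
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          n_genes = integer(), odds_ratio = numeric(),
                          unadjusted_or = numeric(), p = numeric(),
                          p_bonferroni = numeric(), flagged = logical()))
  }
  res |>
    dplyr::mutate(p_bonferroni = pmin(.data$p * nrow(res), 1)) |>
    dplyr::arrange(.data$p)
}

#' Iterative conditional selection of independent enriched terms
#'
#' Starting from the Bonferroni-significant terms, repeatedly adds the term
#' with the largest marginal odds ratio (ties broken by smaller P, then
#' term id) to the model as a covariate, refits the remaining significant
#' terms conditioning on all previously added terms, and keeps a term in
#' play only while its conditional coefficient stays significant
#' (P < `alpha_conditional`). Returns the ordered retained terms with their
#' conditional statistics.
#'
#' @param results Output of [term_enrichment()].
#' @param universe Tibble from [build_gene_universe()].
#' @param terms Long gene-set tibble.
#' @param alpha Bonferroni significance level for entry (on `p_bonferroni`).
#' @param alpha_conditional Unadjusted threshold for the conditional fits.
#' @return Tibble `term_id`, `order`, `conditional_or`, `conditional_p`,
#'   `conditioned_on` (";"-joined previously retained terms).
#' @export
conditional_term_selection <- function(results, universe, terms,
                                       alpha = 0.05,
                                       alpha_conditional = 0.05) {
  sig <- results |>
    dplyr::filter(.data$p_bonferroni < alpha) |>
    dplyr::arrange(dplyr::desc(.data$odds_ratio), .data$p, .data$term_id)
  if (nrow(sig) == 0) return(tibble::tibble(
    term_id = character(), order = integer(), conditional_or = numeric(),
    conditional_p = numeric(), conditioned_on = character()))
  member_col <- function(tid) as.numeric(
    universe$gene %in% terms$gene[terms$term_id == tid])
  pending <- sig$term_id
  retained <- character()
  out <- list()
  u <- universe
  while (length(pending) > 0) {
    tid <- pending[1]
    pending <- pending[-1]
    covs <- paste0("cov_", seq_along(retained), recycle0 = TRUE)
    for (i in seq_along(retained)) u[[covs[i]]] <- member_col(retained[i])
    u$in_term <- member_col(tid)
    ## drop a term perfectly collinear with an already-retained one
    dup <- length(retained) > 0 &&
      any(vapply(covs, function(cn) all(u[[cn]] == u$in_term), logical(1)))
    if (dup) next
    f <- density_adjusted_fit(u, "in_term",
                              covariate_cols = if (length(covs)) covs)
    if (!is.na(f$p) && f$p < alpha_conditional) {
      retained <- c(retained, tid)
      out[[length(out) + 1]] <- tibble::tibble(
        term_id = tid, order = length(retained),
        conditional_or = exp(f$estimate), conditional_p = f$p,
        conditioned_on = paste(utils::head(retained, -1), collapse = ";")
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Biotype enrichment with optional covariate conditioning
#'
#' Tests whether genes of a given biotype (e.g. snoRNA) are
#' over-represented among differentially methylated genes, using the same
#' probe-density-adjusted logistic model as [term_enrichment()] with the
#' biotype indicator as predictor. `adjust_for` supplies term ids whose
#' membership indicators are added as covariates — the shared-signal
#' adjustment used to ask whether a biotype enrichment survives
#' conditioning on overlapping pathways.
#'
#' @param universe Tibble from [build_gene_universe()] with `biotype`.
#' @param biotype Biotype label to test.
#' @param terms Long gene-set tibble (needed when `adjust_for` is given).
#' @param adjust_for Character vector of term ids to condition on.
#' @return One-row tibble `biotype`, `n_genes`, `odds_ratio`,
#'   `unadjusted_or`, `p`, `conditioned_on`, `flagged`.
#' @export
biotype_enrichment <- function(universe, biotype, terms = NULL,
                               adjust_for = character()) {
  if (!any(universe$biotype %in% biotype)) {
    stop("biotype '", biotype, "' not present in universe", call. = FALSE)
  }
  u <- dplyr::mutate(universe,
                     is_biotype = as.numeric(.data$biotype %in% .env$biotype))
  covs <- character()
  if (length(adjust_for) > 0) {
    stopifnot(!is.null(terms))
    covs <- paste0("cov_", seq_along(adjust_for))
    for (i in seq_along(adjust_for)) {
      u[[covs[i]]] <- as.numeric(
        u$gene %in% terms$gene[terms$term_id == adjust_for[i]])
    }
  }
  f <- density_adjusted_fit(u, "is_biotype",
                            covariate_cols = if (length(covs)) covs)
  a <- sum(u$is_dm & u$is_biotype == 1); b <- sum(u$is_dm & u$is_biotype == 0)
  cc <- sum(!u$is_dm & u$is_biotype == 1); dd <- sum(!u$is_dm & u$is_biotype == 0)
  tibble::tibble(biotype = biotype, n_genes = sum(u$is_biotype),
                 odds_ratio = exp(f$estimate),
                 unadjusted_or = (a * dd) / (b * cc), p = f$p,
                 conditioned_on = paste(adjust_for, collapse = ";"),
                 flagged = f$flagged)
}

#' Fisher's exact overlap test between two item sets
#'
#' Builds the 2x2 table of membership in `set_a` by membership in `set_b`
#' over `background` and runs a two-sided Fisher's exact test, returning
#' the conditional-MLE odds ratio (`Inf` for complete overlap of margins).
#'
#' @param set_a,set_b Item vectors (subsets of `background`).
#' @param background Universe of items.
#' @return One-row tibble `n_overlap`, `odds_ratio`, `p`.
#' @export
fisher_overlap <- function(set_a, set_b, background) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  background <- unique(background)
  if (!all(set_a %in% background) || !all(set_b %in% background)) {
    stop("both sets must be subsets of the background", call. = FALSE)
  }
  in_a <- background %in% set_a
  in_b <- background %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  tibble::tibble(n_overlap = sum(in_a & in_b),
                 odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Overlap of differential positions with target regions across thresholds
#'
#' For each P cut-off, probes below it are called differential and their
#' overlap with the target regions (e.g. ChIP-seq peaks) is tested by
#' Fisher's exact test against the background probes, with a Woolf-logit
#' 95% confidence interval for the odds ratio (Haldane 0.5 correction for
#' empty cells). Thresholds yielding no differential probes are skipped
#' with a warning.
#'
#' @param probe_results Tibble with `probe_id`, `p_genotype`.
#' @param target_regions Region tibble in BED convention (`chrom`, `start`,
#'   `end`; 0-based half-open).
#' @param manifest Probe manifest (probe positions).
#' @param thresholds Numeric vector of >= 2 P cut-offs.
#' @param background Probe ids forming the background (default: all tested).
#' @return Tibble per threshold: `threshold`, `n_dmps`, `n_overlap`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`.
#' @export
threshold_sweep_overlap <- function(probe_results, target_regions, manifest,
                                    thresholds,
                                    background = probe_results$probe_id) {
  stopifnot(length(thresholds) >= 2)
  manifest <- validate_manifest(manifest)
  m <- manifest[match(background, manifest$probe_id), ]
  in_target <- vapply(seq_len(nrow(m)), function(i) {
    any(target_regions$chrom == m$chrom[i] &
          target_regions$start < m$pos[i] &
          target_regions$end >= m$pos[i])
  }, logical(1))
  pvals <- probe_results$p_genotype[match(background, probe_results$probe_id)]
  purrr::map_dfr(sort(thresholds, decreasing = TRUE), function(thr) {
    is_dmp <- !is.na(pvals) & pvals < thr
    if (!any(is_dmp)) {
      warning(sprintf("threshold %g yields no differential probes; skipped",
                      thr), call. = FALSE)
      return(tibble::tibble())
    }
    a <- sum(is_dmp & in_target); b <- sum(is_dmp & !in_target)
    cc <- sum(!is_dmp & in_target); dd <- sum(!is_dmp & !in_target)
    if (all(in_target) || !any(in_target)) {
      ## degenerate margin: overlap carries no information
      return(tibble::tibble(threshold = thr, n_dmps = sum(is_dmp),
                            n_overlap = a, odds_ratio = 1, ci_low = 1,
                            ci_high = 1, p = 1))
    }
    ft <- fisher.test(matrix(c(a, cc, b, dd), 2))
    h <- if (any(c(a, b, cc, dd) == 0)) 0.5 else 0
    lor <- log(((a + h) * (dd + h)) / ((b + h) * (cc + h)))
    se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (dd + h))
    tibble::tibble(threshold = thr, n_dmps = sum(is_dmp), n_overlap = a,
                   odds_ratio = unname(ft$estimate),
                   ci_low = exp(lor - 1.96 * se),
                   ci_high = exp(lor + 1.96 * se), p = ft$p.value)
  })
}

#' Array coverage of a gene set
#'
#' Proportion of a term's genes annotated to at least one variable probe.
#'
#' @param term_genes Character vector of the term's genes.
#' @param universe Tibble from [build_gene_universe()].
#' @return Proportion in \[0, 1\].
#' @export
array_coverage <- function(term_genes, universe) {
  mean(unique(term_genes) %in% universe$gene)
}
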