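test_that("an exact planted genotype effect is recovered with tiny noise", {
  set.seed(41)
  s <- toy_samples(n_per_cell = 3)
  het <- as.numeric(s$genotype == "HET")
  b <- rbind(0.4 + 0.10 * het + rnorm(nrow(s), 0, 1e-4),
             0.4 + 0.10 * het)                    # noiseless: exact fit
  rownames(b) <- c("noisy", "exact")
  res <- fit_probe_models(toy_beta(b, probe_ids = rownames(b),
                                   sample_ids = s$sample_id), s)
  expect_equal(res$beta_genotype, c(0.10, 0.10), tolerance = 1e-3)
  expect_equal(res$beta_genotype[2], 0.10, tolerance = 1e-10)
  expect_lt(res$p_genotype[1], 1e-10)
  expect_equal(res$direction, c(1, 1))
})

test_that("a constant probe gets zero coefficient and P = 1", {
  s <- toy_samples(n_per_cell = 2)
  b <- toy_beta(matrix(0.5, 1, nrow(s)), sample_ids = s$sample_id)
  res <- fit_probe_models(b, s)
  expect_equal(res$beta_genotype, 0)
  expect_equal(res$p_genotype, 1)
  expect_equal(res$direction, 0)
})

test_that("swapping genotype labels flips effect signs and keeps P", {
  set.seed(42)
  s <- toy_samples(n_per_cell = 3)
  b <- toy_beta(matrix(runif(20 * nrow(s), 0.2, 0.8), 20),
                sample_ids = s$sample_id)
  res1 <- fit_probe_models(b, s)
  s2 <- dplyr::mutate(s, genotype = ifelse(.data$genotype == "WT", "HET",
                                           "WT"))
  res2 <- fit_probe_models(b, s2)
  expect_equal(res2$beta_genotype, -res1$beta_genotype, tolerance = 1e-10)
  expect_equal(res2$p_genotype, res1$p_genotype, tolerance = 1e-10)
})

test_that("null probes produce approximately uniform genotype P values", {
  set.seed(43)
  s <- toy_samples(n_per_cell = 5)
  b <- toy_beta(matrix(pmin(pmax(rnorm(1000 * nrow(s), 0.5, 0.05), 0), 1),
                       1000), sample_ids = s$sample_id)
  res <- fit_probe_models(b, s, interaction = FALSE)
  expect_gt(stats::ks.test(res$p_genotype, "punif")$p.value, 0.01)
})

test_that("confounded designs error naming the aliased columns", {
  s <- toy_samples(n_per_cell = 2)
  s$chip_id <- ifelse(s$genotype == "WT", "chip1", "chip2")
  b <- toy_beta(matrix(runif(2 * nrow(s)), 2), sample_ids = s$sample_id)
  expect_error(fit_probe_models(b, s), "rank deficient.*chip")
})

test_that("interaction F test: additive data are calibrated, a planted
          crossover is detected, and identical fits give F = 0", {
  set.seed(44)
  s <- toy_samples(n_per_cell = 5)
  het <- as.numeric(s$genotype == "HET")
  ## type-I calibration on additive data
  b <- toy_beta(matrix(pmin(pmax(0.5 + 0.05 * rep(het, each = 500) +
                                   rnorm(500 * nrow(s), 0, 0.05), 0), 1),
                       500), sample_ids = s$sample_id)
  res <- fit_probe_models(b, s)
  expect_lt(abs(mean(res$p_interaction < 0.05) - 0.05), 0.03)
  expect_equal(unique(res$df_interaction), 4)  # n_ages - 1
  ## planted crossover: +0.1 at E14.5, -0.1 at P70
  eff <- ifelse(s$age_label == "E14.5", 0.1,
                ifelse(s$age_label == "P70", -0.1, 0))
  bx <- toy_beta(matrix(pmin(pmax(0.5 + eff * het +
                                    rnorm(nrow(s), 0, 0.02), 0), 1), 1),
                 sample_ids = s$sample_id)
  rx <- fit_probe_models(bx, s)
  expect_lt(rx$p_interaction, 0.05 / 1000)     # Bonferroni over 1,000 probes
  ## additive-by-construction probe: interaction adds nothing
  by <- toy_beta(matrix(0.5, 1, nrow(s)), sample_ids = s$sample_id)
  ry <- fit_probe_models(by, s)
  expect_equal(ry$F_interaction, 0)
  expect_equal(ry$p_interaction, 1)
})

test_that("the interaction F statistic ignores the age reference level", {
  set.seed(45)
  s <- toy_samples(n_per_cell = 3)
  b <- toy_beta(matrix(runif(5 * nrow(s), 0.2, 0.8), 5),
                sample_ids = s$sample_id)
  f1 <- fit_probe_models(b, s)$F_interaction
  ## oracle: per-probe nested lm anova with a different age reference level
  f2 <- vapply(seq_len(nrow(b)), function(i) {
    d <- dplyr::mutate(s, y = unclass(b)[i, ],
                       genotype = factor(.data$genotype, c("WT", "HET")),
                       age_label = stats::relevel(factor(.data$age_label),
                                                  ref = "P70"),
                       chip_id = factor(.data$chip_id))
    m0 <- lm(y ~ genotype + age_label + chip_id + neuronal_prop, d)
    m1 <- lm(y ~ genotype * age_label + chip_id + neuronal_prop, d)
    anova(m0, m1)$F[2]
  }, numeric(1))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("Bonferroni DMP classification uses a strict threshold", {
  res <- tibble::tibble(probe_id = c("a", "b", "c"),
                        beta_genotype = c(-0.1, 0.1, 0.2),
                        se = 0.01,
                        p_genotype = c(1e-9, 0.05, 0.04999),
                        direction = c(-1, 1, 1))
  out <- bonferroni_dmps(res, n_tests = 1)
  expect_equal(out$threshold[1], 0.05)
  expect_equal(out$is_dmp, c(TRUE, FALSE, TRUE))  # P = threshold is not a DMP
  expect_equal(out$dmp_direction, c("hypo", NA, "hyper"))
  out2 <- bonferroni_dmps(res)                     # default: n tested
  expect_equal(out2$threshold[1], 0.05 / 3)
})
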