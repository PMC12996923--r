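test_that("reference training selects 100 sites for a saturated 2-type panel", {
  set.seed(21)
  n <- 2000
  m_n <- runif(n, 0.3, 0.7)
  m_g <- m_n
  strong <- sample(n, 500)
  m_g[strong] <- pmin(pmax(m_n[strong] +
                             sample(c(-0.5, 0.5), 500, TRUE), 0.02), 0.98)
  tr <- reference_truth(m_n, m_g, n_per_type = 25, within_sd = 0.05)
  ref <- simulate_reference_panel(tr, seed = 1)
  man <- toy_manifest(pos = seq_len(n) * 1000L, ids = rownames(ref$beta))
  panel <- train_reference(ref$beta, ref$labels, man)
  expect_equal(nrow(panel$profile), 100)
  expect_equal(ncol(panel$profile), 2)
  expect_true(all(panel$profile >= 0 & panel$profile <= 1))
  ## training is deterministic
  panel2 <- train_reference(ref$beta, ref$labels, man)
  expect_identical(panel$profile, panel2$profile)
})

test_that("sites with no between-type difference are never selected, and a
          depleted direction yields a smaller panel with a warning", {
  set.seed(22)
  n <- 500
  m_n <- runif(n, 0.3, 0.7)
  m_g <- m_n
  hypo <- 1:30    # NeuNpos below NeuNneg only at 30 sites
  hyper <- 31:110 # NeuNpos above at 80 sites
  m_g[hypo] <- pmin(m_n[hypo] + 0.5, 0.98)
  m_g[hyper] <- pmax(m_n[hyper] - 0.5, 0.02)
  tr <- reference_truth(m_n, m_g, n_per_type = 20, within_sd = 0.03)
  ref <- simulate_reference_panel(tr, seed = 2)
  man <- toy_manifest(pos = seq_len(n) * 1000L, ids = rownames(ref$beta))
  expect_warning(panel <- train_reference(ref$beta, ref$labels, man),
                 "only 30 hypo")
  expect_equal(nrow(panel$profile), 80)  # 30 hypo + 50 hyper, deduplicated
  flat <- setdiff(rownames(ref$beta), rownames(ref$beta)[1:110])
  expect_false(any(flat %in% rownames(panel$profile)))
})

test_that("autosomal filter excludes sex-chromosome sites from the panel", {
  set.seed(23)
  n <- 300
  m_n <- runif(n, 0.3, 0.7); m_g <- m_n
  m_g[1:100] <- pmin(pmax(m_n[1:100] + sample(c(-0.5, 0.5), 100, TRUE),
                          0.02), 0.98)
  tr <- reference_truth(m_n, m_g, n_per_type = 15, within_sd = 0.04)
  ref <- simulate_reference_panel(tr, seed = 3)
  man <- toy_manifest(pos = seq_len(n) * 1000L, ids = rownames(ref$beta))
  man$autosomal[1:50] <- FALSE
  man$chrom[1:50] <- "chrX"
  suppressWarnings(panel <- train_reference(ref$beta, ref$labels, man))
  expect_false(any(man$probe_id[1:50] %in% rownames(panel$profile)))
})

test_that("noiseless mixtures are recovered exactly", {
  profile <- cbind(NeuNpos = c(0.9, 0.1, 0.8, 0.2, 0.6),
                   NeuNneg = c(0.1, 0.9, 0.3, 0.7, 0.4))
  rownames(profile) <- sprintf("p%03d", 1:5)
  panel <- structure(list(profile = profile, selection = NULL,
                          cell_types = colnames(profile)),
                     class = "methdev_panel")
  b <- profile %*% c(0.7, 0.3)
  res <- project_proportions(beta_matrix(b, rownames(profile), "mix"), panel)
  expect_equal(res$prop_NeuNpos, 0.7, tolerance = 1e-6)
  expect_equal(res$prop_NeuNneg, 0.3, tolerance = 1e-6)
  expect_lt(res$error_score, 1e-8)
  ## pure profile
  pure <- project_proportions(
    beta_matrix(profile[, 1, drop = FALSE], rownames(profile), "pure"), panel)
  expect_equal(pure$prop_NeuNpos, 1, tolerance = 1e-6)
  expect_equal(pure$prop_NeuNneg, 0, tolerance = 1e-6)
  expect_equal(pure$neuronal_prop, pure$prop_NeuNpos)
})

test_that("identical type profiles are rejected as rank deficient", {
  profile <- cbind(a = c(0.5, 0.5), b = c(0.5, 0.5))
  rownames(profile) <- c("p1", "p2")
  panel <- structure(list(profile = profile, cell_types = c("a", "b")),
                     class = "methdev_panel")
  expect_error(project_proportions(c(p1 = 0.5, p2 = 0.5), panel),
               "collinear")
})

test_that("noisy mixtures: proportions within tolerance and error score
          tracks the noise level", {
  set.seed(24)
  n_sites <- 100
  profile <- cbind(NeuNpos = runif(n_sites, 0.1, 0.9),
                   NeuNneg = runif(n_sites, 0.1, 0.9))
  rownames(profile) <- sprintf("p%03d", seq_len(n_sites))
  panel <- structure(list(profile = profile, cell_types = colnames(profile)),
                     class = "methdev_panel")
  w_true <- runif(100, 0.2, 0.8)
  noise_sd <- 0.02
  mix <- vapply(w_true, function(w)
    profile %*% c(w, 1 - w) + rnorm(n_sites, 0, noise_sd),
    numeric(n_sites))
  rownames(mix) <- rownames(profile)
  colnames(mix) <- sprintf("M%03d", seq_along(w_true))
  res <- project_proportions(beta_matrix(pmin(pmax(mix, 0), 1),
                                         rownames(mix), colnames(mix)), panel)
  rmse <- sqrt(mean((res$prop_NeuNpos - w_true)^2))
  expect_lt(rmse, 0.05)
  expect_true(all(abs(res$prop_NeuNpos - w_true) < 0.1))
  expect_gt(mean(res$error_score), 0.5 * noise_sd)
  expect_lt(mean(res$error_score), 2 * noise_sd)

  ## error score grows with observation noise (in expectation)
  err_by_sd <- vapply(c(0.01, 0.03, 0.06), function(sdv) {
    m2 <- profile %*% c(0.5, 0.5) + rnorm(n_sites, 0, sdv)
    project_proportions(stats::setNames(as.numeric(m2), rownames(profile)),
                        panel)$error_score
  }, numeric(1))
  expect_true(all(diff(err_by_sd) > 0))
})

test_that("projection errors when too few panel sites overlap the data", {
  profile <- cbind(a = runif(10, 0.2, 0.8), b = runif(10, 0.2, 0.8))
  rownames(profile) <- sprintf("p%02d", 1:10)
  panel <- structure(list(profile = profile, cell_types = c("a", "b")),
                     class = "methdev_panel")
  b <- stats::setNames(runif(5), sprintf("p%02d", 1:5))
  expect_error(project_proportions(b, panel), "panel sites present")
})
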