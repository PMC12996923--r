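test_that("the generator is deterministic under a fixed seed", {
  d <- simulation_design(n_probes = 400, seed = 3)
  a <- simulate_dataset(d)
  b <- simulate_dataset(d)
  expect_identical(unclass(a$beta), unclass(b$beta))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth$dmps, b$truth$dmps)
})

test_that("degenerate limit: no effects, no noise, pure neuronal mixture", {
  d <- simulation_design(n_probes = 200, n_isolated_dmps = 0,
                         n_dmr_blocks = 0, age_effect_sd = 0,
                         chip_effect_sd = 0, noise_sd = 0,
                         n_clock_sites = 0, neuron_sd = 0,
                         neuronal_prop = 1, seed = 5)
  sim <- simulate_dataset(d)
  for (j in seq_len(ncol(sim$beta))) {
    expect_equal(unname(unclass(sim$beta)[, j]), sim$truth$m_neuron,
                 tolerance = 1e-12)
  }
})

test_that("generated betas stay in [0,1] with a small clipping fraction", {
  sim <- simulate_dataset(simulation_design(n_probes = 2000, seed = 9))
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  expect_lt(sim$truth$clip_frac, 0.01)
})

test_that("invalid designs are rejected", {
  expect_error(simulation_design(n_probes = 0), "at least one probe")
  expect_error(simulation_design(n_per_cell = 0), "sample per cell")
  expect_error(simulation_design(noise_sd = -1), "must be >= 0")
})

test_that("planted truth is written alongside the data", {
  sim <- simulate_dataset(simulation_design(n_probes = 1000, seed = 2))
  expect_true(all(sim$truth$dmps$probe_id %in% sim$manifest$probe_id))
  expect_equal(nrow(sim$truth$dmr_blocks), 8)
  expect_true(all(sim$truth$dmr_blocks$n_probes >= 3 &
                    sim$truth$dmr_blocks$n_probes <= 8))
  ## block probes are consecutive and spaced < 1500 bp
  for (i in seq_len(nrow(sim$truth$dmr_blocks))) {
    ids <- strsplit(sim$truth$dmr_blocks$probe_ids[i], ";")[[1]]
    pos <- sim$manifest$pos[match(ids, sim$manifest$probe_id)]
    expect_true(all(diff(pos) > 0 & diff(pos) < 1500))
  }
  ## snoRNA genes are nested in host genes via shared probes
  sno <- sim$gene_table$gene[sim$gene_table$biotype == "snoRNA"]
  expect_gt(length(sno), 0)
  gm <- manifest_gene_map(sim$manifest)
  shared <- gm$probe_id[gm$gene %in% sno]
  hosts <- gm$gene[gm$probe_id %in% shared & !(gm$gene %in% sno)]
  expect_true(all(grepl("^Rph", hosts)))
})

test_that("reference panel draws samples around type means", {
  tr <- reference_truth(m_neuron = c(0.2, 0.8, 0.5),
                        m_glia = c(0.7, 0.3, 0.5),
                        n_per_type = 3, within_sd = 0)
  ref <- simulate_reference_panel(tr, seed = 1)
  expect_equal(ncol(ref$beta), 6)
  for (s in ref$labels$sample_id[ref$labels$cell_type == "NeuNpos"]) {
    expect_equal(unname(unclass(ref$beta)[, s]), c(0.2, 0.8, 0.5))
  }
  expect_identical(unclass(simulate_reference_panel(tr, seed = 4)$beta),
                   unclass(simulate_reference_panel(tr, seed = 4)$beta))
})

test_that("clock planting: zero slopes give constant expected scores and
          positive slopes an increasing mean score", {
  man <- simulate_dataset(simulation_design(n_probes = 300, seed = 1))$manifest
  cl <- simulate_clock_sites(man, n_sites = 105, seed = 2)
  expect_equal(nrow(cl), 105)
  ## zero-slope clock scores are constant whatever the betas
  cl0 <- dplyr::mutate(cl, slope = 0)
  b <- toy_beta(matrix(runif(300 * 4), 300),
                probe_ids = man$probe_id)
  sc <- score_samples(b, cl0)
  expect_equal(sc$pseudo_age, rep(0, 4))
  ## planted positive slopes: expected score strictly increases with age
  d <- simulation_design(n_probes = 300, noise_sd = 0, age_effect_sd = 0,
                         chip_effect_sd = 0, neuron_sd = 0,
                         n_isolated_dmps = 0, n_dmr_blocks = 0, seed = 6)
  sim <- simulate_dataset(d)
  ## expected score is sum(s_i^2) * age_days plus constants: monotone
  sc <- score_samples(sim$beta, sim$clock)
  means <- dplyr::inner_join(sc, sim$samples, by = "sample_id") |>
    dplyr::group_by(.data$age_days) |>
    dplyr::summarise(m = mean(.data$pseudo_age)) |>
    dplyr::arrange(.data$age_days)
  expect_true(all(diff(means$m) > 0))
})

test_that("gene-set generator plants an enriched term and undersized terms", {
  sim <- simulate_dataset(simulation_design(n_probes = 1000, seed = 4))
  planted <- manifest_gene_map(sim$manifest) |>
    dplyr::filter(.data$probe_id %in% sim$truth$dmps$probe_id) |>
    dplyr::pull("gene") |> unique()
  gs <- simulate_gene_sets(sim$manifest, planted, n_terms = 20, seed = 8)
  sizes <- dplyr::count(gs, .data$term_id)
  expect_true(any(sizes$n < 10))                   # exercises the filter
  enr <- gs$gene[gs$term_id == "TERM_ENRICHED"]
  expect_gte(mean(planted %in% enr), 0.7)
  ## overlap 0 behaves as a null term
  gs0 <- simulate_gene_sets(sim$manifest, planted, n_terms = 5,
                            enriched_term_overlap = 0, seed = 8)
  expect_equal(sum(gs0$gene[gs0$term_id == "TERM_ENRICHED"] %in% planted &
                     !gs0$gene[gs0$term_id == "TERM_ENRICHED"] %in%
                     gs0$gene[gs0$term_id != "TERM_ENRICHED"]) > 10, FALSE)
  expect_identical(gs, simulate_gene_sets(sim$manifest, planted,
                                          n_terms = 20, seed = 8))
})
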