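make_universe <- function(n = 600, n_dm = 60, seed = 71) {
  set.seed(seed)
  tibble::tibble(
    gene = sprintf("G%04d", seq_len(n)),
    is_dm = seq_len(n) %in% sample(n, n_dm),
    probe_density = sample(1:30, n, replace = TRUE),
    biotype = sample(c("protein_coding", "snoRNA"), n, replace = TRUE,
                     prob = c(0.95, 0.05))
  )
}

test_that("terms under the background-size minimum are excluded", {
  u <- make_universe()
  terms <- tibble::tibble(
    term_id = c(rep("big", 20), rep("small", 9)),
    term_name = "t", gene = u$gene[1:29]
  )
  out <- term_enrichment(u, terms)
  expect_equal(out$term_id, "big")
})

test_that("null terms produce approximately uniform Wald P values", {
  set.seed(72)
  u <- make_universe(n = 800, n_dm = 80)
  terms <- purrr::map_dfr(1:500, function(i) {
    tibble::tibble(term_id = sprintf("T%03d", i), term_name = "null",
                   gene = sample(u$gene, sample(30:150, 1)))
  })
  out <- term_enrichment(u, terms)
  expect_gt(stats::ks.test(out$p, "punif")$p.value, 0.01)
})

test_that("with constant probe density the fit reduces to the plain
          logistic regression", {
  u <- make_universe()
  u$probe_density <- 7L
  members <- u$gene[1:80]
  terms <- tibble::tibble(term_id = "t", term_name = "t", gene = members)
  out <- term_enrichment(u, terms)
  plain <- glm(is_dm ~ I(as.numeric(gene %in% members)), binomial(),
               data = u)
  expect_equal(log(out$odds_ratio), unname(coef(plain)[2]), tolerance = 1e-6)
})

test_that("a designed term capturing planted DM genes is Bonferroni
          significant and survives conditional selection", {
  run <- run_pipeline(simulation_design(n_probes = 1500, seed = 73))
  enr <- run$enrichment
  expect_lt(enr$p_bonferroni[enr$term_id == "TERM_ENRICHED"], 0.05)
  kept <- conditional_term_selection(enr, run$universe, run$gene_sets)
  expect_true("TERM_ENRICHED" %in% kept$term_id)
})

test_that("a duplicated term is dropped by conditioning on the first copy", {
  u <- make_universe(n = 400, n_dm = 50, seed = 74)
  members <- c(u$gene[u$is_dm][1:35], u$gene[!u$is_dm][1:20])
  terms <- dplyr::bind_rows(
    tibble::tibble(term_id = "orig", term_name = "t", gene = members),
    tibble::tibble(term_id = "copy", term_name = "t", gene = members)
  )
  res <- term_enrichment(u, terms)
  expect_true(all(res$p_bonferroni < 0.05))
  kept <- conditional_term_selection(res, u, terms)
  expect_equal(nrow(kept), 1)
})

test_that("biotype enrichment detects planted nesting and attenuates after
          conditioning on the host pathway", {
  set.seed(75)
  n <- 500
  u <- tibble::tibble(
    gene = sprintf("G%04d", 1:n),
    probe_density = sample(1:20, n, replace = TRUE),
    biotype = "protein_coding", is_dm = FALSE
  )
  ## hosts: 40 genes, most DM; each snoRNA shares its host's DM status
  hosts <- 1:40
  u$is_dm[hosts] <- runif(40) < 0.8
  sno <- 441:480
  u$biotype[sno] <- "snoRNA"
  u$is_dm[sno] <- u$is_dm[hosts]
  u$is_dm[81:120] <- runif(40) < 0.1   # background DM rate
  host_term <- tibble::tibble(term_id = "HOSTS", term_name = "host pathway",
                              gene = u$gene[c(hosts, sno)])
  before <- biotype_enrichment(u, "snoRNA")
  after <- biotype_enrichment(u, "snoRNA", terms = host_term,
                              adjust_for = "HOSTS")
  expect_gt(before$odds_ratio, 1)
  expect_lt(before$p, 0.05)
  expect_lt(after$odds_ratio, before$odds_ratio)
  ## empty adjust_for is identical to the unadjusted call
  same <- biotype_enrichment(u, "snoRNA", adjust_for = character())
  expect_equal(same$odds_ratio, before$odds_ratio)
  expect_equal(same$p, before$p)
})

test_that("a biotype with zero DM genes is not enriched", {
  u <- make_universe(n = 300, n_dm = 30, seed = 76)
  u$is_dm[u$biotype == "snoRNA"] <- FALSE
  out <- biotype_enrichment(u, "snoRNA")
  expect_lte(out$odds_ratio, 1)
  expect_gt(out$p, 0.05)
})

test_that("Fisher overlap handles independence, complete overlap and
          matches the hypergeometric oracle", {
  bg <- sprintf("i%03d", 1:40)
  a <- bg[1:20]; b <- bg[c(1:10, 21:30)]       # 2x2 table (10,10;10,10)
  out <- fisher_overlap(a, b, bg)
  expect_equal(out$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(out$p, 1)
  full <- fisher_overlap(bg[1:20], bg[1:20], bg)
  expect_equal(full$odds_ratio, Inf)
  expect_lt(full$p, 1e-9)
  ## symmetry
  expect_equal(fisher_overlap(a, b, bg)$p, fisher_overlap(b, a, bg)$p)
  ## hypergeometric enumeration oracle on random draws
  set.seed(77)
  for (i in 1:50) {
    bg2 <- sprintf("x%03d", 1:200)
    s1 <- sample(bg2, sample(5:80, 1))
    s2 <- sample(bg2, sample(5:80, 1))
    got <- fisher_overlap(s1, s2, bg2)
    k <- length(intersect(s1, s2))
    ## two-sided exact P: sum of hypergeometric point masses <= P(k)
    d <- stats::dhyper(0:length(s1), length(s2), 200 - length(s2),
                       length(s1))
    want <- sum(d[d <= d[k + 1] * (1 + 1e-7)])
    expect_equal(got$p, want, tolerance = 1e-9)
  }
})

test_that("threshold sweep: saturated targets give OR 1, planted targets a
          non-decreasing OR, empty thresholds are skipped", {
  man <- toy_manifest(pos = as.integer(seq(1000, 100000, length.out = 200)))
  res <- tibble::tibble(probe_id = man$probe_id,
                        p_genotype = seq(1e-12, 1, length.out = 200))
  all_cover <- tibble::tibble(chrom = "chr1", start = 0, end = 200000)
  sw <- threshold_sweep_overlap(res, all_cover, man, c(1e-3, 1e-2, 0.05))
  expect_true(all(sw$odds_ratio == 1))
  ## noiseless fixture: strong signal concentrated in the target probes
  in_target <- seq_len(200) <= 100
  p2 <- numeric(200)
  p2[in_target] <- c(rep(1e-6, 30), rep(0.1, 20), runif(50, 0.5, 1))
  p2[!in_target] <- c(rep(1e-6, 5), rep(0.1, 40), runif(55, 0.5, 1))
  res2 <- tibble::tibble(probe_id = man$probe_id, p_genotype = p2)
  target <- tibble::tibble(chrom = "chr1",
                           start = man$pos[1] - 1, end = man$pos[100])
  sw2 <- threshold_sweep_overlap(res2, target, man, c(1e-3, 0.3))
  ## rows are ordered loosest-first: OR must not decrease as the
  ## threshold tightens
  expect_true(all(diff(sw2$odds_ratio) >= 0))
  expect_gt(sw2$odds_ratio[2], sw2$odds_ratio[1])
  expect_warning(
    threshold_sweep_overlap(res2, target, man, c(1e-20, 0.5)),
    "no differential probes")
})

test_that("array coverage is the fraction of term genes with a variable
          probe", {
  u <- make_universe(n = 100)
  expect_equal(array_coverage(c(u$gene[1:3], "absent"), u), 0.75)
})
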