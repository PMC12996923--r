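#' Describe a synthetic methylation study design
#'
#' The generator emulates a two-genotype (WT/HET) by five-stage (E14.5,
#' E18.5, P7, P35, P70) design with `n_per_cell` animals per cell. Probe
#' betas are a cell-type mixture (neuronal/glial reference means, per-sample
#' neuronal weight drifting with age), plus categorical age effects, chip
#' batch shifts, planted genotype effects (isolated positions and clustered
#' region blocks with a common sign), an age-linear clock component, and
#' Gaussian beta-scale noise clipped to \[0, 1\].
#'
#' Defaults are a desk-scale study: 5,000 probes, 50 samples, 8 planted
#' region blocks of 3-8 probes (internal gaps < 1500 bp; background probes
#' spaced >= 1600 bp), 50 isolated planted positions with |delta| = 0.15,
#' two chips with sd 0.01 shifts, noise sd 0.02, 105 clock sites.
#'
#' @param n_probes Number of probes.
#' @param n_per_cell Samples per genotype x age cell.
#' @param n_isolated_dmps Isolated planted differential positions.
#' @param dmp_delta Absolute beta-scale genotype effect at planted probes.
#' @param n_dmr_blocks Number of planted region blocks.
#' @param dmr_block_size Integer range of probes per block.
#' @param age_effect_sd SD of per-probe categorical age shifts.
#' @param chip_effect_sd SD of per-probe chip batch shifts.
#' @param n_chips Number of chips (samples assigned balanced per cell).
#' @param noise_sd Residual beta-scale noise SD.
#' @param n_clock_sites Number of age-clock sites planted.
#' @param clock_slope_max Clock slopes drawn uniform on +/- this (beta/day).
#' @param n_celltype_probes Probes with a true neuron-glia difference.
#' @param celltype_delta_range Range of |neuron - glia| at those probes.
#' @param neuron_base,neuron_age_slope,neuron_sd True neuronal-proportion
#'   model: `base + slope * age_days + N(0, sd)`, clipped to \[0.05, 0.95\].
#' @param neuronal_prop Optional explicit per-sample neuronal proportions
#'   (recycled), overriding the model above.
#' @param flagged_frac,mfg_frac,chrom0_frac,sex_frac Fractions of background
#'   probes given manifest QC flags / chromosome "0" / sex-chromosome status.
#' @param seed Integer seed; every draw derives from it.
#' @return A validated design list of class `methdev_design`.
#' @export
simulation_design <- function(n_probes = 5000,
                              n_per_cell = 5,
                              n_isolated_dmps = 50,
                              dmp_delta = 0.15,
                              n_dmr_blocks = 8,
                              dmr_block_size = c(3, 8),
                              age_effect_sd = 0.02,
                              chip_effect_sd = 0.01,
                              n_chips = 2,
                              noise_sd = 0.02,
                              n_clock_sites = 105,
                              clock_slope_max = 0.002,
                              n_celltype_probes = 500,
                              celltype_delta_range = c(0.2, 0.5),
                              neuron_base = 0.40,
                              neuron_age_slope = 9e-4,
                              neuron_sd = 0.03,
                              neuronal_prop = NULL,
                              flagged_frac = 0.02,
                              mfg_frac = 0.01,
                              chrom0_frac = 0.005,
                              sex_frac = 0.02,
                              seed = 1) {
  design <- as.list(environment())
  if (design$n_probes < 1) stop("design needs at least one probe",
                                call. = FALSE)
  if (design$n_per_cell < 1) stop("design needs at least one sample per cell",
                                  call. = FALSE)
  num <- c("dmp_delta", "age_effect_sd", "chip_effect_sd", "noise_sd",
           "neuron_sd", "clock_slope_max")
  bad <- num[vapply(design[num], function(x) any(x < 0), logical(1))]
  if (length(bad)) stop("variance/effect parameters must be >= 0: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(design, class = c("methdev_design", "list"))
}

#' Generate a synthetic methylation dataset
#'
#' Produces the beta matrix, sample sheet and probe manifest for a design,
#' alongside the planted truth needed to score recovery downstream: the
#' planted differential positions and region blocks, true per-sample
#' neuronal proportions, the planted clock, a gene/biotype table, per-probe
#' detection-failure counts and per-sample QC summaries.
#'
#' A small fraction of genes are "host" genes carrying a nested snoRNA gene
#' on shared probes, mimicking snoRNAs hosted inside ribosomal-protein
#' genes; planted region blocks preferentially land in gene bodies so that
#' gene-level aggregation and enrichment have signal to find.
#'
#' @param design A [simulation_design()].
#' @return List of class `methdev_sim` with elements `beta`, `samples`,
#'   `manifest`, `clock`, `gene_table`, `truth` (list: `dmps`, `dmr_blocks`,
#'   `neuronal_prop`, `clip_frac`), `detection_fail_counts`, `sample_qc`.
#' @export
simulate_dataset <- function(design = simulation_design()) {
  stopifnot(inherits(design, "methdev_design"))
  set.seed(design$seed)
  np <- design$n_probes

  ## --- manifest scaffold: 5 autosomes as contiguous chunks ---------------
  n_chrom <- min(5L, np)
  chrom_of <- sort(rep_len(seq_len(n_chrom), np))
  probe_id <- sprintf("cg%08d", seq_len(np))

  ## planted region blocks: runs of consecutive probes inside one chromosome
  block_sizes <- if (design$n_dmr_blocks > 0) {
    sample(seq(design$dmr_block_size[1], design$dmr_block_size[2]),
           design$n_dmr_blocks, replace = TRUE)
  } else integer()
  in_block <- integer(np)   # 0 = none, else block id
  for (b in seq_along(block_sizes)) {
    k <- block_sizes[b]
    for (try in 1:200) {
      s <- sample.int(np - k + 1, 1)
      idx <- s:(s + k - 1)
      if (length(unique(chrom_of[idx])) == 1 && all(in_block[idx] == 0) &&
          (s == 1 || in_block[s - 1] == 0) &&
          (s + k > np || in_block[s + k] == 0)) {
        in_block[idx] <- b
        break
      }
    }
  }

  ## positions: background gaps >= 1600 bp, within-block gaps < 1500 bp
  gap <- runif(np, 1600, 4000)
  within_block <- in_block > 0 & c(0L, utils::head(in_block, -1)) == in_block
  gap[within_block] <- runif(sum(within_block), 100, 1400)
  pos <- integer(np)
  for (ch in unique(chrom_of)) {
    i <- which(chrom_of == ch)
    pos[i] <- 10000 + round(cumsum(gap[i]))
  }

  ## gene tiling with nested snoRNA hosts
  gene_of <- character(np)
  feature <- character(np)
  host_genes <- character(); sno_of <- character(np)
  gi <- 0L; i <- 1L
  while (i <= np) {
    gi <- gi + 1L
    glen <- sample(4:12, 1)
    idx <- i:min(i + glen - 1, np)
    is_host <- gi %% 20 == 0
    gname <- if (is_host) sprintf("Rph%04d", gi) else sprintf("Gene%04d", gi)
    gene_of[idx] <- gname
    npr <- length(idx)
    feature[idx] <- c(rep("promoter", max(1, ceiling(0.3 * npr))),
                      rep("gene_body", npr))[seq_len(npr)]
    if (is_host && npr >= 3) {
      host_genes <- c(host_genes, gname)
      sno_idx <- idx[2:min(3, npr)]
      sno_of[sno_idx] <- sprintf("Snord%04d", gi)
    }
    i <- i + glen
    ## occasional intergenic spacer probe
    if (i <= np && gi %% 6 == 0) {
      gene_of[i] <- ""; feature[i] <- "intergenic"; i <- i + 1L
    }
  }
  feature[feature == ""] <- "intergenic"
  genes <- ifelse(sno_of != "", paste(gene_of, sno_of, sep = ";"), gene_of)
  biotype <- dplyr::case_when(
    sno_of != "" ~ "snoRNA",
    gene_of == "" ~ NA_character_,
    TRUE ~ "protein_coding"
  )

  ## QC flags on background probes only (planted signal must survive QC)
  clean <- which(in_block == 0)
  pick <- function(pool, frac) {
    n <- round(frac * np)
    if (n == 0 || length(pool) == 0) integer() else
      sample(pool, min(n, length(pool)))
  }
  flagged_i <- pick(clean, design$flagged_frac)
  clean <- setdiff(clean, flagged_i)
  mfg_i <- pick(clean, design$mfg_frac)
  clean <- setdiff(clean, mfg_i)
  chr0_i <- pick(clean, design$chrom0_frac)
  clean <- setdiff(clean, chr0_i)
  sex_i <- pick(clean, design$sex_frac)
  clean <- setdiff(clean, sex_i)

  chrom <- paste0("chr", chrom_of)
  chrom[chr0_i] <- "0"
  chrom[sex_i] <- "chrX"
  autosomal <- !(seq_len(np) %in% c(sex_i, chr0_i))
  flagged <- seq_len(np) %in% flagged_i
  mfg_flag <- seq_len(np) %in% mfg_i

  ## clock sites and isolated planted positions among clean gene probes
  clock_pool <- intersect(clean, which(gene_of != ""))
  clock_i <- sample(clock_pool, min(design$n_clock_sites, length(clock_pool)))
  dmp_pool <- setdiff(clock_pool, clock_i)
  iso_i <- sample(dmp_pool, min(design$n_isolated_dmps, length(dmp_pool)))

  ## cell-type discriminatory probes
  ct_pool <- setdiff(dmp_pool, iso_i)
  ct_i <- sample(ct_pool, min(design$n_celltype_probes, length(ct_pool)))

  ## reference cell-type means
  m_neuron <- runif(np, 0.15, 0.85)
  m_glia <- m_neuron
  ct_delta <- runif(length(ct_i), design$celltype_delta_range[1],
                    design$celltype_delta_range[2]) *
    sample(c(-1, 1), length(ct_i), replace = TRUE)
  m_glia[ct_i] <- pmin(pmax(m_neuron[ct_i] + ct_delta, 0.02), 0.98)

  ## planted genotype effects
  delta <- numeric(np)
  delta[iso_i] <- design$dmp_delta * sample(c(-1, 1), length(iso_i),
                                            replace = TRUE)
  block_sign <- sample(c(-1, 1), length(block_sizes), replace = TRUE)
  for (b in seq_along(block_sizes)) {
    delta[in_block == b] <- design$dmp_delta * block_sign[b]
  }

  ## clock slopes
  slopes <- runif(length(clock_i), -design$clock_slope_max,
                  design$clock_slope_max)
  clock <- tibble::tibble(site_id = probe_id[clock_i], slope = slopes)

  ## sample sheet
  ages <- names(age_day_map())
  grid <- expand.grid(rep = seq_len(design$n_per_cell),
                      genotype = c("WT", "HET"), age_label = ages,
                      stringsAsFactors = FALSE)
  ns <- nrow(grid)
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(ns)),
    genotype = grid$genotype,
    age_label = grid$age_label,
    age_days = age_day_map()[grid$age_label],
    chip_id = paste0("chip", ((seq_len(ns) - 1) %% design$n_chips) + 1)
  )
  w <- if (!is.null(design$neuronal_prop)) {
    rep_len(design$neuronal_prop, ns)
  } else {
    pmin(pmax(design$neuron_base + design$neuron_age_slope * samples$age_days +
                rnorm(ns, 0, design$neuron_sd), 0.05), 0.95)
  }

  ## assemble betas
  age_eff <- matrix(rnorm(np * length(ages), 0, design$age_effect_sd),
                    np, length(ages), dimnames = list(NULL, ages))
  chip_eff <- matrix(rnorm(np * design$n_chips, 0, design$chip_effect_sd),
                     np, design$n_chips,
                     dimnames = list(NULL, paste0("chip", 1:design$n_chips)))
  slope_vec <- numeric(np); slope_vec[clock_i] <- slopes
  het <- as.numeric(samples$genotype == "HET")
  raw <- vapply(seq_len(ns), function(s) {
    w[s] * m_neuron + (1 - w[s]) * m_glia +
      age_eff[, samples$age_label[s]] +
      delta * het[s] +
      slope_vec * samples$age_days[s] +
      chip_eff[, samples$chip_id[s]] +
      rnorm(np, 0, design$noise_sd)
  }, numeric(np))
  clip_frac <- mean(raw < 0 | raw > 1)
  beta <- beta_matrix(pmin(pmax(raw, 0), 1), probe_id, samples$sample_id)

  manifest <- tibble::tibble(
    probe_id = probe_id, chrom = chrom, pos = pos, genes = genes,
    feature = feature, biotype = biotype, flagged = flagged,
    mfg_change_flagged = mfg_flag, autosomal = autosomal
  )
  gene_table <- tibble::tibble(
    gene = unique(c(gene_of[gene_of != ""], sno_of[sno_of != ""]))
  ) |>
    dplyr::mutate(biotype = dplyr::if_else(grepl("^Snord", .data$gene),
                                           "snoRNA", "protein_coding"),
                  host = dplyr::if_else(grepl("^Snord", .data$gene),
                                        sub("^Snord", "Rph", .data$gene),
                                        NA_character_))
  blocks <- purrr::map_dfr(seq_along(block_sizes), function(b) {
    idx <- which(in_block == b)
    tibble::tibble(block_id = b, chrom = chrom[idx[1]],
                   start = min(pos[idx]), end = max(pos[idx]),
                   n_probes = length(idx), delta = design$dmp_delta *
                     block_sign[b],
                   probe_ids = paste(probe_id[idx], collapse = ";"))
  })
  truth <- list(
    dmps = tibble::tibble(probe_id = probe_id[delta != 0],
                          delta = delta[delta != 0],
                          isolated = probe_id[delta != 0] %in% probe_id[iso_i]),
    dmr_blocks = blocks,
    neuronal_prop = tibble::tibble(sample_id = samples$sample_id,
                                   neuronal_prop = w),
    m_neuron = m_neuron, m_glia = m_glia,
    celltype_probes = probe_id[ct_i],
    clip_frac = clip_frac
  )
  det_fail <- integer(np)
  n_det <- max(1L, round(0.002 * np))
  det_pool <- setdiff(clean, c(clock_i, iso_i, ct_i))
  det_i <- sample(det_pool, min(3L * n_det, length(det_pool)))
  det_fail[det_i] <- sample(1:2, length(det_i), replace = TRUE)
  sample_qc <- tibble::tibble(
    sample_id = samples$sample_id,
    median_meth_intensity = rnorm(ns, 3200, 150),
    median_unmeth_intensity = rnorm(ns, 3000, 150),
    frac_probes_failing_detection = runif(ns, 0, 0.008),
    bisulfite_conversion_pct = pmin(rnorm(ns, 96, 1), 100)
  )
  structure(list(beta = beta, samples = samples, manifest = manifest,
                 clock = clock, gene_table = gene_table, truth = truth,
                 detection_fail_counts = stats::setNames(det_fail, probe_id),
                 sample_qc = sample_qc, design = design),
            class = "methdev_sim")
}

#' Generate a labelled reference panel for deconvolution
#'
#' Draws per-cell-type reference samples around supplied type means with
#' Gaussian within-type noise, emulating methylation profiles of
#' nuclei-sorted neuronal (NeuN+) and non-neuronal (NeuN-) fractions.
#'
#' @param truth List with `m` (probes x types matrix of type means, in
#'   \[0,1\], rownames = probe ids), `n_per_type` samples per type, and
#'   `within_sd` noise SD. See [reference_truth()].
#' @param seed Integer seed.
#' @return List with `beta` (a `beta_matrix`) and `labels` (tibble
#'   `sample_id`, `cell_type`).
#' @export
simulate_reference_panel <- function(truth, seed = 1) {
  m <- truth$m
  if (ncol(m) < 2) stop("need at least two cell types", call. = FALSE)
  set.seed(seed)
  types <- colnames(m)
  mats <- lapply(types, function(ct) {
    v <- replicate(truth$n_per_type,
                   pmin(pmax(m[, ct] + rnorm(nrow(m), 0, truth$within_sd),
                             0), 1))
    colnames(v) <- sprintf("%s_%02d", ct, seq_len(truth$n_per_type))
    v
  })
  all <- do.call(cbind, mats)
  labels <- tibble::tibble(
    sample_id = colnames(all),
    cell_type = rep(types, each = truth$n_per_type)
  )
  list(beta = beta_matrix(all, rownames(m), colnames(all)), labels = labels)
}

#' Construct reference-panel truth
#'
#' @param m_neuron,m_glia Numeric vectors of per-probe type means in \[0,1\].
#' @param probe_ids Probe ids (default `cg`-numbered).
#' @param n_per_type Reference samples per type.
#' @param within_sd Within-type beta noise SD.
#' @return Truth list consumed by [simulate_reference_panel()].
#' @export
reference_truth <- function(m_neuron, m_glia,
                            probe_ids = sprintf("cg%08d", seq_along(m_neuron)),
                            n_per_type = 25, within_sd = 0.05) {
  stopifnot(length(m_neuron) == length(m_glia),
            all(m_neuron >= 0 & m_neuron <= 1),
            all(m_glia >= 0 & m_glia <= 1))
  m <- cbind(NeuNpos = m_neuron, NeuNneg = m_glia)
  rownames(m) <- probe_ids
  list(m = m, n_per_type = n_per_type, within_sd = within_sd)
}

#' Plant a synthetic age clock
#'
#' Returns `n_sites` manifest probes with uniform slopes on
#' `slope_range` (beta per day). [simulate_dataset()] embeds a consistent
#' linear-in-age component when handed the same seed/design; this helper is
#' for building clocks against an existing manifest.
#'
#' @param manifest Probe manifest to draw sites from.
#' @param n_sites Number of clock sites (default 105).
#' @param slope_range Length-2 numeric range of slopes.
#' @param seed Integer seed.
#' @return Tibble `site_id`, `slope`.
#' @export
simulate_clock_sites <- function(manifest, n_sites = 105,
                                 slope_range = c(-0.002, 0.002), seed = 1) {
  manifest <- validate_manifest(manifest)
  set.seed(seed)
  ids <- sample(manifest$probe_id, min(n_sites, nrow(manifest)))
  tibble::tibble(site_id = ids,
                 slope = runif(length(ids), slope_range[1], slope_range[2]))
}

#' Generate gene-set collections with one designed enriched term
#'
#' Random terms of sizes 10-200 drawn from the manifest's genes, plus a few
#' deliberately undersized terms (< 10 genes, to exercise the downstream
#' size filter), plus one designed term (`TERM_ENRICHED`) containing a
#' fraction `enriched_term_overlap` of the supplied planted genes topped up
#' with random members.
#'
#' @param manifest Probe manifest (source of the gene universe).
#' @param planted_genes Character vector of genes carrying planted signal.
#' @param n_terms Number of random terms.
#' @param enriched_term_overlap Fraction of planted genes included in the
#'   designed term (0 makes it behave as a null term).
#' @param n_small_terms Number of deliberately undersized terms.
#' @param seed Integer seed.
#' @return Long tibble `term_id`, `term_name`, `gene`.
#' @export
simulate_gene_sets <- function(manifest, planted_genes = character(),
                               n_terms = 50, enriched_term_overlap = 0.8,
                               n_small_terms = 3, seed = 1) {
  set.seed(seed)
  universe <- unique(manifest_gene_map(manifest)$gene)
  rand_term <- function(id, size) {
    tibble::tibble(term_id = id, term_name = paste0("random set ", id),
                   gene = sample(universe, min(size, length(universe))))
  }
  rand <- purrr::map_dfr(seq_len(n_terms), function(i) {
    rand_term(sprintf("TERM%04d", i), sample(10:200, 1))
  })
  small <- purrr::map_dfr(seq_len(n_small_terms), function(i) {
    rand_term(sprintf("SMALL%02d", i), sample(3:9, 1))
  })
  planted_in <- intersect(planted_genes, universe)
  n_keep <- round(enriched_term_overlap * length(planted_in))
  members <- if (n_keep > 0) sample(planted_in, n_keep) else character()
  filler <- sample(setdiff(universe, members),
                   min(max(30, 2 * length(members)),
                       length(setdiff(universe, members))))
  designed <- tibble::tibble(term_id = "TERM_ENRICHED",
                             term_name = "designed enriched term",
                             gene = unique(c(members, filler)))
  dplyr::bind_rows(rand, small, designed)
}
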