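# Small fixtures built in code, shared across test files.

# minimal manifest: probes on one or more chromosomes, no QC flags
toy_manifest <- function(pos, chrom = "chr1", genes = "",
                         feature = "gene_body", biotype = "protein_coding",
                         ids = sprintf("p%03d", seq_along(pos))) {
  tibble::tibble(
    probe_id = ids, chrom = rep_len(chrom, length(pos)), pos = pos,
    genes = rep_len(genes, length(pos)),
    feature = rep_len(feature, length(pos)),
    biotype = rep_len(biotype, length(pos)),
    flagged = FALSE, mfg_change_flagged = FALSE, autosomal = TRUE
  )
}

toy_beta <- function(values, probe_ids = NULL, sample_ids = NULL) {
  v <- as.matrix(values)
  if (is.null(probe_ids)) probe_ids <- sprintf("p%03d", seq_len(nrow(v)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ncol(v)))
  beta_matrix(v, probe_ids, sample_ids)
}

# balanced 2-genotype x 5-age sample sheet; neuronal proportion varies
# smoothly so the covariate is never aliased with the intercept
toy_samples <- function(n_per_cell = 2, n_chips = 2, neuronal = NULL) {
  ages <- names(age_day_map())
  grid <- expand.grid(rep = seq_len(n_per_cell), genotype = c("WT", "HET"),
                      age_label = ages, stringsAsFactors = FALSE)
  n <- nrow(grid)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    genotype = grid$genotype, age_label = grid$age_label,
    age_days = age_day_map()[grid$age_label],
    chip_id = paste0("chip", ((seq_len(n) - 1) %% n_chips) + 1),
    ## irregular but deterministic, so it is never collinear with the
    ## genotype/age/chip dummies
    neuronal_prop = if (is.null(neuronal))
      0.3 + 0.4 * ((seq_len(n) * 37) %% 17) / 16
    else rep_len(neuronal, n)
  )
}

# independent brute-force DMR oracle: enumerate all maximal windows of
# consecutive tested probes that all qualify, share a sign, and have every
# adjacent gap < gap_bp; report windows of >= 2 probes
oracle_dmr_regions <- function(d, gap_bp = 1500, nominal_p = 0.05) {
  d <- d[order(d$chrom, d$pos), ]
  out <- list()
  for (ch in unique(d$chrom)) {
    x <- d[d$chrom == ch, ]
    n <- nrow(x)
    ok_window <- function(i, j) {
      idx <- i:j
      all(x$p_genotype[idx] < nominal_p) &&
        all(x$direction[idx] != 0) &&
        length(unique(x$direction[idx])) == 1 &&
        (i == j || all(diff(x$pos[idx]) < gap_bp))
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!ok_window(i, j)) next
        maximal <- (i == 1 || !ok_window(i - 1, j)) &&
          (j == n || !ok_window(i, j + 1))
        if (maximal && j - i + 1 >= 2) {
          out[[length(out) + 1]] <- tibble::tibble(
            chrom = ch, start = x$pos[i], end = x$pos[j],
            probe_ids = paste(x$probe_id[i:j], collapse = ";")
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), probe_ids = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# random probe-result + manifest configuration for oracle comparisons
random_dmr_config <- function(n = 200, seed = 1) {
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", 1:3), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i) {
    10000 + cumsum(sample(c(100, 400, 900, 1400, 1500, 1600, 3000),
                          length(i), replace = TRUE))
  }))
  man <- toy_manifest(pos = as.integer(pos), chrom = chrom,
                      ids = sprintf("q%04d", seq_len(n)))
  res <- tibble::tibble(
    probe_id = man$probe_id,
    p_genotype = ifelse(runif(n) < 0.4, runif(n, 0, 0.049), runif(n, 0.05, 1)),
    direction = sample(c(-1, 1), n, replace = TRUE)
  )
  betas <- matrix(runif(n * 10), n, dimnames =
                    list(man$probe_id, sprintf("S%02d", 1:10)))
  list(manifest = man, results = res,
       beta = beta_matrix(betas, man$probe_id, colnames(betas)))
}
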