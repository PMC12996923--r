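#' Construct a validated beta-value matrix
#'
#' The central container of the pipeline is a probes x samples matrix of
#' methylation beta values (proportion methylated, in \[0, 1\]), with probe
#' ids as row names and sample ids as column names. This constructor checks
#' the invariants and is used by every reader and the simulator.
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#' @param probe_ids,sample_ids Optional character vectors; default to the
#'   dimnames of `values`.
#' @param allow_missing Permit `NA` entries (only sensible pre-QC).
#' @return A numeric matrix with class `beta_matrix` prepended.
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values),
                        allow_missing = FALSE) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("beta_matrix needs probe and sample ids", call. = FALSE)
  }
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("id lists do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (!allow_missing && anyNA(values)) {
    stop("missing beta values are not allowed here", call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < -1e-9 | values > 1 + 1e-9))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "beta value %.6g outside [0,1] at probe '%s', sample '%s'",
      values[bad[1]], probe_ids[ij[1]], sample_ids[ij[2]]
    ), call. = FALSE)
  }
  values[] <- pmin(pmax(values, 0), 1)
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' Convert a beta matrix to a long tibble
#'
#' @param beta A `beta_matrix`.
#' @return Tibble with columns `probe_id`, `sample_id`, `beta`.
#' @export
beta_tidy <- function(beta) {
  tibble::as_tibble(as.table(unclass(beta)), .name_repair = "minimal") |>
    stats::setNames(c("probe_id", "sample_id", "beta"))
}

#' Validate a probe manifest
#'
#' A manifest has one row per probe: `probe_id`, `chrom`, `pos` (1-based bp),
#' `genes` (`;`-separated symbols, possibly empty), `feature` (promoter /
#' gene_body / intergenic), `biotype` (protein_coding / snoRNA /
#' other_noncoding / NA), `flagged`, `mfg_change_flagged`, `autosomal`.
#' Chromosome "0" is permitted on input; such probes are removed during QC.
#'
#' @param manifest A data frame.
#' @return The manifest as a tibble, invisibly checked.
#' @export
validate_manifest <- function(manifest) {
  manifest <- tibble::as_tibble(manifest)
  needed <- c("probe_id", "chrom", "pos", "genes", "feature", "biotype",
              "flagged", "mfg_change_flagged", "autosomal")
  miss <- setdiff(needed, names(manifest))
  if (length(miss)) {
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$probe_id)) {
    stop("manifest probe ids must be unique", call. = FALSE)
  }
  if (any(manifest$pos < 1)) stop("manifest positions are 1-based (>= 1)",
                                  call. = FALSE)
  ok_feat <- c("promoter", "gene_body", "intergenic")
  if (!all(manifest$feature %in% ok_feat)) {
    stop("manifest feature must be one of ", paste(ok_feat, collapse = "/"),
         call. = FALSE)
  }
  manifest
}

#' Expand manifest gene annotations to probe-gene pairs
#'
#' @param manifest A probe manifest.
#' @param feature_filter Optional feature class to keep (e.g. "promoter").
#' @return Tibble `probe_id`, `gene`, one row per annotation.
#' @export
manifest_gene_map <- function(manifest, feature_filter = NULL) {
  m <- validate_manifest(manifest)
  if (!is.null(feature_filter)) {
    m <- dplyr::filter(m, .data$feature %in% feature_filter)
  }
  m |>
    dplyr::select("probe_id", "genes") |>
    dplyr::filter(!is.na(.data$genes), .data$genes != "") |>
    dplyr::mutate(gene = strsplit(.data$genes, ";", fixed = TRUE)) |>
    tidyr::unnest("gene") |>
    dplyr::distinct(.data$probe_id, .data$gene)
}

#' Validate a sample sheet
#'
#' Columns: `sample_id`, `genotype` (WT/HET), `age_label` (E14.5, E18.5, P7,
#' P35, P70), `chip_id`; plus the derived `age_days`, `neuronal_prop` and
#' `pseudo_age` which may be missing until the relevant stage has run.
#'
#' @param samples A data frame.
#' @return The sample sheet as a tibble with `age_days` filled in.
#' @export
validate_sample_sheet <- function(samples) {
  samples <- tibble::as_tibble(samples)
  needed <- c("sample_id", "genotype", "age_label", "chip_id")
  miss <- setdiff(needed, names(samples))
  if (length(miss)) {
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (anyNA(samples$genotype) || anyNA(samples$age_label)) {
    stop("genotype and age_label must be non-missing", call. = FALSE)
  }
  if (!all(samples$genotype %in% c("WT", "HET"))) {
    stop("genotype must be WT or HET", call. = FALSE)
  }
  if (!all(samples$age_label %in% names(age_day_map()))) {
    stop("age_label must be one of ", paste(names(age_day_map()),
                                            collapse = ", "), call. = FALSE)
  }
  if (!"age_days" %in% names(samples) || anyNA(samples$age_days)) {
    samples$age_days <- age_day_map()[samples$age_label]
  }
  samples
}

#' Developmental stage to days-since-E14.5 encoding
#'
#' E14.5 is day 0; birth falls at day 19 of gestation, so P7 = 26, P35 = 54,
#' P70 = 89. Used only where age enters a model continuously (per-day
#' slopes); differential models treat age as categorical.
#'
#' @return Named numeric vector.
#' @export
age_day_map <- function() {
  c(E14.5 = 0, E18.5 = 4, P7 = 26, P35 = 54, P70 = 89)
}

#' Read a beta-value matrix from delimited text
#'
#' First column must be the probe id; remaining columns one per sample.
#' Probes absent from the manifest are dropped with a warning giving the
#' count. Values outside \[0, 1\] (beyond 1e-9) or non-numeric cells are
#' hard errors naming the offending cell.
#'
#' @param path TSV file path.
#' @param manifest Probe manifest the matrix is restricted to.
#' @return A `beta_matrix`.
#' @export
read_beta_matrix <- function(path, manifest) {
  manifest <- validate_manifest(manifest)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) stop("beta file needs a probe id column plus samples",
                          call. = FALSE)
  probe_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA")
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(vals))
    stop(sprintf("malformed numeric value '%s' at row %d (probe '%s'), column '%s'",
                 vals[bad[1]], ij[1], probe_ids[ij[1]],
                 colnames(vals)[ij[2]]), call. = FALSE)
  }
  out <- which(!is.na(num) & (num < -1e-9 | num > 1 + 1e-9))
  if (length(out)) {
    ij <- arrayInd(out[1], dim(vals))
    stop(sprintf("beta value %s outside [0,1] at probe '%s', sample '%s'",
                 vals[out[1]], probe_ids[ij[1]], colnames(vals)[ij[2]]),
         call. = FALSE)
  }
  keep <- probe_ids %in% manifest$probe_id
  if (!all(keep)) {
    warning(sprintf("%d probe(s) absent from manifest dropped", sum(!keep)),
            call. = FALSE)
  }
  beta_matrix(num[keep, , drop = FALSE], probe_ids[keep], colnames(vals),
              allow_missing = TRUE)
}

#' Write a beta-value matrix as TSV
#'
#' @param beta A `beta_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- tibble::as_tibble(unclass(beta), rownames = "probe_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and write sample sheets and manifests
#'
#' Plain TSV with a header row; `read_sample_sheet()` validates and fills
#' `age_days`, `read_manifest()` validates probe columns.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), genotype = readr::col_character(),
    age_label = readr::col_character(), chip_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
}

#' @rdname read_sample_sheet
#' @param x Tibble to write.
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
read_manifest <- function(path) {
  validate_manifest(readr::read_tsv(path, col_types = readr::cols(
    pos = readr::col_integer(),
    flagged = readr::col_logical(), mfg_change_flagged = readr::col_logical(),
    autosomal = readr::col_logical(), .default = readr::col_character()
  ), progress = FALSE))
}

#' @rdname read_sample_sheet
#' @export
write_manifest <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a BED file into a region tibble
#'
#' Regions are kept in BED convention in memory: 0-based half-open
#' `start`/`end`. `bed_to_closed()` / `closed_to_bed()` convert to and from
#' 1-based closed intervals (the manifest/DMR convention).
#'
#' @param path BED file (3+ columns, tab separated, no header).
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types =
                           readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  out <- tibble::tibble(
    chrom = raw[[1]],
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    name = if (ncol(raw) >= 4) raw[[4]] else NA_character_,
    score = if (ncol(raw) >= 5) as.numeric(raw[[5]]) else NA_real_
  )
  if (any(out$start >= out$end)) stop("BED intervals need start < end",
                                      call. = FALSE)
  out
}

#' @rdname read_bed
#' @param regions Region tibble in BED convention.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start >= regions$end)) {
    stop("BED intervals need start < end", call. = FALSE)
  }
  out <- regions |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::transmute(
      .data$chrom, start = format(.data$start, scientific = FALSE, trim = TRUE),
      end = format(.data$end, scientific = FALSE, trim = TRUE),
      name = if ("name" %in% names(regions)) dplyr::coalesce(.data$name, ".") else ".",
      score = if ("score" %in% names(regions)) dplyr::coalesce(.data$score, 0) else 0,
      strand = "."
    )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @param x Region tibble.
#' @export
bed_to_closed <- function(x) dplyr::mutate(x, start = .data$start + 1)

#' @rdname read_bed
#' @export
closed_to_bed <- function(x) dplyr::mutate(x, start = .data$start - 1)

#' Export called DMRs as BED6
#'
#' Internal DMR coordinates are 1-based inclusive outermost-probe positions;
#' the export converts to 0-based half-open. The name field joins annotated
#' gene symbols with ";"; the score is -log10(adjusted P), capped at 1000.
#'
#' @param dmrs DMR result tibble from [call_dmrs()].
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  out <- dmrs |>
    dplyr::transmute(
      .data$chrom,
      start = .data$start - 1,
      end = .data$end,
      name = dplyr::coalesce(.data$genes, ""),
      score = pmin(-log10(pmax(.data$adjusted_p, 1e-1000)), 1000)
    )
  write_bed(out, path)
}

#' Read and write GMT gene-set files
#'
#' GMT lines are `term_id<TAB>description<TAB>gene1<TAB>gene2...`. The
#' in-memory form is a long tibble (`term_id`, `term_name`, `gene`) with no
#' duplicate gene within a term.
#'
#' @param path GMT file path.
#' @return Long tibble of term memberships.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line needs id, description and >=1 gene",
                            call. = FALSE)
    tibble::tibble(term_id = f[1], term_name = f[2],
                   gene = unique(f[-(1:2)]))
  })
}

#' @rdname read_gmt
#' @param gene_sets Long tibble (`term_id`, `term_name`, `gene`).
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(line = paste(unique(.data$gene), collapse = "\t"),
                     .groups = "drop") |>
    dplyr::mutate(line = paste(.data$term_id, .data$term_name, .data$line,
                               sep = "\t"))
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Pipeline configuration with defaults
#'
#' Reads a YAML key/value file and merges it over the documented defaults,
#' which are the analysis constants used throughout: detection P 0.05 with at
#' most 1% of probes failing per sample, minimum median signal intensity
#' 2000, bisulfite conversion >= 90%, variable-probe range 0.05 over the
#' inner 80% of samples, DMR gap 1500 bp at nominal P 0.05, reference-panel
#' ANOVA selection P 1e-8 with top 50 sites per direction, and a 10-gene
#' minimum for enrichment terms. Unknown keys are an error listing the valid
#' keys.
#'
#' @param path Optional YAML file; `NULL` returns pure defaults.
#' @param overrides Named list applied after the file (e.g. from a caller).
#' @return Named list of configuration values.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    detection_p = 0.05,
    max_detection_fail_frac = 0.01,
    min_median_intensity = 2000,
    min_bisulfite_pct = 90,
    max_detection_fail_samples = 1,
    variability_range = 0.05,
    inner_fraction = 0.8,
    dmr_gap_bp = 1500,
    dmr_nominal_p = 0.05,
    anova_selection_p = 1e-8,
    top_k = 50,
    go_min_genes = 10,
    n_tests = NA,
    seed = 1
  )
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(names(defaults), collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, user)
}
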