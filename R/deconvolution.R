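#' Train a cell-type reference panel
#'
#' Selects discriminatory sites from labelled reference profiles (e.g.
#' nuclei-sorted NeuN+ / NeuN- fractions) and builds the mean methylation
#' profile per cell type used by the constrained-projection deconvolution.
#'
#' After restricting to autosomal sites, a per-site one-way ANOVA across
#' cell types is computed; among sites with P below `p_threshold`
#' (default 1e-8), each cell type contributes its `top_k` (default 50) most
#' significant sites where that type's mean is below all other types'
#' means (hypo) and `top_k` where it is above (hyper). The panel is the
#' deduplicated union; with two cell types the directions mirror each other
#' and the union is exactly `2 * top_k` sites when both directions are
#' saturated.
#'
#' @param reference_beta A `beta_matrix` of reference samples.
#' @param labels Tibble `sample_id`, `cell_type` (>= 2 types, >= 2 samples
#'   each).
#' @param manifest Probe manifest (for the autosomal filter).
#' @param p_threshold ANOVA significance cut-off.
#' @param top_k Sites per direction per cell type.
#' @return List of class `methdev_panel`: `profile` (sites x types mean
#'   matrix), `selection` (tibble with per-site F, P, direction and the
#'   selecting type), `cell_types`.
#' @export
train_reference <- function(reference_beta, labels, manifest,
                            p_threshold = 1e-8, top_k = 50) {
  manifest <- validate_manifest(manifest)
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("sample_id", "cell_type") %in% names(labels)))
  labels <- labels[match(colnames(reference_beta), labels$sample_id), ]
  if (anyNA(labels$cell_type)) {
    stop("every reference sample needs a cell-type label", call. = FALSE)
  }
  types <- sort(unique(labels$cell_type))
  if (length(types) < 2) stop("need >= 2 labelled cell types", call. = FALSE)
  if (any(table(labels$cell_type) < 2)) {
    stop("need >= 2 samples per cell type", call. = FALSE)
  }
  auto <- manifest$probe_id[manifest$autosomal]
  x <- unclass(reference_beta)[rownames(reference_beta) %in% auto, ,
                               drop = FALSE]
  if (nrow(x) == 0) stop("no autosomal sites in reference data", call. = FALSE)

  ## vectorised one-way ANOVA across cell types
  g <- factor(labels$cell_type, levels = types)
  n <- ncol(x)
  k <- length(types)
  grand <- rowMeans(x)
  gm <- vapply(types, function(t) rowMeans(x[, g == t, drop = FALSE]),
               numeric(nrow(x)))
  ng <- as.numeric(table(g)[types])
  ssb <- as.numeric((gm - grand)^2 %*% ng)
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- n - k
  Fstat <- (ssb / df1) / (ssw / df2)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb > 0] <- 0
  p[ssb == 0] <- 1

  qual <- which(p < p_threshold)
  if (length(qual) == 0) stop("no sites pass the ANOVA selection threshold",
                              call. = FALSE)
  sel <- purrr::map_dfr(types, function(t) {
    others <- setdiff(types, t)
    below <- qual[gm[qual, t] < apply(gm[qual, others, drop = FALSE], 1, min)]
    above <- qual[gm[qual, t] > apply(gm[qual, others, drop = FALSE], 1, max)]
    take <- function(idx, dir) {
      got <- idx[order(p[idx])][seq_len(min(top_k, length(idx)))]
      if (length(idx) < top_k) {
        warning(sprintf("only %d %s sites qualify for %s (wanted %d)",
                        length(idx), dir, t, top_k), call. = FALSE)
      }
      if (length(got) == 0) return(tibble::tibble())
      tibble::tibble(probe_id = rownames(x)[got], F = Fstat[got], p = p[got],
                     direction = dir, cell_type = t)
    }
    dplyr::bind_rows(take(below, "hypo"), take(above, "hyper"))
  })
  sites <- unique(sel$probe_id)
  profile <- vapply(types, function(t)
    rowMeans(x[sites, g == t, drop = FALSE]), numeric(length(sites)))
  profile <- matrix(profile, nrow = length(sites),
                    dimnames = list(sites, types))
  structure(list(profile = profile, selection = sel, cell_types = types),
            class = "methdev_panel")
}

#' Estimate cell-type proportions by constrained projection
#'
#' Solves, per sample, the non-negative least-squares problem
#' min ||b - M w||^2 subject to w >= 0 (no sum-to-one constraint), where M
#' is the panel's sites x types profile matrix, in the spirit of the
#' Houseman reference-based approach. The reconstruction-error score is the
#' root-mean-square deviation between the observed and reconstructed
#' profile over panel sites (a CETYGO-style quality metric): high values
#' flag samples unlike any mixture of the reference types.
#'
#' @param beta A `beta_matrix` of bulk samples (or a single named vector
#'   over panel sites).
#' @param panel A `methdev_panel` from [train_reference()].
#' @param min_site_overlap Minimum fraction of panel sites that must be
#'   present in `beta` (default 0.8).
#' @return Tibble with `sample_id`, one proportion column per cell type,
#'   `neuronal_prop` (the first cell type's weight, conventionally NeuN+),
#'   and `error_score`.
#' @export
project_proportions <- function(beta, panel, min_site_overlap = 0.8) {
  if (is.null(dim(beta))) {
    beta <- matrix(beta, ncol = 1, dimnames = list(names(beta), "sample"))
  }
  M <- panel$profile
  if (qr(M)$rank < ncol(M)) {
    stop("reference profiles are collinear; cannot deconvolve", call. = FALSE)
  }
  common <- intersect(rownames(M), rownames(beta))
  if (length(common) < min_site_overlap * nrow(M)) {
    stop(sprintf("only %d/%d panel sites present in data (need >= %.0f%%)",
                 length(common), nrow(M), 100 * min_site_overlap),
         call. = FALSE)
  }
  Mc <- M[common, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(ncol(beta)), function(j) {
    b <- unclass(beta)[common, j]
    fit <- pracma::lsqnonneg(Mc, b)
    w <- fit$x
    err <- sqrt(mean((b - Mc %*% w)^2))
    out <- tibble::tibble(sample_id = colnames(beta)[j])
    for (t in seq_along(panel$cell_types)) {
      out[[paste0("prop_", panel$cell_types[t])]] <- w[t]
    }
    out$neuronal_prop <- w[1]
    out$error_score <- err
    out
  })
  ## NeuN+ convention: prefer a type whose name marks the neuronal fraction
  neu <- grep("pos|NeuN\\+|neuron", panel$cell_types, ignore.case = TRUE)
  if (length(neu)) {
    res$neuronal_prop <- res[[paste0("prop_", panel$cell_types[neu[1]])]]
  }
  res
}
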