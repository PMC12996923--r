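#' Fit a standard curve
#'
#' Ordinary least-squares regression of known concentration on absorbance
#' (>= 3 standards), used to map kinetic absorbance readings onto
#' concentrations, e.g. the complex I dye standards (0-100 nM at 600 nm) or
#' Bradford protein standards.
#'
#' @param concentrations Known standard concentrations.
#' @param absorbances Measured absorbances of the standards.
#' @return List of class `methdev_stdcurve` with `slope`, `intercept`,
#'   `range` and a `predict(absorbance)` closure.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  stopifnot(length(concentrations) == length(absorbances))
  if (length(concentrations) < 3) {
    stop("a standard curve needs >= 3 standards", call. = FALSE)
  }
  fit <- lm(concentrations ~ absorbances)
  b <- unname(coef(fit))
  structure(list(
    intercept = b[1], slope = b[2],
    range = range(concentrations),
    fit = fit,
    predict = function(absorbance) b[1] + b[2] * absorbance
  ), class = "methdev_stdcurve")
}

#' Net complex I enzymatic activity
#'
#' Converts the two kinetic absorbance series (with and without the
#' inhibitor rotenone) to dye concentrations via the standard curve,
#' estimates the concentration change per second in each series, and
#' returns the rotenone-sensitive activity
#' `((dC/dt)_without - (dC/dt)_with) * D / protein_mass` in mU per ug,
#' where the protein mass is concentration x loaded volume. The rate is
#' the OLS slope of concentration on time by default (`method =
#' "first_last"` reproduces the two-point version). Negative net activity
#' is permitted and flagged with a warning (inhibitor-insensitive signal).
#'
#' @param minus_rotenone,plus_rotenone Tibbles `time_s`, `a600` on the same
#'   strictly increasing time grid (e.g. 34 s steps up to 374 s).
#' @param curve A `methdev_stdcurve`.
#' @param protein_conc Mitochondrial protein concentration (ug/uL).
#' @param volume_ul Loaded volume (uL); protein mass = conc x volume.
#' @param dilution Dilution factor D.
#' @param method Rate estimator: OLS `"slope"` (default) or `"first_last"`.
#' @return Net activity (mU/ug), a single number.
#' @export
net_complex1_activity <- function(minus_rotenone, plus_rotenone, curve,
                                  protein_conc = 0.66, volume_ul = 2,
                                  dilution = 1,
                                  method = c("slope", "first_last")) {
  method <- match.arg(method)
  stopifnot(protein_conc > 0, volume_ul > 0, dilution > 0)
  for (s in list(minus_rotenone, plus_rotenone)) {
    stopifnot(all(c("time_s", "a600") %in% names(s)))
    if (any(diff(s$time_s) <= 0)) {
      stop("timepoints must be strictly increasing", call. = FALSE)
    }
  }
  if (!identical(as.numeric(minus_rotenone$time_s),
                 as.numeric(plus_rotenone$time_s))) {
    stop("the two series must share the same time grid", call. = FALSE)
  }
  rate <- function(s) {
    conc <- curve$predict(s$a600)
    if (method == "slope") {
      unname(coef(lm(conc ~ s$time_s))[2])
    } else {
      (conc[length(conc)] - conc[1]) / (s$time_s[length(conc)] - s$time_s[1])
    }
  }
  mass_ug <- protein_conc * volume_ul
  act <- (rate(minus_rotenone) - rate(plus_rotenone)) * dilution / mass_ug
  if (act < 0) warning("negative net activity: inhibitor-insensitive signal",
                       call. = FALSE)
  act
}

#' Two-way ANOVA group comparison with Sidak-adjusted contrasts
#'
#' Standard two-way ANOVA of activity on genotype, a second factor and
#' their interaction, plus pairwise genotype contrasts within each level of
#' the second factor using the pooled residual variance, Sidak-adjusted
#' (adjusted p = 1 - (1 - p)^m over the m contrasts).
#'
#' @param activities Numeric response vector.
#' @param genotypes Factor-like vector (two levels).
#' @param group Second factor (e.g. timepoint or sex).
#' @return List with `anova` (tidy table: `term`, `df`, `F`, `p`) and
#'   `contrasts` (per level of `group`: `estimate`, `p`, `p_sidak`).
#' @export
compare_groups <- function(activities, genotypes, group) {
  d <- tibble::tibble(y = activities, g = factor(genotypes),
                      t = factor(group))
  two_way <- nlevels(d$t) > 1
  fit <- if (two_way) aov(y ~ g * t, data = d) else aov(y ~ g, data = d)
  a <- summary(fit)[[1]]
  atab <- tibble::tibble(
    term = trimws(rownames(a)[-nrow(a)]),
    df = a$Df[-nrow(a)], F = a$`F value`[-nrow(a)],
    p = a$`Pr(>F)`[-nrow(a)]
  )
  mse <- a$`Mean Sq`[nrow(a)]
  dfres <- a$Df[nrow(a)]
  lv <- levels(d$g)
  contr <- purrr::map_dfr(levels(d$t), function(tl) {
    y1 <- d$y[d$g == lv[1] & d$t == tl]
    y2 <- d$y[d$g == lv[2] & d$t == tl]
    if (length(y1) == 0 || length(y2) == 0) return(tibble::tibble())
    est <- mean(y2) - mean(y1)
    se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
    p <- if (se > 0) {
      2 * pt(abs(est / se), dfres, lower.tail = FALSE)
    } else if (abs(est) > 0) 0 else 1
    tibble::tibble(group = tl, estimate = est, p = p)
  })
  m <- nrow(contr)
  contr$p_sidak <- 1 - (1 - contr$p)^m
  list(anova = atab, contrasts = contr)
}

#' @importFrom stats aov
NULL
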