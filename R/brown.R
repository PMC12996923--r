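#' Combine dependent P values with the Empirical Brown's method
#'
#' Extends Fisher's combination of k P values to dependent tests by
#' estimating the covariance of the transformed statistics from the raw
#' data used in those tests. For each test i with data row x_i over n
#' samples, the row is standardised and transformed through its empirical
#' CDF: w_i(s) = -2 ln(F_i(x_i(s))), where F_i assigns rank/n in (0, 1]
#' (right-continuous, so log(0) never occurs). The Fisher statistic
#' Psi = -2 sum ln p_i has nominal mean 2k; its variance is estimated as
#' 4k + 2 * sum_{i<j} cov(w_i, w_j). Psi is then referred to a scaled
#' chi-square with df = 2 (2k)^2 / var and scale c = var / (2 * 2k); when
#' the estimated variance falls below the independent value 4k, the method
#' degrades gracefully to Fisher (c = 1, df = 2k).
#'
#' With fully dependent rows the covariance sums to var(w) per pair, the
#' effective number of tests approaches one, and the combined P of k
#' identical tests returns approximately their shared single-test P. For
#' k = 1 the input P is returned unchanged.
#'
#' @param p_values Numeric vector of raw P values in (0, 1].
#' @param data_rows Numeric matrix, one row per test (same order as
#'   `p_values`), columns = samples; the data the dependence is estimated
#'   from.
#' @return Single combined P value.
#' @export
brown_combine <- function(p_values, data_rows) {
  k <- length(p_values)
  stopifnot(k >= 1, all(p_values > 0 & p_values <= 1))
  if (k == 1) return(p_values)
  data_rows <- as.matrix(data_rows)
  if (nrow(data_rows) != k) {
    stop("data_rows must have one row per p value", call. = FALSE)
  }
  w <- brown_transform(data_rows)
  cw <- cov(t(w))
  var_psi <- 4 * k + 2 * sum(cw[upper.tri(cw)])
  psi <- -2 * sum(log(p_values))
  mean_psi <- 2 * k
  if (var_psi <= mean_psi * 2) {            # at or below independence: Fisher
    return(pchisq(psi, df = 2 * k, lower.tail = FALSE))
  }
  f <- 2 * mean_psi^2 / var_psi
  c_scale <- var_psi / (2 * mean_psi)
  pchisq(psi / c_scale, df = f, lower.tail = FALSE)
}

# -2 log empirical CDF transform of standardised rows; returns k x n matrix
brown_transform <- function(data_rows) {
  t(apply(data_rows, 1, function(x) {
    s <- sd(x)
    if (s == 0) {
      ## degenerate row: constant, carries no dependence information
      rep(-2 * log(1), length(x))
    } else {
      z <- (x - mean(x)) / s
      -2 * log(rank(z, ties.method = "max") / length(z))
    }
  }))
}

#' Fisher's combination of independent P values
#'
#' Reference combination used as an oracle and as the fallback of
#' [brown_combine()] under estimated independence:
#' P = upper tail of chi-square_{2k} at -2 sum ln p_i.
#'
#' @param p_values Numeric vector of P values in (0, 1].
#' @return Combined P value.
#' @export
fisher_combine <- function(p_values) {
  k <- length(p_values)
  stopifnot(k >= 1, all(p_values > 0 & p_values <= 1))
  pchisq(-2 * sum(log(p_values)), df = 2 * k, lower.tail = FALSE)
}
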