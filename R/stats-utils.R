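#' Benjamini-Hochberg step-up significance flags
#'
#' Applies the Benjamini-Hochberg false-discovery-rate step-up procedure to a
#' family of p-values and returns logical significance flags.  The family is
#' intended to be the set of predictor tests sharing one outcome variable;
#' group p-values per outcome before calling.
#'
#' Sorted p-values \eqn{p_{(1)} \le \dots \le p_{(m)}} are flagged up to
#' \eqn{k = \max\{ j : p_{(j)} \le j\alpha/m \}}; all flags are \code{FALSE}
#' when no such \eqn{j} exists.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha target false-discovery rate (default 0.05).
#' @return logical vector, same length and order as \code{p}.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0 & p <= 1),
            length(alpha) == 1L, alpha > 0, alpha < 1)
  m <- length(p)
  if (m == 0L) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  pass <- which(ps <= seq_len(m) * alpha / m)
  flags <- logical(m)
  if (length(pass)) flags[ord[seq_len(max(pass))]] <- TRUE
  flags
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' Sample Pearson correlation with the exact t-based two-sided p-value on
#' \code{n - 2} degrees of freedom for the null of zero correlation.
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite values.
#' @return list with elements \code{r}, \code{p}, \code{n}.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L, all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0)
    stop("pearson_with_p: zero variance in input")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Z-score a measurement against reference-population constants
#'
#' Computes \code{(value - mean) / sd} with reference mean and SD looked up
#' from a user-supplied configuration table keyed by measure name and sex.
#' Reference constants (e.g. normal ventricular volumes, mass, ejection
#' fraction) are supplied by the caller and are never embedded in the package.
#'
#' @param value numeric measurement.
#' @param measure character, measure name as keyed in \code{reference}.
#' @param sex character, sex key as used in \code{reference}.
#' @param reference data frame with columns \code{measure}, \code{sex},
#'   \code{mean}, \code{sd}.
#' @return numeric z-score.
#' @export
zscore_against_reference <- function(value, measure, sex, reference) {
  stopifnot(is.data.frame(reference),
            all(c("measure", "sex", "mean", "sd") %in% names(reference)))
  row <- reference[reference$measure == measure & reference$sex == sex, ]
  if (nrow(row) == 0L)
    stop(sprintf("no reference entry for measure '%s', sex '%s'", measure, sex))
  if (nrow(row) > 1L)
    stop(sprintf("ambiguous reference entry for measure '%s', sex '%s'",
                 measure, sex))
  if (row$sd <= 0) stop("reference sd must be > 0")
  (value - row$mean) / row$sd
}

#' Mean coefficient of variation for paired observer measurements
#'
#' Implements the paired-observation mean CoV: the sum over cases of the
#' two-observation standard deviation, divided by the absolute sum of the
#' per-case means,
#' \deqn{\mathrm{CoV} = \frac{\sum_i SD(x_{1i}, x_{2i})}
#'   {\left| \sum_i (x_{1i} + x_{2i})/2 \right|}.}
#' The per-case SD of two observations equals \eqn{|x_1 - x_2| / \sqrt{2}}.
#'
#' @param obs1,obs2 numeric vectors of paired measurements (observer 1 and 2).
#' @return mean CoV in percent.
#' @export
mean_cov <- function(obs1, obs2) {
  stopifnot(is.numeric(obs1), is.numeric(obs2),
            length(obs1) == length(obs2), length(obs1) >= 1L,
            all(is.finite(obs1)), all(is.finite(obs2)))
  denom <- sum((obs1 + obs2) / 2)
  if (denom == 0) stop("mean_cov: sum of per-case means is zero")
  100 * sum(abs(obs1 - obs2) / sqrt(2)) / abs(denom)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Bias is the mean paired difference; the limits of agreement are
#' bias +/- 1.96 times the sample standard deviation (divisor n - 1) of the
#' differences.
#'
#' @param obs1,obs2 numeric vectors of paired measurements, length >= 2.
#' @return list with \code{bias}, \code{loa_lower}, \code{loa_upper},
#'   \code{sd_diff}, \code{n}.
#' @export
bland_altman <- function(obs1, obs2) {
  stopifnot(is.numeric(obs1), is.numeric(obs2),
            length(obs1) == length(obs2), length(obs1) >= 2L,
            all(is.finite(obs1)), all(is.finite(obs2)))
  d <- obs1 - obs2
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}
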