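#' Shift a response vector for a gamma fit
#'
#' Gamma GLMs require strictly positive responses; metrics that span zero
#' are shifted up before fitting and predictions are shifted back. The
#' shift is `-min(y) + 0.001 * range(y)` when `min(y) <= 0`, else 0.
#'
#' @param y numeric response vector (finite).
#' @return list with `yShifted` and `shift`.
#' @examples
#' shiftForGamma(c(-2, 3, 8))$shift  # 2.01
#' @export
shiftForGamma <- function(y) {
  stopifnot(all(is.finite(y)))
  if (min(y) > 0) return(list(yShifted = y, shift = 0))
  rg <- diff(range(y))
  if (rg == 0)
    stop("constant non-positive response: no shift can make it gamma-fittable")
  shift <- -min(y) + 1e-3 * rg
  list(yShifted = y + shift, shift = shift)
}

#' Fit a pH-response generalized linear model
#'
#' Gaussian with identity link (ordinary least squares) or Gamma with log
#' link (iteratively reweighted least squares); responses that are not
#' strictly positive are shifted via [shiftForGamma] before a gamma fit and
#' the shift is recorded so predictions can be returned on the original
#' scale. The slope p-value is the Wald test from the fit summary.
#'
#' @param ph numeric pH values.
#' @param y responses (same length, n >= 3).
#' @param family "gaussian_identity" or "gamma_log".
#' @param maxIter IRLS iteration cap (non-convergence is an error).
#' @return A [GLMResult-class].
#' @seealso [predictResponse], [netZeroPh]
#' @export
fitPhGlm <- function(ph, y, family = c("gaussian_identity", "gamma_log"),
                     maxIter = 100) {
  family <- match.arg(family)
  stopifnot(length(ph) == length(y), all(is.finite(ph)), all(is.finite(y)))
  if (length(y) < 3) stop("at least 3 observations are required")
  shift <- 0
  if (family == "gamma_log") {
    sh <- shiftForGamma(y)
    y <- sh$yShifted
    shift <- sh$shift
    fit <- stats::glm(y ~ ph, family = stats::Gamma(link = "log"),
                      control = list(maxit = maxIter, epsilon = 1e-8))
    if (!fit$converged)
      stop("gamma IRLS did not converge in ", maxIter, " iterations")
  } else {
    fit <- stats::glm(y ~ ph, family = stats::gaussian())
  }
  sm <- summary(fit)$coefficients
  new("GLMResult", family = family,
      coefficients = unname(coef(fit)), se = unname(sm[, 2]),
      pValue = unname(sm[2, 4]), shift = shift, n = length(y), fit = fit)
}

#' Predict from a fitted pH-response model on the original scale
#'
#' @param result a [GLMResult-class].
#' @param ph pH values to predict at.
#' @return Predicted responses; gamma predictions are back-shifted to the
#'   original scale.
#' @export
predictResponse <- function(result, ph) {
  stopifnot(is(result, "GLMResult"))
  eta <- result@coefficients[1] + result@coefficients[2] * ph
  if (result@family == "gamma_log") exp(eta) - result@shift else eta
}

#' Compare a functional-group metric between two reef sites
#'
#' Two-sided, two-sample tests: `"wilcoxon"` is the rank-sum test (exact
#' enumeration when both groups have at most 8 observations and no ties;
#' with ties it falls back to the normal approximation with a warning),
#' `"welch_t"` is the unequal-variance t-test with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param valuesA,valuesB metric values from the two sites (each n >= 2).
#' @param test "wilcoxon" or "welch_t".
#' @return list with `statistic`, `pValue`, `test` and (for welch_t) `df`.
#' @examples
#' compareSites(c(4, 5, 6), c(1, 2, 3))$pValue  # exact 2/choose(6,3)*2 = 0.1
#' @export
compareSites <- function(valuesA, valuesB, test = c("wilcoxon", "welch_t")) {
  test <- match.arg(test)
  stopifnot(length(valuesA) >= 2, length(valuesB) >= 2)
  if (test == "wilcoxon") {
    exact <- length(valuesA) <= 8 && length(valuesB) <= 8
    ht <- stats::wilcox.test(valuesA, valuesB, exact = exact,
                             alternative = "two.sided")
    list(statistic = unname(ht$statistic), pValue = ht$p.value,
         test = "wilcoxon")
  } else {
    ht <- stats::t.test(valuesA, valuesB, var.equal = FALSE,
                        alternative = "two.sided")
    list(statistic = unname(ht$statistic), pValue = ht$p.value,
         df = unname(ht$parameter), test = "welch_t")
  }
}

#' pH at which pooled 24-h net calcification crosses zero
#'
#' Fits a gaussian identity GLM to the pooled 24-h calcification responses
#' (they span both signs, which rules out an unshifted gamma) and solves
#' the fitted line for zero. The confidence interval is a case-resampling
#' percentile bootstrap, seed-reproducible.
#'
#' @param ph pooled pH values (n >= 6).
#' @param g24 pooled 24-h calcification rates; must span both signs.
#' @param nBoot bootstrap replicates (>= 1000 recommended).
#' @param seed RNG seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @return A [CrossingEstimate-class].
#' @examples
#' tab <- makePhResponseTable(-39, 5, n = 60, noiseSd = 0.2, seed = 7)
#' netZeroPh(tab$ph, tab$response, nBoot = 200, seed = 1)
#' @export
netZeroPh <- function(ph, g24, nBoot = 1000, seed = 1L, level = 0.95) {
  stopifnot(length(ph) == length(g24))
  n <- length(ph)
  if (n < 6) stop("at least 6 pooled observations are required")
  if (all(g24 > 0) || all(g24 < 0))
    stop("responses do not span both signs (all ",
         if (all(g24 > 0)) "positive" else "negative",
         "): no crossing exists in the data")
  olsRoot <- function(x, y) {
    b1 <- stats::cov(x, y) / stats::var(x)
    b0 <- mean(y) - b1 * mean(x)
    -b0 / b1
  }
  root <- olsRoot(ph, g24)
  if (!is.finite(root) || root < min(ph) || root > max(ph)) {
    predSigns <- sign(mean(g24[ph <= stats::median(ph)])) *
      sign(mean(g24[ph > stats::median(ph)]))
    stop(sprintf(
      "fitted prediction has no root inside the observed pH range [%.3f, %.3f] (fitted crossing %.3f; low/high prediction sign product %d)",
      min(ph), max(ph), root, predSigns))
  }
  set.seed(seed)
  roots <- vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    olsRoot(ph[idx], g24[idx])
  }, numeric(1))
  roots <- roots[is.finite(roots)]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(roots, c(alpha, 1 - alpha), names = FALSE)
  new("CrossingEstimate", phAtZero = root,
      ciLow = min(ci[1], root), ciHigh = max(ci[2], root),
      nPooled = as.integer(n), nBoot = as.integer(nBoot))
}
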