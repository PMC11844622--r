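# Group-level statistics: bootstrap confidence intervals and between-method
# comparisons (one-way ANOVA + Tukey HSD).

#' Bootstrap confidence interval for a mean
#'
#' Percentile bootstrap or bias-corrected and accelerated (BCa) interval,
#' 10,000 resamples by default, seeded. A constant sample yields a
#' zero-width interval with a warning.
#'
#' @param samples numeric vector (n >= 2).
#' @param nIter bootstrap iterations (default 10000).
#' @param method "bca" (default) or "percentile".
#' @param conf confidence level (default 0.95).
#' @param seed resampling seed.
#' @return numeric c(low, high).
#' @examples
#' bootstrapCI(rnorm(50), nIter = 2000, seed = 1)
#' @export
bootstrapCI <- function(samples, nIter = 10000L,
                        method = c("bca", "percentile"), conf = 0.95,
                        seed = 1L) {
  method <- match.arg(method)
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (diff(range(samples)) == 0) {
    warning("constant sample: zero-width interval")
    return(c(samples[1], samples[1]))
  }
  rng <- localRNG(seed)
  est <- mean(samples)
  boots <- rng$sample(n, n * nIter, replace = TRUE)
  bootMeans <- colMeans(matrix(samples[boots], nrow = n))
  alpha <- (1 - conf) / 2
  if (method == "percentile") {
    return(unname(stats::quantile(bootMeans, c(alpha, 1 - alpha))))
  }
  ## BCa: bias correction from the bootstrap distribution, acceleration
  ## from the jackknife skewness of the mean.
  z0 <- stats::qnorm(mean(bootMeans < est))
  if (!is.finite(z0)) z0 <- 0
  jack <- (sum(samples) - samples) / (n - 1)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  unname(stats::quantile(bootMeans, c(adj(zlo), adj(zhi))))
}

#' Compare methods with one-way ANOVA and Tukey HSD
#'
#' For each metric, tests the null hypothesis that all methods share the
#' same mean (one-way ANOVA), followed by Tukey's honestly significant
#' difference test for all pairwise comparisons at the requested alpha.
#'
#' @param values numeric vector of per-image metric values.
#' @param groups factor/character of the same length labelling the method
#'   of each value (>= 2 groups, each with >= 2 values).
#' @param alpha significance level (default 0.05).
#' @return list with \code{fStatistic}, \code{pValue}, and \code{tukey}
#'   (data.frame: pair, diff, low, high, pAdj, significant).
#' @export
compareMethods <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("need at least 2 groups to compare", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      low = tk[, "lwr"], high = tk[, "upr"],
                      pAdj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(fStatistic = an[["F value"]][1], pValue = an[["Pr(>F)"]][1],
       tukey = tukey)
}
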