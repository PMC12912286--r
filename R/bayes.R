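# Directional Jeffreys-Zellner-Siow (JZS) Bayes-factor t-tests.

# Marginal likelihood ratio for the JZS t-test, integrating the noncentral-t
# likelihood over the Cauchy prior on the standardized effect. One-sided
# variants truncate (and renormalize) the prior to a half-line.
bf_jzs_t <- function(t, n1, n2 = NULL,
                     direction = c("two.sided", "positive", "negative"),
                     rscale = sqrt(2) / 2, rel_tol = 1e-8) {
  direction <- match.arg(direction)
  if (is.null(n2)) {
    df <- n1 - 1; neff <- n1
  } else {
    df <- n1 + n2 - 2; neff <- n1 * n2 / (n1 + n2)
  }
  stopifnot(df >= 1, is.finite(t))
  lik <- function(d) suppressWarnings(stats::dt(t, df, ncp = d * sqrt(neff)))
  center <- max(1, abs(t) / sqrt(neff))
  int2 <- function(f, lo, hi) {
    stats::integrate(f, lo, hi, rel.tol = rel_tol,
                     stop.on.error = FALSE)$value
  }
  if (direction == "two.sided") {
    f <- function(d) lik(d) * stats::dcauchy(d, 0, rscale)
    m1 <- int2(f, -Inf, -center) + int2(f, -center, 0) +
      int2(f, 0, center) + int2(f, center, Inf)
  } else {
    sgn <- if (direction == "positive") 1 else -1
    f <- function(d) lik(sgn * d) * 2 * stats::dcauchy(d, 0, rscale)
    m1 <- int2(f, 0, center) + int2(f, center, Inf)
  }
  m0 <- stats::dt(t, df)
  m1 / m0
}

#' Directional one-sample Bayes-factor t-test
#'
#' JZS default Bayes factor for a one-sample t-test against zero, with a
#' Cauchy prior of scale `sqrt(2)/2` on the standardized effect, truncated
#' to the requested direction (one-tailed). `bf10` quantifies evidence for
#' the directional alternative over the point null.
#'
#' @param x Numeric sample (e.g. one beta per subject).
#' @param direction `"positive"`, `"negative"` or `"two.sided"`.
#' @param rscale Cauchy prior scale.
#' @return A `bf_result`: list with `bf10`, `t`, `n`, `direction`.
#' @export
bf_one_sample <- function(x, direction = c("positive", "negative",
                                           "two.sided"),
                          rscale = sqrt(2) / 2) {
  direction <- match.arg(direction)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate sample: zero variance")
  t <- mean(x) / (s / sqrt(n))
  structure(list(bf10 = bf_jzs_t(t, n, direction = direction,
                                 rscale = rscale),
                 t = t, n = n, direction = direction),
            class = "bf_result")
}

#' Directional two-sample Bayes-factor t-test
#'
#' Independent-samples JZS Bayes factor (pooled variance) for the difference
#' `mean(x) - mean(y)`, with directional prior truncation as in
#' [bf_one_sample()].
#'
#' @param x,y Numeric samples.
#' @param direction Direction of the alternative for `mean(x) - mean(y)`.
#' @param rscale Cauchy prior scale.
#' @return A `bf_result` with `n1`, `n2`.
#' @export
bf_two_sample <- function(x, y, direction = c("positive", "negative",
                                              "two.sided"),
                          rscale = sqrt(2) / 2) {
  direction <- match.arg(direction)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3 || n2 < 3) stop("need at least 3 observations per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("degenerate samples: zero pooled variance")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(list(bf10 = bf_jzs_t(t, n1, n2, direction = direction,
                                 rscale = rscale),
                 t = t, n1 = n1, n2 = n2, direction = direction),
            class = "bf_result")
}

#' Evidence category of a Bayes factor
#'
#' Conventional interpretation bands for `BF10`: `(1, 3]` weak, `(3, 10]`
#' positive, `(10, 100]` strong, `> 100` decisive evidence for the
#' alternative; values at or below 1 favour the null (`(1/3, 1]` weak,
#' `(0.01, 1/3]` positive, `(0.001, 0.01]` strong, `<= 0.001` decisive).
#'
#' @param bf10 Numeric vector of Bayes factors.
#' @return Character vector of categories.
#' @export
bf_category <- function(bf10) {
  stopifnot(all(bf10 > 0))
  cut(bf10,
      breaks = c(0, 0.001, 0.01, 1 / 3, 1, 3, 10, 100, Inf),
      labels = c("decisive_null", "strong_null", "positive_null",
                 "weak_null", "weak", "positive", "strong", "decisive"),
      right = TRUE) |> as.character()
}
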