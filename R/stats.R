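# Trend and group-comparison statistics used to summarize combination
# sweeps: Spearman trend with t-approximation P, the two-sided
# Brunner-Munzel test, Fisher's method for aggregating P-values, the
# two-proportion z test, and Bonferroni adjustment.

#' Spearman correlation with a t-approximation P-value
#'
#' Rank correlation with mid-ranks for ties; the two-sided P-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (pairs with missing values dropped).
#' @return List `(rho, p, n)`; `rho` is `NA` when fewer than 3 complete
#'   pairs or zero variance.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p = r_to_pvalue(rho, n), n = n)
}

#' Two-sided Brunner-Munzel test
#'
#' Rank-based studentized test of the stochastic superiority
#' `P(X < Y) + 0.5 P(X = Y)` against 0.5, with Satterthwaite-style
#' t-approximation degrees of freedom.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return List `(statistic, p, estimate, df)`; `estimate` is the
#'   stochastic superiority of `y` over `x`.
#' @export
brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("both samples must have >= 2 values")
  r <- rank(c(x, y), ties.method = "average")
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  r1i <- rank(x, ties.method = "average")
  r2i <- rank(y, ties.method = "average")
  m1 <- mean(r1); m2 <- mean(r2)
  pst <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - r1i - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - r2i - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (n1 * v1 + n2 * v2 == 0) {
    if (m1 == m2) {
      # all values tied across both samples: no evidence either way
      return(list(statistic = 0, p = 1, estimate = pst, df = NA_real_))
    }
    stop("degenerate variance in Brunner-Munzel samples")
  }
  statistic <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(n1 * v1 + n2 * v2)
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  list(statistic = statistic, p = 2 * stats::pt(-abs(statistic), df),
       estimate = pst, df = df)
}

#' Fisher's method for combining independent P-values
#'
#' `chi^2 = -2 sum(log p)` on `2k` degrees of freedom.
#'
#' @param p_values Numeric vector of P-values in `(0, 1]`.
#' @return List `(chisq, df, p)`.
#' @export
fishers_method <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) return(list(chisq = NA_real_, df = 0L,
                                          p = NA_real_))
  if (any(p_values <= 0 | p_values > 1)) stop("P-values must lie in (0, 1]")
  chisq <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Two-proportion z test (no continuity correction)
#'
#' @param x1,n1 Successes and trials in the first group.
#' @param x2,n2 Successes and trials in the second group.
#' @return List `(statistic, p)`; two-sided P from the standard z
#'   statistic under the pooled-proportion null.
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1L || n2 < 1L) stop("need at least one trial per group")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(statistic = 0, p = 1))
  z <- (p1 - p2) / se
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni adjustment
#' @param p_values Numeric vector.
#' @return Adjusted P-values (multiplied by the test count, capped at 1).
#' @export
bonferroni_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "bonferroni")
}
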