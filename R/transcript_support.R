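# Two-proportion U test for transcriptome support of PPS predictions:
# compares the fraction of PPSs with transcript evidence downstream of
# their putative start against the same fraction at random genomic
# positions.

#' Two-proportion U statistic
#'
#' \deqn{U = \frac{m_1/n_1 - m_2/n_2}
#'   {\sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)}}, \quad
#'   \hat p = \frac{m_1 + m_2}{n_1 + n_2}}
#' the pooled-variance two-proportion z statistic (no continuity
#' correction).
#'
#' @param m1,n1 supported count and total for the PPS group.
#' @param m2,n2 supported count and total for the random-position group.
#' @return the U statistic.
#' @export
u_statistic <- function(m1, n1, m2, n2) {
  stopifnot(n1 > 0, n2 > 0, m1 >= 0, m2 >= 0, m1 <= n1, m2 <= n2)
  p <- (m1 + m2) / (n1 + n2)
  if (p <= 0 || p >= 1)
    stop("pooled proportion is 0 or 1; U is undefined")
  (m1 / n1 - m2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

#' Decide the two-sided support test
#'
#' Rejects the null hypothesis of equal support proportions when
#' |U| exceeds the standard-normal quantile at 1 - alpha/2.
#'
#' @param U the statistic from [u_statistic()].
#' @param alpha significance level in (0, 1).
#' @return list: \code{U}, \code{critical}, \code{alpha}, \code{reject},
#'   \code{decision} ("reject H0" / "fail to reject H0").
#' @export
decide_support <- function(U, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  crit <- qnorm(1 - alpha / 2)
  reject <- abs(U) > crit
  list(U = U, critical = crit, alpha = alpha, reject = reject,
       decision = if (reject) "reject H0" else "fail to reject H0")
}

#' Transcriptome-support test from counts
#'
#' Convenience wrapper: computes U and the decision in one call.
#'
#' @inheritParams u_statistic
#' @param alpha significance level.
#' @return as [decide_support()].
#' @export
u_test <- function(m1, n1, m2, n2, alpha = 0.05)
  decide_support(u_statistic(m1, n1, m2, n2), alpha)
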