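#' Analytic power of the two-sample t-test
#'
#' Exact power for detecting a standardized mean difference (Cohen's d)
#' between two groups of equal size, from the noncentral t
#' distribution with `2n - 2` degrees of freedom and noncentrality
#' `d * sqrt(n / 2)`. For a two-tailed test both rejection regions are
#' summed.
#'
#' @param n_per_group sample size per group (>= 2).
#' @param d standardized effect size (Cohen's d).
#' @param alpha significance level, in (0, 1).
#' @param tails `"two"` (default) or `"one"` (directional hypothesis).
#' @return the power, a number in \[0, 1\].
#' @examples
#' t_test_power(66, 0.5, alpha = 0.05, tails = "one")
#' @export
t_test_power <- function(n_per_group, d, alpha = 0.05,
                         tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (n_per_group < 2) stop("t_test_power: need n_per_group >= 2")
  stopifnot(alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (tails == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  } else {
    tc <- qt(1 - alpha / 2, df)
    (1 - pt(tc, df, ncp = ncp)) + pt(-tc, df, ncp = ncp)
  }
}
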