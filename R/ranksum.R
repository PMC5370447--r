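#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Computes the rank-sum statistic of `x` against `y` and a p-value under the
#' permutation null. For group sizes of at most 10 on both sides the p-value
#' is exact: every assignment of the pooled observations to the two groups is
#' enumerated, so ties are handled without approximation. For larger groups
#' the normal approximation with the usual tie correction and a continuity
#' correction of 1/2 is used.
#'
#' Two-sided p-values double the smaller tail probability, capped at 1.
#'
#' @param x,y Numeric vectors of observations for the two groups.
#' @param alternative One of `"greater"` (x tends larger), `"less"`, or
#'   `"two.sided"`.
#' @param exact_max Largest group size for which the exact enumeration is
#'   used (default 10).
#' @return A list with `statistic` (rank sum of `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' rank_sum_test(c(3, 4, 5), c(0, 1, 2), "greater")$p_value # 1/20
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                          exact_max = 10L) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1, length(y) >= 1)
  if (anyNA(x) || anyNA(y)) stop("rank_sum_test: missing values not allowed")
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])

  if (max(nx, ny) <= exact_max) {
    combos <- utils::combn(nx + ny, nx)
    w_all <- colSums(matrix(r[combos], nrow = nx))
    eps <- 1e-9
    p_greater <- mean(w_all >= w_obs - eps)
    p_less <- mean(w_all <= w_obs + eps)
    method <- "exact"
  } else {
    n <- nx + ny
    mu <- nx * (n + 1) / 2
    ties <- table(pooled)
    tie_corr <- sum(ties^3 - ties) / ((n) * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      # all observations identical: statistic is its null mean
      p_greater <- 1
      p_less <- 1
    } else {
      sd0 <- sqrt(sigma2)
      p_greater <- stats::pnorm((w_obs - mu - 0.5) / sd0, lower.tail = FALSE)
      p_less <- stats::pnorm((w_obs - mu + 0.5) / sd0, lower.tail = TRUE)
    }
    method <- "normal"
  }
  p <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two.sided = min(1, 2 * min(p_greater, p_less))
  )
  list(statistic = w_obs, p_value = min(1, max(p, .Machine$double.xmin)),
       method = method)
}

#' Exact two-sided binomial test by tail doubling
#'
#' P-value for observing `k` successes in `n` trials at null proportion `p0`,
#' two-sided by doubling the smaller exact tail probability and capping at 1.
#'
#' @param k Observed success count.
#' @param n Number of trials.
#' @param p0 Null success probability, strictly inside (0, 1).
#' @return The two-sided p-value.
#' @examples
#' binom_twosided(4, 4, 0.5) # 0.125
#' @export
binom_twosided <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, n >= 1)
  if (p0 <= 0 || p0 >= 1) stop("binom_twosided: p0 must be in (0, 1)")
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}
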