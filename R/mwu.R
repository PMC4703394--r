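#' Mann-Whitney U test on per-site insertion counts
#'
#' Two-sided rank-sum comparison of two count vectors over the same set of
#' TA sites (zeros included as observations). For small samples the p-value
#' is computed exactly by dynamic programming over all `choose(n1+n2, n1)`
#' rank splits of the observed (mid-)ranks, which handles ties exactly; for
#' larger samples a normal approximation with tie correction and continuity
#' correction is used.
#'
#' The exact routine enumerates the conditional null distribution of the
#' rank sum given the observed tie pattern, so it agrees with brute-force
#' enumeration over rank splits for any data, tied or not.
#'
#' @param x,y Numeric vectors (reference and selected per-site counts).
#' @param exact Use the exact distribution; default when both samples have
#'   at most `exact_max_n` observations.
#' @param exact_max_n Sample-size threshold for the exact default.
#' @return A list with `statistic` (U for the `x` sample, in `[0, n1*n2]`),
#'   `p.value`, and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_u(c(5, 7, 6, 8), c(0, 0, 0, 0))
mann_whitney_u <- function(x, y, exact = NULL, exact_max_n = 8) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) tn_stop("mann_whitney_u: empty sample")
  if (is.null(exact)) exact <- (n1 <= exact_max_n && n2 <= exact_max_n)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- if (exact) mwu_p_exact(r, n1) else mwu_p_normal(c(x, y), r, n1, n2)
  list(statistic = U, p.value = p, method = if (exact) "exact" else "normal")
}

## Exact two-sided p from the conditional rank-sum distribution.
## r: midranks of the pooled sample; n1: size of the first group.
## Doubling the midranks makes them integers; a DP over items counts, for
## each subset size j and doubled rank sum s, the number of j-subsets
## attaining s. Two-sided p sums all splits at least as far from the mean
## rank sum as observed.
mwu_p_exact <- function(r, n1) {
  N <- length(r)
  if (N > 100) tn_stop("exact Mann-Whitney enumeration limited to n1+n2 <= 100")
  r2 <- as.integer(round(2 * r))
  S <- sum(r2)
  f <- matrix(0, nrow = n1 + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  rows <- 2L:(n1 + 1L)
  for (i in seq_len(N)) {
    ri <- r2[i]
    ## simultaneous update: RHS is evaluated before assignment, so each
    ## item is used at most once per subset
    f[rows, (ri + 1L):(S + 1L)] <- f[rows, (ri + 1L):(S + 1L)] + f[rows - 1L, 1L:(S + 1L - ri)]
  }
  cnt <- f[n1 + 1L, ]
  mu2 <- n1 * (N + 1)                      # doubled mean rank sum
  w2 <- sum(r2[seq_len(n1)])
  dev <- abs(w2 - mu2)
  s_vals <- seq_along(cnt) - 1
  min(1, sum(cnt[abs(s_vals - mu2) >= dev - 1e-9]) / sum(cnt))
}

## Normal approximation with tie correction and continuity correction.
mwu_p_normal <- function(pooled, r, n1, n2) {
  N <- n1 + n2
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  t <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  if (z < 0) z <- 0
  min(1, 2 * pnorm(-z))
}
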