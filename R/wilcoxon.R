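#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The nonparametric two-group comparison used throughout NRP analysis (e.g.
#' treated vs. control plasma reductive capacity, oxidized vs. untreated
#' aliquot pairs). For combined sample sizes up to `exact_max` the exact null
#' distribution of the rank sum is computed by dynamic programming over all
#' \eqn{\binom{m+n}{m}} group assignments of the pooled (mid)ranks — exact
#' even in the presence of ties. Larger samples use the normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' The reported statistic is the Mann-Whitney U of group `a`
#' (`rank sum of a - n_a (n_a + 1) / 2`), matching the convention of
#' `stats::wilcox.test(a, b)`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param exact_max Largest combined sample size for the exact test
#'   (default 20).
#' @return Tibble with one row: `statistic` (U), `p_value` (two-sided),
#'   `method` (`"exact"` or `"normal_approximation"`), `n_a`, `n_b`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
compare_groups <- function(a, b, exact_max = 20L) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient data: each group needs at least 2 observations",
         call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("inputs must be finite", call. = FALSE)
  }
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  w_a <- sum(r[seq_len(m)])
  u <- w_a - m * (m + 1) / 2
  if (N <= exact_max) {
    p <- exact_ranksum_p(r, m, w_a)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- m * n / 2
    sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal_approximation"
  }
  tibble::tibble(statistic = u, p_value = p, method = method, n_a = m, n_b = n)
}

# Exact two-sided p for the rank sum of the first group: DP over doubled
# midranks (integers), counting subsets of size m by doubled-rank sum.
exact_ranksum_p <- function(r, m, w_a) {
  d <- as.integer(round(2 * r))       # doubled midranks are integers
  smax <- sum(d)
  # ways[k + 1, s + 1] = number of size-k subsets with doubled sum s
  ways <- matrix(0, nrow = m + 1L, ncol = smax + 1L)
  ways[1L, 1L] <- 1
  for (di in d) {
    kmax <- m
    for (k in kmax:1L) {
      nz <- which(ways[k, ] > 0)
      if (length(nz)) {
        ways[k + 1L, nz + di] <- ways[k + 1L, nz + di] + ways[k, nz]
      }
    }
  }
  counts <- ways[m + 1L, ]
  total <- sum(counts)
  w2 <- as.integer(round(2 * w_a))
  s <- seq_along(counts) - 1L
  p_lo <- sum(counts[s <= w2]) / total
  p_hi <- sum(counts[s >= w2]) / total
  min(1, 2 * min(p_lo, p_hi))
}
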