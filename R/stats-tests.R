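#' Two-sample Wilcoxon rank-sum test with a small-sample exact path
#'
#' For combined sample sizes up to `exact_max` the two-sided p-value is
#' computed by exact enumeration of all group assignments of the observed
#' values (handling ties through midranks), so small-sample p-values agree
#' with a brute-force permutation test. Larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max Largest combined size for the exact path (default 12).
#' @return A list with `statistic` (rank sum of `x`), `p_value` and
#'   `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)])
  if (n1 + n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    e_w <- n1 * (n1 + n2 + 1) / 2
    p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-12)
    return(list(statistic = w_obs, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  e_w <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v_w <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v_w <= 0) return(list(statistic = w_obs, p_value = 1, method = "normal"))
  z <- (w_obs - e_w - sign(w_obs - e_w) * 0.5) / sqrt(v_w)
  list(
    statistic = w_obs,
    p_value = min(1, 2 * stats::pnorm(-abs(z))),
    method = "normal"
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon convention). Up to
#' `exact_max` non-zero differences the two-sided p-value is computed by
#' exact enumeration of all sign patterns (valid with tied absolute
#' values); larger samples use the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_max Largest number of non-zero differences for the exact
#'   path (default 25; enumeration is over `2^n` sign patterns).
#' @return A list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_used` and `method`.
#' @export
signed_rank_test <- function(d, exact_max = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  e_v <- n * (n + 1) / 4
  if (n <= exact_max) {
    # Exact distribution of V over all 2^n sign patterns, by convolution.
    # Midranks are doubled so the support is integer (ranks are k or k.5).
    r2 <- as.integer(round(2 * r))
    dist <- c(1)  # probability mass (x 2^n) over support 0..sum(r2)
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist)
      dist <- c(dist, rep(0, ri)) + shifted
    }
    support <- seq_along(dist) - 1  # values of 2 * V
    dev <- abs(support / 2 - e_v)
    p <- sum(dist[dev >= abs(v_obs - e_v) - 1e-12]) / 2^n
    return(list(statistic = v_obs, p_value = p, n_used = n, method = "exact"))
  }
  ties <- table(r)
  v_v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v_obs - e_v - sign(v_obs - e_v) * 0.5) / sqrt(v_v)
  list(
    statistic = v_obs,
    p_value = min(1, 2 * stats::pnorm(-abs(z))),
    n_used = n,
    method = "normal"
  )
}
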