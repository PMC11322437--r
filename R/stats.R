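#' Exact two-sided Mann-Whitney test by full enumeration
#'
#' Computes the Mann-Whitney U statistic on mid-ranks and its exact
#' two-sided p-value by enumerating all `choose(na + nb, na)` assignments
#' of the pooled values to the two groups: p is the fraction of
#' assignments whose U deviates from its null mean `na * nb / 2` at least
#' as much as observed.  With two groups of six in complete separation
#' (every value of one group exceeding every value of the other) this
#' yields the minimum attainable p of 2/924 = 0.0022.
#'
#' @param a,b numeric vectors (1 to 12 values each; the exact enumeration
#'   regime).
#' @return A [TestResult-class] with method `mann_whitney_exact`.
#' @examples
#' round(exactMannWhitney(1:6, 7:12)@p_value, 4)  # 0.0022
#' @export
exactMannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(a) > 12 || length(b) > 12) {
    stop("exact enumeration supports at most 12 values per group")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))  # mid-ranks for ties
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  EU <- na * nb / 2
  idx <- combn(n, na)
  sums <- colSums(matrix(r[idx], nrow = na))
  U_all <- sums - na * (na + 1) / 2
  k <- sum(abs(U_all - EU) >= abs(U_obs - EU) - 1e-9)
  new("TestResult", statistic = U_obs, p_value = k / ncol(idx),
      method = "mann_whitney_exact", n_per_group = c(na, nb),
      n_extreme = k, n_total = ncol(idx))
}

# tie-corrected Kruskal-Wallis H from pooled values and group labels
kwStatistic <- function(values, grp) {
  N <- length(values)
  r <- rank(values)
  R <- tapply(r, grp, sum)
  ng <- tabulate(grp)
  H <- 12 / (N * (N + 1)) * sum(R^2 / ng) - 3 * (N + 1)
  tie <- table(values)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) return(0)  # all values identical
  H / C
}

# all assignments of N items into groups of the given sizes, as an integer
# label matrix (N x n_arrangements)
allGroupAssignments <- function(sizes) {
  N <- sum(sizes)
  recurse <- function(remaining, sizes_left, g) {
    if (length(sizes_left) == 1) {
      lab <- matrix(0L, N, 1)
      lab[remaining, 1] <- g
      return(lab)
    }
    picks <- combn(length(remaining), sizes_left[1])
    out <- vector("list", ncol(picks))
    for (j in seq_len(ncol(picks))) {
      chosen <- remaining[picks[, j]]
      rest <- recurse(setdiff(remaining, chosen), sizes_left[-1], g + 1L)
      rest[chosen, ] <- g
      out[[j]] <- rest
    }
    do.call(cbind, out)
  }
  recurse(seq_len(N), as.integer(sizes), 1L)
}

#' Kruskal-Wallis test with exact small-sample enumeration
#'
#' Computes the tie-corrected H statistic.  When the pooled sample size is
#' at most `exact_threshold` the p-value is exact: all distinct
#' assignments of the pooled values into groups of the observed sizes are
#' enumerated and p is the fraction with H at least as large as observed.
#' Larger samples use the chi-squared approximation with `k - 1` degrees
#' of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @param exact_threshold maximum pooled n for exact enumeration
#'   (default 12).
#' @return A [TestResult-class] with method `kruskal_wallis_exact` or
#'   `kruskal_wallis_chi2`.
#' @examples
#' kruskalWallisExact(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskalWallisExact <- function(groups, exact_threshold = 12L) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!lengths(groups))) stop("all groups must be non-empty")
  sizes <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_along(groups), sizes)
  N <- length(values)
  H_obs <- kwStatistic(values, grp)
  if (all(values == values[1])) {
    # degenerate: every value identical => H = 0, p = 1 by convention
    return(new("TestResult", statistic = 0, p_value = 1,
               method = "kruskal_wallis_exact",
               n_per_group = as.integer(sizes), n_extreme = 1,
               n_total = 1))
  }
  if (N <= exact_threshold) {
    lab <- allGroupAssignments(sizes)
    H_all <- apply(lab, 2, function(g) kwStatistic(values, g))
    k <- sum(H_all >= H_obs - 1e-9)
    new("TestResult", statistic = H_obs, p_value = k / ncol(lab),
        method = "kruskal_wallis_exact", n_per_group = as.integer(sizes),
        n_extreme = k, n_total = ncol(lab))
  } else {
    p <- pchisq(H_obs, df = length(groups) - 1, lower.tail = FALSE)
    new("TestResult", statistic = H_obs, p_value = p,
        method = "kruskal_wallis_chi2", n_per_group = as.integer(sizes),
        n_extreme = 0, n_total = 0)
  }
}
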