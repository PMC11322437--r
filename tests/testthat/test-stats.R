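# independent Mann-Whitney oracle: U by pairwise counting, p by
# enumerating all value-to-group assignments directly on the data
oracleMW <- function(a, b) {
  U_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  U_obs <- U_of(a, b)
  EU <- na * nb / 2
  idx <- combn(na + nb, na)
  U_all <- apply(idx, 2, function(sel) {
    U_of(pooled[sel], pooled[-sel])
  })
  list(U = U_obs,
       p = mean(abs(U_all - EU) >= abs(U_obs - EU) - 1e-9))
}

test_that("complete separation of 6 vs 6 gives the minimum exact p 0.0022", {
  t <- exactMannWhitney(c(10, 11, 12, 13, 14, 15), c(1, 2, 3, 4, 5, 6))
  expect_identical(t@method, "mann_whitney_exact")
  expect_equal(t@n_extreme, 2)
  expect_equal(t@n_total, choose(12, 6))
  expect_equal(round(t@p_value, 4), 0.0022)
})

test_that("degenerate and small exact Mann-Whitney cases are correct", {
  # identical multisets: every assignment at least as extreme
  expect_equal(exactMannWhitney(c(1, 2, 3), c(1, 2, 3))@p_value, 1)
  # complete separation at 3 vs 3: 2 of the 20 assignments
  expect_equal(exactMannWhitney(c(1, 2, 3), c(4, 5, 6))@p_value, 0.1)
  expect_error(exactMannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with an independent enumeration oracle", {
  withr::with_seed(42, {
    for (trial in 1:50) {
      na <- sample(2:5, 1); nb <- sample(2:5, 1)
      a <- sample(1:8, na, replace = TRUE)  # integer data with ties
      b <- sample(1:8, nb, replace = TRUE)
      mine <- exactMannWhitney(a, b)
      oracle <- oracleMW(a, b)
      expect_equal(mine@statistic, oracle$U)
      expect_equal(mine@p_value, oracle$p)
      # exact p is a ratio of integer counts in (0, 1]
      expect_equal(mine@p_value, mine@n_extreme / mine@n_total)
      expect_true(mine@p_value > 0 && mine@p_value <= 1)
      expect_equal(mine@n_extreme, round(mine@n_extreme))
    }
  })
})

test_that("Kruskal-Wallis H matches stats::kruskal.test including ties", {
  withr::with_seed(11, {
    for (trial in 1:10) {
      g <- lapply(1:3, function(i) sample(1:6, sample(4:8, 1),
                                          replace = TRUE))
      mine <- kruskalWallisExact(g, exact_threshold = 0)  # force chi2
      ref <- stats::kruskal.test(g)
      expect_equal(mine@statistic, unname(ref$statistic))
      expect_equal(mine@p_value, ref$p.value)
      expect_identical(mine@method, "kruskal_wallis_chi2")
    }
  })
})

test_that("exact Kruskal-Wallis enumeration matches a brute-force oracle", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  mine <- kruskalWallisExact(groups)
  expect_identical(mine@method, "kruskal_wallis_exact")
  expect_equal(mine@statistic, 7.2)
  # oracle: enumerate every assignment, scoring H with stats::kruskal.test
  pooled <- unlist(groups)
  sel1 <- combn(9, 3)
  count <- 0L; total <- 0L
  for (i in seq_len(ncol(sel1))) {
    rest <- setdiff(1:9, sel1[, i])
    sel2 <- combn(rest, 3)
    for (j in seq_len(ncol(sel2))) {
      g1 <- pooled[sel1[, i]]
      g2 <- pooled[sel2[, j]]
      g3 <- pooled[setdiff(rest, sel2[, j])]
      H <- unname(stats::kruskal.test(list(g1, g2, g3))$statistic)
      total <- total + 1L
      if (H >= mine@statistic - 1e-9) count <- count + 1L
    }
  }
  expect_identical(total, 1680L)
  expect_identical(count, 6L)   # the 3! block permutations
  expect_equal(mine@p_value, count / total)
})

test_that("degenerate Kruskal-Wallis inputs follow the stated conventions", {
  t <- kruskalWallisExact(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(t@statistic, 0)
  expect_equal(t@p_value, 1)
  expect_error(kruskalWallisExact(list(1:3)), "two groups")
  expect_error(kruskalWallisExact(list(1:3, numeric(0))), "non-empty")
})

test_that("two-group exact Kruskal-Wallis equals the exact Mann-Whitney p", {
  # with two groups H is a monotone function of |U - E[U]|, so the exact
  # tail sets coincide
  withr::with_seed(23, {
    for (trial in 1:5) {
      a <- sample(1:9, 4, replace = TRUE)
      b <- sample(1:9, 5, replace = TRUE)
      pkw <- kruskalWallisExact(list(a, b))@p_value
      pmw <- exactMannWhitney(a, b)@p_value
      expect_equal(pkw, pmw)
    }
  })
})
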