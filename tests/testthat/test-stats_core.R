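# Exact overlap statistics: tail probabilities, overlap test, BH, correlation.

test_that("hypergeometric upper tail matches enumeration on small cases", {
  # full enumeration of C(6,3) = 20 draws: P(X=2) = 9/20, P(X=3) = 1/20
  expect_equal(hypergeom_upper_tail(2, 3, 3, 6), 0.5, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(3, 3, 3, 6), 1 / 20, tolerance = 1e-12)
  # k = 0 covers the whole support for any valid margins
  expect_identical(hypergeom_upper_tail(0, 10, 5, 30), 1)
  expect_identical(hypergeom_upper_tail(0, 0, 0, 7), 1)
  # degenerate margins
  expect_equal(hypergeom_upper_tail(5, 5, 5, 5), 1)
})

test_that("pmf sums to one over its support", {
  cases <- list(c(3, 3, 6), c(10, 7, 25), c(50, 20, 60), c(0, 4, 9),
                c(124, 107, 5985))
  for (cs in cases) {
    pmf <- hypergeom_pmf(cs[1], cs[2], cs[3])
    expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  }
})

test_that("tails agree with brute-force enumeration across a small grid", {
  for (N in c(5, 12, 25)) {
    for (K in 0:N) for (n in 0:N) {
      ks <- max(0, K + n - N):min(K, n)
      mine <- hypergeom_upper_tail(ks, K, n, N)
      oracle <- vapply(ks, brute_upper_tail, numeric(1), K = K, n = n,
                       N = N)
      expect_equal(mine, oracle, tolerance = 1e-12)
    }
  }
})

test_that("tails agree with phyper at genome-scale margins", {
  set.seed(11)
  for (i in 1:50) {
    N <- sample(1e4:1e6, 1)
    K <- sample.int(min(N, 5000), 1)
    n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    # the log-space recurrence walks supports of ~1e5 terms here; allow
    # the accumulated rounding that implies (still far sub-ulp of any
    # scientific use).  Exactness to 1e-12 is asserted at N <= 60.
    expect_equal(hypergeom_upper_tail(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-8)
    expect_equal(hypergeom_lower_tail(k, K, n, N),
                 phyper(k, K, N - K, n),
                 tolerance = 1e-8)
  }
})

test_that("tail arguments are validated", {
  expect_error(hypergeom_upper_tail(4, 3, 3, 6), "min")
  expect_error(hypergeom_upper_tail(1, 7, 3, 6), "exceed")
  expect_error(hypergeom_upper_tail(-1, 3, 3, 6), "non-negative")
  expect_error(hypergeom_upper_tail(1, 3, 3, 0), "N")
})

test_that("overlap_test reproduces the conserved-ortholog worked example", {
  u <- sprintf("g%04d", 1:5985)
  st <- overlap_test(u[1:124], u[c(1:15, 1000:1091)], u)
  expect_identical(st$k, 15L)
  expect_equal(st$expected, 124 * 107 / 5985)
  expect_equal(st$fold, 15 / (124 * 107 / 5985), tolerance = 1e-12)
  expect_equal(st$fold, 6.77, tolerance = 0.001)
  expect_lt(st$p_value, 1e-8)
})

test_that("overlap_test handles degenerate and extreme sets", {
  u <- sprintf("g%02d", 1:40)
  disjoint <- overlap_test(u[1:10], u[11:20], u)
  expect_identical(disjoint$k, 0L)
  expect_identical(disjoint$fold, 0)
  expect_equal(disjoint$p_value, 1)
  full <- overlap_test(u, u, u)
  expect_identical(full$k, 40L)
  expect_equal(full$fold, 1)
  expect_equal(full$p_value, 1)
  expect_error(overlap_test(u[1:3], u[1:3], character(0)), "universe")
})

test_that("overlap_test is symmetric in its two sets", {
  set.seed(5)
  u <- sprintf("g%03d", 1:300)
  for (i in 1:20) {
    s1 <- sample(u, sample(5:80, 1))
    s2 <- sample(u, sample(5:80, 1))
    a <- overlap_test(s1, s2, u)
    b <- overlap_test(s2, s1, u)
    expect_identical(a$k, b$k)
    expect_equal(a$expected, b$expected)
    expect_equal(a$fold, b$fold)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("membership outside the universe is dropped, not fatal", {
  u <- sprintf("g%02d", 1:20)
  expect_message(st <- overlap_test(c(u[1:5], "retired1"), u[1:10], u),
                 "dropped")
  expect_identical(st$K, 5L)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.9)), c(0.015, 0.06, 0.9))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_lte(max(bh_adjust(runif(100))), 1)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("log_correlation behaves on identity, reversal and a toy oracle", {
  x <- c(0, 1, 5, 10, 50, 100, 3, 7, 22, 0.5)
  expect_equal(log_correlation(x, x), 1)
  expect_equal(log_correlation(x, max(x) - x + 1, method = "spearman"), -1)
  y <- c(0.2, 2, 4, 15, 40, 120, 2, 9, 18, 1)
  expect_equal(log_correlation(x, y),
               pearson_formula(log10(x + 1), log10(y + 1)),
               tolerance = 1e-12)
  expect_error(log_correlation(x, y[-1]), "equal length")
  expect_error(log_correlation(1:2, 1:2), "at least 3")
})

test_that("p-value display follows the table printing convention", {
  expect_identical(format_p_display(0.2), "n.s.")
  expect_identical(format_p_display(0.05), "n.s.")
  expect_identical(format_p_display(0.02), "0.02")
  expect_identical(format_p_display(3e-13), "<10^-12")
  expect_identical(format_p_display(1e-3), "<10^-2")
  expect_identical(format_p_display(0), "<10^-308")
})
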