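test_that("the exact 2x2 test reproduces enumeration and flags degenerate tables", {
  # heterozygosity of complex events in the cohesin vs recombination mutant
  het <- matrix(c(17, 10, 22, 0), 2, byrow = TRUE)
  expect_equal(pValue(fisherExact2x2(het)), 0.0011, tolerance = 5e-3)
  expect_equal(pValue(fisherExact2x2(het)), enumFisherP(het),
               tolerance = 1e-12)

  expect_equal(pValue(fisherExact2x2(matrix(5, 2, 2))), 1)
  perfect <- matrix(c(2, 0, 0, 2), 2)
  expect_equal(pValue(fisherExact2x2(perfect)), 1 / 3, tolerance = 1e-12)
  expect_equal(enumFisherP(perfect), 1 / 3)

  expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  expect_error(fisherExact2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")

  # random tables: wrapper and enumeration agree exactly
  set.seed(2)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(pValue(fisherExact2x2(tab)), enumFisherP(tab),
                 tolerance = 1e-12)
  }
})

test_that("the two-proportion chi-square matches the pooled-proportion formula", {
  eq <- twoProportionChisq(30, 100, 30, 100)
  expect_equal(testStatistic(eq), 0)
  expect_equal(pValue(eq), 1)

  # hand computation: (p1 - p2)^2 / (p (1-p) (1/n1 + 1/n2))
  res <- twoProportionChisq(30, 100, 15, 100)
  p <- 45 / 200
  byHand <- (0.30 - 0.15)^2 / (p * (1 - p) * (1 / 100 + 1 / 100))
  expect_equal(testStatistic(res), byHand, tolerance = 1e-12)
  expect_equal(testStatistic(res), 6.45, tolerance = 1e-3)
  expect_equal(pValue(res), pchisq(byHand, 1, lower.tail = FALSE))

  extreme <- twoProportionChisq(10, 10, 0, 10)
  expect_equal(testStatistic(extreme), 20)
  expect_lt(pValue(extreme), 1e-4)

  expect_warning(twoProportionChisq(1, 3, 0, 3), "fisherExact2x2")
})

test_that("the Holm adjustment follows the step-down definition", {
  expect_equal(holmBonferroni(0.03), 0.03)
  expect_equal(holmBonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holmBonferroni(rep(1, 4)), rep(1, 4))
  expect_error(holmBonferroni(c(0.5, 1.2)), "0, 1")

  # independent step-down oracle
  holmOracle <- function(p) {
    o <- order(p); n <- length(p)
    adj <- pmin(1, (n - seq_len(n) + 1) * p[o])
    adj <- cummax(adj)
    out <- numeric(n); out[o] <- adj
    out
  }
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holmBonferroni(p)
    expect_equal(adj, holmOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("independence products and their binomial bound behave as rates", {
  # segmental-recombination x chromosome-loss product
  prod <- independenceExpectedRate(12e-5, 5531e-7)
  expect_equal(prod, 12e-5 * 5531e-7)
  expect_equal(signif(prod, 1), 7e-8)
  expect_equal(independenceExpectedRate(3e-4, 0), 0)
  expect_equal(independenceExpectedRate(2e-5, 7e-6),
               independenceExpectedRate(7e-6, 2e-5))

  expect_equal(pValue(binomialIndependenceTest(0, 1000, 0.01)), 1)
  # exact tail oracle by direct summation
  pSum <- sum(dbinom(5:1000, 1000, 0.001))
  res <- binomialIndependenceTest(5, 1000, 0.001)
  expect_equal(pValue(res), pSum, tolerance = 1e-12)
  expect_equal(pValue(res), 3.7e-3, tolerance = 2e-2)
  # large-n regime stays exact (incomplete-beta evaluation)
  for (n in c(1e5, 1e6, 1e7)) {
    k <- round(6e-6 * n)
    direct <- sum(dbinom(k:(k + 2000), n, 7e-8))
    expect_equal(pValue(binomialIndependenceTest(k, n, 7e-8)), direct,
                 tolerance = 1e-6)
  }
})

test_that("Welch t and rank-sum tests agree with permutation and enumeration oracles", {
  expect_equal(pValue(welchTTest(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(testStatistic(welchTTest(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_lt(pValue(welchTTest(c(1, 2, 3), c(11, 12, 13))), 0.01)
  expect_error(welchTTest(c(2, 2), c(3, 3)), "zero variance")

  set.seed(4)
  a <- rnorm(6); b <- rnorm(6, mean = 1)
  tObs <- abs(testStatistic(welchTTest(a, b)))
  pooled <- c(a, b)
  perms <- replicate(20000, {
    i <- sample(12, 6)
    abs(testStatistic(welchTTest(pooled[i], pooled[-i])))
  })
  expect_lt(abs(pValue(welchTTest(a, b)) - mean(perms >= tObs - 1e-12)),
            0.02)

  expect_equal(pValue(mannWhitney(c(1, 1), c(1, 1))), 1)  # all tied
  mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(pValue(mw), 0.1)
  expect_equal(pValue(mw), enumRankSumP(c(1, 2, 3), c(4, 5, 6)))
  # rank test is invariant under monotone transforms of the pooled data
  expect_equal(pValue(mannWhitney(exp(a), exp(b))),
               pValue(mannWhitney(a, b)))
})

test_that("PFGE band fractions normalize chromosome II against the reference bands", {
  expect_equal(pfgeChr2Fraction(1, 1, 1), 1 / 3)
  # halving the chromosome II band (monosomy signature) gives 0.2
  expect_equal(pfgeChr2Fraction(0.5, 1, 1), 0.2)
  expect_equal(pfgeChr2Fraction(3 * 7, 3 * 9, 3 * 5),
               pfgeChr2Fraction(7, 9, 5))
  expect_equal(pfgeChr2Fraction(c(1, 0.5), c(1, 1), c(1, 1)),
               c(1 / 3, 0.2))
  expect_error(pfgeChr2Fraction(0, 0, 0), "undefined")
  expect_error(pfgeChr2Fraction(-1, 1, 1), ">= 0")
})
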