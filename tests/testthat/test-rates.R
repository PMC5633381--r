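test_that("the median-equation solver matches a bisection oracle and is monotone", {
  expect_equal(leaCoulsonM(1.24), 1, tolerance = 1e-12)
  expect_equal(leaCoulsonM(10), bisectLeaCoulson(10), tolerance = 1e-9)
  # spot value: m(log m + 1.24) = 10 has its root near 3.86
  expect_equal(leaCoulsonM(10), 3.86, tolerance = 1e-3)
  m <- leaCoulsonM(1000)
  expect_equal(m * (log(m) + 1.24), 1000, tolerance = 1e-9)

  set.seed(1)
  r <- 10^runif(50, -3, 6)
  m <- vapply(r, leaCoulsonM, numeric(1))
  expect_equal(m, vapply(r, bisectLeaCoulson, numeric(1)),
               tolerance = 1e-9)
  # monotone increasing in the median count
  o <- order(r)
  expect_false(is.unsorted(m[o]))

  expect_error(leaCoulsonM(0), "p0")
  expect_error(leaCoulsonM(-1), "rMed")
})

test_that("the p0 method recovers m from the zero-culture fraction", {
  expect_equal(p0MethodM(1), 0)
  expect_equal(p0MethodM(exp(-1)), 1)
  expect_equal(p0MethodM(0.5), log(2))
  expect_error(p0MethodM(0), "median method")
})

test_that("per-culture rates follow the median relation and flag zeros", {
  expect_equal(cultureRate(1.24, nFinal = 1e6 + 10, n0 = 10), 1e-6)
  expect_equal(cultureRate(10, nFinal = 1e7 + 1, n0 = 1),
               3.86e-7, tolerance = 1e-3)
  expect_true(is.na(cultureRate(0, 1e6, 1)))
  expect_error(cultureRate(10, nFinal = 5, n0 = 10), "nFinal")
  expect_error(cultureRate(20, nFinal = 10, n0 = 1), "data error")
  # increasing the count never decreases the rate
  rr <- cultureRate(1:50, 1e6, 1)
  expect_false(is.unsorted(rr))
})

test_that("order-statistic median CIs use the exact binomial ranks", {
  # n = 6: the extreme ranks give exact coverage 1 - 2 (1/2)^6
  est <- medianWithCI(c(2, 4, 9, 1, 7, 3), level = 0.95)
  expect_equal(unname(rateCI(est)), c(1, 9))
  expect_equal(achievedLevel(est), 1 - 2 * (0.5)^6)
  expect_equal(achievedLevel(est), 0.96875)

  # n = 8: ranks (2,7) would cover only 1 - 2 * 9 / 2^8 < 0.95,
  # so the interval stays at (1,8) with coverage 1 - 2 / 2^8
  est8 <- medianWithCI(1:8, level = 0.95)
  expect_equal(unname(rateCI(est8)), c(1, 8))
  expect_equal(achievedLevel(est8), 1 - 2 * pbinom(0, 8, 0.5))
  expect_lt(1 - 2 * pbinom(1, 8, 0.5), 0.95)

  # n = 24 admits ranks (7, 18)
  est24 <- medianWithCI(1:24, level = 0.95)
  expect_equal(unname(rateCI(est24)), c(7, 18))
  expect_equal(achievedLevel(est24), 1 - 2 * pbinom(6, 24, 0.5))

  # constant sample: interval collapses onto the constant
  estC <- medianWithCI(rep(3.3, 10))
  expect_equal(unname(rateCI(estC)), c(3.3, 3.3))

  # n too small for the requested level: widest interval, flagged
  est3 <- medianWithCI(c(1, 2, 3), level = 0.95)
  expect_lt(achievedLevel(est3), 0.95)
  expect_match(est3@note, "below requested")
  est1 <- medianWithCI(5)
  expect_false(est1@ciAvailable)
})

test_that("order-statistic CIs attain their stated coverage on a known distribution", {
  set.seed(20)
  n <- 10
  trueMedian <- qexp(0.5)
  hits <- logical(3000)
  achieved <- NA_real_
  for (i in seq_along(hits)) {
    est <- medianWithCI(rexp(n), level = 0.95)
    ci <- rateCI(est)
    achieved <- achievedLevel(est)
    hits[i] <- ci[1] <= trueMedian && trueMedian <= ci[2]
  }
  expect_equal(achieved, 1 - 2 * pbinom(1, n, 0.5))
  expect_equal(mean(hits), achieved, tolerance = 0.025)
})

test_that("class rate tables estimate, dilution-correct and bound absent classes", {
  mkCounts <- function(r, dilution = 1, genotype = "g") {
    data.frame(genotype = genotype,
               culture_id = as.character(seq_along(r)),
               class = "CHROMOSOME_LOSS", r = r, n0 = 1,
               n_final = 1e6 + 1, dilution = dilution,
               stringsAsFactors = FALSE)
  }
  r <- c(3, 8, 1, 15, 6, 4, 9, 2)
  tab <- classRateTable(mkCounts(r))
  expect_equal(rateMedian(tab$CHROMOSOME_LOSS),
               median(vapply(r, function(x) leaCoulsonM(x) / 1e6,
                             numeric(1))))
  expect_equal(rateMedian(tab$TOTAL), rateMedian(tab$CHROMOSOME_LOSS))

  # dilution correction: counts observed after 10x dilution estimate the
  # same rate as the undiluted counts
  tabDil <- classRateTable(mkCounts(r, dilution = 0.1))
  tabRef <- classRateTable(mkCounts(r / 0.1))
  expect_equal(rateMedian(tabDil$CHROMOSOME_LOSS),
               rateMedian(tabRef$CHROMOSOME_LOSS))

  # pooled-median variant agrees with the per-culture variant up to the
  # monotone count-to-rate map (odd n, no zeros)
  r7 <- c(3, 8, 1, 15, 6, 4, 9)
  perC <- classRateTable(mkCounts(r7))$CHROMOSOME_LOSS
  pooled <- classRateTable(mkCounts(r7),
                           estimator = "pooled-median")$CHROMOSOME_LOSS
  expect_equal(rateMedian(perC), rateMedian(pooled))
  expect_equal(perC@achievedLevel, pooled@achievedLevel)

  # a class absent everywhere gets a p0-style upper bound, not an estimate
  cts <- rbind(mkCounts(r),
               within(mkCounts(rep(0, 8)), class <- "COMPLEX"))
  tab2 <- classRateTable(cts)
  expect_equal(rateMedian(tab2$COMPLEX), 0)
  expect_equal(unname(rateCI(tab2$COMPLEX)["upper"]),
               -log((8 - 0.5) / 8) / 1e6)
  expect_match(tab2$COMPLEX@note, "absent")

  # median count zero switches to the p0 method
  tab3 <- classRateTable(mkCounts(c(0, 0, 0, 0, 0, 2, 3, 1)))
  expect_equal(rateMedian(tab3$CHROMOSOME_LOSS), -log(5 / 8) / 1e6)
  expect_false(tab3$CHROMOSOME_LOSS@ciAvailable)

  expect_error(classRateTable(mkCounts(5)), "two cultures")
})

test_that("rate subtraction clamps at zero and refuses mismatched assays", {
  mk <- function(med, label, assay = "a") {
    medianWithCI(rep(med, 6), classLabel = label, assay = assay)
  }
  d <- subtractRates(mk(100e-7, "TOTAL"), mk(96e-7, "CHROMOSOME_LOSS"))
  expect_equal(rateMedian(d), 4e-7)
  expect_false(d@ciAvailable)   # CIs do not propagate through differences

  expect_equal(rateMedian(subtractRates(mk(5e-7, "TOTAL"),
                                        mk(5e-7, "CL"))), 0)
  expect_warning(d0 <- subtractRates(mk(5e-7, "TOTAL"), mk(9e-7, "CL")),
                 "clamping")
  expect_equal(rateMedian(d0), 0)
  expect_error(subtractRates(mk(5e-7, "TOTAL", "a"), mk(1e-7, "CL", "b")),
               "different assays")
})

test_that("the estimator recovers simulated rates within its documented bias", {
  # moderate-m regime: mu (nFinal - n0) = 10, where the median method is
  # well conditioned
  mu <- 1e-5
  cfg <- cultureConfig(n0 = 1e3, nFinal = 1e6)
  meds <- vapply(1:20, function(i) {
    cults <- simulateAssay(eventRates(chromosomeLoss = mu), cfg, 12,
                           seed = 100 + i)
    rateMedian(classRateTable(culturesToCounts(cults))$CHROMOSOME_LOSS)
  }, numeric(1))
  expect_lt(abs(median(meds) / mu - 1), 0.35)

  # a 3:1 rate ratio is recovered as roughly 3 (expected events per
  # culture 30 and 10, where the median method is well conditioned)
  ratios <- vapply(1:10, function(i) {
    cults <- simulateAssay(eventRates(chromosomeLoss = 3e-5,
                                      geneConversion = 1e-5),
                           cfg, 24, seed = 200 + i)
    tab <- classRateTable(culturesToCounts(cults))
    rateMedian(tab$CHROMOSOME_LOSS) / rateMedian(tab$GENE_CONVERSION)
  }, numeric(1))
  expect_gt(mean(ratios >= 2 & ratios <= 4.5), 0.7)
})
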