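#' @include AllClasses.R AllGenerics.R
NULL

.testResult <- function(method, statistic, pValue, tails, n,
                        pAdjusted = NA_real_) {
  new("TestResult", method = method, statistic = as.numeric(statistic),
      pValue = min(max(pValue, 0), 1), pAdjusted = pAdjusted,
      tails = tails, n = as.numeric(n))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the point-probability convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param tails `"two-sided"` (default), `"greater"` or `"less"`.
#' @return a [TestResult].
#' @examples
#' # heterozygous vs homozygous complex events in two repair backgrounds
#' pValue(fisherExact2x2(matrix(c(17, 10, 22, 0), 2, byrow = TRUE)))
#' @export
fisherExact2x2 <- function(table, tails = c("two-sided", "greater", "less")) {
  tails <- match.arg(tails)
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) ||
      any(table != round(table)))
    stop("need a 2x2 table of non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin: the exact test is undefined")
  alt <- switch(tails, `two-sided` = "two.sided", greater = "greater",
                less = "less")
  ft <- stats::fisher.test(table, alternative = alt)
  .testResult("fisher_exact_2x2", NA_real_, ft$p.value, tails, sum(table))
}

#' Pearson chi-square test for two proportions
#'
#' 1-df chi-square on the 2x2 table of successes/failures, without the
#' Yates continuity correction (switchable).
#'
#' @param k1,n1,k2,n2 successes and totals in the two groups.
#' @param correct apply the continuity correction?
#' @return a [TestResult].
#' @export
twoProportionChisq <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  if (k1 / n1 == k2 / n2)   # includes the degenerate all-0 / all-n cases
    return(.testResult("two_proportion_chisq", 0, 1, "two-sided", n1 + n2))
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp < 1))
    warning("expected cell below 1: prefer fisherExact2x2")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  .testResult("two_proportion_chisq", ct$statistic, ct$p.value,
              "two-sided", n1 + n2)
}

#' Holm step-down multiplicity adjustment
#'
#' @param pValues numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values (monotone, capped at 1), in input order.
#' @export
holmBonferroni <- function(pValues) {
  if (any(is.na(pValues)) || any(pValues < 0) || any(pValues > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pValues, method = "holm")
}

#' Expected rate of a compound event under independence
#'
#' If two chromosome transactions occur independently in different cell
#' divisions, the per-division rate of observing both in one lineage is
#' the product of the individual per-division rates. Comparing this
#' product with the observed rate of the compound phenotype tests whether
#' the compound events can be explained as two independent steps.
#'
#' @param rateA,rateB per-division rates (same units).
#' @return the product rate.
#' @examples
#' # segmental-recombination x chromosome-loss product
#' signif(independenceExpectedRate(12e-5, 5531e-7), 1)
#' @export
independenceExpectedRate <- function(rateA, rateB) {
  stopifnot(rateA >= 0, rateB >= 0)
  rateA * rateB
}

#' Upper-tail binomial test against an independence null
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`: the probability of observing at
#' least the seen number of compound events in `n` cell divisions if they
#' arose at the independence-product rate `p0`. The tail is evaluated
#' exactly via the regularized incomplete beta function at any `n`.
#'
#' @param kObserved observed event count.
#' @param nDivisions number of cell divisions (trials).
#' @param p0 null per-division probability.
#' @return a [TestResult] (`statistic` is the observed count).
#' @export
binomialIndependenceTest <- function(kObserved, nDivisions, p0) {
  stopifnot(p0 >= 0, p0 <= 1, kObserved >= 0, kObserved <= nDivisions)
  p <- if (kObserved == 0) 1
       else stats::pbinom(kObserved - 1, nDivisions, p0, lower.tail = FALSE)
  .testResult("binomial_independence", kObserved, p, "greater", nDivisions)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test, e.g. on per-culture rates of two
#' genotypes.
#'
#' @param sampleA,sampleB numeric samples (each n >= 2).
#' @return a [TestResult].
#' @export
welchTTest <- function(sampleA, sampleB) {
  stopifnot(length(sampleA) >= 2, length(sampleB) >= 2)
  if (stats::var(sampleA) == 0 && stats::var(sampleB) == 0) {
    if (isTRUE(all.equal(mean(sampleA), mean(sampleB))))
      return(.testResult("welch_t", 0, 1, "two-sided",
                         length(sampleA) + length(sampleB)))
    stop("both samples have zero variance: t statistic undefined")
  }
  tt <- stats::t.test(sampleA, sampleB, var.equal = FALSE)
  .testResult("welch_t", tt$statistic, tt$p.value, "two-sided",
              length(sampleA) + length(sampleB))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p for combined n <= 20 without ties; otherwise the
#' normal approximation with tie correction.
#'
#' @param sampleA,sampleB numeric samples (each n >= 2).
#' @return a [TestResult].
#' @export
mannWhitney <- function(sampleA, sampleB) {
  stopifnot(length(sampleA) >= 2, length(sampleB) >= 2)
  pooled <- c(sampleA, sampleB)
  n <- length(pooled)
  if (length(unique(pooled)) == 1)
    return(.testResult("mann_whitney", NA_real_, 1, "two-sided", n))
  exact <- n <= 20 && !anyDuplicated(pooled)
  wt <- suppressWarnings(stats::wilcox.test(sampleA, sampleB,
                                            exact = exact,
                                            correct = !exact))
  .testResult("mann_whitney", wt$statistic, wt$p.value, "two-sided", n)
}

#' Chromosome II band fraction from PFGE densitometry
#'
#' Normalizes the chromosome II band volume by the summed volumes of
#' chromosomes II, XIV and X in the same lane, giving a lane-to-lane
#' comparable copy-number proxy (about 1/3 for disomy, falling toward 0.2
#' when one homolog of chromosome II is lost).
#'
#' @param volII,volXIV,volX band volumes (any common units); vectorized.
#' @return fraction(s) in [0, 1].
#' @export
pfgeChr2Fraction <- function(volII, volXIV, volX) {
  if (any(volII < 0 | volXIV < 0 | volX < 0))
    stop("band volumes must be >= 0")
  tot <- volII + volXIV + volX
  if (any(tot == 0))
    stop("all three band volumes are zero: fraction undefined")
  volII / tot
}

#' @rdname TestResult-accessors
#' @param x a [TestResult].
#' @name TestResult-accessors
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname TestResult-accessors
#' @export
setMethod("testStatistic", "TestResult", function(x) x@statistic)

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult [%s, %s]: p = %.4g%s%s (n = %g)\n",
              object@method, object@tails, object@pValue,
              if (!is.na(object@statistic))
                sprintf(", statistic = %.4g", object@statistic) else "",
              if (!is.na(object@pAdjusted))
                sprintf(", adjusted p = %.4g", object@pAdjusted) else "",
              object@n))
})

#' TestResult as a JSON-ready record
#'
#' @param x a [TestResult].
#' @return named list `{method, statistic, p_raw, p_adjusted, tails, n}`.
#' @export
testRecord <- function(x) {
  stopifnot(is(x, "TestResult"))
  list(method = x@method,
       statistic = if (is.na(x@statistic)) NULL else unname(x@statistic),
       p_raw = x@pValue,
       p_adjusted = if (is.na(x@pAdjusted)) NULL else x@pAdjusted,
       tails = x@tails, n = x@n)
}
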