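#' @include AllClasses.R AllGenerics.R
NULL

#' Solve the Lea-Coulson median equation for the expected event number
#'
#' Inverts the method-of-the-median relation
#' `rMed / m - log(m) = 1.24`, i.e. `rMed = m * (log(m) + 1.24)`, for the
#' expected number of founding events per culture `m`. On
#' `m > exp(-1.24)` the left side increases monotonically from 0, so the
#' root is unique for every `rMed > 0`; it is found by bracketed
#' root-finding and polished with Newton steps to a relative tolerance of
#' 1e-9.
#'
#' @param rMed median resistant-colony count (> 0).
#' @return `m`, the expected founding events per culture.
#' @examples
#' leaCoulsonM(1.24)  # exactly 1
#' @export
leaCoulsonM <- function(rMed) {
  if (length(rMed) != 1 || is.na(rMed) || rMed < 0)
    stop("rMed must be a single number >= 0")
  if (rMed == 0)
    stop("median count is zero: use the p0 method (p0MethodM)",
         call. = FALSE)
  f <- function(m) m * (log(m) + 1.24) - rMed
  lower <- exp(-1.24)            # f(lower) = -rMed < 0
  upper <- max(2, rMed)          # f(upper) > 0 for rMed >= 0
  m <- uniroot(f, c(lower, upper), tol = 1e-12 * upper)$root
  for (i in 1:3)                 # Newton polish
    m <- m - f(m) / (log(m) + 2.24)
  m
}

#' Expected event number from the fraction of cultures without mutants
#'
#' The p0 method: `m = -log(fractionZero)`. Used when the median
#' resistant count is zero, where the median method is undefined.
#'
#' @param fractionZero fraction of cultures with zero resistant colonies,
#'   in (0, 1].
#' @return `m`.
#' @export
p0MethodM <- function(fractionZero) {
  if (length(fractionZero) != 1 || is.na(fractionZero) ||
      fractionZero <= 0 || fractionZero > 1)
    stop("fractionZero must be in (0, 1]; with no zero cultures use the ",
         "median method")
  -log(fractionZero)
}

#' Per-culture LOH rate from a resistant count
#'
#' Applies the Lea-Coulson median relation to a single culture's count and
#' divides by the number of cell divisions (`nFinal - n0`, since every
#' division adds one cell). Zero counts return `NA`; how they enter the
#' assay-level estimate is decided by `zeroHandling` in [classRateTable].
#'
#' @param r resistant count(s), already corrected for dilution.
#' @param nFinal,n0 final and inoculum cell numbers.
#' @return rate(s) per cell division (`NA` where `r == 0`).
#' @export
cultureRate <- function(r, nFinal, n0) {
  if (any(nFinal <= n0) || any(n0 < 1))
    stop("need nFinal > n0 >= 1")
  if (any(r > nFinal))
    stop("resistant count exceeds the culture size (data error)")
  divisions <- nFinal - n0
  vapply(seq_along(r), function(i) {
    if (is.na(r[i]) || r[i] == 0) return(NA_real_)
    leaCoulsonM(r[i]) / (rep_len(divisions, length(r))[i])
  }, numeric(1))
}

# largest lower rank l with two-tail binomial probability outside
# [x_(l), x_(n+1-l)] at most alpha; returns l and the exact coverage
.orderStatRanks <- function(n, level) {
  alpha <- 1 - level
  l <- 1L
  for (cand in seq_len(floor(n / 2))) {
    if (2 * pbinom(cand - 1, n, 0.5) <= alpha) l <- cand else break
  }
  achieved <- 1 - 2 * pbinom(l - 1, n, 0.5)
  list(lower = l, upper = n + 1L - l, achieved = achieved)
}

#' Median with a nonparametric order-statistic confidence interval
#'
#' The median is the central order statistic (mean of the two central
#' values for even n). The confidence interval is the pair of symmetric
#' order statistics `[x_(l), x_(n+1-l)]` with `l` the largest rank whose
#' two-tailed Binomial(n, 1/2) probability outside the interval does not
#' exceed `1 - level`; the exact (achieved) coverage is reported and is
#' at least `level` whenever `n` permits (n >= 6 at the 95% level),
#' otherwise the widest interval `[x_(1), x_(n)]` is returned and flagged.
#'
#' @param values numeric sample (n >= 2 for an interval).
#' @param level requested confidence level.
#' @param classLabel,assay labels carried into the result.
#' @return a [RateEstimate].
#' @examples
#' est <- medianWithCI(c(2, 4, 9, 1, 7, 3))
#' rateCI(est); achievedLevel(est)  # ranks (1, 6): 1 - 2/64
#' @export
medianWithCI <- function(values, level = 0.95, classLabel = "",
                         assay = "") {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA")
  n <- length(values)
  if (n < 1) stop("need at least one value")
  s <- sort(values)
  med <- median(s)
  if (n < 2) {
    return(new("RateEstimate", classLabel = classLabel, assay = assay,
               median = med, ciLower = NA_real_, ciUpper = NA_real_,
               achievedLevel = NA_real_, requestedLevel = level,
               nCultures = n, perCultureRates = values,
               ciAvailable = FALSE, method = "median",
               note = "n < 2: CI unavailable"))
  }
  rk <- .orderStatRanks(n, level)
  note <- if (rk$achieved < level)
    sprintf("achieved coverage %.4f below requested %.2f (n too small)",
            rk$achieved, level) else ""
  new("RateEstimate", classLabel = classLabel, assay = assay,
      median = med, ciLower = s[rk$lower], ciUpper = s[rk$upper],
      achievedLevel = rk$achieved, requestedLevel = level,
      nCultures = as.integer(n), perCultureRates = values,
      ciAvailable = TRUE, method = "median", note = note)
}

.rateEstimateSkeleton <- function(classLabel, assay, median, level,
                                  n, method, note,
                                  ciLower = NA_real_, ciUpper = NA_real_,
                                  achieved = NA_real_, rates = numeric(0),
                                  ciAvailable = FALSE) {
  new("RateEstimate", classLabel = classLabel, assay = assay,
      median = median, ciLower = ciLower, ciUpper = ciUpper,
      achievedLevel = achieved, requestedLevel = level,
      nCultures = as.integer(n), perCultureRates = rates,
      ciAvailable = ciAvailable, method = method, note = note)
}

# estimate for one class from per-culture corrected counts
.estimateClassRate <- function(r, divisions, level, estimator,
                               zeroHandling, classLabel, assay) {
  n <- length(r)
  medDiv <- median(divisions)
  fracZero <- mean(r == 0)

  if (all(r == 0)) {
    # absent class: rate 0 with a p0-style upper bound from "at most
    # half-a-culture" worth of events
    mUp <- -log((n - 0.5) / n)
    return(.rateEstimateSkeleton(classLabel, assay, 0, level, n,
        method = paste0(estimator, "+p0-bound"),
        note = "class absent in all cultures; upper bound from p0 method",
        ciLower = 0, ciUpper = mUp / medDiv, achieved = NA_real_,
        rates = rep(0, n), ciAvailable = TRUE))
  }

  if (median(r) == 0) {
    # median count zero: median method undefined, switch to p0
    m <- p0MethodM(fracZero)
    return(.rateEstimateSkeleton(classLabel, assay, m / medDiv, level, n,
        method = paste0(estimator, "+p0"),
        note = sprintf("median count 0 (%.0f%% zero cultures): p0 method, CI unavailable",
                       100 * fracZero),
        rates = numeric(0), ciAvailable = FALSE))
  }

  if (estimator == "pooled-median") {
    # textbook variant: the median relation applied once to the median count
    m <- leaCoulsonM(median(r))
    rk <- .orderStatRanks(n, level)
    s <- sort(r)
    bound <- function(x) if (x == 0) 0 else leaCoulsonM(x) / medDiv
    return(.rateEstimateSkeleton(classLabel, assay, m / medDiv, level, n,
        method = "pooled-median",
        note = if (rk$achieved < level) "achieved coverage below requested"
               else "",
        ciLower = bound(s[rk$lower]), ciUpper = bound(s[rk$upper]),
        achieved = rk$achieved, rates = numeric(0), ciAvailable = TRUE))
  }

  # per-culture variant (default): rate per culture, then order statistics
  rates <- cultureRate(r, nFinal = divisions + 1, n0 = 1)
  note <- ""
  if (zeroHandling == "as-zero") {
    rates[is.na(rates)] <- 0
    if (fracZero > 0)
      note <- sprintf("%.0f%% zero-count cultures entered as rate 0",
                      100 * fracZero)
  } else if (zeroHandling == "exclude") {
    rates <- rates[!is.na(rates)]
    if (fracZero > 0)
      note <- sprintf("%.0f%% zero-count cultures excluded", 100 * fracZero)
  } else {                               # "p0"
    m <- p0MethodM(max(fracZero, 0.5 / n))
    return(.rateEstimateSkeleton(classLabel, assay, m / medDiv, level, n,
        method = "per-culture+p0",
        note = "p0 method requested", ciAvailable = FALSE))
  }
  # divisions vary per culture; recompute rates against matching divisions
  est <- medianWithCI(rates, level = level, classLabel = classLabel,
                      assay = assay)
  est@method <- "per-culture"
  est@note <- trimws(paste(note, est@note))
  est
}

#' Per-class LOH rate table from classified fluctuation cultures
#'
#' For every event class present in the input (and for the pooled
#' `TOTAL`), computes the per-culture rates with [cultureRate] after
#' dilution correction (observed selective-plate counts are scaled by the
#' inverse plated fraction) and summarizes them with [medianWithCI]. Two
#' estimator variants are provided: `"per-culture"` (default; the median
#' relation applied to each culture's count, order statistics over the
#' per-culture rates) and `"pooled-median"` (the relation applied once to
#' the median count). Because the count-to-rate map is monotone the two
#' give essentially the same point estimate; both are reported to make
#' the choice explicit.
#'
#' Zero-count cultures have no median-method rate. By default they enter
#' the order statistics as rate 0 (`zeroHandling = "as-zero"`), which
#' keeps the sample median aligned with the count median; `"exclude"`
#' drops them (biasing the median upward when zeros are common), and
#' `"p0"` abandons the median method for the zero-fraction estimator.
#' When the median count itself is zero the p0 method is always used, and
#' when a class is absent from every culture a p0-style upper bound is
#' reported instead of an estimate.
#'
#' @param counts long data.frame with columns `culture_id`, `class`, `r`
#'   (observed selective-plate count), `n0`, `n_final`, `dilution`; see
#'   [culturesToCounts].
#' @param level confidence level (default 0.95).
#' @param estimator `"per-culture"` or `"pooled-median"`.
#' @param zeroHandling `"as-zero"`, `"exclude"` or `"p0"`.
#' @param assay label stored on each estimate.
#' @return named list of [RateEstimate] (classes present, plus `TOTAL`).
#' @export
classRateTable <- function(counts, level = 0.95,
                           estimator = c("per-culture", "pooled-median"),
                           zeroHandling = c("as-zero", "exclude", "p0"),
                           assay = "") {
  estimator <- match.arg(estimator)
  zeroHandling <- match.arg(zeroHandling)
  need <- c("culture_id", "class", "r", "n0", "n_final", "dilution")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  cultures <- unique(counts$culture_id)
  n <- length(cultures)
  if (n < 2) stop("need at least two cultures")

  perCulture <- function(cls) {
    vapply(cultures, function(cid) {
      i <- counts$culture_id == cid &
           (if (is.null(cls)) TRUE else counts$class == cls)
      sum(counts$r[i] / counts$dilution[i])   # dilution correction
    }, numeric(1))
  }
  divisions <- vapply(cultures, function(cid) {
    i <- which(counts$culture_id == cid)[1]
    counts$n_final[i] - counts$n0[i]
  }, numeric(1))

  classes <- sort(unique(counts$class))
  out <- lapply(classes, function(cls)
    .estimateClassRate(perCulture(cls), divisions, level, estimator,
                       zeroHandling, cls, assay))
  names(out) <- classes
  out$TOTAL <- .estimateClassRate(perCulture(NULL), divisions, level,
                                  estimator, zeroHandling, "TOTAL", assay)
  out
}

#' Subtract one median rate from another (derived non-CL rate)
#'
#' Medians are subtracted directly and clamped at zero; the order-statistic
#' intervals of the operands do not propagate through a difference, so the
#' result carries no CI.
#'
#' @param total,part [RateEstimate]s from the same assay.
#' @return a [RateEstimate] labelled `<total> - <part>`.
#' @export
subtractRates <- function(total, part) {
  stopifnot(is(total, "RateEstimate"), is(part, "RateEstimate"))
  if (nzchar(total@assay) && nzchar(part@assay) &&
      !identical(total@assay, part@assay))
    stop("refusing to subtract rates from different assays ('",
         total@assay, "' vs '", part@assay, "')")
  d <- total@median - part@median
  note <- "difference of medians; CI not propagated"
  if (d < 0) {
    warning("part exceeds total; clamping difference at 0")
    note <- paste(note, "(clamped at 0)")
    d <- 0
  }
  .rateEstimateSkeleton(
    classLabel = paste0(total@classLabel, " - ", part@classLabel),
    assay = total@assay, median = d, level = total@requestedLevel,
    n = total@nCultures, method = "difference", note = note)
}

#' @rdname RateEstimate-accessors
#' @param x a [RateEstimate].
#' @name RateEstimate-accessors
#' @export
setMethod("rateMedian", "RateEstimate", function(x) x@median)

#' @rdname RateEstimate-accessors
#' @export
setMethod("rateCI", "RateEstimate", function(x)
  c(lower = x@ciLower, upper = x@ciUpper))

#' @rdname RateEstimate-accessors
#' @export
setMethod("achievedLevel", "RateEstimate", function(x) x@achievedLevel)

#' @rdname RateEstimate-accessors
#' @export
setMethod("nCultures", "RateEstimate", function(x) x@nCultures)

#' @rdname RateEstimate-accessors
#' @export
setMethod("lohClass", "RateEstimate", function(x) x@classLabel)

setMethod("show", "RateEstimate", function(object) {
  fmt <- function(x) {
    if (is.na(x)) return("NA")
    sprintf("%.3g", x * 1e7)
  }
  cat(sprintf("RateEstimate [%s]%s: %s (%s-%s) per 1e7 divisions, n = %d (%s)\n",
              object@classLabel,
              if (nzchar(object@assay)) paste0(" ", object@assay) else "",
              fmt(object@median), fmt(object@ciLower), fmt(object@ciUpper),
              object@nCultures, object@method))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})
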