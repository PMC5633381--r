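#' @include AllClasses.R classify.R rates.R statTests.R io.R
NULL

#' Class-distribution report from a phenotype table
#'
#' Classifies every colony and tabulates counts and percentages per
#' genotype. Rows whose growth calls are incomplete are rejected with
#' their row numbers and reported, not dropped silently; anomalous
#' phenotype patterns are listed as their own `ANOMALOUS` category, never
#' merged into a class. Deterministic.
#'
#' @param phenotypes phenotype table (see [readPhenotypeTable]).
#' @return list with `distribution` (data.frame: genotype, class, n,
#'   percent), `rejected` (data.frame: row, reason), `nInput`.
#' @export
runClassify <- function(phenotypes) {
  n <- nrow(phenotypes)
  cats <- c(LOH_CLASSES, "ANOMALOUS")
  if (n == 0) {
    return(list(distribution = data.frame(genotype = character(0),
                                          class = character(0),
                                          n = integer(0),
                                          percent = numeric(0)),
                rejected = data.frame(row = integer(0),
                                      reason = character(0)),
                nInput = 0L))
  }
  cls <- classifyPhenotype(phenotypes)
  bad <- which(is.na(cls))
  rejected <- data.frame(row = bad,
                         reason = rep("incomplete growth calls",
                                      length(bad)),
                         stringsAsFactors = FALSE)
  keep <- !is.na(cls)
  geno <- if ("genotype" %in% names(phenotypes)) phenotypes$genotype
          else rep("unspecified", n)
  dist <- do.call(rbind, lapply(unique(geno[keep]), function(g) {
    i <- keep & geno == g
    counts <- table(factor(cls[i], levels = cats))
    data.frame(genotype = g, class = cats, n = as.integer(counts),
               percent = round(100 * as.integer(counts) / sum(i), 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(distribution = dist, rejected = rejected, nInput = n)
}

#' Per-genotype rate table from classified fluctuation cultures
#'
#' Runs [classRateTable] per genotype on a long class-count table and
#' appends the derived non-chromosome-loss rate
#' (`TOTAL - CHROMOSOME_LOSS`, by [subtractRates]). Genotypes with fewer
#' than two cultures are skipped with a warning.
#'
#' @param counts long class-count data.frame (see [culturesToCounts] or
#'   [joinCultureClasses]); must include a `genotype` column.
#' @param ... passed to [classRateTable] (`level`, `estimator`,
#'   `zeroHandling`).
#' @return data.frame of rate rows (see [rateTableFrame]).
#' @export
runRates <- function(counts, ...) {
  stopifnot("genotype" %in% names(counts))
  out <- list()
  for (g in unique(counts$genotype)) {
    sub <- counts[counts$genotype == g, ]
    if (length(unique(sub$culture_id)) < 2) {
      warning("genotype '", g, "' has fewer than two cultures: skipped")
      next
    }
    est <- classRateTable(sub, assay = g, ...)
    if (!is.null(est$CHROMOSOME_LOSS))
      est$NON_CL <- local({
        e <- subtractRates(est$TOTAL, est$CHROMOSOME_LOSS)
        e@classLabel <- "NON_CL"
        e
      })
    out[[g]] <- rateTableFrame(est, genotype = g)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Complex-event analysis panel
#'
#' Bundles the genotypic analyses of complex LOH events:
#' \itemize{
#'   \item subclass distribution per genotype, from zygosity calls;
#'   \item Fisher exact test comparing heterozygosity at the retained
#'     telomeric locus between two genotypes;
#'   \item the independence product of the segmental and chromosome-loss
#'     rates, with an upper-tail binomial test of the observed complex
#'     count against it;
#'   \item pulsed-field gel chromosome II band fractions compared between
#'     groups (Mann-Whitney by default, Welch t by flag).
#' }
#' Items whose inputs are missing are marked unavailable, not failed.
#'
#' @param phenotypes phenotype table with zygosity columns; only colonies
#'   classified `COMPLEX` are used. `NULL` to skip.
#' @param hetCompare character vector of two genotype names to compare by
#'   Fisher test (heterozygous vs not, at the retained locus).
#' @param segmentalRate,clRate per-division rates whose product is the
#'   independence expectation. `NULL` to skip.
#' @param observedComplexRate observed per-division complex-event rate.
#' @param nDivisions cell divisions supporting the binomial test.
#' @param pfge data.frame with columns `group`, `vol_ii`, `vol_xiv`,
#'   `vol_x`; the first group is compared against each other group.
#'   `NULL` to skip.
#' @param pfgeTest `"mann-whitney"` (default) or `"welch"`.
#' @return list with elements `subclasses`, `heterozygosity`,
#'   `independence`, `pfge`; unavailable items carry a `note`.
#' @export
runComplexPanel <- function(phenotypes = NULL, hetCompare = NULL,
                            segmentalRate = NULL, clRate = NULL,
                            observedComplexRate = NULL, nDivisions = NULL,
                            pfge = NULL,
                            pfgeTest = c("mann-whitney", "welch")) {
  pfgeTest <- match.arg(pfgeTest)
  panel <- list()

  if (is.null(phenotypes) || nrow(phenotypes) == 0) {
    panel$subclasses <- list(note = "no phenotype table supplied")
  } else {
    cls <- classifyPhenotype(phenotypes)
    cx <- phenotypes[!is.na(cls) & cls == "COMPLEX", , drop = FALSE]
    if (nrow(cx) == 0) {
      panel$subclasses <- list(note = "no complex colonies in input")
    } else {
      subs <- vapply(phenotypesFromTable(cx), subclassifyComplex, "")
      panel$subclasses <- do.call(rbind, lapply(unique(cx$genotype),
        function(g) {
          counts <- table(factor(subs[cx$genotype == g],
                                 levels = COMPLEX_SUBCLASSES))
          data.frame(genotype = g, subclass = COMPLEX_SUBCLASSES,
                     n = as.integer(counts), stringsAsFactors = FALSE,
                     row.names = NULL)
        }))
      if (!is.null(hetCompare) && length(hetCompare) == 2 &&
          all(hetCompare %in% cx$genotype)) {
        hetTab <- t(vapply(hetCompare, function(g) {
          i <- cx$genotype == g
          het <- sum(subs[i] == "HET_TELOMERIC")
          resolved <- sum(subs[i] != "UNRESOLVED")
          c(het = het, nonHet = resolved - het)
        }, numeric(2)))
        panel$heterozygosity <- list(
          table = hetTab, test = fisherExact2x2(hetTab))
      } else {
        panel$heterozygosity <- list(
          note = "heterozygosity comparison unavailable (need two genotypes with complex colonies)")
      }
    }
  }
  if (is.null(panel$heterozygosity))
    panel$heterozygosity <- list(note = "no zygosity input")

  if (!is.null(segmentalRate) && !is.null(clRate)) {
    expected <- independenceExpectedRate(segmentalRate, clRate)
    item <- list(expected_rate = expected,
                 expected_rate_1sf = signif(expected, 1))
    if (!is.null(observedComplexRate) && !is.null(nDivisions)) {
      k <- round(observedComplexRate * nDivisions)
      item$observed_rate <- observedComplexRate
      item$test <- binomialIndependenceTest(k, nDivisions, expected)
    }
    panel$independence <- item
  } else {
    panel$independence <- list(note = "independence product unavailable (need segmental and CL rates)")
  }

  if (!is.null(pfge) && nrow(pfge) > 0) {
    pfge$fraction <- pfgeChr2Fraction(pfge$vol_ii, pfge$vol_xiv, pfge$vol_x)
    groups <- unique(pfge$group)
    comps <- list()
    if (length(groups) >= 2) {
      ref <- pfge$fraction[pfge$group == groups[1]]
      for (g in groups[-1]) {
        other <- pfge$fraction[pfge$group == g]
        comps[[paste(groups[1], "vs", g)]] <-
          if (pfgeTest == "mann-whitney") mannWhitney(ref, other)
          else welchTTest(ref, other)
      }
    }
    panel$pfge <- list(fractions = pfge, comparisons = comps)
  } else {
    panel$pfge <- list(note = "no band volumes supplied")
  }
  panel
}

#' Simulation recovery study over a grid of event rates
#'
#' For each grid point, repeatedly simulates a fluctuation assay, runs the
#' rate estimation and reports, per event class, the relative bias of the
#' median-rate estimate across replicates and the empirical coverage of
#' the order-statistic CI for the true rate. Grid points whose total rate
#' violates the rare-event assumption are skipped and logged. Seeded and
#' deterministic.
#'
#' @param ratesGrid list of [EventRates].
#' @param config a [CultureConfig].
#' @param nCultures cultures per assay.
#' @param nReplicates assay replicates per grid point.
#' @param seed master seed.
#' @param ... passed to [classRateTable].
#' @return data.frame: grid point, class, true rate, median relative
#'   bias, CI coverage, mean achieved level, replicates.
#' @export
runSimulationStudy <- function(ratesGrid, config, nCultures = 24,
                               nReplicates = 20, seed = 1, ...) {
  if (is(ratesGrid, "EventRates")) ratesGrid <- list(ratesGrid)
  seeds <- .spawnSeeds(seed, length(ratesGrid) * nReplicates)
  out <- list()
  skipped <- character(0)
  for (gi in seq_along(ratesGrid)) {
    rates <- ratesGrid[[gi]]
    if (sum(rates@rates) >= 0.1) {
      skipped <- c(skipped, sprintf("grid point %d: total rate >= 0.1", gi))
      next
    }
    truth <- rates@rates
    truth["GENE_CONVERSION"] <- truth["GENE_CONVERSION"] +
      truth["POINT_MUTATION"]
    truth <- truth[setdiff(names(truth), "POINT_MUTATION")]
    est <- list()
    for (rep in seq_len(nReplicates)) {
      s <- seeds[(gi - 1) * nReplicates + rep]
      cults <- simulateAssay(rates, config, nCultures, seed = s)
      est[[rep]] <- classRateTable(culturesToCounts(cults), ...)
    }
    for (cls in names(truth)) {
      if (truth[[cls]] == 0) next
      meds <- vapply(est, function(e) e[[cls]]@median, numeric(1))
      cis <- vapply(est, function(e) {
        ci <- rateCI(e[[cls]])
        e[[cls]]@ciAvailable && !anyNA(ci) &&
          ci[1] <= truth[[cls]] && truth[[cls]] <= ci[2]
      }, logical(1))
      lev <- vapply(est, function(e) e[[cls]]@achievedLevel, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        gridPoint = gi, class = cls, trueRate = truth[[cls]],
        medianRelBias = median(meds / truth[[cls]] - 1),
        ciCoverage = mean(cis), meanAchievedLevel = mean(lev, na.rm = TRUE),
        nReplicates = nReplicates, stringsAsFactors = FALSE,
        row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  res
}
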