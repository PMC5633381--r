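#' @include AllClasses.R AllGenerics.R classify.R
NULL

#' Construct per-class event rates
#'
#' Rates are events per cell division. The subclass distribution applies
#' to complex events only.
#'
#' @param chromosomeLoss,geneConversion,segmental,complex,pointMutation
#'   per-division rates (>= 0).
#' @param complexSubclassProbs named probabilities over
#'   `HET_TELOMERIC`, `HALF_CO_NAT_TYR1`, `HALF_CO_TYR1_URA3`. The default
#'   follows the observed genotyped spectrum of complex events
#'   (17 heterozygous : 3 : 7).
#' @return an [EventRates].
#' @examples
#' # rates reported for the cohesin hypomorph, per cell division
#' eventRates(chromosomeLoss = 5531e-7, geneConversion = 30e-7,
#'            complex = 54e-7)
#' @export
eventRates <- function(chromosomeLoss = 0, geneConversion = 0,
                       segmental = 0, complex = 0, pointMutation = 0,
                       complexSubclassProbs = c(HET_TELOMERIC = 17 / 27,
                                                HALF_CO_NAT_TYR1 = 3 / 27,
                                                HALF_CO_TYR1_URA3 = 7 / 27)) {
  new("EventRates",
      rates = c(CHROMOSOME_LOSS = chromosomeLoss,
                GENE_CONVERSION = geneConversion,
                SEGMENTAL = segmental, COMPLEX = complex,
                POINT_MUTATION = pointMutation),
      complexSubclassProbs = complexSubclassProbs)
}

#' Construct a culture growth/plating configuration
#'
#' Defaults emulate the fluctuation protocol: a small inoculum grown to
#' ~1e6-1e7 cells and plated on 5FOA either undiluted or 10- to 100-fold
#' diluted. The inoculum default of 1e3 reflects a patched single colony;
#' estimates are insensitive to it once `nFinal/n0 >= 1e3`.
#'
#' @param n0 inoculum cells.
#' @param nFinal final culture size (cells).
#' @param dilution fraction of the culture plated selectively, (0, 1].
#' @param platingEfficiency probability a plated resistant cell forms a
#'   colony, (0, 1].
#' @return a [CultureConfig].
#' @export
cultureConfig <- function(n0 = 1e3, nFinal = 1e6, dilution = 1,
                          platingEfficiency = 1) {
  new("CultureConfig", n0 = n0, nFinal = nFinal, dilution = dilution,
      platingEfficiency = platingEfficiency)
}

# per-culture seed stream: seeds are drawn once from the master seed by
# sample.int, so culture i is reproducible given (seed, i)
.spawnSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Forward-simulate one fluctuation culture
#'
#' Growth proceeds in synchronous generations from `n0` cells; in each
#' generation every cell produces one daughter (one division = one new
#' cell), except that the last generation is partial so that the culture
#' stops at exactly `nFinal` cells -- total divisions are therefore
#' `nFinal - n0`. New LOH events of class k arise among the dividing cells
#' as Binomial(divisions, mu_k); each founding event starts a resistant
#' clone that grows at the wild-type rate thereafter (full phenotypic
#' expression, no lag, no fitness cost, no secondary events on mutant
#' lineages). Finally the culture is plated: observed per-class counts are
#' Binomial(clone cells, dilution x platingEfficiency).
#'
#' @param rates an [EventRates].
#' @param config a [CultureConfig].
#' @param seed optional integer seed for this culture.
#' @param fitnessCost relative growth handicap of mutant clones in (0, 1);
#'   0 (default) grows mutants at the wild-type rate.
#' @return a [CultureResult].
#' @export
simulateCulture <- function(rates, config, seed = NULL, fitnessCost = 0) {
  stopifnot(is(rates, "EventRates"), is(config, "CultureConfig"))
  mu <- rates@rates
  if (sum(mu) >= 0.1)
    stop("total event rate >= 0.1 per division: ",
         "rare-event model assumptions violated")
  if (!is.null(seed)) set.seed(seed)
  stopifnot(fitnessCost >= 0, fitnessCost < 1)

  n <- config@n0
  nFinal <- config@nFinal
  mutants <- setNames(numeric(length(SIM_CLASSES)), SIM_CLASSES)
  log <- list()
  gen <- 0L
  while (n < nFinal) {
    gen <- gen + 1L
    d <- min(n, nFinal - n)            # divisions this generation
    frac <- d / n                      # fraction of cells that divide
    # resident mutant clones double along with the rest of the culture
    grow <- rbinom(length(mutants), size = as.integer(mutants),
                   prob = frac * (1 - fitnessCost))
    mutants <- mutants + grow
    newEv <- rbinom(length(mu), size = d, prob = mu)
    names(newEv) <- names(mu)
    mutants <- mutants + newEv[names(mutants)]
    if (any(newEv > 0)) {
      nz <- newEv[newEv > 0]
      log[[length(log) + 1L]] <- data.frame(
        generation = gen, class = names(nz), nEvents = as.integer(nz),
        stringsAsFactors = FALSE)
    }
    n <- n + d
  }
  thin <- config@dilution * config@platingEfficiency
  plated <- rbinom(length(mutants), size = as.integer(mutants), prob = thin)
  names(plated) <- names(mutants)
  eventLog <- if (length(log)) do.call(rbind, log)
              else data.frame(generation = integer(0), class = character(0),
                              nEvents = integer(0))
  new("CultureResult", n0 = config@n0, nFinal = n,
      dilution = config@dilution,
      platingEfficiency = config@platingEfficiency,
      counts = plated, countsPrePlating = mutants, eventLog = eventLog)
}

#' Simulate a parallel-culture fluctuation assay
#'
#' Independent cultures with per-culture seeds derived from the master
#' seed; the whole assay is reproducible given `seed`.
#'
#' @param rates an [EventRates].
#' @param config a [CultureConfig] shared by all cultures.
#' @param nCultures number of parallel cultures (>= 2).
#' @param seed master integer seed.
#' @param fitnessCost see [simulateCulture].
#' @return list of [CultureResult].
#' @export
simulateAssay <- function(rates, config, nCultures, seed = 1,
                          fitnessCost = 0) {
  stopifnot(nCultures >= 2)
  seeds <- .spawnSeeds(seed, nCultures)
  lapply(seeds, function(s)
    simulateCulture(rates, config, seed = s, fitnessCost = fitnessCost))
}

#' Simulate independent 5FOA-resistant colonies (mini-culture design)
#'
#' Emulates the pronged mini-culture protocol in which each culture
#' contributes exactly one resistant colony: for every colony a fresh
#' culture is simulated and one resistant cell is drawn with class
#' probability proportional to that culture's per-class resistant counts
#' (so jackpot cultures distort the class spectrum exactly as in the
#' bench assay). Cultures without resistant cells are redrawn and tallied.
#'
#' @param rates an [EventRates].
#' @param config a [CultureConfig] describing one mini-culture.
#' @param nColonies number of colonies wanted.
#' @param seed master integer seed.
#' @param map [MarkerMap] used to realize phenotypes (defaults to the
#'   centromeric-URA3 map).
#' @param maxRetries retry budget for all-zero cultures per colony.
#' @return list of [ColonyPhenotype] with attribute `log`, a data.frame
#'   recording each colony's true class, subclass and retry count.
#' @export
simulateIndependentColonies <- function(rates, config, nColonies, seed = 1,
                                        map = markerMapCentromericURA3(),
                                        maxRetries = 1000L) {
  stopifnot(nColonies >= 1)
  seeds <- .spawnSeeds(seed, nColonies)
  g0 <- startingGenotype(map)
  phenos <- vector("list", nColonies)
  log <- data.frame(colony = seq_len(nColonies),
                    trueClass = NA_character_, subclass = NA_character_,
                    retries = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nColonies)) {
    set.seed(seeds[i])
    retries <- 0L
    repeat {
      cult <- simulateCulture(rates, config)
      counts <- cult@countsPrePlating   # replica plating, no dilution
      if (sum(counts) > 0) break
      retries <- retries + 1L
      if (retries > maxRetries)
        stop("no resistant cells after ", maxRetries,
             " mini-cultures; event rates too low for this design")
    }
    cls <- sample(names(counts), 1L, prob = counts)
    sub <- NA_character_
    event <- cls
    if (cls == "COMPLEX") {
      p <- rates@complexSubclassProbs
      sub <- sample(names(p), 1L, prob = p)
      event <- sub
    }
    phenos[[i]] <- phenotypeOf(applyEvent(g0, event, map), map)
    log$trueClass[i] <- cls
    log$subclass[i] <- sub
    log$retries[i] <- retries
  }
  structure(phenos, log = log)
}

#' @rdname cultureCounts
#' @export
setMethod("cultureCounts", "CultureResult",
function(x, prePlating = FALSE) {
  if (prePlating) x@countsPrePlating else x@counts
})

setMethod("show", "CultureResult", function(object) {
  cat(sprintf(
    "CultureResult: %g -> %g cells, dilution %g; resistant plated: %d (%d founding events)\n",
    object@n0, object@nFinal, object@dilution, sum(object@counts),
    sum(object@eventLog$nEvents)))
  nz <- object@counts[object@counts > 0]
  if (length(nz)) print(nz)
})

setMethod("show", "EventRates", function(object) {
  cat("EventRates (events per cell division):\n")
  print(object@rates)
})

#' Convert simulated cultures to the long class-count table
#'
#' One row per culture x event class with the observed (plated) resistant
#' counts, in the layout [runRates] and [classRateTable] consume. The
#' phenotype-level classes are used: `POINT_MUTATION` clones are counted
#' as `GENE_CONVERSION`, which is what a bench classification of the
#' colonies would report.
#'
#' @param cultures list of [CultureResult].
#' @param genotype label column value.
#' @return data.frame with columns `genotype`, `culture_id`, `class`, `r`,
#'   `n0`, `n_final`, `dilution`.
#' @export
culturesToCounts <- function(cultures, genotype = "sim") {
  phenoClass <- function(counts) {
    counts["GENE_CONVERSION"] <- counts["GENE_CONVERSION"] +
      counts["POINT_MUTATION"]
    counts[setdiff(names(counts), "POINT_MUTATION")]
  }
  do.call(rbind, lapply(seq_along(cultures), function(i) {
    cc <- phenoClass(cultureCounts(cultures[[i]]))
    data.frame(genotype = genotype, culture_id = as.character(i),
               class = names(cc), r = as.numeric(cc),
               n0 = cultures[[i]]@n0, n_final = cultures[[i]]@nFinal,
               dilution = cultures[[i]]@dilution,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
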