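#' @import methods
NULL

#' Loss-of-heterozygosity class codes
#'
#' The five phenotype classes used throughout the package:
#' `CHROMOSOME_LOSS` (all four ectopic markers lost), `GENE_CONVERSION`
#' (only the counter-selected URA3 marker lost), `SEGMENTAL` (right-arm
#' markers URA3 and NAT lost together), `COMPLEX` (exactly one telomeric
#' marker retained, the other three lost) and `NO_LOH` (5FOA-sensitive).
#' Growth-call patterns outside this enumeration are reported as
#' `"ANOMALOUS"`, never silently merged into a class.
#'
#' @format Character vector of class codes.
#' @export
LOH_CLASSES <- c("CHROMOSOME_LOSS", "GENE_CONVERSION", "SEGMENTAL",
                 "COMPLEX", "NO_LOH")

#' Complex-event subclass codes
#'
#' Genotypic subclasses of complex LOH events, assigned from PCR zygosity
#' at the retained telomeric locus and at the internal TYR1 diagnostic
#' locus: `HET_TELOMERIC` (retained locus heterozygous; consistent with
#' break-induced replication through the centromere or ectopic capture of
#' the telomeric fragment), `HALF_CO_NAT_TYR1` and `HALF_CO_TYR1_URA3`
#' (retained locus homozygous with a single TYR1 allele, placing a half
#' crossover in the corresponding interval), `UNRESOLVED` (zygosity calls
#' missing) and `ANOMALOUS` (combinations outside the model, e.g.
#' heterozygous NAT with homozygous TYR1).
#'
#' @format Character vector of subclass codes.
#' @export
COMPLEX_SUBCLASSES <- c("HET_TELOMERIC", "HALF_CO_NAT_TYR1",
                        "HALF_CO_TYR1_URA3", "UNRESOLVED", "ANOMALOUS")

#' Event classes understood by the culture simulator
#'
#' The four LOH classes that found resistant clones, plus
#' `POINT_MUTATION` (inactivating mutation of URA3 itself, which is
#' phenotypically indistinguishable from gene conversion in this assay).
#'
#' @format Character vector of simulator event classes.
#' @export
SIM_CLASSES <- c("CHROMOSOME_LOSS", "GENE_CONVERSION", "SEGMENTAL",
                 "COMPLEX", "POINT_MUTATION")

.TERNARY <- c("yes", "no", "untested")
.ZYG     <- c("heterozygous", "homozygous", "untested")
.TYR1ALL <- c("1", "2", "both", "untested")

#' MarkerMap: ordered marker loci on the chromosome II homolog pair
#'
#' Describes the diploid marker strain: an ordered set of loci with kb
#' positions, the allele identity carried by each homolog (IIa is the
#' marked homolog, carrying the "-2" PCR alleles; IIb carries the "-1"
#' alleles), whether each allele confers its growth phenotype, and which
#' selection channel ("trp", "hyg", "foa", "nat" or "none") the locus
#' drives. The "foa" channel is the recessive counter-selected URA3 locus.
#'
#' @slot name label of the map variant.
#' @slot loci data.frame with columns `name`, `kb`, `channel`, `alleleA`,
#'   `alleleB`, `functionalA`, `functionalB` (A = homolog IIa, B = IIb),
#'   ordered by increasing `kb`.
#' @slot chromLengthKb chromosome length in kb.
#' @slot centromereKb centromere position in kb.
#' @export
setClass("MarkerMap",
  representation(name = "character", loci = "data.frame",
                 chromLengthKb = "numeric", centromereKb = "numeric"))

setValidity("MarkerMap", function(object) {
  lc <- object@loci
  need <- c("name", "kb", "channel", "alleleA", "alleleB",
            "functionalA", "functionalB")
  if (!all(need %in% names(lc)))
    return(paste("loci must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(lc$name)) return("duplicated locus names")
  if (is.unsorted(lc$kb, strictly = TRUE))
    return("locus positions must be strictly increasing (kb)")
  if (!all(lc$channel %in% c("trp", "hyg", "foa", "nat", "none")))
    return("unknown selection channel")
  if (any(tabulate(factor(lc$channel, c("trp", "hyg", "foa", "nat"))) > 1))
    return("at most one locus per selection channel")
  if (length(object@centromereKb) != 1 ||
      object@centromereKb < min(lc$kb) || object@centromereKb > max(lc$kb))
    return("centromere position must lie between the outermost loci")
  if (object@chromLengthKb < max(lc$kb))
    return("chromosome length smaller than the rightmost locus")
  TRUE
})

#' DiploidGenotype: per-homolog allele states and homolog copy numbers
#'
#' The object LOH events act on. Allele identities are character ids drawn
#' from the marker map; a lost homolog has copy number 0 and `NA` allele
#' states at every locus.
#'
#' @slot alleles character matrix, loci x homologs (`"IIa"`, `"IIb"`).
#' @slot copyNumber named integer vector (0 or 1 per homolog).
#' @slot mapName name of the [MarkerMap] the genotype refers to.
#' @export
setClass("DiploidGenotype",
  representation(alleles = "matrix", copyNumber = "integer",
                 mapName = "character"))

setValidity("DiploidGenotype", function(object) {
  cn <- object@copyNumber
  if (length(cn) != 2 || !identical(names(cn), c("IIa", "IIb")))
    return("copyNumber must be named c(IIa=, IIb=)")
  if (!all(cn %in% 0:1)) return("homolog copy number must be 0 or 1")
  if (!identical(colnames(object@alleles), c("IIa", "IIb")))
    return("allele matrix must have columns IIa, IIb")
  for (h in c("IIa", "IIb")) {
    if (cn[[h]] == 0L && !all(is.na(object@alleles[, h])))
      return(sprintf("homolog %s is lost but carries allele states", h))
    if (cn[[h]] == 1L && anyNA(object@alleles[, h]))
      return(sprintf("homolog %s is present but has NA allele states", h))
  }
  TRUE
})

#' ColonyPhenotype: growth calls plus optional zygosity calls
#'
#' Ternary growth calls (`"yes"`, `"no"`, `"untested"`) on the four test
#' media -- 5FOA, NAT, hygromycin, tryptophan dropout -- and optional PCR
#' zygosity calls at the NAT, TRP1 and TYR1 loci. `tyr1Alleles` records
#' which TYR1 truncation allele(s) were detected (`"1"`, `"2"`, `"both"`).
#'
#' @slot foa,nat,hyg,trp growth calls.
#' @slot natZyg,trp1Zyg,tyr1Zyg zygosity calls
#'   (`"heterozygous"`, `"homozygous"`, `"untested"`).
#' @slot tyr1Alleles which TYR1 allele(s) were detected.
#' @export
setClass("ColonyPhenotype",
  representation(foa = "character", nat = "character", hyg = "character",
                 trp = "character", natZyg = "character",
                 trp1Zyg = "character", tyr1Zyg = "character",
                 tyr1Alleles = "character"))

setValidity("ColonyPhenotype", function(object) {
  for (s in c("foa", "nat", "hyg", "trp")) {
    v <- slot(object, s)
    if (length(v) != 1 || !v %in% .TERNARY)
      return(sprintf("%s must be one of %s", s,
                     paste(.TERNARY, collapse = "/")))
  }
  for (s in c("natZyg", "trp1Zyg", "tyr1Zyg")) {
    if (!slot(object, s) %in% .ZYG)
      return(sprintf("%s must be one of %s", s, paste(.ZYG, collapse = "/")))
  }
  if (!object@tyr1Alleles %in% .TYR1ALL)
    return("tyr1Alleles must be one of 1/2/both/untested")
  TRUE
})

#' EventRates: per-class LOH event rates for the simulator
#'
#' Rates are per cell division. The complex class carries a categorical
#' distribution over its genotypic subclasses.
#'
#' @slot rates named numeric vector over [SIM_CLASSES], events per division.
#' @slot complexSubclassProbs named numeric probabilities over the three
#'   constructible complex subclasses; must sum to 1.
#' @export
setClass("EventRates",
  representation(rates = "numeric", complexSubclassProbs = "numeric"))

setValidity("EventRates", function(object) {
  if (!identical(sort(names(object@rates)), sort(SIM_CLASSES)))
    return("rates must be named by SIM_CLASSES")
  if (any(object@rates < 0)) return("rates must be >= 0")
  p <- object@complexSubclassProbs
  ok <- c("HET_TELOMERIC", "HALF_CO_NAT_TYR1", "HALF_CO_TYR1_URA3")
  if (!all(names(p) %in% ok)) return("unknown complex subclass in probs")
  if (any(p < 0)) return("subclass probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-8) return("subclass probabilities must sum to 1")
  TRUE
})

#' CultureConfig: one fluctuation culture's growth and plating design
#'
#' @slot n0 inoculum size (cells).
#' @slot nFinal target final culture size (cells).
#' @slot dilution fraction of the culture plated on selective medium,
#'   in (0, 1].
#' @slot platingEfficiency fraction of plated resistant cells that form a
#'   colony, in (0, 1].
#' @export
setClass("CultureConfig",
  representation(n0 = "numeric", nFinal = "numeric", dilution = "numeric",
                 platingEfficiency = "numeric"))

setValidity("CultureConfig", function(object) {
  if (object@n0 < 1 || object@n0 != round(object@n0))
    return("n0 must be a positive integer")
  if (object@nFinal < object@n0) return("nFinal must be >= n0")
  if (object@nFinal != round(object@nFinal))
    return("nFinal must be an integer cell count")
  if (object@dilution <= 0 || object@dilution > 1)
    return("dilution must be in (0, 1]")
  if (object@platingEfficiency <= 0 || object@platingEfficiency > 1)
    return("platingEfficiency must be in (0, 1]")
  TRUE
})

#' CultureResult: outcome of one simulated fluctuation culture
#'
#' @slot n0,nFinal inoculum and realized final cell count.
#' @slot dilution,platingEfficiency plating model actually applied.
#' @slot counts named resistant-cell counts per event class, after
#'   dilution/plating thinning (what is observed on the selective plate).
#' @slot countsPrePlating resistant cells in the culture before thinning.
#' @slot eventLog data.frame (`generation`, `class`, `nEvents`) of founding
#'   events.
#' @export
setClass("CultureResult",
  representation(n0 = "numeric", nFinal = "numeric", dilution = "numeric",
                 platingEfficiency = "numeric", counts = "numeric",
                 countsPrePlating = "numeric", eventLog = "data.frame"))

setValidity("CultureResult", function(object) {
  if (!identical(sort(names(object@counts)), sort(SIM_CLASSES)))
    return("counts must be named by SIM_CLASSES")
  if (any(object@counts > object@countsPrePlating[names(object@counts)]))
    return("plated counts exceed pre-plating counts")
  if (sum(object@countsPrePlating) > object@nFinal)
    return("resistant cells exceed the culture size")
  TRUE
})

#' RateEstimate: median LOH rate with an order-statistic confidence interval
#'
#' @slot classLabel event class (or `"TOTAL"`, `"NON_CL"`).
#' @slot assay free-text assay/genotype label used to guard arithmetic
#'   between estimates from different assays.
#' @slot median point estimate, events per cell division.
#' @slot ciLower,ciUpper confidence bounds (NA when unavailable).
#' @slot achievedLevel exact coverage of the order-statistic interval.
#' @slot requestedLevel nominal level asked for.
#' @slot nCultures number of cultures behind the estimate.
#' @slot perCultureRates the per-culture rates the order statistics act on.
#' @slot ciAvailable whether the interval is meaningful.
#' @slot method estimator variant used.
#' @slot note flags (zero-count handling, p0 fallback, ...).
#' @export
setClass("RateEstimate",
  representation(classLabel = "character", assay = "character",
                 median = "numeric", ciLower = "numeric", ciUpper = "numeric",
                 achievedLevel = "numeric", requestedLevel = "numeric",
                 nCultures = "integer", perCultureRates = "numeric",
                 ciAvailable = "logical", method = "character",
                 note = "character"))

setValidity("RateEstimate", function(object) {
  if (object@median < 0) return("median rate must be >= 0")
  if (object@ciAvailable) {
    if (is.na(object@ciLower) || is.na(object@ciUpper))
      return("CI marked available but bounds are NA")
    if (object@ciLower > object@median + 1e-12 ||
        object@ciUpper < object@median - 1e-12)
      return("CI must bracket the median")
  }
  TRUE
})

#' TestResult: outcome of one statistical test
#'
#' @slot method test label.
#' @slot statistic test statistic (NA for exact tests without one).
#' @slot pValue raw p-value.
#' @slot pAdjusted multiplicity-adjusted p-value (NA if not adjusted).
#' @slot tails `"two-sided"`, `"greater"` or `"less"`.
#' @slot n problem size (total observations).
#' @export
setClass("TestResult",
  representation(method = "character", statistic = "numeric",
                 pValue = "numeric", pAdjusted = "numeric",
                 tails = "character", n = "numeric"))

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (is.na(p) || p < 0 || p > 1) return("pValue must be in [0, 1]")
  pa <- object@pAdjusted
  if (!is.na(pa) && (pa < 0 || pa > 1)) return("pAdjusted must be in [0, 1]")
  if (!is.na(pa) && pa < p - 1e-12) return("adjusted p below raw p")
  TRUE
})
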