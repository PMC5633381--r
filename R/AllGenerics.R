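#' @include AllClasses.R
NULL

#' Deduce a colony phenotype from a diploid genotype
#'
#' Growth on each test medium is scored from the dominance rules of the
#' assay: resistance/prototrophy is `"yes"` iff at least one retained
#' homolog carries a functional dominant allele of the corresponding
#' marker; 5FOA resistance is recessive and is `"yes"` iff no retained
#' homolog carries a functional URA3 allele. Zygosity calls at NAT, TRP1
#' and TYR1 are filled in from the allele identities.
#'
#' @param genotype a [DiploidGenotype].
#' @param map the [MarkerMap] the genotype refers to.
#' @return a [ColonyPhenotype].
#' @export
setGeneric("phenotypeOf", function(genotype, map)
  standardGeneric("phenotypeOf"))

#' Classify a colony phenotype into an LOH class
#'
#' Deterministic mapping from the four growth calls: 5FOA-sensitive
#' colonies are `NO_LOH`; among 5FOA-resistant colonies,
#' (trp-, hyg-, nat-) is `CHROMOSOME_LOSS`, (trp+, hyg+, nat+) is
#' `GENE_CONVERSION`, (trp+, hyg+, nat-) is `SEGMENTAL`, and retention of
#' exactly one telomeric marker, (trp+, hyg-, nat-) or (trp-, hyg-, nat+),
#' is `COMPLEX`. Any other pattern returns `"ANOMALOUS"` (reported, never
#' merged into a class).
#'
#' @param x a [ColonyPhenotype], or a data.frame in the phenotype-table
#'   dialect (see [readPhenotypeTable]) for the vectorized method.
#' @param ... unused.
#' @return class code(s); see [LOH_CLASSES].
#' @export
setGeneric("classifyPhenotype", function(x, ...)
  standardGeneric("classifyPhenotype"))

#' Subclassify a complex LOH event from zygosity calls
#'
#' Applies only to colonies classified `COMPLEX`. On the NAT side
#' (trp-, hyg-, nat+), both the NAT and TYR1 zygosity calls are required;
#' a heterozygous NAT locus indicates the telomeric fragment was preserved
#' next to the intact homolog (`HET_TELOMERIC`); a homozygous NAT locus
#' with only TYR1 allele 1 places a half crossover between NAT and TYR1
#' (`HALF_CO_NAT_TYR1`), with only allele 2 between TYR1 and URA3
#' (`HALF_CO_TYR1_URA3`). Heterozygous NAT with homozygous TYR1 is
#' `ANOMALOUS`. Missing calls give `UNRESOLVED` (not an error). On the
#' TRP1 side only the telomeric-locus call is informative: heterozygous is
#' `HET_TELOMERIC`, anything else `UNRESOLVED`.
#'
#' @param x a [ColonyPhenotype] whose class is `COMPLEX`.
#' @param ... unused.
#' @return a subclass code; see [COMPLEX_SUBCLASSES].
#' @export
setGeneric("subclassifyComplex", function(x, ...)
  standardGeneric("subclassifyComplex"))

#' Apply an LOH event to a heterozygous starting genotype
#'
#' @param genotype the URA3-heterozygous starting [DiploidGenotype] with
#'   both homologs present.
#' @param event an event class from [SIM_CLASSES] or a constructible
#'   complex subclass (`HET_TELOMERIC`, `HALF_CO_NAT_TYR1`,
#'   `HALF_CO_TYR1_URA3`).
#' @param map the [MarkerMap].
#' @return the post-event [DiploidGenotype].
#' @export
setGeneric("applyEvent", function(genotype, event, map)
  standardGeneric("applyEvent"))

#' PCR zygosity at a locus
#'
#' Heterozygous when the retained homologs carry two distinct PCR alleles
#' at the locus, homozygous when a single allele identity is detected
#' (PCR cannot distinguish one copy from two identical copies).
#'
#' @param genotype a [DiploidGenotype].
#' @param locus locus name.
#' @return `"heterozygous"` or `"homozygous"`, plus attribute `alleles`
#'   with the detected allele ids.
#' @export
setGeneric("zygosityAt", function(genotype, locus)
  standardGeneric("zygosityAt"))

#' @rdname RateEstimate-accessors
#' @export
setGeneric("rateMedian", function(x) standardGeneric("rateMedian"))

#' @rdname RateEstimate-accessors
#' @export
setGeneric("rateCI", function(x) standardGeneric("rateCI"))

#' @rdname RateEstimate-accessors
#' @export
setGeneric("achievedLevel", function(x) standardGeneric("achievedLevel"))

#' @rdname RateEstimate-accessors
#' @export
setGeneric("nCultures", function(x) standardGeneric("nCultures"))

#' @rdname RateEstimate-accessors
#' @export
setGeneric("lohClass", function(x) standardGeneric("lohClass"))

#' Accessors for marker maps
#'
#' @param x a [MarkerMap].
#' @return `markerLoci` returns the locus table; `centromereKb` the
#'   centromere position in kb.
#' @rdname MarkerMap-accessors
#' @export
setGeneric("markerLoci", function(x) standardGeneric("markerLoci"))

#' @rdname MarkerMap-accessors
#' @export
setGeneric("centromereKb", function(x) standardGeneric("centromereKb"))

#' Accessors for culture results
#'
#' @param x a [CultureResult].
#' @param prePlating return counts before dilution/plating thinning?
#' @return named per-class resistant-cell counts.
#' @export
setGeneric("cultureCounts", function(x, prePlating = FALSE)
  standardGeneric("cultureCounts"))

#' @rdname TestResult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname TestResult-accessors
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
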