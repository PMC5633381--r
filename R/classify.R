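#' @include AllClasses.R AllGenerics.R genotype.R
NULL

# core classifier on bare growth calls ("yes"/"no"); vectorized
.classifyCalls <- function(foa, trp, hyg, nat) {
  pattern <- paste(trp, hyg, nat)
  cls <- rep("ANOMALOUS", length(foa))
  cls[pattern == "no no no"]    <- "CHROMOSOME_LOSS"
  cls[pattern == "yes yes yes"] <- "GENE_CONVERSION"
  cls[pattern == "yes yes no"]  <- "SEGMENTAL"
  cls[pattern %in% c("yes no no", "no no yes")] <- "COMPLEX"
  cls[foa == "no"] <- "NO_LOH"
  cls
}

#' @rdname classifyPhenotype
#' @export
setMethod("classifyPhenotype", "ColonyPhenotype", function(x, ...) {
  calls <- c(x@foa, x@trp, x@hyg, x@nat)
  if (any(calls == "untested"))
    stop("classification requires yes/no growth calls on all four media")
  .classifyCalls(x@foa, x@trp, x@hyg, x@nat)
})

#' @rdname classifyPhenotype
#' @export
setMethod("classifyPhenotype", "data.frame", function(x, ...) {
  need <- c("foa", "trp", "hyg", "nat")
  if (!all(need %in% names(x)))
    stop("phenotype table must have columns foa, nat, hyg, trp")
  ok <- !Reduce(`|`, lapply(x[need], function(v) is.na(v) | v == "untested"))
  cls <- rep(NA_character_, nrow(x))
  cls[ok] <- .classifyCalls(x$foa[ok], x$trp[ok], x$hyg[ok], x$nat[ok])
  cls
})

#' @rdname subclassifyComplex
#' @export
setMethod("subclassifyComplex", "ColonyPhenotype", function(x, ...) {
  if (classifyPhenotype(x) != "COMPLEX")
    stop("subclassification applies only to COMPLEX colonies")
  if (x@nat == "yes") {                       # NAT side
    if (x@natZyg == "untested" || x@tyr1Zyg == "untested")
      return("UNRESOLVED")
    if (x@natZyg == "heterozygous") {
      if (x@tyr1Zyg == "homozygous") return("ANOMALOUS")
      return("HET_TELOMERIC")
    }
    # NAT homozygous: the detected TYR1 allele places the exchange
    if (x@tyr1Zyg == "heterozygous") return("ANOMALOUS")
    if (x@tyr1Alleles == "1") return("HALF_CO_NAT_TYR1")
    if (x@tyr1Alleles == "2") return("HALF_CO_TYR1_URA3")
    return("UNRESOLVED")
  }
  # TRP1 side: no internal diagnostic locus on the left arm
  if (x@trp1Zyg == "heterozygous") return("HET_TELOMERIC")
  "UNRESOLVED"
})

#' Convert a phenotype-table row block to ColonyPhenotype objects
#'
#' @param df a phenotype table (see [readPhenotypeTable]).
#' @return list of [ColonyPhenotype].
#' @export
phenotypesFromTable <- function(df) {
  z <- function(v) ifelse(is.na(v), "untested", v)
  lapply(seq_len(nrow(df)), function(i)
    colonyPhenotype(
      foa = z(df$foa[i]), nat = z(df$nat[i]), hyg = z(df$hyg[i]),
      trp = z(df$trp[i]),
      natZyg = z(df$nat_zyg[i]), trp1Zyg = z(df$trp1_zyg[i]),
      tyr1Zyg = if (is.na(df$tyr1_alleles[i])) "untested"
                else if (df$tyr1_alleles[i] == "both") "heterozygous"
                else "homozygous",
      tyr1Alleles = z(df$tyr1_alleles[i])))
}

#' Convert ColonyPhenotype objects to a phenotype table
#'
#' @param phenos list of [ColonyPhenotype].
#' @param culture_id,colony_id,genotype recycled label columns.
#' @return data.frame in the phenotype-table dialect.
#' @export
phenotypesToTable <- function(phenos, culture_id = seq_along(phenos),
                              colony_id = seq_along(phenos),
                              genotype = "sim") {
  u <- function(v) ifelse(v == "untested", NA_character_, v)
  data.frame(
    culture_id = rep_len(as.character(culture_id), length(phenos)),
    colony_id = rep_len(as.character(colony_id), length(phenos)),
    genotype = rep_len(genotype, length(phenos)),
    foa = u(vapply(phenos, slot, "", "foa")),
    nat = u(vapply(phenos, slot, "", "nat")),
    hyg = u(vapply(phenos, slot, "", "hyg")),
    trp = u(vapply(phenos, slot, "", "trp")),
    nat_zyg = u(vapply(phenos, slot, "", "natZyg")),
    trp1_zyg = u(vapply(phenos, slot, "", "trp1Zyg")),
    tyr1_alleles = u(vapply(phenos, slot, "", "tyr1Alleles")),
    stringsAsFactors = FALSE)
}
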