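#' @include AllClasses.R AllGenerics.R markerMap.R
NULL

#' The heterozygous starting genotype of a marker map
#'
#' Both homologs present, homolog IIa carrying the ectopic markers and
#' homolog IIb the reciprocal alleles; 5FOA-sensitive.
#'
#' @param map a [MarkerMap].
#' @return a [DiploidGenotype].
#' @examples
#' g0 <- startingGenotype(markerMapCentromericURA3())
#' classifyPhenotype(phenotypeOf(g0, markerMapCentromericURA3()))
#' @export
startingGenotype <- function(map) {
  stopifnot(is(map, "MarkerMap"))
  lc <- map@loci
  al <- cbind(IIa = lc$alleleA, IIb = lc$alleleB)
  rownames(al) <- lc$name
  new("DiploidGenotype", alleles = al,
      copyNumber = c(IIa = 1L, IIb = 1L), mapName = map@name)
}

#' Construct a colony phenotype
#'
#' @param foa,nat,hyg,trp growth calls (`"yes"`, `"no"`, `"untested"`).
#' @param natZyg,trp1Zyg,tyr1Zyg zygosity calls
#'   (`"heterozygous"`, `"homozygous"`, `"untested"`).
#' @param tyr1Alleles `"1"`, `"2"`, `"both"` or `"untested"`.
#' @return a [ColonyPhenotype].
#' @export
colonyPhenotype <- function(foa, nat, hyg, trp,
                            natZyg = "untested", trp1Zyg = "untested",
                            tyr1Zyg = "untested", tyr1Alleles = "untested") {
  new("ColonyPhenotype", foa = foa, nat = nat, hyg = hyg, trp = trp,
      natZyg = natZyg, trp1Zyg = trp1Zyg, tyr1Zyg = tyr1Zyg,
      tyr1Alleles = tyr1Alleles)
}

.checkGenotypeMap <- function(genotype, map) {
  if (!identical(rownames(genotype@alleles), map@loci$name))
    stop("genotype loci do not match the marker map '", map@name,
         "' (configuration error)")
}

.retainedAlleles <- function(genotype, locus) {
  keep <- names(genotype@copyNumber)[genotype@copyNumber == 1L]
  unique(genotype@alleles[locus, keep])
}

#' @rdname zygosityAt
#' @export
setMethod("zygosityAt", signature("DiploidGenotype", "character"),
function(genotype, locus) {
  if (!locus %in% rownames(genotype@alleles))
    stop("locus '", locus, "' not in genotype (configuration error)")
  ids <- .retainedAlleles(genotype, locus)
  if (length(ids) == 0)
    stop("no retained homolog carries locus '", locus, "'")
  z <- if (length(ids) >= 2) "heterozygous" else "homozygous"
  structure(z, alleles = ids)
})

# growth call for a dominant channel: yes iff a retained homolog carries a
# functional allele of the channel's locus
.dominantCall <- function(genotype, map, channel) {
  locus <- .channelLocus(map, channel)
  if (is.na(locus)) return("untested")
  ids <- .retainedAlleles(genotype, locus)
  if (any(ids %in% .functionalAlleles(map, locus))) "yes" else "no"
}

#' @rdname phenotypeOf
#' @export
setMethod("phenotypeOf", signature("DiploidGenotype", "MarkerMap"),
function(genotype, map) {
  .checkGenotypeMap(genotype, map)
  if (sum(genotype@copyNumber) == 0)
    stop("both homologs lost: inviable state")
  foaLocus <- .channelLocus(map, "foa")
  if (is.na(foaLocus)) stop("map has no URA3 (foa) locus")
  uraIds <- .retainedAlleles(genotype, foaLocus)
  foa <- if (any(uraIds %in% .functionalAlleles(map, foaLocus)))
    "no" else "yes"   # URA3 is recessive: resistance requires no functional copy

  zygOf <- function(locus) {
    if (is.na(locus) || !locus %in% rownames(genotype@alleles))
      return(structure("untested", alleles = character(0)))
    zygosityAt(genotype, locus)
  }
  natZ  <- zygOf(.channelLocus(map, "nat"))
  trpZ  <- zygOf(.channelLocus(map, "trp"))
  tyrZ  <- zygOf(if ("TYR1" %in% rownames(genotype@alleles)) "TYR1"
                 else NA_character_)
  tyrIds <- attr(tyrZ, "alleles")
  tyrAll <- if (length(tyrIds) == 0) "untested"
            else if (all(c("TYR1-1", "TYR1-2") %in% tyrIds)) "both"
            else if ("TYR1-2" %in% tyrIds) "2" else "1"

  colonyPhenotype(
    foa = foa,
    nat = .dominantCall(genotype, map, "nat"),
    hyg = .dominantCall(genotype, map, "hyg"),
    trp = .dominantCall(genotype, map, "trp"),
    natZyg = as.character(natZ), trp1Zyg = as.character(trpZ),
    tyr1Zyg = as.character(tyrZ), tyr1Alleles = tyrAll)
})

# midpoint break positions used by the complex-event edits
.breakKb <- function(map, left, right) {
  (map@loci[left, "kb"] + map@loci[right, "kb"]) / 2
}

.requireComplexGeometry <- function(map) {
  foaLocus <- .channelLocus(map, "foa")
  natLocus <- .channelLocus(map, "nat")
  if (is.na(foaLocus) || is.na(natLocus) ||
      !"TYR1" %in% map@loci$name ||
      !(map@loci[foaLocus, "kb"] < map@loci["TYR1", "kb"] &&
        map@loci["TYR1", "kb"] < map@loci[natLocus, "kb"]))
    stop("complex-event edits require the URA3 < TYR1 < NAT geometry of ",
         "the centromeric-URA3 map")
  c(foa = foaLocus, nat = natLocus)
}

#' @rdname applyEvent
#' @export
setMethod("applyEvent",
          signature("DiploidGenotype", "character", "MarkerMap"),
function(genotype, event, map) {
  .checkGenotypeMap(genotype, map)
  if (genotype@copyNumber[["IIa"]] == 0L)
    stop("invalid state: event applied to a genotype lacking homolog IIa")
  lc <- map@loci
  al <- genotype@alleles
  cn <- genotype@copyNumber
  foaLocus <- .channelLocus(map, "foa")

  loseIIa <- function() {
    al[, "IIa"] <<- NA_character_
    cn[["IIa"]] <<- 0L
  }
  # copy homolog IIb's alleles onto IIa at loci with kb >= from
  iiaFromB <- function(fromKb) {
    i <- lc$kb >= fromKb
    al[i, "IIa"] <<- lc$alleleB[i]
  }
  # copy homolog IIa's alleles onto IIb at loci with kb >= from
  iibFromA <- function(fromKb) {
    i <- lc$kb >= fromKb
    al[i, "IIb"] <<- lc$alleleA[i]
  }

  switch(event,
    CHROMOSOME_LOSS = loseIIa(),
    GENE_CONVERSION = {
      al[foaLocus, "IIa"] <- lc[foaLocus, "alleleB"]
    },
    POINT_MUTATION = {
      # inactivating mutation of the URA3 ORF itself; new allele id is not
      # in the map's functional set
      al[foaLocus, "IIa"] <- paste0(lc[foaLocus, "alleleA"], "*")
    },
    SEGMENTAL = {
      # homozygosis from URA3 through the right telomere
      iiaFromB(lc[foaLocus, "kb"])
    },
    COMPLEX = ,          # unspecified complex event: model the common case
    HET_TELOMERIC = {
      loci <- .requireComplexGeometry(map)
      # broken IIa; telomeric fragment distal of a break in (URA3, TYR1)
      # is preserved against a IIb template (BIR through the centromere or
      # ectopic capture): IIa becomes IIb-like proximal of the break
      brk <- .breakKb(map, loci[["foa"]], "TYR1")
      al[lc$kb < brk, "IIa"] <- lc$alleleB[lc$kb < brk]
    },
    HALF_CO_NAT_TYR1 = {
      loci <- .requireComplexGeometry(map)
      # half crossover in (TYR1, NAT): IIb captures IIa's segment distal
      # of the break; the rest of IIa is lost
      iibFromA(.breakKb(map, "TYR1", loci[["nat"]]))
      loseIIa()
    },
    HALF_CO_TYR1_URA3 = {
      loci <- .requireComplexGeometry(map)
      iibFromA(.breakKb(map, loci[["foa"]], "TYR1"))
      loseIIa()
    },
    stop("unknown event class: ", event)
  )
  new("DiploidGenotype", alleles = al, copyNumber = cn,
      mapName = genotype@mapName)
})

setMethod("show", "DiploidGenotype", function(object) {
  cn <- object@copyNumber
  cat(sprintf("DiploidGenotype on map '%s' (copy number IIa=%d, IIb=%d)\n",
              object@mapName, cn[["IIa"]], cn[["IIb"]]))
  print(object@alleles)
})

setMethod("show", "ColonyPhenotype", function(object) {
  g <- function(v) switch(v, yes = "+", no = "-", "?")
  cat(sprintf("ColonyPhenotype: 5FOA%s NAT%s HYG%s TRP%s\n",
              g(object@foa), g(object@nat), g(object@hyg), g(object@trp)))
  z <- c(NAT = object@natZyg, TRP1 = object@trp1Zyg, TYR1 = object@tyr1Zyg)
  z <- z[z != "untested"]
  if (length(z))
    cat("  zygosity:", paste(names(z), z, sep = "=", collapse = ", "),
        if (object@tyr1Alleles != "untested")
          sprintf("(TYR1 allele %s)", object@tyr1Alleles) else "", "\n")
})
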