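test_that("the starting heterozygote and canonical events give the expected phenotypes", {
  map <- markerMapCentromericURA3()
  g0 <- startingGenotype(map)

  p0 <- phenotypeOf(g0, map)
  expect_equal(p0@foa, "no")     # functional URA3 present: 5FOA-sensitive
  expect_equal(c(p0@nat, p0@hyg, p0@trp), rep("yes", 3))

  # whole-homolog loss: all four markers lost together
  pCL <- phenotypeOf(applyEvent(g0, "CHROMOSOME_LOSS", map), map)
  expect_equal(pCL@foa, "yes")
  expect_equal(c(pCL@nat, pCL@hyg, pCL@trp), rep("no", 3))

  # local conversion of URA3 only: everything else retained
  pGC <- phenotypeOf(applyEvent(g0, "GENE_CONVERSION", map), map)
  expect_equal(pGC@foa, "yes")
  expect_equal(c(pGC@nat, pGC@hyg, pGC@trp), rep("yes", 3))

  # right-arm homozygosis: URA3 and NAT lost, left arm kept
  pSeg <- phenotypeOf(applyEvent(g0, "SEGMENTAL", map), map)
  expect_equal(c(pSeg@foa, pSeg@trp, pSeg@hyg, pSeg@nat),
               c("yes", "yes", "yes", "no"))

  # a URA3 point mutation is phenotypically a gene conversion
  pPM <- phenotypeOf(applyEvent(g0, "POINT_MUTATION", map), map)
  expect_equal(classifyPhenotype(pPM), "GENE_CONVERSION")
})

test_that("classification maps the growth-call patterns onto the class scheme", {
  expect_equal(classifyPhenotype(callPattern("+---")), "CHROMOSOME_LOSS")
  expect_equal(classifyPhenotype(callPattern("++++")), "GENE_CONVERSION")
  expect_equal(classifyPhenotype(callPattern("+++-")), "SEGMENTAL")
  expect_equal(classifyPhenotype(callPattern("++--")), "COMPLEX")  # TRP side
  expect_equal(classifyPhenotype(callPattern("+--+")), "COMPLEX")  # NAT side
  expect_equal(classifyPhenotype(callPattern("-+++")), "NO_LOH")

  # classification needs complete growth calls
  expect_error(classifyPhenotype(colonyPhenotype("yes", "untested",
                                                 "no", "no")),
               "growth calls")
})

test_that("the sixteen growth-call patterns partition into classes with anomalies surfaced", {
  pats <- expand.grid(foa = c("+", "-"), trp = c("+", "-"),
                      hyg = c("+", "-"), nat = c("+", "-"),
                      stringsAsFactors = FALSE)
  cls <- vapply(seq_len(nrow(pats)), function(i)
    classifyPhenotype(callPattern(paste0(pats$foa[i], pats$trp[i],
                                         pats$hyg[i], pats$nat[i]))), "")
  expect_equal(sum(cls == "NO_LOH"), 8)       # all 5FOA-sensitive patterns
  counts <- table(cls[pats$foa == "+"])
  expect_equal(as.integer(counts[c("CHROMOSOME_LOSS", "GENE_CONVERSION",
                                   "SEGMENTAL", "COMPLEX", "ANOMALOUS")]),
               c(1L, 1L, 1L, 2L, 3L))
  # anomalous patterns are exactly those retaining HYG with a broken flank
  anom <- pats[pats$foa == "+" & cls == "ANOMALOUS", ]
  expect_true(all(anom$hyg == "+" | (anom$trp == "+" & anom$nat == "+")))
})

test_that("complex events subclassify from zygosity calls as in the genotyping scheme", {
  natSide <- function(natZyg, tyr1Zyg, tyr1All)
    colonyPhenotype("yes", "yes", "no", "no", natZyg = natZyg,
                    tyr1Zyg = tyr1Zyg, tyr1Alleles = tyr1All)
  expect_equal(subclassifyComplex(
    natSide("heterozygous", "heterozygous", "both")), "HET_TELOMERIC")
  expect_equal(subclassifyComplex(
    natSide("homozygous", "homozygous", "1")), "HALF_CO_NAT_TYR1")
  expect_equal(subclassifyComplex(
    natSide("homozygous", "homozygous", "2")), "HALF_CO_TYR1_URA3")
  # the combination never observed in the genotyped spectrum
  expect_equal(subclassifyComplex(
    natSide("heterozygous", "homozygous", "1")), "ANOMALOUS")
  # missing calls are unresolved, not an error
  expect_equal(subclassifyComplex(
    natSide("untested", "untested", "untested")), "UNRESOLVED")
  expect_equal(subclassifyComplex(
    natSide("homozygous", "untested", "untested")), "UNRESOLVED")

  # TRP side: only the telomeric-locus call is informative
  trpSide <- colonyPhenotype("yes", "no", "no", "yes",
                             trp1Zyg = "heterozygous")
  expect_equal(subclassifyComplex(trpSide), "HET_TELOMERIC")

  expect_error(subclassifyComplex(callPattern("++++")), "COMPLEX")
})

test_that("event application round-trips through phenotype and classification", {
  map <- markerMapCentromericURA3()
  g0 <- startingGenotype(map)
  events <- c(CHROMOSOME_LOSS = "CHROMOSOME_LOSS",
              GENE_CONVERSION = "GENE_CONVERSION",
              SEGMENTAL = "SEGMENTAL",
              HET_TELOMERIC = "COMPLEX",
              HALF_CO_NAT_TYR1 = "COMPLEX",
              HALF_CO_TYR1_URA3 = "COMPLEX")
  for (e in names(events)) {
    p <- phenotypeOf(applyEvent(g0, e, map), map)
    expect_equal(classifyPhenotype(p), unname(events[e]), label = e)
    if (events[e] == "COMPLEX")
      expect_equal(subclassifyComplex(p), e)
  }
  # the preserved-fragment scenarios leave the telomeric locus heterozygous
  gHet <- applyEvent(g0, "HET_TELOMERIC", map)
  expect_equal(as.character(zygosityAt(gHet, "NAT")), "heterozygous")
  # half crossovers leave it homozygous for the marked-homolog allele
  gHC <- applyEvent(g0, "HALF_CO_NAT_TYR1", map)
  z <- zygosityAt(gHC, "NAT")
  expect_equal(as.character(z), "homozygous")
  expect_equal(attr(z, "alleles"), "NAT-2")

  expect_error(applyEvent(applyEvent(g0, "CHROMOSOME_LOSS", map),
                          "GENE_CONVERSION", map), "IIa")
})

test_that("phenotypes are invariant to locus order in the map definition", {
  map <- markerMapCentromericURA3()
  loci <- markerLoci(map)
  set.seed(11)
  shuffled <- MarkerMap(loci[sample(nrow(loci)), ],
                        chromLengthKb = 813, centromereKb = 238)
  g0 <- startingGenotype(map)
  gS <- startingGenotype(shuffled)
  for (e in c("CHROMOSOME_LOSS", "SEGMENTAL", "HET_TELOMERIC")) {
    pA <- phenotypeOf(applyEvent(g0, e, map), map)
    pB <- phenotypeOf(applyEvent(gS, e, shuffled), shuffled)
    expect_equal(pA, pB, label = e)
  }
})

test_that("marker maps validate their geometry and round-trip through JSON", {
  map <- markerMapCentromericURA3()
  expect_equal(markerLoci(map)$kb[markerLoci(map)$name == "URA3"], 241)
  expect_equal(centromereKb(map), 238)

  # the telomeric-URA3 variant puts the counter-selected marker at 795 kb
  tel <- markerMapTelomericURA3()
  expect_equal(markerLoci(tel)$channel[markerLoci(tel)$kb > 700],
               c("foa", "nat"))
  g <- applyEvent(startingGenotype(tel), "SEGMENTAL", tel)
  expect_equal(classifyPhenotype(phenotypeOf(g, tel)), "SEGMENTAL")

  bad <- markerLoci(map); bad$kb[2] <- bad$kb[1]  # duplicate position
  expect_error(MarkerMap(bad, 813, 238), "increasing")
  expect_error(MarkerMap(markerLoci(map), 813, 900), "centromere")

  f <- tempfile(fileext = ".json")
  writeMarkerMap(map, f)
  map2 <- readMarkerMap(f)
  expect_equal(markerLoci(map2), markerLoci(map))
  expect_equal(selectMarkerMap("cen")@name, map@name)

  # genotype from one map refuses a mismatched map
  expect_error(phenotypeOf(startingGenotype(map),
                           markerMapTelomericURA3()),
               "configuration error")
})
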