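---
title: "Classifying LOH events and estimating their rates from fluctuation assays"
author: "fluctLOH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying LOH events and estimating their rates from fluctuation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctLOH)
```

## The assay and its genetic model

The package analyses a diploid yeast loss-of-heterozygosity (LOH) assay
built on chromosome II. One homolog (called IIa here) carries four ectopic
markers: *TRP1* near the left telomere, a hygromycin-resistance cassette
(HYG) centromere-proximal on the left arm, *URA3* just right of the
centromere at 241 kb, and a nourseothricin-resistance cassette (NAT) at
795 kb near the right telomere. Both homologs additionally carry distinct
truncated *TYR1* alleles at ~583 kb (~230 kb from the right telomere);
these confer no growth phenotype in this assay and serve purely as a PCR
diagnostic. Cells that lose the functional *URA3* become resistant to
5-fluoroorotic acid (5FOA), so plating on 5FOA selects LOH around the
centromere; the surviving colonies are then scored on NAT, hygromycin and
tryptophan-dropout media.

`markerMapCentromericURA3()` encodes this strain; a second bundled map,
`markerMapTelomericURA3()`, places *URA3* next to NAT at 795 kb and is
used to measure LOH of a telomeric marker. Allele identifiers follow the
PCR naming of the assay: homolog IIa carries the "-2" alleles and homolog
IIb the "-1" alleles.

Growth calls follow two dominance rules, implemented in `phenotypeOf()`:

* NAT/HYG/TRP resistance or prototrophy is **dominant**: one functional
  allele on a retained homolog suffices.
* 5FOA resistance is **recessive**: it requires that *no* retained
  homolog carry a functional *URA3*.

`classifyPhenotype()` maps the four growth calls onto the event classes:

| trp | hyg | nat | class |
|-----|-----|-----|-------|
| −   | −   | −   | `CHROMOSOME_LOSS` (whole-homolog aneuploidy) |
| +   | +   | +   | `GENE_CONVERSION` (local loss of *URA3* only) |
| +   | +   | −   | `SEGMENTAL` (right-arm homozygosis) |
| +   | −   | −   | `COMPLEX`, TRP1 side (one telomeric marker retained) |
| −   | −   | +   | `COMPLEX`, NAT side |

5FOA-sensitive colonies are `NO_LOH`. The three remaining patterns (all
retaining HYG with a broken flank, or retaining both telomeric markers
without HYG) fall outside the four-scenario model; they are returned as
`"ANOMALOUS"` and reported with counts, never merged into a class. The
biological rationale: the assay's scenarios were enumerated from
single-transaction chromosome mechanics, and a pattern outside them means
either a scoring error or a multi-step event that deserves scrutiny, not
silent binning.

### Complex events

Complex events retain exactly one telomeric marker and require more than
one chromosome transaction. `subclassifyComplex()` resolves their
mechanism from PCR zygosity at the retained telomeric locus and at
*TYR1*:

* retained locus **heterozygous** — the telomeric fragment of IIa
  persists next to an intact IIb; consistent with break-induced
  replication (BIR) through the centromere or ectopic capture of the
  fragment (`HET_TELOMERIC`);
* retained locus **homozygous** with only *TYR1* allele 1 — half
  crossover between NAT and *TYR1* (`HALF_CO_NAT_TYR1`);
* homozygous with only *TYR1* allele 2 — half crossover between *TYR1*
  and *URA3* (`HALF_CO_TYR1_URA3`);
* heterozygous NAT with homozygous *TYR1* is geometrically inconsistent
  with all of the above and returns `ANOMALOUS`;
* missing calls return `UNRESOLVED` (not an error; genotyping is
  optional).

On the TRP1 side there is no internal diagnostic locus between the
telomeric marker and *URA3*, so only `HET_TELOMERIC` can be positively
identified; homozygous-TRP1 complex events are reported `UNRESOLVED`.
This is a deliberate design choice: inventing a left-arm half-crossover
subclass without a marker to place the exchange would overstate the
assay's resolution.

`applyEvent()` is the inverse direction: it edits the heterozygous
starting genotype according to an event class. For the half crossovers the
edit transfers homolog IIa's segment distal of a break (placed at the
midpoint of the flanking marker interval — the exact position within the
interval is unidentifiable and phenotypically irrelevant) onto IIb and
discards IIa; for `HET_TELOMERIC` the proximal part of IIa is rewritten
from the IIb template with the break placed between *URA3* and *TYR1*,
which reproduces the commonly observed fully heterozygous telomeric
segment. Every constructible event round-trips:
`classifyPhenotype(phenotypeOf(applyEvent(g0, e))) == class(e)`, and the
test suite checks this exhaustively.

```{r roundtrip}
map <- markerMapCentromericURA3()
g0 <- startingGenotype(map)
p <- phenotypeOf(applyEvent(g0, "HALF_CO_TYR1_URA3", map), map)
classifyPhenotype(p)
subclassifyComplex(p)
```

## The synthetic-culture generator

`simulateCulture()` is a forward Luria–Delbrück simulator that replaces
the wet-lab fluctuation assay. Its model and defaults:

* **Synchronous doublings.** Growth proceeds in generations from `n0` to
  `nFinal`; the last generation is partial so the culture stops at
  exactly `nFinal` cells. One division produces one new cell, so total
  divisions equal `nFinal - n0`, matching the "per cell division" rate
  unit used throughout. A continuous-time birth process would sharpen the
  clone-size distribution slightly but adds nothing for estimator
  validation, which only needs the jackpot-tailed mutant-count law.
* **Events.** In each generation, new events of class *k* arise as
  Binomial(divisions, mu_k); each founds a resistant clone that then
  grows at the wild-type rate (full phenotypic expression, no lag, no
  death). The simulator refuses total rates at or above 0.1 per division,
  where the rare-event bookkeeping (mutants drawn from all dividing
  cells, secondary events ignored) breaks down.
* **Neutrality by default.** Monosomic and recombinant clones grow at the
  wild-type rate because the estimator assumes neutrality; a
  `fitnessCost` knob exists to probe violations (e.g. poorly viable
  aneuploids) but defaults to 0.
* **No compound events.** A lineage that has already converted is not hit
  again: the crossover-then-chromosome-loss route to complex phenotypes
  is precisely the hypothesis the independence test is designed to
  examine, so the generator must not assume it.
* **Plating.** Observed counts are Binomial(clone cells,
  dilution × platingEfficiency); both default to 1 and dilution mirrors
  the protocol's 10–100× dilutions for high-rate genotypes.
* **Inoculum.** The patch-based protocol leaves `n0` ill-defined; the
  default is 1e3 cells, and estimates are insensitive to it once
  `nFinal/n0 >= 1e3` because the early generations contribute almost no
  divisions.
* **Seeding.** `simulateAssay()` draws one sub-seed per culture from the
  master seed via `sample.int`, so any culture is reproducible from
  `(seed, index)` and whole assays are deterministic.

`simulateIndependentColonies()` emulates the pronged mini-culture design
in which each culture contributes exactly one resistant colony: a culture
is simulated, one resistant cell is drawn with class probability
proportional to that culture's per-class counts, and zero-count cultures
are redrawn (with a retry budget and tally). Sampling within cultures —
rather than from the rate ratios — preserves the jackpot distortion of
class spectra that the bench design exhibits. `POINT_MUTATION` events
(inactivating *URA3* itself) produce the conversion phenotype, which is
exactly how they confound the bench assay.

What the generator does **not** emulate: cell death and viability
differences between classes (beyond the optional fitness knob), scoring
error on replica plates, cell-cycle structure (a G2-arrest condition is a
label on inputs, not dynamics), and dose–response of DNA-damaging
treatments (treatments enter as different rate configurations). Passing
recovery tests therefore validate the estimator's statistics, not these
biological complications.

## Rate estimation by the method of the median

For a culture with resistant count *r*, the Lea–Coulson median relation

$$ \frac{r}{m} - \ln m = 1.24 $$

links the count to the expected number *m* of founding events per
culture. `leaCoulsonM()` inverts it on the increasing branch
(*m* > e^{-1.24}), where the root is unique for every *r* > 0, using
bracketed root-finding polished by Newton steps to a relative tolerance
of 1e-9 (checked against a bisection oracle across nine decades of *r*).
The per-division rate is `m / (nFinal - n0)`.

`classRateTable()` assembles per-class estimates from classified
cultures:

1. per-culture counts are corrected for plating dilution (divided by the
   plated fraction);
2. each culture's count is converted to a rate (`"per-culture"` variant,
   the default) or the relation is applied once to the median count
   (`"pooled-median"`); the count-to-rate map is monotone, so the two
   point estimates agree up to even-*n* interpolation — both are provided
   because the literature uses both and the choice should be explicit;
3. the median and its confidence interval come from order statistics
   (below);
4. a class absent from every culture is reported as rate 0 with a
   p0-style upper bound (−ln((n−0.5)/n) events over the median division
   count) rather than an estimate.

**Zero-count cultures.** The median relation is undefined at *r* = 0.
The default (`zeroHandling = "as-zero"`) enters such cultures into the
order statistics as rate 0, which keeps the sample median of rates
aligned with the median count; this matters because excluding zeros
(`"exclude"`, also available) conditions the median on *r* > 0 and
inflates the estimate by ~70% when the expected events per culture is
near 1. When the median *count* itself is zero the median method is
abandoned for the p0 estimator `m = -ln(fraction of zero cultures)`
(`p0MethodM()`), which carries a point estimate but no order-statistic
interval.

**Confidence intervals.** `medianWithCI()` returns the nonparametric
order-statistic interval `[x_(l), x_(n+1-l)]` with `l` the largest rank
whose two-tailed Binomial(n, 1/2) probability outside the interval stays
within 1 − level. The *achieved* (exact) coverage is reported — e.g.
0.969 at n = 6 and 0.977 at n = 24 for a 95% request — and when n is too
small for the requested level (n < 6 at 95%) the widest interval is
returned and flagged. The interval covers the sampling median of the
per-culture rate; with heavily discrete counts this exceeds the nominal
level slightly (ties make the interval conservative). Interpolated ranks
are deliberately not used: exact ranks with stated coverage are easier to
audit than interpolation with approximate coverage.

**Derived rates.** `subtractRates()` implements the reported
"non-chromosome-loss" rates as a clamped difference of medians; order
statistic intervals do not propagate through differences, so the result
carries no CI, and estimates from different assays refuse to combine.

### Known estimator behaviour at m ≈ 1

The method of the median is a quantile estimator on a heavily discrete
distribution. When the expected events per culture are near 1 (e.g.
mu = 1e-5 with 1e5-cell cultures), the observed median count across 24
cultures is almost always 0, 1, 1.5 or 2, which maps to rate estimates of
roughly −40%, −10%, +12% and +34% relative to truth. Recovery within a
fixed ±30% band is therefore structurally capped near ~65% of replicate
assays in this regime, for any estimator in the median family — a
granularity effect, not an implementation defect. The acceptance script
computes this pass fraction (`fraction_within_30pct`) so the behaviour is
measured, not asserted; at 10+ expected events per culture the estimator
recovers rates and 3:1 rate contrasts comfortably (see the test suite),
and the interval coverage matches its stated exact level in both regimes.

## The inferential toolkit

The contingency and location tests delegate to the standard R
implementations behind a uniform `TestResult` interface, with the
conventions fixed to those that reproduce the published analyses:

* `fisherExact2x2()` — two-sided exact p by point-probability ordering
  (verified against full hypergeometric enumeration for every table with
  total ≤ 40);
* `twoProportionChisq()` — 1-df Pearson chi-square **without** continuity
  correction (the correction is switchable; uncorrected matches the
  reported large-sample significances), with a warning recommending the
  exact test when an expected cell falls below 1;
* `holmBonferroni()` — Holm step-down adjustment (uniformly more powerful
  than Bonferroni, identical for one test); the original analysis does
  not name its correction, so the default is the safer of the two;
* `independenceExpectedRate()` and `binomialIndependenceTest()` — the
  product-rate null for compound events and its upper-tail binomial
  p-value, evaluated exactly at any number of divisions via the
  incomplete-beta form of the binomial tail (no approximation switch is
  needed);
* `welchTTest()`, `mannWhitney()` — two-sided location tests on
  per-culture rates or band fractions; the rank test is exact for
  combined n ≤ 20 without ties. The published gel comparison does not
  name its test, so both are available with the rank test as default
  (band fractions are bounded and small-sample).
* `pfgeChr2Fraction()` — chromosome II band volume normalized by the
  summed II + XIV + X volumes of the same lane; ~1/3 at disomy, ~0.2
  after loss of one homolog.

## Pipeline and worked example

```{r pipeline}
ph <- readPhenotypeTable(system.file("extdata", "example-phenotypes.tsv",
                                     package = "fluctLOH"))
runClassify(ph)$distribution

cults <- readCultureTable(system.file("extdata", "example-cultures.tsv",
                                      package = "fluctLOH"), n0 = 1e3)
cols <- readPhenotypeTable(system.file("extdata",
                                       "example-culture-colonies.tsv",
                                       package = "fluctLOH"))
runRates(joinCultureClasses(cults, cols))[, c("genotype", "class",
                                              "median_per_1e7",
                                              "ci_lower_per_1e7",
                                              "ci_upper_per_1e7")]
```

Rates are reported both at full precision and rounded to two significant
figures per 1e7 divisions, the conventional presentation scale.
`runComplexPanel()` bundles the complex-event analyses (subclass
distribution, heterozygosity comparison, independence product and bound,
gel fractions), and `runSimulationStudy()` wraps simulate → estimate
loops into bias/coverage reports. A thin command-line front end over
these functions ships in `inst/scripts/loh-pipeline.R`.

## Problem sizes and reproducibility

The shipped validation uses deliberately moderate sizes chosen to
exercise the statistics well: exhaustive enumeration of 2×2 tables to
total 40 (~1.2e5 tables); 1e3 random points for the median-equation
oracle; 100 replicate assays of 24 cultures for recovery and coverage;
1e4 cultures for the jackpot (Fano factor) check; 300–400 independent
colonies per genotype for class-spectrum checks, matching the scale of
the bench experiments. All stochastic steps run from explicit seeds, and
assay-level results are byte-reproducible given the same seed and
configuration.

## Limitations

* The classifier is only as good as the four-media scoring; it has no
  notion of scoring noise, and anomalous patterns are surfaced rather
  than resolved.
* The estimator family assumes neutral, fully expressed mutants in
  exponentially growing cultures; differential viability (e.g. of
  monosomic clones) biases rates downward and can only be explored, not
  corrected, via the simulator's fitness knob.
* Complex-event subclassification resolves mechanism only on the NAT
  side, and `HET_TELOMERIC` deliberately lumps BIR-through-centromere
  with ectopic capture — distinguishing them needs karyotype-level data
  (e.g. pulsed-field gels), which enter this package only as band
  volumes.
* Rate differences carry no confidence intervals (order statistics do
  not subtract); treat derived non-CL rates as point summaries.
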