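#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a marker map
#'
#' Low-level constructor; most users want [markerMapCentromericURA3()] or
#' [markerMapTelomericURA3()].
#'
#' @param loci data.frame with columns `name`, `kb`, `channel`, `alleleA`,
#'   `alleleB`, `functionalA`, `functionalB`; rows are sorted by `kb`.
#' @param chromLengthKb chromosome length in kb.
#' @param centromereKb centromere position in kb.
#' @param name map label.
#' @return a [MarkerMap].
#' @export
MarkerMap <- function(loci, chromLengthKb, centromereKb, name = "custom") {
  loci <- loci[order(loci$kb), , drop = FALSE]
  rownames(loci) <- loci$name
  new("MarkerMap", name = name, loci = loci,
      chromLengthKb = as.numeric(chromLengthKb),
      centromereKb = as.numeric(centromereKb))
}

.lociDF <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df
}

#' Bundled marker maps of the diploid chromosome II LOH strain
#'
#' `markerMapCentromericURA3()` is the standard assay strain: homolog IIa
#' carries TRP1 at the left telomere, a hygromycin-resistance cassette
#' centromere-proximal on the left arm, URA3 at 241 kb just right of the
#' centromere, a truncated TYR1 allele at ~583 kb (~230 kb from the right
#' telomere) and a nourseothricin-resistance cassette at 795 kb; homolog
#' IIb carries the reciprocal "-1" PCR alleles, including the second TYR1
#' truncation, and no functional copy of any cassette (ura3-delta at the
#' URA3 locus). `markerMapTelomericURA3()` is the variant with URA3
#' inserted next to NAT at 795 kb, used to measure telomeric-marker LOH.
#'
#' @return a [MarkerMap].
#' @examples
#' markerMapCentromericURA3()
#' @export
markerMapCentromericURA3 <- function() {
  MarkerMap(
    .lociDF(
      name        = c("TRP1",   "HYG",   "URA3",   "TYR1",   "NAT"),
      kb          = c(5,        230,     241,      583,      795),
      channel     = c("trp",    "hyg",   "foa",    "none",   "nat"),
      alleleA     = c("TRP1-2", "HYG-2", "URA3-2", "TYR1-2", "NAT-2"),
      alleleB     = c("TRP1-1", "HYG-1", "ura3-1", "TYR1-1", "NAT-1"),
      functionalA = c(TRUE,     TRUE,    TRUE,     FALSE,    TRUE),
      functionalB = c(FALSE,    FALSE,   FALSE,    FALSE,    FALSE)),
    chromLengthKb = 813, centromereKb = 238,
    name = "chrII-centromeric-URA3")
}

#' @rdname markerMapCentromericURA3
#' @export
markerMapTelomericURA3 <- function() {
  MarkerMap(
    .lociDF(
      name        = c("TRP1",   "HYG",   "TYR1",   "URA3",   "NAT"),
      kb          = c(5,        230,     583,      794,      795),
      channel     = c("trp",    "hyg",   "none",   "foa",    "nat"),
      alleleA     = c("TRP1-2", "HYG-2", "TYR1-2", "URA3-2", "NAT-2"),
      alleleB     = c("TRP1-1", "HYG-1", "TYR1-1", "ura3-1", "NAT-1"),
      functionalA = c(TRUE,     TRUE,    FALSE,    TRUE,     TRUE),
      functionalB = c(FALSE,    FALSE,   FALSE,    FALSE,    FALSE)),
    chromLengthKb = 813, centromereKb = 238,
    name = "chrII-telomeric-URA3")
}

#' Select a bundled marker map by keyword
#'
#' @param which `"cen"`, `"tel"`, or a path to a marker-map JSON file.
#' @return a [MarkerMap].
#' @export
selectMarkerMap <- function(which = c("cen", "tel")) {
  if (length(which) == 1 && file.exists(which)) return(readMarkerMap(which))
  which <- match.arg(which)
  switch(which,
         cen = markerMapCentromericURA3(),
         tel = markerMapTelomericURA3())
}

#' Read / write a marker map as JSON
#'
#' The JSON layout is a list of locus records
#' `{name, kb, channel, alleleA, alleleB, functionalA, functionalB}` plus
#' `chromLengthKb`, `centromereKb` and `name` fields.
#'
#' @param path file path.
#' @param map a [MarkerMap].
#' @return `readMarkerMap` returns a [MarkerMap]; `writeMarkerMap` returns
#'   `path` invisibly.
#' @export
readMarkerMap <- function(path) {
  x <- jsonlite::fromJSON(path)
  MarkerMap(loci = as.data.frame(x$loci, stringsAsFactors = FALSE),
            chromLengthKb = x$chromLengthKb,
            centromereKb = x$centromereKb,
            name = if (is.null(x$name)) "custom" else x$name)
}

#' @rdname readMarkerMap
#' @export
writeMarkerMap <- function(map, path) {
  stopifnot(is(map, "MarkerMap"))
  x <- list(name = map@name, chromLengthKb = map@chromLengthKb,
            centromereKb = map@centromereKb, loci = map@loci)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname MarkerMap-accessors
#' @export
setMethod("markerLoci", "MarkerMap", function(x) x@loci)

#' @rdname MarkerMap-accessors
#' @export
setMethod("centromereKb", "MarkerMap", function(x) x@centromereKb)

# locus driving a selection channel, or NA if the map lacks it
.channelLocus <- function(map, channel) {
  i <- which(map@loci$channel == channel)
  if (length(i) == 0) NA_character_ else map@loci$name[i]
}

# allele ids considered functional at a locus
.functionalAlleles <- function(map, locus) {
  row <- map@loci[locus, ]
  out <- character(0)
  if (isTRUE(row$functionalA)) out <- c(out, row$alleleA)
  if (isTRUE(row$functionalB)) out <- c(out, row$alleleB)
  out
}

setMethod("show", "MarkerMap", function(object) {
  cat(sprintf("MarkerMap '%s': %d loci on chromosome II (%g kb, CEN at %g kb)\n",
              object@name, nrow(object@loci), object@chromLengthKb,
              object@centromereKb))
  print(object@loci, row.names = FALSE)
})
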