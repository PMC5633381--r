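#' @include AllClasses.R simulate.R
NULL

# growth-call recoding between the TSV dialect (+/-/NA) and yes/no
.callFromSymbol <- function(v) {
  v <- as.character(v)
  v[v %in% c("+", "yes")] <- "yes"
  v[v %in% c("-", "−", "no")] <- "no"
  v[!v %in% c("yes", "no")] <- NA_character_
  v
}

.symbolFromCall <- function(v) {
  out <- rep(NA_character_, length(v))
  out[v == "yes"] <- "+"
  out[v == "no"] <- "-"
  out
}

#' Read / write per-colony phenotype tables
#'
#' Tab-delimited, header row, UTF-8, `NA` for missing. Columns:
#' `culture_id`, `colony_id`, optional `genotype`, growth calls `foa`,
#' `nat`, `hyg`, `trp` coded `+`/`-`, and optional zygosity columns
#' `nat_zyg`, `trp1_zyg` (`het`/`hom`) and `tyr1_alleles`
#' (`1`/`2`/`both`). On reading, growth calls become `yes`/`no` and
#' zygosity calls `heterozygous`/`homozygous`.
#'
#' @param path file path.
#' @return data.frame in the internal phenotype-table layout.
#' @export
readPhenotypeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), colClasses = "character")
  need <- c("culture_id", "colony_id", "foa", "nat", "hyg", "trp")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  for (col in c("foa", "nat", "hyg", "trp"))
    df[[col]] <- .callFromSymbol(df[[col]])
  zmap <- c(het = "heterozygous", hom = "homozygous",
            heterozygous = "heterozygous", homozygous = "homozygous")
  for (col in c("nat_zyg", "trp1_zyg")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    else df[[col]] <- unname(zmap[df[[col]]])
  }
  if (!"tyr1_alleles" %in% names(df)) df$tyr1_alleles <- NA_character_
  if (!"genotype" %in% names(df)) df$genotype <- "unspecified"
  df
}

#' @rdname readPhenotypeTable
#' @param df phenotype table as returned by [readPhenotypeTable] or
#'   [phenotypesToTable].
#' @export
writePhenotypeTable <- function(df, path) {
  out <- df
  for (col in c("foa", "nat", "hyg", "trp"))
    out[[col]] <- .symbolFromCall(out[[col]])
  zmap <- c(heterozygous = "het", homozygous = "hom")
  for (col in c("nat_zyg", "trp1_zyg"))
    if (col %in% names(out)) out[[col]] <- unname(zmap[out[[col]]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-culture totals table
#'
#' Tab-delimited with columns `culture_id`, `genotype`,
#' `cells_plated_total_medium`, `dilution_total`, `colonies_total_medium`,
#' `colonies_5foa`, `dilution_5foa`. The culture size is inferred from the
#' permissive-plate count and its dilution
#' (`colonies_total_medium / dilution_total`).
#'
#' @param path file path.
#' @param n0 assumed inoculum size per culture.
#' @return data.frame with derived columns `n_final` and `n0`.
#' @export
readCultureTable <- function(path, n0 = 1e3) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("culture_id", "genotype", "dilution_total",
            "colonies_total_medium", "colonies_5foa", "dilution_5foa")
  if (!all(need %in% names(df)))
    stop("culture table must have columns: ", paste(need, collapse = ", "))
  df$n_final <- df$colonies_total_medium / df$dilution_total
  df$n0 <- n0
  df
}

#' Join culture totals with classified colonies into class counts
#'
#' Classifies the colony phenotypes and counts, per culture, the
#' 5FOA-resistant colonies in each LOH class. The per-class selective
#' plate counts are the class counts themselves (every resistant colony
#' on the plate is classified); the plated fraction is taken from the
#' culture table's `dilution_5foa`.
#'
#' @param cultures data.frame from [readCultureTable].
#' @param phenotypes data.frame from [readPhenotypeTable].
#' @return long class-count data.frame for [classRateTable] /
#'   [runRates], with anomalous colonies kept under class `ANOMALOUS`.
#' @export
joinCultureClasses <- function(cultures, phenotypes) {
  phenotypes$loh_class <- classifyPhenotype(phenotypes)
  classes <- sort(unique(stats::na.omit(phenotypes$loh_class)))
  classes <- setdiff(classes, "NO_LOH")
  do.call(rbind, lapply(seq_len(nrow(cultures)), function(i) {
    cid <- cultures$culture_id[i]
    ph <- phenotypes[phenotypes$culture_id == cid &
                     !is.na(phenotypes$loh_class), ]
    data.frame(genotype = cultures$genotype[i], culture_id = cid,
               class = classes,
               r = vapply(classes,
                          function(cl) sum(ph$loh_class == cl), numeric(1)),
               n0 = cultures$n0[i], n_final = cultures$n_final[i],
               dilution = cultures$dilution_5foa[i],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Read event rates / culture configuration from JSON
#'
#' The rates JSON maps class names (`chromosomeLoss`, `geneConversion`,
#' `segmental`, `complex`, `pointMutation`) to per-division rates, with an
#' optional `complexSubclassProbs` object; the config JSON holds `n0`,
#' `nFinal`, `dilution`, `platingEfficiency`.
#'
#' @param path file path.
#' @return an [EventRates] or [CultureConfig].
#' @export
readEventRates <- function(path) {
  x <- jsonlite::fromJSON(path)
  args <- x[intersect(names(x), c("chromosomeLoss", "geneConversion",
                                  "segmental", "complex", "pointMutation"))]
  if (!is.null(x$complexSubclassProbs))
    args$complexSubclassProbs <- unlist(x$complexSubclassProbs)
  do.call(eventRates, args)
}

#' @rdname readEventRates
#' @export
readCultureConfig <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(cultureConfig,
          x[intersect(names(x), c("n0", "nFinal", "dilution",
                                  "platingEfficiency"))])
}

#' Rate table rows from a list of RateEstimates
#'
#' @param estimates named list of [RateEstimate] (see [classRateTable]).
#' @param genotype label column.
#' @return data.frame with one row per class: median, CI bounds and n,
#'   both per division and per 1e7 divisions (2 significant figures, the
#'   conventional reporting scale).
#' @export
rateTableFrame <- function(estimates, genotype = "") {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(genotype = genotype, class = e@classLabel,
               median = e@median, ci_lower = e@ciLower,
               ci_upper = e@ciUpper, achieved_level = e@achievedLevel,
               n_cultures = e@nCultures, method = e@method,
               median_per_1e7 = signif(e@median * 1e7, 2),
               ci_lower_per_1e7 = signif(e@ciLower * 1e7, 2),
               ci_upper_per_1e7 = signif(e@ciUpper * 1e7, 2),
               note = e@note, stringsAsFactors = FALSE, row.names = NULL)
  }))
}
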