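# Coverage of a metagenomic taxon profile by a culture collection:
# stratified count coverage, the cultured-but-undetected complement, and
# abundance-mass coverage.

#' One-decimal percentage, half away from zero
#'
#' `100 * n / d` rounded half-away-from-zero to one decimal, in exact
#' integer arithmetic scaled by ten (no floating-point rounding artefacts).
#' This is the reporting convention used for all coverage percentages.
#'
#' @param numerator integer vector (>= 0 in typical use).
#' @param denominator positive integer (vector recycled as usual).
#' @return numeric vector of percentages with one decimal.
#' @export
round1 <- function(numerator, denominator) {
  if (any(denominator == 0)) stop("undefined percent: denominator is 0")
  if (any(numerator != trunc(numerator)) || any(denominator != trunc(denominator)))
    stop("round1 takes integer counts")
  s <- sign(numerator) * sign(denominator)
  n <- abs(numerator); d <- abs(denominator)
  # tenths of a percent: floor((1000 n + d/2) / d) done as integers
  tenths <- (2000 * n + d) %/% (2 * d)
  s * tenths / 10
}

new_coverage_report <- function(rank, stratum, covered, total, uncovered) {
  structure(list(rank = rank, stratum = stratum,
                 covered = covered, total = total,
                 percent = if (total > 0) round1(covered, total) else NULL,
                 uncovered_taxa = sort(uncovered)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  pct <- if (is.null(x$percent)) "NA" else sprintf("%.1f%%", x$percent)
  cat(sprintf("coverage [%s rank, %s stratum]: %d/%d (%s)\n",
              x$rank, x$stratum, x$covered, x$total, pct))
  invisible(x)
}

#' Stratified coverage of a taxon profile by a roster
#'
#' Of the profiled taxa in a stratum, how many have a cultured
#' representative? The `"medium_above"` selector *includes* the high
#' stratum (strata are nested: medium-above means mean relative abundance at
#' or above the medium cut); `"all"` covers every profiled taxon.
#'
#' @param profiles data frame from [taxon_profiles()] (columns `taxon`,
#'   `stratum`), all at the requested rank.
#' @param roster a [biobank_roster()].
#' @param syn a [synonym_map()] or `NULL`.
#' @param stratum one of `"low"`, `"medium_above"`, `"high"`, `"all"`.
#' @param rank `"species"` or `"genus"`.
#' @return a `coverage_report`: rank, stratum, covered, total, one-decimal
#'   percent (`NULL` when the stratum is empty) and the sorted uncovered
#'   taxa.
#' @export
stratified_coverage <- function(profiles, roster, syn = default_synonym_map(),
                                stratum = c("medium_above", "high", "low", "all"),
                                rank = c("species", "genus")) {
  stratum <- match.arg(stratum)
  rank <- match.arg(rank)
  stopifnot(is.data.frame(profiles),
            all(c("taxon", "stratum") %in% names(profiles)))
  prank <- attr(profiles, "rank")
  if (!is.null(prank) && prank != rank)
    stop("profiles are at rank '", prank, "', not '", rank, "'")
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(profiles)),
                 high = profiles$stratum == "high",
                 medium_above = profiles$stratum %in% c("medium_above", "high"),
                 low = profiles$stratum == "low")
  taxa <- profiles$taxon[keep]
  hit <- !is.na(match_taxa(taxa, roster, syn, rank))
  new_coverage_report(rank, stratum, sum(hit), length(taxa), taxa[!hit])
}

#' Cultured species absent from the detected set
#'
#' The complement view of coverage: roster species with no synonym-aware
#' match among the metagenomically detected species.
#'
#' @param roster a [biobank_roster()].
#' @param detected_species character vector of detected species names.
#' @param syn a [synonym_map()] or `NULL`.
#' @return a list with `cultured_total`, `undetected` (sorted names) and
#'   `percent` (one decimal, of cultured species that went undetected).
#' @export
undetected_cultured <- function(roster, detected_species,
                                syn = default_synonym_map()) {
  stopifnot(inherits(roster, "biobank_roster"))
  sp <- roster_species(roster)
  det <- unique(syn_canonical(detected_species, syn))
  und <- sp[!(syn_canonical(sp, syn) %in% det)]
  list(cultured_total = length(sp),
       undetected = sort(und),
       percent = if (length(sp) > 0) round1(length(und), length(sp)) else NULL)
}

#' Abundance-mass coverage
#'
#' The percentage of total abundance mass (summed over all taxa and
#' samples) carried by taxa with a cultured representative. This is a
#' taxon-level approximation of sequence-level coverage; it is not a
#' read-mapping statistic.
#'
#' @param table an [abundance_table()].
#' @param roster a [biobank_roster()].
#' @param syn a [synonym_map()] or `NULL`.
#' @return a single percent value.
#' @export
mass_coverage <- function(table, roster, syn = default_synonym_map()) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table) == 0L || ncol(table) == 0L) stop("empty abundance table")
  total <- sum(table)
  if (total == 0) stop("abundance table carries no mass")
  hit <- !is.na(match_taxa(rownames(table), roster, syn, table_rank(table)))
  100 * sum(table[hit, , drop = FALSE]) / total
}

#' Write a coverage report as JSON
#'
#' Serializes `{rank, stratum, covered, total, percent, uncovered_taxa[]}`;
#' an empty stratum's percent is `null`.
#'
#' @param report a `coverage_report` from [stratified_coverage()].
#' @param path output file.
#' @export
write_coverage_json <- function(report, path) {
  stopifnot(inherits(report, "coverage_report"))
  obj <- list(rank = report$rank, stratum = report$stratum,
              covered = report$covered, total = report$total,
              percent = report$percent,
              uncovered_taxa = as.list(report$uncovered_taxa))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
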