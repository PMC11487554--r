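# Dual-threshold core-microbiome extraction: dominant (mean relative
# abundance gate) AND common (prevalence gate) taxa.

#' Extract dominant, common and core taxa
#'
#' A taxon is *dominant* when its mean relative abundance over all samples
#' is at or above `cfg$medium_cut`, *common* when its prevalence (FO) is at
#' or above `cfg$prevalence_cut`, and *core* when both hold. Both gates are
#' inclusive. The ranked core list orders core taxa by mean relative
#' abundance descending, ties broken alphabetically.
#'
#' @param table a normalized [abundance_table()].
#' @param cfg a [strata_config()].
#' @return a `core_result`: a data frame with columns `taxon`, `mean_ra`,
#'   `prevalence`, `dominant`, `common`, `core`, carrying attributes
#'   `core_taxa` (the ranked core list) and `rank`.
#' @export
extract_core <- function(table, cfg = strata_config()) {
  stopifnot(inherits(table, "abundance_table"))
  if (ncol(table) < 1L) stop("empty abundance table")
  prof <- taxon_profiles(table, cfg)
  dominant <- prof$mean_ra >= cfg$medium_cut
  common <- prof$prevalence >= cfg$prevalence_cut
  core <- dominant & common
  out <- data.frame(taxon = prof$taxon, mean_ra = prof$mean_ra,
                    prevalence = prof$prevalence,
                    dominant = dominant, common = common, core = core,
                    stringsAsFactors = FALSE)
  core_rows <- out[out$core, , drop = FALSE]
  ord <- order(-core_rows$mean_ra, core_rows$taxon)
  attr(out, "core_taxa") <- core_rows$taxon[ord]
  attr(out, "rank") <- table_rank(table)
  class(out) <- c("core_result", "data.frame")
  out
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf("core_result (%s rank): %d dominant, %d common, %d core of %d taxa\n",
              attr(x, "rank"), sum(x$dominant), sum(x$common), sum(x$core),
              nrow(x)))
  top <- utils::head(attr(x, "core_taxa"), 5L)
  if (length(top)) cat("  top core:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Top-k core taxa
#'
#' The first `min(k, number of core taxa)` entries of the ranked core list
#' (mean relative abundance descending, alphabetical tie-break).
#'
#' @param result a `core_result` from [extract_core()].
#' @param k positive integer.
#' @return character vector of taxon names.
#' @export
top_core <- function(result, k) {
  stopifnot(inherits(result, "core_result"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != trunc(k))
    stop("`k` must be a positive integer")
  utils::head(attr(result, "core_taxa"), k)
}

#' Write a core report as TSV
#'
#' Columns: taxon, mean_ra, FO, dominant, common, core.
#'
#' @param result a `core_result`.
#' @param path output file.
#' @export
write_core_tsv <- function(result, path) {
  stopifnot(inherits(result, "core_result"))
  df <- data.frame(taxon = result$taxon,
                   mean_ra = result$mean_ra,
                   FO = result$prevalence,
                   dominant = result$dominant,
                   common = result$common,
                   core = result$core)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
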