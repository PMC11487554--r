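# Compositional abundance tables (taxa x samples, percent units) and
# per-taxon summary statistics.

#' Construct an abundance table
#'
#' An `abundance_table` is a numeric matrix of relative abundances in percent
#' units, taxa in rows and samples in columns, tagged with a taxonomic rank
#' (`"species"` or `"genus"`). Columns of a *normalized* table sum to 100;
#' use [normalize_to_relative()] to close raw counts or un-normalized values.
#'
#' @param values numeric matrix, taxa in rows (rownames required), samples in
#'   columns (colnames required); all entries must be non-negative.
#' @param rank `"species"` or `"genus"`.
#' @return an `abundance_table` object (a matrix with a `rank` attribute).
#' @export
abundance_table <- function(values, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("abundance table needs at least one taxon and one sample")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("taxon identifiers must be unique within a rank")
  if (anyDuplicated(colnames(values)))
    stop("sample identifiers must be unique")
  if (anyNA(values)) stop("abundance values must not be missing")
  if (any(values < 0)) stop("abundance values must be non-negative")
  structure(values, rank = rank, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d %s-rank taxa x %d samples\n",
              nrow(x), attr(x, "rank"), ncol(x)))
  cat(sprintf("  column sums: [%.6g, %.6g]\n",
              min(colSums(x)), max(colSums(x))))
  invisible(x)
}

table_rank <- function(table) attr(table, "rank")

#' Close a raw taxa-by-sample matrix to percent relative abundances
#'
#' Every sample column is scaled so that it sums to exactly 100. Raw inputs
#' may be read counts or arbitrary non-negative measurements; an all-zero
#' sample carries no compositional information and is an error rather than a
#' silent `NaN` column.
#'
#' @param raw non-negative numeric matrix, taxa in rows, samples in columns.
#' @param rank taxonomic rank tag for the result.
#' @return a normalized [abundance_table()].
#' @export
normalize_to_relative <- function(raw, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("`raw` must be a numeric matrix")
  if (nrow(raw) < 1L || ncol(raw) < 1L)
    stop("need at least one taxon and one sample")
  if (anyNA(raw)) stop("raw values must not be missing")
  if (any(raw < 0)) stop("negative entry in raw abundance matrix")
  totals <- colSums(raw)
  if (any(totals == 0)) {
    bad <- colnames(raw)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("degenerate all-zero sample column(s): ",
         paste(bad, collapse = ", "))
  }
  out <- sweep(raw, 2L, totals / 100, "/")
  abundance_table(out, rank = rank)
}

#' Strata and threshold configuration
#'
#' Thresholds governing abundance strata, the prevalence gate and the
#' detection floor, all in percent units. All comparisons are inclusive
#' (`>=`), except the detection floor which is strict (`>`): a taxon counts
#' as present in a sample when its abundance is strictly above
#' `detection_threshold`.
#'
#' @param medium_cut mean relative abundance (percent) at or above which a
#'   taxon is medium-above abundant (and "dominant"); default 0.2.
#' @param high_cut mean relative abundance (percent) at or above which a
#'   taxon is highly abundant; default 1.
#' @param prevalence_cut prevalence (percent of samples) at or above which a
#'   taxon is "common"; default 80.
#' @param detection_threshold percent abundance strictly above which a taxon
#'   is detected in a sample; default 0.
#' @return a `strata_config` list.
#' @export
strata_config <- function(medium_cut = 0.2, high_cut = 1,
                          prevalence_cut = 80, detection_threshold = 0) {
  stopifnot(is.numeric(medium_cut), is.numeric(high_cut),
            is.numeric(prevalence_cut), is.numeric(detection_threshold))
  if (!(detection_threshold >= 0 && detection_threshold < medium_cut &&
        medium_cut < high_cut && high_cut <= 100))
    stop("need 0 <= detection_threshold < medium_cut < high_cut <= 100")
  if (!(prevalence_cut > 0 && prevalence_cut <= 100))
    stop("need 0 < prevalence_cut <= 100")
  structure(list(medium_cut = medium_cut, high_cut = high_cut,
                 prevalence_cut = prevalence_cut,
                 detection_threshold = detection_threshold),
            class = "strata_config")
}

assign_stratum <- function(mean_ra, cfg) {
  ifelse(mean_ra >= cfg$high_cut, "high",
         ifelse(mean_ra >= cfg$medium_cut, "medium_above", "low"))
}

#' Per-taxon summary profile
#'
#' Mean relative abundance over *all* samples (zeros included), prevalence
#' (the frequency of occurrence, FO: percent of samples with abundance
#' strictly above the detection floor) and the abundance stratum.
#'
#' @param table an [abundance_table()].
#' @param taxon a taxon identifier present in `table`.
#' @param cfg a [strata_config()].
#' @return a one-row data frame with columns `taxon`, `mean_ra`,
#'   `prevalence`, `stratum`.
#' @export
taxon_profile <- function(table, taxon, cfg = strata_config()) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(taxon) != 1L || !taxon %in% rownames(table))
    stop("unknown taxon: ", taxon)
  x <- table[taxon, ]
  mean_ra <- mean(x)
  prev <- 100 * mean(x > cfg$detection_threshold)
  data.frame(taxon = taxon, mean_ra = mean_ra, prevalence = prev,
             stratum = assign_stratum(mean_ra, cfg),
             stringsAsFactors = FALSE)
}

#' Profiles for every taxon in a table
#'
#' @inheritParams taxon_profile
#' @return a data frame, one row per taxon, with attribute `rank` carrying
#'   the table's rank.
#' @export
taxon_profiles <- function(table, cfg = strata_config()) {
  stopifnot(inherits(table, "abundance_table"))
  mean_ra <- rowMeans(table)
  prev <- 100 * rowMeans(table > cfg$detection_threshold)
  out <- data.frame(taxon = rownames(table), mean_ra = mean_ra,
                    prevalence = prev,
                    stratum = assign_stratum(mean_ra, cfg),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "rank") <- table_rank(table)
  out
}

species_genus <- function(species, genus = NULL) {
  # first binomial token, unless an explicit mapping overrides it
  if (!is.null(genus)) {
    g <- genus[species]
    if (!anyNA(g)) return(unname(g))
  }
  parts <- strsplit(species, "[ ]+")
  tok <- vapply(parts, function(p) p[1L], character(1))
  bad <- lengths(parts) < 2L
  if (!is.null(genus)) bad <- bad & !(species %in% names(genus))
  if (any(bad))
    stop("non-binomial taxon identifier(s) without explicit genus: ",
         paste(utils::head(species[bad], 5L), collapse = ", "))
  if (!is.null(genus)) {
    g <- genus[species]
    tok[!is.na(g)] <- g[!is.na(g)]
  }
  tok
}

#' Aggregate a species-rank table to genus rank
#'
#' Genus abundance in a sample is the sum of its member species' abundances,
#' so per-sample totals are conserved. The genus is the first token of each
#' binomial species identifier unless `genus` supplies an explicit mapping.
#'
#' @param table a species-rank [abundance_table()].
#' @param genus optional named character vector mapping species identifiers
#'   to genus names, for identifiers that are not plain binomials.
#' @return a genus-rank [abundance_table()].
#' @export
aggregate_to_genus <- function(table, genus = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (table_rank(table) != "species")
    stop("aggregate_to_genus expects a species-rank table")
  g <- species_genus(rownames(table), genus)
  agg <- rowsum(unclass(table), group = g, reorder = TRUE)
  abundance_table(agg, rank = "genus")
}

#' Read / write abundance tables as TSV
#'
#' Format: a `#rank=species|genus` pragma line (optional on read if `rank` is
#' given), other `#`-prefixed comment lines ignored, then a header line with
#' first column `taxon` followed by sample identifiers, values in decimal
#' percent.
#'
#' @param path file path.
#' @param rank rank to assume when the file carries no `#rank=` pragma.
#' @return [read_abundance_tsv()] returns an [abundance_table()];
#'   `write_abundance_tsv()` returns `path` invisibly.
#' @export
read_abundance_tsv <- function(path, rank = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  pragma <- grep("^#rank=", lines, value = TRUE)
  if (length(pragma) >= 1L) {
    rank <- sub("^#rank=", "", pragma[1L])
  } else if (is.null(rank)) {
    stop("no #rank= pragma in ", path, " and no `rank` given")
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "taxon") stop("first column must be named 'taxon'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$taxon
  abundance_table(m, rank = rank)
}

#' @rdname read_abundance_tsv
#' @param table an [abundance_table()] to write.
#' @export
write_abundance_tsv <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(sprintf("#rank=%s", table_rank(table)), con, sep = "\n")
  header <- paste(c("taxon", colnames(table)), collapse = "\t")
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i],
            formatC(table[i, ], format = "g", digits = 15)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}
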