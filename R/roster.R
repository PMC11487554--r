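# Culture-collection rosters: strain records with taxonomic lineage,
# synonym-aware species matching, cross-biobank overlap.

#' Normalize a taxon name for matching
#'
#' Case-folds, trims, maps underscores to spaces, collapses internal
#' whitespace and drops a trailing "sp."/"spp." qualifier token. Genus
#' abbreviations are *not* expanded; inputs must carry full genus names.
#'
#' @param name character vector of taxon names.
#' @return normalized names.
#' @export
normalize_taxon_name <- function(name) {
  x <- tolower(trimws(name))
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  sub(" (sp|spp)\\.?$", "", x)
}

#' Species synonym map
#'
#' A symmetric (and transitively closed) set of equivalent species names.
#' Matching is performed on equivalence-class representatives, so
#' `match_taxon(a -> b)` holds iff `match_taxon(b -> a)` does. The default
#' map ships with the one reassignment most relevant to human gut taxa,
#' *Phocaeicola vulgatus* = *Bacteroides vulgatus*; extend it from a
#' two-column CSV with [read_synonym_csv()].
#'
#' @param name_a,name_b character vectors of paired equivalent names.
#' @return a `synonym_map` object.
#' @export
synonym_map <- function(name_a = character(), name_b = character()) {
  if (length(name_a) != length(name_b))
    stop("`name_a` and `name_b` must have equal length")
  a <- normalize_taxon_name(name_a)
  b <- normalize_taxon_name(name_b)
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty synonym name")
  nodes <- unique(c(a, b))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {                       # path-halving union-find
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(a)) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) parent[[rb]] <- ra
  }
  class_of <- vapply(nodes, find, character(1))
  structure(list(class_of = class_of), class = "synonym_map")
}

#' @rdname synonym_map
#' @export
default_synonym_map <- function() {
  synonym_map("Phocaeicola vulgatus", "Bacteroides vulgatus")
}

#' @rdname synonym_map
#' @param path CSV file with header columns `name_a`, `name_b`.
#' @export
read_synonym_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name_a", "name_b") %in% names(df)))
    stop("synonym CSV needs columns name_a, name_b")
  synonym_map(df$name_a, df$name_b)
}

# canonical equivalence-class id for each (already raw) name
syn_canonical <- function(name, syn) {
  x <- normalize_taxon_name(name)
  if (is.null(syn)) return(x)
  stopifnot(inherits(syn, "synonym_map"))
  hit <- syn$class_of[x]
  ifelse(is.na(hit), x, unname(hit))
}

#' Construct a biobank roster
#'
#' @param strains data frame with columns `strain_id`, `species` and
#'   optionally `genus`, `family`, `phylum`, `novel` (logical) and
#'   `deposits`; `genus` defaults to the first token of `species`.
#' @param name label for the biobank.
#' @return a `biobank_roster` object.
#' @export
biobank_roster <- function(strains, name = "biobank") {
  stopifnot(is.data.frame(strains))
  need <- c("strain_id", "species")
  if (!all(need %in% names(strains)))
    stop("roster needs columns: ", paste(need, collapse = ", "))
  if (nrow(strains) > 0L) {
    if (anyDuplicated(strains$strain_id))
      stop("strain_id must be unique within a roster")
    if (any(!nzchar(trimws(strains$species))))
      stop("species must be non-empty for every strain")
  }
  if (is.null(strains$genus)) {
    strains$genus <- vapply(strsplit(as.character(strains$species), "[ _]+"),
                            function(p) p[1L], character(1))
  }
  for (col in c("family", "phylum"))
    if (is.null(strains[[col]]))
      strains[[col]] <- rep(NA_character_, nrow(strains))
  if (is.null(strains$novel)) strains$novel <- rep(FALSE, nrow(strains))
  if (is.null(strains$deposits))
    strains$deposits <- rep(NA_character_, nrow(strains))
  structure(list(name = name, strains = strains), class = "biobank_roster")
}

#' @export
print.biobank_roster <- function(x, ...) {
  s <- roster_summarize(x)
  cat(sprintf("biobank_roster '%s': %d strains, %d species (%d novel), %d genera\n",
              x$name, s$strains, s$species, s$novel_species, s$genera))
  invisible(x)
}

#' Read a roster CSV
#'
#' Columns: `strain_id`, `species`, `genus`, `family`, `phylum`,
#' `novel` (true/false), `deposits` (semicolon-joined accessions); header
#' required, `strain_id` and `species` mandatory.
#'
#' @param path CSV file path.
#' @param name biobank label (defaults to the file name).
#' @export
read_roster_csv <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$novel)) df$novel <- as.logical(df$novel)
  biobank_roster(df, name = if (is.null(name))
    sub("\\.csv$", "", basename(path)) else name)
}

#' @rdname read_roster_csv
#' @param roster a [biobank_roster()] to write.
#' @export
write_roster_csv <- function(roster, path) {
  stopifnot(inherits(roster, "biobank_roster"))
  utils::write.csv(roster$strains, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

roster_species <- function(roster) unique(roster$strains$species)

roster_genera <- function(roster) {
  g <- roster$strains$genus
  sp_tok <- vapply(strsplit(as.character(roster$strains$species), "[ _]+"),
                   function(p) p[1L], character(1))
  unique(c(g[!is.na(g) & nzchar(g)], sp_tok))
}

#' Roster counts per taxonomic rank
#'
#' Cardinalities of the deduplicated name sets at each rank, plus the number
#' of novel species.
#'
#' @param roster a [biobank_roster()].
#' @return a list with `strains`, `species`, `genera`, `families`, `phyla`,
#'   `novel_species`.
#' @export
roster_summarize <- function(roster) {
  stopifnot(inherits(roster, "biobank_roster"))
  s <- roster$strains
  uniq_n <- function(x) length(unique(x[!is.na(x) & nzchar(x)]))
  novel_sp <- unique(s$species[which(s$novel)])
  list(strains = nrow(s),
       species = uniq_n(s$species),
       genera = uniq_n(s$genus),
       families = uniq_n(s$family),
       phyla = uniq_n(s$phylum),
       novel_species = length(novel_sp))
}

#' Match a metagenomic taxon name against a roster
#'
#' Species-rank queries match (synonym-aware, after name normalization)
#' against the roster's species set; genus-rank queries match against the
#' genus set derived from roster species binomials plus explicit genus
#' fields.
#'
#' @param name a taxon name (species binomial or genus).
#' @param roster a [biobank_roster()].
#' @param syn a [synonym_map()] or `NULL`.
#' @param rank `"species"` or `"genus"`.
#' @return the matched roster name, or `NA_character_` if unmatched.
#' @export
match_taxon <- function(name, roster, syn = default_synonym_map(),
                        rank = c("species", "genus")) {
  rank <- match.arg(rank)
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    stop("taxon name must be a single non-empty string")
  hits <- match_taxa(name, roster, syn, rank)
  hits[[1L]]
}

# vectorized matcher; returns roster name or NA per query
match_taxa <- function(names, roster, syn = default_synonym_map(),
                       rank = c("species", "genus")) {
  rank <- match.arg(rank)
  stopifnot(inherits(roster, "biobank_roster"))
  pool <- if (rank == "species") roster_species(roster) else roster_genera(roster)
  key <- syn_canonical(pool, syn)
  q <- syn_canonical(names, syn)
  pool[match(q, key)]
}

#' Species unique to one biobank
#'
#' Target species with no synonym-aware match in the union of the other
#' collections' species sets.
#'
#' @param target a [biobank_roster()].
#' @param others list of character vectors of species names (one per other
#'   biobank).
#' @param syn a [synonym_map()] or `NULL`.
#' @return a list with `unique_species` (sorted), `n_unique`, and
#'   `others_union` (number of distinct species, synonym classes collapsed,
#'   in the union of `others`).
#' @export
cross_biobank_unique <- function(target, others, syn = default_synonym_map()) {
  stopifnot(inherits(target, "biobank_roster"), is.list(others))
  tsp <- roster_species(target)
  other_names <- unique(unlist(others, use.names = FALSE))
  other_keys <- unique(syn_canonical(other_names, syn))
  uniq <- tsp[!(syn_canonical(tsp, syn) %in% other_keys)]
  list(unique_species = sort(uniq), n_unique = length(uniq),
       others_union = length(other_keys))
}
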