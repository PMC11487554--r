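make_roster <- function(species, ids = sprintf("HA%04d", seq_along(species)),
                        ...) {
  biobank_roster(data.frame(strain_id = ids, species = species,
                            stringsAsFactors = FALSE, ...), name = "t")
}

test_that("roster_summarize counts deduplicated names per rank", {
  empty <- biobank_roster(data.frame(strain_id = character(),
                                     species = character()))
  expect_equal(unlist(roster_summarize(empty)), c(strains = 0, species = 0,
               genera = 0, families = 0, phyla = 0, novel_species = 0))

  r <- make_roster(c("Blautia longa", "Blautia longa", "Blautia ovalis"))
  s <- roster_summarize(r)
  expect_equal(c(s$strains, s$species, s$genera), c(3, 2, 1))

  # seeded 200-strain roster against brute-force set construction
  set.seed(42)
  pool_g <- sprintf("Genus%02d", 1:25)
  sp <- paste(sample(pool_g, 200, TRUE), sprintf("sp%03d", sample(60, 200, TRUE)))
  fam <- sprintf("Family%02d", sample(9, 200, TRUE))
  phy <- sprintf("Phylum%d", sample(4, 200, TRUE))
  nov <- sample(c(TRUE, FALSE), 200, TRUE)
  r2 <- biobank_roster(data.frame(strain_id = sprintf("X%03d", 1:200),
                                  species = sp, family = fam, phylum = phy,
                                  novel = nov, stringsAsFactors = FALSE))
  s2 <- roster_summarize(r2)
  seen_sp <- seen_g <- seen_f <- seen_p <- seen_nov <- character()
  for (i in 1:200) {                       # explicit set-building loop
    if (!sp[i] %in% seen_sp) seen_sp <- c(seen_sp, sp[i])
    g <- strsplit(sp[i], " ")[[1]][1]
    if (!g %in% seen_g) seen_g <- c(seen_g, g)
    if (!fam[i] %in% seen_f) seen_f <- c(seen_f, fam[i])
    if (!phy[i] %in% seen_p) seen_p <- c(seen_p, phy[i])
    if (nov[i] && !sp[i] %in% seen_nov) seen_nov <- c(seen_nov, sp[i])
  }
  expect_equal(s2$species, length(seen_sp))
  expect_equal(s2$genera, length(seen_g))
  expect_equal(s2$families, length(seen_f))
  expect_equal(s2$phyla, length(seen_p))
  expect_equal(s2$novel_species, length(seen_nov))

  # invariant under strain reordering
  r3 <- biobank_roster(r2$strains[sample(200), ])
  expect_equal(roster_summarize(r3), s2)
})

test_that("roster validation catches duplicates and empty species", {
  expect_error(make_roster(c("A b", "C d"), ids = c("x", "x")), "unique")
  expect_error(make_roster(c("A b", " ")), "non-empty")
})

test_that("match_taxon normalizes, honours synonyms, and is symmetric", {
  r <- make_roster(c("Bacteroides uniformis", "Phocaeicola vulgatus"))
  expect_equal(match_taxon("bacteroides uniformis", r), "Bacteroides uniformis")
  expect_equal(match_taxon("Bacteroides_uniformis ", r), "Bacteroides uniformis")
  expect_equal(match_taxon("Bacteroides vulgatus", r), "Phocaeicola vulgatus")
  expect_true(is.na(match_taxon("Prevotella copri", r)))
  expect_error(match_taxon("  ", r), "non-empty")

  # symmetry: with the roles swapped the synonym still resolves
  r2 <- make_roster("Bacteroides vulgatus")
  expect_equal(match_taxon("Phocaeicola vulgatus", r2), "Bacteroides vulgatus")

  # genus-rank matching uses the genus set
  expect_equal(match_taxon("bacteroides", r, rank = "genus"), "Bacteroides")
  expect_true(is.na(match_taxon("Prevotella", r, rank = "genus")))

  # "sp."-qualifier stripping
  r3 <- make_roster("Subdoligranulum sp")
  expect_equal(match_taxon("Subdoligranulum_sp.", r3), "Subdoligranulum sp")
})

test_that("synonym maps close transitively and load from CSV", {
  syn <- synonym_map(c("A one", "B one"), c("B one", "C one"))
  r <- make_roster("C one")
  expect_equal(match_taxon("A one", r, syn = syn), "C one")

  path <- withr::local_tempfile(lines = c("name_a,name_b",
                                          "Phocaeicola vulgatus,Bacteroides vulgatus"))
  syn2 <- read_synonym_csv(path)
  expect_equal(match_taxon("Bacteroides vulgatus",
                           make_roster("Phocaeicola vulgatus"), syn = syn2),
               "Phocaeicola vulgatus")
})

test_that("cross_biobank_unique equals brute force and is anti-monotone", {
  tgt <- make_roster(c("A a", "B b", "C c", "Phocaeicola vulgatus"))
  all_unique <- cross_biobank_unique(tgt, list())
  expect_equal(all_unique$n_unique, 4)
  expect_equal(all_unique$others_union, 0)

  full <- cross_biobank_unique(tgt, list(c("A a", "B b"),
                                         c("C c", "Bacteroides vulgatus")))
  expect_equal(full$n_unique, 0)

  set.seed(8)
  pool <- paste("Genus", sprintf("sp%03d", 1:80))
  pool <- paste0(sprintf("Genus%02d ", sample(9, 80, TRUE)), sprintf("sp%03d", 1:80))
  tsp <- sample(pool, 30)
  others <- list(sample(pool, 25), sample(pool, 25), sample(pool, 10))
  res <- cross_biobank_unique(make_roster(tsp), others)
  # O(n*m) pairwise oracle on normalized names
  manual <- character()
  for (s in tsp) {
    hit <- FALSE
    for (o in unlist(others))
      if (tolower(s) == tolower(o)) hit <- TRUE
    if (!hit) manual <- c(manual, s)
  }
  expect_setequal(res$unique_species, manual)

  # adding species to another roster never enlarges the unique set
  others2 <- others
  others2[[1]] <- c(others2[[1]], sample(pool, 20))
  res2 <- cross_biobank_unique(make_roster(tsp), others2)
  expect_true(all(res2$unique_species %in% res$unique_species))
})

test_that("roster CSV round-trips", {
  r <- make_roster(c("Blautia longa", "Waltera fermentans"),
                   novel = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_roster_csv(r, path)
  back <- read_roster_csv(path, name = "t")
  expect_equal(back$strains$species, r$strains$species)
  expect_equal(back$strains$novel, c(TRUE, FALSE))
})
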