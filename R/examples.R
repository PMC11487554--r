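# A fully synthetic worked example for the coverage operations: a one-sample
# species profile (480 detected species: 26 high, 33 medium-only, 421 low),
# a one-sample genus profile (132 genera: 21 high, 12 medium-only, 99 low),
# and a 280-species culture collection whose overlaps are fixed by
# construction: 135 detected species cultured (25 of the 26 high, 30 of the
# 33 medium-only, 80 low), 145 cultured species never detected, 81 of the
# 132 detected genera cultured (all 21 high genera among them).

#' Worked-example inputs for coverage assessment
#'
#' Constructs deterministic synthetic inputs whose stratum counts and
#' culture-collection overlaps are fixed exactly by construction (no
#' randomness), so every coverage percentage they yield is a pure count
#' ratio: species coverage 55/59 medium-above, 25/26 high, 135/480 overall;
#' 145/280 cultured-but-undetected; genus coverage 81/132 overall, 21/21
#' high; core-list coverage 18/20 at species rank and 20/20 at genus rank.
#' Useful as a worked example and as an end-to-end exercise of
#' [stratified_coverage()], [undetected_cultured()] and [mass_coverage()].
#'
#' @return a list with `species_table` and `genus_table` (one-sample
#'   normalized [abundance_table()]s), `roster` (a [biobank_roster()]),
#'   `core_species` and `core_genera` (20-name character vectors of which
#'   18 and 20 are cultured, respectively).
#' @export
coverage_example <- function() {
  genus_id <- function(i) sprintf("G%03d", i)
  # --- detected species, one sample, strata set by per-sample value -----
  high_g <- genus_id(((seq_len(26) - 1) %% 21) + 1)          # G001..G021
  high_sp <- sprintf("%s highsp%03d", high_g, seq_len(26))
  med_g <- genus_id(((seq_len(33) - 1) %% 12) + 22)          # G022..G033
  med_sp <- sprintf("%s medsp%03d", med_g, seq_len(33))
  # cultured low species stay within genera G034..G081 so the cultured
  # genus set is exactly G001..G081
  lowc_g <- genus_id(((seq_len(80) - 1) %% 48) + 34)         # G034..G081
  lowu_g <- genus_id(((seq_len(341) - 1) %% 99) + 34)        # G034..G132
  low_sp <- c(sprintf("%s lowsp%03d", lowc_g, seq_len(80)),
              sprintf("%s lowsp%03d", lowu_g, 80 + seq_len(341)))
  species <- c(high_sp, med_sp, low_sp)
  vals <- matrix(c(rep(1.5, 26), rep(0.4, 33), rep(47.8 / 421, 421)),
                 ncol = 1, dimnames = list(species, "S1"))
  species_table <- normalize_to_relative(vals, rank = "species")

  # --- detected genera, one sample ---------------------------------------
  genera <- genus_id(seq_len(132))
  gvals <- matrix(c(rep(3.5, 21), rep(0.7, 12), rep(18.1 / 99, 99)),
                  ncol = 1, dimnames = list(genera, "S1"))
  genus_table <- normalize_to_relative(gvals, rank = "genus")

  # --- culture collection -------------------------------------------------
  cultured_detected <- c(high_sp[1:25], med_sp[1:30], low_sp[1:80])
  cultured_only <- sprintf("G%03d extrasp%03d",
                           ((seq_len(145) - 1) %% 18) + 133,  # G133..G150
                           seq_len(145))
  roster_sp <- c(cultured_detected, cultured_only)
  roster <- biobank_roster(data.frame(
    strain_id = sprintf("ST%04d", seq_along(roster_sp)),
    species = roster_sp,
    novel = c(rep(FALSE, length(cultured_detected)),
              rep(TRUE, length(cultured_only))),
    stringsAsFactors = FALSE), name = "worked-example-biobank")

  list(species_table = species_table,
       genus_table = genus_table,
       roster = roster,
       core_species = c(high_sp[1:18], high_sp[26], med_sp[31]),
       core_genera = genus_id(seq_len(20)))
}
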