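test_that("spearman_assoc recovers perfect monotone relations", {
  x <- c(3, 8, 1, 5, 9, 2, 7)
  expect_equal(spearman_assoc(x, exp(x))$rho, 1)
  expect_equal(spearman_assoc(x, -x^3)$rho, -1)
  expect_error(spearman_assoc(1:3, 3:1), "insufficient")
  expect_error(spearman_assoc(1:5, rep(2, 5)), "zero variance")
})

test_that("exact Spearman p equals full-permutation enumeration", {
  # n = 7 with one tie pair
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(2.1, 2.1, 3.5, 1.0, 4.2, 5.9, 5.0)
  got <- spearman_assoc(x, y)
  expect_equal(got$method, "exact")
  orc <- oracle_spearman_exact(x, y)
  expect_equal(got$rho, orc$rho)
  expect_equal(got$p_value, orc$p)

  # tie-free cases also agree with the reference implementation
  for (seed in 1:3) {
    set.seed(seed)
    a <- rnorm(6); b <- rnorm(6)
    got <- spearman_assoc(a, b)
    orc <- oracle_spearman_exact(a, b)
    expect_equal(got$p_value, orc$p)
    ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                            exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample Spearman p uses the t approximation", {
  set.seed(4)
  x <- rnorm(25); y <- x + rnorm(25, sd = 2)
  got <- spearman_assoc(x, y)
  expect_equal(got$method, "t-approximation")
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE, continuity = FALSE))
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("spearman is sign-symmetric and monotone-transform invariant", {
  set.seed(9)
  for (n in c(7, 40)) {
    x <- rnorm(n); y <- rnorm(n)
    a <- spearman_assoc(x, y)
    b <- spearman_assoc(x, -y)
    expect_equal(b$rho, -a$rho)
    expect_equal(b$p_value, a$p_value)
    cc <- spearman_assoc(exp(x), y^3 + 10 * y)   # strictly increasing maps
    expect_equal(cc$rho, a$rho)
    expect_equal(cc$p_value, a$p_value)
  }
})

test_that("missing values are dropped pairwise", {
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, 4, 5, NA, 9, 12)
  got <- spearman_assoc(x, y)
  expect_equal(got$n_used, 4)
  expect_equal(got$rho, 1)
})

test_that("wilcoxon_compare: exchangeable, separated, and tied cases", {
  same <- wilcoxon_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
  expect_true(same$exact)

  sep <- wilcoxon_compare(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(sep$p_value, 2 / 70)
  expect_equal(sep$direction, "higher-in-B")
  expect_equal(sep$star, "*")

  expect_error(wilcoxon_compare(1:2, 1:5), "insufficient")

  # seeded 30 vs 30 with ties: approximate path matches the re-derived
  # tie-corrected continuity-corrected z formula
  set.seed(14)
  a <- sample(1:8, 30, TRUE); b <- sample(2:9, 30, TRUE)
  got <- wilcoxon_compare(a, b)
  expect_false(got$exact)
  expect_equal(got$p_value, oracle_wilcoxon_normal(a, b))
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("exact and approximate Wilcoxon p agree for small tie-free data", {
  # below 5 observations per group the normal approximation is coarser
  # than 0.02 even with continuity correction; the exact path covers that
  set.seed(20)
  for (i in 1:10) {
    na <- sample(5:8, 1); nb <- sample(5:8, 1)
    a <- rnorm(na); b <- rnorm(nb, mean = sample(c(0, 2), 1))
    pe <- wilcoxon_compare(a, b)$p_value
    pa <- wilcoxon_compare(a, b, max_enum = 0)$p_value
    expect_lt(abs(pe - pa), 0.02)
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(pe, ref, tolerance = 1e-12)
  }
})

test_that("star annotation uses strict legend bins", {
  expect_equal(star_annotation(c(0.02, 0.05, 0.00005, 0.009, 0.0009, 1)),
               c("*", "", "****", "**", "***", ""))
  expect_error(star_annotation(0), "0, 1")
  expect_error(star_annotation(1.2), "0, 1")
})

test_that("associate_all aligns samples and matches direct computation", {
  tab <- rand_table(6, 20, seed = 33)
  set.seed(34)
  cl <- clinical_table(data.frame(
    sample_id = colnames(tab),
    ESR = rnorm(20, 20, 5),
    CRP = c(rnorm(18, 5, 1), NA, NA)))

  one <- associate_all(tab, cl, taxa = rownames(tab)[1])
  expect_equal(nrow(one), 2)
  direct <- spearman_assoc(tab[1, ], cl$indices$ESR)
  got <- one[one$index == "ESR", ]
  expect_equal(got$rho, direct$rho)
  expect_equal(got$p_value, direct$p_value)
  expect_equal(one[one$index == "CRP", ]$n_used, 18)

  # no overlapping samples
  cl2 <- clinical_table(data.frame(sample_id = paste0("zz", 1:5),
                                   ESR = rnorm(5)))
  expect_error(associate_all(tab, cl2), "overlap")

  # BH never yields q < p and preserves p-ordering
  full <- associate_all(tab, cl, correction = "BH")
  ok <- !is.na(full$p_value)
  expect_true(all(full$q_value[ok] >= full$p_value[ok]))
  o <- order(full$p_value[ok])
  expect_true(all(diff(full$q_value[ok][o]) >= -1e-12))
})

test_that("planted monotone clinical effects are detected", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_cohort(synthetic_spec(n_taxa = 40, n_samples_B = 0,
                                          planted_differential = integer(),
                                          seed = 100 + s))
    res <- associate_all(sim$table_A, sim$clinical,
                         taxa = sim$truth$planted_assoc[[1]]$taxon)
    row <- res[res$index == "ESR", ]
    row$rho > 0 && row$p_value < 0.05
  }, logical(1))
  expect_true(all(hits))
})

test_that("clinical TSV round-trips with missing cells", {
  cl <- clinical_table(data.frame(sample_id = c("a", "b", "c", "d"),
                                  ESR = c(10, NA, 30, 12),
                                  age = c(50, 61, NA, 47),
                                  cohort = "A"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_tsv(cl, path)
  back <- read_clinical_tsv(path)
  expect_equal(back$samples, cl$samples)
  expect_equal(back$indices$ESR, cl$indices$ESR)
  expect_equal(back$cohort, rep("A", 4))
})
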