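# Rank-based taxon-phenotype association: Spearman correlation with exact
# small-n permutation p-values, Wilcoxon rank-sum cohort comparison, and the
# figure-legend star convention.

# all n! permutations of 1..n as an n! x n index matrix (n small)
perm_index_matrix <- function(n) {
  P <- matrix(1L, 1L, 1L)
  if (n == 1L) return(P)
  for (k in 2:n) {
    blocks <- vector("list", k)
    for (j in seq_len(k)) {
      s <- seq_len(k)[-j]
      blocks[[j]] <- cbind(rep.int(j, nrow(P)),
                           matrix(s[P], nrow(P)))
    }
    P <- do.call(rbind, blocks)
  }
  P
}

# exact two-sided permutation p for Spearman, by full n! enumeration of the
# assignments of one rank vector; ties enter through mid-ranks. Blocks on
# the first position so the largest materialized matrix is (n-1)! rows.
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  ctr <- sum(rx) * sum(ry) / n          # rho is linear in S = rx . ry[perm]
  s_obs <- sum(rx * ry)
  dev_obs <- abs(s_obs - ctr) - 1e-9
  P <- perm_index_matrix(n - 1L)
  count <- 0
  for (j in seq_len(n)) {
    s <- ry[j] * rx[1L] +
      as.vector(matrix(ry[-j][P], nrow(P)) %*% rx[-1L])
    count <- count + sum(abs(s - ctr) >= dev_obs)
  }
  count / factorial(n)
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' Pairs with a missing value in either vector are dropped. The two-sided
#' p-value comes from full permutation enumeration over all `n!`
#' assignments when `n_used <= 10`, and from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` degrees of freedom otherwise.
#'
#' @param x,y paired numeric vectors.
#' @return a list with `rho`, `p_value`, `n_used` and `method`
#'   (`"exact"` or `"t-approximation"`).
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("insufficient data: need >= 4 complete pairs, got ", n)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: zero variance in ranked vector")
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    p <- spearman_exact_p(rx, ry)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(max(p, 1e-300), 1)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n_used = n, method = method)
}

#' Two-sided Wilcoxon rank-sum comparison of two cohorts
#'
#' The statistic is the mid-rank sum of group `a` in the pooled ranking.
#' When the number of group labelings `choose(n_a + n_b, n_a)` is at most
#' `max_enum`, the null is enumerated exhaustively over all labelings of the
#' pooled mid-ranks (so ties are handled exactly); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Two-sided p is the probability of a rank-sum deviation from its null
#' mean at least as large as observed. Direction is by median difference.
#'
#' @param a,b numeric vectors (>= 3 observations each after NA removal).
#' @param max_enum labeling-count cap for the exact path (default `1e5`).
#' @return a list with `statistic` (rank sum of `a`), `p_value`,
#'   `direction` (`"higher-in-A"`, `"higher-in-B"` or `"none"`), `star`,
#'   `exact` (logical), `n_a`, `n_b`.
#' @export
wilcoxon_compare <- function(a, b, max_enum = 1e5) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 3L || nb < 3L)
    stop("insufficient data: each group needs >= 3 observations")
  n <- na + nb
  r <- rank(c(a, b), ties.method = "average")
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (choose(n, na) <= max_enum) {
    cmb <- utils::combn(n, na)
    w_all <- colSums(matrix(r[cmb], nrow = na))
    p <- mean(abs(w_all - mu) >= abs(w - mu) - 1e-9)
    exact <- TRUE
  } else {
    tie_tab <- table(r)
    tie_sum <- sum(tie_tab^3 - tie_tab)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_sum / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- w - mu
      z <- sign(z) * max(abs(z) - 0.5, 0)   # continuity correction
      p <- min(2 * stats::pnorm(-abs(z) / sqrt(sigma2)), 1)
      p <- max(p, 1e-300)
    }
    exact <- FALSE
  }
  med_diff <- stats::median(a) - stats::median(b)
  direction <- if (med_diff > 0) "higher-in-A"
               else if (med_diff < 0) "higher-in-B" else "none"
  list(statistic = w, p_value = p, direction = direction,
       star = star_annotation(p), exact = exact, n_a = na, n_b = nb)
}

#' Significance stars
#'
#' Strict-inequality bins: p < 0.0001 -> `"****"`, < 0.001 -> `"***"`,
#' < 0.01 -> `"**"`, < 0.05 -> `"*"`, else `""`.
#'
#' @param p_value numeric vector in (0, 1].
#' @return character vector of star symbols.
#' @export
star_annotation <- function(p_value) {
  if (any(is.na(p_value)) || any(p_value <= 0) || any(p_value > 1))
    stop("p-value must lie in (0, 1]")
  ifelse(p_value < 0.0001, "****",
  ifelse(p_value < 0.001, "***",
  ifelse(p_value < 0.01, "**",
  ifelse(p_value < 0.05, "*", ""))))
}

#' Clinical metadata table
#'
#' @param df data frame whose first column (or the column named by
#'   `sample_col`) holds sample identifiers; remaining columns are numeric
#'   clinical indices, except an optional character `cohort` column with a
#'   two-level label. Missing values are permitted.
#' @param sample_col name of the sample-identifier column.
#' @return a `clinical_table` object.
#' @export
clinical_table <- function(df, sample_col = names(df)[1L]) {
  stopifnot(is.data.frame(df), sample_col %in% names(df))
  ids <- as.character(df[[sample_col]])
  if (anyDuplicated(ids)) stop("sample identifiers must be unique")
  idx_cols <- setdiff(names(df), c(sample_col, "cohort"))
  for (col in idx_cols)
    if (!is.numeric(df[[col]]))
      stop("clinical index column '", col, "' must be numeric")
  structure(list(samples = ids,
                 indices = df[idx_cols],
                 cohort = if ("cohort" %in% names(df))
                   as.character(df$cohort) else NULL),
            class = "clinical_table")
}

#' Read / write clinical TSV
#'
#' First column sample ID, remaining numeric index columns (empty cell =
#' missing); an optional column named `cohort` carries the cohort label.
#'
#' @param path file path.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  clinical_table(df)
}

#' @rdname read_clinical_tsv
#' @param clinical a [clinical_table()] to write.
#' @export
write_clinical_tsv <- function(clinical, path) {
  stopifnot(inherits(clinical, "clinical_table"))
  df <- data.frame(sample_id = clinical$samples, clinical$indices,
                   check.names = FALSE)
  if (!is.null(clinical$cohort)) df$cohort <- clinical$cohort
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", eol = "\n")
  invisible(path)
}

#' Associate taxa with clinical indices
#'
#' One [spearman_assoc()] per (taxon, index) pair, with pairwise deletion of
#' missing clinical values. Pairs whose data are degenerate (fewer than 4
#' complete pairs, or zero rank variance) yield `NA` rho/p. Optional
#' Benjamini-Hochberg q-values across the full matrix.
#'
#' @param table an [abundance_table()].
#' @param clinical a [clinical_table()] aligned by sample identifiers.
#' @param taxa taxa to test: a `core_result` (its core set is used), a
#'   character vector, or `NULL` for every taxon in `table`.
#' @param correction `"none"` (default, matching uncorrected reporting) or
#'   `"BH"`.
#' @return an `association_result` data frame in long format: `taxon`,
#'   `index`, `rho`, `p_value`, `n_used`, `star`, and `q_value` when
#'   correction is enabled.
#' @export
associate_all <- function(table, clinical, taxa = NULL,
                          correction = c("none", "BH")) {
  correction <- match.arg(correction)
  stopifnot(inherits(table, "abundance_table"),
            inherits(clinical, "clinical_table"))
  if (inherits(taxa, "core_result")) taxa <- attr(taxa, "core_taxa")
  if (is.null(taxa)) taxa <- rownames(table)
  if (!all(taxa %in% rownames(table)))
    stop("unknown taxa: ",
         paste(utils::head(setdiff(taxa, rownames(table)), 5L), collapse = ", "))
  common <- intersect(colnames(table), clinical$samples)
  if (length(common) == 0L)
    stop("no overlapping samples between abundance and clinical tables")
  idx_names <- names(clinical$indices)
  cl_pos <- match(common, clinical$samples)
  grid <- expand.grid(taxon = taxa, index = idx_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- table[grid$taxon[i], common]
    y <- clinical$indices[[grid$index[i]]][cl_pos]
    tryCatch(spearman_assoc(x, y),
             error = function(e) list(rho = NA_real_, p_value = NA_real_,
                                      n_used = sum(stats::complete.cases(x, y)),
                                      method = NA_character_))
  })
  out <- data.frame(grid,
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    p_value = vapply(res, `[[`, numeric(1), "p_value"),
                    n_used = vapply(res, `[[`, numeric(1), "n_used"),
                    stringsAsFactors = FALSE)
  out$star <- ifelse(is.na(out$p_value), NA_character_,
                     star_annotation(pmin(pmax(out$p_value, 1e-300), 1)))
  if (correction == "BH")
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "samples_used") <- common
  class(out) <- c("association_result", "data.frame")
  out
}

#' Write association results
#'
#' Long-format TSV (taxon, index, rho, p, q, n_used, star) and a JSON
#' matrix (taxa x indices) of rho with parallel p and star matrices.
#'
#' @param result an `association_result`.
#' @param path output file.
#' @export
write_association_tsv <- function(result, path) {
  stopifnot(inherits(result, "association_result"))
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_association_tsv
#' @export
write_association_json <- function(result, path) {
  stopifnot(inherits(result, "association_result"))
  taxa <- unique(result$taxon); idx <- unique(result$index)
  shape <- function(col) {
    m <- matrix(result[[col]][order(match(result$index, idx),
                                    match(result$taxon, taxa))],
                nrow = length(taxa), dimnames = list(taxa, idx))
    lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  }
  obj <- list(taxa = taxa, indices = idx,
              rho = shape("rho"), p_value = shape("p_value"),
              star = shape("star"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA, na = "null")
  invisible(path)
}
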