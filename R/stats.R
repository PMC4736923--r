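# Implemented descriptive and inferential statistics for ordinal iris
# feature data: Goodman-Kruskal gamma, linear weighted kappa, Pearson
# chi-square homogeneity, grouped-count two-sample t-tests, Bonferroni
# thresholds, one-way ANOVA and the tabulation helpers for the published
# frequency tables. All statistics are computed directly from their
# definitions rather than wrapped from other packages.

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p = p, method = method),
            class = "iris_test")
}

#' @export
print.iris_test <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else sprintf(", df = %s", paste(signif(x$df, 6), collapse = ", "))
  ps <- if (is.na(x$p)) "" else sprintf(", p = %.4g", x$p)
  cat(sprintf("%s: statistic = %.4f%s%s\n", x$method, x$statistic, dfs, ps))
  invisible(x)
}

# concordant / discordant partner counts per cell of a cross-tabulation
.concordance_counts <- function(tab) {
  R <- nrow(tab); C <- ncol(tab)
  A <- D <- matrix(0, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    con <- 0; dis <- 0
    if (i > 1 && j > 1) con <- con + sum(tab[1:(i - 1), 1:(j - 1)])
    if (i < R && j < C) con <- con + sum(tab[(i + 1):R, (j + 1):C])
    if (i > 1 && j < C) dis <- dis + sum(tab[1:(i - 1), (j + 1):C])
    if (i < R && j > 1) dis <- dis + sum(tab[(i + 1):R, 1:(j - 1)])
    A[i, j] <- con; D[i, j] <- dis
  }
  list(A = A, D = D)
}

#' Goodman-Kruskal gamma
#'
#' Rank correlation for ordinal pairs: `G = (C - D) / (C + D)` over all
#' concordant (`C`) and discordant (`D`) pairs; ties contribute to neither.
#' The null-hypothesis test uses the Brown-Benedetti standard error (the
#' convention of the major commercial statistics packages), z = G / ASE0
#' with `ASE0^2 = 4 (sum n_ij (A_ij - D_ij)^2 - (P - Q)^2 / n) / (P + Q)^2`,
#' where `A_ij`/`D_ij` count each cell's concordant/discordant partners and
#' `P = 2C`, `Q = 2D`.
#'
#' @param x,y Equal-length ordinal vectors (integers or ordered factors).
#' @return A `gamma_result` with fields `C`, `D`, `G`, `se`, `z`, `p`, `n`.
#' @export
gk_gamma <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_validation("x and y must be equal-length vectors of length >= 2")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  tab <- table(factor(x), factor(y))
  cd <- .concordance_counts(tab)
  P <- sum(tab * cd$A); Q <- sum(tab * cd$D)  # 2C and 2D
  C <- P / 2; D <- Q / 2
  if (C + D == 0)
    stop_validation("gamma undefined: all pairs are tied")
  G <- (P - Q) / (P + Q)
  v0 <- 4 / (P + Q)^2 * (sum(tab * (cd$A - cd$D)^2) - (P - Q)^2 / n)
  se <- sqrt(max(v0, 0))
  z <- if (se > 0) G / se else sign(G) * Inf
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(C = C, D = D, G = G, se = se, z = z, p = p, n = n),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("Goodman-Kruskal gamma: G = %.4f (C = %g, D = %g, n = %d), z = %.3f, p = %.4g\n",
              x$G, x$C, x$D, x$n, x$z, x$p))
  invisible(x)
}

#' Linear weighted kappa
#'
#' Chance-corrected agreement between two raters on a k-category ordinal
#' scale with linear weights `w_ij = 1 - |i - j| / (k - 1)`:
#' `kappa = (po_w - pe_w) / (1 - pe_w)` with observed and chance-expected
#' weighted agreement computed from the confusion matrix and its marginals.
#' With `k = 2` this reduces to unweighted Cohen's kappa.
#'
#' @param r1,r2 Equal-length vectors of ratings in `1..k`.
#' @param k Number of categories (>= 2).
#' @return An `iris_test` with the kappa statistic.
#' @export
weighted_kappa <- function(r1, r2, k) {
  if (k < 2) stop_validation("k must be at least 2")
  if (length(r1) != length(r2) || length(r1) == 0)
    stop_validation("r1 and r2 must be equal-length non-empty vectors")
  if (any(!r1 %in% 1:k) || any(!r2 %in% 1:k))
    stop_validation("ratings must be integers in 1..k")
  n <- length(r1)
  O <- table(factor(r1, levels = 1:k), factor(r2, levels = 1:k)) / n
  W <- 1 - abs(outer(1:k, 1:k, "-")) / (k - 1)
  E <- outer(rowSums(O), colSums(O))
  po <- sum(W * O); pe <- sum(W * E)
  kap <- (po - pe) / (1 - pe)
  test_result(statistic = kap, df = NA_real_, p = NA_real_,
              method = sprintf("linear weighted kappa (k = %d)", k))
}

#' Pearson chi-square test of homogeneity
#'
#' `chi^2 = sum (O - E)^2 / E` with expected counts from the product of the
#' margins, `df = (r - 1)(c - 1)`, no continuity correction.
#'
#' @param t A [contingency_table()] (or plain count matrix).
#' @return An `iris_test`.
#' @export
chi2_homogeneity <- function(t) {
  m <- unclass(as.matrix(t))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_validation("chi-square undefined: zero row or column margin")
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  test_result(statistic = stat, df = df,
              p = stats::pchisq(stat, df, lower.tail = FALSE),
              method = "Pearson chi-square test of homogeneity")
}

# mean and corrected sum of squares of equally spaced scores implied by
# per-category counts
.count_moments <- function(counts, scores = seq_along(counts)) {
  n <- sum(counts)
  m <- sum(scores * counts) / n
  ss <- sum(counts * (scores - m)^2)
  list(n = n, mean = m, ss = ss, var = ss / (n - 1))
}

#' Two-sample t-test on grouped ordinal counts
#'
#' Expands per-category counts to equally spaced grade scores and computes
#' the two-sample t statistic `(mean_A - mean_B) / se`. The result is
#' invariant to affine recoding of the grade scale (0-based vs 1-based
#' labels give the same t). Pooled variance is the default; a Welch variant
#' is provided.
#'
#' @param countsA,countsB Per-category counts (same number of categories).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return An `iris_test`.
#' @export
grouped_grade_ttest <- function(countsA, countsB,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(countsA) != length(countsB) || length(countsA) < 2L)
    stop_validation("count vectors must have the same length >= 2")
  A <- .count_moments(countsA); B <- .count_moments(countsB)
  if (A$n < 2 || B$n < 2) stop_validation("each group needs at least 2 observations")
  if (A$ss == 0 && B$ss == 0)
    stop_validation("t undefined: zero variance in both groups")
  if (variant == "pooled") {
    sp2 <- (A$ss + B$ss) / (A$n + B$n - 2)
    se <- sqrt(sp2 * (1 / A$n + 1 / B$n))
    df <- A$n + B$n - 2
  } else {
    va <- A$var / A$n; vb <- B$var / B$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (A$n - 1) + vb^2 / (B$n - 1))
  }
  t <- (A$mean - B$mean) / se
  test_result(statistic = t, df = df,
              p = 2 * stats::pt(-abs(t), df),
              method = sprintf("independent samples t-test (%s) on grouped grades", variant))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`, reported to 4 decimal places (e.g. 0.05 over 3 pairwise
#' comparisons gives 0.0167).
#'
#' @param alpha Nominal level. @param m Number of comparisons (>= 1).
#' @return Corrected threshold.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 3) {
  if (m < 1) stop_validation("m must be at least 1")
  round_half_up(alpha / m, 4)
}

#' One-way analysis of variance
#'
#' @param groups A list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return An `iris_test` with the F statistic and `(k - 1, N - k)` df.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_validation("groups must be a list of at least 2 numeric vectors")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop_validation("each group needs at least 2 values")
  all_v <- unlist(groups)
  k <- length(groups); N <- length(all_v)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0 && ssb == 0)
    stop_validation("F undefined: all values identical")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  test_result(statistic = f, df = c(k - 1, N - k),
              p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
              method = "one-way ANOVA")
}

#' Tabulate a feature by population
#'
#' Counts each feature category by population over an (already filtered)
#' graded cohort, in the shape of the published frequency tables.
#'
#' @param cohort An `iris_cohort` data.frame.
#' @param feature One of `"crypt"`, `"furrow"`, `"nodule"`, `"spot"`,
#'   `"spot_raw"`, `"melanosis"`, `"colour"`.
#' @return A [contingency_table()] with populations as rows.
#' @export
tabulate_feature <- function(cohort, feature) {
  if (!feature %in% FEATURES)
    stop_validation(sprintf("unknown feature '%s'", feature))
  if (NROW(cohort) == 0) stop_validation("cohort is empty")
  col <- if (feature %in% c("melanosis", "colour")) feature
         else paste0(feature, "_grade")
  levels <- FEATURE_LEVELS[[feature]]
  pops <- intersect(POPULATIONS, unique(cohort$population))
  v <- cohort[[col]]
  counts <- t(vapply(pops, function(p)
    as.integer(table(factor(v[cohort$population == p], levels = levels))),
    integer(length(levels))))
  contingency_table(counts, row_labels = pops, col_labels = as.character(levels))
}

#' Per-quadrant feature prevalence
#'
#' Share of irises (per population) in which the feature is present in each
#' quadrant. For crypts the quadrant flags record large crypts only, per the
#' published quadrant table's convention.
#'
#' @param cohort An `iris_cohort` data.frame.
#' @param feature One of `"crypt"`, `"furrow"`, `"nodule"`, `"spot"`.
#' @return A matrix of percentages (1 d.p., round-half-up), populations by
#'   quadrants, with count attribute `"counts"`.
#' @export
quadrant_prevalence <- function(cohort, feature) {
  if (!feature %in% c("crypt", "furrow", "nodule", "spot"))
    stop_validation(sprintf("feature '%s' has no quadrant flags", feature))
  if (NROW(cohort) == 0) stop_validation("cohort is empty")
  pops <- intersect(POPULATIONS, unique(cohort$population))
  cols <- paste0(feature, "_q", 1:4)
  counts <- t(vapply(pops, function(p) {
    sub <- cohort[cohort$population == p, cols]
    vapply(sub, function(v) sum(v %in% TRUE), integer(1))
  }, integer(4)))
  ns <- vapply(pops, function(p) sum(cohort$population == p), integer(1))
  pct <- round_half_up(100 * counts / ns, 1)
  dimnames(pct) <- list(pops, paste0("Q", 1:4))
  attr(pct, "counts") <- counts
  pct
}
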