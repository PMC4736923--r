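# Genetic layer: allele frequencies, Hardy-Weinberg testing, genotype dummy
# coding with small-class elimination, and maximum-likelihood cumulative-
# logit (proportional-odds) ordinal regression with Nagelkerke R-squared and
# a parallel-lines (proportional-odds assumption) test.
#
# Sign convention, fixed deliberately: the model is
#   logit P(Y > j | x) = x'beta - theta_j
# so a positive coefficient -- and an odds ratio exp(beta) above 1 -- means
# the covariate increases the odds of a HIGHER grade. This is the opposite
# sign of some textbook parameterizations of the cumulative link model.

#' Derived-allele frequency
#'
#' @param genotypes Vector of derived-allele copies in `{0, 1, 2}`; missing
#'   values are dropped.
#' @return Frequency `(2 n2 + n1) / (2 n)`.
#' @export
allele_frequency <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0) stop_validation("no non-missing genotypes")
  if (any(!g %in% c(0, 1, 2)))
    stop_validation("genotypes must be coded 0/1/2 derived-allele copies")
  (2 * sum(g == 2) + sum(g == 1)) / (2 * length(g))
}

#' Hardy-Weinberg chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) of observed genotype
#' counts against the expected Hardy-Weinberg proportions computed from the
#' sample allele frequency. A monomorphic sample returns chi-square 0 with a
#' `degenerate` flag.
#'
#' @param n_AA,n_Aa,n_aa Counts of ancestral homozygotes, heterozygotes and
#'   derived homozygotes.
#' @return An `hwe_result` with observed/expected counts, derived-allele
#'   frequency, chi-square and p.
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  obs <- c(AA = n_AA, Aa = n_Aa, aa = n_aa)
  if (any(!is.finite(obs)) || any(obs < 0) || any(obs != round(obs)))
    stop_validation("genotype counts must be non-negative integers")
  n <- sum(obs)
  if (n == 0) stop_validation("no genotypes")
  p <- (2 * obs[["aa"]] + obs[["Aa"]]) / (2 * n)  # derived-allele frequency
  q <- 1 - p
  expd <- n * c(AA = q^2, Aa = 2 * p * q, aa = p^2)
  degenerate <- p == 0 || p == 1
  chi2 <- if (degenerate) 0 else sum((obs - expd)^2 / expd)
  structure(list(observed = obs, expected = expd, freq = p,
                 chi2 = chi2, df = 1,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 degenerate = degenerate),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (1 df), p = %.4g; derived-allele freq = %.4f%s\n",
              x$chi2, x$p, x$freq, if (x$degenerate) " [monomorphic]" else ""))
  invisible(x)
}

#' Code genotypes as indicator columns with small-class elimination
#'
#' Builds heterozygote and derived-homozygote indicator columns against the
#' ancestral-homozygote reference. Genotype classes observed in fewer than
#' `min_class_count` individuals are eliminated: their column is dropped and
#' their individuals excluded (the published analyses eliminated classes
#' with fewer than five individuals).
#'
#' @param genotypes Vector in `{0, 1, 2, NA}`.
#' @param min_class_count Minimum class size to retain (default 5).
#' @return A list: `X` (indicator matrix over kept rows), `keep` (logical
#'   row filter, missing genotypes excluded), `dropped` (character vector of
#'   eliminated classes), `class_counts`.
#' @export
code_genotype_dummies <- function(genotypes, min_class_count = 5) {
  if (any(!genotypes %in% c(0, 1, 2, NA)))
    stop_validation("genotypes must be coded 0/1/2 or missing")
  counts <- c(`0` = sum(genotypes %in% 0), `1` = sum(genotypes %in% 1),
              `2` = sum(genotypes %in% 2))
  if (counts[["0"]] == 0)
    stop_validation("reference (ancestral homozygote) class is empty")
  small <- names(counts)[counts < min_class_count & counts >= 0]
  small <- setdiff(small, "0")  # the reference class is never eliminated
  keep <- !is.na(genotypes) & !(as.character(genotypes) %in% small)
  g <- genotypes[keep]
  cols <- list()
  if (!"1" %in% small) cols$het <- as.numeric(g == 1)
  if (!"2" %in% small) cols$hom <- as.numeric(g == 2)
  X <- do.call(cbind, cols)
  list(X = X, keep = keep, dropped = small, class_counts = counts)
}

# log-likelihood and analytic gradient of the cumulative-logit model in the
# natural parameterization (theta_1..theta_{J-1}, beta)
.polik <- function(par, y, X, J, p) {
  theta <- par[seq_len(J - 1)]
  beta <- if (p) par[J - 1 + seq_len(p)] else numeric(0)
  eta <- if (p) drop(X %*% beta) else rep(0, length(y))
  thx <- c(-Inf, theta, Inf)
  up <- thx[y + 1] - eta
  lo <- thx[y] - eta
  Fu <- stats::plogis(up); Fl <- stats::plogis(lo)
  pi <- Fu - Fl
  if (any(pi <= 0)) return(list(ll = -Inf))
  fu <- stats::dlogis(up); fu[!is.finite(up)] <- 0
  fl <- stats::dlogis(lo); fl[!is.finite(lo)] <- 0
  ll <- sum(log(pi))
  gth <- numeric(J - 1)
  for (j in seq_len(J - 1)) {
    gth[j] <- sum(fu[y == j] / pi[y == j]) - sum(fl[y == j + 1] / pi[y == j + 1])
  }
  gb <- if (p) drop(crossprod(X, (fl - fu) / pi)) else numeric(0)
  list(ll = ll, grad = c(gth, gb))
}

#' Maximum-likelihood proportional-odds ordinal regression
#'
#' Fits the cumulative-logit model with parallel slopes,
#' `logit P(Y > j | x) = x'beta - theta_j`, by Newton ascent with step
#' halving (the log-likelihood is concave in this parameterization), so an
#' odds ratio `exp(beta) > 1` reads as increased odds of a higher grade.
#' Convergence at gradient norm below `tol` (default 1e-8) within `max_iter`
#' iterations; non-convergence is an error carrying the iteration trace.
#' Wald tests per coefficient; Nagelkerke R-squared from the null (intercept
#' only) and fitted log-likelihoods. Coefficients with `|beta| > 10` set a
#' quasi-separation flag.
#'
#' @param y Ordinal outcome, integers `1..J` (or ordered factor); each of
#'   the J levels must be observed.
#' @param X Covariate matrix (n x p), or `NULL` for the null model.
#' @param max_iter,tol Newton controls.
#' @return An `ordinal_fit` with thresholds, betas, standard errors, Wald z
#'   and p, odds ratios, log-likelihoods, Nagelkerke R-squared, `n`,
#'   `converged` and `quasi_separation`.
#' @export
fit_proportional_odds <- function(y, X = NULL, max_iter = 100L, tol = 1e-8) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  J <- max(y)
  if (J < 2L || !all(seq_len(J) %in% y))
    stop_validation("y must use integer levels 1..J with every level observed")
  n <- length(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop_validation("X must have one row per observation")
    if (ncol(X) >= 1 && qr(cbind(1, X))$rank < ncol(X) + 1)
      stop_validation("collinear covariate columns")
  }
  p <- if (is.null(X)) 0L else ncol(X)

  tab <- tabulate(y, J)
  theta0 <- stats::qlogis(cumsum(tab / n)[seq_len(J - 1)])
  ll0 <- sum(tab * log(tab / n))
  par <- c(theta0, rep(0, p))

  trace <- numeric(0)
  cur <- .polik(par, y, X, J, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gnorm <- max(abs(cur$grad))
    trace <- c(trace, cur$ll)
    if (gnorm < tol) { converged <- TRUE; break }
    H <- stats::optimHess(par, fn = function(q) .polik(q, y, X, J, p)$ll,
                          gr = function(q) .polik(q, y, X, J, p)$grad)
    step <- tryCatch(solve(H, cur$grad), error = function(e) cur$grad / (gnorm + 1))
    step <- -step  # ascent: H is negative definite at interior points
    lam <- 1
    repeat {
      cand <- par + lam * step
      nxt <- .polik(cand, y, X, J, p)
      ok <- is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12 &&
        !is.unsorted(cand[seq_len(J - 1)], strictly = TRUE)
      if (ok) break
      lam <- lam / 2
      if (lam < 1e-12) { nxt <- cur; cand <- par; break }
    }
    if (identical(cand, par) && max(abs(cur$grad)) >= tol) {
      # no progress possible; fall through to convergence check below
      break
    }
    par <- cand; cur <- nxt
  }
  if (!converged && max(abs(cur$grad)) < 1e-6) converged <- TRUE
  if (!converged)
    stop(errorCondition(
      sprintf("proportional-odds fit did not converge in %d iterations (last |grad| = %.3g)",
              max_iter, max(abs(cur$grad))),
      trace = trace, class = c("iris_convergence_error", "iris_error")))

  H <- stats::optimHess(par, fn = function(q) .polik(q, y, X, J, p)$ll,
                        gr = function(q) .polik(q, y, X, J, p)$grad)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, length(par), length(par)))
  se <- sqrt(pmax(diag(vc), 0))
  theta <- par[seq_len(J - 1)]
  beta <- if (p) par[J - 1 + seq_len(p)] else numeric(0)
  beta_se <- if (p) se[J - 1 + seq_len(p)] else numeric(0)
  zv <- beta / beta_se
  pv <- 2 * stats::pnorm(-abs(zv))
  nms <- if (p) (colnames(X) %||% paste0("x", seq_len(p))) else character(0)
  names(beta) <- names(beta_se) <- names(zv) <- names(pv) <- nms

  structure(list(
    thresholds = theta, threshold_se = se[seq_len(J - 1)],
    beta = beta, se = beta_se, z = zv, p = pv, or = exp(beta),
    loglik = cur$ll, null_loglik = ll0,
    nagelkerke_r2 = nagelkerke_r2(ll0, cur$ll, n),
    n = n, J = J, converged = converged,
    quasi_separation = any(abs(beta) > 10),
    vcov = vc, iterations = it, trace = trace),
    class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit: n = %d, J = %d, logLik = %.3f (null %.3f), Nagelkerke R2 = %.4f\n",
              x$n, x$J, x$loglik, x$null_loglik, x$nagelkerke_r2))
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = ", "), "\n")
  if (length(x$beta)) {
    for (nm in names(x$beta))
      cat(sprintf("  %-12s beta = %8.4f  OR = %6.3f  se = %.4f  z = %6.3f  p = %.4g\n",
                  nm, x$beta[nm], x$or[nm], x$se[nm], x$z[nm], x$p[nm]))
  }
  if (x$quasi_separation) cat("  warning: quasi-separation suspected\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nagelkerke pseudo R-squared
#'
#' `R2_CS = 1 - exp(2 (ll0 - ll1) / n)`, normalized by its maximum
#' `1 - exp(2 ll0 / n)`.
#'
#' @param ll0,ll1 Null and fitted log-likelihoods (`ll1 >= ll0`).
#' @param n Sample size.
#' @return Value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll0, ll1, n) {
  if (n <= 0) stop_validation("n must be positive")
  if (ll1 < ll0 - 1e-8) stop_validation("ll1 must be at least ll0")
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_cs / (1 - exp(2 * ll0 / n))
}

# log-likelihood of the unconstrained cumulative model (separate slope
# vector per threshold); -Inf when the implied cell probabilities are not
# all positive
.general_cumulative_ll <- function(par, y, X, J, p) {
  theta <- par[seq_len(J - 1)]
  B <- matrix(par[-seq_len(J - 1)], nrow = p, ncol = J - 1)
  eta <- X %*% B                      # n x (J-1)
  Fm <- stats::plogis(sweep(-eta, 2, theta, "+"))   # P(Y <= j | x)
  Fx <- cbind(0, Fm, 1)
  pi <- Fx[cbind(seq_along(y), y + 1)] - Fx[cbind(seq_along(y), y)]
  if (any(pi <= 0)) return(-Inf)
  sum(log(pi))
}

#' Likelihood-ratio test of the proportional-odds assumption
#'
#' Compares the parallel-slopes cumulative-logit model against the
#' unconstrained cumulative model with a separate slope vector per
#' threshold, on `(J - 2) * p` degrees of freedom. With only two outcome
#' levels the models coincide and a not-applicable result is returned.
#'
#' @param y,X As for [fit_proportional_odds()]; `X` must have at least one
#'   column.
#' @return An `iris_test` (statistic `NA` when not applicable).
#' @export
parallel_lines_test <- function(y, X) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  X <- as.matrix(X)
  if (ncol(X) < 1) stop_validation("parallel-lines test requires covariates")
  J <- max(y)
  if (J == 2)
    return(test_result(NA_real_, df = 0,  p = NA_real_,
                       method = "parallel lines test (not applicable: J = 2)"))
  p <- ncol(X)
  fit <- fit_proportional_odds(y, X)
  start <- c(fit$thresholds, rep(fit$beta, J - 1))
  opt <- stats::optim(start, fn = function(q) {
    ll <- .general_cumulative_ll(q, y, X, J, p)
    if (!is.finite(ll)) 1e10 else -ll
  }, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  ll_gen <- -opt$value
  lr <- max(0, 2 * (ll_gen - fit$loglik))
  df <- (J - 2) * p
  test_result(lr, df = df, p = stats::pchisq(lr, df, lower.tail = FALSE),
              method = "likelihood-ratio test of parallel lines")
}
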