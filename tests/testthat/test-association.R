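test_that("allele frequency counts derived alleles", {
  expect_equal(allele_frequency(rep(2, 10)), 1)
  expect_equal(allele_frequency(rep(c(0, 1, 2), times = c(25, 50, 25))), 0.5)
  set.seed(3)
  g <- sample(c(0:2, NA), 200, replace = TRUE)
  gg <- g[!is.na(g)]
  expect_equal(allele_frequency(g), sum(gg) / (2 * length(gg)))
  expect_error(allele_frequency(c(NA, NA)), class = "iris_validation_error")
  expect_error(allele_frequency(c(0, 3)), class = "iris_validation_error")
})

test_that("Hardy-Weinberg chi-square matches hand summation", {
  expect_equal(hwe_chi2(25, 50, 25)$chi2, 0)
  h <- hwe_chi2(30, 40, 30)
  expect_equal(h$freq, 0.5)
  expect_equal(h$chi2, 4)  # contributions 1 + 2 + 1
  expect_equal(sum(h$expected), 100)

  mono <- hwe_chi2(100, 0, 0)
  expect_equal(mono$chi2, 0)
  expect_true(mono$degenerate)

  # chi2 == 0 iff n1^2 == 4 n0 n2 (exact Hardy-Weinberg configuration);
  # compared at a numerical tolerance since the expected counts involve
  # non-dyadic allele-frequency fractions
  for (n0 in 0:6) for (n1 in 0:6) for (n2 in 0:6) {
    if (n0 + n1 + n2 == 0) next
    h <- hwe_chi2(n0, n1, n2)
    expect_equal(h$chi2 < 1e-9, n1^2 == 4 * n0 * n2)
  }
  expect_error(hwe_chi2(-1, 5, 5), class = "iris_validation_error")
})

test_that("genotype dummy coding eliminates small classes", {
  g <- rep(c(0, 1, 2), times = c(50, 30, 3))
  cd <- code_genotype_dummies(g)
  expect_equal(cd$dropped, "2")
  expect_equal(colnames(cd$X), "het")
  expect_equal(sum(cd$keep), 80)
  expect_equal(sum(cd$X[, "het"]), 30)

  g2 <- rep(c(0, 1, 2), times = c(40, 40, 20))
  cd2 <- code_genotype_dummies(g2)
  expect_equal(length(cd2$dropped), 0L)
  expect_equal(colnames(cd2$X), c("het", "hom"))
  expect_equal(colSums(cd2$X), c(het = 40, hom = 20))

  expect_error(code_genotype_dummies(rep(c(1, 2), 20)),
               class = "iris_validation_error")
  # missing genotypes are excluded, not counted in any class
  g3 <- c(g2, NA, NA)
  expect_equal(sum(code_genotype_dummies(g3)$keep), 100)
})

test_that("null proportional-odds thresholds equal empirical cumulative log-odds", {
  set.seed(41)
  y <- sample(1:4, 300, replace = TRUE, prob = c(0.2, 0.4, 0.25, 0.15))
  fit <- fit_proportional_odds(y)
  emp <- qlogis(cumsum(table(y)) / 300)[1:3]
  expect_equal(unname(fit$thresholds), unname(emp), tolerance = 1e-8)
  expect_equal(fit$nagelkerke_r2, 0, tolerance = 1e-10)
})

test_that("binary-outcome fit recovers the closed-form 2x2 log odds ratio", {
  # table: x=0 -> (a successes, b failures); x=1 -> (c, d) on outcome 2 vs 1
  a <- 30; b <- 70; c <- 55; d <- 45
  y <- rep(c(2, 1, 2, 1), times = c(a, b, c, d))
  x <- rep(c(0, 0, 1, 1), times = c(a, b, c, d))
  fit <- fit_proportional_odds(y, cbind(x = x))
  expect_equal(unname(fit$beta), log((c * b) / (d * a)), tolerance = 1e-7)
  expect_equal(unname(fit$or), (c / d) / (a / b), tolerance = 1e-6)
})

test_that("fit agrees with an established optimizer and respects sign conventions", {
  skip_if_not_installed("MASS")
  set.seed(7)
  n <- 600
  X <- cbind(dose = rbinom(n, 2, 0.4), z = rnorm(n))
  eta <- drop(X %*% c(0.6, -0.3))
  cum <- plogis(outer(-eta, c(-1, 0.5, 1.5), "+"))
  y <- 1L + rowSums(runif(n) > cum)

  fit <- fit_proportional_odds(y, X)
  ref <- MASS::polr(factor(y) ~ X, method = "logistic", Hess = TRUE)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$thresholds), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))[1:2]), tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(unname(fit$or), exp(unname(fit$beta)))
  expect_true(all(diff(fit$thresholds) > 0))

  # reversing the outcome order negates every coefficient
  rev_fit <- fit_proportional_odds(5L - y, X)
  expect_equal(unname(rev_fit$beta), -unname(fit$beta), tolerance = 1e-7)
  expect_equal(unname(rev_fit$or), 1 / unname(fit$or), tolerance = 1e-6)
})

test_that("fit recovers the published derived-homozygote effect size", {
  # single simulation at n = 5000 with beta = log(2.203), the European
  # derived-homozygote crypt odds ratio
  set.seed(19)
  n <- 5000
  beta <- log(2.203)
  x <- rbinom(n, 1, 0.25)
  theta <- qlogis(c(0.092, 0.472, 0.781))  # baseline crypt cumulative probs
  cum <- plogis(outer(-x * beta, theta, "+"))
  y <- 1L + rowSums(runif(n) > cum)
  fit <- fit_proportional_odds(y, cbind(hom = x))
  expect_lt(abs(fit$beta[["hom"]] - beta) / fit$se[["hom"]], 3)
})

test_that("degenerate fits are rejected or flagged", {
  # perfectly separated data either fail to converge or converge to a
  # quasi-separated solution that is flagged
  sep <- tryCatch(
    fit_proportional_odds(rep(c(1, 2), each = 20),
                          cbind(x = rep(c(0, 1), each = 20))),
    iris_error = function(e) e)
  expect_true(inherits(sep, "iris_error") || sep$quasi_separation)
  y <- rep(1:3, 20)
  expect_error(fit_proportional_odds(y, cbind(a = rep(1:2, 30), b = rep(1:2, 30) * 2)),
               class = "iris_validation_error")
  expect_error(fit_proportional_odds(c(1, 1, 3, 3)), class = "iris_validation_error")
})

test_that("Nagelkerke R2 follows the normalized likelihood-ratio formula", {
  expect_equal(nagelkerke_r2(-100, -100, 50), 0)
  expect_equal(nagelkerke_r2(-100, 0, 50), 1)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    ll0 <- -runif(1, 50, 200)
    ll1 <- ll0 + runif(1, 0, 40)
    cs <- 1 - exp(2 * (ll0 - ll1) / n)
    expect_equal(nagelkerke_r2(ll0, ll1, n), cs / (1 - exp(2 * ll0 / n)))
  }
  expect_error(nagelkerke_r2(-10, -5, 0), class = "iris_validation_error")
  expect_error(nagelkerke_r2(-5, -10, 10), class = "iris_validation_error")
})

test_that("parallel-lines test: not applicable at J = 2, detects violations", {
  y2 <- rep(1:2, each = 30)
  x2 <- cbind(x = rnorm(60))
  na_res <- parallel_lines_test(y2, x2)
  expect_true(is.na(na_res$statistic))
  expect_match(na_res$method, "not applicable")

  # strongly non-parallel slopes at n = 2000 must be detected
  set.seed(73)
  n <- 2000
  x <- rnorm(n)
  cum1 <- plogis(-1 - 1.5 * x)     # slope differs across thresholds
  cum2 <- plogis(1 + 0.8 * x)
  cum2 <- pmax(cum1 + 1e-6, cum2)
  u <- runif(n)
  y <- ifelse(u < cum1, 1L, ifelse(u < cum2, 2L, 3L))
  res <- parallel_lines_test(y, cbind(x = x))
  expect_equal(res$df, 1)
  expect_lt(res$p, 0.001)

  # data generated under proportional odds are usually not flagged
  set.seed(74)
  eta <- rnorm(500)
  cum <- plogis(outer(-0.5 * eta, c(-1, 0, 1), "+"))
  yp <- 1L + rowSums(runif(500) > cum)
  res_ok <- parallel_lines_test(yp, cbind(x = eta))
  expect_gt(res_ok$p, 0.001)
})

test_that("parallel-lines rejection rate is near nominal under the null", {
  # scaled down (150 reps at n = 300) to keep the suite fast; compared
  # against 99% binomial bounds around the nominal 0.05
  set.seed(31415)
  reps <- 150L; rej <- 0L; done <- 0L
  for (r in seq_len(reps)) {
    x <- rnorm(300)
    cum <- plogis(outer(-0.5 * x, c(-1, 0.2, 1.2), "+"))
    y <- 1L + rowSums(runif(300) > cum)
    if (!all(1:4 %in% y)) next
    done <- done + 1L
    if (parallel_lines_test(y, cbind(x = x))$p < 0.05) rej <- rej + 1L
  }
  rate <- rej / done
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / done)
  expect_gte(rate, 0.05 - half)
  expect_lte(rate, 0.05 + half)
})
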