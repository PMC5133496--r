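test_that("identity-only fits collapse to ordinary least squares", {
  set.seed(1)
  n <- 60
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- 2 + 0.5 * X[, 2] + rnorm(n)
  fit <- fit_lmm(y, X, ped = NULL, K = NULL, ids = NULL,
                 kernels = character(0))
  ols <- stats::lm.fit(X, y)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals_conditional - ols$residuals)), 1e-8)
  expect_equal(unname(fit$sigma2[c("g", "v")]), c(0, 0))
})

test_that("balanced family-block REML matches the closed-form ANOVA estimator", {
  m <- 8; k <- 6; n <- m * k
  ped <- as_pedigree(data.frame(fid = rep(paste0("f", 1:m), each = k),
                                iid = paste0("i", 1:n),
                                father = NA, mother = NA, sex = 1))
  set.seed(4)
  fam <- rep(1:m, each = k)
  y <- rnorm(m, 0, 1)[fam] + rnorm(n, 0, 0.8)
  fit <- fit_lmm(y, NULL, ped = ped, K = NULL, ids = ped$iid,
                 kernels = "family")
  gm <- tapply(y, fam, mean)
  msb <- k * sum((gm - mean(y))^2) / (m - 1)
  msw <- sum((y - gm[fam])^2) / (n - m)
  expect_equal(unname(fit$sigma2["e"]), msw, tolerance = 1e-5)
  expect_equal(unname(fit$sigma2["v"]), (msb - msw) / k, tolerance = 1e-4)
})

test_that("variance components are recovered on simulated family data", {
  ped <- simulate_pedigree(sim_config(family_sizes = c(30, 25, 25),
                                      seed = 8))
  K <- kinship_matrix(ped)
  Lg <- t(chol(2 * K))
  fam <- factor(ped$fid)
  set.seed(21)
  est <- t(replicate(30, {
    y <- as.numeric(Lg %*% rnorm(nrow(ped))) +
      rnorm(nlevels(fam), 0, sqrt(0.5))[as.integer(fam)] + rnorm(nrow(ped))
    fit_lmm(y, NULL, ped = ped, K = K, ids = ped$iid)$sigma2
  }))
  mu <- colMeans(est)
  expect_true(all(abs(mu - c(1, 0.5, 1)) / c(1, 0.5, 1) < 0.35))
  expect_true(all(est >= 0))
})

test_that("Wald test maps effect sizes to two-sided normal p-values", {
  set.seed(2)
  n <- 40
  x <- rnorm(n)
  y0 <- rnorm(n)
  # orthogonalise so the OLS slope is exactly zero
  y <- stats::resid(stats::lm(y0 ~ x))
  fit <- fit_lmm(y, cbind(`(Intercept)` = 1, x = x), ped = NULL, K = NULL,
                 ids = NULL, kernels = character(0))
  w <- wald_test(fit, "x")
  expect_equal(w$beta, 0, tolerance = 1e-12)
  expect_equal(w$p, 1, tolerance = 1e-10)
  expect_error(wald_test(fit, 1), "intercept")
  # z of 1.959964 corresponds to p = 0.05
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
})

test_that("heritability is the genetic share of total variance", {
  fake <- structure(list(sigma2 = c(g = 1, v = 0, e = 1)),
                    class = "famnet_lmm")
  expect_equal(heritability(fake), 0.5)
  fake$sigma2 <- c(g = 0, v = 2, e = 1)
  expect_equal(heritability(fake), 0)
  fake$sigma2 <- c(g = 0, v = 0, e = 0)
  expect_error(heritability(fake), "undefined")
})

test_that("decorrelation removes family covariance and centers plain noise", {
  ped <- simulate_pedigree(sim_config(family_sizes = c(40, 35, 30),
                                      seed = 3))
  K <- kinship_matrix(ped)
  # no structure: conditional residuals are just the centered input
  cfg0 <- sim_config(family_sizes = c(40, 35, 30), n_probes = 40,
                     modules = data.frame(size = integer(0),
                                          loading = numeric(0),
                                          shared = logical(0)),
                     sigma2_g = 0, sigma2_v = 0, sigma2_e = 1,
                     age_effect = 0, sex_effect = 0, seed = 5)
  ex0 <- simulate_expression(ped, cfg0)$expr
  d0 <- decorrelate(ex0, ped, K)
  centered <- ex0 - rowMeans(ex0)
  # components estimated at the zero boundary give exactly centered rows;
  # the rest differ only by mild random-effect shrinkage
  expect_lt(mean((d0 - centered)^2), 0.1 * mean(centered^2))
  row_cor <- vapply(seq_len(nrow(ex0)),
                    function(i) cor(d0[i, ], centered[i, ]), 0)
  expect_gt(min(row_cor), 0.9)

  # strong family effects: within-family intraclass correlation shrinks
  cfg1 <- sim_config(family_sizes = c(20, 16, 14), n_probes = 60,
                     modules = data.frame(size = integer(0),
                                          loading = numeric(0),
                                          shared = logical(0)),
                     sigma2_g = 0.5, sigma2_v = 3, sigma2_e = 1,
                     age_effect = 0, sex_effect = 0, seed = 6)
  ex1 <- simulate_expression(ped, cfg1)$expr
  d1 <- decorrelate(ex1, ped, K)
  fam <- factor(ped$fid)
  fstat <- function(M) mean(apply(M, 1, function(x)
    summary(stats::aov(x ~ fam))[[1]][1, 4]))
  expect_lt(fstat(d1), 0.5 * fstat(ex1))

  # constant probe: zero residuals plus a warning
  ex1[1, ] <- 7
  expect_warning(d2 <- decorrelate(ex1, ped, K), "constant")
  expect_true(all(d2[1, ] == 0))
})
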