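test_that("biweight midcorrelation hits the exact anchors", {
  set.seed(5)
  x <- rnorm(30)
  X <- rbind(a = x, b = -x, c = rnorm(30))
  C <- bicor_matrix(X)
  expect_equal(unname(C["a", "a"]), 1)
  expect_equal(unname(C["a", "b"]), -1)
  expect_true(all(C >= -1 & C <= 1))
  expect_equal(C, t(C))
})

test_that("bicor equals Pearson without outliers and resists a gross one", {
  set.seed(6)
  n <- 500
  x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  C <- bicor_matrix(rbind(x = x, y = y))
  expect_lt(abs(C["x", "y"] - cor(x, y)), 0.05)

  # bounded data (no point near 9 MADs): close agreement with Pearson
  set.seed(7)
  u <- runif(60); v <- 0.5 * u + 0.5 * runif(60)
  C2 <- bicor_matrix(rbind(u = u, v = v))
  expect_lt(abs(C2["u", "v"] - cor(u, v)), 0.05)

  # single gross outlier: bicor closer to the true r than Pearson
  wins <- replicate(60, {
    x <- rnorm(50); y <- 0.6 * x + 0.8 * rnorm(50)
    x[1] <- 10; y[1] <- -10
    b <- bicor_matrix(rbind(x, y))[1, 2]
    abs(b - 0.6) < abs(cor(x, y) - 0.6)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("zero-MAD probes fall back to Pearson with a warning", {
  x <- c(rep(1, 18), 5, 9)   # median run makes MAD zero
  y <- rnorm(20)
  expect_warning(C <- bicor_matrix(rbind(x = x, y = y, z = y + 1)),
                 "zero MAD")
  expect_equal(unname(C["x", "y"]), cor(x, y), tolerance = 1e-10)
})

test_that("signed adjacency follows its closed form and monotonicities", {
  C <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3)
  A <- signed_adjacency(C, 6)
  expect_equal(A[1, 3], 0)
  expect_equal(A[1, 2], 0.5^6)
  expect_equal(A[1, 2], 0.015625)
  expect_equal(diag(A), rep(1, 3))

  grid <- seq(-0.99, 0.99, length.out = 41)
  for (g in c(2, 6, 12)) {
    a <- vapply(grid, function(r)
      signed_adjacency(matrix(c(1, r, r, 1), 2), g)[1, 2], 0)
    expect_true(all(diff(a) >= 0))      # non-decreasing in correlation
  }
  a6 <- abs(0.5 + 0.5 * grid)^6
  a12 <- abs(0.5 + 0.5 * grid)^12
  expect_true(all(a12 <= a6))           # non-increasing in gamma
})

test_that("soft-threshold selection prefers scale-free fits", {
  # hub-like generative model: power-law factor loadings give a heavy-
  # tailed connectivity distribution
  set.seed(8)
  n <- 80; P <- 300
  lam <- runif(P)^2
  f <- rnorm(n)
  X <- lam %o% f + sqrt(1 - lam^2) * matrix(rnorm(P * n), P, n)
  rownames(X) <- paste0("p", seq_len(P))
  C <- bicor_matrix(X)
  expect_equal(as.numeric(pick_soft_threshold(C, candidates = 6)), 6)
  g <- pick_soft_threshold(C)
  fit <- attr(g, "fit_table")
  expect_gte(max(fit$rsq), 0.8)
  expect_gte(fit$rsq[fit$gamma == as.numeric(g)], 0.8)

  # pure noise: falls through to the max-R2 branch without raising
  set.seed(9)
  Cn <- bicor_matrix(matrix(rnorm(100 * 40), 100, 40))
  expect_no_error(gn <- pick_soft_threshold(Cn))
  expect_true(as.numeric(gn) %in% seq(2, 20, 2))

  expect_error(pick_soft_threshold(matrix(1, 4, 4)), "degenerate")
})

test_that("topological overlap equals the brute-force triple loop", {
  set.seed(10)
  n <- 20
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  tom <- tom_similarity(A)
  brute <- matrix(0, n, n)
  for (l in 1:n) for (k in 1:n) {
    if (l == k) { brute[l, k] <- 1; next }
    s <- 0
    for (m in seq_len(n)) if (m != l && m != k) s <- s + A[l, m] * A[m, k]
    kl <- sum(A[l, -l]); kk <- sum(A[k, -k])
    brute[l, k] <- (s + A[l, k]) / (min(kl, kk) + 1 - A[l, k])
  }
  expect_lt(max(abs(tom - brute)), 1e-10)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))

  # 2-probe network: TOM reduces to the adjacency off-diagonal
  A2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(tom_similarity(A2)[1, 2], 0.3)
})

test_that("module detection recovers planted modules and refuses noise", {
  # zero-noise planted blocks: exact recovery
  set.seed(2)
  n <- 50
  f1 <- rnorm(n); f2 <- rnorm(n)
  X0 <- rbind(matrix(rep(f1, each = 50), 50, n),
              matrix(rep(f2, each = 50), 50, n)) +
    matrix(rnorm(100 * n, 0, 1e-6), 100, n)
  rownames(X0) <- paste0("p", 1:100)
  net0 <- build_network(X0, gamma = 6, min_module_size = 30)
  expect_equal(adjusted_rand(net0$partition, rep(1:2, each = 50)), 1)

  # noisy planted modules
  pl <- plant_modules(seed = 3)
  net <- build_network(pl$expr, gamma = 6, min_module_size = 30)
  expect_gt(adjusted_rand(net$partition, pl$labels), 0.8)
  expect_equal(length(net$eigengenes), 4)

  # pure noise: mostly grey
  set.seed(4)
  Xn <- matrix(rnorm(200 * 80), 200, 80,
               dimnames = list(paste0("p", 1:200), NULL))
  netn <- build_network(Xn, gamma = 6, min_module_size = 30)
  expect_gte(mean(netn$partition == "grey"), 0.6)

  # label-stable under probe reordering
  perm <- sample(nrow(pl$expr))
  net2 <- build_network(pl$expr[perm, ], gamma = 6, min_module_size = 30)
  expect_equal(adjusted_rand(net2$partition[rownames(pl$expr)],
                             net$partition), 1)

  expect_warning(detect_modules(matrix(0.5, 5, 5), min_module_size = 30),
                 "fewer probes")
})

test_that("module eigengenes summarise their gene set", {
  set.seed(12)
  n <- 40
  f <- rnorm(n)
  # identical probes: all variance on the first component
  Xi <- matrix(rep(f, each = 6), 6, n,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
  eg <- module_eigengene(Xi, paste0("g", 1:6))
  expect_equal(eg$var_explained, 1, tolerance = 1e-9)
  expect_equal(stats::sd(eg$scores), 1, tolerance = 1e-9)
  expect_gt(cor(eg$scores, f) * sign(cor(eg$scores, f)), 0.99)

  # independent probes: variance explained near 1/k
  set.seed(13)
  k <- 10; n2 <- 2000
  Xr <- matrix(rnorm(k * n2), k, n2,
               dimnames = list(paste0("g", 1:k), NULL))
  egr <- module_eigengene(Xr, paste0("g", 1:k))
  expect_lt(abs(egr$var_explained - 1 / k), 3 * sqrt(2 / n2))

  # flipping one probe's sign leaves variance explained unchanged
  Xf <- Xi; Xf[3, ] <- -Xf[3, ]
  expect_equal(module_eigengene(Xf, paste0("g", 1:6))$var_explained,
               eg$var_explained, tolerance = 1e-9)

  # zero-variance member is dropped with a warning; tiny sets error
  Xz <- Xi; Xz[2, ] <- 3
  expect_warning(egz <- module_eigengene(Xz, paste0("g", 1:6)),
                 "zero-variance")
  expect_equal(length(egz$genes), 5)
  expect_error(module_eigengene(Xi, "g1"), "at least 2")
})
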