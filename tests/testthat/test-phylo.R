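test_that("phylo_cov reproduces shared path lengths on the worked 3-taxon tree", {
  C <- phylo_cov(tiny_tree())
  expected <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                     dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unclass(C)[1:3, 1:3], expected, ignore_attr = TRUE)
  Cs <- phylo_cov(tiny_tree(), scale_to_unit_height = TRUE)
  expect_equal(unclass(Cs)[1:3, 1:3],
               expected / 2, ignore_attr = TRUE)
  expect_equal(attr(Cs, "height"), 2)
})

test_that("phylo_cov equals a brute-force MRCA path-sum double loop", {
  tr <- simulate_tree(20, 1, seed = 12)
  C <- unclass(phylo_cov(tr))
  depths <- ape::node.depth.edgelength(tr)
  mr <- ape::mrca(tr)
  brute <- matrix(NA_real_, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    brute[i, j] <- if (i == j) depths[i] else depths[mr[i, j]]
  }
  expect_equal(C, brute, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("phylo_cov is PSD for simulated trees and rejects unrooted input", {
  for (s in 1:10) {
    C <- phylo_cov(simulate_tree(15, 1, seed = s))
    expect_gte(min(eigen(unclass(C), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
  unr <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  expect_error(phylo_cov(unr), class = "phyloyawn_domain_error")
})

test_that("lambda transform scales only the off-diagonal", {
  C <- unclass(phylo_cov(tiny_tree()))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- matrix(c(2, 0.5, 0, 0.5, 2, 0, 0, 0, 2), 3, 3)
  expect_equal(lambda_transform(C, 0.5), half, ignore_attr = TRUE)
  expect_error(lambda_transform(C, 1.5), class = "phyloyawn_domain_error")
  expect_error(lambda_transform(C, -0.1), class = "phyloyawn_domain_error")
})

test_that("lambda ML matches a dense grid search and an external implementation", {
  tr <- simulate_tree(60, 1, seed = 13)
  C <- phyloyawn:::unit_correlation(tr)
  set.seed(14)
  y <- drop(phyloyawn:::psd_factor(lambda_transform(C, 0.6)) %*% rnorm(60))
  fit <- estimate_lambda(y, tr)
  grid <- seq(0, 1, by = 0.01)
  gl <- vapply(grid, function(l)
    phyloyawn:::lambda_profile_loglik(y, C, l), numeric(1))
  expect_lte(abs(fit$lambda - grid[which.max(gl)]), 0.01)
  skip_if_not_installed("phytools")
  ext <- phytools::phylosig(tr, setNames(y, tr$tip.label), method = "lambda")
  expect_equal(fit$lambda, ext$lambda, tolerance = 0.05)
})

test_that("lambda ML separates strong signal from none", {
  n <- 100
  hi <- lo <- logical(20)
  for (s in 1:20) {
    tr <- simulate_tree(n, 1, seed = 200 + s)
    C <- phyloyawn:::unit_correlation(tr)
    set.seed(300 + s)
    y1 <- drop(phyloyawn:::psd_factor(C) %*% rnorm(n))
    y0 <- rnorm(n)
    hi[s] <- estimate_lambda(y1, tr)$lambda > 0.8
    lo[s] <- estimate_lambda(y0, tr)$lambda < 0.2
  }
  expect_gte(sum(hi), 18)
  expect_gte(sum(lo), 18)
  tr <- simulate_tree(10, 1, seed = 1)
  expect_error(estimate_lambda(rep(1, 10), tr),
               class = "phyloyawn_domain_error")
})

test_that("PGLS reduces to OLS on a star tree and to zero residuals on exact fits", {
  star <- ape::stree(10, "star")
  star$edge.length <- rep(1, 10)
  set.seed(15)
  x <- rnorm(10); y <- 1 + 2 * x + rnorm(10)
  fit <- pgls_fit(y, cbind(1, x), star, lambda = 1)
  ols <- unname(coef(lm(y ~ x)))
  expect_equal(unname(fit$coefficients), ols, tolerance = 1e-10)
  # exact linear system: zero residuals at any lambda
  ye <- 3 - 0.5 * x
  tr <- simulate_tree(10, 1, seed = 16)
  for (lam in c(0, 0.4, 1)) {
    f <- pgls_fit(ye, cbind(1, x), tr, lambda = lam)
    expect_equal(f$residuals, rep(0, 10), tolerance = 1e-12)
  }
})

test_that("PGLS matches the direct GLS matrix formula on the 3-taxon case", {
  tr <- tiny_tree()
  y <- c(1, 2, 4)
  C <- phyloyawn:::unit_correlation(tr)
  fit <- pgls_fit(y, matrix(1, 3, 1), tr, lambda = 1)
  # independent route: explicit inverse
  Vi <- solve(C)
  bhat <- drop(solve(t(rep(1, 3)) %*% Vi %*% rep(1, 3)) %*%
                 t(rep(1, 3)) %*% Vi %*% y)
  expect_equal(unname(fit$coefficients), bhat, tolerance = 1e-10)
})

test_that("PGLS with lambda=0 equals weighted least squares with 1/diag weights", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  # non-ultrametric: scaled diagonal differs across tips
  C <- phyloyawn:::unit_correlation(tr)
  set.seed(17)
  # need >=4 tips for nothing here; 3 is fine for the algebra
  y <- c(1.2, 0.7, 2.5)
  x <- c(0, 1, 2)
  fit <- pgls_fit(y, cbind(1, x), tr, lambda = 0)
  wls <- unname(coef(lm(y ~ x, weights = 1 / diag(C))))
  expect_equal(unname(fit$coefficients), wls, tolerance = 1e-10)
})

test_that("PGLS profile-ML lambda agrees with estimate_lambda for intercept-only designs", {
  tr <- simulate_tree(40, 1, seed = 18)
  C <- phyloyawn:::unit_correlation(tr)
  set.seed(19)
  y <- drop(phyloyawn:::psd_factor(lambda_transform(C, 0.7)) %*% rnorm(40))
  f1 <- estimate_lambda(y, tr)
  f2 <- pgls_fit(y, matrix(1, 40, 1), tr, lambda = "ml")
  expect_equal(f1$lambda, f2$lambda_used, tolerance = 1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("rank-deficient designs error naming the collinear columns", {
  tr <- simulate_tree(10, 1, seed = 20)
  x <- rnorm(10)
  X <- cbind(intercept = 1, a = x, b = 2 * x)
  expect_error(pgls_fit(rnorm(10), X, tr), "b",
               class = "phyloyawn_domain_error")
  expect_error(pgls_fit(rnorm(10), cbind(a = x), tr), "intercept",
               class = "phyloyawn_domain_error")
})

test_that("phylogenetic correlation hits exact limits and recovers truth", {
  tr <- simulate_tree(20, 1, seed = 21)
  set.seed(22)
  x <- rnorm(20)
  expect_equal(phylo_correlation(x, x, tr), 1.0)
  expect_equal(phylo_correlation(x, -2 * x + 5, tr), -1.0)
  expect_error(phylo_correlation(x, rep(1, 20), tr),
               class = "phyloyawn_domain_error")
  hits <- vapply(1:20, function(s) {
    tr <- simulate_tree(200, 1, seed = 400 + s)
    evo <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
    bm <- simulate_bm_traits(tr, c(0, 0), evo, seed = 500 + s)
    abs(phylo_correlation(bm$log_body, bm$log_brain, tr) - 0.9) <= 0.05
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("vif matches its closed form and brute-force regressions", {
  # orthogonal designs
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(X)), c(1, 1))
  # exact sample correlation 0.6 -> VIF = 1/(1-0.36) = 1.5625
  a <- c(-1, 0, 1); a <- (a - mean(a)) / sd(a)
  b0 <- c(1, -2, 1); b0 <- resid(lm(b0 ~ a)); b0 <- b0 / sd(b0)
  b <- 0.6 * a + sqrt(1 - 0.36) * b0
  expect_equal(unname(vif(cbind(a = a, b = b))), c(1.5625, 1.5625),
               tolerance = 1e-10)
  # random 5-column matrix vs per-column lm oracle
  set.seed(23)
  Z <- matrix(rnorm(200), 40, 5)
  Z[, 2] <- Z[, 1] * 0.8 + 0.3 * Z[, 2]
  v <- vif(Z)
  oracle <- vapply(1:5, function(j) {
    1 / (1 - summary(lm(Z[, j] ~ Z[, -j]))$r.squared)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-8)
  # perfect collinearity reports Inf, not an error
  expect_equal(unname(vif(cbind(a = a, b = 2 * a + 1))), c(Inf, Inf))
})
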