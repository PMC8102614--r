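test_that("gamma log density matches its special case, stats::dgamma, and integrates to 1", {
  expect_equal(gamma_loglik(1, 1, 1), -1)
  grid <- expand.grid(y = c(0.3, 1, 4), mu = c(0.5, 2), a = c(0.8, 5))
  ours <- with(grid, gamma_loglik(y, mu, a))
  ref <- with(grid, dgamma(y, shape = a, rate = a / mu, log = TRUE))
  expect_equal(ours, ref, tolerance = 1e-12)
  for (mu in c(0.5, 2)) for (a in c(0.8, 5)) {
    total <- integrate(function(y) exp(gamma_loglik(y, mu, a)), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_lt(abs(total - 1), 1e-6)
  }
  expect_error(gamma_loglik(-1, 1, 1), class = "phyloyawn_domain_error")
})

test_that("the mean/shape Gamma sampler has the requested mean", {
  set.seed(30)
  draws <- phyloyawn:::rgamma_mean(1e6, mu = 3.4, shape = 4)
  expect_equal(mean(draws), 3.4, tolerance = 0.01 / 3.4)
})

test_that("the linear predictor matches arithmetic and a hand-rolled loop", {
  spec <- yawn_model("z")
  dat <- tibble::tibble(species = letters[1:5], z = c(-1, 0, 0.5, 1, 2))
  zero <- list(beta0 = log(3.4), beta = c(z = 0), b = rep(0, 5), u = rep(0, 5))
  expect_equal(build_linear_predictor(spec, dat, zero)$eta,
               rep(log(3.4), 5))
  one <- list(beta0 = log(3.4), beta = c(z = 0.35), b = rep(0, 5),
              u = rep(0, 5))
  expect_equal(build_linear_predictor(spec, dat, one)$mu[4], 3.4 * exp(0.35))
  # loop oracle with random effects and order slopes
  set.seed(31)
  dat$ord <- c("x", "x", "y", "y", "y")
  spec2 <- yawn_model("z", slopes_by = "ord")
  par <- list(beta0 = 0.7, beta = c(z = 0.2), b = rnorm(5), u = rnorm(5),
              order_dev = c(x = 0.1, y = -0.3))
  got <- build_linear_predictor(spec2, dat, par)
  for (i in 1:5) {
    eta_i <- par$beta0 + par$beta["z"] * dat$z[i] + par$b[i] + par$u[i] +
      par$order_dev[dat$ord[i]] * dat$z[i]
    expect_equal(got$eta[i], unname(eta_i))
  }
  expect_error(build_linear_predictor(spec, dat, zero[-1]),
               class = "phyloyawn_domain_error")
})

test_that("waic handles its degenerate cases and matches a naive oracle", {
  ll0 <- matrix(rep(c(-1.2, -0.4, -2, -0.7, -1), each = 150), 150, 5)
  w0 <- waic(ll0)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * sum(ll0[1, ]))
  set.seed(32)
  ll <- matrix(rnorm(200 * 5, -1, 0.3), 200, 5)
  w <- waic(ll)
  expect_equal(waic(cbind(ll, ll))$waic, 2 * w$waic, tolerance = 1e-10)
  # naive high-precision oracle
  lppd <- log(colMeans(exp(ll)))
  p <- apply(ll, 2, var)
  expect_equal(w$waic, -2 * sum(lppd - p), tolerance = 1e-8)
  expect_equal(w$se, sqrt(5 * var(-2 * (lppd - p))), tolerance = 1e-8)
  bad <- ll; bad[1, 1] <- Inf
  expect_error(waic(bad), class = "phyloyawn_domain_error")
  expect_error(waic(ll[1:50, ]), class = "phyloyawn_domain_error")
})

test_that("waic comparison applies the dWAIC >= 2 rule with the right sign", {
  set.seed(33)
  ll <- matrix(rnorm(200 * 6, -1, 0.3), 200, 6,
               dimnames = list(NULL, letters[1:6]))
  self <- suppressMessages(compare_waic(ll, ll))
  expect_equal(self$delta, 0)
  expect_equal(self$decision, "fixed")
  # shift the alternative's pointwise log-lik by a constant c per species:
  # delta = 2 * n * c exactly
  shift_for <- function(delta) delta / (2 * ncol(ll))
  just_below <- suppressMessages(compare_waic(ll, ll + shift_for(1.9)))
  expect_equal(just_below$delta, 1.9, tolerance = 1e-8)
  expect_equal(just_below$decision, "fixed")
  above <- suppressMessages(compare_waic(ll, ll + shift_for(2.5)))
  expect_equal(above$decision, "slopes")
  colnames(ll) <- letters[7:12]
  expect_error(suppressMessages(compare_waic(ll, ll[, 6:1])),
               class = "phyloyawn_domain_error")
})

test_that("posterior summaries compute median, MAD, CI and p+ as defined", {
  sd35 <- phyloyawn:::summarize_draws(rep(0.35, 500))
  expect_equal(sd35$median, 0.35)
  expect_equal(sd35$mad, 0)
  expect_equal(sd35$p_plus, 1.0)
  sym <- phyloyawn:::summarize_draws(c(-3:3))
  expect_equal(sym$p_plus, 3 / 7)  # strict inequality: zero not positive
  set.seed(34)
  z <- rnorm(1e5)
  sz <- phyloyawn:::summarize_draws(z)
  expect_equal(sz$ci_lower, -1.645, tolerance = 0.02)
  expect_equal(sz$ci_upper, 1.645, tolerance = 0.02)
  expect_equal(sz$p_plus, 0.5, tolerance = 0.01)
})

test_that("split R-hat and bulk ESS behave on iid and autocorrelated draws", {
  set.seed(35)
  x <- rnorm(4000); ch <- rep(1:4, each = 1000)
  expect_lt(rhat(x, ch), 1.01)
  expect_gt(ess_bulk(x, ch), 3000)
  slow <- as.numeric(stats::arima.sim(list(ar = 0.95), 4000))
  expect_lt(ess_bulk(slow, ch), 600)
})

test_that("fits are deterministic given the seed", {
  q <- quick_clade(n = 12, seed = 41)
  f1 <- quick_fit(q$data, q$tree, seed = 2, iterations = 700)
  f2 <- quick_fit(q$data, q$tree, seed = 2, iterations = 700)
  expect_identical(f1$draws$beta_z, f2$draws$beta_z)
  f3 <- quick_fit(q$data, q$tree, seed = 3, iterations = 700)
  expect_false(identical(f1$draws$beta_z, f3$draws$beta_z))
})

test_that("the convergence gate rejects deliberately short runs with diagnostics", {
  q <- quick_clade(n = 15, seed = 42)
  err <- tryCatch(
    fit_model(q$data, q$tree, yawn_model("z"), chains = 2,
              iterations = 700, warmup = 350, seed = 1,
              check_convergence = "error"),
    phyloyawn_convergence_error = function(e) e)
  expect_s3_class(err, "phyloyawn_convergence_error")
  expect_s3_class(err$diagnostics, "tbl_df")
  expect_true(all(c("rhat", "ess") %in% names(err$diagnostics)))
})

test_that("prior-predictive draws match the declared priors", {
  q <- quick_clade(n = 8, seed = 43)
  fit <- fit_model(q$data, q$tree, yawn_model("z"), chains = 2,
                   iterations = 4000, warmup = 1000, seed = 5,
                   check_convergence = "none", sample_prior = TRUE)
  b <- fit$draws$beta_z
  expect_equal(mean(b), 0, tolerance = 0.08)
  expect_equal(sd(b), 1, tolerance = 0.08)
  s <- fit$draws$sigma_phylo
  expect_equal(mean(s), 1 / 3, tolerance = 0.05)
  expect_null(fit$pointwise_loglik)
})

test_that("posterior uncertainty in the slope contracts as species are added", {
  sds <- vapply(1:10, function(s) {
    small <- quick_clade(n = 20, seed = 600 + s)
    large <- quick_clade(n = 40, seed = 600 + s)
    f_s <- quick_fit(small$data, small$tree, seed = s, iterations = 900)
    f_l <- quick_fit(large$data, large$tree, seed = s, iterations = 900)
    c(sd(f_s$draws$beta_z), sd(f_l$draws$beta_z))
  }, numeric(2))
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("misaligned data and tree are refused", {
  q <- quick_clade(n = 10, seed = 44)
  shuffled <- q$data[sample(nrow(q$data)), ]
  expect_error(quick_fit(shuffled, q$tree), class = "phyloyawn_domain_error")
})
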