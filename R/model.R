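#' Gamma log density in mean/shape form
#'
#' Log density of the Gamma distribution parameterized by its mean `mu`
#' and shape `shape` (the response family of the yawn-duration model,
#' whose log link acts on `mu`):
#' `shape*log(shape/mu) + (shape-1)*log(y) - shape*y/mu - lgamma(shape)`.
#'
#' @param duration Observed duration(s), positive.
#' @param mu Mean(s), positive.
#' @param shape Shape parameter, positive.
#' @return Elementwise log density, recycled to the common length.
#' @export
gamma_loglik <- function(duration, mu, shape) {
  if (any(duration <= 0) || any(mu <= 0) || any(shape <= 0)) {
    stop_domain("duration, mu and shape must all be positive")
  }
  shape * log(shape / mu) + (shape - 1) * log(duration) -
    shape * duration / mu - lgamma(shape)
}

# Draws from the mean/shape Gamma parameterization.
rgamma_mean <- function(n, mu, shape) {
  rgamma(n, shape = shape, rate = shape / mu)
}

#' Define a yawn-duration model
#'
#' Declarative specification of the multilevel phylogenetic Gamma
#' regression: species mean yawn duration ~ Gamma(log link) with the
#' named standardized predictors as fixed effects, a phylogenetically
#' structured random intercept (covariance `sigma_phylo^2` times the
#' unit-height phylogenetic correlation matrix) and an independent
#' species-level intercept. Priors: Normal(0,1) on intercept and slopes,
#' Exponential(3) on random-effect SDs, Gamma(0.01, 0.01) on the shape.
#'
#' @param predictors Character vector of predictor column names (one
#'   brain measure, optionally plus standardized log body mass).
#' @param slopes_by Optional column name of a grouping factor (taxonomic
#'   order) receiving random slope deviations on the first predictor.
#' @param intercept_by Optional column name of a grouping factor (e.g.
#'   clade) giving group-specific intercepts, random-effect SDs and
#'   Gamma shapes, used by the constrained joint cross-clade model.
#' @param response Response column (default `mean_duration`, seconds).
#' @param shape_prior Length-2 `c(shape, rate)` of the Gamma prior on
#'   the response shape.
#' @return An object of class `yawn_model_spec`.
#' @export
yawn_model <- function(predictors, slopes_by = NULL, intercept_by = NULL,
                       response = "mean_duration",
                       shape_prior = c(0.01, 0.01)) {
  stopifnot(is.character(predictors), length(predictors) >= 1L)
  structure(list(predictors = predictors,
                 slope_on = predictors[1L],
                 slopes_by = slopes_by,
                 intercept_by = intercept_by,
                 response = response,
                 shape_prior = shape_prior),
            class = "yawn_model_spec")
}

#' Evaluate the linear predictor of a model specification
#'
#' Computes `eta_i = beta0 + sum_k beta_k x_ik + b_i + u_i` (plus the
#' order slope deviation times the first predictor when present) and
#' `mu_i = exp(eta_i)` for given parameter values. Used for simulation
#' and for verifying the sampler's internal predictor.
#'
#' @param spec A [yawn_model()].
#' @param data Species-level tibble containing the predictor columns
#'   (and the grouping columns the spec names).
#' @param params List with `beta0` (scalar, or named by intercept group),
#'   `beta` (named by predictor), `b`, `u` (per-species vectors), and
#'   optionally `order_dev` (named by order level).
#' @return Tibble with `species`, `eta`, `mu`.
#' @export
build_linear_predictor <- function(spec, data, params) {
  need <- c("beta0", "beta", "b", "u")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop_domain(paste0("missing parameter(s): ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(data[spec$predictors])
  beta <- params$beta[spec$predictors]
  if (anyNA(beta)) stop_domain("params$beta must be named by the predictors")
  beta0 <- params$beta0
  if (!is.null(spec$intercept_by)) {
    beta0 <- params$beta0[as.character(data[[spec$intercept_by]])]
  }
  eta <- unname(beta0) + drop(X %*% beta) + params$b + params$u
  if (!is.null(spec$slopes_by) && !is.null(params$order_dev)) {
    dev <- params$order_dev[as.character(data[[spec$slopes_by]])]
    eta <- eta + unname(dev) * X[, spec$slope_on]
  }
  tibble(species = data$species, eta = eta, mu = exp(eta))
}

# ---- JAGS model assembly -------------------------------------------------

jags_model_string <- function(has_slopes, shape_prior, sample_prior = FALSE) {
  slope_term <- if (has_slopes) " + gdev[ord[i]] * X[i,1]" else ""
  slope_block <- if (has_slopes) "
  for (j in 1:J) {
    gdev[j] <- sigma_slope * zg[j]
    zg[j] ~ dnorm(0, 1)
  }
  sigma_slope ~ dexp(3)
" else ""
  lik <- if (sample_prior) "" else
    "\n    y[i] ~ dgamma(alpha[g[i]], alpha[g[i]] / mu[i])"
  sprintf("
model {
  for (i in 1:N) {%s
    mu[i] <- exp(eta[i])
    eta[i] <- beta0[g[i]] + inprod(X[i,1:K], beta[1:K]) + b[i] + u[i]%s
    u[i] <- sigma_species[g[i]] * zu[i]
    zu[i] ~ dnorm(0, 1)
    zb[i] ~ dnorm(0, 1)
    b[i] <- sigma_phylo[g[i]] * Lz[i]
  }
  Lz <- L %%*%% zb
  for (gg in 1:G) {
    beta0[gg] ~ dnorm(0, 1)
    sigma_phylo[gg] ~ dexp(3)
    sigma_species[gg] ~ dexp(3)
    alpha[gg] ~ dgamma(%g, %g)
  }
  for (k in 1:K) {
    beta[k] ~ dnorm(0, 1)
  }%s
}", lik, slope_term, shape_prior[1L], shape_prior[2L], slope_block)
}

#' Fit the Bayesian multilevel phylogenetic Gamma regression
#'
#' Samples the posterior of the model declared by [yawn_model()] with
#' JAGS, using a non-centered parameterization of the phylogenetic
#' intercepts (`b = sigma_phylo * L z`, `L` the Cholesky factor of the
#' unit-height phylogenetic correlation matrix). The run is rejected
#' with a convergence error unless every reported parameter satisfies
#' the gate (`rhat_max`, `ess_min`); pass `check_convergence = "warn"`
#' or `"none"` for deliberately short exploratory or simulation-suite
#' runs. Draws are deterministic given `(seed, chains, iterations)` on a
#' fixed platform.
#'
#' @param data Species-level tibble (one row per species) containing the
#'   response and predictor columns, in tree tip order.
#' @param tree Matched `phylo` tree (tips aligned to `data$species`), or
#'   `NULL` if `C_corr` is given.
#' @param spec A [yawn_model()].
#' @param chains Number of MCMC chains (default 4).
#' @param iterations Iterations per chain including warmup (default
#'   2000, half of which is warmup).
#' @param warmup Warmup iterations per chain (adaptation plus burn-in).
#' @param seed Integer seed controlling all chains.
#' @param check_convergence `"error"` (default), `"warn"` or `"none"`.
#' @param rhat_max,ess_min Convergence gate: maximum split R-hat and
#'   minimum bulk ESS over reported parameters (defaults 1.01 and 400).
#' @param C_corr Optional species correlation matrix replacing the one
#'   computed from `tree` (used for the block-diagonal cross-clade
#'   model).
#' @param sample_prior If `TRUE`, drop the likelihood and sample the
#'   prior instead (prior-predictive checks); no pointwise
#'   log-likelihood is produced.
#' @return An object of class `yawn_fit` with elements `draws` (tibble,
#'   one row per draw: `.chain`, `.iteration`, scalar parameters, and
#'   per-species `b_*`, `u_*`, `eta_*`), `pointwise_loglik` (draws x
#'   species matrix), `diagnostics`, `data`, `spec`, `seed`.
#' @export
fit_model <- function(data, tree, spec = yawn_model("z_log_brain"),
                      chains = 4L, iterations = 2000L,
                      warmup = floor(iterations / 2),
                      seed = 1L,
                      check_convergence = c("error", "warn", "none"),
                      rhat_max = 1.01, ess_min = 400,
                      C_corr = NULL, sample_prior = FALSE) {
  check_convergence <- match.arg(check_convergence)
  n <- nrow(data)
  if (n < 4L) stop_domain("need at least 4 species")
  y <- data[[spec$response]]
  if (is.null(y) || any(!is.finite(y)) || any(y <= 0)) {
    stop_domain(paste0("response '", spec$response,
                       "' must be positive and complete"))
  }
  for (p in spec$predictors) {
    if (is.null(data[[p]]) || any(!is.finite(data[[p]]))) {
      stop_domain(paste0("predictor '", p, "' missing or incomplete"))
    }
  }
  if (is.null(C_corr)) {
    if (!identical(canonicalize_species(tree$tip.label),
                   canonicalize_species(data$species))) {
      stop_domain("data rows must be aligned to the tree tips; see match_tree()")
    }
    C_corr <- unit_correlation(tree)
  }
  X <- as.matrix(data[spec$predictors])
  K <- ncol(X)
  g <- if (is.null(spec$intercept_by)) rep(1L, n) else {
    as.integer(factor(data[[spec$intercept_by]]))
  }
  glev <- if (is.null(spec$intercept_by)) "" else {
    levels(factor(data[[spec$intercept_by]]))
  }
  G <- max(g)
  has_slopes <- !is.null(spec$slopes_by)
  jd <- list(y = y, X = X, N = n, K = K, G = G, g = g,
             L = t(chol_psd(C_corr)))
  if (sample_prior) jd$y <- NULL
  if (has_slopes) {
    ord <- factor(data[[spec$slopes_by]])
    if (nlevels(ord) < 2L) stop_domain("random slopes need >= 2 orders")
    jd$ord <- as.integer(ord)
    jd$J <- nlevels(ord)
  }
  seeds <- derive_seeds(seed, chains + 1L)
  inits <- lapply(seq_len(chains), function(i) {
    set.seed(seeds[i])
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = seeds[i],
      beta0 = rnorm(G, 0, 0.3),
      beta = rnorm(K, 0, 0.3),
      sigma_phylo = rep(0.2, G) * exp(rnorm(G, 0, 0.2)),
      sigma_species = rep(0.1, G) * exp(rnorm(G, 0, 0.2)),
      alpha = rep(10, G) * exp(rnorm(G, 0, 0.2)),
      zu = rnorm(n, 0, 0.1), zb = rnorm(n, 0, 0.1)
    )
    if (has_slopes) {
      ini$zg <- rnorm(jd$J, 0, 0.1)
      ini$sigma_slope <- 0.1 * exp(rnorm(1, 0, 0.2))
    }
    ini
  })
  adapt <- max(300L, floor(warmup / 2))
  burn <- max(0L, warmup - adapt)
  monitors <- c("beta0", "beta", "sigma_phylo", "sigma_species", "alpha",
                "eta", "b", "u")
  if (has_slopes) monitors <- c(monitors, "sigma_slope", "gdev")
  t0 <- Sys.time()
  jm <- rjags::jags.model(textConnection(jags_model_string(
    has_slopes, spec$shape_prior, sample_prior)),
    data = jd, inits = inits, n.chains = chains,
    n.adapt = adapt, quiet = TRUE)
  if (burn > 0L) update(jm, burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iterations - warmup,
                              progress.bar = "none")
  runtime <- as.numeric(Sys.time() - t0, units = "secs")

  draws <- purrr::map_dfr(seq_along(samp), function(ch) {
    m <- as.matrix(samp[[ch]])
    d <- as_tibble(m)
    d$.chain <- ch
    d$.iteration <- seq_len(nrow(m))
    d
  })
  draws <- rename_jags_columns(draws, spec, data$species, G, glev, K,
                               if (has_slopes) levels(factor(
                                 data[[spec$slopes_by]])) else NULL)

  core <- core_parameters(spec, G, glev)
  eta_cols <- paste0("eta_", data$species)
  alpha_cols <- if (G == 1L) rep("alpha", n) else paste0("alpha_", glev)[g]
  ll <- NULL
  if (!sample_prior) {
    ll <- matrix(NA_real_, nrow(draws), n,
                 dimnames = list(NULL, data$species))
    for (i in seq_len(n)) {
      ll[, i] <- gamma_loglik(y[i], exp(draws[[eta_cols[i]]]),
                              draws[[alpha_cols[i]]])
    }
    if (any(!is.finite(ll))) {
      abort("non-finite pointwise log-likelihoods",
            class = "phyloyawn_fit_error")
    }
  }
  diag_tbl <- diagnostics_table(draws, core)
  fit <- structure(list(
    draws = draws, pointwise_loglik = ll, diagnostics = diag_tbl,
    data = data, spec = spec, species = data$species,
    C_corr = C_corr, seed = seed, chains = chains,
    iterations = iterations, warmup = warmup, runtime = runtime,
    group_levels = glev
  ), class = "yawn_fit")
  bad <- diag_tbl$rhat > rhat_max | diag_tbl$ess < ess_min
  if (any(bad) && check_convergence != "none") {
    msg <- paste0(
      "convergence gate failed (R-hat < ", rhat_max, ", ESS > ", ess_min,
      ") for: ",
      paste(sprintf("%s (rhat %.3f, ess %.0f)", diag_tbl$term[bad],
                    diag_tbl$rhat[bad], diag_tbl$ess[bad]), collapse = "; "),
      ". Increase iterations/chains.")
    if (check_convergence == "error") {
      cnd <- rlang::error_cnd(class = "phyloyawn_convergence_error",
                              message = msg, diagnostics = diag_tbl)
      rlang::cnd_signal(cnd)
    }
    warn(msg)
  }
  fit
}

core_parameters <- function(spec, G, glev) {
  base <- c("beta0", "sigma_phylo", "sigma_species", "alpha")
  core <- if (G == 1L) base else {
    as.vector(vapply(base, function(b) paste0(b, "_", glev), character(G)))
  }
  core <- c(core, paste0("beta_", spec$predictors))
  if (!is.null(spec$slopes_by)) core <- c(core, "sigma_slope")
  core
}

rename_jags_columns <- function(draws, spec, species, G, glev, K, ord_lev) {
  nm <- names(draws)
  relab <- function(prefix, labels) {
    idx <- grep(paste0("^", prefix, "\\["), nm)
    if (length(idx)) {
      pos <- as.integer(sub(paste0("^", prefix, "\\[(\\d+)\\]$"), "\\1",
                            nm[idx]))
      nm[idx] <<- paste0(prefix, "_", labels[pos])
    } else if (prefix %in% nm && length(labels) == 1L) {
      nm[nm == prefix] <<- paste0(prefix, "_", labels)
    }
  }
  if (G == 1L) {
    for (p in c("beta0", "sigma_phylo", "sigma_species", "alpha")) {
      nm[nm == paste0(p, "[1]")] <- p
      nm[nm == p] <- p
    }
  } else {
    for (p in c("beta0", "sigma_phylo", "sigma_species", "alpha")) {
      relab(p, glev)
    }
  }
  relab("beta", spec$predictors)
  if (K == 1L) nm[nm == "beta"] <- paste0("beta_", spec$predictors)
  relab("eta", species)
  relab("b", species)
  relab("u", species)
  if (!is.null(ord_lev)) relab("gdev", ord_lev)
  names(draws) <- nm
  draws
}

#' @export
print.yawn_fit <- function(x, ...) {
  cat("Bayesian phylogenetic Gamma regression (", length(x$species),
      " species, ", nrow(x$draws), " draws, ", x$chains, " chains)\n",
      sep = "")
  print(tidy.yawn_fit(x))
  invisible(x)
}
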