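#' Standardize to z-scores
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) SD. The center and
#' scale are stored as attributes so the transformation is invertible
#' with [unstandardize()].
#'
#' @param x Numeric vector with at least 2 distinct values.
#' @return Standardized vector with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  if (length(unique(x[is.finite(x)])) < 2L) {
    stop_domain("need at least 2 distinct values to standardize")
  }
  s <- sd(x)
  if (s == 0) stop_domain("zero variance; cannot standardize")
  structure((x - mean(x)) / s, center = mean(x), scale = s)
}

#' Invert a standardization
#' @param z Vector produced by [standardize()] (or any vector, with
#'   `center`/`scale` supplied).
#' @param center,scale Mean and SD used in the forward transform.
#' @return The original-scale values.
#' @export
unstandardize <- function(z, center = attr(z, "center"),
                          scale = attr(z, "scale")) {
  as.numeric(z) * scale + center
}

measure_log_col <- function(measure) {
  switch(measure,
         brain_mass = "log_brain",
         total_neurons = "log_total_neurons",
         cortex_neurons = "log_cortex_neurons",
         neuron_density = "log_neuron_density",
         stop_domain(paste0("unknown measure: ", measure)))
}

#' Define an analysis plan
#'
#' Collects the tunable settings of the per-clade analysis: which brain
#' measures to fit, whether and how to correct for body size (the VIF
#' gate), the random-slope policy across taxonomic orders, and MCMC
#' settings.
#'
#' @param measures Subset of `"brain_mass"`, `"total_neurons"`,
#'   `"cortex_neurons"`, `"neuron_density"`.
#' @param adjust_body Also fit body-size-adjusted models (default TRUE).
#' @param vif_threshold Collinearity gate; VIF above it routes the
#'   adjustment through PGLS residualization instead of a body-mass
#'   covariate (default 3).
#' @param random_slopes `"auto"` (WAIC decides), `"on"`, or `"off"`.
#' @param chains,iterations,warmup,check_convergence,rhat_max,ess_min
#'   Passed to [fit_model()].
#' @param min_species Minimum species for a measure to be fitted at all
#'   (default 4); a warning is logged below `warn_species` (default 15).
#' @param seed Master seed for all fits in the plan.
#' @return An object of class `yawn_plan`.
#' @export
analysis_plan <- function(measures = c("brain_mass"),
                          adjust_body = TRUE,
                          vif_threshold = 3,
                          random_slopes = c("auto", "on", "off"),
                          chains = 4L, iterations = 4000L,
                          warmup = floor(iterations / 2),
                          check_convergence = "warn",
                          rhat_max = 1.01, ess_min = 400,
                          min_species = 4L, warn_species = 15L,
                          seed = 1L) {
  if (vif_threshold <= 1) stop_domain("vif_threshold must be > 1")
  structure(list(measures = measures, adjust_body = adjust_body,
                 vif_threshold = vif_threshold,
                 random_slopes = match.arg(random_slopes),
                 chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 check_convergence = check_convergence,
                 rhat_max = rhat_max, ess_min = ess_min,
                 min_species = as.integer(min_species),
                 warn_species = as.integer(warn_species),
                 seed = as.integer(seed)),
            class = "yawn_plan")
}

plan_fit <- function(data, tree, spec, plan, seed, C_corr = NULL) {
  fit_model(data, tree, spec, chains = plan$chains,
            iterations = plan$iterations, warmup = plan$warmup,
            seed = seed, check_convergence = plan$check_convergence,
            rhat_max = plan$rhat_max, ess_min = plan$ess_min,
            C_corr = C_corr)
}

#' Fit one brain measure within a clade
#'
#' Runs the per-measure analysis: the primary unadjusted model (the
#' absolute measure as sole predictor), and — when `plan$adjust_body` —
#' a body-size-adjusted model whose form is gated on collinearity. If
#' the VIF of the standardized measure and standardized log body mass
#' exceeds `plan$vif_threshold`, the measure is residualized against
#' body mass by ML-lambda PGLS and the re-standardized residuals become
#' the sole predictor; otherwise body mass enters as a second covariate.
#' A WAIC check decides whether per-order random slopes are retained
#' (policy `plan$random_slopes`).
#'
#' @param data Species-level tibble for one clade (from
#'   [aggregate_species()]).
#' @param tree The clade phylogeny.
#' @param measure One of the measure names in [analysis_plan()].
#' @param plan A [analysis_plan()].
#' @return `NULL` (with a message) when too few species carry the
#'   measure; otherwise a `yawn_measure_result` list: `fits`
#'   (unadjusted/adjusted `yawn_fit`s), `branch`, `vifs`, `slope_check`,
#'   `n_species`.
#' @export
run_measure <- function(data, tree, measure, plan = analysis_plan()) {
  log_col <- measure_log_col(measure)
  keep <- is.finite(data[[log_col]]) & is.finite(data$log_body)
  if (sum(keep) < plan$min_species) {
    message("skipping ", measure, ": only ", sum(keep),
            " species with the measure (need ", plan$min_species, ")")
    return(NULL)
  }
  sub <- data[keep, , drop = FALSE]
  if (nrow(sub) < plan$warn_species) {
    warn(paste0(measure, ": only ", nrow(sub),
                " species; estimates will be imprecise"))
  }
  m <- match_tree(sub, tree)
  sub <- m$data
  tree <- m$tree
  sub$z_measure <- as.numeric(standardize(sub[[log_col]]))
  sub$z_body <- as.numeric(standardize(sub$log_body))
  seeds <- derive_seeds(plan$seed + match(measure, c(
    "brain_mass", "total_neurons", "cortex_neurons", "neuron_density")),
    4L)

  slope_check <- NULL
  slopes_by <- NULL
  if (plan$random_slopes != "off" && "order" %in% names(sub) &&
      dplyr::n_distinct(sub$order) >= 2L) {
    if (plan$random_slopes == "on") {
      slopes_by <- "order"
    } else {
      slope_check <- run_random_slope_check(sub, tree, "z_measure", plan,
                                            seed = seeds[1L])
      if (slope_check$decision == "slopes") slopes_by <- "order"
    }
  } else if (plan$random_slopes == "auto") {
    slope_check <- list(decision = "fixed",
                        reason = "fewer than 2 orders present")
  }

  fit_un <- plan_fit(sub, tree, yawn_model("z_measure", slopes_by = slopes_by),
                     plan, seed = seeds[2L])
  branch <- "none"
  vifs <- NULL
  fit_adj <- NULL
  if (plan$adjust_body) {
    vifs <- vif(cbind(z_measure = sub$z_measure, z_body = sub$z_body))
    if (max(vifs) > plan$vif_threshold) {
      branch <- "residual"
      pg <- pgls_fit(sub[[log_col]],
                     cbind("(Intercept)" = 1, log_body = sub$log_body),
                     tree, lambda = "ml")
      sub$z_resid_measure <- as.numeric(standardize(pg$residuals))
      fit_adj <- plan_fit(sub, tree,
                          yawn_model("z_resid_measure", slopes_by = slopes_by),
                          plan, seed = seeds[3L])
    } else {
      branch <- "covariate"
      fit_adj <- plan_fit(sub, tree,
                          yawn_model(c("z_measure", "z_body"),
                                     slopes_by = slopes_by),
                          plan, seed = seeds[3L])
    }
    message(measure, ": max VIF = ", format(max(vifs), digits = 4),
            " -> ", branch, " branch")
  }
  structure(list(measure = measure, n_species = nrow(sub),
                 branch = branch, vifs = vifs, slope_check = slope_check,
                 fits = list(unadjusted = fit_un, adjusted = fit_adj),
                 data = sub, tree = tree),
            class = "yawn_measure_result")
}

#' @export
print.yawn_measure_result <- function(x, ...) {
  cat("Measure:", x$measure, "(", x$n_species, "species ), adjustment branch:",
      x$branch, "\n")
  print(tidy.yawn_measure_result(x))
  invisible(x)
}

#' Tidy a per-measure result
#' @param x A `yawn_measure_result`.
#' @param ... Unused.
#' @return Tibble of posterior summaries labeled by model
#'   (unadjusted/adjusted).
#' @exportS3Method generics::tidy
tidy.yawn_measure_result <- function(x, ...) {
  out <- dplyr::bind_rows(
    mutate(tidy.yawn_fit(x$fits$unadjusted), model = "unadjusted"),
    if (!is.null(x$fits$adjusted)) {
      mutate(tidy.yawn_fit(x$fits$adjusted), model = "adjusted")
    }
  )
  mutate(out, measure = x$measure, branch = x$branch)
}

#' WAIC check of per-order random slopes
#'
#' Fits the fixed-slope and order-random-slope variants of the model for
#' `predictor` and compares them by paired pointwise WAIC. The slopes
#' model is adopted only if it beats the fixed model by at least 2 WAIC
#' units.
#'
#' @param data Matched species-level tibble with an `order` column.
#' @param tree Matched phylogeny.
#' @param predictor Predictor column name.
#' @param plan A [analysis_plan()].
#' @param seed Seed for both fits.
#' @return List with `delta`, `se`, `decision`, and the two WAIC values.
#' @export
run_random_slope_check <- function(data, tree, predictor, plan, seed = 1L) {
  if (dplyr::n_distinct(data$order) < 2L) {
    return(list(decision = "fixed", delta = NA_real_, se = NA_real_,
                reason = "single order"))
  }
  f_fixed <- plan_fit(data, tree, yawn_model(predictor), plan, seed)
  f_slopes <- plan_fit(data, tree, yawn_model(predictor, slopes_by = "order"),
                       plan, seed)
  cw <- suppressMessages(compare_waic(f_fixed, f_slopes))
  list(decision = cw$decision, delta = cw$delta, se = cw$se,
       waic_fixed = cw$waic_simple$waic, waic_slopes = cw$waic_slopes$waic)
}

#' Contrast posterior distributions across clades
#'
#' Forms paired difference draws (first minus second) for every shared
#' reported parameter of two independently fitted models, thinning both
#' draw sequences to a common length, and summarizes each difference
#' (median, MAD, 90% CI, p+).
#'
#' @param fit_a,fit_b `yawn_fit`s for the two clades, fitted with the
#'   same measure and standardization convention.
#' @param min_draws Minimum paired draws required (default 1000).
#' @return Tibble of `delta_*` rows; difference draws are attached as
#'   `attr(, "draws")`.
#' @export
contrast_clades <- function(fit_a, fit_b, min_draws = 1000L) {
  terms_a <- core_parameters(fit_a$spec, 1L, "")
  terms_b <- core_parameters(fit_b$spec, 1L, "")
  shared <- intersect(terms_a, terms_b)
  S <- min(nrow(fit_a$draws), nrow(fit_b$draws))
  if (S < min_draws) {
    stop_domain(paste0("only ", S, " paired draws; need >= ", min_draws))
  }
  ia <- round(seq(1L, nrow(fit_a$draws), length.out = S))
  ib <- round(seq(1L, nrow(fit_b$draws), length.out = S))
  dd <- lapply(shared, function(p) fit_a$draws[[p]][ia] - fit_b$draws[[p]][ib])
  names(dd) <- paste0("delta_", shared)
  out <- purrr::map_dfr(names(dd), function(p) summarize_draws(dd[[p]], p))
  attr(out, "draws") <- as_tibble(dd)
  out
}

#' Posterior expected yawn duration at a reference predictor value
#'
#' Marginalizes over the Gaussian species-level random intercepts in
#' closed form: per draw, `E[duration] = exp(beta0 + sum(beta * z_ref) +
#' (sigma_phylo^2 + sigma_species^2) / 2)` (lognormal mean), then
#' summarizes the draws.
#'
#' @param fit A `yawn_fit`.
#' @param z_ref Reference value(s) of the standardized predictor(s);
#'   scalar or named by predictor. Should lie within +-3 SD of the
#'   training range.
#' @param group For group-intercept (joint) fits, the group level to
#'   predict for.
#' @param return_draws Attach the per-draw durations as an attribute.
#' @return One-row tibble: median, MAD and 90% CI of the expected
#'   duration in seconds.
#' @export
predict_duration <- function(fit, z_ref = 0, group = NULL,
                             return_draws = FALSE) {
  preds <- fit$spec$predictors
  if (length(z_ref) == 1L && is.null(names(z_ref))) {
    z_ref <- setNames(rep(z_ref, length(preds)), preds)
  }
  if (any(abs(z_ref) > 3)) {
    warn("z_ref outside +-3 SD of the training range; extrapolating")
  }
  d <- fit$draws
  suffix <- if (is.null(group)) "" else paste0("_", group)
  beta0 <- d[[paste0("beta0", suffix)]]
  sp <- d[[paste0("sigma_phylo", suffix)]]
  ss <- d[[paste0("sigma_species", suffix)]]
  lin <- beta0
  for (p in preds) lin <- lin + d[[paste0("beta_", p)]] * z_ref[[p]]
  dur <- exp(lin + (sp^2 + ss^2) / 2)
  out <- summarize_draws(dur, paste0("predicted_duration", suffix))
  if (return_draws) attr(out, "draws") <- dur
  out
}

#' Constrained cross-clade model with matched-size predictions
#'
#' Fits both clades jointly with slopes constrained to equivalence:
#' clade-specific intercepts, random-effect SDs and Gamma shapes, a
#' shared slope for each predictor standardized on the pooled two-clade
#' scale, and a block-diagonal phylogenetic correlation (one block per
#' clade tree). Predicts the expected yawn duration for each clade at
#' the second clade's sample-mean predictor values (so "a mammal the
#' size of the average bird"), marginalizing over random intercepts.
#'
#' @param data_a,data_b Species-level tibbles for the two clades.
#' @param tree_a,tree_b Their phylogenies.
#' @param measure Brain measure to fit.
#' @param include_body Also include pooled-standardized log body mass as
#'   a shared-slope covariate.
#' @param plan A [analysis_plan()].
#' @return List with the joint `fit`, `contrast` (`delta_beta0_*` rows,
#'   clade a minus clade b), `predictions` (per clade at the reference),
#'   `prediction_gap` (posterior summary of the log-duration gap at the
#'   reference), and `z_ref`.
#' @export
constrained_joint_fit <- function(data_a, data_b, tree_a, tree_b,
                                  measure = "brain_mass",
                                  include_body = FALSE,
                                  plan = analysis_plan()) {
  if (is.null(tree_a) || is.null(tree_b)) stop_domain("both clade trees required")
  log_col <- measure_log_col(measure)
  prep <- function(data, tree) {
    keep <- is.finite(data[[log_col]]) & is.finite(data$log_body)
    match_tree(data[keep, , drop = FALSE], tree)
  }
  ma <- prep(data_a, tree_a)
  mb <- prep(data_b, tree_b)
  combined <- bind_rows(ma$data, mb$data)
  pooled_z <- standardize(combined[[log_col]])
  combined$z_measure <- as.numeric(pooled_z)
  preds <- "z_measure"
  if (include_body) {
    pooled_zb <- standardize(combined$log_body)
    combined$z_body <- as.numeric(pooled_zb)
    preds <- c(preds, "z_body")
  }
  na <- nrow(ma$data)
  Ca <- unit_correlation(ma$tree)
  Cb <- unit_correlation(mb$tree)
  C <- matrix(0, nrow(combined), nrow(combined))
  C[seq_len(na), seq_len(na)] <- Ca
  C[(na + 1L):nrow(C), (na + 1L):nrow(C)] <- Cb
  spec <- yawn_model(preds, intercept_by = "clade")
  fit <- plan_fit(combined, NULL, spec, plan,
                  seed = derive_seeds(plan$seed, 1L), C_corr = C)

  lev <- fit$group_levels
  lev_a <- as.character(combined$clade[1L])
  lev_b <- setdiff(lev, lev_a)
  # reference: clade b's sample mean, on the pooled z scale
  z_ref <- c(z_measure = (mean(mb$data[[log_col]]) - attr(pooled_z, "center")) /
               attr(pooled_z, "scale"))
  if (include_body) {
    z_ref["z_body"] <- (mean(mb$data$log_body) - attr(pooled_zb, "center")) /
      attr(pooled_zb, "scale")
  }
  pred_a <- predict_duration(fit, z_ref, group = lev_a, return_draws = TRUE)
  pred_b <- predict_duration(fit, z_ref, group = lev_b, return_draws = TRUE)
  gap <- log(attr(pred_a, "draws")) - log(attr(pred_b, "draws"))
  contrast <- summarize_draws(
    fit$draws[[paste0("beta0_", lev_a)]] - fit$draws[[paste0("beta0_", lev_b)]],
    "delta_beta0")
  preds_tbl <- bind_rows(mutate(pred_a, clade = lev_a),
                         mutate(pred_b, clade = lev_b))
  list(fit = fit, contrast = contrast, predictions = preds_tbl,
       prediction_gap = summarize_draws(gap, "log_duration_gap"),
       z_ref = z_ref)
}

#' Simulation-based power analysis
#'
#' Simulates `reps` datasets from the template fit's posterior-median
#' nuisance parameters (intercept, random-effect SDs, Gamma shape) with
#' the slope forced to `beta_true` on the given tree, refits each, and
#' reports the fraction of replicates whose 90% credible interval
#' excludes zero. Replicates failing the (relaxed) convergence gate are
#' re-run with a fresh seed up to 3 times, then counted as missing.
#'
#' @param template_fit A single-clade `yawn_fit` providing nuisance
#'   parameters and the predictor values.
#' @param beta_true True slope used in simulation.
#' @param tree The phylogeny to simulate on (tips matching the template
#'   fit's species).
#' @param reps Number of replicates (>= 20).
#' @param seed Master seed.
#' @param chains,iterations,warmup MCMC settings per replicate.
#' @param rhat_max,ess_min Convergence gate per replicate.
#' @return One-row tibble: `power`, binomial `se`, `detected`,
#'   `reps_effective`, `reps_missing`, `beta_true`, `n_species`.
#' @export
power_analysis <- function(template_fit, beta_true, tree, reps = 50L,
                           seed = 1L, chains = 2L, iterations = 1500L,
                           warmup = 750L, rhat_max = 1.1, ess_min = 40) {
  if (reps < 20L) stop_domain("reps must be >= 20")
  pred <- template_fit$spec$predictors[1L]
  z <- template_fit$data[[pred]]
  n <- length(z)
  med <- function(p) median(template_fit$draws[[p]])
  beta0 <- med("beta0"); sp <- med("sigma_phylo")
  ss <- med("sigma_species"); alpha <- med("alpha")
  C <- lambda_transform(unit_correlation(tree), 1)
  Lc <- psd_factor(C)
  seeds <- derive_seeds(seed, reps * 4L)
  detected <- logical(reps)
  missing <- logical(reps)
  for (r in seq_len(reps)) {
    ok <- FALSE
    for (attempt in 1:3) {
      s <- seeds[(r - 1L) * 4L + attempt]
      set.seed(s)
      b <- sp * drop(Lc %*% rnorm(n))
      u <- rnorm(n, 0, ss)
      mu <- exp(beta0 + beta_true * z + b + u)
      ysim <- rgamma_mean(n, mu, alpha)
      dat <- tibble(species = template_fit$data$species,
                    mean_duration = ysim)
      dat[[pred]] <- z
      fit_r <- tryCatch(
        fit_model(dat, tree, yawn_model(pred), chains = chains,
                  iterations = iterations, warmup = warmup, seed = s,
                  check_convergence = "error",
                  rhat_max = rhat_max, ess_min = ess_min),
        phyloyawn_convergence_error = function(e) NULL)
      if (!is.null(fit_r)) {
        ci <- quantile(fit_r$draws[[paste0("beta_", pred)]], c(0.05, 0.95))
        detected[r] <- ci[1L] > 0 || ci[2L] < 0
        ok <- TRUE
        break
      }
    }
    if (!ok) missing[r] <- TRUE
  }
  eff <- sum(!missing)
  p <- sum(detected[!missing]) / eff
  tibble(power = p, se = sqrt(p * (1 - p) / eff),
         detected = sum(detected[!missing]),
         reps_effective = eff, reps_missing = sum(missing),
         beta_true = beta_true, n_species = n)
}

#' Residual-on-residual PGLS sensitivity analysis
#'
#' Gaussian counterpart of the body-size-adjusted models: body-size
#' effects are first partialled out of both log yawn duration and the
#' log brain measure by ML-lambda PGLS, and the two residual series are
#' then related by a further PGLS. Log duration is used so the Gaussian
#' assumption is tenable.
#'
#' @param data Species-level tibble for one clade.
#' @param tree The clade phylogeny.
#' @param measure Brain measure name.
#' @return Tibble with the residual-association slope: estimate,
#'   std.error, t statistic, two-sided p-value, and the lambda of the
#'   final fit.
#' @export
residual_on_residual_pgls <- function(data, tree, measure = "brain_mass") {
  log_col <- measure_log_col(measure)
  keep <- is.finite(data[[log_col]]) & is.finite(data$log_body) &
    is.finite(data$mean_duration)
  m <- match_tree(data[keep, , drop = FALSE], tree)
  Xb <- cbind("(Intercept)" = 1, log_body = m$data$log_body)
  ry <- pgls_fit(log(m$data$mean_duration), Xb, m$tree, "ml")$residuals
  rx <- pgls_fit(m$data[[log_col]], Xb, m$tree, "ml")$residuals
  fit <- pgls_fit(ry, cbind("(Intercept)" = 1, resid_measure = rx),
                  m$tree, "ml")
  out <- tidy.pgls_fit(fit)
  out <- out[out$term == "resid_measure", , drop = FALSE]
  out$term <- paste0("residual_", measure)
  out$lambda <- fit$lambda_used
  out$n_species <- fit$n
  out
}

#' Run the full two-clade analysis
#'
#' Orchestrates the pipeline end-to-end: aggregation and filtering, tree
#' matching per clade, per-measure fits with the VIF-gated body-size
#' adjustment and random-slope WAIC checks, cross-clade posterior
#' contrasts of the unadjusted fits, and the constrained joint model
#' with matched-size predictions.
#'
#' @param events,traits Tibbles from the readers (or the simulator).
#' @param trees Named list of `phylo` trees, one per clade.
#' @param exclude Species to drop explicitly.
#' @param plan A [analysis_plan()].
#' @return A list of class `yawn_analysis`: `table` (aggregated
#'   species table), `clades` (per clade: list of `yawn_measure_result`
#'   per measure), `contrasts` (per shared measure), `joint`.
#' @export
run_analysis <- function(events, traits, trees, exclude = character(),
                         plan = analysis_plan()) {
  agg <- aggregate_species(events, traits, exclude = exclude)
  clades <- intersect(unique(agg$clade), names(trees))
  if (length(clades) == 0L) stop_domain("no clade in the data has a tree")
  results <- lapply(clades, function(cl) {
    sub <- agg[agg$clade == cl, , drop = FALSE]
    res <- lapply(plan$measures, function(msr)
      run_measure(sub, trees[[cl]], msr, plan))
    names(res) <- plan$measures
    res
  })
  names(results) <- clades
  contrasts <- NULL
  joint <- NULL
  if (length(clades) >= 2L) {
    a <- clades[1L]; b <- clades[2L]
    contrasts <- lapply(plan$measures, function(msr) {
      fa <- results[[a]][[msr]]; fb <- results[[b]][[msr]]
      if (is.null(fa) || is.null(fb)) return(NULL)
      contrast_clades(fa$fits$unadjusted, fb$fits$unadjusted)
    })
    names(contrasts) <- plan$measures
    if ("brain_mass" %in% plan$measures) {
      joint <- constrained_joint_fit(
        agg[agg$clade == a, ], agg[agg$clade == b, ],
        trees[[a]], trees[[b]], measure = "brain_mass", plan = plan)
    }
  }
  structure(list(table = agg, clades = results, contrasts = contrasts,
                 joint = joint, plan = plan),
            class = "yawn_analysis")
}
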