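# Posterior summary of a single vector of draws: median, MAD,
# equal-tailed 90% interval, and p+ = Pr(draw > 0) (strict inequality).
summarize_draws <- function(x, term = "value") {
  tibble(term = term,
         median = median(x),
         mad = mad(x),
         ci_lower = unname(quantile(x, 0.05)),
         ci_upper = unname(quantile(x, 0.95)),
         p_plus = mean(x > 0))
}

effect_label <- function(d) {
  ifelse(is.na(d), NA_character_,
         ifelse(abs(d) >= 0.8, "large",
                ifelse(abs(d) >= 0.5, "medium",
                       ifelse(abs(d) >= 0.2, "small", "negligible"))))
}

#' Summarize a fitted model's posterior
#'
#' For every reported parameter: posterior median, median absolute
#' deviation (MAD), equal-tailed 90% credible interval, the posterior
#' probability of a positive value (`p_plus`), and convergence
#' diagnostics. Slope terms additionally get a Cohen's d standardized
#' effect size, computed per draw as `beta / sqrt(sigma_phylo^2 +
#' sigma_species^2)` (link-scale standardization by the total
#' species-level SD) and then summarized; `|d|` >= 0.2 / 0.5 / 0.8 are
#' labeled small / medium / large.
#'
#' @param x A `yawn_fit`.
#' @param ... Unused.
#' @return A tibble with one row per reported parameter.
#' @exportS3Method generics::tidy
tidy.yawn_fit <- function(x, ...) {
  glev <- x$group_levels
  G <- if (identical(glev, "")) 1L else length(glev)
  core <- core_parameters(x$spec, G, glev)
  out <- purrr::map_dfr(core, function(p) summarize_draws(x$draws[[p]], p))
  out$d <- NA_real_
  out$d_mad <- NA_real_
  if (G == 1L) {
    denom <- sqrt(x$draws$sigma_phylo^2 + x$draws$sigma_species^2)
    for (p in paste0("beta_", x$spec$predictors)) {
      d_draws <- x$draws[[p]] / denom
      out$d[out$term == p] <- median(d_draws)
      out$d_mad[out$term == p] <- mad(d_draws)
    }
  }
  out$effect_size <- effect_label(out$d)
  dplyr::left_join(out, x$diagnostics, by = "term")
}

#' One-row model-level summary
#'
#' @param x A `yawn_fit`.
#' @param ... Unused.
#' @return Tibble with species count, draw count, WAIC, effective number
#'   of parameters, and worst-case convergence diagnostics.
#' @exportS3Method generics::glance
glance.yawn_fit <- function(x, ...) {
  w <- waic(x)
  tibble(n_species = length(x$species),
         n_draws = nrow(x$draws),
         chains = x$chains,
         waic = w$waic,
         p_waic = w$p_waic,
         max_rhat = max(x$diagnostics$rhat),
         min_ess = min(x$diagnostics$ess),
         runtime_s = x$runtime)
}
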