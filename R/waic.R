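#' Watanabe-Akaike information criterion
#'
#' WAIC from a pointwise posterior log-likelihood matrix:
#' `lppd_i = log mean_d exp(ll_di)` (computed stably),
#' `p_i = var_d(ll_di)`, `WAIC = -2 sum(lppd_i - p_i)`, with standard
#' error `sqrt(n * var_i(-2 (lppd_i - p_i)))`.
#'
#' @param pointwise_loglik Draws-by-species matrix of log-likelihoods
#'   (>= 100 draws, >= 4 species), or a `yawn_fit`.
#' @return List with `waic`, `se`, `p_waic` and the `pointwise` tibble.
#' @export
waic <- function(pointwise_loglik) {
  if (inherits(pointwise_loglik, "yawn_fit")) {
    pointwise_loglik <- pointwise_loglik$pointwise_loglik
  }
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 100L) stop_domain("need at least 100 draws")
  if (ncol(ll) < 4L) stop_domain("need at least 4 species")
  if (any(!is.finite(ll))) stop_domain("non-finite log-likelihoods")
  lppd <- apply(ll, 2L, logmeanexp)
  p <- apply(ll, 2L, var)
  elpd_i <- lppd - p
  n <- ncol(ll)
  list(
    waic = -2 * sum(elpd_i),
    se = sqrt(n * var(-2 * elpd_i)),
    p_waic = sum(p),
    pointwise = tibble(species = colnames(ll) %||% as.character(seq_len(n)),
                       lppd = lppd, p_waic = p, elpd = elpd_i)
  )
}

#' Compare two models by paired pointwise WAIC
#'
#' `delta = WAIC(simple) - WAIC(slopes)`, so positive values favor the
#' more complex (random slopes) model; the SE uses the paired
#' per-species contributions. The decision rule adopts the slopes model
#' only when `delta >= 2`, the conventional minimal-evidence threshold.
#'
#' @param fit_simple,fit_slopes `yawn_fit` objects (or `waic()` inputs)
#'   fitted to identical data rows.
#' @return List with `delta`, `se`, `decision` (`"slopes"` or
#'   `"fixed"`), and both `waic` objects.
#' @export
compare_waic <- function(fit_simple, fit_slopes) {
  w1 <- waic(fit_simple)
  w2 <- waic(fit_slopes)
  if (!identical(w1$pointwise$species, w2$pointwise$species)) {
    stop_domain("models were fitted to different species sets")
  }
  d_i <- -2 * w1$pointwise$elpd - (-2 * w2$pointwise$elpd)
  delta <- sum(d_i)
  se <- sqrt(length(d_i) * var(d_i))
  decision <- if (delta >= 2) "slopes" else "fixed"
  message(sprintf("dWAIC = %.2f [%.2f]; decision: %s model",
                  delta, se, decision))
  list(delta = delta, se = se, decision = decision,
       waic_simple = w1, waic_slopes = w2)
}
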