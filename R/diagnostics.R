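# Rank-normalized split-chain convergence diagnostics.
# x: numeric vector of draws; chain: integer chain label per draw.
# Chains are split in half before computing between/within variances, so
# within-chain trends register as apparent non-convergence.

rank_normalize <- function(x) {
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

split_chains <- function(x, chain) {
  pieces <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  n <- min(lengths(pieces))
  vapply(pieces, function(v) v[seq_len(n)], numeric(n))
}

#' Split R-hat of a parameter
#'
#' Rank-normalized split-chain potential scale reduction factor. Values
#' near 1 indicate between-chain agreement; the sampling gate requires
#' < 1.01 by default.
#'
#' @param x Numeric vector of posterior draws.
#' @param chain Integer chain label for each draw (>= 2 chains).
#' @return A scalar R-hat.
#' @export
rhat <- function(x, chain) {
  m <- split_chains(rank_normalize(x), chain)
  n <- nrow(m)
  if (sd(x) == 0) return(1)
  W <- mean(apply(m, 2L, var))
  B <- n * var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size
#'
#' Rank-normalized split-chain effective sample size using Geyer's
#' initial monotone positive sequence estimator of the autocorrelation
#' time.
#'
#' @inheritParams rhat
#' @return A scalar ESS estimate.
#' @export
ess_bulk <- function(x, chain) {
  if (sd(x) == 0) return(length(x))
  m <- split_chains(rank_normalize(x), chain)
  n <- nrow(m)
  k <- ncol(m)
  max_lag <- min(n - 1L, 1000L)
  acov <- apply(m, 2L, function(v) {
    drop(acf(v, lag.max = max_lag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf) * (n - 1) / n
  })
  W <- mean(acov[1L, ] * n / (n - 1))
  var_plus <- (n - 1) / n * W + n * var(colMeans(m)) / n
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotonicity
  tau <- rho[1L]
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
    t <- t + 2L
  }
  max(k * n / max(tau, 1e-12), 1)
}

# Diagnostics table for the reported (scalar) parameters of a draws tibble.
diagnostics_table <- function(draws, pars) {
  tibble(
    term = pars,
    rhat = vapply(pars, function(p) rhat(draws[[p]], draws$.chain), numeric(1)),
    ess = vapply(pars, function(p) ess_bulk(draws[[p]], draws$.chain),
                 numeric(1))
  )
}
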